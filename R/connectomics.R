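#' Osteocyte network graph
#'
#' An `lcn_graph` holds the node/edge view of a segmented field:
#' `nodes` (one osteocyte component per row: id, centroid `x`/`y` in pixels,
#' `area_px`), `edges` (dendrite components linking two nodes, with length
#' and mean thickness in micrometres), `dead_ends` (dendrite components
#' touching exactly one node), `isolated` (components touching none) and a
#' per-dendrite-component `components` table. Constructed by [build_graph()]
#' / [label_to_graph()] or planted by [generate_scene()].
#'
#' @param nodes,edges,dead_ends,isolated,components data frames as above.
#' @param um_per_px pixel calibration in micrometres.
#' @return an object of class `lcn_graph`.
#' @export
new_lcn_graph <- function(nodes, edges, dead_ends, isolated, components,
                          um_per_px) {
  structure(list(nodes = nodes, edges = edges, dead_ends = dead_ends,
                 isolated = isolated, components = components,
                 um_per_px = um_per_px),
            class = "lcn_graph")
}

#' @export
print.lcn_graph <- function(x, ...) {
  cat(sprintf("<lcn_graph> %d nodes, %d edges, %d dead ends, %d isolated components\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$dead_ends), nrow(x$isolated)))
  invisible(x)
}

#' Split a three-class label into binary class masks
#'
#' @param label integer matrix with values 0 (background), 1 (osteocyte),
#'   2 (dendrite).
#' @return list with logical matrices `osteo` and `dend`.
#' @export
prepare_masks <- function(label) {
  stopifnot(is.matrix(label), all(label %in% c(0L, 1L, 2L)))
  list(osteo = label == 1L, dend = label == 2L)
}

#' Dilate class masks before component merging
#'
#' Applies the component-merging dilation used ahead of graph extraction:
#' a 4x4 ellipse on the osteocyte mask and a 2x2 cross on the dendrite mask
#' (footprints in [se_ellipse4()] / [se_cross2()]). This fuses nearby
#' fragments that represent a single biological structure and guarantees
#' pixel overlap between dendrites and the somas they touch.
#'
#' @param osteo,dend logical matrices of equal shape.
#' @return list with dilated `osteo` and `dend` masks (supersets of inputs).
#' @export
dilate_for_merging <- function(osteo, dend) {
  stopifnot(is.matrix(osteo), is.matrix(dend), all(dim(osteo) == dim(dend)))
  list(osteo = dilate_mask(osteo, se_ellipse4()),
       dend = dilate_mask(dend, se_cross2()))
}

#' Connected-component labelling
#'
#' Labels maximal connected foreground sets 1..n. Labelling is deterministic:
#' components are numbered by the raster-order (row-major) position of their
#' first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background) with attribute `n`,
#'   the number of components.
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg) == 0L) { attr(lab, "n") <- 0L; return(lab) }
  vid <- integer(H * W)
  vid[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ed <- list()
  for (o in offs) {
    nb <- shift_mat(mask, o[1L], o[2L], FALSE)
    both <- which(mask & nb)
    if (length(both) > 0L) {
      nb_idx <- both + o[1L] + o[2L] * H
      ed[[length(ed) + 1L]] <- cbind(vid[both], vid[nb_idx])
    }
  }
  memb <- if (length(ed) > 0L) {
    g <- igraph::graph_from_edgelist(do.call(rbind, ed), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    igraph::components(g)$membership
  } else {
    seq_along(fg)
  }
  # renumber by raster order (row-major) of each component's first pixel
  row <- ((fg - 1L) %% H) + 1L
  col <- ((fg - 1L) %/% H) + 1L
  raster <- (row - 1L) * W + col
  first <- tapply(raster, memb, min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  lab[fg] <- remap[memb]
  attr(lab, "n") <- length(first)
  lab
}

#' Topology-preserving thinning (skeletonisation)
#'
#' Zhang-Suen thinning to a 1-px-wide, 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      s <- function(dr, dc) shift_mat(m, dr, dc, FALSE)
      p2 <- s(-1L, 0L); p3 <- s(-1L, 1L); p4 <- s(0L, 1L); p5 <- s(1L, 1L)
      p6 <- s(1L, 0L);  p7 <- s(1L, -1L); p8 <- s(0L, -1L); p9 <- s(-1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- m & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Weighted pixel-adjacency graph of a skeleton: unit steps for 4-neighbours,
# sqrt(2) for diagonals. Returns NULL for an empty skeleton.
skeleton_graph <- function(skel) {
  fg <- which(skel)
  if (length(fg) == 0L) return(NULL)
  H <- nrow(skel)
  vid <- integer(length(skel)); vid[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  ed <- list(); wt <- list()
  for (o in offs) {
    nb <- shift_mat(skel, o[1L], o[2L], FALSE)
    both <- which(skel & nb)
    if (length(both) > 0L) {
      nb_idx <- both + o[1L] + o[2L] * H
      ed[[length(ed) + 1L]] <- cbind(vid[both], vid[nb_idx])
      wt[[length(wt) + 1L]] <- rep(o[3L], length(both))
    }
  }
  g <- if (length(ed) > 0L)
    igraph::graph_from_edgelist(do.call(rbind, ed), directed = FALSE)
  else igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  if (length(wt) > 0L) igraph::E(g)$weight <- unlist(wt)
  list(g = g, pixels = fg,
       row = ((fg - 1L) %% H) + 1L, col = ((fg - 1L) %/% H) + 1L)
}

# Skeleton path length in pixels: pixel count along the geodesic spine,
# with sqrt(2)-weighted diagonal steps (a straight 10-px line measures 10).
# Disconnected skeletons contribute the sum of their parts.
skeleton_length_px <- function(skel, sg = skeleton_graph(skel)) {
  if (is.null(sg)) return(0)
  if (length(sg$pixels) == 1L) return(0)
  g <- sg$g
  memb <- igraph::components(g)$membership
  total <- 0
  for (cmp in unique(memb)) {
    vs <- which(memb == cmp)
    if (length(vs) == 1L) { total <- total + 1; next }
    sub <- igraph::induced_subgraph(g, vs)
    # weighted double-sweep: farthest vertex from an arbitrary start, then
    # the geodesic from there (exact on trees, which thinned curves are)
    d1 <- igraph::distances(sub, v = 1)
    u <- which.max(d1)
    d2 <- igraph::distances(sub, v = u)
    total <- total + max(d2[is.finite(d2)]) + 1
  }
  total
}

# Geodesic length (px) along a component's skeleton between two somas:
# the shortest path between the skeleton's contact sets with each soma
# (falling back to the pixels nearest the soma centroids when the skeleton
# does not reach a soma footprint). NA when the parts are disconnected.
skeleton_pair_length_px <- function(sg, va, vb, ax, ay, bx, by) {
  if (is.null(sg) || length(sg$pixels) == 0L) return(NA_real_)
  if (length(sg$pixels) == 1L) return(1)
  if (length(va) == 0L) va <- which.min((sg$col - ax)^2 + (sg$row - ay)^2)
  if (length(vb) == 0L) vb <- which.min((sg$col - bx)^2 + (sg$row - by)^2)
  d <- min(igraph::distances(sg$g, v = va, to = vb))
  if (!is.finite(d)) return(NA_real_)
  d + 1
}

#' Length of a dendrite component
#'
#' Thins the component to a 1-px skeleton and measures the geodesic spine
#' with sqrt(2) weighting for diagonal steps, scaled by the pixel size.
#'
#' @param mask logical matrix containing the single component.
#' @param um_per_px pixel calibration in micrometres.
#' @return length in micrometres.
#' @export
connection_length <- function(mask, um_per_px = 1) {
  stopifnot(is.matrix(mask), um_per_px > 0)
  if (!any(mask)) stop("empty component")
  skeleton_length_px(skeletonize(mask)) * um_per_px
}

#' Mean thickness of a dendrite component
#'
#' Estimated as component area divided by skeleton length (an area-stable
#' estimator at the 1-3 px widths of canalicular processes), scaled by the
#' pixel size. A component whose skeleton degenerates to a point is assigned
#' one pixel of thickness.
#'
#' @param mask logical matrix containing the single component.
#' @param um_per_px pixel calibration in micrometres.
#' @param length_px optional precomputed skeleton length in pixels.
#' @return thickness in micrometres.
#' @export
connection_thickness <- function(mask, um_per_px = 1, length_px = NULL) {
  stopifnot(is.matrix(mask), um_per_px > 0)
  if (!any(mask)) stop("empty component")
  if (is.null(length_px)) length_px <- skeleton_length_px(skeletonize(mask))
  if (length_px <= 0) return(um_per_px)
  sum(mask) / length_px * um_per_px
}

#' Build an osteocyte graph from labelled component maps
#'
#' For every dendrite component the set of overlapped osteocyte components
#' determines its role: 0 overlaps = isolated, 1 = dead end, 2 = edge, and 3
#' or more contributes one edge per overlapped pair (clique rule; such
#' components are visible through `n_overlap` in the components table).
#' Overlap is pixel coincidence on the (dilated) component maps; geometry
#' (area, centroid, length, thickness) is measured on the original masks
#' when provided.
#'
#' Connection lengths are measured per edge as the geodesic along the
#' component's skeleton between the two somas it joins, so a component
#' serving several node pairs contributes each pair's own span.
#'
#' @param osteo_cc,dend_cc integer component maps (from
#'   [connected_components()] on the dilated masks) of equal shape.
#' @param osteo_orig,dend_orig optional original (undilated) binary masks on
#'   which geometry is measured; default to the component maps' foreground.
#' @param um_per_px pixel calibration in micrometres.
#' @param min_component_px dendrite components with fewer original pixels
#'   are treated as segmentation debris (below the footprint of a minimal
#'   resolvable process) and dropped before role assignment.
#' @return an `lcn_graph`.
#' @export
build_graph <- function(osteo_cc, dend_cc, osteo_orig = NULL, dend_orig = NULL,
                        um_per_px = 1, min_component_px = 5L) {
  stopifnot(is.matrix(osteo_cc), is.matrix(dend_cc),
            all(dim(osteo_cc) == dim(dend_cc)))
  H <- nrow(osteo_cc)
  if (is.null(osteo_orig)) osteo_orig <- osteo_cc > 0L
  if (is.null(dend_orig)) dend_orig <- dend_cc > 0L

  n_nodes <- max(0L, max(osteo_cc))
  nodes <- if (n_nodes > 0L) {
    idx <- which(osteo_cc > 0L & osteo_orig)
    # fall back to dilated pixels for components erased in the original mask
    lab <- osteo_cc[idx]
    row <- ((idx - 1L) %% H) + 1L
    col <- ((idx - 1L) %/% H) + 1L
    x <- tapply(col, lab, mean)
    y <- tapply(row, lab, mean)
    area <- tapply(row, lab, length)
    ids <- as.integer(names(x))
    full <- data.frame(id = seq_len(n_nodes), x = NA_real_, y = NA_real_,
                       area_px = 0L)
    full$x[ids] <- as.numeric(x); full$y[ids] <- as.numeric(y)
    full$area_px[ids] <- as.integer(area)
    full
  } else {
    data.frame(id = integer(0), x = numeric(0), y = numeric(0), area_px = integer(0))
  }

  n_dend <- max(0L, max(dend_cc))
  comp_rows <- vector("list", n_dend)
  edge_rows <- list(); de_rows <- list(); iso_rows <- list()
  for (d in seq_len(n_dend)) {
    in_comp <- dend_cc == d
    geom <- in_comp & dend_orig
    if (!any(geom)) geom <- in_comp
    if (sum(geom) < min_component_px) next
    overlapped <- sort(unique(osteo_cc[in_comp & osteo_cc > 0L]))
    sg <- skeleton_graph(skeletonize(geom))
    skel_len <- skeleton_length_px(NULL, sg = sg)
    len_um <- skel_len * um_per_px
    thick_um <- connection_thickness(geom, um_per_px, length_px = skel_len)
    comp_rows[[d]] <- data.frame(
      component = d, area_px = sum(geom), length_px = skel_len,
      length_um = len_um, thickness_um = thick_um,
      n_overlap = length(overlapped),
      role = c("isolated", "dead_end", "edge")[min(length(overlapped), 2L) + 1L],
      stringsAsFactors = FALSE)
    if (length(overlapped) == 0L) {
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(component = d)
    } else if (length(overlapped) == 1L) {
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        node = overlapped, component = d, length_um = len_um)
    } else {
      pr <- utils::combn(overlapped, 2L)
      contact <- if (!is.null(sg)) osteo_cc[sg$pixels] else integer(0)
      for (q in seq_len(ncol(pr))) {
        a <- pr[1L, q]; b <- pr[2L, q]
        span <- skeleton_pair_length_px(sg, which(contact == a), which(contact == b),
                                        nodes$x[a], nodes$y[a],
                                        nodes$x[b], nodes$y[b])
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          node_a = a, node_b = b, component = d,
          length_um = (if (is.finite(span)) span else skel_len) * um_per_px,
          thickness_um = thick_um)
      }
    }
  }

  new_lcn_graph(
    nodes = nodes,
    edges = rbind_or_empty(edge_rows, c("node_a", "node_b", "component", "length_um", "thickness_um")),
    dead_ends = rbind_or_empty(de_rows, c("node", "component", "length_um")),
    isolated = rbind_or_empty(iso_rows, "component"),
    components = rbind_or_empty(comp_rows, c("component", "area_px", "length_px",
                                             "length_um", "thickness_um", "n_overlap", "role")),
    um_per_px = um_per_px)
}

#' Extract the osteocyte graph from a three-class label mask
#'
#' Convenience composition: [prepare_masks()] -> [dilate_for_merging()] ->
#' [connected_components()] (8-connectivity) -> [build_graph()], with
#' geometry measured on the original class masks.
#'
#' @param label integer label matrix (0/1/2).
#' @param um_per_px pixel calibration in micrometres.
#' @param connectivity pixel connectivity for component labelling.
#' @param min_component_px noise floor forwarded to [build_graph()].
#' @return an `lcn_graph`.
#' @export
label_to_graph <- function(label, um_per_px = 1, connectivity = 8,
                           min_component_px = 5L) {
  m <- prepare_masks(label)
  dil <- dilate_for_merging(m$osteo, m$dend)
  occ <- connected_components(dil$osteo, connectivity)
  dcc <- connected_components(dil$dend, connectivity)
  build_graph(occ, dcc, m$osteo, m$dend, um_per_px, min_component_px)
}

#' Per-image network metrics
#'
#' Computes the connectomics summary of a field: node count, dead ends per
#' node, connections per node (2 |E| / |V|), mean connection length and
#' thickness, network-wide mean dendrite thickness (total dendrite area over
#' total skeleton length), and the mean shortest path in hops over connected
#' node pairs. An empty graph yields zeros and `empty_graph = TRUE`.
#'
#' @param graph an `lcn_graph`.
#' @param um_per_px pixel calibration; defaults to the graph's own.
#' @return an object of class `connectomics_report` (named list).
#' @export
network_metrics <- function(graph, um_per_px = graph$um_per_px) {
  stopifnot(inherits(graph, "lcn_graph"))
  V <- nrow(graph$nodes)
  E <- nrow(graph$edges)
  comp <- graph$components
  rep_ <- list(
    n_nodes = V,
    dead_ends_per_node = if (V > 0L) nrow(graph$dead_ends) / V else 0,
    connections_per_node = if (V > 0L) 2 * E / V else 0,
    mean_connection_length_um = if (E > 0L) mean(graph$edges$length_um) else NA_real_,
    mean_connection_diameter_um = if (E > 0L) mean(graph$edges$thickness_um) else NA_real_,
    mean_network_diameter_um =
      if (nrow(comp) > 0L && sum(comp$length_px) > 0)
        sum(comp$area_px) / sum(comp$length_px) * um_per_px else NA_real_,
    mean_shortest_path = NA_real_,
    n_edges = E,
    n_isolated = nrow(graph$isolated),
    empty_graph = V == 0L)
  if (V > 0L && E > 0L) {
    g <- igraph::make_empty_graph(n = V, directed = FALSE)
    g <- igraph::add_edges(g, rbind(graph$edges$node_a, graph$edges$node_b))
    g <- igraph::simplify(g)
    D <- igraph::distances(g)
    d <- D[upper.tri(D)]
    d <- d[is.finite(d) & d > 0]
    if (length(d) > 0L) rep_$mean_shortest_path <- mean(d)
  }
  if (V == 0L) {
    rep_$mean_connection_length_um <- 0
    rep_$mean_connection_diameter_um <- 0
    rep_$mean_network_diameter_um <- 0
    rep_$mean_shortest_path <- 0
  }
  class(rep_) <- "connectomics_report"
  rep_
}

#' @export
print.connectomics_report <- function(x, ...) {
  cat("Connectomics report\n")
  cat(sprintf("  Average nodes:                 %.2f\n", x$n_nodes))
  cat(sprintf("  Average dead ends per node:    %.2f\n", x$dead_ends_per_node))
  cat(sprintf("  Average connections per node:  %.2f\n", x$connections_per_node))
  cat(sprintf("  Average length of connections: %.2f um\n", x$mean_connection_length_um))
  cat(sprintf("  Average diameter of connections: %.3f um\n", x$mean_connection_diameter_um))
  cat(sprintf("  Average diameter of network:   %.3f um\n", x$mean_network_diameter_um))
  cat(sprintf("  Mean shortest path (hops):     %.2f\n", x$mean_shortest_path))
  invisible(x)
}

#' Flatten a connectomics report to a one-row data frame
#'
#' @param report a `connectomics_report`.
#' @return data frame with one row.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "connectomics_report"))
  as.data.frame(report[c("n_nodes", "dead_ends_per_node", "connections_per_node",
                         "mean_connection_length_um", "mean_connection_diameter_um",
                         "mean_network_diameter_um", "mean_shortest_path",
                         "n_edges", "n_isolated")])
}
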