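#' Image input/output
#'
#' Grayscale intensity images are exchanged as 8-bit TIFF or PNG (values
#' rescaled from the 0-255 working scale); three-class label masks as
#' single-channel indexed PNG holding the raw values 0/1/2.
#'
#' @param image numeric matrix on the 0-255 scale (RGB arrays are accepted
#'   by the reader and returned as `H x W x 3`).
#' @param path file path; the writer picks the format from the extension
#'   (`.tif`/`.tiff` or `.png`).
#' @return `read_lcn_image` returns a numeric matrix (or array) on the
#'   0-255 scale; writers return `path` invisibly.
#' @export
write_lcn_image <- function(image, path) {
  stopifnot(is.numeric(image))
  scaled <- pmin(pmax(image, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_lcn_image
#' @export
read_lcn_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image extension: ", ext)
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  if (length(dim(x)) == 3L && dim(x)[3L] == 4L) x <- x[, , 1:3]
  x * 255
}

#' Label mask input/output
#'
#' Losslessly round-trips three-class label masks through single-channel
#' indexed PNG (stored values 0/1/2).
#'
#' @param label integer matrix with values in \{0, 1, 2\}.
#' @param path PNG file path.
#' @return `read_label_png` returns the integer label matrix; the writer
#'   returns `path` invisibly.
#' @export
write_label_png <- function(label, path) {
  stopifnot(is.matrix(label), all(label %in% c(0L, 1L, 2L)))
  png::writePNG(label / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  lab <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  if (!all(lab %in% c(0L, 1L, 2L))) stop("not a 3-class label PNG: ", path)
  lab
}

#' Osteocyte graph input/output (GraphML)
#'
#' Serialises an `lcn_graph` to GraphML: nodes carry centroid and area,
#' edges carry component id, length and thickness; dead ends, isolated
#' components and the pixel calibration are stored as counts/attributes.
#'
#' @param graph an `lcn_graph`.
#' @param path GraphML file path.
#' @return `read_lcn_graph` returns the reconstructed `lcn_graph`; the
#'   writer returns `path` invisibly.
#' @export
write_lcn_graph <- function(graph, path) {
  stopifnot(inherits(graph, "lcn_graph"))
  V <- nrow(graph$nodes)
  g <- igraph::make_empty_graph(n = V, directed = FALSE)
  if (V > 0L) {
    de_count <- tabulate(graph$dead_ends$node, nbins = V)
    g <- igraph::set_vertex_attr(g, "x", value = as.numeric(graph$nodes$x))
    g <- igraph::set_vertex_attr(g, "y", value = as.numeric(graph$nodes$y))
    g <- igraph::set_vertex_attr(g, "area_px", value = as.numeric(graph$nodes$area_px))
    g <- igraph::set_vertex_attr(g, "dead_ends", value = as.numeric(de_count))
  }
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$edges$node_a, graph$edges$node_b))
    g <- igraph::set_edge_attr(g, "component", value = as.numeric(graph$edges$component))
    g <- igraph::set_edge_attr(g, "length_um", value = graph$edges$length_um)
    g <- igraph::set_edge_attr(g, "thickness_um", value = graph$edges$thickness_um)
  }
  g <- igraph::set_graph_attr(g, "um_per_px", graph$um_per_px)
  g <- igraph::set_graph_attr(g, "n_isolated", as.numeric(nrow(graph$isolated)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_lcn_graph
#' @export
read_lcn_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  V <- igraph::vcount(g)
  nodes <- if (V > 0L) {
    data.frame(id = seq_len(V),
               x = igraph::vertex_attr(g, "x"),
               y = igraph::vertex_attr(g, "y"),
               area_px = as.integer(round(igraph::vertex_attr(g, "area_px"))))
  } else data.frame(id = integer(0), x = numeric(0), y = numeric(0), area_px = integer(0))
  E <- igraph::ecount(g)
  edges <- if (E > 0L) {
    el <- igraph::as_edgelist(g, names = FALSE)
    data.frame(node_a = as.integer(el[, 1L]), node_b = as.integer(el[, 2L]),
               component = as.integer(round(igraph::edge_attr(g, "component"))),
               length_um = igraph::edge_attr(g, "length_um"),
               thickness_um = igraph::edge_attr(g, "thickness_um"))
  } else data.frame(node_a = integer(0), node_b = integer(0), component = integer(0),
                    length_um = numeric(0), thickness_um = numeric(0))
  de_count <- if (V > 0L) as.integer(round(igraph::vertex_attr(g, "dead_ends"))) else integer(0)
  dead_ends <- data.frame(node = rep(seq_len(V), times = de_count),
                          component = NA_integer_, length_um = NA_real_)
  n_iso <- as.integer(round(igraph::graph_attr(g, "n_isolated")))
  new_lcn_graph(nodes, edges, dead_ends,
                isolated = data.frame(component = rep(NA_integer_, n_iso)),
                components = data.frame(component = integer(0), area_px = integer(0),
                                        length_px = numeric(0), length_um = numeric(0),
                                        thickness_um = numeric(0), n_overlap = integer(0),
                                        role = character(0)),
                um_per_px = igraph::graph_attr(g, "um_per_px"))
}

#' Scene configuration input/output
#'
#' Writes/reads a [scene_config()] as a flat `key = value` text file (TOML
#' dialect); numeric pairs are comma-separated.
#'
#' @param cfg a `scene_config`.
#' @param path text file path.
#' @return `read_scene_config` returns the `scene_config`; the writer
#'   returns `path` invisibly.
#' @export
write_scene_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scene_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- stats::setNames(
    lapply(kv, function(p) as.numeric(trimws(strsplit(p[[2L]], ",")[[1L]]))),
    vapply(kv, function(p) trimws(p[[1L]]), character(1)))
  do.call(scene_config, args)
}

#' Write a generated scene to disk
#'
#' Writes image (8-bit TIFF or PNG), mask (indexed PNG), planted graph
#' (GraphML) and configuration (flat TOML) under a common prefix.
#'
#' @param scene an `lcn_scene` from [generate_scene()].
#' @param prefix path prefix; files get suffixes `_image.tif`, `_mask.png`,
#'   `_graph.graphml`, `_config.toml`.
#' @param image_format `"tif"` or `"png"`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, prefix, image_format = c("tif", "png")) {
  stopifnot(inherits(scene, "lcn_scene"), !is.null(scene$image))
  image_format <- match.arg(image_format)
  paths <- c(image = paste0(prefix, "_image.", image_format),
             mask = paste0(prefix, "_mask.png"),
             graph = paste0(prefix, "_graph.graphml"),
             config = paste0(prefix, "_config.toml"))
  write_lcn_image(scene$image, paths[["image"]])
  write_label_png(scene$mask, paths[["mask"]])
  write_lcn_graph(scene$graph, paths[["graph"]])
  write_scene_config(scene$config, paths[["config"]])
  invisible(paths)
}
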