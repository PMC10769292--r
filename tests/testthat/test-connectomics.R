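test_that("class masks partition the label foreground", {
  sc <- make_scene(small_scene_config(), 4)
  m <- prepare_masks(sc$mask)
  expect_false(any(m$osteo & m$dend))
  expect_equal(m$osteo | m$dend, sc$mask > 0L)
  expect_equal(sum(m$osteo), sum(sc$mask == 1L))
  e <- prepare_masks(matrix(0L, 5, 5))
  expect_false(any(e$osteo)); expect_false(any(e$dend))
  expect_error(prepare_masks(matrix(3L, 2, 2)))
})

test_that("merge dilation fuses near-adjacent fragments", {
  expect_false(any(dilate_for_merging(matrix(FALSE, 6, 6),
                                      matrix(FALSE, 6, 6))$dend))
  # diagonally adjacent pixels are already one component and stay merged
  d0 <- matrix(FALSE, 8, 8); d0[3, 3] <- TRUE; d0[4, 4] <- TRUE
  dd0 <- dilate_for_merging(matrix(FALSE, 8, 8), d0)$dend
  expect_equal(attr(connected_components(dd0, 8), "n"), 1L)
  # a one-pixel axial gap is bridged by the 2x2 cross dilation
  d <- matrix(FALSE, 8, 8); d[3, 3] <- TRUE; d[3, 5] <- TRUE
  expect_equal(attr(connected_components(d, 8), "n"), 2L)
  dd <- dilate_for_merging(matrix(FALSE, 8, 8), d)$dend
  expect_equal(attr(connected_components(dd, 8), "n"), 1L)
  # extensivity chain
  o <- matrix(runif(64) < 0.2, 8, 8)
  dil <- dilate_for_merging(o, d)
  expect_true(all(dil$osteo[o])); expect_true(all(dil$dend[d]))
})

test_that("connected components match brute-force flood fill", {
  expect_equal(attr(connected_components(matrix(FALSE, 5, 5), 8), "n"), 0L)
  m <- matrix(FALSE, 8, 8); m[1:2, 1:2] <- TRUE; m[6:7, 5:6] <- TRUE
  cc <- connected_components(m, 4)
  expect_equal(attr(cc, "n"), 2L)
  expect_equal(sort(tabulate(cc[cc > 0])), c(4L, 4L))
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4, 8)) {
      expect_identical(unclass(connected_components(m, conn))[TRUE],
                       brute_flood_fill(m, conn)[TRUE])
    }
  }
})

test_that("thinning preserves single-pixel curves and thins bars", {
  line <- matrix(FALSE, 10, 20); line[5, 3:18] <- TRUE
  expect_equal(skeletonize(line), line)
  bar <- matrix(FALSE, 12, 24); bar[5:8, 3:22] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(colSums(sk[, 6:19]) <= 1))
  expect_lt(sum(sk), sum(bar) / 2)
  expect_equal(attr(connected_components(sk, 8), "n"), 1L)
})

test_that("connection length and thickness follow their estimators", {
  line <- matrix(FALSE, 10, 20); line[5, 3:12] <- TRUE   # 10-px line
  expect_equal(connection_length(line, 1), 10)
  diagm <- matrix(FALSE, 20, 20)
  for (i in 1:10) diagm[i + 3, i + 3] <- TRUE            # 10-px diagonal
  expect_equal(connection_length(diagm, 1), 9 * sqrt(2) + 1, tolerance = 0.1)
  expect_equal(connection_length(diagm, 1), 10 * sqrt(2), tolerance = 0.8)
  bar <- matrix(FALSE, 12, 30); bar[5:7, 4:23] <- TRUE   # 3 x 20 bar
  expect_equal(connection_thickness(bar, 1), 3, tolerance = 0.6)
  expect_equal(connection_thickness(line, 1), 1)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(connection_thickness(single, 0.284), 0.284)
  expect_error(connection_length(matrix(FALSE, 3, 3)), "empty")
})

test_that("graph building classifies bridges, stubs and isolated pieces", {
  sc <- make_scene(clean_scene_config(n_osteocytes = 2L,
                                      connection_probability = 1,
                                      connection_radius = 1000,
                                      dead_end_rate = 0), 2)
  g <- label_to_graph(sc$mask, sc$config$um_per_px)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(nrow(g$dead_ends), 0L)
  sc2 <- make_scene(clean_scene_config(n_osteocytes = 1L,
                                       connection_probability = 0,
                                       dead_end_rate = 2), 3)
  g2 <- label_to_graph(sc2$mask, sc2$config$um_per_px)
  expect_equal(nrow(g2$nodes), 1L)
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(nrow(g2$dead_ends), nrow(sc2$graph$dead_ends))
  # roles are mutually exclusive per dendrite component
  both <- intersect(g2$dead_ends$component, g2$edges$component)
  expect_length(both, 0L)
  # an isolated fragment is reported separately, not as a dead end
  lab <- matrix(0L, 30, 30); lab[5:10, 5:12] <- 1L; lab[25, 5:25] <- 2L
  g3 <- label_to_graph(lab, 1)
  expect_equal(nrow(g3$isolated), 1L)
  expect_equal(nrow(g3$dead_ends), 0L)
})

test_that("graph extraction recovers planted topology exactly on clean scenes", {
  for (seed in 1:6) {
    sc <- make_scene(clean_scene_config(), seed)
    g <- label_to_graph(sc$mask, sc$config$um_per_px)
    expect_equal(nrow(g$nodes), nrow(sc$graph$nodes))
    expect_equal(nrow(g$edges), nrow(sc$graph$edges))
    expect_equal(nrow(g$dead_ends), nrow(sc$graph$dead_ends))
  }
})

test_that("network metrics satisfy closed-form identities", {
  nodes <- data.frame(id = 1:2, x = c(1, 10), y = c(1, 1), area_px = c(5L, 5L))
  edges <- data.frame(node_a = 1L, node_b = 2L, component = 1L,
                      length_um = 4, thickness_um = 0.5)
  g <- new_lcn_graph(nodes, edges,
                     data.frame(node = integer(0), component = integer(0),
                                length_um = numeric(0)),
                     data.frame(component = integer(0)),
                     data.frame(component = 1L, area_px = 10L, length_px = 14,
                                length_um = 4, thickness_um = 0.5,
                                n_overlap = 2L, role = "edge"),
                     um_per_px = 0.284)
  r <- network_metrics(g)
  expect_equal(r$connections_per_node, 1)
  expect_equal(r$mean_shortest_path, 1)
  expect_equal(r$mean_connection_length_um, 4)
  # path graph A-B-C: hops (1 + 1 + 2) / 3
  nodes3 <- rbind(nodes, data.frame(id = 3L, x = 20, y = 1, area_px = 5L))
  edges3 <- rbind(edges, data.frame(node_a = 2L, node_b = 3L, component = 2L,
                                    length_um = 6, thickness_um = 0.4))
  g3 <- new_lcn_graph(nodes3, edges3, g$dead_ends, g$isolated,
                      g$components, 0.284)
  expect_equal(network_metrics(g3)$mean_shortest_path, 4 / 3)
  # empty graph: zeros and the explicit flag
  ge <- new_lcn_graph(nodes[0, ], edges[0, ], g$dead_ends, g$isolated,
                      g$components[0, ], 0.284)
  re <- network_metrics(ge)
  expect_true(re$empty_graph)
  expect_equal(re$n_nodes, 0)
})

test_that("metrics on random planted graphs match a brute-force computation", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(3:7, 1)
    m <- sample(1:6, 1)
    ea <- sample(n, m, TRUE); eb <- sample(n, m, TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    if (length(ea) == 0L) next
    nodes <- data.frame(id = seq_len(n), x = runif(n), y = runif(n),
                        area_px = 10L)
    edges <- data.frame(node_a = ea, node_b = eb,
                        component = seq_along(ea),
                        length_um = runif(length(ea), 5, 20),
                        thickness_um = runif(length(ea), 0.3, 0.9))
    comps <- data.frame(component = seq_along(ea), area_px = 20L,
                        length_px = 10, length_um = edges$length_um,
                        thickness_um = edges$thickness_um,
                        n_overlap = 2L, role = "edge")
    g <- new_lcn_graph(nodes, edges,
                       data.frame(node = integer(0), component = integer(0),
                                  length_um = numeric(0)),
                       data.frame(component = integer(0)), comps, 1)
    r <- network_metrics(g)
    expect_equal(r$connections_per_node, 2 * length(ea) / n)
    expect_equal(r$mean_connection_length_um, mean(edges$length_um))
    expect_equal(r$mean_shortest_path,
                 brute_mean_shortest_path(n, ea, eb))
  }
})

test_that("metrics are invariant under translation and rotation of the label", {
  sc <- make_scene(clean_scene_config(), 5)
  lab <- sc$mask
  r0 <- report_row(network_metrics(label_to_graph(lab, 0.284)))
  rot <- t(lab)[rev(seq_len(ncol(lab))), ]               # 90-degree rotation
  r90 <- report_row(network_metrics(label_to_graph(rot, 0.284)))
  # topology is exactly invariant; skeleton-derived geometry only up to the
  # (slight) directional bias of thinning
  expect_identical(r0$n_nodes, r90$n_nodes)
  expect_identical(r0$n_edges, r90$n_edges)
  expect_identical(r0$dead_ends_per_node, r90$dead_ends_per_node)
  expect_identical(r0$mean_shortest_path, r90$mean_shortest_path)
  expect_equal(r0, r90, tolerance = 0.01)
  shifted <- matrix(0L, nrow(lab) + 6, ncol(lab) + 6)
  shifted[4:(nrow(lab) + 3), 4:(ncol(lab) + 3)] <- lab
  rs <- report_row(network_metrics(label_to_graph(shifted, 0.284)))
  expect_equal(r0, rs, tolerance = 1e-9)
})
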