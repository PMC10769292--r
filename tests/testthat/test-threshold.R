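test_that("preprocessing rescales 16-bit inputs and smooths", {
  img <- matrix(c(0, 65535), 16, 16)
  sm <- preprocess_image(img, 2)
  expect_lte(max(sm), 255)
  img8 <- matrix(120, 10, 10)
  expect_equal(preprocess_image(img8, 2), img8)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0), 2), "empty")
})

test_that("candidate split separates thick blobs from thin processes", {
  img <- matrix(0, 40, 40)
  img[10:22, 10:22] <- 200                 # 13-px blob: osteocyte candidate
  img[30:31, 5:35] <- 150                  # 2-px line: dendrite candidate
  cand <- split_candidate_masks(img, threshold_config())
  expect_true(all(cand$osteo[12:20, 12:20]))
  expect_true(all(cand$dend[30:31, 8:30]))
  expect_false(any(cand$osteo & cand$dend))
  # a faint line below the second threshold is suppressed
  img[30:31, 5:35] <- 72
  cand <- split_candidate_masks(img, threshold_config())
  expect_false(any(cand$dend[30:31, ]))
  # empty image yields empty candidates
  cand <- split_candidate_masks(matrix(0, 20, 20), threshold_config())
  expect_false(any(cand$osteo)); expect_false(any(cand$dend))
})

test_that("osteocyte candidates cover planted somas on noise-free scenes", {
  for (seed in 1:3) {
    sc <- make_scene(clean_scene_config(), seed)
    cand <- split_candidate_masks(preprocess_image(sc$image, 2),
                                  threshold_config())
    soma <- sc$mask == 1L
    expect_gte(sum(cand$osteo & soma) / sum(soma), 0.9)
  }
})

test_that("the Otsu core matches exhaustive between-class-variance search", {
  img <- matrix(c(rep(90, 50), rep(200, 50)), 10, 10)
  m <- otsu_core(img, lo = 80)
  t <- attr(m, "threshold")
  expect_gt(t, 90); expect_lte(t, 200)
  expect_equal(unname(which(m)), which(img == 200))
  set.seed(5)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 400, TRUE), 20, 20)
    expect_equal(attr(otsu_core(img, 80, 255), "threshold"),
                 brute_otsu(img, 80L, 255L))
  }
  expect_false(any(otsu_core(matrix(10, 8, 8) + diag(8), lo = 80)))
  expect_error(otsu_core(matrix(100, 8, 8), lo = 80), "degenerate")
})

test_that("the Canny core responds to edges and nothing else", {
  expect_false(any(canny_core(matrix(50, 32, 32), 70, 220)))
  # ideal step edge: a thin vertical response at the boundary
  img <- matrix(0, 32, 32); img[, 17:32] <- 255
  edges <- canny_core(img, 70, 220)
  cols <- unique(which(edges, arr.ind = TRUE)[, 2])
  expect_true(length(cols) > 0)
  expect_true(all(cols %in% 15:18))
  per_row <- rowSums(edges[5:28, , drop = FALSE])
  expect_true(all(per_row <= 2))           # non-maximum suppression thins
  # a 2-px ridge yields responses flanking it on both sides; closing fills
  # the enclosed ridge into one solid component
  img <- matrix(0, 32, 32); img[15:16, 4:28] <- 255
  edges <- canny_core(img, 70, 220)
  expect_true(any(edges[13:14, 10:22]))    # response above the ridge
  expect_true(any(edges[17:18, 10:22]))    # response below the ridge
  expect_false(any(edges[c(1:10, 22:32), ]))
  merged <- close_mask(edges, se_square(3))
  expect_equal(attr(connected_components(merged, 8), "n"), 1L)
  expect_true(all(merged[15:16, 10:22]))
})

test_that("postprocessing closes gaps and keeps classes disjoint", {
  dend <- matrix(FALSE, 20, 20)
  dend[10:11, 3:18] <- TRUE
  dend[10:11, 9] <- FALSE                  # 1-px gap in a 2-px line
  osteo <- matrix(FALSE, 20, 20); osteo[3:6, 3:6] <- TRUE
  lab <- postprocess_label(osteo, dend, 3L)
  expect_equal(lab[10, 9], 2L)             # gap bridged by closing
  expect_true(all(lab[osteo] == 1L))
  overlap <- osteo; overlap[10:11, 5] <- TRUE
  lab2 <- postprocess_label(overlap, dend, 3L)
  expect_false(any(lab2 == 1L & lab2 == 2L))
  expect_true(all(lab2[overlap] == 1L))
  expect_error(postprocess_label(osteo, dend[1:10, ], 3L), "shape")
})

test_that("segmentation is deterministic and handles empty fields", {
  cfg <- small_scene_config(n_osteocytes = 0L, dead_end_rate = 0)
  sc <- generate_scene(cfg)
  expect_true(all(segment_lcn(sc$image, "otsu") == 0L))
  sc2 <- make_scene(small_scene_config(), 5)
  a <- segment_lcn(sc2$image, "otsu")
  expect_identical(a, segment_lcn(sc2$image, "otsu"))
  expect_true(all(a %in% 0:2))
})

test_that("the Otsu pipeline recovers osteocytes well on noise-free scenes", {
  ious <- vapply(1:5, function(seed) {
    sc <- make_scene(clean_scene_config(), seed)
    lab <- segment_lcn(sc$image, "otsu")
    evaluate_label(lab, sc$mask)$iou_per_class[["osteocyte"]]
  }, numeric(1))
  expect_true(all(ious >= 0.5))
})
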