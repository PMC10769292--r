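test_that("grayscale conversion extracts the red channel exactly", {
  rgb <- array(0, c(6, 8, 3)); rgb[, , 1] <- 200
  expect_equal(to_grayscale(rgb), matrix(200, 6, 8))
  rgb[, , 1] <- 0; rgb[, , 2] <- 130
  expect_equal(to_grayscale(rgb), matrix(0, 6, 8))
  src <- matrix(runif(48, 0, 255), 6, 8)
  rgb2 <- array(0, c(6, 8, 3)); rgb2[, , 1] <- src
  expect_identical(to_grayscale(rgb2), src)
  expect_error(to_grayscale(array(0, c(4, 4, 2))), "3")
})

test_that("augmentation is seeded, shape-safe and tally-preserving", {
  sc <- make_scene(small_scene_config(), 3)
  for (seed in 1:6) {
    a <- augment_pair(sc$image, sc$mask, seed = seed)
    b <- augment_pair(sc$image, sc$mask, seed = seed)
    expect_identical(a$image, b$image)
    expect_identical(a$label, b$label)
    expect_true(is.integer(a$label))
    expect_equal(table(a$label), table(sc$mask))   # no crop: tallies kept
    expect_equal(sort(as.vector(a$image)), sort(as.vector(sc$image)))
  }
  cr <- augment_pair(sc$image, sc$mask, seed = 1, crop_size = c(32L, 48L))
  expect_equal(dim(cr$image), c(32L, 48L))
  expect_equal(dim(cr$label), c(32L, 48L))
})

test_that("dendrite label dilation grows dendrites without eating osteocytes", {
  lab <- matrix(0L, 10, 10)
  expect_identical(dilate_dendrite_labels(lab, "3x3"), lab)
  lab[5, 5] <- 2L
  d3 <- dilate_dendrite_labels(lab, "3x3")
  expect_equal(sum(d3 == 2L), 9L)
  expect_true(all(d3[4:6, 4:6] == 2L))
  lab[4, 4] <- 1L
  d3b <- dilate_dendrite_labels(lab, "3x3")
  expect_equal(d3b[4, 4], 1L)              # osteocyte never overwritten
  expect_true(all(d3b[lab == 2L] == 2L))   # superset property
  sc <- make_scene(clean_scene_config(), 2)
  d2 <- dilate_dendrite_labels(sc$mask, "2x2")
  expect_gt(sum(d2 == 2L), sum(sc$mask == 2L))
})

test_that("the masked DiceCE loss vanishes for perfect predictions and empty masks", {
  lab <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  probs <- array(1e-9, c(2, 2, 3))
  for (k in 0:2) probs[, , k + 1L][lab == k] <- 1 - 2e-9
  msk <- matrix(TRUE, 2, 2)
  expect_lt(masked_dice_ce_loss(probs, lab, msk), 1e-6)
  expect_warning(l0 <- masked_dice_ce_loss(probs, lab, matrix(FALSE, 2, 2)),
                 "empty")
  expect_equal(as.numeric(l0), 0)
})

test_that("the masked loss equals the loss of the annotated crop alone", {
  set.seed(8)
  z <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  probs <- osteolcn:::softmax_channels(z)
  lab <- matrix(sample(0:2, 144, TRUE), 12, 12)
  msk <- matrix(FALSE, 12, 12); msk[1:6, ] <- TRUE
  full <- masked_dice_ce_loss(probs, lab, msk)
  crop <- masked_dice_ce_loss(probs[1:6, , , drop = FALSE], lab[1:6, ],
                              matrix(TRUE, 6, 12))
  expect_equal(full, crop, tolerance = 1e-12)
})

test_that("loss gradients vanish exactly outside the annotation mask", {
  set.seed(4)
  z <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  lab <- matrix(sample(0:2, 100, TRUE), 10, 10)
  msk <- matrix(runif(100) < 0.5, 10, 10)
  probs <- osteolcn:::softmax_channels(z)
  l <- masked_dice_ce_loss(probs, lab, msk, return_grad = TRUE)
  gp <- attr(l, "gradient")
  outside <- which(array(rep(!msk, 3), dim(gp)))
  expect_true(all(gp[outside] == 0))
  lg <- osteolcn:::masked_loss_logits(z, lab, msk)
  expect_true(all(lg$grad_logits[outside] == 0))
})

test_that("the logit gradient matches numerical differentiation", {
  set.seed(13)
  z <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  lab <- matrix(sample(0:2, 20, TRUE), 4, 5)
  msk <- matrix(sample(c(TRUE, TRUE, FALSE), 20, TRUE), 4, 5)
  lg <- osteolcn:::masked_loss_logits(z, lab, msk)
  f <- function(zz) osteolcn:::masked_loss_logits(zz, lab, msk)$loss
  eps <- 1e-6
  num <- array(0, dim(z))
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num[i] <- (f(zp) - f(zm)) / (2 * eps)
  }
  expect_equal(lg$grad_logits, num, tolerance = 1e-6)
})

test_that("the fragmentation penalty follows its component-size algebra", {
  lab <- matrix(0L, 8, 8)
  z <- logits_from_label(lab)
  expect_equal(fragmentation_penalty(z, regulariser_config(weight = 1)), 0)
  lab[3, 3:6] <- 2L                        # one component of size 4
  z <- logits_from_label(lab)
  expect_equal(fragmentation_penalty(z, regulariser_config(1, 1)), 0.25)
  lab2 <- matrix(0L, 8, 8); lab2[3, 3:4] <- 2L; lab2[6, 3:4] <- 2L
  z2 <- logits_from_label(lab2)
  expect_equal(fragmentation_penalty(z2, regulariser_config(1, 1)), 1.0)
  # linear in weight; merging components strictly decreases the penalty
  expect_equal(fragmentation_penalty(z2, regulariser_config(1, 0.3)), 0.3)
  expect_lt(fragmentation_penalty(z, regulariser_config(1, 1)),
            fragmentation_penalty(z2, regulariser_config(1, 1)))
  # batch input sums over items
  expect_equal(fragmentation_penalty(list(z, z2), regulariser_config(1, 1)),
               1.25)
})

test_that("the fragmentation penalty matches a brute-force component sum", {
  set.seed(17)
  for (rep in 1:30) {
    lab <- matrix(sample(c(0L, 0L, 2L), 100, TRUE), 10, 10)
    z <- logits_from_label(lab)
    pf <- sample(c(0.5, 1, 2), 1)
    expect_equal(fragmentation_penalty(z, regulariser_config(pf, 1)),
                 brute_penalty(lab == 2L, pf, 1), tolerance = 1e-12)
  }
})

test_that("the cosine schedule hits its endpoints", {
  expect_equal(cosine_annealing_lr(0, 1e-3, 5e-6, 100), 1e-3)
  expect_equal(cosine_annealing_lr(100, 1e-3, 5e-6, 100), 5e-6)
  mid <- cosine_annealing_lr(50, 1e-3, 5e-6, 100)
  expect_equal(mid, (1e-3 + 5e-6) / 2, tolerance = 1e-12)
})

test_that("zero-epoch training leaves parameters untouched", {
  sc <- make_scene(train_scene_config(), 1)
  bb <- feature_backbone()
  fit <- train_backbone(bb, list(list(image = sc$image, label = sc$mask)),
                        train_config(epochs = 0L))
  expect_identical(fit$params, bb$init(1L))
  expect_equal(nrow(fit$history), 0L)
})

test_that("merged per-class predictions give osteocytes precedence", {
  o <- matrix(FALSE, 4, 4); o[1:2, 1:2] <- TRUE
  d <- matrix(FALSE, 4, 4); d[3:4, 3:4] <- TRUE
  m <- merge_class_predictions(o, d)
  expect_equal(sum(m == 1L), 4L); expect_equal(sum(m == 2L), 4L)
  d2 <- d; d2[1, 1] <- TRUE
  m2 <- merge_class_predictions(o, d2)
  expect_equal(m2[1, 1], 1L)
  m3 <- merge_class_predictions(o, matrix(FALSE, 4, 4))
  expect_true(all(m3 %in% c(0L, 1L)))
  expect_error(merge_class_predictions(o, d[1:2, ]), "shape")
})

test_that("halo suppression removes soma-adjacent dendrite debris only", {
  lab <- matrix(0L, 12, 12)
  lab[5:7, 5:7] <- 1L
  lab[4, 4:8] <- 2L                        # halo hugging the soma
  lab[10, 2:11] <- 2L                      # distant genuine process
  out <- suppress_soma_halo(lab, 1L)
  expect_false(any(out[4, ] == 2L))
  expect_true(all(out[10, 2:11] == 2L))
  expect_identical(suppress_soma_halo(lab, 0L), lab)
})
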