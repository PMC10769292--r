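#' Training configuration
#'
#' Hyperparameters of the optimisation loop used to fit per-pixel
#' classifiers: AdamW with cosine-annealed learning rate (period
#' `tmax_frac` of the total step count, floor `lr_floor`), global
#' gradient-norm clipping, and the weighted DiceCE loss restricted to
#' annotated pixels.
#'
#' @param learning_rate initial learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param lr_floor minimum learning rate reached by the cosine schedule.
#' @param tmax_frac cosine half-period as a fraction of total steps.
#' @param grad_clip_norm global L2 clipping threshold for gradients.
#' @param epochs,batch_size loop sizes.
#' @param seed integer seed controlling shuffling and initialisation.
#' @param dice_weight,ce_weight loss term weights.
#' @param dilate_dendrite_labels `NULL`, `"2x2"` or `"3x3"`: optional label
#'   dilation applied to the dendrite class before training.
#' @param finetune_mode one of `"none"`, `"freeze_all_but_io"`,
#'   `"freeze_all_but_head"`, `"reduced_lr_backbone"`; interpreted via the
#'   backbone's parameter groups.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         lr_floor = 5e-6, tmax_frac = 0.1,
                         grad_clip_norm = 1, epochs = 30L, batch_size = 4L,
                         seed = 1L, dice_weight = 1, ce_weight = 1,
                         dilate_dendrite_labels = NULL,
                         finetune_mode = c("none", "freeze_all_but_io",
                                           "freeze_all_but_head",
                                           "reduced_lr_backbone")) {
  finetune_mode <- match.arg(finetune_mode)
  stopifnot(learning_rate > lr_floor, batch_size >= 1, epochs >= 0,
            grad_clip_norm > 0, tmax_frac > 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_floor = lr_floor, tmax_frac = tmax_frac,
                 grad_clip_norm = grad_clip_norm, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 dice_weight = dice_weight, ce_weight = ce_weight,
                 dilate_dendrite_labels = dilate_dendrite_labels,
                 finetune_mode = finetune_mode),
            class = "train_config")
}

#' Dendrite-fragmentation regulariser configuration
#'
#' @param penalty_factor positive exponent: a component of size s adds
#'   `s^(-penalty_factor)` to the penalty, so fragmented predictions (many
#'   small components) are penalised more than a single long process.
#' @param weight non-negative multiplier on the summed penalty.
#' @param class_index label value of the regularised class (dendrite = 2).
#' @return an object of class `regulariser_config`.
#' @export
regulariser_config <- function(penalty_factor = 1, weight = 0.01,
                               class_index = 2L) {
  stopifnot(penalty_factor > 0, weight >= 0)
  structure(list(penalty_factor = penalty_factor, weight = weight,
                 class_index = as.integer(class_index)),
            class = "regulariser_config")
}

#' Extract the informative channel of an RGB microscopy image
#'
#' Phalloidin scans carry signal only in the red channel; grayscale
#' conversion is therefore red-channel extraction.
#'
#' @param rgb numeric array `H x W x 3`.
#' @return numeric matrix (the red channel, values unchanged).
#' @export
to_grayscale <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an H x W x 3 array")
  rgb[, , 1L]
}

#' Seeded geometric augmentation of an image/label pair
#'
#' Random horizontal/vertical flips, 90-degree rotations and (optionally) a
#' random crop, with the identical transform applied to image and label so
#' labels stay integer-valued. Deterministic under `seed`.
#'
#' @param image numeric matrix.
#' @param label integer matrix of the same shape.
#' @param seed optional integer seed (caller RNG untouched when given).
#' @param crop_size optional `c(h, w)` of a random crop; `NULL` disables
#'   cropping, in which case class pixel tallies are preserved.
#' @return list with transformed `image`, `label` and the drawn `ops`.
#' @export
augment_pair <- function(image, label, seed = NULL, crop_size = NULL) {
  stopifnot(is.matrix(image), is.matrix(label), all(dim(image) == dim(label)))
  draw <- function() {
    ops <- list(hflip = stats::runif(1) < 0.5,
                vflip = stats::runif(1) < 0.5,
                rot = sample(0:3, 1L))
    if (!is.null(crop_size)) {
      ops$crop <- c(sample.int(nrow(image) - crop_size[1L] + 1L, 1L),
                    sample.int(ncol(image) - crop_size[2L] + 1L, 1L))
    }
    ops
  }
  ops <- if (!is.null(seed)) withr::with_seed(as.integer(seed), draw()) else draw()
  tf <- function(m) {
    if (ops$hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (ops$vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    k <- ops$rot
    while (k > 0L) { m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]; k <- k - 1L }
    if (!is.null(crop_size)) {
      m <- m[ops$crop[1L]:(ops$crop[1L] + crop_size[1L] - 1L),
             ops$crop[2L]:(ops$crop[2L] + crop_size[2L] - 1L), drop = FALSE]
    }
    m
  }
  lab <- tf(label)
  storage.mode(lab) <- "integer"
  list(image = tf(image), label = lab, ops = ops)
}

#' Dilate dendrite labels
#'
#' Thickens the dendrite class of a label mask by a small square dilation
#' (compensates annotation imprecision on 1.5-3 px structures). Dilated
#' pixels never overwrite osteocyte pixels, and the output dendrite set is
#' a superset of the input.
#'
#' @param label integer label matrix (0/1/2).
#' @param kernel `"2x2"` or `"3x3"` (2x2 anchors at its top-left pixel).
#' @return integer label matrix.
#' @export
dilate_dendrite_labels <- function(label, kernel = c("3x3", "2x2")) {
  kernel <- match.arg(kernel)
  stopifnot(is.matrix(label), all(label %in% c(0L, 1L, 2L)))
  k <- if (kernel == "3x3") 3L else 2L
  dil <- dilate_mask(label == 2L, se_square(k))
  out <- label
  out[dil & label != 1L] <- 2L
  out
}

channel_slices <- function(a) lapply(seq_len(dim(a)[3L]), function(k) a[, , k])

# per-pixel argmax over channels, returned as 0-based class values
argmax_channels <- function(logits) {
  C <- dim(logits)[3L]
  lab <- max.col(matrix(logits, ncol = C), ties.method = "first") - 1L
  matrix(as.integer(lab), dim(logits)[1L], dim(logits)[2L])
}

softmax_channels <- function(logits) {
  sl <- channel_slices(logits)
  m <- Reduce(pmax, sl)
  e <- lapply(sl, function(z) exp(z - m))
  s <- Reduce(`+`, e)
  array(unlist(lapply(e, function(x) x / s)), dim(logits))
}

#' Masked DiceCE loss for partial labels
#'
#' Weighted sum of soft Dice loss and cross-entropy, computed exclusively
#' over annotated pixels (`annotation_mask == 1`); predictions outside the
#' mask carry exactly zero loss and zero gradient. An entirely unannotated
#' batch yields a defined zero loss with a warning.
#'
#' @param probs numeric array `H x W x C` of per-pixel class probabilities
#'   (channels sum to 1), channel `k` holding class `k - 1`.
#' @param label integer matrix of class values `0..C-1`.
#' @param annotation_mask logical/0-1 matrix marking annotated pixels.
#' @param dice_weight,ce_weight term weights.
#' @param return_grad if `TRUE`, attach the gradient with respect to
#'   `probs` as attribute `"gradient"`.
#' @return scalar loss.
#' @export
masked_dice_ce_loss <- function(probs, label, annotation_mask,
                                dice_weight = 1, ce_weight = 1,
                                return_grad = FALSE) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L,
            all(dim(probs)[1:2] == dim(label)),
            all(dim(label) == dim(annotation_mask)))
  C <- dim(probs)[3L]
  msk <- annotation_mask != 0
  Nm <- sum(msk)
  if (Nm == 0L) {
    warning("annotation mask is empty; loss defined as 0")
    loss <- 0
    if (return_grad) attr(loss, "gradient") <- array(0, dim(probs))
    return(loss)
  }
  eps <- 1e-7
  widx <- which(msk)
  lab_m <- label[widx]
  grad <- if (return_grad) array(0, dim(probs)) else NULL
  HW <- prod(dim(label))

  # cross entropy over annotated pixels
  p_true <- probs[widx + HW * lab_m]
  ce <- -mean(log(pmax(p_true, 1e-12)))
  if (return_grad) {
    g <- -1 / (Nm * pmax(p_true, 1e-12))
    grad[widx + HW * lab_m] <- grad[widx + HW * lab_m] + ce_weight * g
  }

  # soft Dice per class over annotated pixels
  dice_sum <- 0
  for (k in 0:(C - 1L)) {
    pk <- probs[widx + HW * k]
    gk <- as.numeric(lab_m == k)
    num <- 2 * sum(pk * gk) + eps
    den <- sum(pk) + sum(gk) + eps
    dice_sum <- dice_sum + num / den
    if (return_grad) {
      dd <- (2 * gk * den - num) / den^2       # d dice_k / d p_k
      grad[widx + HW * k] <- grad[widx + HW * k] - dice_weight * dd / C
    }
  }
  dice_loss <- 1 - dice_sum / C

  loss <- dice_weight * dice_loss + ce_weight * ce
  if (return_grad) attr(loss, "gradient") <- grad
  loss
}

# Loss and gradient with respect to logits (chains the softmax Jacobian).
masked_loss_logits <- function(logits, label, annotation_mask,
                               dice_weight = 1, ce_weight = 1) {
  probs <- softmax_channels(logits)
  loss <- suppressWarnings(
    masked_dice_ce_loss(probs, label, annotation_mask,
                        dice_weight, ce_weight, return_grad = TRUE))
  gp <- attr(loss, "gradient")
  inner <- Reduce(`+`, channel_slices(gp * probs))
  gz <- probs * (gp - array(rep(inner, dim(probs)[3L]), dim(probs)))
  list(loss = as.numeric(loss), grad_logits = gz, probs = probs)
}

#' Connected-component fragmentation penalty
#'
#' Regularisation term that discourages fragmented dendrite predictions:
#' softmax -> per-pixel argmax -> binary map of the regularised class ->
#' 8-connected components; each component of size s contributes
#' `s^(-penalty_factor)`, summed over the batch and scaled by `weight`.
#' Larger, merged components yield a strictly smaller penalty. Computed on
#' hard predictions, it is used as a monitored auxiliary term.
#'
#' @param logits numeric array `H x W x C`, or a list of such arrays
#'   (a batch).
#' @param cfg a [regulariser_config()].
#' @return scalar penalty (0 when the class is absent).
#' @export
fragmentation_penalty <- function(logits, cfg = regulariser_config()) {
  stopifnot(inherits(cfg, "regulariser_config"))
  batch <- if (is.list(logits)) logits else list(logits)
  total <- 0
  for (z in batch) {
    stopifnot(is.array(z), length(dim(z)) == 3L)
    pred <- argmax_channels(softmax_channels(z))
    bin <- pred == cfg$class_index
    if (!any(bin)) next
    cc <- connected_components(bin, 8)
    sizes <- tabulate(cc[cc > 0L])
    total <- total + sum(sizes^(-cfg$penalty_factor))
  }
  total * cfg$weight
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = floor + (lr0 - floor) * (1 + cos(pi * t / t_max)) / 2`, the
#' standard per-step cosine schedule: `lr0` at step 0 and `floor` at step
#' `t_max`.
#'
#' @param step 0-based step index.
#' @param lr0 initial learning rate.
#' @param lr_floor minimum learning rate.
#' @param t_max half-period in steps.
#' @return learning rate at `step`.
#' @export
cosine_annealing_lr <- function(step, lr0, lr_floor, t_max) {
  lr_floor + (lr0 - lr_floor) * (1 + cos(pi * step / t_max)) / 2
}

#' Compact per-pixel classification backbone
#'
#' The package's reference backbone: a softmax head over a fixed bank of
#' multi-scale convolutional features (the min-max-normalised image, three
#' Gaussian scales, a gradient magnitude and a band-pass residual). All
#' trainable parameters sit in the head, with analytic gradients, which
#' keeps desk-scale training fast and exactly reproducible; any model
#' exposing the same `forward`/`backward`/`init` contract can replace it in
#' [train_backbone()].
#'
#' @param n_classes number of output classes.
#' @param sigmas Gaussian feature scales in pixels.
#' @return an object of class `lcn_backbone`: list with `n_classes`,
#'   `n_params`, `param_groups`, `init(seed)`, `features(image)`,
#'   `forward(params, image)` (returns `H x W x C` logits) and
#'   `backward(params, image, grad_logits)`.
#' @export
feature_backbone <- function(n_classes = 3L, sigmas = c(1, 2, 4)) {
  K <- length(sigmas) + 3L   # raw + gaussians + gradmag + bandpass
  n_params <- (K + 1L) * n_classes
  cache <- new.env(parent = emptyenv())
  compute_features <- function(image) {
    rng <- range(image)
    x <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
    gs <- lapply(sigmas, function(s) gaussian_smooth(x, s))
    g <- sobel_gradients(gs[[1L]])
    feats <- c(list(x), gs,
               list(sqrt(g$gx^2 + g$gy^2) / 8, x - gs[[length(gs)]]))
    do.call(cbind, lapply(feats, as.vector))
  }
  features <- function(image) {
    # the bank is fixed, so memoise it per image (training revisits images)
    key <- paste(nrow(image), ncol(image), sum(image),
                 image[1L], image[length(image)], sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (length(ls(cache)) >= 64L) rm(list = ls(cache), envir = cache)
    cache[[key]] <- compute_features(image)
  }
  structure(list(
    n_classes = as.integer(n_classes),
    n_params = n_params,
    n_features = K,
    param_groups = list(head = seq_len(n_params)),
    init = function(seed = 1L) {
      withr::with_seed(as.integer(seed),
                       stats::rnorm(n_params, 0, 0.01))
    },
    features = features,
    forward = function(params, image) {
      Wm <- matrix(params[seq_len(K * n_classes)], K, n_classes)
      b <- params[K * n_classes + seq_len(n_classes)]
      FN <- features(image)
      Z <- FN %*% Wm
      Z <- sweep(Z, 2L, b, `+`)
      array(Z, c(nrow(image), ncol(image), n_classes))
    },
    backward = function(params, image, grad_logits) {
      FN <- features(image)
      dZ <- matrix(grad_logits, ncol = n_classes)
      c(as.vector(crossprod(FN, dZ)), colSums(dZ))
    }),
    class = "lcn_backbone")
}

#' Predicted label map of a backbone
#'
#' @param backbone an `lcn_backbone`.
#' @param params parameter vector.
#' @param image numeric matrix.
#' @return integer label matrix (argmax class values `0..C-1`).
#' @export
predict_label <- function(backbone, params, image) {
  argmax_channels(backbone$forward(params, image))
}

foreground_dice <- function(pred, truth) dice_score(pred > 0L, truth > 0L)

#' Train a per-pixel classification backbone
#'
#' Optimisation loop with AdamW (decoupled weight decay), per-step cosine
#' learning-rate annealing, global gradient-norm clipping and the masked
#' DiceCE loss; optionally monitors the dendrite fragmentation penalty.
#' Dataset items are lists with `image`, `label` and optional `mask`
#' (annotation mask, default fully annotated). Fully reproducible under
#' `cfg$seed`; `epochs = 0` returns the initial parameters unchanged.
#'
#' @param backbone an `lcn_backbone` (or any object honouring its
#'   contract).
#' @param dataset list of training items.
#' @param cfg a [train_config()].
#' @param reg optional [regulariser_config()] monitored per epoch.
#' @param validation optional list of items for the per-epoch foreground
#'   Dice; defaults to the training set.
#' @param params optional starting parameter vector (default
#'   `backbone$init(cfg$seed)`).
#' @return list with `params`, `backbone` and `history` (data frame with
#'   per-epoch loss, validation foreground Dice, learning rate and, when
#'   monitored, the fragmentation penalty).
#' @export
train_backbone <- function(backbone, dataset, cfg = train_config(),
                           reg = NULL, validation = NULL, params = NULL) {
  stopifnot(length(dataset) >= 1L)
  if (is.null(validation)) validation <- dataset
  if (!is.null(cfg$dilate_dendrite_labels)) {
    dataset <- lapply(dataset, function(it) {
      it$label <- dilate_dendrite_labels(it$label, cfg$dilate_dendrite_labels)
      it
    })
  }
  dataset <- lapply(dataset, function(it) {
    if (is.null(it$mask)) it$mask <- matrix(TRUE, nrow(it$label), ncol(it$label))
    it
  })
  if (is.null(params)) params <- backbone$init(cfg$seed)

  n <- length(dataset)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  t_max <- max(1L, round(cfg$tmax_frac * total_steps))

  active <- rep(TRUE, length(params))
  lr_scale <- rep(1, length(params))
  pg <- backbone$param_groups
  if (!is.null(pg) && cfg$finetune_mode != "none") {
    head_ids <- unique(c(pg$head, pg$input))
    if (cfg$finetune_mode == "freeze_all_but_head") {
      active[] <- FALSE; active[pg$head] <- TRUE
    } else if (cfg$finetune_mode == "freeze_all_but_io") {
      active[] <- FALSE; active[head_ids] <- TRUE
    } else if (cfg$finetune_mode == "reduced_lr_backbone") {
      lr_scale[] <- 0.1; lr_scale[pg$head] <- 1
    }
  }

  m <- numeric(length(params)); v <- numeric(length(params))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  history <- vector("list", cfg$epochs)

  eval_val_dice <- function(p) {
    if (length(validation) == 0L) return(NA_real_)
    mean(vapply(validation, function(it)
      foreground_dice(predict_label(backbone, p, it$image), it$label),
      numeric(1)))
  }

  run_epochs <- function() {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batch <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        items <- dataset[ord[b0:min(n, b0 + cfg$batch_size - 1L)]]
        g <- numeric(length(params))
        loss_b <- 0
        for (it in items) {
          z <- backbone$forward(params, it$image)
          lg <- masked_loss_logits(z, it$label, it$mask,
                                   cfg$dice_weight, cfg$ce_weight)
          loss_b <- loss_b + lg$loss
          g <- g + backbone$backward(params, it$image, lg$grad_logits)
        }
        g <- g / length(items)
        loss_b <- loss_b / length(items)
        if (!is.finite(loss_b))
          stop("training diverged: non-finite loss at epoch ", ep)
        gn <- sqrt(sum(g^2))
        if (gn > cfg$grad_clip_norm) g <- g * cfg$grad_clip_norm / gn
        lr <- cosine_annealing_lr(step, cfg$learning_rate, cfg$lr_floor, t_max)
        step <<- step + 1L
        m <<- beta1 * m + (1 - beta1) * g
        v <<- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^step)
        vh <- v / (1 - beta2^step)
        upd <- lr * lr_scale * (mh / (sqrt(vh) + adam_eps) + cfg$weight_decay * params)
        params[active] <<- params[active] - upd[active]
        ep_loss <- ep_loss + loss_b; n_batch <- n_batch + 1L
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n_batch,
                        val_dice = eval_val_dice(params),
                        lr = cosine_annealing_lr(step - 1L, cfg$learning_rate,
                                                 cfg$lr_floor, t_max))
      if (!is.null(reg)) {
        row$penalty <- mean(vapply(dataset, function(it)
          fragmentation_penalty(backbone$forward(params, it$image), reg),
          numeric(1)))
      }
      history[[ep]] <<- row
    }
  }
  if (cfg$epochs > 0L) withr::with_seed(cfg$seed, run_epochs())

  list(params = params, backbone = backbone,
       history = if (cfg$epochs > 0L) do.call(rbind, history)
                 else data.frame(epoch = integer(0), loss = numeric(0),
                                 val_dice = numeric(0), lr = numeric(0)))
}

#' Suppress partial-volume dendrite halos around predicted somas
#'
#' Per-pixel classifiers tend to label the blur transition zone around each
#' soma as dendrite, which welds unrelated processes into one component
#' circling the cell. This cleanup removes dendrite pixels within `halo`
#' pixels of the osteocyte class; genuine contacts are re-established by
#' the component-merging dilation during graph extraction.
#'
#' @param label integer label matrix (0/1/2).
#' @param halo halo width in pixels.
#' @return cleaned integer label matrix.
#' @export
suppress_soma_halo <- function(label, halo = 1L) {
  stopifnot(is.matrix(label), all(label %in% c(0L, 1L, 2L)), halo >= 0L)
  if (halo == 0L) return(label)
  ring <- dilate_mask(label == 1L, se_square(2L * as.integer(halo) + 1L))
  out <- label
  out[out == 2L & ring] <- 0L
  out
}

#' Merge per-class model predictions
#'
#' Aggregates the outputs of two single-class models (one predicting
#' osteocytes, one dendrites) into a final label; the osteocyte class wins
#' conflicting pixels.
#'
#' @param osteo_pred,dend_pred logical matrices of equal shape.
#' @return integer label matrix (0/1/2) with disjoint classes.
#' @export
merge_class_predictions <- function(osteo_pred, dend_pred) {
  if (!is.matrix(osteo_pred) || !is.matrix(dend_pred) ||
      !all(dim(osteo_pred) == dim(dend_pred)))
    stop("shape mismatch between class predictions")
  out <- matrix(0L, nrow(osteo_pred), ncol(osteo_pred))
  out[dend_pred != 0] <- 2L
  out[osteo_pred != 0] <- 1L
  out
}
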