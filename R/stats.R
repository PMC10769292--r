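#' Batch connectomics over a directory of images
#'
#' Reads every image in a directory (TIFF/PNG, filename order), segments it
#' with the requested method, extracts the osteocyte graph and returns one
#' [network_metrics()] row per image. Unreadable or failing files are
#' skipped and recorded in the `errors` attribute.
#'
#' @param input_dir directory of grayscale images.
#' @param method `"otsu"`, `"canny"` or `"model"`.
#' @param cfg a [threshold_config()] (ignored for `method = "model"`).
#' @param um_per_px pixel calibration in micrometres.
#' @param model for `method = "model"`: list with `backbone` and `params`.
#' @return data frame, one row per successfully processed image (column
#'   `file` first), with attribute `errors` (data frame of failures).
#' @export
run_batch <- function(input_dir, method = c("otsu", "canny", "model"),
                      cfg = threshold_config(), um_per_px = 0.284,
                      model = NULL) {
  method <- match.arg(method)
  if (method == "model" && (is.null(model$backbone) || is.null(model$params)))
    stop("method = \"model\" requires `model = list(backbone, params)`")
  files <- sort(list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  rows <- list(); errs <- list()
  for (f in files) {
    res <- tryCatch({
      img <- read_lcn_image(f)
      if (length(dim(img)) == 3L) img <- to_grayscale(img)
      label <- if (method == "model")
        predict_label(model$backbone, model$params, img)
      else segment_lcn(img, method, cfg)
      r <- report_row(network_metrics(label_to_graph(label, um_per_px)))
      cbind(data.frame(file = basename(f), stringsAsFactors = FALSE), r)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(file = basename(f),
                                              error = conditionMessage(res),
                                              stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    warning("no images processed in ", input_dir)
    cbind(data.frame(file = character(0)),
          report_row(network_metrics(new_lcn_graph(
            data.frame(id = integer(0), x = numeric(0), y = numeric(0), area_px = integer(0)),
            data.frame(node_a = integer(0), node_b = integer(0), component = integer(0),
                       length_um = numeric(0), thickness_um = numeric(0)),
            data.frame(node = integer(0), component = integer(0), length_um = numeric(0)),
            data.frame(component = integer(0)),
            data.frame(component = integer(0), area_px = integer(0), length_px = numeric(0),
                       length_um = numeric(0), thickness_um = numeric(0),
                       n_overlap = integer(0), role = character(0)),
            um_per_px)))[0, ])
  }
  attr(out, "errors") <- if (length(errs) > 0L) do.call(rbind, errs) else
    data.frame(file = character(0), error = character(0))
  out
}

# Pooled-variance two-sample Student's t; returns c(t, df, p).
student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  df <- na + nb - 2L
  sp2 <- (sum((a - ma)^2) + sum((b - mb)^2)) / df
  if (sp2 == 0) {
    if (ma == mb) return(c(t = 0, df = df, p = 1))
    return(c(t = sign(ma - mb) * Inf, df = df, p = 0))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare two groups of per-image network metrics
#'
#' Per-metric two-sided two-sample t-test between groups of per-image
#' reports (Student's pooled-variance by default, Welch behind a flag),
#' reporting mean and SD per group. Rows with missing values for a metric
#' (e.g. connection length in an edge-free field) are dropped for that
#' metric. Two groups with zero variance and equal means yield `t = 0`,
#' `p = 1`.
#'
#' @param reports_a,reports_b data frames of per-image metrics (as returned
#'   by [run_batch()] or built from [report_row()]).
#' @param alpha significance level (`significant` is `p < alpha`).
#' @param metrics metric columns to compare; defaults to the shared numeric
#'   columns.
#' @param welch if `TRUE`, use Welch's unequal-variance t-test.
#' @return data frame with one row per metric: group means and SDs, group
#'   sizes, `t`, `df`, `p` and `significant`.
#' @export
compare_groups <- function(reports_a, reports_b, alpha = 1e-4,
                           metrics = NULL, welch = FALSE) {
  num_a <- names(reports_a)[vapply(reports_a, is.numeric, logical(1))]
  num_b <- names(reports_b)[vapply(reports_b, is.numeric, logical(1))]
  if (is.null(metrics)) metrics <- setdiff(intersect(num_a, num_b),
                                           c("n_edges", "n_isolated"))
  rows <- lapply(metrics, function(mn) {
    a <- reports_a[[mn]]; b <- reports_b[[mn]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("fewer than 2 finite observations for metric ", mn)
    res <- if (welch) {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    } else {
      student_t(a, b)
    }
    data.frame(metric = mn,
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               t = res[["t"]], df = res[["df"]], p = res[["p"]],
               significant = res[["p"]] < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
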