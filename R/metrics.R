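# distance-tolerant edge-map evaluation ---------------------------------------

as_map <- function(x, dim = NULL) {
  if (inherits(x, "gestalt_contours")) return(x$gestalt_map)
  if (inherits(x, "cep_set")) return(cep_to_map(x))
  if (is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))) return(x != 0)
  if (is.matrix(x) && ncol(x) == 2) {
    if (is.null(dim)) stop("coordinate input needs explicit image bounds")
    m <- matrix(FALSE, dim[1], dim[2]); m[x] <- TRUE
    return(m)
  }
  stop("cannot interpret input as an edge map")
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `map`
dist_to <- function(map) {
  if (!any(map)) return(matrix(Inf, nrow(map), ncol(map)))
  as.matrix(EBImage::distmap(1 - map, metric = "euclidean"))
}

#' Distance-tolerant TP/FP/FN counts
#'
#' One-sided matching: a detected pixel counts as a true positive when its
#' Euclidean distance to the nearest ground-truth pixel is at most `d0`
#' (boundary inclusive); otherwise it is a false positive.  A ground-truth
#' pixel with no detection within `d0` is a false negative.  No one-to-one
#' assignment is enforced.
#'
#' @param dp detected pixels (binary matrix, `cep_set`, `gestalt_contours`,
#'   or coordinate matrix with `dim`).
#' @param gt ground-truth contour map (same forms).
#' @param d0 tolerance in pixels, 1–5.
#' @param dim image bounds when coordinates are supplied.
#' @return list with `tp`, `fp`, `fn`, `n_dp`, `n_gt`.
#' @export
tolerant_match <- function(dp, gt, d0 = 1, dim = NULL) {
  if (!(d0 %in% 1:5)) stop("d0 must be an integer in 1..5")
  dp <- as_map(dp, dim); gt <- as_map(gt, dim %||% base::dim(dp))
  stopifnot(identical(base::dim(dp), base::dim(gt)))
  n_dp <- sum(dp); n_gt <- sum(gt)
  if (n_gt == 0) return(list(tp = 0L, fp = n_dp, fn = 0L,
                             n_dp = n_dp, n_gt = 0L))
  dg <- dist_to(gt)
  tp <- sum(dp & dg <= d0)
  fp <- n_dp - tp
  dd <- dist_to(dp)
  fn <- sum(gt & dd > d0)
  list(tp = tp, fp = fp, fn = fn, n_dp = n_dp, n_gt = n_gt)
}

#' Pratt's figure of merit
#'
#' `FoM = 1/max(n_DP, n_GT) * sum over DP of 1 / (1 + (d/d0)^2)` where `d`
#' is the distance-transform distance from each detected pixel to the
#' ground truth.  1 iff the maps coincide; empty detection gives 0.
#'
#' @inheritParams tolerant_match
#' @return value in \[0, 1].
#' @export
pratt_fom <- function(dp, gt, d0 = 1, dim = NULL) {
  dp <- as_map(dp, dim); gt <- as_map(gt, dim %||% base::dim(dp))
  n_dp <- sum(dp); n_gt <- sum(gt)
  if (n_gt == 0) stop("ground truth is empty")
  if (n_dp == 0) return(0)
  d <- dist_to(gt)[dp]
  sum(1 / (1 + (d / d0)^2)) / max(n_dp, n_gt)
}

#' Edge quality, map quality and the F1 form
#'
#' `EQ = TP/(TP+FP)` (precision of the detected pixels),
#' `MQ = TP/(n_GT + FP)` and the F1 variant
#' `MQ_f1 = TP/(TP + 0.5*(FP+FN))`.  Zero denominators give `NA`
#' (undefined), not 0.
#'
#' @param tp,fp,fn tolerant-matched counts (see [tolerant_match()]).
#' @param n_gt number of ground-truth pixels.
#' @return list with `eq`, `mq`, `mq_f1`.
#' @export
eq_mq <- function(tp, fp, fn, n_gt) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, n_gt >= 0)
  list(
    eq = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    mq = if (n_gt + fp > 0) tp / (n_gt + fp) else NA_real_,
    mq_f1 = if (tp + 0.5 * (fp + fn) > 0)
      tp / (tp + 0.5 * (fp + fn)) else NA_real_)
}

#' Screening rate
#'
#' Percentage of candidate pixels removed by the classifier:
#' `sR = (n_CEP - n_DT) / n_CEP * 100`.
#'
#' @param n_cep number of candidate edge pixels (> 0).
#' @param n_dt number of retained (detected) pixels, `0 <= n_dt <= n_cep`.
#' @return percentage in \[0, 100].
#' @export
screening_rate <- function(n_cep, n_dt) {
  if (n_cep <= 0) stop("screening rate undefined for an empty candidate set")
  if (n_dt < 0 || n_dt > n_cep) stop("n_dt must lie in [0, n_cep]")
  (n_cep - n_dt) / n_cep * 100
}

#' Full evaluation report for one detection
#'
#' @param dp detected pixels.
#' @param gt ground-truth contour map.
#' @param d0 matching tolerance in pixels.
#' @param n_cep optional candidate count for the screening rate.
#' @param dim image bounds when coordinates are supplied.
#' @return object of class `eval_report` with `d0`, the matched counts and
#'   `eq`, `mq`, `mq_f1`, `fom`, `sr`, plus a `working_zone` flag
#'   (`|MQ - EQ| <= 0.2` and `MQ >= 0.5`, the Half-GT diagnostic).
#' @export
eval_report <- function(dp, gt, d0 = 1, n_cep = NULL, dim = NULL) {
  m <- tolerant_match(dp, gt, d0, dim)
  q <- eq_mq(m$tp, m$fp, m$fn, m$n_gt)
  fom <- if (m$n_gt > 0) pratt_fom(dp, gt, d0, dim) else NA_real_
  sr <- if (!is.null(n_cep) && n_cep > 0) screening_rate(n_cep, m$n_dp)
        else NA_real_
  structure(c(list(d0 = d0), m, q, list(
    fom = fom, sr = sr,
    working_zone = isTRUE(!is.na(q$mq) && !is.na(q$eq) &&
                          abs(q$mq - q$eq) <= 0.2 && q$mq >= 0.5))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Edge-map evaluation (d0 = ", x$d0, "): TP ", x$tp, ", FP ", x$fp,
      ", FN ", x$fn, "\n", sep = "")
  cat(sprintf("  EQ %.3f | MQ %.3f | MQ_f1 %.3f | FoM %.3f",
              x$eq, x$mq, x$mq_f1, x$fom))
  if (!is.na(x$sr)) cat(sprintf(" | sR %.1f%%", x$sr))
  cat(if (x$working_zone) "  [working zone]" else "", "\n")
  invisible(x)
}

#' Precision–recall sweep over detector parameters
#'
#' Runs the full extractor over a grid of Canny high thresholds and Bayes
#' thresholds on a list of scenes with ground truth, and averages precision
#' (`EQ`) and recall (`TP/(TP+FN)`) over the scenes for each setting.
#'
#' @param scenes list of scenes; each a list with `image` and `gt_contours`
#'   (e.g. from [shape_scene()]).
#' @param h_t_grid,k_grid parameter grids.
#' @param d0 matching tolerance.
#' @param ... further arguments to [gestalt_contours()].
#' @return data frame with columns `h_t`, `k`, `precision`, `recall`.
#' @export
pr_sweep <- function(scenes, h_t_grid = c(0.1, 0.2, 0.3),
                     k_grid = c(0.4, 0.5, 0.6), d0 = 1, ...) {
  stopifnot(length(scenes) >= 1)
  grid <- expand.grid(h_t = h_t_grid, k = k_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- vapply(scenes, function(sc) {
      fit <- gestalt_contours(sc$image, h_t = grid$h_t[i], k = grid$k[i], ...)
      m <- tolerant_match(fit$gestalt_map, sc$gt_contours, d0)
      c(if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0,
        if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0)
    }, numeric(2))
    c(precision = mean(pr[1, ]), recall = mean(pr[2, ]))
  })
  cbind(grid, do.call(rbind, res))
}
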