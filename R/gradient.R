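# 2-D correlation with reflected borders ------------------------------------

pad_reflect <- function(x, pr, pc) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(n), n - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(m), m - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

#' 2-D filtering by direct correlation (reflect padding)
#'
#' @param x numeric matrix.
#' @param k odd-sized kernel matrix.
#' @return matrix of the same shape as `x`.
#' @keywords internal
convolve2 <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  xp <- pad_reflect(x, max(pr, 1L) * (pr > 0) + 0L, max(pc, 1L) * (pc > 0) + 0L)
  if (pr == 0L && pc == 0L) xp <- x
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[i:(i + nrow(x) - 1L), j:(j + ncol(x) - 1L)]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(x, sigma) {
  k <- gaussian_kernel_1d(sigma)
  convolve2(convolve2(x, matrix(k, nrow = 1)), matrix(k, ncol = 1))
}

#' Prefilter an image
#'
#' Optional smoothing step before gradient computation: low-pass Gaussian
#' (good against additive Gaussian noise), median (good against impulsive
#' noise), or none.
#'
#' @param image numeric matrix.
#' @param kind `"gaussian"`, `"median"` or `"none"`.
#' @param param Gaussian sigma in pixels (default `sqrt(2)`) or odd median
#'   window size (default 3).
#' @return filtered matrix, same shape.
#' @export
prefilter <- function(image, kind = c("gaussian", "median", "none"),
                      param = NULL) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite 2-D matrix")
  kind <- match.arg(kind)
  if (kind == "none") return(image)
  if (kind == "gaussian") {
    sigma <- param %||% sqrt(2)
    return(gaussian_blur(image, sigma))
  }
  w <- as.integer(param %||% 3L)
  if (w < 1L || w %% 2L == 0L) stop("median window must be odd and >= 1")
  r <- (w - 1L) %/% 2L
  xp <- pad_reflect(image, r, r)
  stack <- array(NA_real_, c(nrow(image), ncol(image), w * w))
  s <- 1L
  for (i in seq_len(w)) {
    for (j in seq_len(w)) {
      stack[, , s] <- xp[i:(i + nrow(image) - 1L), j:(j + ncol(image) - 1L)]
      s <- s + 1L
    }
  }
  apply(stack, c(1, 2), median)
}

kernels <- list(
  sobel   = list(x = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
                 y = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)),
  prewitt = list(x = matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3),
                 y = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)),
  roberts = list(x = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3),
                 y = matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3))
)

#' Gradient magnitude and orientation field
#'
#' Convolves the image with a first-derivative operator and returns per-pixel
#' magnitude `g = sqrt(gx^2 + gy^2)`, normalized log-magnitude `gn` (see
#' [normalize_magnitude()]) and orientation `theta` in degrees in
#' \[-90, 90).  With the default `convention = "tangent"` the orientation is
#' `atan2(gx, gy)`, which for an intensity edge is the direction of the edge
#' itself (the level line), e.g. a vertical edge gives |theta| = 90.  Set
#' `convention = "gradient"` for the usual `atan2(gy, gx)`.  `theta` is `NA`
#' (undefined) wherever `g = 0`.
#'
#' @param image numeric matrix (at least 3x3).
#' @param operator `"sobel"`, `"prewitt"` or `"roberts"`.
#' @param convention orientation formula, see above.
#' @param normalize if `TRUE` (default) also compute `gn`.
#' @return an object of class `gradient_field`: list with `g`, `gn`, `theta`,
#'   `gx`, `gy`, `dim`.
#' @export
gradient_field <- function(image, operator = c("sobel", "prewitt", "roberts"),
                           convention = c("tangent", "gradient"),
                           normalize = TRUE) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  operator <- match.arg(operator)
  convention <- match.arg(convention)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3 for ", operator)
  ks <- kernels[[operator]]
  gx <- convolve2(image, ks$x)   # d/dx, x = columns
  gy <- convolve2(image, ks$y)   # d/dy, y = rows (downward)
  g <- sqrt(gx^2 + gy^2)
  # zap floating-point cancellation dust from flat regions: responses many
  # orders of magnitude below the intensity scale (or below the strongest
  # response) are rounding residue, not gradients
  floor_ <- max(1e-10 * max(abs(image)), 1e-12 * max(g))
  g[g <= floor_] <- 0
  theta <- if (convention == "tangent") {
    atan2(gx, gy) * 180 / pi
  } else {
    atan2(gy, gx) * 180 / pi
  }
  theta <- wrap_axial(theta)
  theta[g == 0] <- NA_real_
  gn <- if (normalize && any(g > 0)) normalize_magnitude(g) else g * 0
  structure(
    list(g = g, gn = gn, theta = theta, gx = gx, gy = gy,
         operator = operator, convention = convention, dim = dim(image)),
    class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("Gradient field (", x$operator, ", ", x$convention, " orientation): ",
      x$dim[1], " x ", x$dim[2], " pixels, ",
      sum(!is.na(x$theta)), " with defined orientation\n", sep = "")
  invisible(x)
}

#' Log min-max magnitude normalization
#'
#' Maps gradient magnitudes to \[0, 1] by a min-max rescaling of
#' `log(g)` over the positive magnitudes; the largest magnitude maps to 1,
#' the smallest positive magnitude to 0, and zero-magnitude pixels to 0.
#' Invariant to positive rescaling of `g`.  If all positive magnitudes are
#' equal the positive pixels map to 1 (with a warning).
#'
#' @param g non-negative matrix (or vector) with at least one positive value.
#' @param clip_percentiles optional `c(lo, hi)` percentiles (in \[0,100]) at
#'   which the log-magnitudes are clipped before rescaling.
#' @return matrix of the same shape with values in \[0, 1].
#' @export
normalize_magnitude <- function(g, clip_percentiles = NULL) {
  if (any(g < 0)) stop("magnitudes must be non-negative")
  pos <- g > 0
  if (!any(pos)) stop("degenerate input: all magnitudes are zero")
  lg <- log(g[pos])
  if (!is.null(clip_percentiles)) {
    q <- quantile(lg, clip_percentiles / 100, names = FALSE)
    lg <- pmin(pmax(lg, q[1]), q[2])
  }
  lo <- min(lg); hi <- max(lg)
  out <- g * 0
  if (hi == lo) {
    warning("constant positive magnitude; gn set to 1 on positive pixels")
    out[pos] <- 1
  } else {
    out[pos] <- pmin(pmax((lg - lo) / (hi - lo), 0), 1)
  }
  out
}

#' Select the class-splitting threshold tau
#'
#' The median (default) or mean of the normalized log-magnitude `gn` over
#' pixels with a defined orientation.  `tau` splits the orientation field
#' into the strong-gradient class (candidate contour material) and its
#' complement.
#'
#' @param x a `gradient_field`, or a numeric vector/matrix of `gn` values.
#' @param mode `"median"` or `"mean"`.
#' @return tau, strictly inside (0, 1).
#' @export
select_tau <- function(x, mode = c("median", "mean")) {
  mode <- match.arg(mode)
  v <- if (inherits(x, "gradient_field")) x$gn[!is.na(x$theta)] else as.numeric(x)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined-orientation pixels to compute tau over")
  tau <- if (mode == "median") median(v) else mean(v)
  if (!(tau > 0 && tau < 1))
    stop("degenerate input: tau = ", format(tau),
         " does not strictly separate the magnitude classes")
  tau
}

#' Build the pair of null-masked orientation feature maps
#'
#' `theta_tau` keeps the orientation only where `gn > tau` (strong-gradient
#' class); `theta_bar_tau` keeps it only where `gn <= tau`.  Pixels with
#' undefined orientation (zero gradient) are null in both.  The two non-null
#' supports partition the set of orientation-defined pixels.
#'
#' @param field a [gradient_field()].
#' @param tau threshold in (0, 1); default [select_tau()] of the field.
#' @param bn number of orientation bins (default 49, the 7x7 mask area).
#' @param tau_mode passed to [select_tau()] when `tau` is `NULL`.
#' @return object of class `feature_maps`: `theta` (raw), `theta_tau`,
#'   `theta_bar_tau`, `gn`, `tau`, `bn`, `bin_width`, `dim`.
#' @export
feature_maps <- function(field, tau = NULL, bn = 49L,
                         tau_mode = c("median", "mean")) {
  stopifnot(inherits(field, "gradient_field"))
  if (is.null(tau)) tau <- select_tau(field, match.arg(tau_mode))
  if (!(tau > 0 && tau < 1)) stop("tau must lie strictly in (0, 1)")
  bn <- as.integer(bn)
  if (bn < 1L) stop("bn must be a positive integer")
  th_t <- field$theta
  th_t[field$gn <= tau] <- NA_real_
  th_b <- field$theta
  th_b[field$gn > tau] <- NA_real_
  structure(
    list(theta = field$theta, theta_tau = th_t, theta_bar_tau = th_b,
         gn = field$gn, tau = tau, bn = bn, bin_width = 180 / bn,
         dim = field$dim),
    class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat("Feature maps: ", x$dim[1], " x ", x$dim[2],
      ", tau = ", signif(x$tau, 4),
      ", Bn = ", x$bn, " (bin width ", signif(x$bin_width, 4), " deg)\n",
      "  strong-gradient class: ", sum(!is.na(x$theta_tau)), " px",
      " | complement: ", sum(!is.na(x$theta_bar_tau)), " px\n", sep = "")
  invisible(x)
}

#' Two-plane array export of feature maps (NaN as the null sentinel)
#' @param x a `feature_maps` object.
#' @param ... unused.
#' @export
as.array.feature_maps <- function(x, ...) {
  a <- array(NaN, c(x$dim, 2L),
             dimnames = list(NULL, NULL, c("theta_tau", "theta_bar_tau")))
  a[, , 1] <- ifelse(is.na(x$theta_tau), NaN, x$theta_tau)
  a[, , 2] <- ifelse(is.na(x$theta_bar_tau), NaN, x$theta_bar_tau)
  a
}
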