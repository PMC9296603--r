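# EM-driven deformable/rotatable sampling mask -------------------------------

#' Entropy upper bound for Bn bins
#'
#' `-log(1/Bn)` in natural-log units; the Shannon entropy of any histogram
#' over `bn` bins is bounded above by this value, attained only when all
#' occupied bins are equal in height across all bins.
#'
#' @param bn number of bins (positive integer).
#' @return entropy bound in nats.
#' @export
entropy_upper_bound <- function(bn) {
  if (length(bn) != 1L || is.na(bn) || bn < 1)
    stop("bn must be a positive integer")
  log(bn)
}

#' Rasterize the rotated rectangular mask
#'
#' Pixels whose centers lie within the rectangle of half-extents `L/2` x
#' `W/2`, long axis at `phi` degrees (measured counterclockwise from the
#' column axis in display orientation), centered on `center`.  The target
#' pixel is always included; the footprint is clipped at the image borders.
#'
#' @param center `c(row, col)` of the target pixel.
#' @param L,W long/short axis lengths in pixels (`L` may be non-integer).
#' @param phi rotation in degrees.
#' @param dim image bounds `c(nrow, ncol)`.
#' @return integer matrix of (row, col) coordinates.
#' @export
rasterize_mask <- function(center, L, W, phi, dim) {
  stopifnot(L >= 1, W >= 1)
  rad <- ceiling(sqrt(L^2 + W^2) / 2)
  dr <- rep(-rad:rad, times = 2L * rad + 1L)
  dc <- rep(-rad:rad, each = 2L * rad + 1L)
  a <- phi * pi / 180
  # axis direction in (col, up) coordinates; rows grow downward
  du <- dc * cos(a) - dr * sin(a)
  dv <- dc * sin(a) + dr * cos(a)
  eps <- 1e-9
  inside <- abs(du) <= L / 2 + eps & abs(dv) <= W / 2 + eps
  rr <- center[1] + dr[inside]
  cc <- center[2] + dc[inside]
  keep <- rr >= 1L & rr <= dim[1] & cc >= 1L & cc <= dim[2]
  fp <- cbind(row = rr[keep], col = cc[keep])
  if (!any(fp[, 1] == center[1] & fp[, 2] == center[2]))
    fp <- rbind(fp, center)
  fp
}

#' Orientation histogram of a mask footprint
#'
#' Normalized bin heights of the orientations sampled from a (null-masked)
#' orientation map over the footprint.  Null samples are excluded from the
#' normalization; with no samples at all the histogram is all-zero.
#' The target bin is derived from the raw target orientation even when the
#' target itself is null in the sampled map.
#'
#' @param map orientation matrix with `NA` nulls.
#' @param footprint (row, col) coordinate matrix from [rasterize_mask()].
#' @param bn number of bins.
#' @param target_theta raw orientation of the target pixel (or `NA`).
#' @return object of class `orientation_histogram`: `heights` (length `bn`,
#'   summing to 1 when any sample), `n_samples`, `target_bin`, `h_t`,
#'   `h_max`, `h_min_pos`.
#' @export
orientation_histogram <- function(map, footprint, bn, target_theta = NA) {
  if (!nrow(footprint)) stop("footprint must be non-empty")
  smp <- map[footprint]
  smp <- smp[!is.na(smp)]
  n <- length(smp)
  heights <- if (n) tabulate(orientation_bin(smp, bn), bn) / n else numeric(bn)
  tb <- if (is.na(target_theta)) NA_integer_ else orientation_bin(target_theta, bn)
  pos <- heights[heights > 0]
  structure(
    list(heights = heights, n_samples = n, target_bin = tb,
         h_t = if (is.na(tb)) 0 else heights[tb],
         h_max = if (n) max(heights) else 0,
         h_min_pos = if (length(pos)) min(pos) else 0,
         bn = as.integer(bn)),
    class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat("Orientation histogram: ", x$n_samples, " samples over ", x$bn,
      " bins; h_T = ", signif(x$h_t, 4), ", h_max = ", signif(x$h_max, 4),
      "\n", sep = "")
  invisible(x)
}

#' Shannon entropy of an orientation histogram
#'
#' `-sum(h * log(h))` in nats over the occupied bins (empty bins contribute
#' zero).  An empty-sample histogram has entropy 0 by convention.
#'
#' @param hist an `orientation_histogram` (or a numeric vector of heights).
#' @return entropy in `[0, entropy_upper_bound(bn)]`.
#' @export
shannon_entropy <- function(hist) {
  h <- if (inherits(hist, "orientation_histogram")) hist$heights else hist
  h <- h[h > 0]
  if (!length(h)) return(0)
  -sum(h * log(h))
}

#' Gestalt (strong-gradient class) likelihood
#'
#' `p = alpha * (H_max - H) / H_max` with belief `alpha = h_T / h_max`: the
#' normalized entropy deficit (directivity) of the sampled orientations,
#' weighted by how strongly the target pixel's own bin participates in the
#' principal direction.  Degenerate cases (no samples, empty maximal bin,
#' undefined target bin) give 0.
#'
#' @param hist `orientation_histogram` sampled from the strong-gradient map.
#' @param bn bin count (defaults to the histogram's).
#' @return likelihood in \[0, 1].
#' @export
gestalt_likelihood <- function(hist, bn = hist$bn) {
  if (hist$n_samples == 0 || hist$h_max == 0 || is.na(hist$target_bin))
    return(0)
  alpha <- hist$h_t / hist$h_max
  hmax <- entropy_upper_bound(bn)
  p <- alpha * (hmax - shannon_entropy(hist)) / hmax
  min(max(p, 0), 1)
}

#' Non-gestalt (complement class) likelihood
#'
#' `p_bar = beta * H_bar / H_max` with `beta = h_min_pos / h_bar_T`: a
#' uniform (high-entropy) complement histogram whose target bin is occupied
#' supports the non-gestalt class.  `h_bar_T = 0` or an empty sample gives 0.
#'
#' @param hist `orientation_histogram` sampled from the complement map.
#' @param bn bin count (defaults to the histogram's).
#' @return likelihood in \[0, 1].
#' @export
nongestalt_likelihood <- function(hist, bn = hist$bn) {
  if (hist$n_samples == 0 || is.na(hist$target_bin) || hist$h_t == 0)
    return(0)
  beta <- hist$h_min_pos / hist$h_t
  p <- beta * shannon_entropy(hist) / entropy_upper_bound(bn)
  min(max(p, 0), 1)
}

#' Width update of the deformable mask
#'
#' `W = floor(r * (1 - p_t))` when the likelihood did not decrease (the mask
#' narrows and elongates), `W = ceiling(r * (1 - p_t))` when it decreased
#' (the mask widens), and 1 whenever the branch value would not exceed 1.
#' Always within `[1, ceiling(r)]`.
#'
#' @param p_t,p_prev current and previous likelihood in \[0, 1].
#' @param r `sqrt(Bn)`, the constant geometric scale of the mask.
#' @return integer width.
#' @export
update_width <- function(p_t, p_prev, r) {
  v <- r * (1 - p_t)
  w <- if (p_t >= p_prev && floor(v) > 1) {
    floor(v)
  } else if (p_t < p_prev && ceiling(v) > 1) {
    ceiling(v)
  } else 1
  as.integer(min(max(w, 1), ceiling(r)))
}

#' Length update: constant-area constraint
#'
#' `L = Bn / W`, so the footprint area (and bin budget) `L * W = Bn` is
#' invariant; `L` may be non-integer.
#'
#' @param bn bin/area budget.
#' @param w current width (>= 1).
#' @return length.
#' @export
update_length <- function(bn, w) {
  stopifnot(w >= 1)
  bn / w
}

#' Principal direction of an orientation histogram
#'
#' Center angle of the maximal bin.  Ties are broken toward the bin whose
#' center is angularly closest (mod 180) to `prev_phi`; with no previous
#' angle the lowest-index bin wins.  An empty histogram returns `NA`.
#'
#' @param hist an `orientation_histogram`.
#' @param prev_phi previous mask rotation in degrees, or `NULL`.
#' @return angle in degrees in \[-90, 90), or `NA`.
#' @export
principal_direction <- function(hist, prev_phi = NULL) {
  if (hist$n_samples == 0) return(NA_real_)
  mx <- which(hist$heights == max(hist$heights))
  ctr <- bin_center(mx, hist$bn)
  if (length(mx) > 1L && !is.null(prev_phi) && !is.na(prev_phi))
    ctr <- ctr[which.min(axial_dist(ctr, prev_phi))]
  wrap_axial(ctr[1])
}

#' Squared width residual of the Lyapunov objective
#' @param w mask width.
#' @param p likelihood.
#' @param r `sqrt(Bn)`.
#' @return `(w - r(1-p))^2`.
#' @export
objective_term <- function(w, p, r) (w - r * (1 - p))^2

#' Mean Lyapunov objective over a candidate set
#' @param terms per-target squared residuals.
#' @param n_cep number of candidate pixels (defaults to `length(terms)`).
#' @return mean squared residual.
#' @export
objective_value <- function(terms, n_cep = length(terms)) sum(terms) / n_cep

# one-step objective change, the sign-analysed quantity of the stability proof
delta_objective <- function(w, p_t, p_prev, r) {
  2 * r * (w - r * (1 - p_t)) * (p_t - p_prev)
}

#' Run the EM loop for one target pixel
#'
#' Starting from a square mask (`phi = 0`), each iteration samples the
#' strong-gradient orientation map over the current footprint, evaluates the
#' gestalt likelihood from the orientation histogram, updates the width by
#' [update_width()] (length via `L = Bn/W`), and rotates the long axis to
#' the histogram's principal direction.  Convergence is reached when the
#' width stops changing.  A second mask samples the complement map for the
#' non-gestalt likelihood, either with its own mirrored dynamics driven by
#' `p_bar` (default) or sharing the primary mask's geometry (`"shadow"`).
#'
#' @param fm a [feature_maps()] object.
#' @param target `c(row, col)` of the target pixel (inside bounds).
#' @param mask_size initial square mask side (default 7); the bin/area
#'   budget is `Bn = mask_size^2` (`bn_mode = "area"`) or a quarter of it.
#' @param bn_mode `"area"` or `"quarter"`.
#' @param max_iter iteration cap (default 50).
#' @param mbar `"mirror"` or `"shadow"` complement-mask dynamics.
#' @return object of class `em_mask`: converged likelihoods `p_c`,
#'   `p_bar_c`, `principal_direction`, final `L`, `W`, `phi`, `footprint`,
#'   `footprint_union`, per-iteration `trace` (t, L, W, phi, p, p_bar,
#'   term, delta_E), `converged`, `flag`.
#' @export
run_em <- function(fm, target, mask_size = 7L,
                   bn_mode = c("area", "quarter"), max_iter = 50L,
                   mbar = c("mirror", "shadow")) {
  stopifnot(inherits(fm, "feature_maps"))
  bn_mode <- match.arg(bn_mode)
  mbar <- match.arg(mbar)
  target <- as.integer(target)
  if (target[1] < 1L || target[1] > fm$dim[1] ||
      target[2] < 1L || target[2] > fm$dim[2])
    stop("target outside image bounds")
  bn <- if (bn_mode == "area") as.integer(mask_size)^2 else
    max(1L, as.integer(round(mask_size^2 / 4)))
  if (bn != fm$bn)
    warning("mask bin budget (", bn, ") differs from feature-map bn (",
            fm$bn, "); using ", bn)
  r <- sqrt(bn)
  target_theta <- fm$theta[target[1], target[2]]

  W0 <- as.integer(ceiling(r)); L0 <- bn / W0
  state <- list(L = L0, W = W0, phi = 0)
  base_trace <- data.frame(t = 0L, L = L0, W = W0, phi = 0, p = 0, p_bar = 0,
                           term = objective_term(W0, 0, r), delta_E = 0)

  if (is.na(target_theta)) {
    fp <- rasterize_mask(target, L0, W0, 0, fm$dim)
    return(structure(
      list(target = target, p_c = 0, p_bar_c = 0,
           principal_direction = NA_real_, L = L0, W = W0, phi = 0,
           bn = bn, r = r, footprint = fp, footprint_union = fp,
           trace = base_trace, iterations = 0L, converged = FALSE,
           flag = "null_theta"),
      class = "em_mask"))
  }

  p_prev <- 0; pbar_prev <- 0
  W_prev <- W0
  bar <- list(L = L0, W = W0, phi = 0)
  trace <- base_trace
  fp_union <- rasterize_mask(target, L0, W0, 0, fm$dim)
  flag <- "none"; converged <- FALSE
  phi <- 0; L <- L0; W <- W0
  hist <- NULL
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    fp <- rasterize_mask(target, L, W, phi, fm$dim)
    hist <- orientation_histogram(fm$theta_tau, fp, bn, target_theta)
    p_t <- gestalt_likelihood(hist, bn)
    fpb <- if (mbar == "shadow") fp else
      rasterize_mask(target, bar$L, bar$W, bar$phi, fm$dim)
    histb <- orientation_histogram(fm$theta_bar_tau, fpb, bn, target_theta)
    pbar_t <- nongestalt_likelihood(histb, bn)

    W_t <- update_width(p_t, p_prev, r)
    L_t <- update_length(bn, W_t)
    phi_new <- principal_direction(hist, phi)
    if (is.na(phi_new)) phi_new <- phi
    trace <- rbind(trace, data.frame(
      t = t, L = L_t, W = W_t, phi = phi_new, p = p_t, p_bar = pbar_t,
      term = objective_term(W_t, p_t, r),
      delta_E = delta_objective(W_t, p_t, p_prev, r)))
    fp_union <- unique(rbind(fp_union, fp))

    if (mbar == "mirror") {
      Wb <- update_width(pbar_t, pbar_prev, r)
      bar <- list(L = update_length(bn, Wb), W = Wb,
                  phi = {
                    pb <- principal_direction(histb, bar$phi)
                    if (is.na(pb)) bar$phi else pb
                  })
    }

    if (W_t == W_prev) {
      converged <- TRUE
      L <- L_t; W <- W_t; phi <- phi_new
      p_prev <- p_t; pbar_prev <- pbar_t
      break
    }
    # period-2 width oscillation: keep the state with the larger likelihood
    nt <- nrow(trace)
    if (nt >= 4L && trace$W[nt] == trace$W[nt - 2L] &&
        trace$W[nt] != trace$W[nt - 1L] &&
        trace$W[nt - 1L] == if (nt >= 4L) trace$W[nt - 3L] else NA) {
      pick <- if (trace$p[nt] >= trace$p[nt - 1L]) nt else nt - 1L
      L <- trace$L[pick]; W <- trace$W[pick]; phi <- trace$phi[pick]
      p_prev <- trace$p[pick]; pbar_prev <- trace$p_bar[pick]
      converged <- TRUE
      flag <- "oscillation"
      break
    }
    W_prev <- W_t
    L <- L_t; W <- W_t; phi <- phi_new
    p_prev <- p_t; pbar_prev <- pbar_t
  }
  if (!converged && t >= max_iter) flag <- "max_iter"
  final_fp <- rasterize_mask(target, L, W, phi, fm$dim)
  fp_union <- unique(rbind(fp_union, final_fp))
  structure(
    list(target = target, p_c = p_prev, p_bar_c = pbar_prev,
         principal_direction = phi, L = L, W = W, phi = phi,
         bn = bn, r = r, footprint = final_fp, footprint_union = fp_union,
         trace = trace, iterations = t, converged = converged, flag = flag),
    class = "em_mask")
}

#' @export
print.em_mask <- function(x, ...) {
  cat("EM mask at (", x$target[1], ", ", x$target[2], "): ",
      if (x$converged) "converged" else "iteration cap",
      " after ", x$iterations, " iteration(s)\n",
      "  p_c = ", signif(x$p_c, 4), ", p_bar_c = ", signif(x$p_bar_c, 4),
      ", L = ", signif(x$L, 4), ", W = ", x$W,
      ", phi = ", signif(x$phi, 4), " deg",
      if (x$flag != "none") paste0(" [", x$flag, "]"), "\n", sep = "")
  invisible(x)
}

#' Export an EM trace as line-delimited records
#' @param x an `em_mask`.
#' @param path output file (one `t L W phi p p_bar term delta_E` record per
#'   line, tab-separated, with header).
#' @export
write_em_trace <- function(x, path) {
  stopifnot(inherits(x, "em_mask"))
  write.table(x$trace, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
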