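# Bayes classification and pipeline orchestration ----------------------------

#' Posterior probability of the gestalt class
#'
#' Bayes rule with the normalized log-magnitude as the prior:
#' `p(gestalt) = p_c * gn / (p_c * gn + p_bar_c * (1 - gn))`.  A zero
#' denominator (both weighted likelihoods vanish) yields posterior 0 — the
#' target carries no evidence for the gestalt class.
#'
#' @param p_c,p_bar_c converged class likelihoods in \[0, 1] (vectorized).
#' @param gn normalized gradient magnitude prior in \[0, 1].
#' @return numeric matrix with columns `gestalt`, `non_gestalt` summing to 1.
#' @export
posterior_gestalt <- function(p_c, p_bar_c, gn) {
  num <- p_c * gn
  den <- num + p_bar_c * (1 - gn)
  p <- ifelse(den > 0, num / den, 0)
  cbind(gestalt = p, non_gestalt = 1 - p)
}

#' Threshold classification of a posterior
#'
#' Gestalt iff `posterior >= k`.  The useful range of `k` is 0.4–0.9; values
#' outside it trigger a warning.  `k = 0.5` is the Bayes-optimal choice.
#'
#' @param p_omega posterior probability (vectorized).
#' @param k decision threshold.
#' @return character vector `"gestalt"`/`"non_gestalt"`.
#' @export
classify_gestalt <- function(p_omega, k = 0.5) {
  if (k < 0.4 || k > 0.9)
    warning("k = ", k, " outside the recommended range [0.4, 0.9]")
  ifelse(p_omega >= k, "gestalt", "non_gestalt")
}

#' Co-label footprint pixels aligned with an accepted target
#'
#' Pixels of the converged footprint whose strong-gradient orientation falls
#' in the target's bin lie on the same line or curve (continuity law) and
#' are marked gestalt without running EM on them.
#'
#' @param cm a converged [run_em()] result for an accepted target.
#' @param fm the [feature_maps()] the mask was run on.
#' @return (row, col) matrix of co-labeled pixels (target excluded).
#' @export
co_label <- function(cm, fm) {
  stopifnot(inherits(cm, "em_mask"), inherits(fm, "feature_maps"))
  tb <- orientation_bin(fm$theta[cm$target[1], cm$target[2]], fm$bn)
  if (is.na(tb)) return(cbind(row = integer(0), col = integer(0)))
  fp <- cm$footprint
  th <- fm$theta_tau[fp]
  ok <- !is.na(th) & orientation_bin(th, fm$bn) == tb
  out <- fp[ok, , drop = FALSE]
  out[!(out[, 1] == cm$target[1] & out[, 2] == cm$target[2]), , drop = FALSE]
}

#' Extract perceptual contours from a grayscale image
#'
#' The full extractor: prefilter, gradient features and feature maps,
#' candidate edge pixels (Canny unless supplied), then for each candidate in
#' raster order the EM mask probes the principal direction, the Bayes rule
#' classifies the converged likelihoods, and accepted targets co-label the
#' aligned pixels of their converged footprint.  Deterministic given the
#' image and configuration.
#'
#' @param image numeric matrix in \[0, 1], or a file path readable by
#'   [read_gray_image()].
#' @param h_t,l_t,sigma Canny parameters (see [canny_cep()]).
#' @param k Bayes decision threshold (default 0.5).
#' @param mask_size initial mask side (default 7).
#' @param bn_mode `"area"` (default, `Bn = mask_size^2`) or `"quarter"`.
#' @param prefilter_kind `"gaussian"` (default), `"median"` or `"none"`.
#' @param prefilter_param smoothing scale / window, see [prefilter()].
#' @param tau_mode `"median"` or `"mean"` (see [select_tau()]).
#' @param tau override for the class-splitting threshold.
#' @param quantize_bits intensity quantization applied after the prefilter
#'   (default 8, i.e. 256 grey levels; `NULL` disables).  Gradient
#'   magnitudes below one grey level are measurement noise, and anchoring
#'   the log-magnitude normalization on such dust would compress all real
#'   structure into the top of the `gn` scale; quantization gives synthetic
#'   floating-point scenes the same magnitude floor an 8-bit photograph has.
#' @param cep optional externally supplied `cep_set` (skips Canny).
#' @param operator gradient operator for the feature maps.
#' @param mbar complement-mask dynamics, see [run_em()].
#' @param max_iter EM iteration cap per target.
#' @return object of class `gestalt_contours` with elements `gestalt_map`
#'   (logical matrix), `posterior_map` (`NA` where not EM-processed),
#'   `mask_store` (data frame: row, col, phi, L, W, p_c, p_bar_c, posterior,
#'   method), `stats` (n_cep, processed, accepted, rejected, co_labeled),
#'   `objective` (mean converged squared residual), plus the intermediate
#'   `cep`, `fm` and configuration.
#' @export
gestalt_contours <- function(image,
                             h_t = 0.2, l_t = 0.4 * h_t, sigma = sqrt(2),
                             k = 0.5, mask_size = 7L,
                             bn_mode = c("area", "quarter"),
                             prefilter_kind = c("gaussian", "median", "none"),
                             prefilter_param = NULL,
                             tau_mode = c("median", "mean"), tau = NULL,
                             quantize_bits = 8L,
                             cep = NULL,
                             operator = "sobel",
                             mbar = c("mirror", "shadow"),
                             max_iter = 50L) {
  if (is.character(image)) image <- read_gray_image(image)
  bn_mode <- match.arg(bn_mode)
  prefilter_kind <- match.arg(prefilter_kind)
  tau_mode <- match.arg(tau_mode)
  mbar <- match.arg(mbar)
  cfg <- list(h_t = h_t, l_t = l_t, sigma = sigma, k = k,
              mask_size = mask_size, bn_mode = bn_mode,
              prefilter = prefilter_kind, prefilter_param = prefilter_param,
              tau_mode = tau_mode, operator = operator, mbar = mbar,
              max_iter = max_iter)
  bn <- if (bn_mode == "area") as.integer(mask_size)^2 else
    max(1L, as.integer(round(mask_size^2 / 4)))

  img <- prefilter(image, prefilter_kind, prefilter_param)
  if (!is.null(quantize_bits)) {
    # integer grey levels: gradients of flat regions are then exactly zero
    img <- round(img * (2^quantize_bits - 1))
  }
  field <- gradient_field(img, operator = operator)
  fm <- feature_maps(field, tau = tau, bn = bn, tau_mode = tau_mode)
  if (is.null(cep)) cep <- canny_cep(img, h_t = h_t, l_t = l_t, sigma = sigma)
  if (!identical(cep$dim, dim(image)) && !identical(cep$dim, as.integer(dim(image))))
    stop("candidate set bounds do not match the image")

  n_cep <- nrow(cep$pixels)
  gmap <- matrix(FALSE, fm$dim[1], fm$dim[2])
  pmap <- matrix(NA_real_, fm$dim[1], fm$dim[2])
  status <- matrix(0L, fm$dim[1], fm$dim[2]) # 1 accept, 2 reject, 3 co-label
  store <- vector("list", n_cep)
  terms <- numeric(0)
  if (n_cep == 0L) warning("empty candidate set; nothing to classify")

  for (i in seq_len(n_cep)) {
    rc <- cep$pixels[i, ]
    if (status[rc[1], rc[2]] != 0L) next
    cm <- run_em(fm, rc, mask_size = mask_size, bn_mode = bn_mode,
                 max_iter = max_iter, mbar = mbar)
    po <- posterior_gestalt(cm$p_c, cm$p_bar_c, fm$gn[rc[1], rc[2]])[1, 1]
    pmap[rc[1], rc[2]] <- po
    terms <- c(terms, objective_term(cm$W, cm$p_c, cm$r))
    if (cm$flag != "null_theta" && classify_gestalt(po, k) == "gestalt") {
      status[rc[1], rc[2]] <- 1L
      gmap[rc[1], rc[2]] <- TRUE
      store[[i]] <- data.frame(row = rc[1], col = rc[2], phi = cm$phi,
                               L = cm$L, W = cm$W, p_c = cm$p_c,
                               p_bar_c = cm$p_bar_c, posterior = po,
                               method = "em")
      cl <- co_label(cm, fm)
      if (nrow(cl)) {
        pending <- status[cl] == 0L
        cl <- cl[pending, , drop = FALSE]
        if (nrow(cl)) {
          # only candidate pixels may enter the contour map
          cmap <- cep_to_map(cep)
          keep <- cmap[cl]
          cl <- cl[keep, , drop = FALSE]
          if (nrow(cl)) {
            status[cl] <- 3L
            gmap[cl] <- TRUE
            store[[i]] <- rbind(store[[i]], data.frame(
              row = cl[, 1], col = cl[, 2], phi = cm$phi, L = cm$L,
              W = cm$W, p_c = cm$p_c, p_bar_c = cm$p_bar_c,
              posterior = NA_real_, method = "colabel"))
          }
        }
      }
    } else {
      status[rc[1], rc[2]] <- 2L
    }
  }
  cmap <- cep_to_map(cep)
  stats <- list(n_cep = n_cep,
                processed = sum(status[cmap] %in% c(1L, 2L)),
                accepted = sum(status[cmap] == 1L),
                rejected = sum(status[cmap] == 2L),
                co_labeled = sum(status[cmap] == 3L))
  structure(
    list(gestalt_map = gmap, posterior_map = pmap,
         mask_store = do.call(rbind, store[!vapply(store, is.null, TRUE)]),
         stats = stats,
         objective = if (length(terms)) objective_value(terms) else NA_real_,
         cep = cep, fm = fm, config = cfg, dim = dim(image)),
    class = "gestalt_contours")
}

#' @export
print.gestalt_contours <- function(x, ...) {
  s <- x$stats
  cat("Gestalt contour extraction on a ", x$dim[1], " x ", x$dim[2],
      " image\n", sep = "")
  cat("  candidates: ", s$n_cep, " | accepted: ", s$accepted,
      " | co-labeled: ", s$co_labeled, " | rejected: ", s$rejected, "\n",
      sep = "")
  cat("  screening rate: ",
      if (s$n_cep) sprintf("%.1f%%", screening_rate(s$n_cep, sum(x$gestalt_map)))
      else "n/a", "\n", sep = "")
  invisible(x)
}

#' @export
summary.gestalt_contours <- function(object, ...) {
  s <- object$stats
  out <- list(
    dim = object$dim, config = object$config, stats = s,
    screening_rate = if (s$n_cep)
      screening_rate(s$n_cep, sum(object$gestalt_map)) else NA_real_,
    objective = object$objective,
    tau = object$fm$tau,
    posterior = summary(object$posterior_map[!is.na(object$posterior_map)]))
  class(out) <- "summary.gestalt_contours"
  out
}

#' @export
print.summary.gestalt_contours <- function(x, ...) {
  cat("Gestalt contour extraction (", x$dim[1], " x ", x$dim[2], ")\n",
      sep = "")
  cat("  tau = ", signif(x$tau, 4), ", k = ", x$config$k,
      ", H_t = ", x$config$h_t, ", mask ", x$config$mask_size, "x",
      x$config$mask_size, " (", x$config$bn_mode, ")\n", sep = "")
  s <- x$stats
  cat("  candidates ", s$n_cep, ": accepted ", s$accepted, ", co-labeled ",
      s$co_labeled, ", rejected ", s$rejected, "\n", sep = "")
  cat("  screening rate ", sprintf("%.1f%%", x$screening_rate),
      "; mean Lyapunov residual ", signif(x$objective, 4), "\n", sep = "")
  cat("  posterior over processed pixels:\n")
  print(x$posterior)
  invisible(x)
}

#' Plot extracted contours
#'
#' Displays the input-size contour map (black on white); optionally the
#' posterior map.
#'
#' @param x a `gestalt_contours` object.
#' @param which `"contours"` or `"posterior"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gestalt_contours <- function(x, which = c("contours", "posterior"), ...) {
  which <- match.arg(which)
  m <- if (which == "contours") 1 - x$gestalt_map else {
    p <- x$posterior_map
    p[is.na(p)] <- 0
    1 - p
  }
  image(t(m)[, nrow(m):1], col = gray(seq(0, 1, length.out = 256)),
        asp = nrow(m) / ncol(m), axes = FALSE, ...)
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Contour map as 1-bit PNG/PGM, optional posterior map as 16-bit PNG, and
#' the converged-mask store as a tab-separated table.
#'
#' @param x a `gestalt_contours` object.
#' @param contours,posterior,mask_store output paths (`NULL` to skip).
#' @export
write_contours <- function(x, contours = NULL, posterior = NULL,
                           mask_store = NULL) {
  stopifnot(inherits(x, "gestalt_contours"))
  if (!is.null(contours)) write_edge_map(x$gestalt_map, contours)
  if (!is.null(posterior)) {
    p <- x$posterior_map
    p[is.na(p)] <- 0
    EBImage::writeImage(EBImage::Image(t(p)), posterior, bits.per.sample = 16L)
  }
  if (!is.null(mask_store) && !is.null(x$mask_store))
    write.table(x$mask_store, mask_store, sep = "\t", row.names = FALSE,
                quote = FALSE)
  invisible(x)
}
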