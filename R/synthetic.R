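# synthetic fixtures: orientation fields, shape scenes, noise models ---------

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Worked mask-content fixtures
#'
#' The four converged-mask contents used in the qualitative analysis of the
#' likelihood, with `Bn = 49`:
#' * `"a"` — 49 samples spread one per bin (exactly uniform heights, so the
#'   entropy attains its bound and the likelihood is 0);
#' * `"b"` — 18 samples, 15 in one bin and 3 in the target pixel's bin
#'   (belief 0.2, likelihood about 0.177);
#' * `"c"` — the same 15/3 split with the target in the majority bin
#'   (belief 1, likelihood about 0.884);
#' * `"d"` — all samples share the target's bin (likelihood exactly 1).
#'
#' @param case `"a"`, `"b"`, `"c"` or `"d"`.
#' @return list with `map` (orientation matrix), `footprint`, `target`
#'   coordinates, `target_theta`, `bn`.
#' @export
fig6_fixture <- function(case = c("a", "b", "c", "d")) {
  case <- match.arg(case)
  bn <- 49L
  major <- 0   # "->" majority direction
  minor <- 80  # "up-ish" minority direction (a different bin)
  if (case == "a") {
    ang <- bin_center(1:bn, bn)
    map <- matrix(ang, nrow = 7, ncol = 7)
    fp <- as.matrix(expand.grid(row = 1:7, col = 1:7))
    target <- c(4L, 4L)
  } else if (case == "d") {
    map <- matrix(major, nrow = 2, ncol = 9)
    fp <- as.matrix(expand.grid(row = 1:2, col = 1:9))
    target <- c(1L, 5L)
  } else {
    # 18-pixel footprint: 15 at the majority angle, 3 at the minority angle
    vals <- c(rep(major, 15), rep(minor, 3))
    map <- matrix(vals, nrow = 2, ncol = 9)
    fp <- as.matrix(expand.grid(row = 1:2, col = 1:9))
    target <- if (case == "c") c(1L, 1L) else c(2L, 9L)
  }
  colnames(fp) <- c("row", "col")
  list(map = map, footprint = fp, target = target,
       target_theta = map[target[1], target[2]], bn = bn)
}

#' Orientation field with a planted line
#'
#' A square orientation field in which the pixels of a straight line through
#' the center, at the given axial angle, carry that angle; the remaining
#' pixels carry either a constant angle or independent uniform angles.
#'
#' @param angle planted axial angle in degrees, in \[-90, 90).
#' @param extent field side length in pixels (odd recommended).
#' @param background `"random"` (uniform in \[-90, 90)) or `"constant"`.
#' @param bg_angle background angle for `background = "constant"`
#'   (default 90, i.e. the axial direction -90).
#' @param seed RNG seed for the random background.
#' @return list with `field` (orientation matrix), `line_mask` (logical
#'   support of the planted line), `angle`, `center`.
#' @export
line_field <- function(angle, extent = 31L, background = c("random", "constant"),
                       bg_angle = 90, seed = NULL) {
  background <- match.arg(background)
  if (angle < -90 || angle >= 90) stop("angle must lie in [-90, 90)")
  n <- as.integer(extent)
  ctr <- (n + 1) / 2
  field <- with_seed(seed, {
    if (background == "random")
      matrix(runif(n * n, -90, 90), n, n)
    else matrix(wrap_axial(bg_angle), n, n)
  })
  # width-1 digital line through the center at the planted angle:
  # step along the major axis, round the minor coordinate
  a <- angle * pi / 180
  dx <- cos(a); dy <- -sin(a)          # (col, row) step; rows grow downward
  mask <- matrix(FALSE, n, n)
  tmax <- ceiling(sqrt(2) * n)
  for (t in seq(-tmax, tmax, by = 0.5)) {
    r <- round(ctr + t * dy); c <- round(ctr + t * dx)
    if (r >= 1 && r <= n && c >= 1 && c <= n) mask[r, c] <- TRUE
  }
  field[mask] <- angle
  list(field = field, line_mask = mask, angle = angle,
       center = c(ctr, ctr))
}

#' Wrap a raw orientation field as feature maps
#'
#' Builds a [feature_maps()]-compatible object directly from an orientation
#' field, assigning the pixels of `strong_mask` (e.g. a planted contour) to
#' the strong-gradient map and the rest to the complement map — the same
#' split the tau threshold produces on a real image.  With
#' `strong_mask = NULL` every pixel goes to the strong-gradient map.
#'
#' @param field orientation matrix (degrees, `NA` = undefined).
#' @param strong_mask logical matrix or `NULL`.
#' @param bn number of orientation bins.
#' @param gn_strong,gn_weak normalized-magnitude prior assigned to the two
#'   classes (used by the Bayes stage).
#' @return a `feature_maps` object.
#' @export
field_feature_maps <- function(field, strong_mask = NULL, bn = 49L,
                               gn_strong = 0.9, gn_weak = 0.2) {
  stopifnot(is.matrix(field))
  if (is.null(strong_mask)) strong_mask <- !is.na(field)
  stopifnot(identical(dim(strong_mask), dim(field)))
  th_t <- field; th_t[!strong_mask] <- NA_real_
  th_b <- field; th_b[strong_mask] <- NA_real_
  gn <- matrix(gn_weak, nrow(field), ncol(field))
  gn[strong_mask] <- gn_strong
  gn[is.na(field)] <- 0
  tau <- (gn_strong + gn_weak) / 2
  structure(
    list(theta = field, theta_tau = th_t, theta_bar_tau = th_b,
         gn = gn, tau = tau, bn = as.integer(bn), bin_width = 180 / bn,
         dim = dim(field)),
    class = "feature_maps")
}

#' Piecewise-constant scene with exact contour ground truth
#'
#' Renders filled shapes (later shapes occlude earlier ones) on a constant
#' background and returns the exact boundary ground truth: pixels of a
#' visible shape with a 4-neighbor in a different region.  Ground truth is
#' constructed, never detected.
#'
#' @param shapes list of shape specs: `list(kind = "rect", r0, c0, r1, c1,
#'   intensity)`, `list(kind = "disc", row, col, radius, intensity)`, or
#'   `list(kind = "texture", r0, c0, r1, c1, base, amp)` — a clutter patch
#'   of i.i.d. uniform texture in `base + [0, amp]`; texture patches carry
#'   no ground-truth contour (they emulate grass-like clutter a human
#'   observer does not group into an object boundary).
#' @param size scene side length or `c(nrow, ncol)`.
#' @param background background intensity (default 0).
#' @param shading amplitude of a smooth horizontal illumination gradient
#'   blended into the scene (default 0.15; 0 disables).  Real scenes are
#'   piecewise smooth, not piecewise constant: without shading the gradient
#'   magnitudes of a rendered scene collapse onto a few discrete values and
#'   the median-based class threshold can tie with the contour magnitude
#'   itself, a degeneracy natural images do not exhibit.
#' @param noise optional noise spec `list(kind, param)` applied via
#'   [add_noise()].
#' @param seed RNG seed (for the noise).
#' @return object of class `synthetic_scene`: `image`, `gt_contours`
#'   (logical), `labels`, `noise_spec`, `seed`.
#' @export
shape_scene <- function(shapes = list(), size = 64L, background = 0,
                        shading = 0.15, noise = NULL, seed = NULL) {
  size <- rep(as.integer(size), length.out = 2L)
  img <- matrix(background, size[1], size[2])
  lab <- matrix(0L, size[1], size[2])
  tex_seed <- if (is.null(seed)) NULL else seed + 1L
  for (i in seq_along(shapes)) {
    sp <- shapes[[i]]
    if (identical(sp$kind, "texture")) {
      m <- matrix(FALSE, size[1], size[2])
      m[sp$r0:sp$r1, sp$c0:sp$c1] <- TRUE
      img[m] <- with_seed(tex_seed,
                          (sp$base %||% background) + sp$amp * runif(sum(m)))
      next  # clutter: no region label, no ground-truth contour
    }
    sel <- switch(sp$kind,
      rect = {
        m <- matrix(FALSE, size[1], size[2])
        m[sp$r0:sp$r1, sp$c0:sp$c1] <- TRUE
        m
      },
      disc = {
        rr <- row(img) - sp$row; cc <- col(img) - sp$col
        rr^2 + cc^2 <= sp$radius^2
      },
      stop("unknown shape kind: ", sp$kind))
    img[sel] <- sp$intensity
    lab[sel] <- i
  }
  # boundary: visible shape pixel with a 4-neighbor in a different region
  pad <- function(m, dr, dc) {
    out <- matrix(-1L, size[1], size[2])
    rs <- max(1, 1 + dr):min(size[1], size[1] + dr)
    cs <- max(1, 1 + dc):min(size[2], size[2] + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  gt <- matrix(FALSE, size[1], size[2])
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    gt <- gt | (lab != pad(lab, d[1], d[2]) & pad(lab, d[1], d[2]) >= 0L)
  gt <- gt & lab > 0L
  if (shading > 0)
    img <- img * (1 - shading) + shading * (col(img) / size[2])
  if (!is.null(noise))
    img <- add_noise(img, noise$kind, noise$param, seed = seed)
  structure(list(image = img, gt_contours = gt, labels = lab,
                 noise_spec = noise, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("Synthetic scene ", nrow(x$image), " x ", ncol(x$image), ": ",
      sum(x$gt_contours), " ground-truth contour pixels",
      if (!is.null(x$noise_spec))
        paste0(" (+", x$noise_spec$kind, " noise)"), "\n", sep = "")
  invisible(x)
}

#' Add Gaussian or impulsive noise
#'
#' Gaussian: zero-mean additive noise of the given variance, intensities
#' clipped to \[0, 1].  Impulse (salt-and-pepper): exactly
#' `round(frac * n)` pixels replaced by extreme values, half white and half
#' black.
#'
#' @param image numeric matrix in \[0, 1].
#' @param kind `"gaussian"` or `"impulse"`.
#' @param param noise variance (gaussian, default 0.01) or corrupted
#'   fraction (impulse, default 0.1).
#' @param seed RNG seed for reproducibility.
#' @return noisy matrix, same shape.
#' @export
add_noise <- function(image, kind = c("gaussian", "impulse"), param = NULL,
                      seed = NULL) {
  kind <- match.arg(kind)
  n <- length(image)
  if (kind == "gaussian") {
    v <- param %||% 0.01
    if (v <= 0) stop("gaussian variance must be positive")
    out <- with_seed(seed, image + rnorm(n, 0, sqrt(v)))
    return(matrix(pmin(pmax(out, 0), 1), nrow(image), ncol(image)))
  }
  frac <- param %||% 0.1
  if (frac <= 0 || frac > 1) stop("impulse fraction must lie in (0, 1]")
  m <- round(frac * n)
  with_seed(seed, {
    idx <- sample.int(n, m)
    out <- image
    nw <- ceiling(m / 2)
    out[idx[seq_len(nw)]] <- 1
    if (m > nw) out[idx[(nw + 1):m]] <- 0
    out
  })
}
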