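# candidate edge pixels ------------------------------------------------------

new_cep <- function(pixels, dim, source, params = list()) {
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels)) {
    ok <- pixels[, 1] >= 1L & pixels[, 1] <= dim[1] &
      pixels[, 2] >= 1L & pixels[, 2] <= dim[2]
    if (!all(ok)) stop("candidate coordinates outside image bounds")
    pixels <- pixels[order(pixels[, 1], pixels[, 2]), , drop = FALSE]
    pixels <- unique(pixels)
  }
  structure(list(pixels = pixels, dim = as.integer(dim),
                 source = source, params = params),
            class = "cep_set")
}

#' @export
print.cep_set <- function(x, ...) {
  cat("Candidate edge pixels: ", nrow(x$pixels), " px on a ",
      x$dim[1], " x ", x$dim[2], " grid [", paste(x$source, collapse = "+"),
      "]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.cep_set <- function(x, ...) x$pixels

#' Binary edge-map view of a candidate set
#' @param cep a `cep_set`.
#' @return logical matrix.
#' @export
cep_to_map <- function(cep) {
  m <- matrix(FALSE, cep$dim[1], cep$dim[2])
  if (nrow(cep$pixels)) m[cep$pixels] <- TRUE
  m
}

# 8-connected hysteresis: keep weak components seeded by a strong pixel
hysteresis8 <- function(strong, weak) {
  keep <- strong
  repeat {
    grown <- keep
    n <- nrow(keep)
    m <- ncol(keep)
    z <- matrix(FALSE, n, m)
    nb <- z
    sh <- function(dr, dc) {
      out <- z
      rs <- max(1, 1 + dr):min(n, n + dr)
      cs <- max(1, 1 + dc):min(m, m + dc)
      out[rs, cs] <- keep[rs - dr, cs - dc]
      out
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb | sh(dr, dc)
    }
    grown <- keep | (weak & nb)
    if (identical(grown, keep)) break
    keep <- grown
  }
  keep
}

#' Canny candidate edge pixels
#'
#' Standard Canny detector used as the candidate generator: Gaussian
#' smoothing at `sigma`, Sobel gradients, four-sector non-maximum
#' suppression, then dual-threshold hysteresis with 8-connected edge
#' tracking.  Thresholds are interpreted on the gradient magnitude linearly
#' normalized to \[0, 1] by its maximum.
#'
#' @param image numeric matrix.
#' @param h_t high threshold in (0, 1); default 0.2.
#' @param l_t low threshold in (0, `h_t`); default `0.4 * h_t`.
#' @param sigma Gaussian smoothing scale; default `sqrt(2)`.
#' @return a `cep_set`; empty (no error) on a blank image.
#' @export
canny_cep <- function(image, h_t = 0.2, l_t = 0.4 * h_t, sigma = sqrt(2)) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  if (!(h_t > 0 && h_t < 1) || !(l_t > 0 && l_t < h_t))
    stop("thresholds must satisfy 0 < l_t < h_t < 1")
  params <- list(h_t = h_t, l_t = l_t, sigma = sigma)
  sm <- gaussian_blur(image, sigma)
  gx <- convolve2(sm, kernels$sobel$x)
  gy <- convolve2(sm, kernels$sobel$y)
  g <- sqrt(gx^2 + gy^2)
  g[g <= 1e-10 * max(abs(sm))] <- 0   # cancellation dust from flat regions
  mx <- max(g)
  if (mx == 0) return(new_cep(matrix(integer(0), 0, 2), dim(image),
                              "canny", params))
  gn <- g / mx
  # non-maximum suppression along the (quantized) gradient direction
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  n <- nrow(g); m <- ncol(g)
  gp <- pad_reflect(g, 1L, 1L)
  at <- function(dr, dc) gp[(2 + dr):(1 + dr + n), (2 + dc):(1 + dc + m)]
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  nmax <- matrix(FALSE, n, m)
  # gradient along x -> compare left/right; along y -> up/down; diagonals
  cmp <- list(`0` = list(c(0L, 1L), c(0L, -1L)),
              `90` = list(c(1L, 0L), c(-1L, 0L)),
              `45` = list(c(1L, 1L), c(-1L, -1L)),
              `135` = list(c(1L, -1L), c(-1L, 1L)))
  for (s in names(cmp)) {
    a <- at(cmp[[s]][[1]][1], cmp[[s]][[1]][2])
    b <- at(cmp[[s]][[2]][1], cmp[[s]][[2]][2])
    nmax <- nmax | (sector == as.integer(s) & g >= a & g >= b)
  }
  strong <- nmax & gn >= h_t
  weak <- nmax & gn >= l_t
  keep <- hysteresis8(strong, weak)
  new_cep(which(keep, arr.ind = TRUE), dim(image), "canny", params)
}

#' Wrap an external binary edge map as a candidate set
#'
#' Any low-level detector (Gabor energy, Sobel thresholding, ...) can supply
#' candidates; combine with [union_cep()].
#'
#' @param edge_map logical/0-1 matrix.
#' @param dim expected image bounds (defaults to the map's own).
#' @return a `cep_set` tagged `"external"`.
#' @export
external_cep <- function(edge_map, dim = base::dim(edge_map)) {
  if (!is.matrix(edge_map)) stop("edge_map must be a matrix")
  if (!identical(base::dim(edge_map), as.integer(dim)) &&
      !identical(base::dim(edge_map), dim))
    stop("edge map shape does not match the working image")
  new_cep(which(edge_map != 0, arr.ind = TRUE), base::dim(edge_map),
          "external")
}

#' Union of two candidate sets
#'
#' @param a,b `cep_set`s over the same image bounds.
#' @return their union; provenance tags are concatenated.
#' @export
union_cep <- function(a, b) {
  stopifnot(inherits(a, "cep_set"), inherits(b, "cep_set"))
  if (!identical(a$dim, b$dim)) stop("candidate sets have different bounds")
  new_cep(rbind(a$pixels, b$pixels), a$dim,
          unique(c(a$source, b$source)), a$params)
}
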