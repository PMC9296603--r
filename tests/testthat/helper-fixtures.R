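# shared fixtures, all generated in code

# intensity ramps along columns / rows
ramp_cols <- function(n = 9, step = 1) matrix(rep(seq_len(n) * step, each = n), n, n)
ramp_rows <- function(n = 9, step = 1) matrix(rep(seq_len(n) * step, times = n), n, n)

# isotropic random orientation field wrapped as feature maps; about
# `density` of the pixels carry strong-gradient (theta_tau) orientations
random_field_fm <- function(seed, n = 25, density = 0.6) {
  set.seed(seed)
  field <- matrix(runif(n * n, -90, 90), n, n)
  strong <- matrix(runif(n * n) < density, n, n)
  field_feature_maps(field, strong)
}

# the square-object scene used throughout the pipeline tests: a filled
# square spanning the central half of the frame
square_scene <- function(size = 96, noise = NULL, seed = NULL, ...) {
  lo <- round(size * 0.26); hi <- round(size * 0.75)
  shape_scene(list(list(kind = "rect", r0 = lo, c0 = lo, r1 = hi, c1 = hi,
                        intensity = 1)),
              size = size, noise = noise, seed = seed, ...)
}

# noise-screening study scene: a square object over a grass-like texture
# clutter strip (no ground-truth contour), plus 10% impulsive noise
noisy_clutter_scene <- function(seed) {
  shape_scene(list(
    list(kind = "rect", r0 = 25, c0 = 33, r1 = 72, c1 = 80, intensity = 0.95),
    list(kind = "texture", r0 = 4, c0 = 4, r1 = 93, c1 = 28,
         base = 0.05, amp = 0.5)),
    size = 96, background = 0.1, shading = 0,
    noise = list(kind = "impulse", param = 0.1), seed = seed)
}

mq_f1_of <- function(dp, gt, d0 = 1) {
  m <- tolerant_match(dp, gt, d0)
  eq_mq(m$tp, m$fp, m$fn, m$n_gt)$mq_f1
}
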