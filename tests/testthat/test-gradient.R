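test_that("prefilter: fixed points, median impulse removal, gaussian oracle", {
  const <- matrix(0.5, 8, 8)
  expect_equal(prefilter(const, "none"), const)
  expect_equal(prefilter(const, "gaussian"), const)
  expect_equal(prefilter(const, "median"), const)

  imp <- matrix(0.2, 9, 9); imp[5, 5] <- 1
  med <- prefilter(imp, "median")
  expect_equal(med[5, 5], 0.2)  # neighborhood median

  # independent discrete-convolution oracle for the gaussian on a step edge
  step <- matrix(0, 11, 11); step[, 7:11] <- 1
  sm <- prefilter(step, "gaussian", 1)
  k <- exp(-(-3:3)^2 / 2); k <- k / sum(k)
  oracle_row <- sapply(1:11, function(j) {
    idx <- j + (-3:3)
    idx <- pmin(pmax(ifelse(idx < 1, 2 - idx, idx), 1), 11)
    idx[idx > 11] <- 22 - idx[idx > 11]
    sum(k * step[6, idx])
  })
  expect_equal(sm[6, ], oracle_row, tolerance = 1e-12)
  # interior rows are monotone across the step
  expect_true(all(diff(sm[6, ]) >= 0))
  expect_error(prefilter(const, "boxcar"))
})

test_that("gradient_field: ramps give the documented orientation convention", {
  f <- suppressWarnings(gradient_field(ramp_cols(9, 1), "sobel"))
  inner <- f$g[3:7, 3:7]
  expect_true(all(abs(inner - 8) < 1e-12))       # gx = 8 * step, gy = 0
  expect_true(all(abs(abs(f$theta[3:7, 3:7])) == 90))
  fy <- suppressWarnings(gradient_field(ramp_rows(9, 1), "sobel"))
  expect_true(all(abs(fy$theta[3:7, 3:7]) < 1e-12))  # horizontal tangent
  # the conventional arctan(gy/gx) swaps the two
  fg <- suppressWarnings(gradient_field(ramp_cols(9, 1), "sobel", convention = "gradient"))
  expect_true(all(abs(fg$theta[3:7, 3:7]) < 1e-12))

  cf <- gradient_field(matrix(1, 5, 5))
  expect_true(all(cf$g == 0))
  expect_true(all(is.na(cf$theta)))
  expect_error(gradient_field(matrix(1, 2, 5)), "3x3")
})

test_that("orientation convention round-trips under 90-degree image rotation", {
  set.seed(7)
  n <- 9
  img <- matrix(runif(n * n), n, n)
  f <- gradient_field(img)
  # rotating the image by 90 deg maps tangent angles theta -> theta + 90
  # (axially) and pixel (r, c) to (c, n + 1 - r)
  rot <- t(img)[, n:1]
  fr <- gradient_field(rot)
  d <- c()
  for (r in 3:(n - 2)) for (cc in 3:(n - 2)) {
    want <- f$theta[r, cc] + 90
    got <- fr$theta[cc, n + 1 - r]
    d <- c(d, abs(((want - got) + 90) %% 180 - 90))
  }
  expect_true(all(d < 1e-6, na.rm = TRUE))
})

test_that("normalize_magnitude is a log min-max with the stated conventions", {
  expect_equal(as.numeric(normalize_magnitude(c(1, exp(1), exp(2)))),
               c(0, 0.5, 1))
  # invariance to positive rescaling
  g <- matrix(c(0, 1, 3, 9, 27, 2), 2, 3)
  expect_equal(normalize_magnitude(g), normalize_magnitude(5.7 * g))
  # zero magnitudes map to 0; max to 1
  gn <- normalize_magnitude(g)
  expect_equal(gn[g == 0], 0)
  expect_equal(max(gn), 1)
  expect_true(all(gn >= 0 & gn <= 1))
  # renormalizing exp(gn * range + offset) recovers gn (affine invariance)
  gn2 <- normalize_magnitude(matrix(exp(gn * 3 + 1), 2, 3))
  pos <- g > 0
  expect_equal(gn2[pos], gn[pos], tolerance = 1e-12)
  # degenerate cases
  expect_error(normalize_magnitude(matrix(0, 2, 2)), "degenerate")
  expect_warning(out <- normalize_magnitude(c(0, 2, 2)), "constant")
  expect_equal(as.numeric(out), c(0, 1, 1))
})

test_that("select_tau uses defined-orientation pixels and rejects degenerate input", {
  expect_equal(select_tau(c(0.1, 0.2, 0.9), "median"), 0.2)
  expect_equal(select_tau(c(0, 1), "mean"), 0.5)
  expect_error(select_tau(c(0.5, 0.5, 0.5) * 0 + 0, "median"))
  expect_error(select_tau(rep(1, 5), "median"), "degenerate")
  # on a field object only theta-defined pixels count
  set.seed(1)
  img <- matrix(runif(100), 10, 10)
  f <- gradient_field(img)
  expect_equal(select_tau(f), median(f$gn[!is.na(f$theta)]))
})

test_that("feature maps partition the theta-defined pixels at the tau boundary", {
  set.seed(42)
  img <- matrix(runif(400), 20, 20)
  f <- gradient_field(img)
  fm <- feature_maps(f, bn = 49)
  n_def <- sum(!is.na(f$theta))
  expect_equal(sum(!is.na(fm$theta_tau)) + sum(!is.na(fm$theta_bar_tau)), n_def)
  expect_false(any(!is.na(fm$theta_tau) & !is.na(fm$theta_bar_tau)))
  # boundary pixel gn == tau belongs to the complement class
  g2 <- f; g2$gn[5, 5] <- 0.4; g2$theta[5, 5] <- 10
  fm2 <- feature_maps(g2, tau = 0.4)
  expect_true(is.na(fm2$theta_tau[5, 5]))
  expect_equal(fm2$theta_bar_tau[5, 5], 10)
  # all gn > tau: complement map entirely null
  g3 <- f; g3$gn[] <- 0.9; g3$theta[] <- 5
  fm3 <- feature_maps(g3, tau = 0.5)
  expect_equal(sum(!is.na(fm3$theta_bar_tau)), 0)
  expect_error(feature_maps(f, tau = 1.2))
})

test_that("partition property holds across random images", {
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(runif(15 * 18), 15, 18)
    f <- gradient_field(img)
    fm <- feature_maps(f)
    a <- !is.na(fm$theta_tau); b <- !is.na(fm$theta_bar_tau)
    expect_false(any(a & b))
    expect_equal(sum(a | b), sum(!is.na(f$theta)))
  }
})
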