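test_that("entropy upper bound and shannon entropy", {
  expect_equal(entropy_upper_bound(1), 0)
  expect_equal(entropy_upper_bound(49), log(49))
  expect_error(entropy_upper_bound(0))
  # single occupied bin
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  # uniform over bn bins attains the bound
  bn <- 12
  expect_equal(shannon_entropy(rep(1 / bn, bn)), entropy_upper_bound(bn))
  # the 15/18, 3/18 mask content
  h <- c(15, 3) / 18
  expect_equal(shannon_entropy(h), -sum(h * log(h)))
  expect_equal(shannon_entropy(h), 0.4506, tolerance = 1e-4)
})

test_that("mask rasterization: square, rotation symmetry, corner clipping", {
  fp <- rasterize_mask(c(10, 10), 7, 7, 0, c(31, 31))
  expect_equal(nrow(fp), 49)
  expect_setequal(unique(fp[, 1]), 7:13)
  # phi = 90 swaps the axes: footprint is the coordinate-swapped set
  fp2 <- rasterize_mask(c(10, 10), 9, 3, 0, c(31, 31))
  fp3 <- rasterize_mask(c(10, 10), 9, 3, 90, c(31, 31))
  expect_setequal(paste(fp3[, 1], fp3[, 2]), paste(fp2[, 2], fp2[, 1]))
  expect_equal(nrow(fp2), nrow(fp3))
  # corner clipping: 7x7 at the corner keeps a 4x4 block
  fpc <- rasterize_mask(c(1, 1), 7, 7, 0, c(31, 31))
  expect_equal(nrow(fpc), 16)
  # target always included even for a degenerate thin mask
  fpt <- rasterize_mask(c(5, 5), 1, 1, 37, c(9, 9))
  expect_true(any(fpt[, 1] == 5 & fpt[, 2] == 5))
})

test_that("orientation histogram: normalization, nulls, worked 15/3 content", {
  map <- matrix(10, 4, 5)
  fp <- as.matrix(expand.grid(row = 1:4, col = 1:5))
  h <- orientation_histogram(map, fp, 49, 10)
  expect_equal(max(h$heights), 1)        # all samples share a bin
  expect_equal(sum(h$heights), 1)
  fx <- fig6_fixture("b")
  hb <- orientation_histogram(fx$map, fx$footprint, fx$bn, fx$target_theta)
  expect_equal(hb$n_samples, 18)
  expect_equal(hb$h_t, 3 / 18)
  expect_equal(hb$h_max, 15 / 18)
  expect_equal(sort(hb$heights[hb$heights > 0]), c(3, 15) / 18)
  # all-null footprint
  hz <- orientation_histogram(matrix(NA_real_, 4, 5), fp, 49, 10)
  expect_equal(hz$n_samples, 0)
  expect_equal(sum(hz$heights), 0)
  expect_equal(shannon_entropy(hz), 0)
})

test_that("gestalt likelihood reproduces the worked mask contents", {
  lik <- function(case) {
    fx <- fig6_fixture(case)
    gestalt_likelihood(
      orientation_histogram(fx$map, fx$footprint, fx$bn, fx$target_theta))
  }
  expect_equal(lik("c"), 0.885, tolerance = 0.01)
  expect_equal(lik("b"), 0.178, tolerance = 0.01)
  expect_equal(lik("a"), 0, tolerance = 1e-12)  # uniform heights: no directivity
  expect_identical(lik("d"), 1)   # all samples in the target bin
  # the belief weights behind cases b/c
  fx <- fig6_fixture("b")
  hb <- orientation_histogram(fx$map, fx$footprint, fx$bn, fx$target_theta)
  expect_equal(hb$h_t / hb$h_max, 0.2)
  fx <- fig6_fixture("c")
  hc <- orientation_histogram(fx$map, fx$footprint, fx$bn, fx$target_theta)
  expect_equal(hc$h_t / hc$h_max, 1)
})

test_that("non-gestalt likelihood: uniform-with-target gives 1, degenerate gives 0", {
  bn <- 16
  map <- matrix(bin_centers <- -90 + (seq_len(bn) - 0.5) * 180 / bn, 4, 4)
  fp <- as.matrix(expand.grid(row = 1:4, col = 1:4))
  h <- orientation_histogram(map, fp, bn, map[1, 1])
  expect_equal(nongestalt_likelihood(h), 1)     # beta = 1, H = H_max
  # single occupied bin: zero complement entropy
  m1 <- matrix(5, 3, 3)
  f1 <- as.matrix(expand.grid(row = 1:3, col = 1:3))
  expect_equal(nongestalt_likelihood(orientation_histogram(m1, f1, bn, 5)), 0)
  # target bin unoccupied in the complement map
  expect_equal(nongestalt_likelihood(orientation_histogram(m1, f1, bn, -80)), 0)
})

test_that("likelihoods stay in [0, 1] over random histograms", {
  set.seed(99)
  n_cases <- 10000
  p <- pb <- hts <- numeric(n_cases); ok_bound <- logical(n_cases)
  for (i in seq_len(n_cases)) {
    bn <- sample(c(4, 12, 49), 1)
    n <- sample(1:60, 1)
    map <- matrix(runif(n, -90, 90), 1, n)
    if (runif(1) < 0.3) map[sample(n, ceiling(n / 3))] <- NA
    fp <- cbind(row = rep(1L, n), col = seq_len(n))
    tt <- if (runif(1) < 0.1) NA else runif(1, -90, 90)
    h <- orientation_histogram(map, fp, bn, tt)
    p[i] <- gestalt_likelihood(h); pb[i] <- nongestalt_likelihood(h)
    hts[i] <- h$h_max - h$h_t
    ok_bound[i] <- shannon_entropy(h) <= entropy_upper_bound(bn) + 1e-12
  }
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(pb >= 0 & pb <= 1))
  expect_true(all(hts >= 0))       # target bin never exceeds the maximum
  expect_true(all(ok_bound))       # entropy never exceeds its upper bound
})

test_that("width/length updates follow the floor/ceiling rule and bounds", {
  expect_equal(update_width(0.8, 0.5, 7), 1L)    # floor(1.4) = 1 -> clamp
  expect_equal(update_width(0.3, 0.5, 7), 5L)    # ceiling(4.9)
  expect_equal(update_width(0.95, 0.2, 7), 1L)   # r(1-p) <= 1 -> otherwise
  expect_equal(update_width(0.1, 0.0, 7), 6L)    # floor(6.3)
  expect_equal(update_width(0, 0, 7), 7L)
  for (p in seq(0, 1, by = 0.05)) for (pp in c(0, 0.5, 1)) {
    w <- update_width(p, pp, 7)
    expect_true(w >= 1 && w <= 7)
  }
  expect_equal(update_length(49, 7), 7)
  expect_equal(update_length(49, 2), 24.5)
  expect_equal(update_length(49, 1), 49)
})

test_that("principal direction: bin centers, deterministic tie-break", {
  bn <- 36  # 5-degree bins
  h <- orientation_histogram(matrix(c(41, 42, 44), 1, 3),
                             cbind(1L, 1:3), bn, 42)
  expect_equal(principal_direction(h), 42.5)
  # tie between two bins resolved toward the previous rotation
  map <- matrix(c(10, 10, 70, 70), 1, 4)
  ht <- orientation_histogram(map, cbind(1L, 1:4), bn, 10)
  expect_equal(principal_direction(ht, prev_phi = 65), 72.5)
  expect_equal(principal_direction(ht, prev_phi = 5), 12.5)
  expect_equal(principal_direction(ht), 12.5)    # lowest index without prior
  hz <- orientation_histogram(matrix(NA_real_, 1, 3), cbind(1L, 1:3), bn, 10)
  expect_true(is.na(principal_direction(hz)))
})

test_that("run_em recovers a planted principal direction with maximal elongation", {
  for (a in c(-60, -30, 0, 30, 45, 60)) {
    lf <- line_field(a, extent = 31, background = "constant", seed = 1)
    fm <- field_feature_maps(lf$field, lf$line_mask)
    cm <- run_em(fm, lf$center)
    expect_lte(abs(gestaltmask:::wrap_axial(cm$phi - a)), 180 / 49)
    expect_equal(cm$W, 1L)
    expect_gt(cm$p_c, 0.5)
    expect_true(cm$converged)
    # receptive-field enlargement: union of footprints beats the initial 49
    expect_gt(nrow(cm$footprint_union), 49)
  }
})

test_that("run_em degenerate targets and uniform-orientation fields", {
  # all footprint pixels share the target angle: immediate p = 1
  fm <- field_feature_maps(matrix(30, 21, 21))
  cm <- run_em(fm, c(11, 11))
  expect_equal(cm$p_c, 1)
  expect_true(cm$converged)
  expect_equal(cm$W, 1L)
  # null-orientation target short-circuits
  f2 <- matrix(30, 21, 21); f2[11, 11] <- NA
  cm2 <- run_em(field_feature_maps(f2), c(11, 11))
  expect_equal(cm2$flag, "null_theta")
  expect_equal(cm2$p_c, 0)
  expect_equal(cm2$iterations, 0L)
  expect_error(run_em(fm, c(50, 50)), "bounds")
})

test_that("isotropic random fields yield low converged likelihoods", {
  pcs <- vapply(1:100, function(s) run_em(random_field_fm(s), c(13, 13))$p_c,
                numeric(1))
  expect_lt(mean(pcs), 0.2)
  expect_true(all(pcs < 0.5))
})

test_that("objective terms and the descent quantity", {
  expect_equal(objective_term(7 * (1 - 0.4), 0.4, 7), 0)
  expect_equal(objective_term(1, 1, 7), 1)
  expect_equal(objective_value(c(1, 0, 0.5)), 0.5)
  expect_equal(objective_value(c(1, 1), n_cep = 4), 0.5)
  # descent: floor branch makes the residual negative, ceiling positive
  expect_lte(gestaltmask:::delta_objective(update_width(0.4, 0.1, 7), 0.4, 0.1, 7), 0)
  expect_lte(gestaltmask:::delta_objective(update_width(0.1, 0.4, 7), 0.1, 0.4, 7), 0)
})
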