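# Per-point inversion, grid fit, error propagation, weighted mean.

test_that("per-point inversion is the exact algebraic inverse of the branch equation", {
  p <- pair_of("Menthol", "Lauric acid")
  for (zw in seq(-40000, 20000, by = 5000)) {
    for (x in seq(0.1, 0.9, by = 0.1)) {
      tt <- bw_branch_temperature(bw_model(p, zw), x, "a")
      if (is.na(tt)) next
      est <- estimate_zw_from_point(p, x, tt)
      expect_equal(est$zw_a, zw, tolerance = 1e-9)
    }
  }
  # a point on the ideal branch inverts to zw = 0
  t_id <- ideal_branch_temperature(p$a, 0.4)
  expect_equal(estimate_zw_from_point(p, 0.4, t_id)$zw_a, 0,
               tolerance = 1e-8)
  expect_error(estimate_zw_from_point(p, 1, 300), "molar fraction")
})

test_that("the smaller-zw rule picks the limiting branch on liquidus points", {
  p <- pair_of("Menthol", "Lauric acid")
  truth <- -12000
  ds <- generate_dataset(synthetic_spec(p, truth, n_points = 15,
                                        noise_sd = 0, seed = 5))
  est <- estimate_zw_from_point(p, ds$points$x_a, ds$points$t)
  expect_equal(est$zw_chosen, pmin(est$zw_a, est$zw_b))
  # noise-free liquidus points invert exactly through the chosen branch
  expect_equal(est$zw_chosen, rep(truth, 15), tolerance = 1e-7)
  expect_true(all(est$zw_chosen <= est$zw_b + 1e-9))
})

test_that("aad averages absolute residuals over interior points only", {
  p <- pair_of("Menthol", "Lauric acid")
  m <- bw_model(p, -8000)
  x <- c(0.2, 0.5, 0.8)
  tl <- vapply(x, function(xx) max(bw_branch_temperature(m, xx, "a"),
                                   bw_branch_temperature(m, 1 - xx, "b")),
               numeric(1))
  # on-curve data: zero deviation
  expect_equal(aad(sle_dataset(p, x, tl), m), 0)
  # +2 K and -4 K residuals average to 3 K
  expect_equal(aad(sle_dataset(p, x[1:2], tl[1:2] + c(2, -4)), m), 3)
  # boundary points are excluded with a warning
  expect_warning(
    val <- aad(sle_dataset(p, c(x, 1), c(tl, 315.7)), m),
    "boundary")
  expect_equal(val, 0)
})

test_that("grid fit recovers a known zw exactly on noise-free data", {
  p <- pair_of("Menthol", "Lauric acid")
  ds <- generate_dataset(synthetic_spec(p, -20000, n_points = 15,
                                        noise_sd = 0, seed = 2))
  fit <- fit_zw_grid(ds)
  expect_s3_class(fit, "zw_fit")
  expect_equal(fit$zw, -20000, tolerance = 1e-9)
  expect_lt(fit$aad_bw, 1e-9)
  expect_gt(fit$aad_ideal, 1)
  expect_identical(fit$n_points_used, 15L)
})

test_that("data sampled from the ideal curve fit to zw = 0 with zero AAD", {
  p <- pair_of("Thymol", "Capric acid")
  ds <- generate_dataset(synthetic_spec(p, 0, n_points = 12, noise_sd = 0,
                                        seed = 9))
  fit <- fit_zw_grid(ds)
  expect_identical(fit$zw, 0)
  expect_equal(fit$aad_bw, fit$aad_ideal)
  expect_lt(fit$aad_bw, 1e-9)
})

test_that("fitted AAD never exceeds the ideal AAD when the grid contains zero", {
  p <- pair_of("Menthol", "Myristic acid")
  ds <- generate_dataset(synthetic_spec(p, -15000, n_points = 20,
                                        noise_sd = 3, seed = 4))
  fit <- fit_zw_grid(ds)
  expect_lte(fit$aad_bw, fit$aad_ideal)
})

test_that("optional continuous refinement only improves the objective", {
  p <- pair_of("Menthol", "Lauric acid")
  ds <- generate_dataset(synthetic_spec(p, -17050, n_points = 15,
                                        noise_sd = 0, seed = 8))
  coarse <- fit_zw_grid(ds, step = 1000)
  polished <- fit_zw_grid(ds, step = 1000, refine = TRUE)
  expect_lte(polished$aad_bw, coarse$aad_bw)
  expect_lt(abs(polished$zw - -17050), abs(coarse$zw - -17050) + 1e-6)
})

test_that("fit errors on unusable datasets", {
  p <- pair_of("Menthol", "Lauric acid")
  expect_error(suppressWarnings(fit_zw_grid(sle_dataset(p, 1, 315.7))),
               "no interior points")
  expect_error(fit_zw_grid(generate_dataset(
    synthetic_spec(p, 0, 5, noise_sd = 0, seed = 1)), grid_min = 10,
    grid_max = 5), "grid_min < grid_max")
})

test_that("error-propagation formulas are the exact partial derivatives of the inversion", {
  # finite-difference oracle on the inversion zw(T, dHm, Tm), run for all
  # packaged pairs at three interior compositions
  nms <- names(table1$compounds)
  combos <- utils::combn(nms, 2)
  set.seed(1)
  pick <- combos[, sample(ncol(combos), 20)]
  for (k in seq_len(ncol(pick))) {
    p <- pair_of(pick[1, k], pick[2, k])
    for (x in c(0.2, 0.5, 0.8)) {
      tt <- bw_branch_temperature(bw_model(p, -6000), x, "a")
      zw_of <- function(tm, dhm, t) {
        (dhm * (t / tm - 1) - R_GAS * t * log(x)) / (1 - x)^2
      }
      fd_T <- central_diff(function(t) zw_of(p$a$tm, p$a$dhm, t), tt, 1e-4)
      fd_H <- central_diff(function(h) zw_of(p$a$tm, h, tt), p$a$dhm, 1e-4)
      fd_Tm <- central_diff(function(tm) zw_of(tm, p$a$dhm, tt), p$a$tm, 1e-4)
      expect_equal(zw_error_from_temperature(p, x, tt, dT = 1, branch = "a"),
                   abs(fd_T), tolerance = 1e-4)
      expect_equal(zw_error_from_enthalpy(p, x, tt, dH = 1, branch = "a"),
                   abs(fd_H), tolerance = 1e-4)
      expect_equal(zw_error_from_tm(p, x, tt, dTm = 1, branch = "a"),
                   abs(fd_Tm), tolerance = 1e-4)
    }
  }
})

test_that("propagated errors blow up as (1-x)^-2 near the pure ends", {
  p <- pair_of("Thymol", "Camphor")
  tt <- 300
  for (f in list(function(x) zw_error_from_temperature(p, x, tt, 5, "a"),
                 function(x) zw_error_from_tm(p, x, tt, 5, "a"))) {
    expect_gte(f(0.999) / f(0.5), 1e4)
  }
  # enthalpy error vanishes when the measured point sits at Tm exactly
  expect_equal(zw_error_from_enthalpy(p, 0.5, p$a$tm, dH = 5000,
                                      branch = "a"), 0)
})

test_that("curve sensitivity matches a finite difference in zw and stays bounded", {
  p <- pair_of("Menthol", "Lauric acid")
  m <- bw_model(p, -8000)
  for (x in c(0.2, 0.5, 0.9)) {
    fd <- bw_branch_temperature(bw_model(p, -8000 + 1), x, "a") -
      bw_branch_temperature(m, x, "a")
    expect_equal(curve_sensitivity(m, x, dzw = 1), fd, tolerance = 1e-3)
  }
  # bounded over the whole interior range for every packaged compound
  xs <- seq(0.001, 0.999, by = 0.001)
  for (nm in names(table1$compounds)) {
    pp <- binary_pair(compound(table1, nm), pure_compound("other", 300, 2e4))
    s <- curve_sensitivity(bw_model(pp, 0), xs, dzw = 1000)
    expect_true(all(is.finite(s)))
  }
})

test_that("weighted mean follows the inverse-variance closed form", {
  wm <- weighted_mean_zw(c(-10000, -20000), c(1000, 2000))
  expect_equal(wm$mean, -12000)
  expect_equal(wm$err, 2000 / sqrt(5))
  # equal uncertainties reduce to the arithmetic mean
  expect_equal(weighted_mean_zw(c(-1, -5, -9), rep(2, 3))$mean, -5)
  # an infinitely uncertain point drops out
  expect_equal(weighted_mean_zw(c(-10000, 999), c(1, Inf))$mean, -10000)
  # result always lies within the estimate range
  set.seed(42)
  for (i in 1:20) {
    z <- rnorm(6, -10000, 5000); e <- rexp(6, 1 / 2000)
    m <- weighted_mean_zw(z, e)$mean
    expect_gte(m, min(z)); expect_lte(m, max(z))
  }
  expect_error(weighted_mean_zw(c(-1, -2), c(Inf, Inf)), "infinite")
  expect_error(weighted_mean_zw(numeric(0), numeric(0)), "non-empty")
})

test_that("per-point estimation table is consistent and excludes boundary points", {
  p <- pair_of("Thymol", "Camphor")
  ds <- generate_dataset(synthetic_spec(p, -25000, n_points = 9,
                                        noise_sd = 0, seed = 3))
  est <- zw_point_estimates(ds)
  expect_s3_class(est, "zw_point_estimates")
  expect_equal(est$zw_chosen, pmin(est$zw_a, est$zw_b))
  expect_true(all(est$err > 0))
  expect_equal(attr(est, "weighted_mean"), -25000, tolerance = 1e-6)
  wm <- weighted_mean_zw(est$zw_chosen, est$err)
  expect_equal(attr(est, "weighted_mean"), wm$mean)
  # boundary point present: excluded with a warning, table unchanged
  ds2 <- sle_dataset(p, c(ds$points$x_a, 1), c(ds$points$t, p$a$tm))
  expect_warning(est2 <- zw_point_estimates(ds2), "boundary")
  expect_equal(nrow(est2), 9L)
})
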