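test_that("the Wald ratio and its delta-method SE are exact", {
  h <- make_h(bx = 0.5, by = 0.055, sx = 0.001, sy = 0.01)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.11)
  expect_equal(est$se, 0.02)
  expect_equal(est$or, exp(0.11))

  h0 <- make_h(bx = 0.5, by = 0, sx = 0.001, sy = 0.01)
  expect_equal(wald_ratio(h0)$beta, 0)

  # second-order correction is negligible for strong instruments
  h2 <- make_h(bx = 0.5, by = 0.055, sx = 0.01, sy = 0.01)
  first <- wald_ratio(h2)$se
  second <- wald_ratio(h2, second_order = TRUE)$se
  expect_lt(abs(second - first) / first, 0.01)
})

test_that("IVW averages equally weighted ratios and delegates a single IV", {
  h <- make_h(bx = c(1, 1), by = c(0.1, 0.3), sy = 1)
  expect_equal(mr_ivw(h, "fixed")$beta, 0.2)

  h1 <- make_h(bx = 0.5, by = 0.055, sx = 0.001, sy = 0.01)
  expect_equal(mr_ivw(h1)$beta, wald_ratio(h1)$beta)
  expect_equal(mr_ivw(h1)$method, "wald")
})

test_that("IVW equals the zero-intercept WLS slope on random instances", {
  for (s in 1:8) {
    set.seed(s)
    J <- sample(2:8, 1)
    h <- make_h(bx = rnorm(J, 0.4, 0.15), by = rnorm(J, 0.05, 0.03),
                sy = runif(J, 0.01, 0.1))
    est <- mr_ivw(h, "fixed")
    expect_equal(est$beta,
                 oracle_wls_slope(h$beta_exp, h$beta_out, h$se_out),
                 tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches the chi-square arithmetic and I2 clamps", {
  # w = 100 each, ratios 0.1 and 0.3 about beta = 0.2: Q = 2, df = 1
  h <- make_h(bx = c(1, 1), by = c(0.1, 0.3), sy = 0.1)
  est <- mr_ivw(h, "fixed")
  q <- cochran_q(h, est)
  expect_equal(q$q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(q$i2, 0.5)

  same <- make_h(bx = c(1, 1, 1), by = c(0.2, 0.2, 0.2), sy = 0.1)
  qs <- cochran_q(same, mr_ivw(same, "fixed"))
  expect_equal(qs$q, 0)
  expect_equal(qs$pval, 1)
  expect_equal(qs$i2, 0)  # clamped when Q < df
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  het <- make_h(bx = c(1, 1, 1), by = c(0.0, 0.2, 0.4), sy = 0.01)
  fe <- mr_ivw(het, "fixed"); re <- mr_ivw(het, "random")
  expect_gt(re$se, fe$se)
  expect_equal(re$beta, fe$beta)
  expect_equal(mr_ivw(het, "auto")$extra$model_used, "random")

  hom <- make_h(bx = c(1, 1, 1), by = c(0.199, 0.2, 0.201), sy = 0.1)
  expect_equal(mr_ivw(hom, "random")$se, mr_ivw(hom, "fixed")$se)
  expect_equal(mr_ivw(hom, "auto")$extra$model_used, "fixed")
})

test_that("Egger matches the closed-form weighted regression", {
  h <- make_h(bx = c(1, 2, 3), by = c(0.2, 0.3, 0.4), sy = 1)
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.1, tolerance = 1e-10)
  expect_equal(eg$intercept$value, 0.1, tolerance = 1e-10)

  for (s in 1:5) {
    set.seed(100 + s)
    J <- sample(4:8, 1)
    h <- make_h(bx = rnorm(J, 0.4, 0.2), by = rnorm(J, 0.05, 0.05),
                sy = runif(J, 0.02, 0.1))
    eg <- mr_egger(h)
    oc <- oracle_egger(h$beta_exp, h$beta_out, h$se_out)
    expect_equal(eg$intercept$value, oc[1], tolerance = 1e-10)
    expect_equal(eg$slope$beta, oc[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers injected constant pleiotropy and nests IVW", {
  sim <- simulate_mr_dataset(mr_sim_config(
    n_snp = 30, theta = 0.1, se_x = 0.005, se_y = 0.01,
    prop_invalid = 1, pleio_mean = 0.05, pleio_sd = 0.001,
    orient_gamma = TRUE, seed = 12))
  h <- harmonize(sim$exposure, sim$outcome)
  eg <- mr_egger(h)
  expect_lt(abs(eg$intercept$value - 0.05), 3 * eg$intercept$se)
  expect_lt(abs(eg$slope$beta - 0.1), 3 * eg$slope$se)

  # constrained to the origin the slope reproduces fixed-effect IVW
  expect_equal(mr_egger(h, intercept = FALSE)$slope$beta,
               mr_ivw(h, "fixed")$beta, tolerance = 1e-10)
})

test_that("the weighted median interpolates cumulative midpoint weights", {
  h3 <- make_h(bx = c(1, 1, 1), by = c(1, 2, 3), sy = 1)
  expect_equal(weighted_median(h3, n_boot = 50)$beta, 2)
  h4 <- make_h(bx = c(1, 1, 1, 1), by = c(1, 2, 3, 4), sy = 1)
  expect_equal(weighted_median(h4, n_boot = 50)$beta, 2.5)
})

test_that("the weighted median resists a minority of invalid instruments", {
  set.seed(31)
  bx <- rnorm(14, 0.4, 0.1)
  by <- 0.1 * bx
  by[1:4] <- 1.0 * bx[1:4]  # 4/14 outlying instruments at ratio 1.0
  h <- make_h(bx = bx, by = by + rnorm(14, 0, 0.002), sx = 0.002,
              sy = 0.002)
  est <- weighted_median(h, n_boot = 500, seed = 5)
  expect_lt(abs(est$beta - 0.1), 3 * est$se)
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h <- make_h(bx = c(1, 1, 1, 1), by = c(0.1, 0.1, 0.1, 0.5), sy = 1)
  est <- weighted_mode(h, n_boot = 50)
  # independent continuous argmax of the same weighted kernel density
  theta <- h$beta_out / h$beta_exp
  w <- rep(0.25, 4)
  bw <- 0.9 * min(sd(theta), IQR(theta) / 1.34) * 4^(-1 / 5)
  oracle <- optimize(function(x) sum(w * dnorm(x, theta, bw)),
                     c(0, 0.6), maximum = TRUE)$maximum
  expect_equal(est$beta, oracle, tolerance = 0.01)
  expect_lt(abs(est$beta - 0.1), 0.05)

  flat <- make_h(bx = c(1, 2, 4), by = c(0.1, 0.2, 0.4), sy = 1)
  expect_equal(weighted_mode(flat, n_boot = 50)$beta, 0.1,
               tolerance = 1e-9)
})

test_that("the weighted mode recovers theta from a 60%-valid simulation", {
  set.seed(77)
  J <- 15
  bx <- rnorm(J, 0.4, 0.1)
  by <- 0.1 * bx
  by[1:6] <- by[1:6] + rnorm(6, 0.15, 0.08)  # 40% invalid, scattered
  h <- make_h(bx = bx, by = by + rnorm(J, 0, 0.002), sx = 0.002,
              sy = 0.002)
  est <- weighted_mode(h, n_boot = 500, seed = 6)
  # the mode is quantized by its 512-point grid; allow one grid step
  theta <- h$beta_out / h$beta_exp
  bw <- 0.9 * min(sd(theta), IQR(theta) / 1.34) * J^(-1 / 5)
  grid_step <- (diff(range(theta)) + 6 * bw) / 511
  expect_lt(abs(est$beta - 0.1), 3 * est$se + grid_step)
})

test_that("estimate_all runs the applicable methods with matching n_snp", {
  h1 <- make_h(bx = 0.5, by = 0.05, sy = 0.01)
  res1 <- estimate_all(h1)
  expect_equal(res1$estimates$method, "wald")
  expect_null(res1$heterogeneity)

  h5 <- make_h(bx = c(0.35, 0.4, 0.45, 0.5, 0.55),
               by = rnorm(5, 0.04, 0.01), sy = 0.02)
  res5 <- estimate_all(h5, seed = 3, n_boot = 100)
  expect_setequal(res5$estimates$method,
                  c("ivw_fe", "egger", "weighted_median", "weighted_mode"))
  expect_true(all(res5$estimates$n_snp == 5))
  expect_equal(res5$heterogeneity$method, c("ivw", "egger"))

  h2 <- make_h(bx = c(0.4, 0.5), by = c(0.04, 0.05), sy = 0.02)
  expect_equal(nrow(estimate_all(h2)$estimates), 1L)
})

test_that("estimators are invariant to ordering and per-variant sign flips", {
  set.seed(41)
  J <- 7
  h <- make_h(bx = rnorm(J, 0.4, 0.1), by = rnorm(J, 0.05, 0.02),
              sx = 0.01, sy = runif(J, 0.01, 0.05))
  flip <- c(1, -1, 1, -1, -1, 1, 1)
  h2 <- h
  h2$beta_exp <- h$beta_exp * flip
  h2$beta_out <- h$beta_out * flip
  h2 <- h2[sample(J), ]
  class(h2) <- class(h)
  expect_equal(mr_ivw(h2, "fixed")$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-10)
  expect_equal(mr_ivw(h2, "fixed")$se, mr_ivw(h, "fixed")$se,
               tolerance = 1e-10)
  expect_equal(mr_egger(h2)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-10)
  expect_equal(weighted_median(h2, n_boot = 10)$beta,
               weighted_median(h, n_boot = 10)$beta, tolerance = 1e-10)
  expect_equal(weighted_mode(h2, n_boot = 10)$beta,
               weighted_mode(h, n_boot = 10)$beta, tolerance = 1e-10)
})

test_that("all estimator CIs cover a null effect at close to nominal rate", {
  cover <- c(ivw = 0, egger = 0, weighted_median = 0, weighted_mode = 0)
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    sim <- simulate_mr_dataset(mr_sim_config(n_snp = 5, theta = 0,
                                             seed = s))
    h <- harmonize(sim$exposure, sim$outcome)
    e <- estimate_all(h, seed = s + 300, n_boot = 300)$estimates
    for (i in seq_len(nrow(e))) {
      key <- sub("ivw_(fe|re)", "ivw", e$method[i])
      if (e$ci_low[i] <= 0 && e$ci_high[i] >= 0) {
        cover[key] <- cover[key] + 1
      }
    }
  }
  expect_true(all(cover / n_rep >= 0.9))
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(1:30, 1))^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_protmr_error(bh_fdr(c(0.1, 0)), "protmr_domain_error")
})

test_that("degenerate instruments raise classed errors", {
  h <- make_h(bx = c(0, 0.5), by = c(0.1, 0.1), sy = 0.01)
  expect_protmr_error(mr_ivw(h), "protmr_degenerate_instrument_error")
  h3 <- make_h(bx = c(0.4, 0.5), by = c(0.04, 0.05), sy = 0.02)
  expect_protmr_error(mr_egger(h3),
                      "protmr_insufficient_instruments_error")
  same <- make_h(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = 0.1)
  expect_protmr_error(mr_egger(same), "protmr_collinearity_error")
})
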