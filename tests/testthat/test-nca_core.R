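study <- sci_study_profiles()

test_that("Cmax/Tmax are the observed maximum with earliest-time ties", {
  cm1 <- find_cmax(study[["1"]])
  expect_equal(cm1$cmax_mg_per_L, 7.2)
  expect_equal(cm1$tmax_h, 1.5)
  cm4 <- find_cmax(study[["4"]])
  expect_equal(cm4$cmax_mg_per_L, 3.2)
  expect_equal(cm4$tmax_h, 2)
  tie <- pk_profile("tie", c(1, 2, 3), c(5, 5, 1))
  expect_equal(find_cmax(tie)$tmax_h, 1)
  allblq <- pk_profile("b", c(0, 1), c(0, 0), blq = c(TRUE, TRUE))
  expect_warning(cm <- find_cmax(allblq), "degenerate")
  expect_equal(cm$cmax_mg_per_L, 0)
  expect_equal(cm$tmax_h, 0)
  expect_error(find_cmax(pk_profile("e", numeric(0), numeric(0))), "empty")
})

test_that("trapezoid with BLQ-as-zero reproduces all six study AUClast values", {
  printed <- c(`1` = 40.78, `2` = 38.63, `3` = 29.7, `4` = 11.4,
               `5` = 25.3, `6` = 22.6)
  for (id in names(printed)) {
    tr <- integrate_trapezoid(study[[id]])
    expect_equal(round_half_away(tr$auclast_mg_h_per_L, 2),
                 unname(printed[id]), info = paste("rat", id))
  }
  # integration window: through the first BLQ after the last quantifiable
  tr1 <- integrate_trapezoid(study[["1"]])
  expect_equal(tr1$t_last_integrated_h, 12)
  expect_equal(tr1$c_last_quantifiable_mg_per_L, 7.2)
  tr6 <- integrate_trapezoid(study[["6"]])
  expect_equal(tr6$t_first_h, 2)
  expect_equal(tr6$t_last_integrated_h, 36)
})

test_that("trapezoid matches closed forms and the independent oracle", {
  # constant concentration: AUC = C * T
  const <- pk_profile("c", c(0, 3, 10), rep(2.5, 3))
  expect_equal(integrate_trapezoid(const)$auclast_mg_h_per_L, 25)
  # oracle equivalence on the study profiles and random ones (<= 6 points)
  for (id in names(study)) {
    pts <- study[[id]]$points
    quant <- which(pts$conc_mg_per_L > 0)
    end <- min(max(quant) + 1L, nrow(pts))
    expect_equal(integrate_trapezoid(study[[id]])$auclast_mg_h_per_L,
                 oracle_trapz(pts$time_h[1:end], pts$conc_mg_per_L[1:end]))
  }
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    t <- sort(sample(seq(0, 30, 0.5), n))
    conc <- round(runif(n, 0.1, 9), 2)
    p <- pk_profile("r", t, conc)
    tr <- integrate_trapezoid(p)
    expect_equal(tr$auclast_mg_h_per_L, oracle_trapz(t, conc))
    expect_equal(tr$aumclast_mg_h2_per_L, oracle_trapz(t, t * conc))
  }
  expect_error(integrate_trapezoid(pk_profile("x", 1, 1)), "two points")
})

test_that("alternative BLQ rules change the window/value as documented", {
  p <- pk_profile("p", c(0, 1, 2, 4, 8), c(0, 4, 2, 0, 0),
                  blq = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  default <- integrate_trapezoid(p)
  expect_equal(default$auclast_mg_h_per_L,
               oracle_trapz(c(0, 1, 2, 4), c(0, 4, 2, 0)))
  dropped <- integrate_trapezoid(p, blq_rule = "drop_blq")
  expect_equal(dropped$auclast_mg_h_per_L, oracle_trapz(c(1, 2), c(4, 2)))
  half <- integrate_trapezoid(p, blq_rule = "loq_half", loq = 0.5)
  expect_equal(half$auclast_mg_h_per_L,
               oracle_trapz(c(0, 1, 2, 4), c(0.25, 4, 2, 0.25)))
  expect_error(integrate_trapezoid(p, blq_rule = "loq_half"), "loq")
  expect_warning(
    z <- integrate_trapezoid(pk_profile("b", c(0, 1), c(0, 0))), "all-BLQ")
  expect_equal(z$auclast_mg_h_per_L, 0)
})

test_that("AUC invariants: additivity, refinement, monotonicity, scaling", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    t <- sort(sample(seq(0, 40, 0.25), n))
    conc <- round(runif(n, 0.2, 9), 3)
    # additivity across an interior sampled time
    b <- sample(2:(n - 1), 1)
    full <- oracle_trapz(t, conc)
    expect_equal(oracle_trapz(t[1:b], conc[1:b]) +
                 oracle_trapz(t[b:n], conc[b:n]), full)
    p <- pk_profile("p", t, conc)
    auc <- integrate_trapezoid(p)$auclast_mg_h_per_L
    # refinement: a point on the chord leaves the integral unchanged
    j <- sample(seq_len(n - 1L), 1)
    tm <- (t[j] + t[j + 1L]) / 2
    cm <- (conc[j] + conc[j + 1L]) / 2
    refined <- pk_profile("p2", sort(c(t, tm)),
                          append(conc, cm, after = j))
    expect_equal(integrate_trapezoid(refined)$auclast_mg_h_per_L, auc)
    # monotonicity: pointwise-larger concentrations never decrease AUC
    bigger <- pk_profile("p3", t, conc + runif(n, 0, 2))
    expect_gte(integrate_trapezoid(bigger)$auclast_mg_h_per_L, auc)
    # scale equivariance
    s <- runif(1, 0.5, 4)
    scaled <- pk_profile("p4", t, s * conc)
    expect_equal(integrate_trapezoid(scaled)$auclast_mg_h_per_L, s * auc)
  }
})

test_that("trapezoidal AUC converges ~quadratically on an exponential", {
  k <- 0.3
  truth <- (1 - exp(-10)) / k
  err <- vapply(c(20, 40, 80), function(n) {
    t <- seq(0, 10 / k, length.out = n + 1)
    abs(oracle_trapz(t, exp(-k * t)) - truth)
  }, numeric(1))
  # halving the step divides the error by ~4
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("terminal log-linear regression matches closed forms and the oracle", {
  # noise-free exponential: exact rate recovery
  t <- c(2, 4, 8)
  p <- pk_profile("e", t, 5 * exp(-0.2 * t))
  fit <- fit_lambda_z(p)
  expect_equal(fit$k_per_h, 0.2, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
  # two points: K = ln(C1/C2)/(t2-t1)
  p2 <- pk_profile("two", c(3, 7), c(6, 1.5))
  expect_equal(fit_lambda_z(p2)$k_per_h, log(6 / 1.5) / 4)
  # random declining profiles vs direct normal equations
  set.seed(31)
  for (i in 1:10) {
    pr <- random_declining_profile(5)
    f <- fit_lambda_z(pr, window = range(pr$points$time_h))
    o <- oracle_loglinear(pr$points$time_h, pr$points$conc_mg_per_L)
    expect_equal(f$k_per_h, -o$slope, tolerance = 1e-10)
    expect_equal(f$intercept_ln_conc, o$intercept, tolerance = 1e-10)
  }
})

test_that("lambda-z selection and degenerate phases behave as documented", {
  # automatic window starts at or after Tmax and ends at last quantifiable
  t <- c(0, 0.5, 1, 2, 4, 8, 12)
  conc <- c(0, 3, 6, 5 * exp(-0.25 * (2 - 2)), 5 * exp(-0.25 * 2),
            5 * exp(-0.25 * 6), 5 * exp(-0.25 * 10))
  p <- pk_profile("a", t, conc)
  fit <- fit_lambda_z(p)
  expect_gte(fit$window[["start_h"]], 1)
  expect_equal(fit$window[["end_h"]], 12)
  expect_equal(fit$k_per_h, 0.25, tolerance = 1e-6)
  # rising terminal phase: flagged, K unset
  rising <- pk_profile("r", c(1, 2, 4), c(1, 2, 3))
  f <- fit_lambda_z(rising)
  expect_false(f$declining)
  expect_true(is.na(f$k_per_h))
  # fewer than two usable points
  expect_error(fit_lambda_z(pk_profile("s", c(0, 1), c(0, 1))), "two")
  expect_error(fit_lambda_z(p, window = c(11, 12)), "window")
})

test_that("derived-parameter chain reproduces the study's per-rat values", {
  # rat 5: dose 4.06 mg, K 0.161, AUClast 25.3
  d5 <- derive_parameters(25.3, 0.161, 4.06)
  expect_equal(d5$vd_L, 0.9967, tolerance = 5e-4)
  expect_equal(d5$cl_L_per_h, 0.160, tolerance = 5e-3)
  expect_equal(d5$t_half_h, 4.306, tolerance = 5e-3)
  expect_equal(d5$mrt_h, 6.212, tolerance = 5e-4)
  # rat 2: very slow elimination
  d2 <- derive_parameters(38.63, 0.01387, 4.25)
  expect_equal(d2$t_half_h, 49.97, tolerance = 5e-3)
  expect_equal(d2$mrt_h, 72.09, tolerance = 5e-3)
  # exact closed forms
  expect_equal(derive_parameters(1, log(2), 1)$t_half_h, 1)
  expect_equal(derive_parameters(10, 0.5, 2,
                                 ln2_constant = 0.693)$t_half_h, 0.693 / 0.5)
  expect_equal(derive_parameters(10, 0.5, 2, mrt_method = "aumc",
                                 aumclast = 40)$mrt_h, 4)
  expect_error(derive_parameters(0, 1, 1), "auclast")
  expect_error(derive_parameters(1, -1, 1), "k_per_h")
  expect_error(derive_parameters(1, 1, 0), "dose")
})

test_that("pooled mean profile reproduces the group-level concentrations", {
  pooled <- pooled_mean_profile(study)
  at <- function(tt) pooled$points$conc_mg_per_L[pooled$points$time_h == tt]
  expect_equal(round_half_away(at(1.5), 2), 5.93)
  expect_equal(round_half_away(at(2), 2), 4.13)
  expect_equal(round_half_away(at(4), 2), 3.43)
  expect_equal(round_half_away(at(8), 2), 0.33)
  expect_equal(pooled$points$time_h,
               sort(unique(c(0, 0.25, 0.5, 1, 1.5, 2, 4, 8, 12, 24, 36, 48))))
  expect_equal(pooled$dose_mg, 3.92, tolerance = 1e-2)
  # identity for a single profile
  solo <- pooled_mean_profile(study["1"])
  expect_equal(solo$points$conc_mg_per_L, study[["1"]]$points$conc_mg_per_L)
  expect_error(pooled_mean_profile(list()), "no profiles")
})

test_that("full NCA of the pooled profile matches the study's group table", {
  pooled <- pooled_mean_profile(study, rounding_dp = 2)
  res <- run_nca(pooled, nca_config(lambda_z_mode = "fixed",
                                    fixed_k = 0.0689))
  expect_equal(round_half_away(res$auclast_mg_h_per_L, 2), 23.47)
  expect_equal(res$cmax_mg_per_L, 5.93)
  expect_equal(res$tmax_h, 1.5)
  expect_equal(res$vd_L, 2.43, tolerance = 5e-3)
  expect_equal(res$cl_L_per_h, 0.167, tolerance = 5e-3)
  expect_equal(res$t_half_h, 10.07, tolerance = 5e-3)
  expect_equal(res$mrt_h, 14.52, tolerance = 5e-3)
})

test_that("NCA results satisfy the derived-chain identities", {
  configs <- list(nca_config(lambda_z_mode = "fixed", fixed_k = 0.3),
                  nca_config())
  set.seed(41)
  profiles <- c(study, replicate(5, random_declining_profile(6),
                                 simplify = FALSE))
  for (p in profiles) {
    if (is.na(p$dose_mg)) p$dose_mg <- 4
    for (cfg in configs) {
      r <- run_nca(p, cfg)
      if (!r$complete) next
      expect_equal(r$t_half_h * r$k_per_h, log(2), tolerance = 1e-10)
      expect_equal(r$mrt_h * r$k_per_h, 1, tolerance = 1e-10)
      expect_equal(r$vd_L * r$k_per_h * r$auclast_mg_h_per_L, r$dose_mg,
                   tolerance = 1e-10)
      expect_equal(r$cl_L_per_h, r$k_per_h * r$vd_L, tolerance = 1e-12)
    }
  }
})

test_that("scale equivariance holds through the whole NCA chain", {
  set.seed(51)
  p <- random_declining_profile(6)
  s <- 3.7
  ps <- pk_profile("scaled", p$points$time_h, s * p$points$conc_mg_per_L,
                   dose_mg = p$dose_mg)
  r1 <- run_nca(p)
  r2 <- run_nca(ps)
  expect_equal(r2$cmax_mg_per_L, s * r1$cmax_mg_per_L)
  expect_equal(r2$auclast_mg_h_per_L, s * r1$auclast_mg_h_per_L)
  expect_equal(r2$k_per_h, r1$k_per_h, tolerance = 1e-10)
  expect_equal(r2$t_half_h, r1$t_half_h, tolerance = 1e-10)
  expect_equal(r2$mrt_h, r1$mrt_h, tolerance = 1e-10)
  expect_equal(r2$vd_L, r1$vd_L / s, tolerance = 1e-10)
})

test_that("profiles without a usable terminal phase yield partial results", {
  allblq <- pk_profile("b", c(0, 1, 2), c(0, 0, 0), blq = rep(TRUE, 3),
                       dose_mg = 4)
  r <- run_nca(allblq)
  expect_false(r$complete)
  expect_equal(r$cmax_mg_per_L, 0)
  rising <- pk_profile("r", c(1, 2, 4), c(1, 2, 3), dose_mg = 4)
  r2 <- run_nca(rising)
  expect_false(r2$complete)
  expect_equal(r2$cmax_mg_per_L, 3)
  expect_false(is.na(r2$auclast_mg_h_per_L))
  expect_true(is.na(r2$k_per_h))
})
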