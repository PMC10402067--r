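test_that("occupancy ODEs satisfy boundary conditions and conservation", {
  ind <- default_induction()
  tp <- cc_timepoints()
  sol <- solve_turnover_odes(1, log(2) / 5, ind, tp)
  expect_equal(sol$theta_B[sol$time == 0], 0)
  expect_equal(sol$theta_ratio[sol$time == 0], 0)
  expect_equal(sol$theta_A[sol$time == 0], 1 / (1 + log(2) / 5))
  # late-time plateau reaches the induction amplitude
  late <- solve_turnover_odes(1, log(2) / 5, ind, c(0, 1000))
  expect_lt(abs(late$theta_ratio[2] - ind$XP) / ind$XP, 0.005)
  # no induction: constitutive isoform stays at steady state, competitor at 0
  flat <- induction_model(XP = 1e-12, t_half_ind = 43, n = 4)
  s0 <- solve_turnover_odes(2, 0.3, flat, tp)
  expect_equal(s0$theta_A, rep(2 / 2.3, length(s0$time)), tolerance = 1e-6)
  expect_lt(max(s0$theta_B), 1e-10)
  # conservation on random parameter draws
  set.seed(42)
  for (i in 1:50) {
    ka <- exp(stats::runif(1, log(1e-2), log(1e2)))
    kd <- exp(stats::runif(1, log(log(2) / 1000), log(log(2) / 0.05)))
    s <- solve_turnover_odes(ka, kd, ind, tp)
    expect_true(all(s$theta_A + s$theta_B <= 1 + 1e-8))
    expect_true(all(s$theta_A >= -1e-10 & s$theta_B >= -1e-10))
  }
  expect_error(solve_turnover_odes(-1, 1, ind, tp), "positive")
})

test_that("fast exchange collapses the ratio onto the induction curve", {
  ind <- default_induction()
  tp <- cc_timepoints()
  sol <- solve_turnover_odes(1, log(2) / 0.01, ind, tp)
  expect_lt(max(abs(sol$theta_ratio - induction_curve(ind, tp))), 0.01)
})

test_that("site Hill fit recovers amplitude, half-time and background", {
  tp <- cc_timepoints()
  R <- 0.8 * hill_value(tp, 1, 35, 4) + 0.1
  f <- fit_site_hill(tp, R, 4)
  expect_true(f$converged)
  expect_equal(f$XCC, 0.8, tolerance = 1e-4)
  expect_equal(f$t_half_cc, 35, tolerance = 1e-4)
  expect_equal(f$B, 0.1, tolerance = 1e-4)
  # constant series: amplitude collapses, flagged degenerate
  fc <- fit_site_hill(tp, rep(0.4, length(tp)), 4)
  expect_true(fc$degenerate || !fc$converged)
  # a series equal to the induction curve has the induction half-time
  ind <- default_induction()
  fi <- fit_site_hill(tp, induction_curve(ind, tp), 4)
  expect_equal(fi$t_half_cc, ind$t_half_ind, tolerance = 1e-3)
})

test_that("occupancy scaling obeys its boundary cases", {
  expect_equal(scale_to_occupancy_ratio(0.2, XCC = 0.7, B = 0.2, XP = 1), 0)
  expect_equal(scale_to_occupancy_ratio(0.2 + 0.7, XCC = 0.7, B = 0.2, XP = 1), 1)
  R <- c(0.1, 0.4, 0.9)
  expect_equal(scale_to_occupancy_ratio(R, XCC = 1, B = 0, XP = 1), R)
  expect_error(scale_to_occupancy_ratio(R, XCC = 0, B = 0, XP = 1), "XCC")
})

test_that("residence-time initializer follows the lag formula with clamping", {
  expect_equal(initialize_half_time(50, 43), 4.3)
  expect_equal(initialize_half_time(43, 43), 0.1)
  expect_equal(initialize_half_time(40, 43), 0.1)
})

test_that("turnover fit recovers rates from noise-free occupancy series", {
  ind <- default_induction()
  tp <- cc_timepoints()
  th <- solve_turnover_odes(1, log(2) / 5, ind, tp)$theta_ratio
  f <- fit_turnover(tp, th, ind, init_t_half = 2)
  expect_true(f$converged)
  expect_equal(f$t_half, 5, tolerance = 0.01)
  expect_equal(f$t_half, log(2) / f$kd)
  expect_gt(f$adj_r2, 0.999)
  # a series equal to the induction curve itself is reliably fast
  fi <- fit_turnover(tp, induction_curve(ind, tp), ind, init_t_half = 1)
  expect_lt(fi$t_half, 1)
  # all-zero series cannot be fit
  fz <- fit_turnover(tp, rep(0, length(tp)), ind, init_t_half = 1)
  expect_false(fz$converged)
})

test_that("residence time equals ln2 over the off-rate", {
  ind <- default_induction()
  tp <- cc_timepoints()
  for (t12 in c(1, 10)) {
    th <- solve_turnover_odes(1, log(2) / t12, ind, tp)$theta_ratio
    f <- fit_turnover(tp, th, ind, init_t_half = t12)
    expect_equal(f$t_half * f$kd, log(2), tolerance = 1e-12)
    expect_equal(f$t_half, t12, tolerance = 0.02)
  }
})

test_that("the site half-time lag decreases with the off-rate", {
  ind <- default_induction()
  tp <- cc_timepoints()
  lags <- vapply(c(0.5, 2, 5, 15, 30), function(t12) {
    th <- solve_turnover_odes(1, log(2) / t12, ind, tp)$theta_ratio
    fit_site_hill(tp, th, ind$n)$t_half_cc - ind$t_half_ind
  }, numeric(1))
  expect_true(all(diff(lags) > 0))  # lag grows with residence time (1/kd)
})

test_that("reliability filter enforces both strict thresholds", {
  mk <- function(rel_err, r2) tibble::tibble(
    kacA = 1, kd = 1, delta_kd = rel_err, adj_r2 = r2, t_half = log(2),
    init_t_half = 1, converged = TRUE, at_bound = FALSE
  )
  expect_true(filter_fits(mk(2.9, 0.71)))
  expect_false(filter_fits(mk(3.0, 0.99)))
  expect_false(filter_fits(mk(0.5, 0.70)))
  expect_false(filter_fits(dplyr::mutate(mk(0.5, 0.9), at_bound = TRUE)))
  expect_false(filter_fits(dplyr::mutate(mk(0.5, 0.9), converged = FALSE)))
})

test_that("fast-site classifier applies the strict 2-minute lag rule", {
  ind <- default_induction()
  tp <- cc_timepoints()
  # identity with the induction curve: zero lag, reliably fast
  r1 <- tibble::tibble(site_id = "fast", time = tp,
                       R = induction_curve(ind, tp))
  out1 <- classify_fast_sites(r1, ind)
  expect_identical(out1$class, "reliably_fast")
  expect_equal(out1$delta_t_half, 0, tolerance = 0.02)
  # a site lagging by exactly 2 min fails the strict inequality
  r2 <- tibble::tibble(site_id = "lag2", time = tp,
                       R = hill_value(tp, 1, ind$t_half_ind + 2, ind$n))
  out2 <- classify_fast_sites(r2, ind)
  expect_identical(out2$class, "unreliable")
  # constant series cannot be rescaled: unreliable
  r3 <- tibble::tibble(site_id = "flat", time = tp, R = 0.5)
  expect_identical(classify_fast_sites(r3, ind)$class, "unreliable")
})

test_that("refined initializer map recovers an exact linear relation", {
  lag <- seq(0.5, 40, length.out = 25)
  t12 <- 0.6 * lag + 0.1
  map <- estimate_init_map(t12, lag)
  expect_identical(map$degree, 1L)
  expect_equal(map$coef[1], 0.1, tolerance = 1e-3)
  expect_equal(map$coef[2], 0.6, tolerance = 1e-3)
  expect_equal(map$predict(10), 6.1, tolerance = 1e-6)
  expect_equal(map$predict(-5), 0.1)  # clamped below
  # quadratic relations select the quadratic map
  t12q <- 0.02 * lag^2 + 0.3 * lag + 0.1
  mapq <- estimate_init_map(t12q, lag)
  expect_identical(mapq$degree, 2L)
  expect_error(estimate_init_map(1:5, 1:5), "at least 10")
})

test_that("cohort fitting classifies sites and falls back gracefully", {
  ind <- default_induction()
  e <- simulate_experiment(12, t_half_range = c(1, 15), seed = 6,
                           noise = noise_model(ratio_noise = 0.05),
                           sample_counts = FALSE)
  ratios <- dplyr::select(e$ratio, site_id, time, R)
  # too few sites for the refinement: falls back with a warning
  expect_warning(
    res <- fit_turnover_sites(ratios[ratios$site_id %in%
                                       e$truth$site_id[1:3], ], ind),
    "default initializer"
  )
  expect_identical(nrow(res$records), 3L)
  expect_true(all(res$records$class %in%
                    c("estimated", "reliably_fast", "unreliable")))
  # full cohort: estimated sites carry residence times, others do not
  res2 <- fit_turnover_sites(ratios, ind, two_pass = FALSE)
  est <- res2$records$class == "estimated"
  expect_true(all(is.finite(res2$records$t_half[est])))
  expect_true(all(is.na(res2$records$t_half[!est])))
  expect_s3_class(glance(res2), "tbl_df")
  expect_identical(glance(res2)$n_sites, 12L)
})
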