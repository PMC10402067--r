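#' Solve the mass-action turnover ODEs
#'
#' Integrates the coupled occupancy equations for the constitutive (Myc, "A")
#' and induced competitor (HA, "B") isoforms of a factor competing for the
#' same chromatin site:
#' \deqn{d\theta_B/dt = k_a c_A \, \frac{c_B(t)}{c_A} (1 - \theta_A - \theta_B) - k_d \theta_B}
#' \deqn{d\theta_A/dt = k_a c_A (1 - \theta_A - \theta_B) - k_d \theta_A}
#' Both isoforms share the on-rate product `kacA` and off-rate `kd`. The
#' competitor abundance \eqn{c_B(t)/c_A} follows the fitted induction curve.
#' Initial conditions are \eqn{\theta_B(0) = 0} and \eqn{\theta_A(0)} at the
#' pre-induction steady state \eqn{k_a c_A / (k_a c_A + k_d)}, which
#' enforces the boundary conditions \eqn{\theta_B(0)/\theta_A(0) = 0} and
#' \eqn{\theta_B/\theta_A \to X_P} as \eqn{t \to \infty}.
#'
#' Only the product \eqn{k_a c_A} enters the model; the on-rate and the free
#' protein concentration are not separately identifiable from ratio data.
#'
#' @param kacA Effective on-rate \eqn{k_a c_A} in min^-1 (`> 0`).
#' @param kd Off-rate in min^-1 (`> 0`). Residence time is `log(2)/kd`.
#' @param induction A `cc_induction_fit` giving \eqn{c_B(t)/c_A}.
#' @param times Evaluation times in minutes (must include or start at 0).
#' @param rtol,atol Integrator tolerances (adaptive `lsoda`).
#' @return A tibble with columns `time`, `theta_A`, `theta_B`, `theta_ratio`
#'   (`theta_B / theta_A`).
#' @examples
#' fit <- induction_model(XP = 1, t_half_ind = 43, n = 4)
#' solve_turnover_odes(1, log(2) / 5, fit, cc_timepoints())
#' @export
solve_turnover_odes <- function(kacA, kd, induction, times,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(induction, "cc_induction_fit"))
  if (!is.finite(kacA) || kacA <= 0 || !is.finite(kd) || kd <= 0) {
    stop("`kacA` and `kd` must be positive and finite", call. = FALSE)
  }
  times <- sort(unique(c(0, times)))
  XP <- induction$XP; th <- induction$t_half_ind; n <- induction$n
  y0 <- c(A = kacA / (kacA + kd), B = 0)
  rhs <- function(t, y, parms) {
    cb <- if (t <= 0) 0 else XP * (t / th)^n / (1 + (t / th)^n)
    free <- 1 - y[[1]] - y[[2]]
    list(c(kacA * free - kd * y[[1]],
           kacA * cb * free - kd * y[[2]]))
  }
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 rtol = rtol, atol = atol, maxsteps = 20000),
    warning = function(w) {
      stop(sprintf("ODE solver failed (kacA = %g, kd = %g): %s",
                   kacA, kd, conditionMessage(w)), call. = FALSE)
    },
    error = function(e) {
      stop(sprintf("ODE solver failed (kacA = %g, kd = %g): %s",
                   kacA, kd, conditionMessage(e)), call. = FALSE)
    }
  )
  tibble::tibble(
    time = sol[, "time"],
    theta_A = sol[, "A"],
    theta_B = sol[, "B"],
    theta_ratio = sol[, "B"] / sol[, "A"]
  )
}

# theta_B/theta_A at given times; the model curve fitted to scaled data
turnover_ratio_curve <- function(kacA, kd, induction, times) {
  sol <- solve_turnover_odes(kacA, kd, induction, times)
  sol$theta_ratio[match(times, sol$time)]
}

#' Per-site descriptive Hill fit of a ratio series
#'
#' Fits \eqn{R(t) = X_{CC} \, (t/t_{1/2CC})^n / (1 + (t/t_{1/2CC})^n) + B}
#' to a site's normalized HA/Myc ChIP ratio series, with the integer Hill
#' coefficient `n` held fixed at the value selected by the protein induction
#' fit. The fitted amplitude, half-time rise and additive background are used
#' to scale the series to occupancy-ratio units and to initialize the
#' turnover fit through \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind}}.
#'
#' Starting values are `t_half_cc = 40` min and `XCC = 1`; the background is
#' constrained nonnegative.
#'
#' @param times Measurement times in minutes.
#' @param R Normalized HA/Myc ratio at each time.
#' @param n Integer Hill coefficient from the induction fit.
#' @return A one-row tibble: `XCC`, `t_half_cc`, `B`, `n`, `adj_r2`,
#'   `converged`, `degenerate`.
#' @export
fit_site_hill <- function(times, R, n) {
  stopifnot(length(times) == length(R), length(times) >= 5)
  d <- tibble::tibble(time = times, R = R)
  fail <- tibble::tibble(XCC = NA_real_, t_half_cc = NA_real_, B = NA_real_,
                         n = as.integer(n), adj_r2 = NA_real_,
                         converged = FALSE, degenerate = FALSE)
  amp0 <- max(R) - min(R)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      R ~ hill_value(time, XCC, t_half_cc, n) + B,
      data = d,
      start = list(t_half_cc = 40, XCC = 1, B = max(min(R), 0)),
      lower = c(t_half_cc = 1e-3, XCC = 1e-8, B = 0),
      upper = c(t_half_cc = 1000, XCC = 100, B = max(R) + 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  tibble::tibble(
    XCC = unname(cf[["XCC"]]),
    t_half_cc = unname(cf[["t_half_cc"]]),
    B = unname(cf[["B"]]),
    n = as.integer(n),
    adj_r2 = adjusted_r2(d$R, stats::fitted(fit), p = 3),
    converged = TRUE,
    degenerate = unname(cf[["XCC"]]) < max(1e-3, 0.01 * amp0)
  )
}

#' Scale a ratio series to occupancy-ratio units
#'
#' Applies the observation transform
#' \eqn{\theta_B(t)/\theta_A(t) = (X_P / X_{CC}) (R(t) - B)}:
#' the site background is subtracted and the series rescaled by the site and
#' induction amplitudes so that it satisfies the turnover-model boundary
#' conditions (0 at `t = 0`, plateau `XP` at late times). Values are floored
#' at 0, since fractional occupancies cannot be negative.
#'
#' @param R Normalized HA/Myc ratio series.
#' @param XCC,B Site Hill amplitude and background from [fit_site_hill()].
#' @param XP Induction plateau amplitude.
#' @return Numeric vector \eqn{\theta_B/\theta_A} of the same length as `R`.
#' @export
scale_to_occupancy_ratio <- function(R, XCC, B, XP) {
  if (!is.finite(XCC) || XCC <= 0) stop("`XCC` must be positive", call. = FALSE)
  pmax((XP / XCC) * (R - B), 0)
}

#' Initial residence-time guess from the site/induction half-time lag
#'
#' The lag of a site's ratio rise behind the protein induction curve,
#' \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind}}, approximates the residence
#' time. The default first-pass initializer is
#' \eqn{t_{1/2}^0 = 0.6\,(t_{1/2CC} - t_{1/2ind}) + 0.1} minutes, clamped
#' below at 0.1 min so that sites rising faster than the induction curve
#' still start from a small positive residence time.
#'
#' @param t_half_cc Site Hill half-time (min).
#' @param t_half_ind Induction half-time (min).
#' @return Initial residence-time guess in minutes.
#' @examples
#' initialize_half_time(50, 43) # 4.3
#' @export
initialize_half_time <- function(t_half_cc, t_half_ind) {
  stopifnot(all(t_half_cc > 0), all(t_half_ind > 0))
  pmax(0.6 * (t_half_cc - t_half_ind) + 0.1, 0.1)
}

#' Fit the turnover model to one occupancy-ratio series
#'
#' Nonlinear least squares of the ODE-predicted occupancy ratio
#' \eqn{\theta_B(t)/\theta_A(t)} (see [solve_turnover_odes()]) against a
#' background-subtracted, scaled competition ChIP series. The fit is
#' parameterized in \eqn{(\log k_a c_A, \log k_d)} with box bounds
#' `kd` in `[log(2)/1000, log(2)/0.01]` min^-1 and `kacA` in `[1e-3, 1e3]`
#' min^-1; solutions pinned at a bound are flagged unreliable. The off-rate
#' standard error `delta_kd` comes from the Gauss-Newton covariance at the
#' optimum (delta method through the log parameterization), and the residence
#' time is \eqn{t_{1/2} = \ln 2 / k_d}.
#'
#' @param times Measurement times (min), at least 5 points.
#' @param theta_ratio Scaled occupancy-ratio observations.
#' @param induction A `cc_induction_fit`.
#' @param init_t_half Initial residence-time guess (min); see
#'   [initialize_half_time()].
#' @param init_kacA Initial on-rate product guess (min^-1).
#' @param extra_starts Fallback residence-time starts (min) tried in
#'   addition to `init_t_half`; the converged solution with the lowest
#'   residual sum of squares is kept. Guards against local optima on flat
#'   likelihood surfaces.
#' @param warm_pair Optional `c(kacA, t_half)` warm start (e.g. a previous
#'   pass's optimum) tried in addition to the other starts.
#' @return One-row tibble: `kacA`, `kd`, `delta_kd`, `adj_r2`, `t_half`,
#'   `init_t_half`, `converged`, `at_bound`.
#' @export
fit_turnover <- function(times, theta_ratio, induction, init_t_half,
                         init_kacA = 1, extra_starts = c(0.5, 5, 40),
                         warm_pair = NULL) {
  stopifnot(length(times) == length(theta_ratio))
  fail <- tibble::tibble(kacA = NA_real_, kd = NA_real_, delta_kd = NA_real_,
                         adj_r2 = NA_real_, t_half = NA_real_,
                         init_t_half = init_t_half,
                         converged = FALSE, at_bound = FALSE)
  if (length(times) < 5) return(fail)
  if (all(theta_ratio <= 0)) return(fail)

  lo <- c(log(1e-3), log(log(2) / 1000))
  hi <- c(log(1e3), log(log(2) / 0.01))
  resid_fn <- function(p) {
    pred <- tryCatch(
      turnover_ratio_curve(exp(p[1]), exp(p[2]), induction, times),
      error = function(e) rep(1e6, length(times))
    )
    pred - theta_ratio
  }
  starts <- lapply(unique(c(init_t_half, extra_starts)),
                   function(t) c(init_kacA, t))
  if (!is.null(warm_pair) && all(is.finite(warm_pair))) {
    starts <- c(starts, list(warm_pair))
  }
  out <- NULL
  for (st in starts) {
    par0 <- pmin(pmax(c(log(st[1]), log(log(2) / st[2])), lo), hi)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (is.null(cand) || cand$info %in% c(0, 5, 9)) next
    if (is.null(out) || sum(cand$fvec^2) < sum(out$fvec^2)) out <- cand
  }
  if (is.null(out)) return(fail)
  p <- out$par
  kacA <- exp(p[1]); kd <- exp(p[2])
  pred <- turnover_ratio_curve(kacA, kd, induction, times)
  r2 <- adjusted_r2(theta_ratio, pred, p = 2)

  # SE of log kd from the full Gauss-Newton covariance sigma^2 (J'J)^-1,
  # delta method to the kd scale. The near-flat on-rate direction inflates
  # delta_kd for weakly identified fits, which is exactly what the
  # downstream reliability filter keys on.
  eps <- 1e-6
  dof <- length(times) - 2
  sigma2 <- sum(out$fvec^2) / max(dof, 1)
  cov_log <- tryCatch(sigma2 * solve(out$hessian), error = function(e) NULL)
  var_log_kd <- if (is.null(cov_log)) NA_real_ else cov_log[2, 2]
  delta_kd <- if (!is.finite(var_log_kd) || var_log_kd < 0) Inf else
    kd * sqrt(var_log_kd)

  # only the off-rate bound matters for reliability; kacA pinning is the
  # expected behaviour of a parameter the observable is insensitive to
  at_bound <- p[2] <= lo[2] + eps || p[2] >= hi[2] - eps
  tibble::tibble(
    kacA = kacA, kd = kd, delta_kd = delta_kd, adj_r2 = r2,
    t_half = log(2) / kd, init_t_half = init_t_half,
    converged = TRUE, at_bound = at_bound
  )
}

#' Reliability filter for turnover fits
#'
#' A fitted site is reliable when the off-rate relative error satisfies
#' `delta_kd / kd < 3` and the adjusted R-squared exceeds `0.7` (both strict
#' inequalities), and the optimizer converged away from the parameter bounds.
#' Only reliable fits contribute residence-time estimates downstream.
#'
#' @param fit A turnover-fit table ([fit_turnover()] rows).
#' @param max_rel_error Strict upper bound on `delta_kd / kd`. Default 3.
#' @param min_adj_r2 Strict lower bound on adjusted R-squared. Default 0.7.
#' @return Logical vector: is each fit reliable?
#' @export
filter_fits <- function(fit, max_rel_error = 3, min_adj_r2 = 0.7) {
  stopifnot(is.data.frame(fit))
  ok <- fit$converged & !fit$at_bound &
    is.finite(fit$delta_kd) & is.finite(fit$kd) & is.finite(fit$adj_r2)
  ok & (fit$delta_kd / fit$kd < max_rel_error) & (fit$adj_r2 > min_adj_r2)
}

#' Classify reliably fast sites
#'
#' Sites without a reliable turnover-model residence time are re-examined
#' with a descriptive Hill fit: each site's ratio series is min-max rescaled
#' to `[0, 1]`, fitted to the Hill equation with the induction fit's integer
#' coefficient (starting values `t_half_cc = 40`, `XCC = 1`), and classified
#' `reliably_fast` when its half-time lag behind the induction curve,
#' \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind}}, is strictly less than
#' `max_lag` minutes. Such sites track the competitor induction so closely
#' that their residence time is reported as "< 1 min" rather than as a
#' numeric estimate; all other sites are `unreliable`.
#'
#' @param ratios A ratio table in long form: columns `site_id`, `time`, `R`.
#'   Should contain only sites lacking an estimated residence time.
#' @param induction A `cc_induction_fit`.
#' @param max_lag Strict threshold on the half-time lag (min). Default 2.
#' @return A tibble: `site_id`, `class` (`"reliably_fast"` or
#'   `"unreliable"`), `delta_t_half`.
#' @export
classify_fast_sites <- function(ratios, induction, max_lag = 2) {
  stopifnot(inherits(induction, "cc_induction_fit"))
  check_ratio_long(ratios)
  ratios |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      rng <- range(d$R)
      if (diff(rng) <= 0) {
        return(tibble::tibble(class = "unreliable", delta_t_half = NA_real_))
      }
      y <- (d$R - rng[1]) / diff(rng)
      sf <- fit_site_hill_scaled(d$time, y, induction$n)
      if (!sf$converged) {
        return(tibble::tibble(class = "unreliable", delta_t_half = NA_real_))
      }
      lag <- sf$t_half_cc - induction$t_half_ind
      tibble::tibble(
        class = if (lag < max_lag) "reliably_fast" else "unreliable",
        delta_t_half = lag
      )
    }) |>
    dplyr::ungroup()
}

# Hill fit without background for [0,1]-rescaled series (fast-site classifier)
fit_site_hill_scaled <- function(times, y, n) {
  d <- tibble::tibble(time = times, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ hill_value(time, XCC, t_half_cc, n),
      data = d,
      start = list(t_half_cc = 40, XCC = 1),
      lower = c(t_half_cc = 1e-3, XCC = 1e-8),
      upper = c(t_half_cc = 1000, XCC = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(t_half_cc = NA_real_, XCC = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  tibble::tibble(t_half_cc = unname(cf[["t_half_cc"]]),
                 XCC = unname(cf[["XCC"]]), converged = TRUE)
}

#' Refined initializer map from first-pass fits
#'
#' Regresses first-pass residence times on the half-time lag
#' \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind}} with degree-1 and degree-2
#' polynomials and keeps the one with the higher adjusted R-squared. The
#' chosen polynomial replaces the default initializer
#' ([initialize_half_time()]) in the second fitting pass. Only reliable
#' first-pass fits enter the regression.
#'
#' @param t_half First-pass residence times (reliable fits only).
#' @param delta_t_half Corresponding half-time lags (min).
#' @return A list with `degree`, `coef` (intercept-first), `adj_r2`, and
#'   `predict(x)` evaluating the map clamped below at 0.1 min.
#' @export
estimate_init_map <- function(t_half, delta_t_half) {
  stopifnot(length(t_half) == length(delta_t_half))
  keep <- is.finite(t_half) & is.finite(delta_t_half)
  t_half <- t_half[keep]; delta_t_half <- delta_t_half[keep]
  if (length(t_half) < 10) {
    stop("need at least 10 reliable fits to refine the initializer", call. = FALSE)
  }
  d <- tibble::tibble(y = t_half, x = delta_t_half)
  m1 <- stats::lm(y ~ x, data = d)
  m2 <- stats::lm(y ~ x + I(x^2), data = d)
  a1 <- adjusted_r2(d$y, stats::fitted(m1), p = 1)
  a2 <- adjusted_r2(d$y, stats::fitted(m2), p = 2)
  if (a2 > a1) {
    cf <- stats::coef(m2); deg <- 2L; ar <- a2
  } else {
    cf <- stats::coef(m1); deg <- 1L; ar <- a1
  }
  cf <- unname(cf)
  list(
    degree = deg, coef = cf, adj_r2 = ar,
    predict = function(x) {
      v <- cf[1] + cf[2] * x + if (deg == 2L) cf[3] * x^2 else 0
      pmax(v, 0.1)
    }
  )
}

#' Fit residence times for a cohort of sites
#'
#' The full per-site estimation pipeline for a table of normalized HA/Myc
#' ratio series:
#' 1. per-site Hill fit ([fit_site_hill()]) with the induction fit's integer
#'    coefficient, giving `XCC`, `t_half_cc`, `B`;
#' 2. scaling to occupancy-ratio units ([scale_to_occupancy_ratio()]);
#' 3. first-pass turnover fit ([fit_turnover()]) initialized by
#'    [initialize_half_time()];
#' 4. optionally, a second pass whose initializer is the polynomial lag map
#'    refit from reliable first-pass fits ([estimate_init_map()]); the
#'    refined pass falls back to the default initializer (with a warning)
#'    when fewer than 10 reliable fits are available;
#' 5. reliability filtering ([filter_fits()]) and classification of the
#'    remaining sites as reliably fast or unreliable
#'    ([classify_fast_sites()]).
#'
#' @param ratios Long ratio table: `site_id`, `time`, `R`.
#' @param induction A `cc_induction_fit`.
#' @param two_pass Run the refined second pass? Default `TRUE`.
#' @param max_rel_error,min_adj_r2,max_lag Filter and classifier thresholds;
#'   see [filter_fits()] and [classify_fast_sites()].
#' @return An object of class `cc_turnover_fits`: a list with
#'   `fits` (per-site tibble: site Hill parameters, turnover parameters,
#'   `reliable`, `class`, `t_half`), `records` (site_id, class, t_half),
#'   `init_map` (NULL for single pass), `first_pass` (the pass-1 fit table),
#'   and `induction`.
#' @export
fit_turnover_sites <- function(ratios, induction, two_pass = TRUE,
                               max_rel_error = 3, min_adj_r2 = 0.7,
                               max_lag = 2) {
  stopifnot(inherits(induction, "cc_induction_fit"))
  check_ratio_long(ratios)
  nested <- ratios |>
    dplyr::arrange(.data$site_id, .data$time) |>
    tidyr::nest(series = c("time", "R"))

  site_fits <- nested |>
    dplyr::mutate(hill = purrr::map(.data$series, function(s) {
      fit_site_hill(s$time, s$R, induction$n)
    })) |>
    tidyr::unnest("hill") |>
    dplyr::rename(hill_adj_r2 = "adj_r2", hill_converged = "converged")

  # warm: named vector of previous-pass residence times used as extra starts,
  # so a refit can never lose a solution the first pass already found
  run_pass <- function(init_fun, warm = NULL) {
    site_fits |>
      dplyr::mutate(fit = purrr::pmap(
        list(.data$site_id, .data$series, .data$XCC, .data$B,
             .data$t_half_cc, .data$hill_converged, .data$degenerate),
        function(id, s, XCC, B, t_half_cc, converged, degenerate) {
          if (!converged || degenerate || !is.finite(XCC) || XCC <= 0) {
            return(tibble::tibble(
              kacA = NA_real_, kd = NA_real_, delta_kd = NA_real_,
              adj_r2 = NA_real_, t_half = NA_real_, init_t_half = NA_real_,
              converged = FALSE, at_bound = FALSE))
          }
          theta <- scale_to_occupancy_ratio(s$R, XCC, B, induction$XP)
          fit_turnover(s$time, theta, induction, init_fun(t_half_cc),
                       warm_pair = if (is.null(warm)) NULL else warm[[id]])
        })) |>
      tidyr::unnest("fit")
  }

  default_init <- function(t_half_cc) {
    initialize_half_time(t_half_cc, induction$t_half_ind)
  }
  pass1 <- run_pass(default_init)
  pass1$reliable <- filter_fits(pass1, max_rel_error, min_adj_r2)

  init_map <- NULL
  final <- pass1
  if (two_pass) {
    rel <- dplyr::filter(pass1, .data$reliable)
    if (nrow(rel) >= 10) {
      init_map <- estimate_init_map(rel$t_half,
                                    rel$t_half_cc - induction$t_half_ind)
      warm <- stats::setNames(
        purrr::map2(pass1$kacA, pass1$t_half, c), pass1$site_id)
      pass2 <- run_pass(function(t_half_cc) {
        init_map$predict(t_half_cc - induction$t_half_ind)
      }, warm = warm)
      pass2$reliable <- filter_fits(pass2, max_rel_error, min_adj_r2)
      final <- pass2
    } else {
      warning("fewer than 10 reliable first-pass fits; ",
              "keeping the default initializer", call. = FALSE)
    }
  }

  final$class <- ifelse(final$reliable, "estimated", NA_character_)
  pending <- final$site_id[!final$reliable]
  if (length(pending)) {
    fast <- classify_fast_sites(
      dplyr::filter(ratios, .data$site_id %in% pending),
      induction, max_lag = max_lag
    )
    final <- dplyr::rows_update(final,
                                dplyr::select(fast, "site_id", "class"),
                                by = "site_id", unmatched = "ignore")
  }
  final$class[is.na(final$class)] <- "unreliable"

  records <- final |>
    dplyr::transmute(
      .data$site_id, .data$class,
      t_half = dplyr::if_else(.data$class == "estimated", .data$t_half, NA_real_)
    )
  structure(
    list(fits = dplyr::select(final, -"series"), records = records,
         init_map = init_map,
         first_pass = dplyr::select(pass1, -"series"),
         induction = induction),
    class = "cc_turnover_fits"
  )
}

check_ratio_long <- function(ratios) {
  stopifnot(is.data.frame(ratios))
  if (!all(c("site_id", "time", "R") %in% names(ratios))) {
    stop("ratio table must have columns `site_id`, `time`, `R`", call. = FALSE)
  }
  invisible(ratios)
}

#' @export
print.cc_turnover_fits <- function(x, ...) {
  tab <- table(x$records$class)
  cat("Competition ChIP turnover fits:", nrow(x$records), "sites\n")
  for (cl in names(tab)) cat(sprintf("  %-14s %d\n", cl, tab[[cl]]))
  if (!is.null(x$init_map)) {
    cat(sprintf("  second-pass initializer: degree-%d polynomial of the half-time lag\n",
                x$init_map$degree))
  }
  invisible(x)
}

#' Tidy a cohort turnover fit
#'
#' @param x A `cc_turnover_fits` object.
#' @param ... Unused.
#' @return The per-site fit tibble (one row per site).
#' @export
tidy.cc_turnover_fits <- function(x, ...) x$fits

#' One-row cohort summary of a turnover fit
#'
#' @param x A `cc_turnover_fits` object.
#' @param ... Unused.
#' @return A one-row tibble with site counts per class and the median
#'   adjusted R-squared of reliable fits.
#' @export
glance.cc_turnover_fits <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$records),
    n_estimated = sum(x$records$class == "estimated"),
    n_reliably_fast = sum(x$records$class == "reliably_fast"),
    n_unreliable = sum(x$records$class == "unreliable"),
    median_adj_r2 = stats::median(x$fits$adj_r2[x$fits$reliable], na.rm = TRUE)
  )
}

#' Plot the residence-time distribution of a cohort fit
#'
#' Histogram of estimated residence times; reliably fast sites (reported as
#' "< 1 min") are drawn as uniform draws on (0, 1) left of a dashed line,
#' mirroring the plotting convention for sites without a numeric estimate.
#'
#' @param object A `cc_turnover_fits` object.
#' @param seed Seed for the uniform plotting draws. Default 42.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_turnover_fits <- function(object, seed = 42, ...) {
  rec <- object$records
  fast <- rec$class == "reliably_fast"
  if (any(fast)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    rec$t_half[fast] <- stats::runif(sum(fast), 0, 1)
    restore_seed(old)
  }
  rec <- dplyr::filter(rec, .data$class != "unreliable")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$t_half, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "residence time (min)", y = "sites",
                  fill = NULL,
                  title = "Residence-time distribution")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
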