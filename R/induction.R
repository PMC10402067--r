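#' Hill curve value
#'
#' Evaluates the Hill induction curve
#' \deqn{f(t) = X \frac{(t/t_{1/2})^n}{1 + (t/t_{1/2})^n}}
#' which describes the rise of the competitor-to-constitutive protein ratio
#' \eqn{c_B(t)/c_A} after induction: zero at \eqn{t = 0}, half the amplitude
#' at \eqn{t = t_{1/2}}, and a plateau of \eqn{X} at late times.
#'
#' @param t Time in minutes (vectorised, must be `>= 0`).
#' @param X Plateau amplitude (dimensionless ratio).
#' @param t_half Half-time in minutes (`> 0`).
#' @param n Hill coefficient (`> 0`; integer in the induction fit).
#' @return Numeric vector of curve values, same length as `t`.
#' @examples
#' hill_value(43, X = 1, t_half = 43, n = 4) # 0.5 by definition
#' @export
hill_value <- function(t, X, t_half, n) {
  if (!is.numeric(t_half) || any(t_half <= 0)) {
    stop("`t_half` must be positive", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  if (any(n <= 0)) stop("`n` must be positive", call. = FALSE)
  r <- (t / t_half)^n
  X * r / (1 + r)
}

#' Fit the competitor-induction Hill model to Western-blot ratio series
#'
#' Fits the induction curve [hill_value()] to measured HA/Myc relative protein
#' levels over time, pooling replicates as independent observations. The Hill
#' coefficient is restricted to integers: for each `n` in `n_grid` the
#' amplitude and half-time are fit by bounded Levenberg-Marquardt least
#' squares, and the integer whose fit maximizes the adjusted R-squared is
#' returned.
#'
#' Adjusted R-squared is \eqn{1 - (1 - R^2)(N - 1)/(N - p - 1)} with `N`
#' pooled observations and `p = 2` fitted parameters (the Hill coefficient is
#' fixed within each candidate fit).
#'
#' @param data A data frame with columns `time` (minutes), `replicate`, and
#'   `ratio` (dimensionless HA/Myc protein level).
#' @param n_grid Integer Hill coefficients to try. Default `1:10`.
#' @return An object of class `cc_induction_fit`: a list with elements
#'   `XP`, `t_half_ind`, `n`, `adj_r2`, `param_stats` (tibble of estimates
#'   and standard errors), and `data` (the input measurements).
#' @examples
#' tp <- cc_timepoints()
#' d <- tibble::tibble(time = tp, replicate = 1L,
#'                     ratio = hill_value(tp, 1, 43, 4))
#' fit <- fit_hill_induction(d)
#' fit$t_half_ind
#' @export
fit_hill_induction <- function(data, n_grid = 1:10) {
  stopifnot(is.data.frame(data))
  req <- c("time", "ratio")
  if (!all(req %in% names(data))) {
    stop("`data` must have columns `time` and `ratio`", call. = FALSE)
  }
  d <- dplyr::filter(data, !is.na(.data$time), !is.na(.data$ratio))
  if (length(unique(d$time)) < 4) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  if (max(d$ratio) <= 0 || max(d$ratio) < 1e-8) {
    stop("degenerate input: no measurable amplitude in the ratio series",
         call. = FALSE)
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 1)) stop("`n_grid` must contain positive integers", call. = FALSE)

  # starting values: plateau ~ max ratio, half-time ~ first crossing of half-max
  x0 <- max(d$ratio)
  half_idx <- which(d$ratio >= x0 / 2)
  t0 <- if (length(half_idx)) max(min(d$time[half_idx]), 1) else stats::median(d$time)

  fits <- purrr::map(n_grid, function(n) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ratio ~ hill_value(time, X, t_half, n),
        data = d,
        start = list(X = x0, t_half = t0),
        lower = c(X = 1e-6, t_half = 1e-3),
        upper = c(X = 10, t_half = 500),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    list(n = n, fit = fit, adj_r2 = adjusted_r2(d$ratio, stats::fitted(fit), p = 2))
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) stop("Hill fit failed to converge for every n in the grid", call. = FALSE)

  best <- fits[[which.max(purrr::map_dbl(fits, "adj_r2"))]]
  cf <- stats::coef(best$fit)
  if (cf[["X"]] < 1e-4) {
    stop("degenerate fit: amplitude collapsed to zero", call. = FALSE)
  }
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(X = NA_real_, t_half = NA_real_))
  structure(
    list(
      XP = unname(cf[["X"]]),
      t_half_ind = unname(cf[["t_half"]]),
      n = best$n,
      adj_r2 = best$adj_r2,
      param_stats = tibble::tibble(
        term = c("XP", "t_half_ind"),
        estimate = unname(cf[c("X", "t_half")]),
        std_error = unname(se[c("X", "t_half")])
      ),
      data = tibble::as_tibble(d)
    ),
    class = "cc_induction_fit"
  )
}

#' Construct an induction model from known parameters
#'
#' Builds the same object [fit_hill_induction()] returns, from parameter
#' values directly. Used to drive simulations and to re-load a fitted model.
#'
#' @param XP Plateau amplitude (`> 0`).
#' @param t_half_ind Induction half-time in minutes (`> 0`).
#' @param n Integer Hill coefficient (`>= 1`).
#' @return A `cc_induction_fit` object.
#' @export
induction_model <- function(XP = 1, t_half_ind = 43, n = 4L) {
  stopifnot(XP > 0, t_half_ind > 0, n >= 1)
  structure(
    list(XP = XP, t_half_ind = t_half_ind, n = as.integer(round(n)),
         adj_r2 = NA_real_,
         param_stats = tibble::tibble(
           term = c("XP", "t_half_ind"),
           estimate = c(XP, t_half_ind),
           std_error = NA_real_),
         data = NULL),
    class = "cc_induction_fit"
  )
}

#' Evaluate an induction model curve
#'
#' @param model A `cc_induction_fit` object.
#' @param t Times in minutes.
#' @return Numeric vector \eqn{c_B(t)/c_A}.
#' @export
induction_curve <- function(model, t) {
  stopifnot(inherits(model, "cc_induction_fit"))
  hill_value(t, model$XP, model$t_half_ind, model$n)
}

# adjusted R^2 with p fitted parameters
adjusted_r2 <- function(obs, fitted, p) {
  n <- length(obs)
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' @export
print.cc_induction_fit <- function(x, ...) {
  cat("Competitor induction Hill fit\n")
  cat(sprintf("  XP = %.4g, t_half_ind = %.4g min, n = %d\n",
              x$XP, x$t_half_ind, x$n))
  if (!is.na(x$adj_r2)) cat(sprintf("  adjusted R^2 = %.4f\n", x$adj_r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an induction fit
#'
#' @param x A `cc_induction_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std_error`), including the fixed integer Hill coefficient.
#' @export
tidy.cc_induction_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$param_stats,
    tibble::tibble(term = "n", estimate = as.numeric(x$n), std_error = NA_real_)
  )
}

#' One-row summary of an induction fit
#'
#' @param x A `cc_induction_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `XP`, `t_half_ind`, `n`, `adj_r2`, `n_obs`.
#' @export
glance.cc_induction_fit <- function(x, ...) {
  tibble::tibble(
    XP = x$XP, t_half_ind = x$t_half_ind, n = x$n, adj_r2 = x$adj_r2,
    n_obs = if (is.null(x$data)) NA_integer_ else nrow(x$data)
  )
}

#' Plot an induction fit
#'
#' Measured HA/Myc protein ratios with the fitted Hill curve overlaid.
#'
#' @param object A `cc_induction_fit` with attached data.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cc_induction_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  grid <- tibble::tibble(
    time = seq(0, max(object$data$time), length.out = 200),
    ratio = induction_curve(object, seq(0, max(object$data$time), length.out = 200))
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "time after induction (min)", y = "HA/Myc protein ratio",
      title = sprintf("Hill induction fit: t1/2 = %.1f min, n = %d",
                      object$t_half_ind, object$n)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' The canonical competition-ChIP sampling times
#'
#' The nine sampling times (minutes after galactose addition) used for both
#' Western blots and ChIP-seq time courses: 0, 10, 20, 25, 30, 40, 60, 90,
#' 120.
#'
#' @return Numeric vector of nine times in minutes.
#' @export
cc_timepoints <- function() c(0, 10, 20, 25, 30, 40, 60, 90, 120)
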