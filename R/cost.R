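
#' Fit a 4-parameter logistic to an amplification curve
#'
#' Least-squares fit of \eqn{F(t) = F_0 + A/(1 + e^{-r(t - t_{inf})})} by
#' Levenberg-Marquardt, with initial values taken from the data (baseline =
#' 5th percentile, amplitude = range, inflection = half-range crossing time,
#' rate from the local slope there) and a single restart from a perturbed
#' start on non-convergence. The fitted `tinf` is, by construction, the time
#' of steepest fluorescence increase.
#'
#' Amplification is called failed when the fit does not converge, the signal
#' has zero variance, or the rise of the fitted curve across the observed
#' time window is smaller than 3x the residual standard deviation of the fit
#' — i.e. when no sigmoid rise stands out from the noise within the data.
#' (The window-rise criterion, rather than the raw amplitude, also catches
#' the saturated-logistic degeneracy where a flat signal is fit by a large
#' amplitude with the inflection pushed outside the data.)
#'
#' @param times Strictly increasing numeric vector, minutes (>= 8 points).
#' @param fluorescence Numeric vector of the same length, arbitrary units.
#' @return An object of class `sag_sigmoid_fit`: a list with elements
#'   `f0`, `amplitude`, `rate`, `tinf`, `rss`, `sigma`, `converged`,
#'   `failed_amplification`, and the input data.
#' @seealso [cost_of()], [amplification_costs()]
#' @export
fit_amplification <- function(times, fluorescence) {
  if (length(times) < 8L) stop_invalid("at least 8 time points are required")
  if (length(times) != length(fluorescence) || anyNA(times) || anyNA(fluorescence)) {
    stop_invalid("`times` and `fluorescence` must be equal-length and NA-free")
  }
  if (any(diff(times) <= 0)) stop_invalid("`times` must be strictly increasing")
  y <- fluorescence
  t <- times
  span <- diff(range(t))

  out <- list(
    f0 = NA_real_, amplitude = NA_real_, rate = NA_real_, tinf = NA_real_,
    rss = NA_real_, sigma = NA_real_, converged = FALSE,
    failed_amplification = TRUE, times = t, fluorescence = y
  )
  class(out) <- "sag_sigmoid_fit"

  if (sd(y) == 0) return(out) # perfectly flat: nothing to fit

  init_from <- function(jitter = 0) {
    f0 <- unname(quantile(y, 0.05)) + jitter * 0.05 * diff(range(y))
    a <- diff(range(y)) * (1 + jitter * 0.2)
    half <- f0 + a / 2
    i <- which(y >= half)[1L]
    tinf <- if (is.na(i)) mean(t) else t[i]
    # logistic slope at inflection is A*r/4
    i0 <- max(1L, i - 2L); i1 <- min(length(t), ifelse(is.na(i), 2L, i + 2L))
    slope <- (y[i1] - y[i0]) / (t[i1] - t[i0])
    r <- max(4 * slope / a, 1e-3)
    c(f0 = f0, a = a, r = r, tinf = tinf + jitter * 0.1 * span)
  }
  do_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ f0 + a / (1 + exp(-r * (t - tinf))),
        start = as.list(start),
        lower = c(f0 = -Inf, a = 0, r = 1e-6, tinf = min(t) - span),
        upper = c(f0 = Inf, a = Inf, r = Inf, tinf = max(t) + span),
        control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                             maxiter = 500L)
      ),
      error = function(e) NULL
    )
  }
  fit <- do_fit(init_from(0))
  if (is.null(fit)) fit <- do_fit(init_from(1))
  if (is.null(fit)) return(out)

  cf <- coef(fit)
  rss <- sum(resid(fit)^2)
  sigma <- sqrt(rss / max(length(y) - 4L, 1L))
  out$f0 <- unname(cf["f0"])
  out$amplitude <- unname(cf["a"])
  out$rate <- unname(cf["r"])
  out$tinf <- unname(cf["tinf"])
  out$rss <- rss
  out$sigma <- sigma
  out$converged <- TRUE
  logi <- function(tt) out$f0 + out$amplitude / (1 + exp(-out$rate * (tt - out$tinf)))
  rise <- logi(max(t)) - logi(min(t))
  out$failed_amplification <- rise < 3 * sigma
  out
}

#' @export
print.sag_sigmoid_fit <- function(x, ...) {
  cat("<sag_sigmoid_fit>", if (x$failed_amplification) "FAILED amplification" else "",
      "\n", sep = "")
  if (x$converged) {
    cat(sprintf("  F0 = %.4g  A = %.4g  r = %.4g /min  tinf = %.4g min\n",
                x$f0, x$amplitude, x$rate, x$tinf))
  }
  invisible(x)
}

#' Selection cost of a fitted amplification curve
#'
#' The cost handed to the cell-selection optimizer is the time to reach the
#' inflection point of the amplification curve; cells whose amplification
#' failed get cost `+Inf` and are thereby excluded from selection.
#'
#' @param fit A `sag_sigmoid_fit` from [fit_amplification()].
#' @return A single number, minutes (or `Inf`).
#' @export
cost_of <- function(fit) {
  stopifnot(inherits(fit, "sag_sigmoid_fit"))
  if (!fit$converged || fit$failed_amplification) return(Inf)
  fit$tinf
}

#' Fit all curves in a long table and derive selection costs
#'
#' @param curves Long tibble: `cell_id`, `time_min`, `fluorescence` (as
#'   emitted by [sim_curves()]).
#' @return Tibble, one row per cell: fitted parameters, `converged`,
#'   `failed`, and `cost` (minutes; `Inf` for failed cells).
#' @export
amplification_costs <- function(curves) {
  stopifnot(all(c("cell_id", "time_min", "fluorescence") %in% names(curves)))
  bind_rows(purrr::map(split(curves, curves$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    f <- fit_amplification(d$time_min, d$fluorescence)
    tibble(
      cell_id = d$cell_id[1L], f0 = f$f0, amplitude = f$amplitude,
      rate = f$rate, tinf = f$tinf, rss = f$rss, converged = f$converged,
      failed = f$failed_amplification, cost = cost_of(f)
    )
  })) |> arrange(.data$cell_id)
}

#' Calibrate cell diameter against forward scatter
#'
#' Flow-cytometric forward scatter (FSC) correlates strongly with cell size;
#' diameters are modeled on the log-log scale as
#' \deqn{D = 10^{a \log_{10}(FSC) - b}}
#' with `a` and `b` estimated by ordinary least squares of `log10(D)` on
#' `log10(FSC)`.
#'
#' @param fsc Positive forward-scatter values (>= 2 distinct).
#' @param diameters Positive cell diameters (micrometers), same length.
#' @return An object of class `sag_calibration`: list with `a`, `b`,
#'   `r_squared`, `n`.
#' @export
fit_fsc_calibration <- function(fsc, diameters) {
  if (length(fsc) < 2L || length(unique(fsc)) < 2L) {
    stop_invalid("at least 2 distinct FSC values are required")
  }
  if (length(fsc) != length(diameters) || any(fsc <= 0) || any(diameters <= 0)) {
    stop_invalid("FSC and diameter values must be positive and matched")
  }
  x <- log10(fsc)
  y <- log10(diameters)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      a = unname(coef(fit)[2L]),
      b = -unname(coef(fit)[1L]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      n = length(fsc)
    ),
    class = "sag_calibration"
  )
}

#' Predict cell diameter from forward scatter
#'
#' Applies \eqn{D = 10^{a \log_{10}(FSC) - b}} from a fitted
#' [fit_fsc_calibration()] model.
#'
#' @param model A `sag_calibration`.
#' @param fsc Positive forward-scatter value(s).
#' @return Predicted diameter(s), micrometers.
#' @export
predict_diameter <- function(model, fsc) {
  stopifnot(inherits(model, "sag_calibration"))
  if (any(fsc <= 0)) stop_invalid("`fsc` must be positive")
  10^(model$a * log10(fsc) - model$b)
}

#' @export
print.sag_calibration <- function(x, ...) {
  cat(sprintf("<sag_calibration> D = 10^(%.4g * log10(FSC) - %.4g), R^2 = %.4f (n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

# broom-style accessors ------------------------------------------------------

#' @export
tidy.sag_sigmoid_fit <- function(x, ...) {
  tibble(
    term = c("f0", "amplitude", "rate", "tinf"),
    estimate = c(x$f0, x$amplitude, x$rate, x$tinf)
  )
}

#' @export
glance.sag_sigmoid_fit <- function(x, ...) {
  tibble(rss = x$rss, sigma = x$sigma, converged = x$converged,
         failed_amplification = x$failed_amplification)
}

#' @export
tidy.sag_calibration <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.sag_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}
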