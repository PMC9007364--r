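#' Simulate real-time whole-genome-amplification curves
#'
#' Successful cells follow a 4-parameter logistic
#' \deqn{F(t) = F_0 + A / (1 + e^{-r (t - t_{inf})})}
#' plus Gaussian noise of SD `config$curve_noise_sd`; a `failure_rate`
#' fraction of cells produce a flat baseline plus noise (failed
#' amplification). The true inflection time of every successful cell is
#' recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @param times Strictly increasing time grid in minutes.
#' @return A list with
#'   \describe{
#'     \item{curves}{long tibble: `cell_id`, `time_min`, `fluorescence`.}
#'     \item{truth}{tibble: `cell_id`, `failed`, `true_inflection` (minutes,
#'       `NA` for failed cells), `true_rate`, `true_baseline`,
#'       `true_amplitude`.}
#'   }
#' @export
sim_curves <- function(config, times = seq(0, 160, by = 2)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(diff(times) <= 0)) stop_invalid("`times` must be strictly increasing.")
  n <- config$n_cells
  with_seed(derive_seed(config$seed, 3L), {
    failed <- runif(n) < config$failure_rate
    span <- diff(range(times))
    tinf <- runif(n, min(times) + 0.25 * span, min(times) + 0.75 * span)
    rate <- runif(n, 0.10, 0.30)
    f0 <- runif(n, 0.05, 0.15)
    amp <- runif(n, 0.8, 1.2)
    tinf[failed] <- NA_real_
    ids <- sprintf("cell%03d", seq_len(n))
    curves <- purrr::map(seq_len(n), function(i) {
      mu <- if (failed[i]) {
        rep(f0[i], length(times))
      } else {
        f0[i] + amp[i] / (1 + exp(-rate[i] * (times - tinf[i])))
      }
      tibble(
        cell_id = ids[i],
        time_min = times,
        fluorescence = mu + rnorm(length(times), 0, config$curve_noise_sd)
      )
    })
    list(
      curves = bind_rows(curves),
      truth = tibble(
        cell_id = ids, failed = failed, true_inflection = tinf,
        true_rate = rate, true_baseline = f0, true_amplitude = amp
      )
    )
  })
}
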