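#' Overall yield of a multi-step single-round transcription
#'
#' The multiplicative step-yield model `E = Ei * Ee^n`: initiation succeeds
#' with probability `Ei`, and each of the `n` post-initiation pause-restart
#' steps retains a fraction `Ee` of elongating complexes.
#'
#' @param Ei Initiation efficiency, in (0, 1].
#' @param Ee Per-step elongation efficiency, in (0, 1].
#' @param n Number of post-initiation steps (non-negative integer); see
#'   [steps_to_n()].
#' @return The overall efficiency `E` in (0, 1].
#' @examples
#' overall_yield(0.8, 0.9, 2) # 0.648
#' @export
overall_yield <- function(Ei, Ee, n) {
  check_prob(Ei, "Ei", open_zero = TRUE)
  check_prob(Ee, "Ee", open_zero = TRUE)
  if (any(n < 0) || any(n != floor(n))) abort("`n` must be a non-negative integer")
  Ei * Ee^n
}

check_prob <- function(x, name, open_zero = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) ||
      any(if (open_zero) x <= 0 else x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in %s", name, if (open_zero) "(0, 1]" else "[0, 1]"))
  }
  invisible(x)
}

#' Post-initiation step count of a k-step reaction
#'
#' A k-step pause-restart reaction has `n = k - 1` post-initiation steps
#' (2, 5, 7 and 9 for the 3-, 6-, 8- and 10-step designs).
#'
#' @param k_steps Total number of steps (>= 1).
#' @return `k_steps - 1`.
#' @export
steps_to_n <- function(k_steps) {
  if (any(k_steps < 1) || any(k_steps != floor(k_steps))) {
    abort("`k_steps` must be an integer >= 1")
  }
  k_steps - 1L
}

#' Fit the multiplicative step-yield model
#'
#' Fits `E = Ei * Ee^n` to observed overall yields by unweighted least squares
#' in log space, where the model is exactly linear:
#' `log E = log Ei + n log Ee`. Back-transformed estimates above 1 are clipped
#' to 1 with an explicit flag — efficiencies are probabilities.
#'
#' @param observations A data frame with columns `n` (post-initiation steps)
#'   and `E` (overall yield in (0, 1]); at least two distinct `n` required.
#' @return An object of class `plor_yield_fit`: a list with `Ei`, `Ee`,
#'   `clipped` (flag), the underlying `lm` fit, the data, and residual
#'   summaries (`sigma`, `max_abs_resid`, on the log scale). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' obs <- data.frame(n = c(2, 5, 7, 9), E = overall_yield(0.8, 0.9, c(2, 5, 7, 9)))
#' fit_yield_params(obs)
#' @export
fit_yield_params <- function(observations) {
  obs <- as.data.frame(observations)
  if (!all(c("n", "E") %in% names(obs))) {
    abort("`observations` must have columns `n` and `E`")
  }
  if (any(!is.finite(obs$E)) || any(obs$E <= 0) || any(obs$E > 1)) {
    abort("every `E` must lie in (0, 1]")
  }
  if (nrow(obs) < 2L || length(unique(obs$n)) < 2L) {
    abort("underdetermined: need observations at >= 2 distinct n")
  }
  fit <- lm(log(E) ~ n, data = obs)
  Ei_raw <- exp(coef(fit)[[1]])
  Ee_raw <- exp(coef(fit)[[2]])
  clipped <- Ei_raw > 1 || Ee_raw > 1
  res <- stats::residuals(fit)
  structure(
    list(
      Ei = min(Ei_raw, 1), Ee = min(Ee_raw, 1),
      Ei_raw = Ei_raw, Ee_raw = Ee_raw, clipped = clipped,
      fit = fit, data = tibble::as_tibble(obs),
      sigma = stats::sigma(fit), max_abs_resid = max(abs(res))
    ),
    class = "plor_yield_fit"
  )
}

#' @export
print.plor_yield_fit <- function(x, ...) {
  cat(sprintf("Step-yield model E = Ei * Ee^n\n  Ei = %.6g  Ee = %.6g%s\n",
              x$Ei, x$Ee, if (x$clipped) "  (clipped to <= 1)" else ""))
  cat(sprintf("  n = %d observations; residual sd (log scale) = %.3g\n",
              nrow(x$data), x$sigma))
  invisible(x)
}

#' @rdname fit_yield_params
#' @param x A `plor_yield_fit`.
#' @param ... Unused.
#' @method tidy plor_yield_fit
#' @export
tidy.plor_yield_fit <- function(x, ...) {
  tibble(
    term = c("Ei", "Ee"),
    estimate = c(x$Ei, x$Ee),
    raw_estimate = c(x$Ei_raw, x$Ee_raw),
    clipped = c(x$Ei_raw > 1, x$Ee_raw > 1)
  )
}

#' @rdname fit_yield_params
#' @method glance plor_yield_fit
#' @export
glance.plor_yield_fit <- function(x, ...) {
  tibble(
    Ei = x$Ei, Ee = x$Ee, clipped = x$clipped,
    sigma = x$sigma, max_abs_resid = x$max_abs_resid,
    # noiseless data fit exactly; summary.lm warns on such fits
    r.squared = suppressWarnings(summary(x$fit)$r.squared),
    nobs = nrow(x$data)
  )
}

#' Predict overall yields from a fitted step-yield model
#'
#' @param object A `plor_yield_fit`.
#' @param n Step counts at which to predict.
#' @param ... Unused.
#' @return Numeric vector of predicted overall efficiencies.
#' @export
predict.plor_yield_fit <- function(object, n, ...) {
  overall_yield(object$Ei, object$Ee, n)
}

#' Termination efficiency from band signals
#'
#' Termination efficiency is the fraction of terminated product in the total
#' transcripts, `T / (T + FL)`; the read-through ratio is `FL / T`, i.e.
#' `(1 - efficiency) / efficiency`, reported as `NA` when `T = 0`.
#'
#' @param T Terminated band signal (arbitrary units, >= 0). Vectorized.
#' @param FL Full-length band signal (>= 0). Vectorized.
#' @return A tibble with columns `T`, `FL`, `efficiency`, `ratio_FL_T`.
#' @examples
#' termination_efficiency(3, 1) # efficiency 0.75, ratio 1/3
#' @export
termination_efficiency <- function(T, FL) {
  if (any(!is.finite(T)) || any(!is.finite(FL)) || any(T < 0) || any(FL < 0)) {
    abort("`T` and `FL` must be finite and >= 0")
  }
  if (any(T + FL == 0)) abort("no signal: T + FL = 0")
  tibble(
    T = as.numeric(T), FL = as.numeric(FL),
    efficiency = T / (T + FL),
    ratio_FL_T = ifelse(T > 0, FL / T, NA_real_)
  )
}
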