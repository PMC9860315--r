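#' Extract per-application peak currents from a continuous trace
#'
#' For each application window, the baseline is the median current over the
#' 2 s preceding the application onset, and the peak is the baseline-
#' subtracted extremum within the window (sign retained, so inward currents
#' give negative peaks). Adding a constant offset to the whole trace leaves
#' the peaks unchanged.
#'
#' @param trace A `tevc_trace` (or any data frame with `time_s`,
#'   `current_uA`).
#' @param windows Data frame with `t_on`, `t_off` in seconds; defaults to the
#'   windows attached to a simulated trace.
#' @return Numeric vector of signed peak currents, microamperes.
#' @export
extract_peak_currents <- function(trace, windows = attr(trace, "windows")) {
  if (is.null(windows)) stop_input("application windows required")
  t <- trace$time_s
  i <- trace$current_uA
  vapply(seq_len(nrow(windows)), function(k) {
    on <- windows$t_on[k]
    off <- windows$t_off[k]
    if (on < min(t) || off > max(t) + 1e-9) {
      stop_input("application window outside trace")
    }
    pre <- i[t >= on - 2 & t < on]
    inside <- i[t >= on & t < off]
    base <- if (length(pre)) median(pre) else inside[1L]
    centered <- inside - base
    centered[which.max(abs(centered))]
  }, numeric(1))
}

#' Normalize peak currents to each oocyte's maximum
#'
#' Each oocyte's peak magnitudes are divided by that oocyte's maximum
#' absolute peak, so every oocyte's largest response maps to 1 (polarity is
#' dropped; inward and outward peaks are treated by magnitude). Oocytes whose
#' peaks are all zero carry no information and are excluded with a warning.
#' The operation is idempotent.
#'
#' @param peaks_by_oocyte Data frame with `oocyte_id`, `conc_uM`, `peak_uA`.
#' @return A `dose_response` data frame (`oocyte_id`, `conc_uM`, `response`).
#' @export
normalize_responses <- function(peaks_by_oocyte) {
  need <- c("oocyte_id", "conc_uM", "peak_uA")
  if (!all(need %in% names(peaks_by_oocyte))) {
    stop_input("need columns: ", paste(need, collapse = ", "))
  }
  parts <- lapply(split(peaks_by_oocyte, peaks_by_oocyte$oocyte_id),
                  function(sub) {
    m <- max(abs(sub$peak_uA))
    if (m == 0) {
      warning("oocyte ", sub$oocyte_id[1L], " has all-zero peaks; excluded")
      return(NULL)
    }
    data.frame(oocyte_id = sub$oocyte_id, conc_uM = sub$conc_uM,
               response = abs(sub$peak_uA) / m)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) stop_input("no usable oocytes")
  structure(do.call(rbind, c(parts, list(make.row.names = FALSE))),
            class = c("dose_response", "data.frame"))
}

# One Hill fit of fixed order via Levenberg-Marquardt least squares on the
# log-concentration scale. `order` 3 fixes bottom = 0 (activation) or
# top = fixed_top (inhibition); order 4 frees all four parameters.
fit_hill_model <- function(conc, response, mode, order, fixed_top = 1) {
  df <- data.frame(lc = log(conc), r = response)
  s <- if (mode == "activation") 1 else -1
  lec0 <- {
    mid <- (max(response) + min(response)) / 2
    df$lc[which.min(abs(response - mid))]
  }
  top0 <- max(response)
  bot0 <- min(response)
  fit <- if (order == 3 && mode == "activation") {
    minpack.lm::nlsLM(
      r ~ top / (1 + exp(s * n * (lec - lc))), data = df,
      start = list(top = top0, n = 1, lec = lec0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  } else if (order == 3) {
    minpack.lm::nlsLM(
      r ~ bottom + (fixed_top - bottom) / (1 + exp(s * n * (lec - lc))),
      data = df,
      start = list(bottom = bot0, n = 1, lec = lec0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  } else {
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + exp(s * n * (lec - lc))), data = df,
      start = list(bottom = bot0, top = top0, n = 1, lec = lec0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  n_obs <- nrow(df)
  k <- length(cf) + 1  # + residual variance
  aicc <- AIC(fit) + 2 * k * (k + 1) / (n_obs - k - 1)
  se_lec <- tryCatch(sqrt(diag(vcov(fit)))[["lec"]], error = function(e) NA_real_)
  list(
    ec50 = exp(cf[["lec"]]),
    hill = cf[["n"]],
    top = if ("top" %in% names(cf)) cf[["top"]] else fixed_top,
    bottom = if ("bottom" %in% names(cf)) cf[["bottom"]] else 0,
    rss = rss, aicc = aicc,
    se_log_ec50 = se_lec,
    r_squared = 1 - rss / max(sum((response - mean(response))^2),
                              .Machine$double.eps),
    order = order
  )
}

select_hill_fit <- function(conc, response, mode, fixed_top = 1) {
  f3 <- tryCatch(fit_hill_model(conc, response, mode, 3, fixed_top),
                 error = function(e) e)
  f4 <- tryCatch(fit_hill_model(conc, response, mode, 4, fixed_top),
                 error = function(e) e)
  if (inherits(f3, "error") && inherits(f4, "error")) {
    stop_input("Hill fit failed to converge (order 3: ", conditionMessage(f3),
               "; order 4: ", conditionMessage(f4), ")")
  }
  if (inherits(f3, "error")) return(f4)
  if (inherits(f4, "error")) return(f3)
  # Both orders converged. On essentially exact data both residuals vanish and
  # the information criteria degenerate; parsimony keeps the nested model.
  scale2 <- max(sum(response^2), .Machine$double.eps)
  if (f3$rss <= 1e-16 * scale2 && f4$rss <= 1e-16 * scale2) return(f3)
  # The extra parameter must buy a conventional AICc margin (> 2) to be kept.
  if (is.finite(f4$aicc) && is.finite(f3$aicc) && f4$aicc < f3$aicc - 2) f4 else f3
}

finish_hill_fit <- function(sel, conc, mode) {
  if (sel$ec50 < min(conc) || sel$ec50 > max(conc)) {
    warning(sprintf(
      "fitted %s (%.3g uM) lies outside the tested concentration range; extrapolated",
      if (mode == "activation") "EC50" else "IC50", sel$ec50))
  }
  structure(
    list(
      ec50 = sel$ec50, hill_coefficient = sel$hill,
      top = sel$top, bottom = sel$bottom,
      model_order = sel$order, mode = mode,
      goodness = list(rss = sel$rss, r_squared = sel$r_squared,
                      aicc = sel$aicc),
      se_log_ec50 = sel$se_log_ec50
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$mode == "activation") "EC50" else "IC50"
  cat(sprintf("%d-parameter Hill fit (%s): %s = %.4g uM, n = %.3g, top = %.3g, bottom = %.3g, R^2 = %.4f\n",
              x$model_order, x$mode, lab, x$ec50, x$hill_coefficient,
              x$top, x$bottom, x$goodness$r_squared))
  invisible(x)
}

# Returns TRUE when the responses carry no dose dependence worth fitting.
check_dose_response <- function(dr, mode) {
  need <- c("conc_uM", "response")
  if (!all(need %in% names(dr))) {
    stop_input("need columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(dr$conc_uM)) < 3L) {
    stop_input("need at least 3 distinct concentrations")
  }
  flat <- diff(range(dr$response)) < 0.02 * max(abs(dr$response), 1e-12)
  if (flat) {
    warning("responses are essentially flat; half-maximal concentration unidentifiable")
  }
  flat
}

# Degenerate fit returned for flat data: everything that depends on a dose
# response is missing, the constant level is kept.
degenerate_hill_fit <- function(dr, mode) {
  structure(
    list(ec50 = NA_real_, hill_coefficient = NA_real_,
         top = mean(dr$response), bottom = mean(dr$response),
         model_order = NA_integer_, mode = mode,
         goodness = list(rss = sum((dr$response - mean(dr$response))^2),
                         r_squared = NA_real_, aicc = NA_real_),
         se_log_ec50 = NA_real_),
    class = "hill_fit"
  )
}

#' Fit the Hill activation model and estimate the EC50
#'
#' Fits `response = bottom + (top - bottom) / (1 + (ec50 / c)^n)` to pooled
#' normalized responses, in both the three-parameter form (bottom fixed at 0)
#' and the free four-parameter form, and keeps the model with the better
#' small-sample-corrected information criterion (AICc); the extra parameter is
#' retained only when it improves AICc by more than the conventional margin
#' of 2, so nested-model parsimony wins on ties. An EC50 outside the tested
#' concentration range triggers an extrapolation warning.
#'
#' @param dr A `dose_response` data frame (`conc_uM`, `response`), e.g. from
#'   [normalize_responses()] or [simulate_dose_response()].
#' @return A `hill_fit` object: `ec50` (uM), `hill_coefficient`, `top`,
#'   `bottom`, `model_order` (3 or 4), `mode`, `goodness` (RSS, R-squared,
#'   AICc) and the standard error of log(EC50).
#' @export
fit_hill_activation <- function(dr) {
  if (check_dose_response(dr, "activation")) {
    return(degenerate_hill_fit(dr, "activation"))
  }
  sel <- select_hill_fit(dr$conc_uM, dr$response, "activation")
  finish_hill_fit(sel, dr$conc_uM, "activation")
}

#' Fit the Hill inhibition model and estimate the IC50
#'
#' For antagonist titrations at a fixed agonist dose: fits the decreasing
#' Hill curve `response = bottom + (top - bottom) / (1 + (c / ic50)^n)`. The
#' three-parameter form fixes the top at the uninhibited control response
#' (`agonist_response`); model selection follows the same AICc-with-margin
#' rule as [fit_hill_activation()].
#'
#' @param dr A `dose_response` data frame of normalized responses at
#'   ascending antagonist concentrations.
#' @param agonist_response Control response without antagonist (fraction,
#'   default 1).
#' @return A `hill_fit` with the IC50 in the `ec50` field and
#'   `mode = "inhibition"`.
#' @export
fit_hill_inhibition <- function(dr, agonist_response = 1) {
  if (check_dose_response(dr, "inhibition")) {
    return(degenerate_hill_fit(dr, "inhibition"))
  }
  sel <- select_hill_fit(dr$conc_uM, dr$response, "inhibition",
                         fixed_top = agonist_response)
  finish_hill_fit(sel, dr$conc_uM, "inhibition")
}

#' Reversal potential of an I-V ramp
#'
#' Locates the zero-current crossing of a voltage ramp: the current is
#' lightly smoothed with a 5-point running median, the sign change is found
#' (if several, the one nearest the median voltage of all sign changes is
#' used), and a local straight line fitted around the crossing gives the
#' root. Invariant to uniform current scaling and to leak conductances
#' sharing the same reversal.
#'
#' @param ramp An `iv_ramp` (or data frame with `voltage_mV`, `current_uA`).
#' @param window_mV Half-width of the local fit window, mV.
#' @return Reversal potential in mV, or `NA` (with a warning) when the
#'   current never changes sign.
#' @export
extract_reversal_potential <- function(ramp, window_mV = 5) {
  v <- ramp$voltage_mV
  i <- ramp$current_uA
  if (length(v) != length(i) || length(v) < 2L) {
    stop_input("ramp needs matched voltage/current arrays of length >= 2")
  }
  s <- if (length(i) >= 5L) runmed(i, 5L) else i
  cross <- which(s[-length(s)] * s[-1L] <= 0 &
                   !(s[-length(s)] == 0 & s[-1L] == 0))
  if (!length(cross) && !any(s == 0)) {
    warning("current never changes sign; reversal potential undefined")
    return(NA_real_)
  }
  vc <- (v[cross] + v[cross + 1L]) / 2
  v0 <- vc[which.min(abs(vc - median(vc)))]
  near <- which(abs(v - v0) <= window_mV)
  if (length(near) < 2L) near <- order(abs(v - v0))[1:5]
  fit <- lm(s[near] ~ v[near])
  b <- coef(fit)
  unname(-b[1L] / b[2L])
}

#' Reversal-potential shift between two extracellular solutions
#'
#' For paired recordings per oocyte (same cell ramped in the reference ND96
#' solution and in an ion-substituted solution), reports the per-oocyte shift
#' `delta = Erev(substituted) - Erev(ND96)` with mean, SEM and N. Under this
#' sign convention a chloride channel assayed in a low-chloride substitution
#' whose planted reversal sits below the ND96 reversal yields a negative mean
#' shift.
#'
#' @param ramps_nd96 List of `iv_ramp` objects in the reference solution.
#' @param ramps_low_cl List of paired ramps in the substituted solution (same
#'   length and order).
#' @return An `erev_result` list: `erev_nd96`, `erev_comparison`, `delta`
#'   (per-oocyte vectors, mV), `mean_delta_mV`, `sem_mV`, `n`.
#' @export
delta_erev <- function(ramps_nd96, ramps_low_cl) {
  if (length(ramps_nd96) != length(ramps_low_cl) || !length(ramps_nd96)) {
    stop_input("ramps must be paired per oocyte (equal, non-zero lengths)")
  }
  e1 <- vapply(ramps_nd96, extract_reversal_potential, numeric(1))
  e2 <- vapply(ramps_low_cl, extract_reversal_potential, numeric(1))
  delta <- e2 - e1
  n <- length(delta)
  structure(
    list(erev_nd96 = e1, erev_comparison = e2, delta = delta,
         mean_delta_mV = mean(delta),
         sem_mV = if (n > 1L) sd(delta) / sqrt(n) else 0,
         n = n),
    class = "erev_result"
  )
}

#' Peak-current ratios across repeated agonist pulses
#'
#' `ratio_i = peak_i / peak_1` for every pulse after the first; ratios near 1
#' indicate full recovery from desensitization within the wash interval.
#'
#' @param peaks Signed peak currents from [extract_peak_currents()]
#'   (>= 2 values).
#' @param wash_s Optional wash duration label (10, 30 or 60 s).
#' @return A `pulse_ratios` list: `wash_s`, `ratios`. Ratios are `NA` with a
#'   warning when the first peak is zero.
#' @export
pulse_ratio <- function(peaks, wash_s = NULL) {
  if (length(peaks) < 2L) stop_input("need at least 2 peaks")
  if (peaks[1L] == 0) {
    warning("first peak is zero; ratios undefined")
    ratios <- rep(NA_real_, length(peaks) - 1L)
  } else {
    ratios <- peaks[-1L] / peaks[1L]
  }
  structure(list(wash_s = wash_s, ratios = ratios), class = "pulse_ratios")
}
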