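#' Two-electrode voltage-clamp pulse protocol
#'
#' Describes a repeated agonist-application protocol: fixed-length
#' applications separated by wash periods, at a fixed holding potential and
#' sampling rate. Defaults match a standard oocyte protocol (10-s pulses,
#' 60-s washes, clamp at -60 mV, 500 Hz acquisition); washes of 10, 30 or
#' 60 s are supported.
#'
#' @param pulse_duration_s Agonist application length, seconds.
#' @param wash_s Wash between applications, one of 10, 30, 60 seconds.
#' @param n_pulses Number of applications.
#' @param holding_potential_mV Holding potential, mV.
#' @param sample_rate_Hz Sampling rate, Hz.
#' @return An object of class `tevc_protocol`.
#' @export
tevc_protocol <- function(pulse_duration_s = 10, wash_s = 60, n_pulses = 3,
                          holding_potential_mV = -60, sample_rate_Hz = 500) {
  check_positive(pulse_duration_s, "pulse_duration_s")
  check_positive(n_pulses, "n_pulses")
  check_positive(sample_rate_Hz, "sample_rate_Hz")
  if (!wash_s %in% c(10, 30, 60)) {
    stop_input("`wash_s` must be one of 10, 30, 60")
  }
  structure(
    list(pulse_duration_s = pulse_duration_s, wash_s = wash_s,
         n_pulses = as.integer(n_pulses),
         holding_potential_mV = holding_potential_mV,
         sample_rate_Hz = sample_rate_Hz),
    class = "tevc_protocol"
  )
}

#' Agonist application windows implied by a protocol
#'
#' The simulated trace opens with one wash-length baseline, then alternates
#' application and wash.
#'
#' @param protocol A [tevc_protocol()].
#' @return Data frame with `t_on`, `t_off` (seconds) per pulse.
#' @export
application_windows <- function(protocol) {
  t_on <- protocol$wash_s +
    (seq_len(protocol$n_pulses) - 1L) * (protocol$pulse_duration_s + protocol$wash_s)
  data.frame(t_on = t_on, t_off = t_on + protocol$pulse_duration_s)
}

#' Simulate a TEVC current trace with repeated agonist pulses
#'
#' Baseline-zero trace with square-ish inward (negative) current deflections.
#' The k-th pulse reaches magnitude `peak_uA * (1 - desensitization_fraction)^(k-1)`;
#' onset and offset follow a fast exponential (tau = 0.2 s) so the deflections
#' look like recorded agonist responses rather than ideal squares. Gaussian
#' noise is added throughout.
#'
#' @param protocol A [tevc_protocol()].
#' @param peak_uA First-pulse peak magnitude, microamperes (>= 0).
#' @param desensitization_fraction Fractional peak reduction per pulse, in
#'   `[0, 1)`.
#' @param noise_sd SD of the white instrument noise, microamperes; the noise
#'   is low-pass filtered at 10 Hz before entering the trace, as an
#'   acquisition chain would do, so the recorded noise is smaller and
#'   correlated.
#' @param seed Integer seed.
#' @return A `tevc_trace`: data frame (`time_s`, `current_uA`) with the
#'   protocol, the application windows and the planted peak magnitudes as
#'   attributes.
#' @export
simulate_tevc_trace <- function(protocol, peak_uA, desensitization_fraction = 0,
                                noise_sd = 0, seed = 1) {
  if (!inherits(protocol, "tevc_protocol")) stop_input("need a tevc_protocol")
  check_nonneg(peak_uA, "peak_uA")
  check_nonneg(noise_sd, "noise_sd")
  if (desensitization_fraction < 0 || desensitization_fraction >= 1) {
    stop_input("`desensitization_fraction` must be in [0, 1)")
  }
  win <- application_windows(protocol)
  total_s <- win$t_off[nrow(win)] + protocol$wash_s
  dt <- 1 / protocol$sample_rate_Hz
  time_s <- seq(0, total_s, by = dt)
  tau <- 0.2
  current <- numeric(length(time_s))
  peaks <- peak_uA * (1 - desensitization_fraction)^(seq_len(protocol$n_pulses) - 1L)
  for (k in seq_len(protocol$n_pulses)) {
    on <- time_s >= win$t_on[k] & time_s < win$t_off[k]
    current[on] <- current[on] -
      peaks[k] * (1 - exp(-(time_s[on] - win$t_on[k]) / tau))
    off <- time_s >= win$t_off[k]
    amp_at_off <- peaks[k] * (1 - exp(-protocol$pulse_duration_s / tau))
    current[off] <- current[off] -
      amp_at_off * exp(-(time_s[off] - win$t_off[k]) / tau)
  }
  if (noise_sd > 0) {
    # emulate the 10-Hz acquisition filter: white instrument noise of SD
    # `noise_sd` is low-passed before it reaches the recorded trace
    w <- max(1L, round(protocol$sample_rate_Hz / 10))
    noise <- with_seed(seed, rnorm(length(current) + w - 1L, 0, noise_sd))
    smoothed <- as.numeric(stats::filter(noise, rep(1 / w, w), sides = 1L))
    current <- current + smoothed[w:length(noise)]
  }
  structure(
    data.frame(time_s = time_s, current_uA = current),
    protocol = protocol, windows = win, planted_peaks_uA = peaks,
    class = c("tevc_trace", "data.frame")
  )
}

#' Simulate a linear current-voltage ramp with known reversal potential
#'
#' `I(V) = conductance * (V - erev) + noise`, sampled along a voltage ramp of
#' the stated rate. This is the ion-selectivity protocol: the reversal
#' potential is where the agonist-induced current crosses zero.
#'
#' @param erev_mV Planted reversal potential, mV.
#' @param conductance Chord conductance, microamperes per mV.
#' @param v_range_mV Ramp endpoints, mV (default -80 to +60).
#' @param ramp_rate_mV_per_s Ramp speed, mV/s (default 20).
#' @param noise_sd Gaussian current noise SD, microamperes.
#' @param seed Integer seed.
#' @param sample_rate_Hz Sampling rate, Hz.
#' @param solution Optional solution label (e.g. `"ND96"`, `"NaGluconate"`).
#' @return An `iv_ramp`: data frame (`voltage_mV`, `current_uA`) with the
#'   planted reversal and solution label as attributes.
#' @export
simulate_iv_ramp <- function(erev_mV, conductance, v_range_mV = c(-80, 60),
                             ramp_rate_mV_per_s = 20, noise_sd = 0, seed = 1,
                             sample_rate_Hz = 500, solution = "ND96") {
  check_positive(conductance, "conductance")
  check_nonneg(noise_sd, "noise_sd")
  if (length(v_range_mV) != 2L || v_range_mV[2L] <= v_range_mV[1L]) {
    stop_input("`v_range_mV` must be an increasing pair")
  }
  n <- ceiling(diff(v_range_mV) / ramp_rate_mV_per_s * sample_rate_Hz) + 1L
  voltage <- seq(v_range_mV[1L], v_range_mV[2L], length.out = n)
  current <- conductance * (voltage - erev_mV)
  if (noise_sd > 0) {
    current <- current + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  structure(
    data.frame(voltage_mV = voltage, current_uA = current),
    planted_erev_mV = erev_mV, solution = solution,
    class = c("iv_ramp", "data.frame")
  )
}

#' Simulate per-oocyte dose-response data from a Hill model
#'
#' For activation, the noiseless response at concentration c is
#' `bottom + (top - bottom) / (1 + (ec50 / c)^hill_n)` (increasing);
#' for inhibition the Hill term is `(c / ec50)^hill_n` (decreasing). Each
#' oocyte receives independent Gaussian noise; responses are clipped below at
#' zero (a normalized response cannot be negative).
#'
#' @param ec50_uM Half-maximal concentration (EC50 or IC50), micromolar.
#' @param hill_n Hill coefficient (positive).
#' @param top,bottom Response asymptotes, as fractions of the maximum.
#' @param concentrations_uM Ascending concentrations, micromolar (> 0).
#' @param n_oocytes Number of oocytes.
#' @param noise_sd Gaussian noise SD (fraction of maximum response).
#' @param seed Integer seed.
#' @param mode `"activation"` (rising) or `"inhibition"` (falling).
#' @return A `dose_response` data frame (`oocyte_id`, `conc_uM`, `response`)
#'   with the generating parameters attached as attributes.
#' @export
simulate_dose_response <- function(ec50_uM, hill_n, top = 1, bottom = 0,
                                   concentrations_uM, n_oocytes = 6,
                                   noise_sd = 0, seed = 1,
                                   mode = c("activation", "inhibition")) {
  mode <- match.arg(mode)
  check_positive(ec50_uM, "ec50_uM")
  check_positive(hill_n, "hill_n")
  check_nonneg(noise_sd, "noise_sd")
  if (length(concentrations_uM) == 0L) stop_input("empty concentration list")
  if (any(concentrations_uM <= 0)) stop_input("concentrations must be > 0")
  mu <- hill_response(concentrations_uM, ec50_uM, hill_n, top, bottom, mode)
  with_seed(seed, {
    rows <- lapply(seq_len(n_oocytes), function(o) {
      r <- mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
      data.frame(oocyte_id = o, conc_uM = concentrations_uM,
                 response = pmax(r, 0))
    })
    structure(
      do.call(rbind, rows),
      ec50_uM = ec50_uM, hill_n = hill_n, top = top, bottom = bottom,
      mode = mode,
      class = c("dose_response", "data.frame")
    )
  })
}

# Hill curve shared by the simulator and the fitters.
hill_response <- function(conc, ec50, n, top, bottom, mode) {
  x <- switch(mode,
    activation = (ec50 / conc)^n,
    inhibition = (conc / ec50)^n
  )
  bottom + (top - bottom) / (1 + x)
}
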