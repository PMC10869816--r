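#' Boolean frequency code
#'
#' Frequency bands mapping spike rates to Boolean values: rates in
#' `[0, 5)` Hz encode logic 0, rates in `[5, 20]` Hz encode logic 1 (the
#' 5 Hz boundary belongs to the one-band). One model time unit corresponds
#' to `time_unit_seconds` of wall time; the default 1 ms places typical
#' model inter-spike intervals of 50-200 time units in the 5-20 Hz band.
#'
#' @param threshold_hz decision boundary (default 5).
#' @param zero_hz default encoding rate for logic 0 (default 2).
#' @param one_hz default encoding rate for logic 1 (default 10).
#' @param one_band upper band limits in Hz.
#' @param time_unit_seconds wall-time length of one model time unit.
#' @return An object of class `"bool_freq_code"`.
#' @export
bool_freq_code <- function(threshold_hz = 5, zero_hz = 2, one_hz = 10,
                           one_band = c(5, 20), time_unit_seconds = 1e-3) {
  if (zero_hz >= threshold_hz || one_hz < threshold_hz)
    stop("encoding rates must fall inside their bands")
  structure(list(threshold_hz = threshold_hz, zero_hz = zero_hz,
                 one_hz = one_hz, one_band = one_band,
                 time_unit_seconds = time_unit_seconds),
            class = "bool_freq_code")
}

#' Encode a Boolean value as a periodic spike train
#'
#' @param bit 0 or 1.
#' @param code a [bool_freq_code()].
#' @param duration train duration in model time units (default 1000, i.e.
#'   one second at the default time mapping).
#' @return A `"spike_train"` at the band's default rate (2 Hz for 0,
#'   10 Hz for 1), first spike one period in.
#' @export
encode_boolean <- function(bit, code = bool_freq_code(), duration = 1000) {
  if (!bit %in% c(0, 1)) stop("bit must be 0 or 1")
  hz <- if (bit == 1) code$one_hz else code$zero_hz
  period <- 1 / (hz * code$time_unit_seconds)   # in model time units
  structure(seq(period, duration, by = period), class = "spike_train",
            window = duration)
}

#' Measure the firing rate of a spike train
#'
#' @param train a `"spike_train"` (or numeric spike times, model time
#'   units).
#' @param window observation window in model time units.
#' @param code a [bool_freq_code()] supplying the time mapping.
#' @return Rate in Hz: spike count divided by the window's wall time.
#' @export
measure_frequency <- function(train, window, code = bool_freq_code()) {
  if (window <= 0) stop("window must be positive")
  length(unclass(train)) / (window * code$time_unit_seconds)
}

#' Decode a spike train (or rate) to a Boolean value
#'
#' @param train a `"spike_train"`, or a single rate in Hz.
#' @param code a [bool_freq_code()].
#' @param window observation window in model time units (needed when a
#'   train is given).
#' @return 0 or 1 (`rate >= threshold_hz` maps to 1).
#' @export
decode_boolean <- function(train, code = bool_freq_code(), window = 1000) {
  rate <- if (inherits(train, "spike_train") || length(train) != 1)
    measure_frequency(train, window, code) else as.numeric(train)
  as.integer(rate >= code$threshold_hz)
}

# per-gate synapse weights and bias current, fixed package calibration
# constants (chosen once by a coarse grid scan of the gate neuron's
# steady-state rate-versus-drive response; see the methods vignette)
.sfg_defaults <- list(
  and = list(w = c(0.50, 0.50), bias = 0.50, tau_rise = 60, tau_decay = 120),
  or  = list(w = c(0.46, 0.46), bias = 0.75, tau_rise = 60, tau_decay = 120),
  not = list(w = c(-0.90),      bias = 1.90, tau_rise = 60, tau_decay = 120)
)

#' Calibration parameters of a spike-frequency gate
#'
#' @param kind `"and"`, `"or"` or `"not"`.
#' @return List with per-input synapse weights `w`, bias current `bias` and
#'   the synaptic rise/decay time constants `tau_rise`, `tau_decay` (model
#'   time units).
#' @export
sfg_gate_params <- function(kind = c("and", "or", "not")) {
  .sfg_defaults[[match.arg(kind)]]
}

# double-exponential (alpha-type) current synapse: unit-area impulse into a
# rise stage then a decay stage; the finite rise time keeps the gate drive
# free of step discontinuities, which would otherwise trigger
# adaptation-rebound bursts in the neuron
syn_current <- function(train, n_steps, dt, tau_rise, tau_decay) {
  inc <- numeric(n_steps)
  steps <- pmin(pmax(round(as.numeric(train) / dt), 1), n_steps)
  for (s in steps) inc[s] <- inc[s] + 1
  u <- stats::filter(inc, exp(-dt / tau_rise), method = "recursive")
  as.numeric(stats::filter(as.numeric(u) * (dt / tau_rise),
                           exp(-dt / tau_decay), method = "recursive"))
}

# logic-level restoration: measure the incoming train's band and regenerate
# the canonical carrier of that band over the full run, as a digital gate
# restores its input levels before computing
condition_input <- function(x, code, total) {
  win <- attr(x, "window")
  if (is.null(win)) win <- total
  encode_boolean(decode_boolean(x, code, window = win), code, total)
}

#' Spike-frequency Boolean gate
#'
#' A single CORDIC neuron computes a Boolean function on frequency-coded
#' spike trains: each input train is filtered through a double-exponential
#' current synapse and injected, together with a bias current, into the
#' fixed-point neuron; the output is the neuron's own spike train, whose
#' rate falls in the correct Boolean band for every input combination.
#' The gate neuron uses a faster adaptation rate (r = 0.01) than the
#' default neuron so that its steady firing encodes the mean synaptic
#' drive. As a digital gate restores logic levels, incoming spike trains
#' are first conditioned: their band is decoded and the canonical carrier
#' of that band (2 or 10 Hz) regenerated, which keeps compositions of
#' gates (e.g. De Morgan circuits) robust to off-canonical rates.
#'
#' @param kind `"and"`, `"or"` or `"not"`.
#' @param inputs list of input `"spike_train"`s (2 for and/or, 1 for not),
#'   or plain bits (0/1) which are encoded via [encode_boolean()].
#' @param code a [bool_freq_code()].
#' @param duration evaluation window in model time units.
#' @param settle lead-in time before the evaluation window (model time
#'   units): the gate is a streaming device, so its rate is measured after
#'   the synaptic currents and the neuron's slow adaptation have reached
#'   steady state. Inputs are applied over the whole run.
#' @param params gate calibration, see [sfg_gate_params()].
#' @param neuron an [hr_params()] for the gate neuron (its `I` is replaced
#'   by the gate drive).
#' @param control a [cordic_control()].
#' @return The output `"spike_train"` within the evaluation window (times
#'   relative to the window start), with attributes `rate_hz` and `bit`.
#' @examples
#' \donttest{
#' out <- sfg_gate("and", list(1, 1))
#' attr(out, "bit")   # 1
#' }
#' @export
sfg_gate <- function(kind = c("and", "or", "not"), inputs,
                     code = bool_freq_code(), duration = 1000, settle = 1000,
                     params = sfg_gate_params(kind),
                     neuron = hr_params(r = 0.01),
                     control = cordic_control()) {
  kind <- match.arg(kind)
  n_in <- if (kind == "not") 1L else 2L
  if (!is.list(inputs)) inputs <- as.list(inputs)
  if (length(inputs) != n_in)
    stop(kind, " gate takes ", n_in, " input(s)")
  total <- settle + duration
  inputs <- lapply(inputs, function(x)
    if (inherits(x, "spike_train")) condition_input(x, code, total)
    else encode_boolean(x, code, total))
  n_steps <- as.integer(floor(total / neuron$dt))
  drive <- rep(params$bias, n_steps)
  for (j in seq_len(n_in))
    drive <- drive + params$w[j] * syn_current(inputs[[j]], n_steps,
                                               neuron$dt, params$tau_rise,
                                               params$tau_decay)
  tr <- simulate_hr(neuron, total, model = "cordic", control = control,
                    I_t = drive)
  all_spikes <- as.numeric(detect_spikes(tr))
  out <- structure(all_spikes[all_spikes > settle] - settle,
                   class = "spike_train")
  rate <- measure_frequency(out, duration, code)
  bit <- decode_boolean(rate, code)
  if (bit == 1 && rate > code$one_band[2])
    warning("gate output rate ", rate, " Hz exceeds the one-band")
  attr(out, "rate_hz") <- rate
  attr(out, "bit") <- bit
  attr(out, "window") <- duration
  out
}

#' Measured truth table of a spike-frequency gate
#'
#' Evaluates the gate on every Boolean input combination and reports the
#' measured output rate and decoded bit next to the expected Boolean value.
#'
#' @inheritParams sfg_gate
#' @return data.frame with columns `in1`, `in2` (NA for not), `rate_hz`,
#'   `bit`, `expected`.
#' @export
sfg_truth_table <- function(kind = c("and", "or", "not"),
                            code = bool_freq_code(), duration = 1000, ...) {
  kind <- match.arg(kind)
  combos <- if (kind == "not") data.frame(in1 = c(0, 1), in2 = NA)
            else expand.grid(in1 = c(0, 1), in2 = c(0, 1))
  fun <- switch(kind,
                and = function(a, b) a & b,
                or = function(a, b) a | b,
                not = function(a, b) !a)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    ins <- if (kind == "not") list(combos$in1[i])
           else list(combos$in1[i], combos$in2[i])
    out <- sfg_gate(kind, ins, code = code, duration = duration, ...)
    data.frame(rate_hz = attr(out, "rate_hz"), bit = attr(out, "bit"))
  })
  cbind(combos, do.call(rbind, res),
        expected = as.integer(fun(combos$in1, combos$in2)))
}
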