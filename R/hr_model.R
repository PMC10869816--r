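#' Hindmarsh-Rose model parameters
#'
#' The three-variable Hindmarsh-Rose neuron
#' \deqn{dX/dt = Y + X^2 (3 - X) - Z + I}
#' \deqn{dY/dt = 1 - 5 X^2 - Y}
#' \deqn{dZ/dt = r (4 (X + 1.6) - Z)}
#' where `X` is the membrane potential, `Y` the fast (sodium/potassium)
#' current and `Z` the slow (calcium) adaptation current, all dimensionless.
#' `I` is the stimulation current and `r` the spike-frequency controller;
#' together they select tonic spiking, bursting or chaotic firing. The
#' default initial state is (0.1, 1, 0.2) and the default Euler step
#' `dt = 1/256`, a power of two so the fixed-point datapath can apply it
#' with a single right shift.
#'
#' @param I stimulation current.
#' @param r slow-variable rate constant.
#' @param dt Euler integration step.
#' @param x0,y0,z0 initial state.
#' @return An object of class `"hr_params"`.
#' @export
hr_params <- function(I = 0.5, r = 0.0021, dt = 1 / 256,
                      x0 = 0.1, y0 = 1, z0 = 0.2) {
  if (dt <= 0) stop("dt must be positive")
  if (r < 0) stop("r must be >= 0")
  structure(list(I = I, r = r, dt = dt, x0 = x0, y0 = y0, z0 = z0),
            class = "hr_params")
}

#' @export
print.hr_params <- function(x, ...) {
  cat(sprintf("HR parameters: I = %g, r = %g, dt = 1/%g, init (%g, %g, %g)\n",
              x$I, x$r, 1 / x$dt, x$x0, x$y0, x$z0))
  invisible(x)
}

#' Fixed-point datapath configuration for the CORDIC neuron
#'
#' Bundles the register layout of the multiplier-free datapath: the
#' Q(15,1,10) I/O format of the CORDIC power blocks, the CORDIC iteration
#' schedule, and the fraction width of the wide state accumulators. The
#' state registers keep `state_frac_bits` fractional bits (default 26, a
#' 31-bit payload) because the slow variable's per-step increment,
#' `dt * r * O(1)`, is far below the Q(15,1,10) LSB; the accumulators are
#' truncated to the 15-bit block format at the power-block input registers.
#'
#' @param fmt block I/O [q_format()].
#' @param n_iter,start_index CORDIC schedule, as in [cordic_config()].
#' @param state_frac_bits fractional bits of the state accumulators.
#' @return An object of class `"cordic_control"`.
#' @export
cordic_control <- function(fmt = q_format(), n_iter = 11L, start_index = 0L,
                           state_frac_bits = 26L) {
  state_frac_bits <- as.integer(state_frac_bits)
  if (state_frac_bits < fmt$frac_bits)
    stop("state_frac_bits must be at least the block fraction width")
  structure(list(fmt = fmt, n_iter = as.integer(n_iter),
                 start_index = as.integer(start_index),
                 state_frac_bits = state_frac_bits),
            class = "cordic_control")
}

dt_shift_of <- function(dt) {
  s <- round(log2(1 / dt))
  if (!isTRUE(all.equal(2^-s, dt)))
    stop("the fixed-point model needs dt equal to a power of two (got ", dt, ")")
  as.integer(s)
}

hr_state_vec <- function(s) {
  if (is.list(s)) s <- unlist(s)
  if (length(s) != 3) stop("state must have components X, Y, Z")
  if (!is.null(names(s)) && all(c("X", "Y", "Z") %in% names(s)))
    s <- s[c("X", "Y", "Z")]
  if (any(!is.finite(s))) stop("state must be finite")
  as.numeric(s)
}

#' One Euler step of the floating-point reference neuron
#'
#' @param state named numeric `c(X=, Y=, Z=)` (or unnamed in that order).
#' @param params an [hr_params()].
#' @return The updated state, named numeric of length 3.
#' @export
hr_reference_step <- function(state, params) {
  s <- hr_state_vec(state)
  out <- hr_sim_ref_cpp(s[1], s[2], s[3], params$I, params$r, params$dt, 1L)
  c(X = out$X[2], Y = out$Y[2], Z = out$Z[2])
}

#' One Euler step of the fixed-point CORDIC neuron
#'
#' Implements the discretized multiplier-free update
#' \deqn{X[i+1] = X[i] + dt (Y + 3 POW2(X) - POW3(X) - Z + I)}
#' \deqn{Y[i+1] = Y[i] + dt (1 - 5 POW2(X) - Y)}
#' \deqn{Z[i+1] = Z[i] + dt (4r X + 6.4 r - r Z)}
#' where POW2/POW3 are the CORDIC power blocks, the constants 3 and 5 are
#' shift-add pairs, `dt` is a right shift and the Z-equation constants are
#' applied by canonical-signed-digit shift-add schedules. The incoming state
#' is quantized into the wide state accumulators.
#'
#' @inheritParams hr_reference_step
#' @param control a [cordic_control()].
#' @return The updated state, named numeric of length 3 (values of the wide
#'   fixed-point accumulators).
#' @export
cordic_hr_step <- function(state, params, control = cordic_control()) {
  s <- hr_state_vec(state)
  out <- hr_sim_cordic_cpp(s[1], s[2], s[3], params$I, params$r,
                           dt_shift_of(params$dt), 1L,
                           control$fmt$total_bits, control$fmt$frac_bits,
                           control$n_iter, control$start_index,
                           control$state_frac_bits)
  c(X = out$X[2], Y = out$Y[2], Z = out$Z[2])
}

#' Simulate a single neuron
#'
#' Integrates either the floating-point reference model or the fixed-point
#' CORDIC approximation from the initial state in `params` for `T` time
#' units with first-order Euler steps. Both paths are fully deterministic:
#' identical inputs give bit-identical traces.
#'
#' @param params an [hr_params()].
#' @param T simulation duration in model time units.
#' @param model `"reference"` or `"cordic"`.
#' @param control a [cordic_control()]; ignored for the reference model.
#' @param I_t optional per-step stimulation current vector (length
#'   `floor(T/dt)`), overriding the constant `params$I`; used for synaptic
#'   drive.
#' @return An `"hr_trace"`: data.frame with columns `t`, `X`, `Y`, `Z`
#'   (`floor(T/dt) + 1` rows) and attributes `model_tag` and `params`.
#' @examples
#' tr <- simulate_hr(hr_params(I = 0.5), T = 50, model = "reference")
#' range(tr$X)
#' @export
simulate_hr <- function(params, T, model = c("reference", "cordic"),
                        control = cordic_control(), I_t = NULL) {
  model <- match.arg(model)
  if (T <= 0) stop("T must be positive")
  n_steps <- as.integer(floor(T / params$dt))
  I <- if (is.null(I_t)) params$I else {
    if (length(I_t) != n_steps)
      stop("I_t must have one entry per step (", n_steps, ")")
    as.numeric(I_t)
  }
  out <- if (model == "reference") {
    hr_sim_ref_cpp(params$x0, params$y0, params$z0, I, params$r,
                   params$dt, n_steps)
  } else {
    hr_sim_cordic_cpp(params$x0, params$y0, params$z0, I, params$r,
                      dt_shift_of(params$dt), n_steps,
                      control$fmt$total_bits, control$fmt$frac_bits,
                      control$n_iter, control$start_index,
                      control$state_frac_bits)
  }
  tr <- data.frame(t = (0:n_steps) * params$dt,
                   X = out$X, Y = out$Y, Z = out$Z)
  attr(tr, "model_tag") <- model
  attr(tr, "params") <- params
  class(tr) <- c("hr_trace", "data.frame")
  tr
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf("<hr_trace: %s model, %d samples, t in [0, %g]>\n",
              attr(x, "model_tag"), nrow(x), x$t[nrow(x)]))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
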