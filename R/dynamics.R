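#' Extract spike times from a membrane-potential trace
#'
#' A spike is recorded at each upward crossing of `X` through `threshold`,
#' with successive spikes at least `min_separation` time units apart.
#' Defaults (threshold 1, separation 1) sit well between the Hindmarsh-Rose
#' resting level near -1.6 and the spike peak near 2.
#'
#' @param trace an `"hr_trace"` from [simulate_hr()].
#' @param threshold crossing level on `X`.
#' @param min_separation refractory separation in time units.
#' @return A `"spike_train"`: numeric vector of strictly increasing spike
#'   times (possibly empty).
#' @export
detect_spikes <- function(trace, threshold = 1, min_separation = 1) {
  x <- trace$X
  t <- trace$t
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  times <- t[up]
  if (length(times) > 1 && min_separation > 0) {
    keep <- times[1]
    for (ti in times[-1]) if (ti - keep[length(keep)] >= min_separation)
      keep <- c(keep, ti)
    times <- keep
  }
  structure(as.numeric(times), class = "spike_train",
            threshold = threshold, min_separation = min_separation)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes>\n", length(unclass(x))))
  if (length(x)) print(utils::head(as.numeric(x), 10))
  invisible(x)
}

#' Inter-spike intervals of a spike train
#'
#' @param spikes a `"spike_train"` (or numeric spike times).
#' @return Numeric vector of consecutive differences (all positive).
#' @export
isi <- function(spikes) {
  d <- diff(as.numeric(spikes))
  if (any(d <= 0)) stop("spike times must be strictly increasing")
  d
}

cluster_isis <- function(isis, rel_tol) {
  ord <- order(isis)
  s <- isis[ord]
  brk <- which(diff(s) > rel_tol * pmax(s[-length(s)], .Machine$double.eps))
  cl_sorted <- cumsum(c(1L, seq_along(s)[-1] %in% (brk + 1L)))
  cl <- integer(length(isis))
  cl[ord] <- cl_sorted
  cl
}

#' Classify a steady-state ISI sequence as periodic or chaotic
#'
#' ISIs are grouped into clusters by single-linkage at a relative gap
#' tolerance. The firing pattern is periodic when the cluster count is at
#' most `chaos_k` and the cluster-label sequence repeats cyclically with
#' some period up to `chaos_k`; the reported period is the number of
#' distinct ISI clusters (the number of branches a bifurcation diagram
#' shows). Otherwise the pattern is chaotic. The classification is invariant
#' to uniform time rescaling and to cyclic rotation of the sequence.
#'
#' @param isis numeric vector of at least 20 steady-state ISIs.
#' @param rel_tol relative tolerance for merging ISI values (default 2\%).
#' @param chaos_k maximum cluster count / cycle length still considered
#'   periodic (default 8).
#' @param match_frac minimum fraction of positions a candidate cycle must
#'   explain (default 0.95, absorbing residual transient at the window edge).
#' @return A list with `kind` (`"periodic"` or `"chaotic"`), `period`
#'   (cluster count when periodic, `NA` otherwise) and `n_clusters`.
#' @examples
#' classify_period(rep(c(10, 14), 20))$period   # 2
#' @export
classify_period <- function(isis, rel_tol = 0.02, chaos_k = 8,
                            match_frac = 0.95) {
  if (length(isis) < 20)
    stop("insufficient data: need at least 20 steady-state ISIs, got ",
         length(isis))
  if (any(isis <= 0)) stop("ISIs must be positive")
  cl <- cluster_isis(isis, rel_tol)
  k <- max(cl)
  if (k > chaos_k)
    return(list(kind = "chaotic", period = NA_integer_, n_clusters = k))
  n <- length(cl)
  cyclic <- FALSE
  for (p in seq_len(chaos_k)) {
    if (p >= n) break
    ok <- mean(cl[seq_len(n - p)] == cl[seq_len(n - p) + p]) >= match_frac
    if (ok) { cyclic <- TRUE; break }
  }
  if (cyclic) list(kind = "periodic", period = as.integer(k), n_clusters = k)
  else list(kind = "chaotic", period = NA_integer_, n_clusters = k)
}

#' Bifurcation sweep over a control parameter
#'
#' For each parameter value, simulates the chosen model, discards the
#' transient, extracts the inter-spike intervals and classifies the firing
#' pattern. This reproduces the ISI-versus-parameter bifurcation structure:
#' a period-adding cascade and chaotic windows as `I` or `r` varies.
#'
#' @param param_name `"I"` or `"r"`.
#' @param values numeric vector of parameter values.
#' @param params base [hr_params()] supplying the fixed parameters.
#' @param model `"reference"` or `"cordic"`.
#' @param T simulation duration per value (default 2000 time units).
#' @param transient duration discarded before ISI extraction (default
#'   `T / 2`).
#' @param control a [cordic_control()] for the fixed-point model.
#' @param threshold,min_separation spike detection settings.
#' @param rel_tol,chaos_k classification settings, see [classify_period()].
#' @return An `"hr_bifurcation"`: list with `param_name`, `values`,
#'   `isi_sets` (list of ISI vectors), and `labels` (data.frame with `kind`,
#'   `period`, `n_clusters`, `n_isis`). Points with too few ISIs get kind
#'   `"insufficient"`.
#' @export
bifurcation_sweep <- function(param_name = c("I", "r"), values, params,
                              model = c("reference", "cordic"), T = 2000,
                              transient = T / 2,
                              control = cordic_control(),
                              threshold = 1, min_separation = 1,
                              rel_tol = 0.02, chaos_k = 8) {
  param_name <- match.arg(param_name)
  model <- match.arg(model)
  if (!length(values)) stop("values must be nonempty")
  isi_sets <- vector("list", length(values))
  lab <- data.frame(kind = character(length(values)),
                    period = NA_integer_, n_clusters = NA_integer_,
                    n_isis = NA_integer_)
  for (i in seq_along(values)) {
    p <- params
    p[[param_name]] <- values[i]
    tr <- simulate_hr(p, T, model = model, control = control)
    tr <- tr[tr$t >= transient, , drop = FALSE]
    iv <- tryCatch(isi(detect_spikes(tr, threshold, min_separation)),
                   error = function(e) numeric(0))
    isi_sets[[i]] <- iv
    res <- tryCatch(classify_period(iv, rel_tol, chaos_k),
                    error = function(e) list(kind = "insufficient",
                                             period = NA_integer_,
                                             n_clusters = NA_integer_))
    lab$kind[i] <- res$kind
    lab$period[i] <- res$period
    lab$n_clusters[i] <- res$n_clusters
    lab$n_isis[i] <- length(iv)
  }
  structure(list(param_name = param_name, values = values,
                 isi_sets = isi_sets, labels = lab, model = model),
            class = "hr_bifurcation")
}

#' @export
print.hr_bifurcation <- function(x, ...) {
  cat(sprintf("<hr_bifurcation: %s model, %s in [%g, %g], %d points>\n",
              x$model, x$param_name, min(x$values), max(x$values),
              length(x$values)))
  print(cbind(value = x$values, x$labels))
  invisible(x)
}

#' Time-domain agreement metrics between two signals
#'
#' Mean absolute error, Pearson correlation (sample, n-1 convention) and
#' root-mean-square error between two equal-length signals, the criteria
#' used to score how closely the fixed-point neuron tracks the
#' floating-point reference.
#'
#' @param a,b numeric vectors, or `"hr_trace"` objects (then `channel`
#'   selects the compared state variable).
#' @param channel `"X"`, `"Y"` or `"Z"` when traces are supplied.
#' @return List with `mae`, `corr`, `rmse`, `n`.
#' @examples
#' error_metrics(1:10, 1:10 + 0.5)   # mae = rmse = 0.5, corr = 1
#' @export
error_metrics <- function(a, b, channel = "X") {
  if (inherits(a, "hr_trace")) a <- a[[channel]]
  if (inherits(b, "hr_trace")) b <- b[[channel]]
  if (length(a) != length(b)) stop("signals must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero-variance input")
  list(mae = mean(abs(a - b)),
       corr = stats::cor(a, b),
       rmse = sqrt(mean((a - b)^2)),
       n = n)
}

ref_x_null_xy <- function(x, I, clamp) x^3 - 3 * x^2 + clamp - I
ref_y_null <- function(x) 1 - 5 * x^2
ref_x_null_xz <- function(x, I, clamp) -x^3 + 3 * x^2 + clamp + I
ref_z_null <- function(x) 4 * x + 6.4

cordic_pows <- function(x, cfg) {
  fmt <- cfg$fmt
  raw <- fp_quantize_cpp(x, fmt$total_bits, fmt$frac_bits, TRUE, TRUE)
  list(p2 = cordic_pow_cpp(raw, 3L, fmt$total_bits, fmt$frac_bits,
                           cfg$n_iter, cfg$start_index, TRUE) * q_lsb(fmt),
       p3 = cordic_pow_cpp(raw, 4L, fmt$total_bits, fmt$frac_bits,
                           cfg$n_iter, cfg$start_index, TRUE) * q_lsb(fmt))
}

#' Nullcline curves in a clamped state plane
#'
#' Samples the two nullclines of the chosen plane with the third variable
#' clamped. In the X-Y plane (Z clamped, default 1): X-nullcline
#' `Y = X^3 - 3 X^2 + Z - I`, Y-nullcline `Y = 1 - 5 X^2`. In the X-Z plane
#' (Y clamped, default 1): X-nullcline `Z = -X^3 + 3 X^2 + Y + I`,
#' Z-nullcline `Z = 4 X + 6.4`. For the CORDIC model the cubic and quadratic
#' terms are evaluated by the fixed-point power blocks.
#'
#' @param plane `"XY"` or `"XZ"`.
#' @param I stimulation current.
#' @param clamp value of the clamped third variable (default 1).
#' @param model `"reference"` or `"cordic"`.
#' @param xlim range of X to sample (within the power-block domain).
#' @param n number of sample points.
#' @param cfg a [cordic_config()] for the CORDIC curves.
#' @return data.frame with columns `X`, `x_null`, `other_null` (the Y- or
#'   Z-nullcline).
#' @export
hr_nullclines <- function(plane = c("XY", "XZ"), I, clamp = 1,
                          model = c("reference", "cordic"),
                          xlim = c(-1.99, 2.49), n = 451,
                          cfg = cordic_config()) {
  plane <- match.arg(plane)
  model <- match.arg(model)
  x <- seq(xlim[1], xlim[2], length.out = n)
  if (model == "reference") {
    x3 <- x^3; x2 <- x^2
  } else {
    p <- cordic_pows(x, cfg); x3 <- p$p3; x2 <- p$p2
  }
  if (plane == "XY") {
    data.frame(X = x,
               x_null = x3 - 3 * x2 + clamp - I,
               other_null = if (model == "reference") ref_y_null(x)
                            else 1 - 5 * x2)
  } else {
    data.frame(X = x,
               x_null = -x3 + 3 * x2 + clamp + I,
               other_null = ref_z_null(x))
  }
}

#' Equilibrium points as nullcline intersections
#'
#' Solves for the intersections of the two nullclines of
#' [hr_nullclines()]. For the reference model the difference is a cubic
#' polynomial solved exactly (X-Y plane with `clamp = 1`:
#' `X^3 + 2 X^2 - I = 0`); for the CORDIC model sign changes of the sampled
#' fixed-point difference curve are located and refined to the block
#' resolution. Nearby duplicate crossings (within one quantization plateau)
#' are merged.
#'
#' @inheritParams hr_nullclines
#' @return data.frame with one row per equilibrium: `X` and the second
#'   coordinate (`Y` or `Z`).
#' @export
find_equilibria <- function(plane = c("XY", "XZ"), I, clamp = 1,
                            model = c("reference", "cordic"),
                            cfg = cordic_config()) {
  plane <- match.arg(plane)
  model <- match.arg(model)
  if (model == "reference") {
    coef <- if (plane == "XY") c(clamp - 1 - I, 0, 2, 1)
            else c(clamp + I - 6.4, -4, 3, -1)
    rt <- polyroot(coef)
    x <- sort(Re(rt[abs(Im(rt)) < 1e-8]))
    x <- x[!duplicated(round(x, 9))]
  } else {
    nc <- hr_nullclines(plane, I, clamp, model = "cordic",
                        xlim = c(-1.99, 2.49), n = 4497, cfg = cfg)
    d <- nc$x_null - nc$other_null
    sgn <- sign(d)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0 | d[-length(d)] == 0)
    x <- (nc$X[cross] + nc$X[cross + 1]) / 2
    if (length(x) > 1) {      # merge crossings within one quantization plateau
      keep <- c(TRUE, diff(x) > 0.05)
      x <- x[keep]
    }
  }
  if (!length(x))
    return(data.frame(X = numeric(0), coord = numeric(0)))
  second <- if (plane == "XY") ref_y_null(x) else ref_z_null(x)
  out <- data.frame(X = x, coord = second)
  names(out)[2] <- if (plane == "XY") "Y" else "Z"
  out
}

#' Phase-space trajectory of a trace
#'
#' @param trace an `"hr_trace"`.
#' @return Numeric matrix with columns X, Y, Z, one row per sample, in time
#'   order.
#' @export
phase_trajectory <- function(trace) {
  as.matrix(trace[, c("X", "Y", "Z")])
}
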