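#' Configuration of the linear-mode CORDIC blocks
#'
#' The rotation-mode linear CORDIC multiplier drives its angle register `z`
#' to zero through the shift schedule `2^-i0, 2^-(i0+1), ...` over `n_iter`
#' iterations while accumulating `x * z` into `y`. Convergence requires
#' `|z| <= sum(2^-i)` over the schedule, which for the default
#' `i0 = 0, n_iter = 11` covers `|z| < 2 - 2^-10` -- exactly the
#' `(-2, 2)` operand range of the squaring block.
#'
#' @param n_iter number of CORDIC iterations (default 11).
#' @param start_index first shift exponent `i0` (default 0).
#' @param fmt I/O [q_format()] of the block (default Q(15,1,10)).
#' @return An object of class `"cordic_config"`.
#' @export
cordic_config <- function(n_iter = 11L, start_index = 0L, fmt = q_format()) {
  n_iter <- as.integer(n_iter)
  start_index <- as.integer(start_index)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (start_index < 0L) stop("start_index must be >= 0")
  structure(list(n_iter = n_iter, start_index = start_index, fmt = fmt),
            class = "cordic_config")
}

#' @export
print.cordic_config <- function(x, ...) {
  cat(sprintf("linear-mode CORDIC: %d iterations, shifts 2^-%d .. 2^-%d, Q(%d,%d,%d)\n",
              x$n_iter, x$start_index, x$start_index + x$n_iter - 1L,
              x$fmt$total_bits, x$fmt$sign_bits, x$fmt$frac_bits))
  invisible(x)
}

cordic_z_bound <- function(cfg) {
  i <- cfg$start_index + seq_len(cfg$n_iter) - 1L
  sum(2^-i)
}

#' Linear-mode rotation CORDIC multiplication
#'
#' Computes `x * z` by shift-and-add iterations: at iteration `i`,
#' `y <- y + d * x * 2^-i` and `z <- z - d * 2^-i` with `d = sign(z)`
#' (`sign(0) = +1`). The result error is bounded by
#' `|x| * 2^-(i0 + n_iter - 1)` plus accumulation rounding.
#'
#' @param x,z operands: `"fixed_value"` or numeric (quantized on the fly).
#'   `z` must lie within the convergence bound of `cfg`.
#' @param cfg a [cordic_config()].
#' @return A `"fixed_value"` approximating `x * z`.
#' @examples
#' fp_value(cordic_mul(1.5, 1.5))   # ~2.25
#' @export
cordic_mul <- function(x, z, cfg = cordic_config()) {
  x <- as_fixed(x, cfg$fmt); z <- as_fixed(z, cfg$fmt)
  if (any(abs(fp_value(z)) > cordic_z_bound(cfg)))
    stop("z outside the CORDIC convergence range |z| <= ",
         format(cordic_z_bound(cfg)))
  raw <- cordic_mul_cpp(x$raw, z$raw, cfg$fmt$total_bits, cfg$fmt$frac_bits,
                        cfg$n_iter, cfg$start_index, TRUE)
  fixed_from_raw(raw, cfg$fmt)
}

cordic_pow_check <- function(x, cfg, lo, hi, what) {
  x <- as_fixed(x, cfg$fmt)
  v <- fp_value(x)
  if (any(v <= lo | v >= hi))
    stop(what, " input outside its domain (", lo, ", ", hi, ")")
  x
}

#' CORDIC squaring block on (-2, 2)
#'
#' Squares its input by a single linear-mode CORDIC rotation with initial
#' `y = 0` and `z = x`, so `y` converges to `x^2`.
#'
#' @param x `"fixed_value"` or numeric in the open interval (-2, 2).
#' @param cfg a [cordic_config()].
#' @return A `"fixed_value"` approximating `x^2`.
#' @export
cordic_pow2 <- function(x, cfg = cordic_config()) {
  x <- cordic_pow_check(x, cfg, -2, 2, "squaring block")
  raw <- cordic_pow_cpp(x$raw, 2L, cfg$fmt$total_bits, cfg$fmt$frac_bits,
                        cfg$n_iter, cfg$start_index, TRUE)
  fixed_from_raw(raw, cfg$fmt)
}

#' Extended-range CORDIC squaring block on (-2, 2.5)
#'
#' The membrane potential of the neuron ranges beyond the (-2, 2) operand
#' domain of the plain squaring block, so the input is first halved by a
#' right shift, squared on the (-2, 2) block, and the output scaled back by
#' 4 with a left shift: `x^2 = 4 * (x/2)^2`, shifts only.
#'
#' @inheritParams cordic_pow2
#' @param x `"fixed_value"` or numeric in (-2, 2.5).
#' @return A `"fixed_value"` approximating `x^2`.
#' @export
cordic_pow2_ext <- function(x, cfg = cordic_config()) {
  x <- cordic_pow_check(x, cfg, -2, 2.5, "extended squaring block")
  raw <- cordic_pow_cpp(x$raw, 3L, cfg$fmt$total_bits, cfg$fmt$frac_bits,
                        cfg$n_iter, cfg$start_index, TRUE)
  fixed_from_raw(raw, cfg$fmt)
}

#' CORDIC cubing block on (-2, 2.5)
#'
#' Two chained CORDIC operations compute the cube: the halved input is
#' squared, the square is multiplied by the halved input, and the result is
#' scaled back by 8 with a left shift: `x^3 = 8 * ((x/2)^2 * (x/2))`.
#'
#' @inheritParams cordic_pow2_ext
#' @return A `"fixed_value"` approximating `x^3`.
#' @export
cordic_pow3 <- function(x, cfg = cordic_config()) {
  x <- cordic_pow_check(x, cfg, -2, 2.5, "cubing block")
  raw <- cordic_pow_cpp(x$raw, 4L, cfg$fmt$total_bits, cfg$fmt$frac_bits,
                        cfg$n_iter, cfg$start_index, TRUE)
  fixed_from_raw(raw, cfg$fmt)
}
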