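#' Q-format fixed-point description
#'
#' Describes a signed two's-complement fixed-point register layout with one
#' sign bit, `int_bits` integer bits and `frac_bits` fractional bits. The
#' default `q_format()` is the 15-bit layout used by the multiplier-free
#' neuron datapath: Q(15,1,10), i.e. 4 integer bits covering the state range
#' of the Hindmarsh-Rose variables with headroom for intermediate sums.
#'
#' @param total_bits total register width in bits (default 15).
#' @param sign_bits number of sign bits; always 1.
#' @param frac_bits number of fractional bits (default 10).
#' @return An object of class `"q_format"` with fields `total_bits`,
#'   `sign_bits`, `frac_bits`, `int_bits` and the representable `range`.
#' @examples
#' fmt <- q_format()
#' fmt$int_bits   # 4
#' q_range(fmt)   # c(-16, 16 - 2^-10)
#' @export
q_format <- function(total_bits = 15L, sign_bits = 1L, frac_bits = 10L) {
  total_bits <- as.integer(total_bits)
  sign_bits <- as.integer(sign_bits)
  frac_bits <- as.integer(frac_bits)
  if (sign_bits != 1L) stop("sign_bits must be 1")
  if (frac_bits < 1L) stop("frac_bits must be >= 1")
  if (total_bits <= sign_bits + frac_bits)
    stop("total_bits must exceed sign_bits + frac_bits")
  structure(
    list(total_bits = total_bits, sign_bits = sign_bits,
         frac_bits = frac_bits,
         int_bits = total_bits - sign_bits - frac_bits),
    class = "q_format")
}

#' @export
print.q_format <- function(x, ...) {
  cat(sprintf("Q(%d,%d,%d) fixed-point format: %d integer bits, range [%g, %g]\n",
              x$total_bits, x$sign_bits, x$frac_bits, x$int_bits,
              q_range(x)[1], q_range(x)[2]))
  invisible(x)
}

#' Representable range of a Q-format
#'
#' @param fmt a [q_format()].
#' @return Numeric length-2 vector `c(min, max)`:
#'   `-2^int_bits` to `2^int_bits - 2^-frac_bits`.
#' @export
q_range <- function(fmt) {
  c(-2^fmt$int_bits, 2^fmt$int_bits - 2^-fmt$frac_bits)
}

q_lsb <- function(fmt) 2^-fmt$frac_bits

#' Quantize real numbers into a fixed-point format
#'
#' Converts real values to two's-complement payloads (`raw`) in the given
#' Q-format. `"nearest"` rounds half away from zero; `"truncate"` floors
#' toward negative infinity, matching the behaviour of dropping low bits in a
#' shift register. Out-of-range values either clip to the range ends
#' (`overflow = "saturate"`) or raise an error.
#'
#' @param x numeric vector of real values.
#' @param fmt a [q_format()].
#' @param rounding `"nearest"` or `"truncate"`.
#' @param overflow `"saturate"` or `"error"`.
#' @return A `"fixed_value"`: list with vector `raw` and the `fmt`.
#' @examples
#' v <- quantize(1.5, q_format())
#' fp_value(v)          # exactly 1.5
#' v$raw                # 1536
#' @export
quantize <- function(x, fmt = q_format(),
                     rounding = c("nearest", "truncate"),
                     overflow = c("saturate", "error")) {
  rounding <- match.arg(rounding)
  overflow <- match.arg(overflow)
  raw <- fp_quantize_cpp(as.numeric(x), fmt$total_bits, fmt$frac_bits,
                         rounding == "nearest", overflow == "saturate")
  fixed_from_raw(raw, fmt)
}

#' Build a fixed-point value from raw payloads
#'
#' @param raw integer payload(s); real value is `raw * 2^-frac_bits`.
#' @param fmt a [q_format()].
#' @return A `"fixed_value"` object.
#' @export
fixed_from_raw <- function(raw, fmt = q_format()) {
  raw <- as.numeric(raw)
  lim <- 2^(fmt$total_bits - 1)
  if (any(raw < -lim | raw > lim - 1))
    stop("raw payload does not fit in ", fmt$total_bits, " bits")
  if (any(raw != trunc(raw))) stop("raw payload must be integral")
  structure(list(raw = raw, fmt = fmt), class = "fixed_value")
}

#' Real value of a fixed-point object
#'
#' @param v a `"fixed_value"`.
#' @return Numeric vector `raw * 2^-frac_bits`.
#' @export
fp_value <- function(v) {
  stopifnot(inherits(v, "fixed_value"))
  v$raw * 2^-v$fmt$frac_bits
}

#' @export
as.numeric.fixed_value <- function(x, ...) fp_value(x)

#' @export
length.fixed_value <- function(x) length(x$raw)

#' @export
print.fixed_value <- function(x, ...) {
  cat(sprintf("<fixed_value Q(%d,%d,%d)>\n", x$fmt$total_bits,
              x$fmt$sign_bits, x$fmt$frac_bits))
  print(fp_value(x))
  invisible(x)
}

as_fixed <- function(x, fmt, ...) {
  if (inherits(x, "fixed_value")) x else quantize(x, fmt, ...)
}

#' Exact multiplication by a power of two
#'
#' Shifts the payload left (`k > 0`) or right (`k < 0`). Right shifts are
#' arithmetic: low bits are discarded, truncating toward negative infinity as
#' a hardware shift register does. Left shifts that leave the representable
#' range saturate or error per `overflow`.
#'
#' @param x a `"fixed_value"` (or numeric, quantized on the fly).
#' @param k signed shift count; result represents `value(x) * 2^k`.
#' @param overflow `"saturate"` or `"error"`.
#' @return A `"fixed_value"` in the same format.
#' @examples
#' fp_value(shift_mul(quantize(1), -8))   # 2^-8
#' @export
shift_mul <- function(x, k, overflow = c("saturate", "error")) {
  overflow <- match.arg(overflow)
  x <- as_fixed(x, q_format())
  raw <- fp_shift_cpp(x$raw, as.integer(k), x$fmt$total_bits,
                      overflow == "saturate")
  fixed_from_raw(raw, x$fmt)
}

#' Multiplier-free multiplication by a constant
#'
#' Multiplies by a real constant using only shifts and additions: the
#' constant is quantized into the format and decomposed into canonical
#' signed digits (CSD), and the product is the signed sum of shifted copies
#' of `x`, each term truncated individually. The error versus the exact real
#' product is at most one LSB per nonzero CSD digit. This is how the neuron
#' datapath applies its model constants (3, 5, 4r, 6.4r, r, dt) without a
#' hardware multiplier.
#'
#' @param x a `"fixed_value"` (or numeric, quantized on the fly).
#' @param c real constant.
#' @param overflow `"saturate"` or `"error"`.
#' @return A `"fixed_value"` in the same format.
#' @examples
#' fp_value(const_mul(quantize(1), 3))    # exactly 3: (x << 1) + x
#' csd_decompose(3, q_format())           # digits +2^2 - 2^0, scaled
#' @export
const_mul <- function(x, c, overflow = c("saturate", "error")) {
  overflow <- match.arg(overflow)
  x <- as_fixed(x, q_format())
  raw <- fp_constmul_cpp(x$raw, c, x$fmt$total_bits, x$fmt$frac_bits,
                         overflow == "saturate")
  fixed_from_raw(raw, x$fmt)
}

#' Canonical signed-digit decomposition of a constant
#'
#' Shows the shift-and-add schedule [const_mul()] uses: the constant,
#' quantized at `fmt`'s resolution, written as a sum of `sign * 2^power`
#' terms with no two adjacent nonzero digits (minimal adder count).
#'
#' @param c real constant.
#' @param fmt a [q_format()] giving the quantization resolution.
#' @return data.frame with columns `power` (exponent of 2, in value scale,
#'   i.e. already offset by `-frac_bits`) and `sign` (+1/-1).
#' @export
csd_decompose <- function(c, fmt = q_format()) {
  raw <- fp_quantize_cpp(c, 63L, fmt$frac_bits, TRUE, FALSE)
  d <- csd_cpp(raw)
  data.frame(power = d$power - fmt$frac_bits, sign = d$sign)
}
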