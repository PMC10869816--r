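#' Threshold a grayscale image to binary
#'
#' @param img numeric matrix (8-bit grayscale, values 0-255, or already
#'   0/1).
#' @param threshold values `>= threshold` map to 1 (default 128).
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(img, threshold = 128) {
  check_image(img)
  m <- (img >= threshold) + 0L
  storage.mode(m) <- "integer"
  m
}

check_image <- function(img, binary = FALSE) {
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a numeric matrix")
  if (binary && !all(img %in% c(0, 1))) stop("binary image expected (values 0/1)")
  invisible(img)
}

# shift a matrix so out[i,j] = img[i+di, j+dj]; border policy: edge
# replication ("replicate") or zero fill ("zero")
shift_image <- function(img, di, dj, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  h <- nrow(img); w <- ncol(img)
  ri <- seq_len(h) + di
  rj <- seq_len(w) + dj
  if (pad == "replicate") {
    img[pmin(pmax(ri, 1L), h), pmin(pmax(rj, 1L), w), drop = FALSE]
  } else {
    out <- matrix(0L, h, w)
    ok_i <- ri >= 1L & ri <= h
    ok_j <- rj >= 1L & rj <= w
    out[ok_i, ok_j] <- img[ri[ok_i], rj[ok_j]]
    out
  }
}

# Boolean operator set for a backend. "logic" evaluates directly;
# "spiking" runs each distinct input combination once through the real
# frequency-coded CORDIC gates and reuses the decoded result for every
# pixel (the gates are deterministic, so one simulation per truth-table
# row is exhaustive).
logic_ops <- function(backend = c("logic", "spiking"), ...) {
  backend <- match.arg(backend)
  if (backend == "logic") {
    list(and = function(a, b) a * b,
         or = function(a, b) pmax(a, b),
         not = function(a) 1L - a)
  } else {
    tabs <- spiking_gate_tables(...)
    list(and = function(a, b) tabs$and[1L + a + 2L * b],
         or = function(a, b) tabs$or[1L + a + 2L * b],
         not = function(a) tabs$not[1L + a])
  }
}

.sfg_table_cache <- new.env(parent = emptyenv())

spiking_gate_tables <- function(code = bool_freq_code(), duration = 1000) {
  key <- paste0("d", duration, "_t", code$threshold_hz)
  if (!is.null(.sfg_table_cache[[key]])) return(.sfg_table_cache[[key]])
  run <- function(kind, ins)
    attr(sfg_gate(kind, ins, code = code, duration = duration), "bit")
  tabs <- list(
    and = vapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                 function(p) run("and", as.list(p)), integer(1)),
    or = vapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                function(p) run("or", as.list(p)), integer(1)),
    not = vapply(list(0, 1), function(p) run("not", list(p)), integer(1)))
  .sfg_table_cache[[key]] <- tabs
  tabs
}

#' Cellular-logic edge detection
#'
#' Per-pixel morphological filter
#' `f = g AND NOT(g_up AND g_left AND g_down AND g_right)`: a foreground
#' pixel survives only if at least one 4-neighbour is background, leaving
#' exactly the boundary of filled regions. Borders use edge replication.
#' The output is always a subset of the input foreground (`f <= g`).
#'
#' @param img 0/1 matrix.
#' @param backend `"logic"` evaluates the Boolean expression directly;
#'   `"spiking"` routes every AND/NOT through frequency-coded CORDIC-neuron
#'   gates (one simulation per distinct input combination, reused across
#'   pixels). Both produce identical output.
#' @param ... passed to the spiking backend ([bool_freq_code()] etc.).
#' @return 0/1 integer matrix of the same shape.
#' @examples
#' img <- matrix(0L, 8, 8); img[3:6, 3:6] <- 1L
#' sum(edge_detect(img))   # boundary of the 4x4 square: 12 pixels
#' @export
edge_detect <- function(img, backend = c("logic", "spiking"), ...) {
  check_image(img, binary = TRUE)
  ops <- logic_ops(backend, ...)
  up <- shift_image(img, -1L, 0L); lf <- shift_image(img, 0L, -1L)
  dn <- shift_image(img, 1L, 0L);  rt <- shift_image(img, 0L, 1L)
  inner <- ops$and(ops$and(up, lf), ops$and(dn, rt))
  out <- ops$and(img, ops$not(inner))
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Cellular-logic image magnification (3x)
#'
#' The source is upsampled onto a 3x grid with each source pixel placed at
#' the anchor of its 3x3 block and zeros elsewhere; each output pixel is
#' the OR of the 3x3 window of this upsampled grid, which fills every block
#' whose source pixel is set. The result is exact 3x block replication.
#'
#' @inheritParams edge_detect
#' @return 0/1 integer matrix of dimensions `3 * dim(img)`.
#' @export
magnify <- function(img, backend = c("logic", "spiking"), ...) {
  check_image(img, binary = TRUE)
  ops <- logic_ops(backend, ...)
  h <- nrow(img); w <- ncol(img)
  g1 <- matrix(0L, 3L * h, 3L * w)
  g1[3L * seq_len(h), 3L * seq_len(w)] <- img
  acc <- g1
  for (a in 0:2) for (b in 0:2) {
    if (a == 0 && b == 0) next
    acc <- ops$or(acc, shift_image(g1, a, b, pad = "zero"))
  }
  matrix(as.integer(acc), 3L * h, 3L * w)
}

#' Cellular-logic noise removal
#'
#' Nine OR-ed three-term AND clauses over the 4-neighbourhood: a pixel is
#' kept (or filled) only when one of nine local support patterns holds, so
#' isolated foreground pixels are removed while solid regions are
#' preserved. Borders use edge replication.
#'
#' @inheritParams edge_detect
#' @return 0/1 integer matrix of the same shape.
#' @export
denoise <- function(img, backend = c("logic", "spiking"), ...) {
  check_image(img, binary = TRUE)
  ops <- logic_ops(backend, ...)
  c0 <- img
  dn <- shift_image(img, 1L, 0L); up <- shift_image(img, -1L, 0L)
  rt <- shift_image(img, 0L, 1L); lf <- shift_image(img, 0L, -1L)
  and3 <- function(a, b, c) ops$and(ops$and(a, b), c)
  clauses <- list(
    and3(c0, dn, rt), and3(c0, rt, lf), and3(c0, dn, up),
    and3(c0, lf, dn), and3(lf, dn, rt), and3(lf, rt, up),
    and3(dn, rt, up), and3(lf, up, dn), and3(lf, up, c0))
  out <- Reduce(ops$or, clauses)
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Noise removal for 8-bit grayscale images
#'
#' Decomposes the image into its 8 binary bit planes, applies the
#' cellular-logic noise filter to each plane, and recombines them.
#'
#' @param img numeric matrix with values in 0-255.
#' @inheritParams edge_detect
#' @return Integer matrix in 0-255 of the same shape.
#' @export
denoise_grayscale <- function(img, backend = c("logic", "spiking"), ...) {
  check_image(img)
  if (any(img < 0 | img > 255 | img != trunc(img)))
    stop("8-bit grayscale image expected (integers 0-255)")
  out <- matrix(0L, nrow(img), ncol(img))
  for (b in 0:7) {
    plane <- (img %/% 2^b) %% 2
    storage.mode(plane) <- "integer"
    out <- out + denoise(plane, backend, ...) * as.integer(2^b)
  }
  out
}

#' Corrupt an image with seeded noise
#'
#' Salt-and-pepper noise replaces each pixel independently with probability
#' `prob` by 0 or 255 (equally likely); Poisson noise adds a zero-mean
#' scaled Poisson deviate (`(rpois(lambda) - lambda) * scale`); Gaussian
#' noise adds `N(0, sigma)`. Additive results are rounded and clipped to
#' 0-255.
#'
#' @param img numeric matrix (0-255).
#' @param kind `"salt_pepper"`, `"poisson"` or `"gaussian"`.
#' @param prob corruption probability for salt-and-pepper (default 0.10).
#' @param lambda Poisson rate (default 1).
#' @param sigma Gaussian standard deviation (default 10).
#' @param scale 8-bit scaling of the Poisson deviate (default 32).
#' @param seed RNG seed.
#' @return Integer matrix of the same shape.
#' @export
add_noise <- function(img, kind = c("salt_pepper", "poisson", "gaussian"),
                      prob = 0.10, lambda = 1, sigma = 10, scale = 32,
                      seed = 1L) {
  kind <- match.arg(kind)
  check_image(img)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(img)
  out <- img
  if (kind == "salt_pepper") {
    hit <- stats::runif(n) < prob
    out[hit] <- ifelse(stats::runif(sum(hit)) < 0.5, 0, 255)
  } else if (kind == "poisson") {
    out <- out + (stats::rpois(n, lambda) - lambda) * scale
  } else {
    out <- out + stats::rnorm(n, 0, sigma)
  }
  out <- round(pmin(pmax(out, 0), 255))
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' @param a,b numeric matrices of the same shape.
#' @param peak peak signal value (default 255 for 8-bit images).
#' @return List with `mse` and `psnr` (dB; `Inf` for identical images).
#' @examples
#' mse_psnr(matrix(0, 2, 2), matrix(16, 2, 2))   # mse 256, psnr ~24.05
#' @export
mse_psnr <- function(a, b, peak = 255) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  mse <- mean((a - b)^2)
  list(mse = mse, psnr = if (mse == 0) Inf else 10 * log10(peak^2 / mse))
}
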