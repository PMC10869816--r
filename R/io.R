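#' Write a simulation trace to CSV
#'
#' Columns `t, X, Y, Z`, plain decimal point regardless of locale,
#' round-trip lossless at double precision via [read_trace()].
#'
#' @param trace an `"hr_trace"` (or data.frame with those columns).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)[, c("t", "X", "Y", "Z")]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation trace from CSV
#'
#' @param path file written by [write_trace()].
#' @return An `"hr_trace"` data.frame. Malformed rows are reported with
#'   their line numbers.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("t", "X", "Y", "Z")
  if (!all(need %in% names(df)))
    stop("trace file must have columns t, X, Y, Z")
  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stop("malformed trace rows at line(s) ",
         paste(bad + 1L, collapse = ", "))
  out <- as.data.frame(num)
  class(out) <- c("hr_trace", "data.frame")
  out
}

#' Read a PGM image
#'
#' Supports plain-text (P2) and binary (P5, 8-bit) portable graymaps.
#'
#' @param path file path.
#' @return Integer matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  tokens <- character(0)
  while (length(tokens) < 3) {
    line <- readone_line(con)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "[ \t]+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    if (maxval > 255) stop("only 8-bit P5 supported")
    vals <- as.integer(readBin(con, "raw", w * h))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

readone_line <- function(con) {
  chars <- character(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b) || b == as.raw(10)) break
    chars <- c(chars, rawToChar(b))
  }
  paste(chars, collapse = "")
}

#' Write a PGM image
#'
#' Writes plain-text (P2) PGM by default, a bit-exact text representation.
#'
#' @param img integer matrix with values in 0..maxval.
#' @param path output file.
#' @param maxval maximum gray value (default 255; use 1 for binary masks).
#' @return The path, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  check_image(img)
  if (any(img < 0 | img > maxval)) stop("pixel values exceed maxval")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(img, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read an image by extension (PGM or PNG)
#'
#' PNG images are converted to 8-bit grayscale (channels averaged).
#'
#' @param path file path ending in `.pgm` or `.png`.
#' @return Integer matrix in 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    return(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
  }
  stop("unsupported image format: ", ext)
}

#' Write an image by extension (PGM or PNG)
#'
#' @param img integer matrix in 0-255 (or 0/1; scaled for PNG).
#' @param path file path ending in `.pgm` or `.png`.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(img, path))
  if (ext == "png") {
    mx <- max(img, 1)
    png::writePNG(img / if (mx <= 1) 1 else 255, path)
    return(invisible(path))
  }
  stop("unsupported image format: ", ext)
}

config_defaults <- function() {
  list(
    model = "cordic",
    hr = list(I = 0.5, r = 0.0021, dt = 1 / 256, x0 = 0.1, y0 = 1, z0 = 0.2),
    fixedpoint = list(total_bits = 15L, frac_bits = 10L,
                      rounding = "nearest", overflow = "saturate"),
    cordic = list(n_iter = 11L, start_index = 0L),
    network = list(n = 1000L, p_connect = 0.2, frac_excitatory = 0.8,
                   weight = 1, g = 0.002, tau_syn = 10),
    seed = 1L)
}

#' Load a run configuration file
#'
#' Reads a YAML configuration, fills in the documented defaults
#' (`dt = 1/256`, 15-bit registers, 11 CORDIC iterations, 1000-neuron
#' network at p = 0.2) and validates the fields; violations are reported
#' with the offending field path.
#'
#' @param path YAML file; an empty or missing-key file yields all defaults.
#' @return A validated `"run_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- utils::modifyList(config_defaults(), user)
  fail <- function(field, msg) stop("config field ", field, ": ", msg)
  if (!cfg$model %in% c("cordic", "reference"))
    fail("model", "must be 'cordic' or 'reference'")
  if (cfg$hr$dt <= 0) fail("hr.dt", "must be positive")
  if (cfg$hr$r < 0) fail("hr.r", "must be >= 0")
  if (cfg$fixedpoint$frac_bits < 1) fail("fixedpoint.frac_bits", "must be >= 1")
  if (!cfg$fixedpoint$rounding %in% c("nearest", "truncate"))
    fail("fixedpoint.rounding", "must be 'nearest' or 'truncate'")
  if (!cfg$fixedpoint$overflow %in% c("saturate", "error"))
    fail("fixedpoint.overflow", "must be 'saturate' or 'error'")
  if (cfg$cordic$n_iter < 1) fail("cordic.n_iter", "must be >= 1")
  if (cfg$network$p_connect < 0 || cfg$network$p_connect > 1)
    fail("network.p_connect", "must be in [0, 1]")
  if (cfg$network$frac_excitatory < 0 || cfg$network$frac_excitatory > 1)
    fail("network.frac_excitatory", "must be in [0, 1]")
  structure(cfg, class = "run_config")
}

#' Synthetic shapes test image
#'
#' A deterministic (given `seed`) grayscale image with a filled rectangle,
#' a filled disc and a bar on black background; foreground covers roughly a
#' quarter of the frame.
#'
#' @param size image side length (default 64).
#' @param seed placement RNG seed.
#' @return Integer matrix `size x size` with values 0/255.
#' @export
shapes_image <- function(size = 64L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  img <- matrix(0L, size, size)
  q <- size %/% 4
  r0 <- sample(2:q, 1)
  img[r0:(r0 + q), r0:(r0 + q)] <- 255L                       # rectangle
  cx <- size - q - sample(0:3, 1); cy <- q + sample(0:3, 1)
  rad <- q %/% 2 + 2
  ix <- matrix(seq_len(size), size, size)
  iy <- t(ix)
  img[(ix - cx)^2 + (iy - cy)^2 <= rad^2] <- 255L             # disc
  br <- size - q
  img[br:(br + 2), (q):(3 * q)] <- 255L                       # bar
  img
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text fixture files: `shapes_image` (64x64 shapes
#' PGM), `noisy_image` (its 10\% salt-and-pepper corruption),
#' `reference_trace` (reference-model trace at I = 0.5 over 100 time
#' units), `gate_traces` (encoded 0/1 input trains as CSV). Identical seeds
#' give byte-identical files.
#'
#' @param kind one of `"shapes_image"`, `"noisy_image"`,
#'   `"reference_trace"`, `"gate_traces"`.
#' @param seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("shapes_image", "noisy_image",
                                       "reference_trace", "gate_traces"),
                              seed = 1L, out_dir = ".") {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(kind,
    shapes_image = {
      p <- file.path(out_dir, "shapes.pgm")
      write_pgm(shapes_image(64L, seed), p)
      p
    },
    noisy_image = {
      p <- file.path(out_dir, "shapes_noisy.pgm")
      write_pgm(add_noise(shapes_image(64L, seed), "salt_pepper",
                          prob = 0.10, seed = seed), p)
      p
    },
    reference_trace = {
      p <- file.path(out_dir, "reference_trace.csv")
      write_trace(simulate_hr(hr_params(I = 0.5, r = 0.0021), T = 100,
                              model = "reference"), p)
      p
    },
    gate_traces = {
      ps <- file.path(out_dir, c("train_bit0.csv", "train_bit1.csv"))
      utils::write.csv(data.frame(t = as.numeric(encode_boolean(0))),
                       ps[1], row.names = FALSE)
      utils::write.csv(data.frame(t = as.numeric(encode_boolean(1))),
                       ps[2], row.names = FALSE)
      ps
    })
  out
}
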