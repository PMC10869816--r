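# independent brute-force oracles for the cellular-logic filters, written as
# direct per-pixel loops over the defining Boolean expressions

replicate_at <- function(g, i, j) {
  g[min(max(i, 1L), nrow(g)), min(max(j, 1L), ncol(g))]
}

oracle_edge <- function(g) {
  f <- g
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    inner <- replicate_at(g, i - 1L, j) & replicate_at(g, i, j - 1L) &
             replicate_at(g, i + 1L, j) & replicate_at(g, i, j + 1L)
    f[i, j] <- as.integer(g[i, j] & !inner)
  }
  f
}

oracle_magnify <- function(g) {
  h <- nrow(g); w <- ncol(g)
  g1 <- matrix(0L, 3L * h + 2L, 3L * w + 2L)   # zero padding for the window
  g1[3L * seq_len(h), 3L * seq_len(w)] <- g
  f <- matrix(0L, 3L * h, 3L * w)
  for (i in seq_len(3L * h)) for (j in seq_len(3L * w)) {
    acc <- 0L
    for (a in 0:2) for (b in 0:2) acc <- acc | g1[i + a, j + b]
    f[i, j] <- as.integer(acc)
  }
  f
}

oracle_denoise_center <- function(nb) {
  # nb: 3x3 neighborhood, center at [2,2]; evaluates the nine clauses
  g <- function(di, dj) nb[2L + di, 2L + dj]
  cl <- c(g(0,0) & g(1,0) & g(0,1),
          g(0,0) & g(0,1) & g(0,-1),
          g(0,0) & g(1,0) & g(-1,0),
          g(0,0) & g(0,-1) & g(1,0),
          g(0,-1) & g(1,0) & g(0,1),
          g(0,-1) & g(0,1) & g(-1,0),
          g(1,0) & g(0,1) & g(-1,0),
          g(0,-1) & g(-1,0) & g(1,0),
          g(0,-1) & g(-1,0) & g(0,0))
  as.integer(any(cl))
}

oracle_denoise <- function(g) {
  f <- g
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    nb <- matrix(0L, 3L, 3L)
    for (a in -1:1) for (b in -1:1) nb[2L + a, 2L + b] <- replicate_at(g, i + a, j + b)
    f[i, j] <- oracle_denoise_center(nb)
  }
  f
}

random_binary_image <- function(h, w, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

lsb10 <- 2^-10
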