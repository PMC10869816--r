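test_that("binarization thresholds 8-bit images", {
  z <- matrix(0, 4, 4)
  expect_equal(binarize(z), matrix(0L, 4, 4))
  expect_equal(binarize(z + 255), matrix(1L, 4, 4))
  cb <- matrix(c(0, 255), 4, 4)
  expect_equal(binarize(cb, 128), matrix(c(0L, 1L), 4, 4))
  expect_error(binarize("x"), "matrix")
})

test_that("edge detection keeps exactly the region boundaries", {
  ones <- matrix(1L, 8, 8)
  expect_equal(edge_detect(ones), matrix(0L, 8, 8))
  single <- matrix(0L, 7, 7); single[4, 4] <- 1L
  expect_equal(edge_detect(single), single)
  sq <- matrix(0L, 30, 30); sq[11:20, 11:20] <- 1L
  expect_equal(edge_detect(sq), oracle_edge(sq))
  # the boundary has 4 * 10 - 4 pixels
  expect_equal(sum(edge_detect(sq)), 36L)
})

test_that("edge output never exceeds the input foreground", {
  for (s in 1:5) {
    g <- random_binary_image(20, 24, p = 0.5, seed = s)
    f <- edge_detect(g)
    expect_true(all(f <= g))
    expect_equal(f, oracle_edge(g))
  }
})

test_that("magnification triples the dimensions by block replication", {
  z <- matrix(0L, 5, 7)
  expect_equal(dim(magnify(z)), c(15L, 21L))
  expect_equal(magnify(z), matrix(0L, 15, 21))
  single <- matrix(0L, 4, 4); single[2, 3] <- 1L
  m <- magnify(single)
  block <- matrix(0L, 12, 12); block[4:6, 7:9] <- 1L
  expect_equal(m, block)
  for (s in 1:3) {
    g <- random_binary_image(6, 5, p = 0.4, seed = s)
    expect_equal(magnify(g), oracle_magnify(g))
    expect_equal(magnify(g), kronecker(g, matrix(1L, 3, 3)))
  }
})

test_that("noise removal deletes isolated pixels and preserves solid regions", {
  z <- matrix(0L, 6, 6)
  expect_equal(denoise(z), z)
  iso <- z; iso[3, 3] <- 1L
  expect_equal(denoise(iso), z)
  solid <- matrix(0L, 10, 10); solid[3:8, 3:8] <- 1L
  expect_true(all(denoise(solid)[4:7, 4:7] == 1L))
  for (s in 1:5) {
    g <- random_binary_image(15, 15, p = 0.3, seed = s + 10)
    expect_equal(denoise(g), oracle_denoise(g))
  }
})

test_that("noise removal matches the clause table on all 512 neighborhoods", {
  # every 3x3 pattern, evaluated at the center of a zero-padded tile so the
  # neighborhood is exactly the pattern
  for (code in 0:511) {
    nb <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    img <- matrix(0L, 5, 5); img[2:4, 2:4] <- nb
    got <- denoise(img)[3, 3]
    expect_identical(got, oracle_denoise_center(nb))
  }
})

test_that("the spiking backend agrees with pure logic pixel-for-pixel", {
  g <- random_binary_image(12, 12, p = 0.35, seed = 4)
  expect_equal(edge_detect(g, backend = "spiking"), edge_detect(g))
  expect_equal(denoise(g, backend = "spiking"), denoise(g))
  small <- random_binary_image(4, 4, p = 0.4, seed = 5)
  expect_equal(magnify(small, backend = "spiking"), magnify(small))
  # all 512 denoise neighborhoods through the gate-mediated backend
  tiles <- lapply(0:511, function(code) {
    img <- matrix(0L, 5, 5)
    img[2:4, 2:4] <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    img
  })
  big <- do.call(rbind, tiles)                       # 2560 x 5 stacked tiles
  got <- denoise(big, backend = "spiking")
  want <- denoise(big, backend = "logic")
  expect_identical(got, want)
})

test_that("grayscale denoising works per bit plane", {
  z <- matrix(0, 8, 8)
  expect_equal(denoise_grayscale(z), matrix(0L, 8, 8))
  salt <- z; salt[c(10, 30, 50)] <- 255
  expect_equal(denoise_grayscale(salt), matrix(0L, 8, 8))
  # a full-width band is a fixed point of the clause set (every boundary
  # pixel keeps a supporting clause under edge replication); note a free
  # corner with only up/right support has no clause and erodes instead
  band <- matrix(0, 12, 12); band[5:8, ] <- 200
  expect_identical(denoise_grayscale(band), matrix(as.integer(band), 12, 12))
  expect_error(denoise_grayscale(band + 0.5), "8-bit")
})

test_that("seeded noise matches its specification", {
  img <- matrix(128, 50, 50)
  expect_equal(add_noise(img, "salt_pepper", prob = 0, seed = 1),
               matrix(128L, 50, 50))
  all_sp <- add_noise(img, "salt_pepper", prob = 1, seed = 1)
  expect_true(all(all_sp %in% c(0L, 255L)))
  big <- matrix(128, 100, 100)
  n_hit <- sum(add_noise(big, "salt_pepper", prob = 0.1, seed = 3) != 128)
  expect_lt(abs(n_hit - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  # determinism
  expect_identical(add_noise(big, "gaussian", sigma = 10, seed = 9),
                   add_noise(big, "gaussian", sigma = 10, seed = 9))
  pois <- add_noise(big, "poisson", lambda = 1, seed = 5)
  expect_true(all(pois >= 0 & pois <= 255))
})

test_that("MSE and PSNR follow their closed forms", {
  a <- matrix(0, 10, 10)
  m0 <- mse_psnr(a, a)
  expect_equal(m0$mse, 0)
  expect_identical(m0$psnr, Inf)
  m16 <- mse_psnr(a, a + 16)
  expect_equal(m16$mse, 256)
  expect_equal(m16$psnr, 10 * log10(65025 / 256))
  b <- a; b[1, 1] <- 255
  expect_equal(mse_psnr(a, b)$mse, 650.25)
  expect_error(mse_psnr(a, matrix(0, 2, 2)), "shape")
})

test_that("salt-and-pepper denoising improves PSNR on the shapes fixture", {
  img <- shapes_image(64, 1)
  noisy <- add_noise(img, "salt_pepper", prob = 0.10, seed = 2)
  den <- denoise_grayscale(noisy)
  expect_gt(mse_psnr(img, den)$psnr, mse_psnr(img, noisy)$psnr)
})
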