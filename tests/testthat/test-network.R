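test_that("random wiring matches the connection probability", {
  expect_equal(synapse_count(build_random_network(network_config(n = 20, p_connect = 0))), 0L)
  expect_equal(synapse_count(build_random_network(network_config(n = 10, p_connect = 1))), 90L)
  net <- build_random_network(network_config(n = 1000, p_connect = 0.2, seed = 1))
  mu <- 1000 * 999 * 0.2
  sd3 <- 3 * sqrt(1000 * 999 * 0.2 * 0.8)
  expect_lt(abs(synapse_count(net) - mu), sd3)
  expect_false(any(net$edges$src == net$edges$dst))   # no self-connections
})

test_that("synapse counts follow binomial moments across seeds", {
  n <- 50; p <- 0.2
  counts <- vapply(1:20, function(s)
    synapse_count(build_random_network(network_config(n = n, p_connect = p,
                                                      seed = s))), integer(1))
  mu <- n * (n - 1) * p
  sigma <- sqrt(n * (n - 1) * p * (1 - p))
  expect_lt(abs(mean(counts) - mu), 4 * sigma / sqrt(20))
  expect_gt(var(counts), sigma^2 / 4)
  expect_lt(var(counts), sigma^2 * 4)
})

test_that("excitatory fraction and sign assignment follow the configuration", {
  net <- build_random_network(network_config(n = 100, frac_excitatory = 0.8, seed = 3))
  expect_equal(sum(net$sign > 0), 80L)
  expect_equal(sort(unique(net$sign)), c(-1, 1))
  # wiring is reproducible for a fixed seed
  net2 <- build_random_network(network_config(n = 100, frac_excitatory = 0.8, seed = 3))
  expect_identical(net$edges, net2$edges)
  expect_identical(net$sign, net2$sign)
})

test_that("an unconnected population decouples into independent neurons", {
  cfg <- network_config(n = 4, p_connect = 0, seed = 2)
  net <- build_random_network(cfg)
  p <- hr_params(I = 1.5, r = 0.0021)
  ras <- simulate_network(net, p, T = 150, model = "cordic")
  single <- detect_spikes(simulate_hr(p, 150, "cordic"))
  for (i in 1:4) expect_equal(ras$spikes[[i]], as.numeric(single))
})

test_that("network simulation is deterministic given the network", {
  net <- build_random_network(network_config(n = 30, p_connect = 0.2, seed = 5))
  p <- hr_params(I = 1.5, r = 0.0021)
  a <- simulate_network(net, p, T = 100, model = "cordic")
  b <- simulate_network(net, p, T = 100, model = "cordic")
  expect_identical(a$spikes, b$spikes)
})

test_that("coupled populations of both models spike in the tonic regime", {
  net <- build_random_network(network_config(n = 40, p_connect = 0.2, seed = 7))
  p <- hr_params(I = 1.5, r = 0.0021)
  rc <- simulate_network(net, p, T = 200, model = "cordic")
  rr <- simulate_network(net, p, T = 200, model = "reference")
  expect_true(all(lengths(rc$spikes) > 0))
  expect_true(all(lengths(rr$spikes) > 0))
  # per-neuron spike counts of the two models stay close
  expect_lt(max(abs(lengths(rc$spikes) - lengths(rr$spikes))), 3)
})

test_that("raster subsetting samples without replacement, reproducibly", {
  net <- build_random_network(network_config(n = 25, p_connect = 0.1, seed = 1))
  ras <- simulate_network(net, hr_params(I = 1.5, r = 0.0021), T = 60)
  expect_identical(raster_subset(ras, 25, seed = 1)$spikes, ras$spikes)
  expect_length(raster_subset(ras, 0, seed = 1)$spikes, 0L)
  s1 <- raster_subset(ras, 5, seed = 42)
  s2 <- raster_subset(ras, 5, seed = 42)
  expect_identical(attr(s1, "neuron_id"), attr(s2, "neuron_id"))
  expect_length(attr(s1, "neuron_id"), 5L)
  tab <- raster_table(s1)
  expect_named(tab, c("neuron_id", "spike_time"))
  expect_true(all(tab$spike_time >= 0 & tab$spike_time <= ras$duration))
})
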