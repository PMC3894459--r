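test_that("plastic wiring respects fan-out and edge clipping", {
  net <- build_network(network_params(n_channels = 32, fan_out = 14))
  syn <- net$synapses
  # channel 1 reaches only the right side
  expect_equal(sum(syn$x == 1), 14)
  # central channel reaches both sides in full
  expect_equal(sum(syn$x == 16), 28)
  # brute-force enumeration of the total
  expected <- sum(vapply(0:31, function(x) min(14, x) + min(14, 31 - x),
                         numeric(1)))
  expect_equal(nrow(syn), expected)
  expect_equal(nrow(syn), 686)
  # no self-channel plastic synapses, fan-out bound holds
  expect_true(all(syn$x != syn$y))
  expect_true(all(abs(syn$x - syn$y) <= 14))
  # delay law baked into the connection list
  expect_equal(syn$delay_ms,
               net$params$d0 + abs(syn$x - syn$y) * net$params$nu)
  expect_true(all(net$synapses$w == 0))
})

test_that("invalid architecture is rejected", {
  expect_error(network_params(n_channels = 8, fan_out = 8), "fan_out")
  expect_error(network_params(n_channels = 8, fan_out = 0), "fan_out")
  expect_error(neuron_params(tau_m = -1))
  expect_error(noise_spec(sigma = -0.1), "sigma")
})

test_that("reset restores low state and is idempotent", {
  net <- tiny_net()
  net$synapses$w <- runif(nrow(net$synapses))
  r1 <- reset_network(net, weights_low = TRUE)
  expect_true(all(r1$synapses$w == 0))
  expect_identical(reset_network(r1, TRUE), r1)
  # weights preserved when weights_low is off
  r2 <- reset_network(net, weights_low = FALSE)
  expect_identical(r2$synapses$w, net$synapses$w)
})

test_that("zero drive with zero efficacies produces an empty raster", {
  sim <- simulate_network(tiny_net(), drive = matrix(0, 8, 500))
  expect_equal(nrow(sim$raster), 0)
})

test_that("a single suprathreshold A spike yields one B1 spike at the fixed latency", {
  net <- tiny_net()
  r <- spike_raster(10, "A", 3, duration = 40)
  sim <- simulate_network(net, a_spikes = r, duration = 40)
  b1 <- sim$raster[sim$raster$population == "B1", ]
  expect_equal(nrow(b1), 1)
  expect_equal(b1$channel, 3)
  expect_equal(b1$time_ms, 10 + net$params$d0)
})

test_that("lateral event latency equals d0 + |x-y| nu exactly", {
  net <- tiny_net(nu = 1.5)
  r <- spike_raster(5, "A", 4, duration = 40)
  sim <- simulate_network(net, a_spikes = r, duration = 40,
                          record_deliveries = TRUE)
  b1 <- sim$raster[sim$raster$population == "B1", ]
  expect_equal(nrow(b1), 1)
  del <- sim$deliveries
  expect_true(all(del$x == 4))
  expect_equal(del$time_ms - b1$time_ms,
               net$params$d0 + abs(del$x - del$y) * net$params$nu)
  # all fan-out targets received exactly one event
  expect_setequal(del$y, c(1, 2, 3, 5, 6, 7))
})

test_that("simulation is deterministic and leaves weights untouched without learning", {
  net <- tiny_net()
  net$synapses$w <- rep(c(0, 1), length.out = nrow(net$synapses))
  dr <- fm_sweep_current(8, 5.5)
  s1 <- simulate_network(net, drive = dr, learning = FALSE)
  s2 <- simulate_network(net, drive = dr, learning = FALSE)
  expect_identical(as.data.frame(s1$raster), as.data.frame(s2$raster))
  expect_identical(s1$net$synapses$w, net$synapses$w)
})

test_that("every B2 spike is preceded by same-channel input within a bounded window", {
  net <- tiny_net()
  dr <- fm_sweep_current(8, 5.5)
  sim <- simulate_network(net, drive = dr)
  ras <- sim$raster
  b2 <- ras[ras$population == "B2", ]
  a <- ras[ras$population == "A", ]
  for (i in seq_len(nrow(b2))) {
    prev <- a$time_ms[a$channel == b2$channel[i] &
                        a$time_ms < b2$time_ms[i] &
                        a$time_ms > b2$time_ms[i] - 8]
    expect_gt(length(prev), 0)
  }
})

test_that("drive dimension mismatch is an input error", {
  expect_error(simulate_network(tiny_net(), drive = matrix(0, 5, 100)),
               "channels")
})
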