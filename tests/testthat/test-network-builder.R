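test_that("expected synapse counts follow P * nY/nX * alpha", {
  expect_equal(synapse_count(1, 100, 100, 209), 209)
  # striato-pallidal example on reference counts
  expect_equal(synapse_count(0.82, 10576, 56, 166), 25707.23, tolerance = 1e-6)
  # minimal cortico-striatal in-degree
  expect_equal(synapse_count(1, 12000, 10576, 248), 281.3918, tolerance = 1e-6)
  expect_error(synapse_count(1, 10, 0, 5), "positive")
  expect_error(synapse_count(1.5, 10, 10, 5), "P in")
})

test_that("distinct-source counts have expectation nu/rho with probabilistic rounding", {
  set.seed(1)
  expect_true(all(source_neuron_count(rep(12, 50), 3) == 4L))
  # 117 synapses at redundancy 3: always 39 distinct sources
  expect_true(all(source_neuron_count(rep(117, 50), 3) == 39L))
  draws <- source_neuron_count(rep(14.1, 1e5), 3)
  expect_true(all(draws %in% c(4L, 5L)))
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(mean(draws) - 4.7), 3 * se)
  expect_error(source_neuron_count(10, 0.5), "rho")
})

test_that("electrotonic length matches hand unit conversion and its scaling law", {
  # MSN dendrite: l=619 um, d=1 um, Ri=200 Ohm cm, Rm=20000 Ohm cm^2
  expect_equal(electrotonic_length(619, 1), 1.238, tolerance = 1e-12)
  expect_equal(electrotonic_length(0, 1), 0)
  L1 <- electrotonic_length(500, 1)
  expect_equal(electrotonic_length(500, 4), L1 / 2, tolerance = 1e-12)
  expect_error(electrotonic_length(500, -1), "positive")
})

test_that("dendritic attenuation obeys its closed form, bounds and monotonicity", {
  expect_equal(attenuation(1.5, 0), 1)
  expect_equal(attenuation(1.5, 1), 1 / cosh(1.5), tolerance = 1e-12)
  expect_equal(attenuation(1.238, 0.9), cosh(1.238 * 0.1) / cosh(1.238),
               tolerance = 1e-12)
  expect_equal(attenuation(1.238, 0.9), 0.539, tolerance = 1e-3)
  ps <- seq(0, 1, length.out = 100)
  g <- attenuation(1.238, ps)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) < 0))
  Ls <- seq(0, 5, length.out = 100)
  gL <- attenuation(Ls, 0.7)
  expect_true(all(diff(gL) < 0))
  expect_equal(attenuation(0, 0.3), 1)  # vanishing cable: no attenuation
  expect_error(attenuation(1, 1.2), "p must")
})

test_that("focused projections draw sources from the target's channel only", {
  net <- test_network()
  syn <- net$synapses[net$synapses$proj == "MSN->GPi", ]
  ch_of <- stats::setNames(net$neurons$channel, net$neurons$id)
  expect_gt(nrow(syn), 0)
  expect_true(all(ch_of[as.character(syn$pre)] ==
                    ch_of[as.character(syn$post)]))
})

test_that("diffuse projections draw uniformly across channels", {
  net <- test_network()
  syn <- net$synapses[net$synapses$proj == "STN->GPe", ]
  ch_of <- stats::setNames(net$neurons$channel, net$neurons$id)
  counts <- table(factor(ch_of[as.character(syn$pre)], levels = 1:3))
  expect_gt(sum(counts), 100)
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, stats::qchisq(0.999, df = 2))
})

test_that("realized in-degrees match the expected nu/rho within binomial error", {
  net <- test_network()
  nu <- expected_indegrees(net$param)
  deg <- realized_indegrees(net)
  for (pid in c("CSN->MSN", "MSN->MSN", "MSN->GPe")) {
    row <- nu[paste(nu$src, nu$tgt, sep = "->") == pid, ]
    m <- row$nu / row$rho
    d <- deg[deg$proj == pid, ]
    f <- m - floor(m)
    se <- sqrt(max(f * (1 - f), 0.25) / d$n_post)
    expect_lt(abs(d$mean_indegree - m), 3 * se + 1e-9)
  }
})

test_that("network realization is deterministic under a fixed seed", {
  p <- test_param()
  a <- suppressWarnings(build_network(p, seed = 5))
  b <- suppressWarnings(build_network(p, seed = 5))
  expect_identical(a$synapses, b$synapses)
  c2 <- suppressWarnings(build_network(p, seed = 6))
  expect_false(identical(a$synapses, c2$synapses))
})

test_that("within-population projections exclude self-synapses", {
  net <- test_network()
  for (pid in c("MSN->MSN", "FSI->FSI", "GPe->GPe")) {
    syn <- net$synapses[net$synapses$proj == pid, ]
    expect_true(all(syn$pre != syn$post))
  }
})

test_that("undersized pools fall back to sampling with replacement with a warning", {
  p <- scale_populations(bg_param(), 0.005)
  w <- capture_warnings(build_network(p, seed = 1))
  expect_true(any(grepl("with replacement", w)))
})

test_that("poissonified projections conserve synapse count, weight and delay", {
  p <- test_param()
  net0 <- suppressWarnings(build_network(p, seed = 9))
  net1 <- suppressWarnings(build_network(
    p, disruptions = disrupt_poissonify("MSN", "MSN", rate = 0.3),
    seed = 9))
  s0 <- net0$synapses[net0$synapses$proj == "MSN->MSN", ]
  s1 <- net1$synapses[net1$synapses$proj == "MSN->MSN", ]
  expect_identical(nrow(s1), nrow(s0))
  expect_identical(s1$post, s0$post)
  expect_equal(s1$weight, s0$weight)
  expect_equal(s1$delay, s0$delay)
  # every replacement generator is a dedicated Poisson source at the rate
  gens <- net1$sources[match(s1$pre, net1$sources$id), ]
  expect_true(all(gens$population == "poisson"))
  expect_true(all(gens$rate == 0.3))
  expect_identical(anyDuplicated(s1$pre), 0L)
})

test_that("make_focused rebuilds the named projection as channel-to-channel", {
  p <- test_param()
  net <- suppressWarnings(build_network(
    p, disruptions = disrupt_make_focused("STN", "GPi"), seed = 3))
  syn <- net$synapses[net$synapses$proj == "STN->GPi", ]
  ch_of <- stats::setNames(net$neurons$channel, net$neurons$id)
  expect_true(all(ch_of[as.character(syn$pre)] ==
                    ch_of[as.character(syn$post)]))
  # in-degree expectation unchanged by the topology rewrite
  net0 <- suppressWarnings(build_network(p, seed = 3))
  d0 <- realized_indegrees(net0)
  d1 <- realized_indegrees(net)
  expect_equal(d1$mean_indegree[d1$proj == "STN->GPi"],
               d0$mean_indegree[d0$proj == "STN->GPi"],
               tolerance = 0.35)
  expect_error(build_network(p, disruptions = disrupt_make_focused("GPi", "STN")),
               "unknown projection")
})

test_that("network export writes readable synapse and neuron tables", {
  net <- test_network()
  stem <- tempfile()
  files <- write_network(net, stem)
  expect_true(all(file.exists(paste0(stem, c("_neurons.tsv",
                                             "_synapses.tsv")))))
  back <- utils::read.delim(paste0(stem, "_synapses.tsv"), comment.char = "#")
  expect_identical(nrow(back), nrow(net$synapses))
})
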