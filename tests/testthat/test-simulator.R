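test_that("alpha kernel has the documented peak, origin and half-decay", {
  fx <- bg_fixed_params()
  tauA <- alpha_tau(fx$D[["AMPA"]])
  expect_equal(alpha_kernel(tauA, "AMPA"), 1)         # peak = amplitude
  expect_equal(alpha_kernel(0, "AMPA"), 0)
  expect_equal(alpha_kernel(0, "GABAA"), 0)
  expect_lt(alpha_kernel(tauA, "GABAA") + 0.25, 1e-12)  # sign and peak

  # time from peak to half-amplitude equals the documented half-time
  for (r in c("AMPA", "NMDA", "GABAA")) {
    tau <- alpha_tau(fx$D[[r]])
    peak <- abs(alpha_kernel(tau, r))
    t_half <- stats::uniroot(function(t) abs(alpha_kernel(t, r)) - peak / 2,
                             c(tau, tau * 20), tol = 1e-10)$root
    expect_equal(t_half - tau, fx$D[[r]], tolerance = 0.01)
  }
  # alternative log-2 reading stays selectable
  expect_equal(alpha_tau(5, "log2"), 5 / log(2))
  expect_error(alpha_kernel(1, "dopamine"))
})

test_that("constant-drive firing matches the closed-form LIF rate within 2%", {
  # ISI = t_ref + tau_m * ln(V_C / (V_C - theta))
  p <- isolated_param(V_C = c(MSN = 0, FSI = 0, STN = 0, GPe = 15, GPi = 0),
                      theta = c(MSN = 29, FSI = 16, STN = 25.5, GPe = 10,
                                GPi = 6))
  net <- build_network(p, seed = 1)
  rec <- run_network(net, duration = 5000, warmup = 0, dt = 0.1, seed = 1)
  isi_th <- 2 + 14 * log(15 / 5)
  expect_equal(population_rate(rec, "GPe"), 1000 / isi_th,
               tolerance = 0.02)
  tt <- rec$spikes$time[rec$spikes$id ==
                          net$neurons$id[net$neurons$nucleus == "GPe"]]
  expect_equal(mean(diff(tt)), isi_th, tolerance = 0.02)
})

test_that("subthreshold or undriven neurons never fire", {
  p <- isolated_param(V_C = c(MSN = 0, FSI = 0, STN = 0, GPe = 0, GPi = 0))
  net <- build_network(p, seed = 1)
  rec <- run_network(net, duration = 1000, warmup = 0, dt = 0.1, seed = 1)
  expect_identical(nrow(rec$spikes), 0L)
  # tonic drive below threshold: still silent
  p2 <- isolated_param(V_C = c(MSN = 0, FSI = 0, STN = 0, GPe = 9, GPi = 0),
                       theta = c(MSN = 29, FSI = 16, STN = 25.5, GPe = 10,
                                 GPi = 6))
  rec2 <- run_network(build_network(p2, seed = 1), duration = 1000,
                      warmup = 0, dt = 0.1, seed = 1)
  expect_identical(nrow(rec2$spikes), 0L)
})

test_that("a single unit-weight AMPA synapse evokes a sub-millivolt PSP that decays away", {
  syn <- data.frame(pre = 1L, post = 0L, weight = 1, delay = 1,
                    transmitter = "glutamate", proj = "test",
                    stringsAsFactors = FALSE)
  net <- micro_network(n_neurons = 1, n_sources = 1, source_rate = 0,
                       synapses = syn)
  rec <- run_network(net, duration = 600, warmup = 0, dt = 0.1, seed = 1,
                     ext_spikes = data.frame(pre = 1L, time = 10),
                     trace_ids = 0L)
  v <- rec$trace[, 1]
  expect_lt(max(v), 1)          # membrane peak below the 1-mV PSP peak
  expect_gt(max(v), 0.2)
  # the slow NMDA kernel has died out by the end of the window
  expect_lt(max(abs(tail(v, 50))), 1e-3)
})

test_that("kernel responses superpose linearly below threshold", {
  syn <- data.frame(pre = 1:2, post = 0L, weight = c(0.8, 1.3),
                    delay = 1, transmitter = c("glutamate", "GABA"),
                    proj = "test", stringsAsFactors = FALSE)
  net <- micro_network(n_neurons = 1, n_sources = 2, synapses = syn)
  tr_a <- data.frame(pre = 1L, time = c(5, 17, 40))
  tr_b <- data.frame(pre = 2L, time = c(9, 22))
  run1 <- function(ext) run_network(net, duration = 120, warmup = 0,
                                    dt = 0.1, seed = 1, ext_spikes = ext,
                                    trace_ids = 0L)$trace[, 1]
  va <- run1(tr_a)
  vb <- run1(tr_b)
  vab <- run1(rbind(tr_a, tr_b))
  expect_equal(vab, va + vb, tolerance = 1e-10)
})

test_that("Poisson afferents deliver the programmed rates", {
  net <- micro_network(n_neurons = 1, n_sources = 1000, source_rate = 4)
  rec <- run_network(net, duration = 10000, warmup = 0, dt = 0.1, seed = 2,
                     record_sources = TRUE)
  n <- sum(rec$spikes$id >= 1)
  expect_lt(abs(n - 40000), 3 * sqrt(40000))

  # zero rate: silence
  net0 <- micro_network(n_neurons = 1, n_sources = 100, source_rate = 0)
  rec0 <- run_network(net0, duration = 1000, warmup = 0, dt = 0.1, seed = 2,
                      record_sources = TRUE)
  expect_identical(nrow(rec0$spikes), 0L)
})

test_that("rate schedules step at their breakpoints", {
  net <- micro_network(n_neurons = 1, n_sources = 400, source_rate = 2)
  # the whole CM/Pf pool steps from 2 to 20 Hz at t = 1 s
  prog <- stim_program(stim_entry("CMPf", size = Inf, times = c(0, 1000),
                                  rates = c(2, 20)))
  rec <- run_network(net, prog, duration = 2000, warmup = 0, dt = 0.1,
                     seed = 3, record_sources = TRUE)
  src <- rec$spikes[rec$spikes$id >= 1, ]
  n1 <- sum(src$time <= 1000)
  n2 <- sum(src$time > 1000)
  expect_lt(abs(n1 - 400 * 2), 3 * sqrt(400 * 2))
  expect_lt(abs(n2 - 400 * 20), 3 * sqrt(400 * 20))
})

test_that("stimulation subsets cannot exceed their pool", {
  net <- test_network()
  prog <- stim_program(stim_entry("CSN", channel = 1, size = 1e7,
                                  rates = 20))
  expect_error(run_network(net, prog, duration = 200, warmup = 0,
                           seed = 1), "exceeds pool")
})

test_that("receptor blocks act only when requested and removal of inhibition disinhibits", {
  net <- test_network()
  rest <- test_rest()
  # blocking nothing reproduces the intact run exactly
  same <- run_network(net, duration = 1500, warmup = 500, dt = 0.1,
                      seed = 42)
  expect_identical(same$spikes, rest$spikes)

  blocked <- run_network(net, duration = 1500, warmup = 500, dt = 0.1,
                         seed = 42,
                         blocks = disrupt_block("GPi", "GABAA"))
  expect_gt(population_rate(blocked, "GPi"), population_rate(rest, "GPi"))
  expect_error(run_network(net, seed = 1, duration = 300, warmup = 0,
                           blocks = disrupt_block("SNc", "GABAA")),
               "unknown nucleus")
})

test_that("runs are reproducible under a fixed seed and differ across seeds", {
  net <- test_network()
  a <- run_network(net, duration = 800, warmup = 0, dt = 0.1, seed = 7)
  b <- run_network(net, duration = 800, warmup = 0, dt = 0.1, seed = 7)
  expect_identical(a$spikes, b$spikes)
  c2 <- run_network(net, duration = 800, warmup = 0, dt = 0.1, seed = 8)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("no neuron ever violates the refractory floor", {
  rest <- test_rest()
  t_ref <- test_param()$fixed$t_ref
  by_id <- split(rest$spikes$time, rest$spikes$id)
  gaps <- unlist(lapply(by_id, function(tt) diff(sort(tt))))
  expect_gte(min(gaps), t_ref - 1e-9)
})

test_that("warm-up spikes are flagged, not deleted", {
  rest <- test_rest()
  expect_true(any(rest$spikes$warmup))
  expect_true(any(!rest$spikes$warmup))
  expect_identical(rest$spikes$warmup, rest$spikes$time <= rest$warmup)
})

test_that("halving dt changes deterministic firing by less than 2%", {
  p <- isolated_param(V_C = c(MSN = 0, FSI = 0, STN = 30, GPe = 15,
                              GPi = 12),
                      theta = c(MSN = 29, FSI = 16, STN = 25.5, GPe = 10,
                                GPi = 6))
  net <- build_network(p, seed = 1)
  r1 <- run_network(net, duration = 5000, warmup = 0, dt = 0.1, seed = 1)
  r2 <- run_network(net, duration = 5000, warmup = 0, dt = 0.05, seed = 1)
  for (nn in c("STN", "GPe", "GPi")) {
    expect_equal(population_rate(r1, nn), population_rate(r2, nn),
                 tolerance = 0.02)
  }
})

test_that("spike records round-trip through the TSV writer", {
  rest <- test_rest()
  path <- tempfile(fileext = ".tsv")
  write_spikes(rest, path)
  back <- utils::read.delim(path, comment.char = "#")
  expect_identical(nrow(back), nrow(rest$spikes))
  expect_equal(back$time, rest$spikes$time)
})
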