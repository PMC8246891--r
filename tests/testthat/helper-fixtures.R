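# Shared desk-scale fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# midpoint parameterization at test scale (2% of reference populations)
test_param <- function() {
  cached("param02", scale_populations(bg_param(), 0.02))
}

# one realized network of the midpoint parameterization
test_network <- function() {
  cached("net02", suppressWarnings(build_network(test_param(), seed = 42)))
}

# a rest run on the shared network
test_rest <- function() {
  cached("rest02", run_network(test_network(), duration = 1500,
                               warmup = 500, dt = 0.1, seed = 42))
}

# parameterization of isolated neurons: no synapses, chosen tonic drives
isolated_param <- function(V_C, theta = NULL) {
  p <- bg_param(n_channels = 1)
  p$nuclei$n <- rep(1L, 5)
  p$fixed$n <- stats::setNames(p$nuclei$n, p$nuclei$name)
  p$fixed$n_input <- 1L
  p$projections$alpha <- 0
  p$nuclei$V_C <- V_C[p$nuclei$name]
  if (!is.null(theta)) p$nuclei$theta <- theta[p$nuclei$name]
  p
}

# hand-built micro network: n neurons of one nucleus plus Poisson sources,
# wired by an explicit synapse table (documented bg_network structure)
micro_network <- function(n_neurons = 1, nucleus = "MSN", V_C = 0,
                          theta = 1000, n_sources = 0, source_rate = 0,
                          synapses = NULL) {
  p <- bg_param(n_channels = 1)
  p$nuclei$V_C[] <- 0
  p$nuclei$V_C[p$nuclei$name == nucleus] <- V_C
  p$nuclei$theta[p$nuclei$name == nucleus] <- theta
  neurons <- data.frame(id = seq_len(n_neurons) - 1L, nucleus = nucleus,
                        channel = 1L, stringsAsFactors = FALSE)
  sources <- data.frame(
    id = n_neurons + seq_len(n_sources) - 1L,
    population = rep("CMPf", n_sources), channel = NA_integer_,
    rate = rep(source_rate, n_sources), stringsAsFactors = FALSE)
  if (is.null(synapses)) {
    synapses <- data.frame(pre = integer(), post = integer(),
                           weight = numeric(), delay = numeric(),
                           transmitter = character(), proj = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(param = p, neurons = neurons, sources = sources,
                 synapses = synapses, n_neurons = n_neurons, seed = 0L,
                 disruptions = list()),
            class = "bg_network")
}

# homogeneous-Poisson spike record for the analysis module
poisson_record <- function(n_neurons, rate_hz, duration_ms, seed = 1,
                           nucleus = "GPe") {
  set.seed(seed)
  sp <- do.call(rbind, lapply(seq_len(n_neurons) - 1L, function(i) {
    k <- stats::rpois(1, rate_hz * duration_ms / 1000)
    if (k == 0) return(NULL)
    data.frame(id = i, time = sort(stats::runif(k, 0, duration_ms)))
  }))
  if (is.null(sp)) sp <- data.frame(id = integer(), time = numeric())
  sp$warmup <- logical(nrow(sp))
  structure(list(spikes = sp, duration = duration_ms, warmup = 0,
                 dt = 1, seed = seed,
                 neurons = data.frame(id = seq_len(n_neurons) - 1L,
                                      nucleus = nucleus, channel = 1L)),
            class = "bg_spikes")
}
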