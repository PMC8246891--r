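#' Alpha-function post-synaptic potential kernel
#'
#' Closed form of the PSP evoked at one synaptic site by a single
#' presynaptic spike at `t = 0`:
#' `f(t) = s * A_n * (t / tau_n) * exp(1 - t / tau_n)`, with `s = +1` for
#' glutamatergic receptors (AMPA, NMDA) and `s = -1` for GABA_A.  The peak
#' magnitude is `A_n`, reached at `t = tau_n`; `f(0) = 0`.
#'
#' The synaptic time constant is derived from the documented PSP half-time
#' `D_n`, interpreted by default as the decay time from the kernel peak to
#' half the peak: `tau_n = D_n / (u* - 1)` where `u*` solves
#' `u * exp(1 - u) = 1/2` (`u*` about 2.678).  Setting
#' `half_mode = "log2"` selects the alternative reading `tau_n = D_n / ln 2`.
#'
#' @param t time since the spike (ms, >= 0); vectorized.
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABAA"`.
#' @param fixed constants list, see [bg_fixed_params()].
#' @param half_mode `"peak_decay"` (default) or `"log2"`.
#' @return PSP contribution in mV (negative for GABA_A).
#' @export
alpha_kernel <- function(t, receptor, fixed = bg_fixed_params(),
                         half_mode = c("peak_decay", "log2")) {
  receptor <- match.arg(receptor, c("AMPA", "NMDA", "GABAA"))
  half_mode <- match.arg(half_mode)
  if (any(t < 0)) stop("t must be >= 0")
  tau <- alpha_tau(fixed$D[[receptor]], half_mode)
  s <- if (receptor == "GABAA") -1 else 1
  s * fixed$A[[receptor]] * (t / tau) * exp(1 - t / tau)
}

#' @rdname alpha_kernel
#' @param D PSP half-time (ms).
#' @export
alpha_tau <- function(D, half_mode = c("peak_decay", "log2")) {
  half_mode <- match.arg(half_mode)
  if (half_mode == "log2") return(D / log(2))
  D / (alpha_half_root() - 1)
}

# root u > 1 of u * exp(1 - u) = 1/2 (decay from peak to half-peak)
alpha_half_root <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- stats::uniroot(function(u) u * exp(1 - u) - 0.5,
                               c(1, 10), tol = 1e-12)$root
    cache
  }
})

#' Stimulation programs
#'
#' A stimulation program lists, per afferent population (and channel for
#' the cortical pools), an activated subset and its piecewise-constant
#' rate schedule; all other generators of the pool stay at the baseline
#' rate (CSN 2, PTN 15, CM/Pf 4 Hz).
#'
#' Subset sizes are expressed at reference (full) scale and are multiplied
#' by the parameterization's population scale factor; `size = Inf`
#' activates the whole pool.  Subset membership is drawn once per run,
#' under the run seed.
#'
#' @param ... `stim_entry()` descriptors.
#' @param population `"CSN"`, `"PTN"` or `"CMPf"`.
#' @param channel channel index (ignored for the shared CM/Pf pool).
#' @param size activated-subset size (reference-scale neuron count).
#' @param times schedule breakpoints (ms), starting at 0.
#' @param rates rates (Hz), one per breakpoint, held constant until the
#'   next breakpoint.
#' @return `stim_program` returns a list of class `bg_stim`.
#' @export
stim_program <- function(...) {
  entries <- list(...)
  stopifnot(all(vapply(entries, inherits, TRUE, "bg_stim_entry")))
  structure(entries, class = "bg_stim")
}

#' @rdname stim_program
#' @export
stim_entry <- function(population, channel = NA_integer_, size = Inf,
                       times = 0, rates) {
  population <- match.arg(population, c("CSN", "PTN", "CMPf"))
  stopifnot(length(times) == length(rates), times[1] == 0, all(rates >= 0),
            !is.unsorted(times))
  if (population != "CMPf" && is.na(channel))
    stop("cortical stimulation entries need a channel")
  structure(list(population = population, channel = channel, size = size,
                 times = times, rates = rates), class = "bg_stim_entry")
}

#' Block receptor types within one nucleus
#'
#' Returns a network view in which the contributions of the named receptor
#' types onto neurons of `nucleus` are multiplied by zero, emulating local
#' antagonist injection.  Everything else is unchanged.
#'
#' @param network a [build_network()] result.
#' @param nucleus target nucleus name.
#' @param receptors subset of `c("AMPA", "NMDA", "GABAA")`.
#' @return The modified `bg_network`.
#' @export
block_receptors <- function(network, nucleus, receptors) {
  stopifnot(inherits(network, "bg_network"))
  if (!nucleus %in% network$param$nuclei$name)
    stop("unknown nucleus: ", nucleus)
  network$blocks <- c(network$blocks,
                      list(disrupt_block(nucleus, receptors)))
  network
}

#' Simulate a network instance
#'
#' Clock-driven integration of the LIF network at resolution `dt`:
#' Poisson afferents (one independent generator per input neuron) drive the
#' circuit; spikes propagate along the realized synapses with their delays;
#' each neuron integrates tonic input plus alpha-PSP kernel states with the
#' exact exponential propagator, fires on threshold crossing, and is
#' clamped at reset for the refractory period (kernel states keep evolving).
#' Spikes emitted during the warm-up window are returned but flagged, and
#' excluded by the analysis functions.
#'
#' @param network a [build_network()] result (possibly with receptor
#'   blocks attached via [block_receptors()]).
#' @param program a [stim_program()] or `NULL` for rest (all afferents at
#'   baseline).
#' @param duration total simulated time (ms).
#' @param warmup convergence window (ms) excluded from analyses.
#' @param dt integration step (ms).
#' @param seed integer seed governing Poisson drive and subset draws; runs
#'   are fully reproducible for a fixed network and seed.
#' @param blocks additional receptor-block descriptors for this run.
#' @param ext_spikes optional data.frame (pre, time) of scripted
#'   presynaptic spikes (ids in the network's global id space).
#' @param trace_ids neuron ids whose membrane potential to record.
#' @param record_sources also record the spikes of the Poisson afferent
#'   generators (ids at and above the neuron count).
#' @param half_mode synaptic half-time interpretation, see [alpha_kernel()].
#' @return An object of class `bg_spikes`: `$spikes` (id, time, warmup
#'   flag), run metadata, and `$trace` when requested.
#' @export
run_network <- function(network, program = NULL, duration = 2000,
                        warmup = 1000, dt = 0.1, seed = 1L,
                        blocks = list(), ext_spikes = NULL,
                        trace_ids = integer(0), record_sources = FALSE,
                        half_mode = c("peak_decay", "log2")) {
  stopifnot(inherits(network, "bg_network"))
  if (!(duration > warmup && warmup >= 0)) stop("need duration > warmup >= 0")
  if (dt <= 0) stop("dt must be positive")
  half_mode <- match.arg(half_mode)
  param <- network$param
  fixed <- param$fixed
  nuc <- param$nuclei
  set.seed(seed)

  # receptor gain matrix (blocks)
  if (inherits(blocks, "bg_disruption")) blocks <- list(blocks)
  blocks <- c(network$blocks, blocks)
  gain <- matrix(1, nrow(nuc), 3,
                 dimnames = list(nuc$name, c("AMPA", "NMDA", "GABAA")))
  for (b in blocks) {
    if (!identical(b$kind, "block_receptor"))
      stop("run-time disruptions must be receptor blocks")
    if (!b$nucleus %in% nuc$name) stop("unknown nucleus: ", b$nucleus)
    gain[b$nucleus, b$receptors] <- 0
  }

  # synapse table -> CSR over presynaptic id, with per-receptor delivery
  # amplitudes (weight x receptor amplitude x sign x block gain)
  syn <- network$synapses
  n_pre_total <- network$n_neurons + nrow(network$sources)
  ord <- order(syn$pre, syn$post)
  syn <- syn[ord, ]
  tgt_nuc <- network$neurons$nucleus[syn$post + 1L]
  glut <- syn$transmitter == "glutamate"
  amp_ampa <- ifelse(glut, gain[cbind(tgt_nuc, "AMPA")] * syn$weight *
                       fixed$A[["AMPA"]], 0)
  amp_nmda <- ifelse(glut, gain[cbind(tgt_nuc, "NMDA")] * syn$weight *
                       fixed$A[["NMDA"]], 0)
  amp_gaba <- ifelse(glut, 0, -gain[cbind(tgt_nuc, "GABAA")] * syn$weight *
                       fixed$A[["GABAA"]])
  delay_steps <- pmax(1L, as.integer(round(syn$delay / dt)))
  syn_offset <- c(0L, cumsum(tabulate(syn$pre + 1L, nbins = n_pre_total)))

  # Poisson source rate schedule
  src <- network$sources
  seg_start <- 0
  rates <- matrix(src$rate, nrow = 1)
  if (!is.null(program)) {
    stopifnot(inherits(program, "bg_stim"))
    seg_start <- sort(unique(c(0, unlist(lapply(program, `[[`, "times")))))
    rates <- matrix(rep(src$rate, each = length(seg_start)),
                    nrow = length(seg_start))
    for (e in program) {
      pool <- if (e$population == "CMPf") {
        which(src$population == "CMPf")
      } else {
        if (is.na(e$channel)) stop("cortical stimulation needs a channel")
        which(src$population == e$population & src$channel == e$channel)
      }
      k <- if (is.finite(e$size)) {
        max(1L, as.integer(round(e$size * param$scale)))
      } else length(pool)
      if (k > length(pool))
        stop(sprintf("activated subset (%d) exceeds pool (%d) for %s",
                     k, length(pool), e$population))
      members <- if (k == length(pool)) pool else
        pool[sample.int(length(pool), k)]
      f <- if (length(e$times) == 1) function(t) rep(e$rates, length(t))
           else stats::stepfun(e$times[-1], e$rates)
      rates[, members] <- f(seg_start)
    }
  }

  tau_syn <- vapply(c("AMPA", "NMDA", "GABAA"),
                    function(r) alpha_tau(fixed$D[[r]], half_mode), 0)

  if (is.null(ext_spikes)) {
    ext_pre <- integer(0); ext_step <- integer(0)
  } else {
    o <- order(ext_spikes$time)
    ext_pre <- as.integer(ext_spikes$pre[o])
    ext_step <- as.integer(floor(ext_spikes$time[o] / dt))
  }

  nuc_index <- match(network$neurons$nucleus, nuc$name) - 1L
  res <- .sim_engine(
    network$n_neurons, nuc_index,
    nuc$tau_m, nuc$theta, nuc$V_C, nuc$t_ref,
    syn_offset, syn$post, delay_steps,
    amp_ampa, amp_nmda, amp_gaba,
    nrow(src), rates, seg_start,
    ext_pre, ext_step,
    tau_syn, dt, duration, as.integer(trace_ids), record_sources)

  spikes <- data.frame(id = res$id, time = res$time)
  spikes$warmup <- spikes$time <= warmup
  structure(
    list(spikes = spikes, duration = duration, warmup = warmup, dt = dt,
         seed = seed, neurons = network$neurons,
         trace = if (length(trace_ids)) res$trace else NULL,
         trace_ids = trace_ids),
    class = "bg_spikes"
  )
}

#' @export
print.bg_spikes <- function(x, ...) {
  n_an <- sum(!x$spikes$warmup)
  cat("Spike record\n")
  cat(sprintf(
    "  %d spikes (%d in the %g-ms analysis window), %d neurons, dt=%g ms, seed=%d\n",
    nrow(x$spikes), n_an, x$duration - x$warmup,
    length(unique(x$neurons$nucleus)) * 0 + nrow(x$neurons), x$dt, x$seed))
  invisible(x)
}

#' Write a spike record as tab-separated text
#'
#' Two columns (neuron_id, time_ms) with `#`-prefixed metadata header
#' lines; warm-up spikes are included and marked by the warmup column.
#'
#' @param record a [run_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(record, path) {
  con <- file(path, "w")
  writeLines(sprintf("# bgspike record: duration=%g warmup=%g dt=%g seed=%d",
                     record$duration, record$warmup, record$dt, record$seed),
             con)
  utils::write.table(record$spikes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  invisible(path)
}
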