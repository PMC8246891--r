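#' Expected synapse count per target neuron
#'
#' The mean number of synapses a neuron of population X receives from
#' population Y: `nu = P * (nY / nX) * alpha`, where `P` is the fraction of
#' Y neurons projecting, `alpha` the mean bouton count per projecting axon
#' and `nY`, `nX` the population sizes.
#'
#' @param P projection fraction in \[0, 1\].
#' @param nY,nX source / target population sizes.
#' @param alpha mean boutons per source axon in the target population.
#' @return Real-valued expected in-degree (synapses per target neuron).
#' @export
synapse_count <- function(P, nY, nX, alpha) {
  if (any(nX == 0)) stop("target population size must be positive")
  if (any(P < 0 | P > 1) || any(nY < 0) || any(alpha < 0))
    stop("inputs must be non-negative, P in [0,1]")
  P * (nY / nX) * alpha
}

#' Number of distinct presynaptic neurons for one target
#'
#' With redundancy `rho` contacts per axon, `nu` synapses come from
#' `nu/rho` distinct source neurons; the non-integer part is used as the
#' probability of adding one more connection, so the expectation is exactly
#' `nu/rho`.
#'
#' @param nu expected synapse count (scalar or vector).
#' @param rho redundancy (>= 1).
#' @return Integer count(s) of distinct presynaptic neurons.
#' @export
source_neuron_count <- function(nu, rho) {
  if (any(rho < 1)) stop("rho must be >= 1")
  if (any(nu < 0)) stop("nu must be >= 0")
  m <- nu / rho
  base <- floor(m)
  as.integer(base + (stats::runif(length(m)) < (m - base)))
}

#' Electrotonic length of a single-compartment dendritic cable
#'
#' `L = l * sqrt((4 / d) * (Ri / Rm))` with the dendritic extent `l` and
#' diameter `d` in micrometres converted to centimetres, the intracellular
#' resistivity `Ri` in Ohm cm and the membrane resistance `Rm` in Ohm cm^2;
#' `L` is dimensionless (length in units of the cable space constant).
#'
#' @param l dendritic extent (um); `l = 0` gives `L = 0`.
#' @param d dendritic diameter (um).
#' @param Ri intracellular resistivity (Ohm cm).
#' @param Rm membrane resistance (Ohm cm^2).
#' @return Dimensionless electrotonic length.
#' @export
electrotonic_length <- function(l, d, Ri = 200, Rm = 20000) {
  if (any(l < 0) || any(d <= 0) || any(Ri <= 0) || any(Rm <= 0))
    stop("cable parameters must be positive (l may be zero)")
  (l * 1e-4) * sqrt((4 / (d * 1e-4)) * (Ri / Rm))
}

#' Dendritic attenuation of a synapse at fractional location p
#'
#' Sealed-end finite-cable attenuation from the synapse site to the soma:
#' `gamma = cosh(L * (1 - p)) / cosh(L)`, with `p = 0` a somatic contact
#' (no attenuation) and `p = 1` a contact at the distal tip.
#'
#' @param L electrotonic length (dimensionless, >= 0).
#' @param p fractional dendritic location in \[0, 1\].
#' @return Attenuation factor in (0, 1\].
#' @export
attenuation <- function(L, p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(L < 0)) stop("L must be >= 0")
  cosh(L * (1 - p)) / cosh(L)
}

#' Disruption descriptors
#'
#' Constructors for the structural and pharmacological circuit disruptions
#' understood by [build_network()] and [run_network()]:
#' replacing a projection's presynaptic neurons by independent Poisson
#' processes at a fixed rate (same synapse count, weights and delays),
#' rebuilding a projection's topology as focused (channel-to-channel) or
#' diffuse (all-to-all), and blocking receptor types within one nucleus.
#'
#' @param src,tgt projection endpoints.
#' @param rate replacement Poisson rate (Hz).
#' @param nucleus target nucleus of a receptor block.
#' @param receptors character subset of `c("AMPA", "NMDA", "GABAA")`.
#' @return A list descriptor of class `bg_disruption`.
#' @name disruptions
NULL

#' @rdname disruptions
#' @export
disrupt_poissonify <- function(src, tgt, rate) {
  stopifnot(is.numeric(rate), rate >= 0)
  structure(list(kind = "poissonify_projection", src = src, tgt = tgt,
                 rate = rate), class = "bg_disruption")
}

#' @rdname disruptions
#' @export
disrupt_make_focused <- function(src, tgt) {
  structure(list(kind = "make_focused", src = src, tgt = tgt),
            class = "bg_disruption")
}

#' @rdname disruptions
#' @export
disrupt_make_diffuse <- function(src, tgt) {
  structure(list(kind = "make_diffuse", src = src, tgt = tgt),
            class = "bg_disruption")
}

#' @rdname disruptions
#' @export
disrupt_block <- function(nucleus, receptors) {
  receptors <- match.arg(receptors, c("AMPA", "NMDA", "GABAA"),
                         several.ok = TRUE)
  structure(list(kind = "block_receptor", nucleus = nucleus,
                 receptors = receptors), class = "bg_disruption")
}

#' Realize a stochastic network instance from a parameterization
#'
#' Draws, for every projection and every postsynaptic neuron, the
#' presynaptic partners: `nu/rho` distinct neurons sampled without
#' replacement from the appropriate pool (the post neuron's own channel for
#' focused projections, the union of channels for diffuse ones;
#' self-connections excluded within a population).  Each realized
#' connection carries the weight `w = gamma * rho` (dendritic attenuation
#' times redundancy, exploiting linearity of the PSP summation) and the
#' projection delay.  When a pool is smaller than the requested number of
#' sources (possible at strongly reduced scale), sampling falls back to
#' with-replacement and a warning is issued once per projection.
#'
#' @param param a [bg_param()] object.
#' @param disruptions list of [disruptions] descriptors applied at build
#'   time (`poissonify_projection`, `make_focused`, `make_diffuse`);
#'   receptor blocks are run-time options of [run_network()].
#' @param seed integer seed; the realized synapse table is identical for a
#'   fixed seed.
#' @return An object of class `bg_network` with `$neurons` (id, nucleus,
#'   channel), `$sources` (Poisson generators: id, population, channel,
#'   rate), `$synapses` (pre, post, weight, delay, transmitter, proj) and
#'   bookkeeping fields.
#' @export
build_network <- function(param, disruptions = list(), seed = 1L) {
  stopifnot(inherits(param, "bg_param"))
  if (inherits(disruptions, "bg_disruption")) disruptions <- list(disruptions)
  set.seed(seed)
  fixed <- param$fixed
  nCh <- param$n_channels
  nuc <- param$nuclei

  # neuron table: grouped by nucleus, then channel
  counts <- rep(nuc$n, each = nCh)
  neurons <- data.frame(
    id = seq_len(sum(counts)) - 1L,
    nucleus = rep(nuc$name, nuc$n * nCh),
    channel = unlist(mapply(function(n) rep(seq_len(nCh), each = n),
                            nuc$n, SIMPLIFY = FALSE)),
    stringsAsFactors = FALSE
  )
  n_neurons <- nrow(neurons)
  # Poisson afferent pools: one per channel for CSN and PTN, one shared
  # pool for CM/Pf
  n_in <- fixed$n_input
  src_pop <- c(rep("CSN", nCh * n_in), rep("PTN", nCh * n_in),
               rep("CMPf", n_in))
  src_ch <- c(rep(seq_len(nCh), each = n_in), rep(seq_len(nCh), each = n_in),
              rep(NA_integer_, n_in))
  sources <- data.frame(
    id = n_neurons + seq_along(src_pop) - 1L,
    population = src_pop, channel = src_ch,
    rate = as.numeric(fixed$phi[src_pop]),
    stringsAsFactors = FALSE
  )

  # apply topology disruptions to the projection table before drawing
  pr <- param$projections
  pr$id <- proj_id(pr$src, pr$tgt)
  for (d in disruptions) {
    if (d$kind %in% c("make_focused", "make_diffuse")) {
      i <- which(pr$id == proj_id(d$src, d$tgt))
      if (!length(i)) stop("unknown projection: ", proj_id(d$src, d$tgt))
      pr$pattern[i] <- if (d$kind == "make_focused") "focused" else "diffuse"
    } else if (d$kind == "poissonify_projection") {
      if (!proj_id(d$src, d$tgt) %in% pr$id)
        stop("unknown projection: ", proj_id(d$src, d$tgt))
    } else if (d$kind != "block_receptor") {
      stop("unknown disruption kind: ", d$kind)
    }
  }
  poissonify <- Filter(function(d) d$kind == "poissonify_projection",
                       disruptions)
  pois_ids <- vapply(poissonify, function(d) proj_id(d$src, d$tgt), "")
  pois_rate <- stats::setNames(
    vapply(poissonify, function(d) d$rate, 0), pois_ids)

  n_all <- c(stats::setNames(nuc$n, nuc$name),
             CSN = n_in, PTN = n_in, CMPf = n_in)
  # id pools per (population, channel)
  nuc_pool <- function(name, ch) {
    neurons$id[neurons$nucleus == name & neurons$channel == ch]
  }
  input_pool <- function(name, ch) {
    if (name == "CMPf") sources$id[sources$population == "CMPf"]
    else sources$id[sources$population == name & sources$channel == ch]
  }

  syn <- vector("list", nrow(pr))
  extra_sources <- list()
  L_by_nuc <- stats::setNames(
    electrotonic_length(nuc$l, nuc$d, fixed$R_i, fixed$R_m), nuc$name)

  for (k in seq_len(nrow(pr))) {
    srcp <- pr$src[k]; tgtp <- pr$tgt[k]
    nu <- synapse_count(pr$P[k], n_all[[srcp]], n_all[[tgtp]], pr$alpha[k])
    if (nu == 0) next
    gamma <- attenuation(L_by_nuc[[tgtp]], pr$p[k])
    w <- gamma * pr$rho[k]
    is_input <- srcp %in% fixed$inputs
    focused <- pr$pattern[k] == "focused"
    post_ids <- neurons$id[neurons$nucleus == tgtp]
    post_ch <- neurons$channel[neurons$nucleus == tgtp]
    ks <- source_neuron_count(rep(nu, length(post_ids)), pr$rho[k])
    warned <- FALSE
    pre_list <- vector("list", length(post_ids))
    # pools per channel (or union) computed once
    pools <- if (is_input) {
      if (srcp == "CMPf" || !focused) {
        # CM/Pf shares one pool; a (non-default) diffuse cortical
        # projection draws from the union of its channel pools
        if (srcp == "CMPf") list(all = input_pool(srcp, 1L))
        else list(all = sources$id[sources$population == srcp])
      } else {
        stats::setNames(lapply(seq_len(nCh), function(ch)
          input_pool(srcp, ch)), seq_len(nCh))
      }
    } else {
      if (focused) {
        stats::setNames(lapply(seq_len(nCh), function(ch)
          nuc_pool(srcp, ch)), seq_len(nCh))
      } else {
        list(all = neurons$id[neurons$nucleus == srcp])
      }
    }
    union_pool <- length(pools) == 1L
    for (i in seq_along(post_ids)) {
      ki <- ks[i]
      if (ki == 0L) { pre_list[[i]] <- integer(0); next }
      pool <- if (union_pool) pools[[1L]] else pools[[as.character(post_ch[i])]]
      if (srcp == tgtp) pool <- pool[pool != post_ids[i]]
      if (ki > length(pool)) {
        if (!warned) {
          warning(sprintf(
            "projection %s: pool (%d) smaller than requested sources (%d); sampling with replacement",
            pr$id[k], length(pool), ki))
          warned <- TRUE
        }
        pre_list[[i]] <- if (length(pool) == 0L) integer(0) else
          pool[sample.int(length(pool), ki, replace = TRUE)]
      } else {
        pre_list[[i]] <- pool[sample.int(length(pool), ki)]
      }
    }
    npre <- lengths(pre_list)
    if (sum(npre) == 0L) next
    tab <- data.frame(
      pre = unlist(pre_list),
      post = rep(post_ids, npre),
      weight = w,
      delay = pr$delay[k],
      transmitter = pr$transmitter[k],
      proj = pr$id[k],
      stringsAsFactors = FALSE
    )
    # poissonified projection: same number of synapses, same weights and
    # delays, but each presynaptic partner replaced by an independent
    # Poisson generator at the prescribed rate
    if (pr$id[k] %in% pois_ids && nrow(tab) > 0) {
      new_ids <- seq_len(nrow(tab)) - 1L  # offset later
      extra_sources[[pr$id[k]]] <- data.frame(
        n = nrow(tab), rate = pois_rate[[pr$id[k]]], proj = pr$id[k],
        stringsAsFactors = FALSE)
      tab$pre <- NA_integer_  # filled below once offsets are known
      attr(tab, "poissonified") <- TRUE
    }
    syn[[k]] <- tab
  }
  synapses <- do.call(rbind, syn)
  if (is.null(synapses)) {
    synapses <- data.frame(pre = integer(), post = integer(),
                           weight = numeric(), delay = numeric(),
                           transmitter = character(), proj = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(synapses) <- NULL

  # allocate dedicated Poisson sources for poissonified projections
  if (length(extra_sources)) {
    next_id <- n_neurons + nrow(sources)
    for (pid in names(extra_sources)) {
      n_new <- extra_sources[[pid]]$n
      ids <- next_id + seq_len(n_new) - 1L
      next_id <- next_id + n_new
      sources <- rbind(sources, data.frame(
        id = ids, population = "poisson", channel = NA_integer_,
        rate = extra_sources[[pid]]$rate, stringsAsFactors = FALSE))
      synapses$pre[synapses$proj == pid] <- ids
    }
  }

  structure(
    list(param = param, neurons = neurons, sources = sources,
         synapses = synapses, n_neurons = n_neurons, seed = seed,
         disruptions = disruptions),
    class = "bg_network"
  )
}

#' @export
print.bg_network <- function(x, ...) {
  cat("Basal ganglia network instance\n")
  cat(sprintf("  %d neurons, %d Poisson sources, %d synapses (seed %d)\n",
              x$n_neurons, nrow(x$sources), nrow(x$synapses), x$seed))
  tab <- table(x$neurons$nucleus)[x$param$nuclei$name]
  cat("  neurons per nucleus:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Export a network instance to tab-separated files
#'
#' Writes `<stem>_neurons.tsv` and `<stem>_synapses.tsv` with headers; the
#' build seed is recorded in a leading `#` comment line.
#'
#' @param network a [build_network()] result.
#' @param stem output path stem.
#' @return The two file paths, invisibly.
#' @export
write_network <- function(network, stem) {
  f1 <- paste0(stem, "_neurons.tsv")
  f2 <- paste0(stem, "_synapses.tsv")
  for (f in list(list(f1, network$neurons), list(f2, network$synapses))) {
    con <- file(f[[1]], "w")
    writeLines(sprintf("# bgspike network, seed=%d", network$seed), con)
    utils::write.table(f[[2]], con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(c(f1, f2))
}

#' Realized mean in-degree per projection
#'
#' Mean number of distinct presynaptic partners per postsynaptic neuron for
#' each projection of a realized network (poissonified projections count
#' their generators).
#'
#' @param network a [build_network()] result.
#' @return data.frame: proj, mean_indegree, n_post.
#' @export
realized_indegrees <- function(network) {
  s <- network$synapses
  post_by_proj <- split(s$post, s$proj)
  nuc_of <- stats::setNames(network$neurons$nucleus, network$neurons$id)
  out <- lapply(names(post_by_proj), function(pid) {
    tgt <- sub("^.*->", "", pid)
    n_post <- sum(network$neurons$nucleus == tgt)
    data.frame(proj = pid,
               mean_indegree = length(post_by_proj[[pid]]) / n_post,
               n_post = n_post, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
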