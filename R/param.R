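#' Construct a model parameterization
#'
#' Assemble a complete parameterization of the spiking basal ganglia model:
#' fixed constants, per-nucleus specs (counts, firing thresholds, tonic
#' inputs, membrane constants, dendritic geometry) and per-projection specs
#' (bouton counts, projection fractions, synapse locations, redundancy,
#' focused/diffuse topology, transmitter, delay).
#'
#' Resting potentials are shifted to 0 by convention, so firing thresholds
#' `theta` and tonic inputs `V_C` are expressed relative to rest.
#'
#' @param theta named numeric vector of firing thresholds (mV) per nucleus;
#'   defaults to the midpoints of the plausible ranges.
#' @param V_C named numeric vector of tonic inputs (mV) per nucleus.
#' @param alpha named numeric vector of bouton counts, names `"SRC->TGT"`;
#'   defaults to range midpoints.
#' @param p named numeric vector of synapse locations (fraction of dendrite,
#'   0 = soma, 1 = distal tip), names `"SRC->TGT"`; defaults to range
#'   midpoints.
#' @param rho redundancy (synaptic contacts per axon per dendritic field).
#' @param delay synaptic transmission delay (ms), applied to every
#'   projection unless overridden via the returned object.
#' @param n_channels number of competing channels.
#' @param seed integer recorded in metadata (provenance only).
#' @return An object of class `bg_param`.
#' @export
bg_param <- function(theta = NULL, V_C = bg_default_vc(), alpha = NULL,
                     p = NULL, rho = NULL, delay = 1, n_channels = 3,
                     seed = NA_integer_) {
  fixed <- bg_fixed_params()
  rng <- bg_param_ranges()
  if (is.null(rho)) rho <- fixed$rho
  pr <- rng$projections
  pid <- proj_id(pr$src, pr$tgt)
  al <- (pr$alpha_lo + pr$alpha_hi) / 2
  pp <- (pr$p_lo + pr$p_hi) / 2
  names(al) <- names(pp) <- pid
  if (!is.null(alpha)) al[names(alpha)] <- alpha
  if (!is.null(p)) pp[names(p)] <- p
  th <- (rng$theta$lo + rng$theta$hi) / 2
  names(th) <- rng$theta$nucleus
  if (!is.null(theta)) th[names(theta)] <- theta

  nuclei <- data.frame(
    name = fixed$nuclei,
    n = as.integer(fixed$n[fixed$nuclei]),
    theta = as.numeric(th[fixed$nuclei]),
    V_C = as.numeric(V_C[fixed$nuclei]),
    tau_m = as.numeric(fixed$tau_m[fixed$nuclei]),
    t_ref = fixed$t_ref,
    l = as.numeric(fixed$l[fixed$nuclei]),
    d = as.numeric(fixed$d[fixed$nuclei]),
    stringsAsFactors = FALSE
  )
  projections <- data.frame(
    src = pr$src, tgt = pr$tgt,
    alpha = as.numeric(al[pid]),
    P = pr$P,
    p = as.numeric(pp[pid]),
    rho = rho,
    pattern = pr$pattern,
    transmitter = pr$transmitter,
    delay = delay,
    stringsAsFactors = FALSE
  )
  structure(
    list(fixed = fixed, nuclei = nuclei, projections = projections,
         n_channels = as.integer(n_channels), scale = 1,
         meta = list(seed = seed)),
    class = "bg_param"
  )
}

#' @export
print.bg_param <- function(x, ...) {
  cat("Basal ganglia LIF parameterization\n")
  cat(sprintf("  channels: %d   scale: %g   redundancy rho: %g\n",
              x$n_channels, x$scale, x$projections$rho[1]))
  cat(sprintf("  nuclei: %s\n",
              paste(sprintf("%s(n=%d)", x$nuclei$name, x$nuclei$n),
                    collapse = " ")))
  cat(sprintf("  projections: %d (%d internal, %d afferent)\n",
              nrow(x$projections),
              sum(x$projections$src %in% x$fixed$nuclei),
              sum(!x$projections$src %in% x$fixed$nuclei)))
  invisible(x)
}

#' @export
summary.bg_param <- function(object, ...) {
  print(object)
  cat("\nProjections:\n")
  print(object$projections, row.names = FALSE)
  cat("\nNuclei:\n")
  print(object$nuclei, row.names = FALSE)
  invisible(object)
}

#' Validate a parameterization against the anatomical plausibility envelope
#'
#' Checks that every bouton count, synapse location and firing threshold
#' lies inside its documented plausible interval, and that the wiring is
#' structurally complete (every default projection present, every
#' projection endpoint known).  An empty report means the anatomical
#' plausibility objective is satisfied by construction.
#'
#' Validation intervals apply at reference (unscaled) population sizes;
#' bouton counts of scaled parameterizations are mapped back to reference
#' scale before checking.
#'
#' @param param a [bg_param()] object.
#' @param strict if `TRUE`, any violation raises an error.
#' @return A data.frame (class `bg_validation`) with one row per violation
#'   (zero rows when valid): parameter, projection/nucleus, value, lo, hi.
#' @export
validate_anatomy <- function(param, strict = FALSE) {
  stopifnot(inherits(param, "bg_param"))
  rng <- bg_param_ranges()
  out <- list()
  pr <- param$projections
  known <- c(param$fixed$nuclei, param$fixed$inputs)
  bad <- !(pr$src %in% known) | !(pr$tgt %in% known)
  if (any(bad)) {
    stop("unknown projection endpoint(s): ",
         paste(proj_id(pr$src[bad], pr$tgt[bad]), collapse = ", "))
  }
  missing <- setdiff(proj_id(rng$projections$src, rng$projections$tgt),
                     proj_id(pr$src, pr$tgt))
  if (length(missing)) {
    stop("missing projection(s): ", paste(missing, collapse = ", "))
  }
  ref <- rng$projections
  idx <- match(proj_id(pr$src, pr$tgt), proj_id(ref$src, ref$tgt))
  # undo population rescaling so alpha is compared at reference scale
  fixed0 <- bg_fixed_params()
  n0 <- c(fixed0$n, CSN = fixed0$n_input, PTN = fixed0$n_input,
          CMPf = fixed0$n_input)
  n1 <- c(stats::setNames(param$nuclei$n, param$nuclei$name),
          CSN = param$fixed$n_input, PTN = param$fixed$n_input,
          CMPf = param$fixed$n_input)
  ratio0 <- n0[pr$src] / n0[pr$tgt]
  ratio1 <- n1[pr$src] / n1[pr$tgt]
  alpha_ref <- pr$alpha * ratio1 / ratio0
  for (i in seq_len(nrow(pr))) {
    j <- idx[i]
    id <- proj_id(pr$src[i], pr$tgt[i])
    if (!is.na(j) && (alpha_ref[i] < ref$alpha_lo[j] ||
                      alpha_ref[i] > ref$alpha_hi[j])) {
      out[[length(out) + 1L]] <- data.frame(
        parameter = "alpha", where = id, value = alpha_ref[i],
        lo = ref$alpha_lo[j], hi = ref$alpha_hi[j])
    }
    if (!is.na(j) && (pr$p[i] < ref$p_lo[j] || pr$p[i] > ref$p_hi[j])) {
      out[[length(out) + 1L]] <- data.frame(
        parameter = "p", where = id, value = pr$p[i],
        lo = ref$p_lo[j], hi = ref$p_hi[j])
    }
  }
  th <- rng$theta
  for (i in seq_len(nrow(param$nuclei))) {
    j <- match(param$nuclei$name[i], th$nucleus)
    v <- param$nuclei$theta[i]
    if (v < th$lo[j] || v > th$hi[j]) {
      out[[length(out) + 1L]] <- data.frame(
        parameter = "theta", where = param$nuclei$name[i], value = v,
        lo = th$lo[j], hi = th$hi[j])
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(parameter = character(), where = character(),
               value = numeric(), lo = numeric(), hi = numeric())
  class(rep) <- c("bg_validation", "data.frame")
  if (strict && nrow(rep) > 0) {
    stop("anatomical plausibility violations:\n",
         paste(utils::capture.output(print.data.frame(rep)), collapse = "\n"))
  }
  rep
}

#' Sample a parameterization within the plausible ranges
#'
#' Draws every ranged parameter (bouton counts, synapse locations, firing
#' thresholds) uniformly within its documented interval.  The result always
#' satisfies [validate_anatomy()] by construction.  Stands in for the
#' model-specific optimized parameter sets, which are not part of this
#' package.
#'
#' @param seed integer RNG seed; fixed seed gives an identical draw.
#' @param n_channels number of channels.
#' @return A [bg_param()] object.
#' @export
sample_parameterization <- function(seed = 1L, n_channels = 3) {
  rng <- bg_param_ranges()
  pr <- rng$projections
  set.seed(seed)
  alpha <- stats::runif(nrow(pr), pr$alpha_lo, pr$alpha_hi)
  p <- stats::runif(nrow(pr), pr$p_lo, pr$p_hi)
  names(alpha) <- names(p) <- proj_id(pr$src, pr$tgt)
  theta <- stats::runif(nrow(rng$theta), rng$theta$lo, rng$theta$hi)
  names(theta) <- rng$theta$nucleus
  bg_param(theta = theta, alpha = alpha, p = p,
           n_channels = n_channels, seed = seed)
}

#' Scale population sizes for desk-scale runs
#'
#' Multiplies per-channel neuron counts and input-pool sizes by `factor`
#' (rounded, minimum one neuron) and rescales bouton counts so each
#' neuron's expected synapse count (the in-degree nu = P * nY/nX * alpha)
#' is preserved exactly despite rounding.
#'
#' @param param a [bg_param()] object.
#' @param factor scale factor in (0, 1].
#' @return The rescaled `bg_param`; `$scale` records the cumulative factor.
#' @export
scale_populations <- function(param, factor) {
  stopifnot(inherits(param, "bg_param"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("factor must be a single number in (0, 1]")
  if (factor == 1) return(param)
  old_n <- c(stats::setNames(param$nuclei$n, param$nuclei$name),
             CSN = param$fixed$n_input, PTN = param$fixed$n_input,
             CMPf = param$fixed$n_input)
  new_counts <- pmax(1L, as.integer(round(param$nuclei$n * factor)))
  new_input <- max(1L, as.integer(round(param$fixed$n_input * factor)))
  new_n <- c(stats::setNames(new_counts, param$nuclei$name),
             CSN = new_input, PTN = new_input, CMPf = new_input)
  pr <- param$projections
  # nu = P * (nY/nX) * alpha must be invariant
  ratio_old <- old_n[pr$src] / old_n[pr$tgt]
  ratio_new <- new_n[pr$src] / new_n[pr$tgt]
  param$projections$alpha <- pr$alpha * ratio_old / ratio_new
  param$nuclei$n <- new_counts
  param$fixed$n <- stats::setNames(new_counts, param$nuclei$name)
  param$fixed$n_input <- new_input
  param$scale <- param$scale * factor
  param$meta$scaled <- TRUE
  param
}

#' Expected in-degrees of a parameterization
#'
#' @param param a [bg_param()] object.
#' @return The projection table with an added `nu` column, the expected
#'   number of synapses per target neuron (see [synapse_count()]).
#' @export
expected_indegrees <- function(param) {
  pr <- param$projections
  n <- c(stats::setNames(param$nuclei$n, param$nuclei$name),
         CSN = param$fixed$n_input, PTN = param$fixed$n_input,
         CMPf = param$fixed$n_input)
  pr$nu <- synapse_count(pr$P, n[pr$src], n[pr$tgt], pr$alpha)
  pr
}

#' Save / load a parameterization (YAML)
#'
#' Lossless round-trip of a [bg_param()] object to a structured-text file
#' with sections `fixed`, `nuclei`, `projections` and `meta`.
#'
#' @param param a `bg_param` object.
#' @param path file path.
#' @return `write_param` returns `path` invisibly; `read_param` the object.
#' @export
write_param <- function(param, path) {
  stopifnot(inherits(param, "bg_param"))
  doc <- list(
    fixed = param$fixed[c("n_input", "phi", "A", "D", "R_m", "R_i",
                          "t_ref", "rho", "channel_fraction")],
    nuclei = lapply(seq_len(nrow(param$nuclei)), function(i)
      as.list(param$nuclei[i, ])),
    projections = lapply(seq_len(nrow(param$projections)), function(i)
      as.list(param$projections[i, ])),
    meta = c(param$meta,
             list(n_channels = param$n_channels, scale = param$scale))
  )
  doc$fixed$phi <- as.list(param$fixed$phi)
  doc$fixed$A <- as.list(param$fixed$A)
  doc$fixed$D <- as.list(param$fixed$D)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_param
#' @export
read_param <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("fixed", "nuclei", "projections", "meta")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("parameterization file missing section(s): ",
         paste(miss, collapse = ", "))
  nuc <- do.call(rbind, lapply(doc$nuclei, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  prj <- do.call(rbind, lapply(doc$projections, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  param <- bg_param(n_channels = doc$meta$n_channels)
  param$nuclei <- nuc
  param$nuclei$n <- as.integer(param$nuclei$n)
  param$projections <- prj
  param$fixed$n <- stats::setNames(nuc$n, nuc$name)
  param$fixed$n_input <- as.integer(doc$fixed$n_input)
  param$fixed$phi <- unlist(doc$fixed$phi)
  param$fixed$A <- unlist(doc$fixed$A)
  param$fixed$D <- unlist(doc$fixed$D)
  param$fixed$R_m <- doc$fixed$R_m
  param$fixed$R_i <- doc$fixed$R_i
  param$fixed$t_ref <- doc$fixed$t_ref
  param$fixed$rho <- doc$fixed$rho
  param$scale <- doc$meta$scale
  param$n_channels <- as.integer(doc$meta$n_channels)
  param$meta <- doc$meta[setdiff(names(doc$meta), c("n_channels", "scale"))]
  param
}
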