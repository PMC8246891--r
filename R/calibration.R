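#' Plausibility tables
#'
#' A plausibility table holds one firing-rate interval per (condition,
#' nucleus) pair used by the physiological score: the five rest rows plus
#' one row per deactivation condition.  The documented rest intervals for
#' the striatum are MSN 0.05-1 Hz and FSI 7.8-14 Hz; all other intervals
#' must be supplied (fixtures generate synthetic ones).
#'
#' @param rows data.frame with columns condition, nucleus, low, high (Hz)
#'   and optionally note.
#' @return data.frame of class `bg_plausibility`.
#' @export
plausibility_table <- function(rows) {
  need <- c("condition", "nucleus", "low", "high")
  stopifnot(all(need %in% names(rows)))
  if (any(rows$low > rows$high)) stop("interval with low > high")
  if (!"note" %in% names(rows)) rows$note <- ""
  rows <- rows[, c(need, "note")]
  class(rows) <- c("bg_plausibility", "data.frame")
  rows
}

#' @rdname plausibility_table
#' @param path CSV file with the table columns.
#' @export
read_plausibility <- function(path) {
  plausibility_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname plausibility_table
#' @param table a `bg_plausibility` table.
#' @export
write_plausibility <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Default striatal rest intervals
#'
#' The two rest intervals with documented numeric bounds: MSN 0.05-1 Hz
#' (lower bound excluding fully silent models) and FSI 7.8-14 Hz (from
#' recent awake-macaque recordings).
#'
#' @return data.frame fragment usable in [plausibility_table()].
#' @export
striatal_rest_intervals <- function() {
  data.frame(condition = "rest", nucleus = c("MSN", "FSI"),
             low = c(0.05, 7.8), high = c(1, 14),
             note = "documented default", stringsAsFactors = FALSE)
}

#' The default deactivation battery
#'
#' Nine simulated antagonist-injection conditions complementing the five
#' rest comparisons: in the GPe, blocking AMPA, NMDA, AMPA+NMDA and
#' GABA_A; in the GPi, blocking AMPA, NMDA, AMPA+NMDA, GABA_A and
#' AMPA+NMDA+GABA_A.  Together with the rest rows this yields the 14
#' comparisons of the physiological score.
#'
#' @return data.frame: condition, nucleus, receptors (list column).
#' @export
default_battery <- function() {
  cond <- list(
    list("GPe_AMPA",            "GPe", c("AMPA")),
    list("GPe_NMDA",            "GPe", c("NMDA")),
    list("GPe_AMPA_NMDA",       "GPe", c("AMPA", "NMDA")),
    list("GPe_GABAA",           "GPe", c("GABAA")),
    list("GPi_AMPA",            "GPi", c("AMPA")),
    list("GPi_NMDA",            "GPi", c("NMDA")),
    list("GPi_AMPA_NMDA",       "GPi", c("AMPA", "NMDA")),
    list("GPi_GABAA",           "GPi", c("GABAA")),
    list("GPi_AMPA_NMDA_GABAA", "GPi", c("AMPA", "NMDA", "GABAA"))
  )
  data.frame(
    condition = vapply(cond, `[[`, "", 1),
    nucleus = vapply(cond, `[[`, "", 2),
    receptors = I(lapply(cond, `[[`, 3)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the rest + deactivation battery
#'
#' Runs the network at rest (returning all five nuclei's mean rates) and
#' once per deactivation condition (returning the targeted nucleus's mean
#' rate with the named receptor types blocked).  Rates are averaged over
#' the given seeds (one network realization and Poisson drive per seed).
#'
#' @param param a [bg_param()] object (scaled as desired).
#' @param seeds integer vector of seeds.
#' @param battery battery table, see [default_battery()].
#' @param duration,warmup,dt simulation controls (ms).
#' @return data.frame (condition, nucleus, rate_hz) with 5 rest rows and
#'   one row per battery condition.
#' @export
deactivation_battery <- function(param, seeds = 1L,
                                 battery = default_battery(),
                                 duration = 2000, warmup = 1000, dt = 0.1) {
  acc <- NULL
  for (seed in seeds) {
    net <- build_network(param, seed = seed)
    rest <- run_network(net, duration = duration, warmup = warmup, dt = dt,
                        seed = seed)
    rows <- rate_summary(rest)
    rows <- data.frame(condition = "rest", nucleus = rows$nucleus,
                       rate_hz = rows$rate_hz, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(battery))) {
      rec <- run_network(net, duration = duration, warmup = warmup, dt = dt,
                         seed = seed,
                         blocks = disrupt_block(battery$nucleus[i],
                                                battery$receptors[[i]]))
      rows <- rbind(rows, data.frame(
        condition = battery$condition[i], nucleus = battery$nucleus[i],
        rate_hz = population_rate(rec, battery$nucleus[i]),
        stringsAsFactors = FALSE))
    }
    acc <- if (is.null(acc)) rows else {
      acc$rate_hz <- acc$rate_hz + rows$rate_hz
      acc
    }
  }
  acc$rate_hz <- acc$rate_hz / length(seeds)
  acc
}

#' Score simulated rates against a plausibility table
#'
#' Each simulated (condition, nucleus) mean rate is tested against its
#' interval; the physiological score F is the number of satisfied
#' comparisons (0 to the table size, 14 with the default battery).
#'
#' @param rates data.frame (condition, nucleus, rate_hz), e.g. from
#'   [deactivation_battery()].
#' @param table a [plausibility_table()].
#' @return list of class `bg_score`: `F`, `max_F`, `detail` (per-row
#'   verdicts).
#' @export
score_rates <- function(rates, table) {
  stopifnot(inherits(table, "bg_plausibility"))
  key_r <- paste(rates$condition, rates$nucleus)
  key_t <- paste(table$condition, table$nucleus)
  idx <- match(key_t, key_r)
  if (anyNA(idx))
    stop("no simulated rate for table row(s): ",
         paste(key_t[is.na(idx)], collapse = ", "))
  detail <- data.frame(
    condition = table$condition, nucleus = table$nucleus,
    low = table$low, high = table$high,
    rate_hz = rates$rate_hz[idx],
    pass = rates$rate_hz[idx] >= table$low & rates$rate_hz[idx] <= table$high
  )
  structure(list(F = sum(detail$pass), max_F = nrow(detail),
                 detail = detail), class = "bg_score")
}

#' @export
print.bg_score <- function(x, ...) {
  cat(sprintf("Physiological score F = %d / %d\n", x$F, x$max_F))
  print(x$detail, row.names = FALSE)
  invisible(x)
}

#' Physiological plausibility score of a parameterization
#'
#' Simulates the rest + deactivation battery and scores the resulting mean
#' rates against the plausibility table.
#'
#' @inheritParams deactivation_battery
#' @param table a [plausibility_table()] covering the simulated conditions.
#' @return A `bg_score`, see [score_rates()].
#' @export
physiological_score <- function(param, table, seeds = 1L,
                                battery = default_battery(),
                                duration = 2000, warmup = 1000, dt = 0.1) {
  rates <- deactivation_battery(param, seeds = seeds, battery = battery,
                                duration = duration, warmup = warmup,
                                dt = dt)
  score_rates(rates, table)
}

#' Hypersphere calibration of tonic inputs
#'
#' Grid search for the most central plausible tonic-input vector: the
#' score `f` is evaluated on every grid point; the feasible set is the set
#' of points attaining the maximal score; the returned centre is the
#' feasible point maximizing the distance to its nearest infeasible grid
#' point (the centre of the largest ball fitting inside the feasible
#' domain).  Ties are broken by proximity to the componentwise median of
#' the feasible set, then lexicographically.
#'
#' The ball metric is Euclidean in grid-step units by default (the
#' "hypersphere"); `metric = "chebyshev"` selects the axis-aligned cube
#' reading instead.
#'
#' @param f scoring function taking one named numeric vector (one grid
#'   point) and returning a scalar score; see
#'   [calibrate_tonic_inputs()] for the simulation-backed wrapper.
#' @param grid named list of axis values (one numeric vector per
#'   dimension, e.g. per nucleus).
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @param full_score the score regarded as complete (e.g. the table
#'   size); when the best achieved score is lower this is reported via
#'   `$complete = FALSE`.
#' @return list of class `bg_calibration`: `center` (named vector),
#'   `achieved_F`, `complete`, `radius` (grid-unit distance to the nearest
#'   infeasible point), `feasible` (matrix), `scores`.
#' @export
hypersphere_calibrate <- function(f, grid, metric = c("euclidean",
                                                      "chebyshev"),
                                  full_score = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.list(grid), length(grid) >= 1)
  pts <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  scores <- apply(pts, 1, function(row) f(stats::setNames(row,
                                                          colnames(pts))))
  Fmax <- max(scores)
  feas <- scores == Fmax
  step <- vapply(grid, function(g)
    if (length(g) > 1) min(diff(sort(unique(g)))) else 1, 0)
  U <- sweep(pts, 2, step, "/")
  fea <- U[feas, , drop = FALSE]
  inf <- U[!feas, , drop = FALSE]
  if (nrow(inf) == 0) {
    d <- rep(Inf, nrow(fea))
  } else {
    d <- vapply(seq_len(nrow(fea)), function(i) {
      dif <- sweep(inf, 2, fea[i, ])
      if (metric == "euclidean") sqrt(min(rowSums(dif^2)))
      else min(apply(abs(dif), 1, max))
    }, 0)
  }
  best <- which(d == max(d))
  if (length(best) > 1) {
    med <- apply(fea, 2, stats::median)
    dm <- rowSums(sweep(fea[best, , drop = FALSE], 2, med)^2)
    best <- best[dm == min(dm)]
    if (length(best) > 1) {
      ord <- do.call(order, as.data.frame(fea[best, , drop = FALSE]))
      best <- best[ord[1]]
    }
  }
  center_u <- fea[best[1], ]
  center <- center_u * step
  names(center) <- colnames(pts)
  structure(list(center = center, achieved_F = Fmax,
                 complete = is.null(full_score) || Fmax >= full_score,
                 radius = d[best[1]],
                 feasible = sweep(fea, 2, step, "*"), scores = scores),
            class = "bg_calibration")
}

#' @export
print.bg_calibration <- function(x, ...) {
  cat(sprintf(
    "Hypersphere calibration: F = %g%s, radius = %g grid units\n",
    x$achieved_F, if (x$complete) "" else " (incomplete)", x$radius))
  cat("  centre:",
      paste(sprintf("%s=%g", names(x$center), x$center), collapse = " "),
      "\n")
  invisible(x)
}

#' Simulation-backed tonic-input calibration
#'
#' Wraps [hypersphere_calibrate()] with the physiological score as the
#' objective: each grid point is a tonic-input vector V_C (mV, one entry
#' per nucleus); the score is F from [physiological_score()].
#'
#' @inheritParams physiological_score
#' @param grid named list of candidate V_C values per nucleus (mV).
#' @param metric ball metric, see [hypersphere_calibrate()].
#' @return A `bg_calibration`; `$center` is the calibrated V_C vector.
#' @export
calibrate_tonic_inputs <- function(param, table, grid, seeds = 1L,
                                   metric = "euclidean",
                                   battery = default_battery(),
                                   duration = 2000, warmup = 1000,
                                   dt = 0.1) {
  f <- function(vc) {
    p <- param
    p$nuclei$V_C <- as.numeric(vc[p$nuclei$name])
    physiological_score(p, table, seeds = seeds, battery = battery,
                        duration = duration, warmup = warmup, dt = dt)$F
  }
  hypersphere_calibrate(f, grid, metric = metric,
                        full_score = nrow(table))
}

#' Screen the cortical responsiveness of a parameterization
#'
#' Simulates vigorous cortico-striatal drive (by default 4,000 activated
#' CSNs per channel at 20 Hz, reference scale) and rejects the
#' parameterization when the mean MSN rate stays strictly below the
#' threshold (default 4 Hz): such models are insufficiently responsive to
#' cortical input.
#'
#' @inheritParams deactivation_battery
#' @param seed integer seed.
#' @param n_csn activated CSN count (reference scale) per channel.
#' @param rate activated CSN rate (Hz).
#' @param threshold acceptance threshold (Hz); rates equal to the
#'   threshold are accepted.
#' @return list: `accept`, `msn_rate_hz`, threshold and stimulus echo.
#' @export
screen_csn_response <- function(param, seed = 1L, n_csn = 4000, rate = 20,
                                threshold = 4, duration = 2000,
                                warmup = 1000, dt = 0.1) {
  net <- build_network(param, seed = seed)
  prog <- do.call(stim_program, lapply(seq_len(param$n_channels),
    function(ch) stim_entry("CSN", channel = ch, size = n_csn,
                            rates = rate)))
  rec <- run_network(net, prog, duration = duration, warmup = warmup,
                     dt = dt, seed = seed)
  r <- population_rate(rec, "MSN")
  list(accept = r >= threshold, msn_rate_hz = r, threshold = threshold,
       n_csn = n_csn, rate = rate)
}
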