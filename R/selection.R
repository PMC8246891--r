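#' Selection efficiency of one channel
#'
#' How strongly a channel is selected: the fractional suppression of its
#' GPi output relative to rest, `e_i = max(0, 1 - y_i / y_rest)`, clipped
#' at zero when the output exceeds the rest rate.
#'
#' @param y channel GPi rate (Hz, >= 0); vectorized.
#' @param y_rest GPi rate at rest (Hz, > 0).
#' @return Efficiency in \[0, 1\].
#' @export
efficiency <- function(y, y_rest) {
  if (any(y_rest <= 0)) stop("y_rest must be positive")
  if (any(y < 0)) stop("y must be >= 0")
  pmax(0, 1 - y / y_rest)
}

#' Selection distortion across channels
#'
#' How much the losing channels are disinhibited alongside the winner:
#' with `e_w = max(e)`, `d_w = (sum(e) - e_w) / sum(e)`.  When no channel
#' is selected (`sum(e) = 0`) the distortion is undefined and `NA` is
#' returned (a value, not an error).
#'
#' @param e numeric vector of channel efficiencies in \[0, 1\].
#' @return Distortion in \[0, 1\], or `NA` when undefined.
#' @export
distortion <- function(e) {
  if (any(e < 0 | e > 1)) stop("efficiencies must be in [0, 1]")
  s <- sum(e)
  if (s == 0) return(NA_real_)
  (s - max(e)) / s
}

#' Map a salience to activated cortical rates
#'
#' Salience `s` in \[0, 1\] scales the activated CSN and PTN subsets
#' linearly from their baselines (2 and 15 Hz) to their maximal rates
#' (20 and 46 Hz).
#'
#' @param s salience value(s) in \[0, 1\].
#' @return data.frame (s, csn_hz, ptn_hz).
#' @export
salience_rates <- function(s) {
  if (any(s < 0 | s > 1)) stop("salience must be in [0, 1]")
  data.frame(s = s, csn_hz = 2 + s * (20 - 2), ptn_hz = 15 + s * (46 - 15))
}

# per-channel population rate
channel_rate <- function(record, population, channel, window = NULL) {
  ids <- record$neurons$id[record$neurons$nucleus == population &
                             record$neurons$channel == channel]
  if (!length(ids)) stop("empty channel population")
  if (is.null(window)) window <- analysis_window(record)
  s <- record$spikes
  n <- sum(s$id %in% ids & s$time > window[1] & s$time <= window[2])
  n / length(ids) / ((window[2] - window[1]) / 1000)
}

#' Action-selection characterization over a salience grid
#'
#' For every pair of saliences (s1, s2) applied to channels 1 and 2 (the
#' third channel, when present, is held at baseline), activates cortical
#' subsets at the salience-mapped rates, simulates, and records the
#' per-channel GPi rates.  Computes per-condition efficiencies, the winner
#' efficiency `e_w`, the distortion `d_w` (NA where undefined) and the
#' winner label (`"both"` when the efficiency difference is inside the tie
#' threshold), plus the global sums `e_sum = sum(e_w)` and `d_sum` over
#' defined conditions.  Rates are averaged across seeds (one network and
#' drive realization per seed) before the metrics are computed.
#'
#' @param param a [bg_param()] object (desk-scaled as desired).
#' @param saliences grid values in \[0, 1\] (default 0 to 1 by 0.1, the
#'   11 x 11 grid).
#' @param seeds integer vector of seeds.
#' @param subset_size activated CSN/PTN subset size per channel
#'   (reference scale).
#' @param cmpf_rate constant CM/Pf rate (Hz) for the whole run.
#' @param disruptions build-time disruptions, see [disruptions].
#' @param tie tie rule: `"absolute"` labels `"both"` when
#'   `|e1 - e2| < tie_threshold`; `"relative"` when the difference is
#'   below `tie_threshold` times the larger efficiency.
#' @param tie_threshold numeric threshold (default 0.1 absolute).
#' @param duration,warmup,dt simulation controls (ms).
#' @return list of class `bg_selection`: `grid` (per-condition table),
#'   `e_sum`, `d_sum`, `y_rest`, `n_conditions`, metadata.
#' @export
run_selection_grid <- function(param, saliences = seq(0, 1, by = 0.1),
                               seeds = 1L, subset_size = 500,
                               cmpf_rate = 4, disruptions = list(),
                               tie = c("absolute", "relative"),
                               tie_threshold = 0.1,
                               duration = 2000, warmup = 1000, dt = 0.1) {
  tie <- match.arg(tie)
  if (param$n_channels < 2) stop("selection needs at least 2 channels")
  conds <- expand.grid(s1 = saliences, s2 = saliences,
                       KEEP.OUT.ATTRS = FALSE)
  y1 <- y2 <- numeric(nrow(conds))
  y_rest_acc <- 0
  for (seed in seeds) {
    net <- build_network(param, disruptions = disruptions, seed = seed)
    rest <- run_network(net, duration = duration, warmup = warmup, dt = dt,
                        seed = seed)
    y_rest_acc <- y_rest_acc + population_rate(rest, "GPi")
    for (i in seq_len(nrow(conds))) {
      prog <- selection_program(conds$s1[i], conds$s2[i], subset_size,
                                cmpf_rate)
      rec <- run_network(net, prog, duration = duration, warmup = warmup,
                         dt = dt, seed = seed)
      y1[i] <- y1[i] + channel_rate(rec, "GPi", 1)
      y2[i] <- y2[i] + channel_rate(rec, "GPi", 2)
    }
  }
  ns <- length(seeds)
  y_rest <- y_rest_acc / ns
  if (y_rest <= 0)
    stop("GPi silent at rest; model is uncalibrated (y_rest = 0)")
  y1 <- y1 / ns; y2 <- y2 / ns
  e1 <- efficiency(y1, y_rest)
  e2 <- efficiency(y2, y_rest)
  e_w <- pmax(e1, e2)
  d_w <- vapply(seq_along(e1), function(i) distortion(c(e1[i], e2[i])), 0)
  tied <- if (tie == "absolute") abs(e1 - e2) < tie_threshold
          else abs(e1 - e2) < tie_threshold * pmax(e1, e2, 1e-12)
  winner <- ifelse(tied, "both", ifelse(e1 >= e2, "1", "2"))
  grid <- data.frame(s1 = conds$s1, s2 = conds$s2, y1 = y1, y2 = y2,
                     e1 = e1, e2 = e2, e_w = e_w, d_w = d_w,
                     winner = winner, stringsAsFactors = FALSE)
  structure(list(grid = grid, e_sum = sum(e_w),
                 d_sum = sum(d_w, na.rm = TRUE), y_rest = y_rest,
                 n_conditions = nrow(grid), seeds = seeds,
                 cmpf_rate = cmpf_rate, subset_size = subset_size,
                 tie = tie, tie_threshold = tie_threshold),
            class = "bg_selection")
}

# stimulation program for one salience condition: channels 1 and 2 driven,
# remaining channels at baseline, CM/Pf constant
selection_program <- function(s1, s2, subset_size, cmpf_rate) {
  r1 <- salience_rates(s1); r2 <- salience_rates(s2)
  stim_program(
    stim_entry("CSN", channel = 1, size = subset_size, rates = r1$csn_hz),
    stim_entry("PTN", channel = 1, size = subset_size, rates = r1$ptn_hz),
    stim_entry("CSN", channel = 2, size = subset_size, rates = r2$csn_hz),
    stim_entry("PTN", channel = 2, size = subset_size, rates = r2$ptn_hz),
    stim_entry("CMPf", size = Inf, rates = cmpf_rate)
  )
}

#' @export
print.bg_selection <- function(x, ...) {
  cat(sprintf(
    "Selection grid: %d conditions, e_sum = %.3f, d_sum = %.3f (y_rest = %.2f Hz)\n",
    x$n_conditions, x$e_sum, x$d_sum, x$y_rest))
  invisible(x)
}

#' Theoretical bounds of the global selection metrics
#'
#' Enumerates the salience grid and evaluates, per condition, the
#' best-case outcome under the selection metrics: the winning channel's
#' GPi fully suppressed (efficiency 1) and the loser at rest (efficiency
#' 0), giving winner efficiency 1 and distortion 0.  Summing over the grid
#' yields the maximal attainable `e_sum` (the number of conditions; 121 on
#' the default 11 x 11 grid) and the minimal attainable `d_sum` (0).
#'
#' @param saliences grid values (default 0 to 1 by 0.1).
#' @param y_rest reference rest rate used in the evaluation (any positive
#'   value; the bounds do not depend on it).
#' @return list: `e_sum_max`, `d_sum_min`, `n_conditions`.
#' @export
selection_grid_bounds <- function(saliences = seq(0, 1, by = 0.1),
                                  y_rest = 60) {
  conds <- expand.grid(s1 = saliences, s2 = saliences,
                       KEEP.OUT.ATTRS = FALSE)
  e_best <- numeric(nrow(conds))
  d_best <- numeric(nrow(conds))
  for (i in seq_len(nrow(conds))) {
    e <- c(efficiency(0, y_rest), efficiency(y_rest, y_rest))
    e_best[i] <- max(e)
    d_best[i] <- distortion(e)
  }
  list(e_sum_max = sum(e_best), d_sum_min = sum(d_best),
       n_conditions = nrow(conds))
}

#' Selection metrics under circuit disruptions
#'
#' Measures `e_sum` and `d_sum` for the intact circuit and the four
#' standard disruptions: replacing the MSN-to-MSN (lateral) and the
#' FSI-to-MSN (feedforward) inhibitions by equal numbers of Poisson
#' processes at the corresponding population's measured rest rate, and
#' turning the diffuse STN-to-GPi / STN-to-GPe projections into focused
#' ones.  All variants share the same seeds and grid.
#'
#' @inheritParams run_selection_grid
#' @return list of class `bg_disruption_cmp`: `table` (variant, e_sum,
#'   d_sum) and `grids` (per-variant `bg_selection` objects).
#' @export
disruption_comparison <- function(param, saliences = seq(0, 1, by = 0.1),
                                  seeds = 1L, subset_size = 500,
                                  cmpf_rate = 4, duration = 2000,
                                  warmup = 1000, dt = 0.1) {
  # rest rates of the disrupted source populations, from the intact circuit
  net0 <- build_network(param, seed = seeds[1])
  rest <- run_network(net0, duration = duration, warmup = warmup, dt = dt,
                      seed = seeds[1])
  msn_rest <- population_rate(rest, "MSN")
  fsi_rest <- population_rate(rest, "FSI")
  variants <- list(
    intact = list(),
    `poisson MSN->MSN` = list(disrupt_poissonify("MSN", "MSN", msn_rest)),
    `poisson FSI->MSN` = list(disrupt_poissonify("FSI", "MSN", fsi_rest)),
    `focused STN->GPi` = list(disrupt_make_focused("STN", "GPi")),
    `focused STN->GPe` = list(disrupt_make_focused("STN", "GPe"))
  )
  grids <- lapply(variants, function(dd)
    run_selection_grid(param, saliences = saliences, seeds = seeds,
                       subset_size = subset_size, cmpf_rate = cmpf_rate,
                       disruptions = dd, duration = duration,
                       warmup = warmup, dt = dt))
  table <- data.frame(
    variant = names(grids),
    e_sum = vapply(grids, `[[`, 0, "e_sum"),
    d_sum = vapply(grids, `[[`, 0, "d_sum"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = table, grids = grids),
            class = "bg_disruption_cmp")
}

#' @export
print.bg_disruption_cmp <- function(x, ...) {
  cat("Selection metrics under circuit disruptions\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Selection grids under increasing CM/Pf drive
#'
#' Repeats the salience-grid benchmark with the whole CM/Pf pool held at
#' each of the given constant rates (default 4, 5, 6, 7 Hz) and summarizes
#' each level by the mean winner efficiency over the grid.
#'
#' @inheritParams run_selection_grid
#' @param levels CM/Pf rates (Hz), at or above the 4-Hz baseline.
#' @return list of class `bg_cmpf_sweep`: `summary` (level, mean_e_w,
#'   e_sum, d_sum) and `grids`.
#' @export
cmpf_sweep <- function(param, levels = c(4, 5, 6, 7),
                       saliences = seq(0, 1, by = 0.1), seeds = 1L,
                       subset_size = 500, duration = 2000, warmup = 1000,
                       dt = 0.1) {
  if (any(levels < 4)) stop("CM/Pf levels must be at or above baseline 4 Hz")
  grids <- lapply(levels, function(lv)
    run_selection_grid(param, saliences = saliences, seeds = seeds,
                       subset_size = subset_size, cmpf_rate = lv,
                       duration = duration, warmup = warmup, dt = dt))
  summary <- data.frame(
    level_hz = levels,
    mean_e_w = vapply(grids, function(g) mean(g$grid$e_w), 0),
    e_sum = vapply(grids, `[[`, 0, "e_sum"),
    d_sum = vapply(grids, `[[`, 0, "d_sum")
  )
  structure(list(summary = summary, grids = grids), class = "bg_cmpf_sweep")
}

#' @export
print.bg_cmpf_sweep <- function(x, ...) {
  cat("CM/Pf sweep\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Default sweep spans per input population
#'
#' Activation spans used by the input-sensitivity sweeps: CSN 2-20 Hz,
#' PTN 15-46 Hz, CM/Pf 4-34 Hz.
#'
#' @return data.frame (population, lo_hz, hi_hz).
#' @export
input_spans <- function() {
  data.frame(population = c("CSN", "PTN", "CMPf"),
             lo_hz = c(2, 15, 4), hi_hz = c(20, 46, 34),
             stringsAsFactors = FALSE)
}

#' Input-sensitivity sweep with trend classification
#'
#' For each activated-subset size and each activation rate of one input
#' population, simulates the circuit and records all five nuclei's mean
#' rates; then classifies each nucleus's response as increasing
#' (`"up"`), decreasing (`"down"`) or flat (`"="`).
#'
#' Classification rule: the nucleus rate is regressed linearly on the
#' input rate, pooled over sizes and seeds; the trend is `up`/`down` when
#' the pooled fitted change over the swept span exceeds
#' `max(0.1 Hz, 10%)` of the baseline (fitted rate at the lowest input
#' level) and every per-seed slope agrees in sign with the pooled slope;
#' otherwise `=`.  The 0.1-Hz floor keeps near-silent striatal trends
#' classifiable while staying above the sampling error of pooled
#' estimates.
#'
#' @param param a [bg_param()] object.
#' @param population `"CSN"`, `"PTN"` or `"CMPf"`.
#' @param sizes activated-subset sizes (reference-scale neuron counts).
#' @param rates activation rates (Hz) within the population's span; a
#'   zero-width span classifies everything `=`.
#' @param seeds integer seeds (>= 3 recommended for classification).
#' @param channel stimulated channel for cortical populations.
#' @param duration,warmup,dt simulation controls (ms).
#' @return list of class `bg_sweep`: `rates` (size, rate_in, seed,
#'   nucleus, rate_hz) and `trends` (nucleus, trend, change_hz, slope).
#' @export
input_sensitivity_sweep <- function(param, population,
                                    sizes = c(250, 500, 1000, 2000, 4000),
                                    rates = NULL, seeds = 1:3, channel = 1,
                                    duration = 2000, warmup = 1000,
                                    dt = 0.1) {
  population <- match.arg(population, c("CSN", "PTN", "CMPf"))
  span <- input_spans()
  span <- span[span$population == population, ]
  if (is.null(rates)) rates <- seq(span$lo_hz, span$hi_hz, length.out = 4)
  if (any(rates < span$lo_hz - 1e-9) || any(rates > span$hi_hz + 1e-9))
    stop(sprintf("rates outside the %s span [%g, %g] Hz",
                 population, span$lo_hz, span$hi_hz))
  nucs <- param$nuclei$name
  out <- list()
  for (seed in seeds) {
    net <- build_network(param, seed = seed)
    for (size in sizes) {
      for (r in rates) {
        prog <- stim_program(stim_entry(population, channel = channel,
                                        size = size, rates = r))
        rec <- run_network(net, prog, duration = duration,
                           warmup = warmup, dt = dt, seed = seed)
        out[[length(out) + 1L]] <- data.frame(
          size = size, rate_in = r, seed = seed, nucleus = nucs,
          rate_hz = vapply(nucs, function(nn) population_rate(rec, nn), 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  trends <- classify_trends(obs)
  structure(list(rates = obs, trends = trends, population = population),
            class = "bg_sweep")
}

# trend classification: pooled linear regression with per-seed sign check
classify_trends <- function(obs, floor_hz = 0.1, rel = 0.1) {
  span <- diff(range(obs$rate_in))
  nucs <- unique(obs$nucleus)
  res <- lapply(nucs, function(nn) {
    d <- obs[obs$nucleus == nn, ]
    if (span == 0) {
      return(data.frame(nucleus = nn, trend = "=", change_hz = 0,
                        slope = 0, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(rate_hz ~ rate_in, data = d)
    slope <- stats::coef(fit)[["rate_in"]]
    baseline <- stats::predict(fit,
                               data.frame(rate_in = min(d$rate_in)))
    change <- slope * span
    per_seed <- vapply(split(d, d$seed), function(ds)
      stats::coef(stats::lm(rate_hz ~ rate_in, data = ds))[["rate_in"]], 0)
    consistent <- all(sign(per_seed) == sign(slope))
    thr <- max(floor_hz, rel * abs(baseline))
    trend <- if (abs(change) > thr && consistent) {
      if (slope > 0) "up" else "down"
    } else "="
    data.frame(nucleus = nn, trend = trend, change_hz = change,
               slope = slope, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.bg_sweep <- function(x, ...) {
  cat(sprintf("Input-sensitivity sweep: %s\n", x$population))
  print(x$trends, row.names = FALSE)
  invisible(x)
}

#' Write selection-grid results
#'
#' CSV of the per-condition table (s1, s2, y1, y2, e1, e2, e_w, d_w,
#' winner) and a JSON summary (e_sum, d_sum, y_rest, seeds).
#'
#' @param sel a [run_selection_grid()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return Paths written, invisibly.
#' @export
write_selection <- function(sel, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(sel$grid, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(e_sum = sel$e_sum, d_sum = sel$d_sum, y_rest = sel$y_rest,
           n_conditions = sel$n_conditions, seeds = sel$seeds,
           cmpf_rate = sel$cmpf_rate),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
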