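# Rate, variability and spectral summaries of spike records.
# All analyses exclude warm-up spikes.

analysis_window <- function(record) {
  c(record$warmup, record$duration)
}

pop_ids <- function(record, population) {
  ids <- record$neurons$id[record$neurons$nucleus == population]
  if (!length(ids)) stop("empty population: ", population)
  ids
}

#' Mean population firing rate
#'
#' Count-based estimate: total spikes emitted by the population inside the
#' analysis window, divided by the number of neurons and the window length.
#'
#' @param record a [run_network()] result.
#' @param population nucleus name.
#' @param window optional `c(start, end)` in ms; defaults to the
#'   post-warm-up window.
#' @return Mean rate in Hz.
#' @export
population_rate <- function(record, population, window = NULL) {
  ids <- pop_ids(record, population)
  if (is.null(window)) window <- analysis_window(record)
  if (window[1] < 0 || window[2] > record$duration || window[2] <= window[1])
    stop("window must lie within the record")
  s <- record$spikes
  n <- sum(s$id %in% ids & s$time > window[1] & s$time <= window[2])
  n / length(ids) / ((window[2] - window[1]) / 1000)
}

#' Per-neuron firing rates
#'
#' @inheritParams population_rate
#' @return data.frame (id, rate_hz) over all neurons of the population.
#' @export
neuron_rates <- function(record, population, window = NULL) {
  ids <- pop_ids(record, population)
  if (is.null(window)) window <- analysis_window(record)
  s <- record$spikes
  s <- s[s$id %in% ids & s$time > window[1] & s$time <= window[2], ]
  counts <- tabulate(match(s$id, ids), nbins = length(ids))
  data.frame(id = ids, rate_hz = counts / ((window[2] - window[1]) / 1000))
}

#' Inter-spike-interval coefficient of variation per neuron
#'
#' CV = sd(ISI) / mean(ISI), computed per neuron from the spikes in the
#' analysis window.  Neurons that emitted two spikes or fewer are excluded
#' from the CV computation and flagged.
#'
#' @inheritParams population_rate
#' @return data.frame (id, n_spikes, cv, excluded).
#' @export
cv_distribution <- function(record, population, window = NULL) {
  ids <- pop_ids(record, population)
  if (is.null(window)) window <- analysis_window(record)
  s <- record$spikes
  s <- s[s$id %in% ids & s$time > window[1] & s$time <= window[2], ]
  out <- data.frame(id = ids, n_spikes = 0L, cv = NA_real_, excluded = TRUE)
  if (nrow(s)) {
    by_id <- split(s$time, s$id)
    for (key in names(by_id)) {
      i <- match(as.integer(key), out$id)
      tt <- sort(by_id[[key]])
      out$n_spikes[i] <- length(tt)
      if (length(tt) >= 3) {
        isi <- diff(tt)
        out$cv[i] <- stats::sd(isi) / mean(isi)
        out$excluded[i] <- FALSE
      }
    }
  }
  out
}

#' Population power spectrum with band maxima
#'
#' Discrete Fourier transform of the mean-subtracted, binned (default 1 ms)
#' summed spike-count series of the population over a single window (no
#' tapering).  Band maxima are extracted for the delta (2-4 Hz),
#' alpha (8-12 Hz), beta (12-35 Hz) and gamma (35-128 Hz) bands; the band
#' peak is the maximum power sample inside the closed band interval, ties
#' resolved toward the lowest frequency.
#'
#' @inheritParams population_rate
#' @param bin bin width (ms).
#' @param duration analysis duration (ms) counted from the end of warm-up;
#'   the record must be long enough.
#' @return A list of class `bg_spectrum`: `freq` (Hz), `power`, `bands`
#'   (data.frame band, lo, hi, peak_freq, peak_power).
#' @export
power_spectrum <- function(record, population, bin = 1, duration = 10000) {
  ids <- pop_ids(record, population)
  t0 <- record$warmup
  if (t0 + duration > record$duration)
    stop("record shorter than requested spectrum duration")
  s <- record$spikes
  tt <- s$time[s$id %in% ids & s$time > t0 & s$time <= t0 + duration]
  n_bins <- as.integer(round(duration / bin))
  counts <- tabulate(pmin(n_bins, as.integer(ceiling((tt - t0) / bin))),
                     nbins = n_bins)
  x <- counts - mean(counts)
  ft <- stats::fft(x)
  half <- seq_len(floor(n_bins / 2) + 1L)
  power <- (Mod(ft)^2 / n_bins)[half]
  freq <- (half - 1L) / (n_bins * bin / 1000)
  bands <- data.frame(
    band = c("delta", "alpha", "beta", "gamma"),
    lo = c(2, 8, 12, 35), hi = c(4, 12, 35, 128),
    peak_freq = NA_real_, peak_power = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(bands))) {
    in_band <- which(freq >= bands$lo[i] & freq <= bands$hi[i])
    if (length(in_band)) {
      j <- in_band[which.max(power[in_band])]  # which.max: first max wins
      bands$peak_freq[i] <- freq[j]
      bands$peak_power[i] <- power[j]
    }
  }
  structure(list(freq = freq, power = power, bands = bands,
                 population = population, bin = bin, duration = duration),
            class = "bg_spectrum")
}

#' @export
print.bg_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %s, %g-ms bins over %g ms\n",
              x$population, x$bin, x$duration))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Rate summary across all nuclei
#'
#' @param record a [run_network()] result.
#' @return data.frame (nucleus, rate_hz).
#' @export
rate_summary <- function(record) {
  nucs <- unique(record$neurons$nucleus)
  data.frame(
    nucleus = nucs,
    rate_hz = vapply(nucs, function(nn) population_rate(record, nn), 0),
    row.names = NULL
  )
}

#' CSV writers for analysis outputs
#'
#' @param x a data.frame or `bg_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(x, path) {
  if (inherits(x, "bg_spectrum"))
    x <- data.frame(frequency = x$freq, power = x$power)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
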