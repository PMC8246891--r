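#' Generate a desk-scale model fixture
#'
#' Samples a parameterization within the plausible anatomical ranges,
#' reduces the population scale, runs the rest + deactivation pilot
#' battery, and builds a synthetic plausibility table centred on the
#' pilot's own measured rates (plus/minus the given margin).  By
#' construction the fixture's parameterization scores the full table, so
#' the calibration machinery always has a non-empty feasible region.
#'
#' The synthetic table stands in for the experimentally derived intervals
#' (which, beyond the documented MSN and FSI rest rows, are not part of
#' this package) and is labelled as synthetic in its note column.
#'
#' @param seed integer seed driving the parameter draw, wiring and pilot.
#' @param scale population scale factor in (0, 1].
#' @param n_channels number of channels.
#' @param margin half-width of the synthetic intervals, as a fraction of
#'   the measured rate.
#' @param duration,warmup,dt pilot simulation controls (ms).
#' @return list of class `bg_fixture`: `param` (scaled `bg_param`),
#'   `table` (synthetic [plausibility_table()]), `pilot_rates`.
#' @export
make_fixture <- function(seed = 1L, scale = 0.05, n_channels = 3,
                         margin = 0.2, duration = 1500, warmup = 500,
                         dt = 0.1) {
  if (!(scale > 0 && scale <= 1)) stop("scale must be in (0, 1]")
  param <- sample_parameterization(seed = seed, n_channels = n_channels)
  param <- scale_populations(param, scale)
  pilot <- deactivation_battery(param, seeds = seed, duration = duration,
                                warmup = warmup, dt = dt)
  lo <- pmax(0, pilot$rate_hz * (1 - margin))
  hi <- pilot$rate_hz * (1 + margin)
  # silent pilot rows still need a non-degenerate interval
  hi[pilot$rate_hz == 0] <- 0.5
  table <- plausibility_table(data.frame(
    condition = pilot$condition, nucleus = pilot$nucleus,
    low = lo, high = hi,
    note = "synthetic (centred on fixture pilot run)",
    stringsAsFactors = FALSE))
  structure(list(param = param, table = table, pilot_rates = pilot,
                 seed = seed, scale = scale,
                 pilot_controls = list(duration = duration,
                                       warmup = warmup, dt = dt)),
            class = "bg_fixture")
}

#' @export
print.bg_fixture <- function(x, ...) {
  cat(sprintf("Model fixture: seed=%d scale=%g channels=%d\n",
              x$seed, x$scale, x$param$n_channels))
  print(x$param)
  invisible(x)
}
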