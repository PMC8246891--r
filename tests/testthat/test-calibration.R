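test_that("plausibility tables validate their structure", {
  tab <- plausibility_table(data.frame(
    condition = "rest", nucleus = c("MSN", "FSI"),
    low = c(0.05, 7.8), high = c(1, 14)))
  expect_s3_class(tab, "bg_plausibility")
  expect_error(plausibility_table(data.frame(
    condition = "rest", nucleus = "MSN", low = 2, high = 1)), "low > high")
  path <- tempfile(fileext = ".csv")
  write_plausibility(tab, path)
  expect_equal(read_plausibility(path)$low, tab$low)
  # documented striatal defaults
  def <- striatal_rest_intervals()
  expect_equal(def$low[def$nucleus == "MSN"], 0.05)
  expect_equal(def$high[def$nucleus == "MSN"], 1)
  expect_equal(def$low[def$nucleus == "FSI"], 7.8)
  expect_equal(def$high[def$nucleus == "FSI"], 14)
})

test_that("the physiological score counts interval hits", {
  rates <- data.frame(condition = rep("rest", 5),
                      nucleus = c("MSN", "FSI", "STN", "GPe", "GPi"),
                      rate_hz = c(0.2, 11, 20, 60, 70))
  tab_all <- plausibility_table(data.frame(
    condition = "rest", nucleus = rates$nucleus,
    low = rates$rate_hz - 1, high = rates$rate_hz + 1))
  expect_identical(score_rates(rates, tab_all)$F, 5L)

  tab_none <- tab_all
  tab_none$low <- 1e6; tab_none$high <- 1e6 + 1
  expect_identical(score_rates(rates, plausibility_table(tab_none))$F, 0L)

  tab_one <- tab_all
  tab_one$high[1] <- tab_one$low[1]  # violate the MSN row
  sc <- score_rates(rates, plausibility_table(tab_one))
  expect_identical(sc$F, 4L)
  expect_false(sc$detail$pass[1])
  expect_error(score_rates(rates[-1, ], tab_all), "no simulated rate")
})

test_that("score is monotone non-increasing as intervals tighten", {
  set.seed(3)
  rates <- data.frame(condition = "rest",
                      nucleus = c("MSN", "FSI", "STN", "GPe", "GPi"),
                      rate_hz = runif(5, 0, 50))
  width <- seq(20, 0.9, length.out = 10)
  Fs <- vapply(width, function(w) {
    tab <- plausibility_table(data.frame(
      condition = "rest", nucleus = rates$nucleus,
      low = rates$rate_hz - w / 4, high = rates$rate_hz - 1 + w))
    score_rates(rates, tab)$F
  }, 0L)
  expect_true(all(diff(Fs) <= 0))
})

test_that("the default battery has the documented composition", {
  bat <- default_battery()
  expect_identical(nrow(bat), 9L)
  expect_identical(sum(bat$nucleus == "GPe"), 4L)
  expect_identical(sum(bat$nucleus == "GPi"), 5L)
  # combined with the five rest rows this gives the 14 comparisons
  expect_identical(nrow(bat) + 5L, 14L)
})

test_that("hypersphere search recovers planted feasible-region centres exactly", {
  axes <- stats::setNames(rep(list(seq(0, 10)), 3), c("a", "b", "c"))
  set.seed(11)
  for (trial in 1:20) {
    r <- sample(1:3, 1)
    # the plant must stay strictly interior to the grid: a ball touching
    # the grid edge has no infeasible neighbours beyond it
    centre <- stats::setNames(sample(seq(r + 1, 9 - r), 3, replace = TRUE),
                              names(axes))
    f <- function(v) as.integer(max(abs(v - centre)) <= r) * 14L
    for (metric in c("euclidean", "chebyshev")) {
      cal <- hypersphere_calibrate(f, axes, metric = metric,
                                   full_score = 14)
      expect_equal(unname(cal$center), unname(centre))
      expect_true(cal$complete)
      expect_equal(cal$achieved_F, 14)
    }
  }
  # full 5-dimensional tonic-input grid, unit-radius plant
  axes5 <- stats::setNames(rep(list(seq(0, 4)), 5),
                           c("MSN", "FSI", "STN", "GPe", "GPi"))
  centre5 <- c(MSN = 2, FSI = 2, STN = 2, GPe = 3, GPi = 2)
  f5 <- function(v) as.integer(max(abs(v - centre5)) <= 1) * 14L
  cal5 <- hypersphere_calibrate(f5, axes5, full_score = 14)
  expect_equal(unname(cal5$center), unname(centre5))
})

test_that("degenerate feasible sets and ties resolve deterministically", {
  axes <- list(a = 0:4, b = 0:4)
  single <- c(a = 3, b = 1)
  f1 <- function(v) as.integer(all(v == single))
  cal1 <- hypersphere_calibrate(f1, axes)
  expect_equal(unname(cal1$center), unname(single))

  # two symmetric feasible blobs: the tie-break is reproducible
  f2 <- function(v) as.integer(all(v == c(0, 2)) || all(v == c(4, 2)))
  cal2a <- hypersphere_calibrate(f2, axes)
  cal2b <- hypersphere_calibrate(f2, axes)
  expect_identical(cal2a$center, cal2b$center)
  expect_true(all(cal2a$center %in% c(0, 4)) || cal2a$center[2] == 2)

  # nothing reaches the full score: reported as incomplete with best F
  f3 <- function(v) sum(v)
  cal3 <- hypersphere_calibrate(f3, axes, full_score = 100)
  expect_false(cal3$complete)
  expect_equal(cal3$achieved_F, 8)
})

test_that("the rest + deactivation battery produces the full comparison set", {
  fx <- cached("fixture", make_fixture(seed = 42, scale = 0.02,
                                       duration = 900, warmup = 400))
  rates <- fx$pilot_rates
  expect_identical(nrow(rates), 14L)
  expect_identical(sum(rates$condition == "rest"), 5L)
  # removing GABA_A inhibition in the GPe disinhibits it
  expect_gt(rates$rate_hz[rates$condition == "GPe_GABAA"],
            rates$rate_hz[rates$condition == "rest" &
                            rates$nucleus == "GPe"])
  # glutamatergic blocks in the GPi combine near-linearly
  rest_gpi <- rates$rate_hz[rates$condition == "rest" &
                              rates$nucleus == "GPi"]
  d_a <- rates$rate_hz[rates$condition == "GPi_AMPA"] - rest_gpi
  d_n <- rates$rate_hz[rates$condition == "GPi_NMDA"] - rest_gpi
  d_an <- rates$rate_hz[rates$condition == "GPi_AMPA_NMDA"] - rest_gpi
  expect_lt(abs(d_an - (d_a + d_n)),
            0.2 * max(abs(d_a + d_n), rest_gpi))
})

test_that("a fixture scores its own synthetic table perfectly", {
  fx <- cached("fixture", make_fixture(seed = 42, scale = 0.02,
                                       duration = 900, warmup = 400))
  sc <- physiological_score(fx$param, fx$table, seeds = fx$seed,
                            duration = fx$pilot_controls$duration,
                            warmup = fx$pilot_controls$warmup,
                            dt = fx$pilot_controls$dt)
  expect_identical(sc$F, sc$max_F)
  expect_identical(sc$max_F, 14L)
})

test_that("cortical-responsiveness screening separates dead from driven striatum", {
  p <- test_param()
  # unresponsive variant: cortico-striatal projections silenced
  p0 <- p
  sel <- p0$projections$src == "CSN" & p0$projections$tgt == "MSN"
  p0$projections$alpha[sel] <- 0
  res0 <- suppressWarnings(screen_csn_response(
    p0, seed = 1, duration = 900, warmup = 400))
  expect_false(res0$accept)
  expect_lt(res0$msn_rate_hz, 4)

  res1 <- suppressWarnings(screen_csn_response(
    p, seed = 1, duration = 900, warmup = 400))
  expect_true(res1$accept)
  expect_gte(res1$msn_rate_hz, 4)
})
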