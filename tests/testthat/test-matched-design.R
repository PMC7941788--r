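test_that("control-day selection is weekday-matched +/- 7k arithmetic", {
  expect_equal(select_control_days(as.Date("2007-10-22"), 2),
               as.Date(c("2007-10-08", "2007-10-15", "2007-10-29", "2007-11-05")))
  expect_equal(select_control_days(as.Date("2007-10-26"), 2),
               as.Date(c("2007-10-12", "2007-10-19", "2007-11-02", "2007-11-09")))
  expect_equal(select_control_days(as.Date("2001-03-15"), 1),
               as.Date(c("2001-03-08", "2001-03-22")))
  # property: weekday preserved, exposed excluded, sorted, for random dates
  set.seed(42)
  for (d in sample(seq(as.Date("1995-01-01"), as.Date("2020-12-31"), by = "day"), 40)) {
    d <- as.Date(d, origin = "1970-01-01")
    for (ww in 1:3) {
      ctrl <- select_control_days(d, ww)
      expect_length(ctrl, 2 * ww)
      expect_false(d %in% ctrl)
      expect_true(all(weekday_index(ctrl) == weekday_index(d)))
      expect_true(all(diff(ctrl) > 0))
      expect_setequal(as.numeric(ctrl - d) / 7, setdiff(-ww:ww, 0))
    }
  }
  expect_error(select_control_days(as.Date("2007-10-22"), 0),
               class = "firexcess_invalid_argument")
})

test_that("excess is exposed count minus even-set control median", {
  units <- "U1"
  dates <- seq(as.Date("2007-10-01"), as.Date("2007-11-15"), by = "day")
  pn <- constant_panel(units, dates, 0L)
  ctrl <- select_control_days(as.Date("2007-10-22"), 2)
  set_count <- function(p, d, v) { p$count[p$date %in% d] <- v; p }

  p1 <- set_count(pn, as.Date("2007-10-22"), 5L)
  p1$count[match(ctrl, p1$date)] <- c(1L, 2L, 3L, 4L)
  expect_equal(excess_count("U1", "2007-10-22", p1), 2.5)

  # identical exposed and control counts -> 0
  expect_equal(excess_count("U1", "2007-10-22", constant_panel(units, dates, 3L)), 0)

  # negative excess with even-median half-integer
  p2 <- pn
  p2$count[match(ctrl, p2$date)] <- c(0L, 0L, 1L, 3L)
  expect_equal(excess_count("U1", "2007-10-22", p2), -0.5)

  # median equals brute-force sort-based median on random 4-subsets
  set.seed(9)
  for (r in 1:25) {
    v <- sample(0:6, 4, replace = TRUE)
    p3 <- pn
    p3$count[match(ctrl, p3$date)] <- v
    p3$count[p3$date == as.Date("2007-10-22")] <- 2L
    s <- sort(v)
    expect_equal(excess_count("U1", "2007-10-22", p3), 2 - (s[2] + s[3]) / 2)
  }
})

test_that("missing cells raise a named error unless treated as zeros", {
  dates <- seq(as.Date("2007-10-01"), as.Date("2007-11-15"), by = "day")
  pn <- constant_panel("U1", dates, 1L)
  pn <- pn[pn$date != as.Date("2007-10-29"), ]  # drop one control cell
  expect_error(excess_count("U1", "2007-10-22", pn, absent_as_zero = FALSE),
               "2007-10-29", class = "firexcess_missing_data")
  # default treats the absent cell as an implicit zero count:
  # controls {0, 1, 1, 1} -> median 1
  expect_equal(excess_count("U1", "2007-10-22", pn), 0)
  # duplicates always rejected
  expect_error(excess_panel(rbind(pn, pn[1, ]), study_design()),
               class = "firexcess_invalid_argument")
})

test_that("excess panel aggregates are additive and reorder-invariant", {
  g <- gen_geometry(12, seed = 3)
  sim <- gen_count_panel(g, scenario_config(seed = 4))
  des <- study_design()
  ep <- excess_panel(sim$panel, des)
  # county per-day totals = sum over units; total = sum of per-day
  for (d in names(ep$per_day))
    expect_equal(ep$per_day[[d]],
                 sum(ep$excess$excess[ep$excess$date == as.Date(d)]))
  expect_equal(ep$total_excess, sum(ep$excess$excess))
  # invariant under row shuffling of the input panel
  set.seed(1)
  ep2 <- excess_panel(sim$panel[sample(nrow(sim$panel)), ], des)
  expect_equal(ep2$per_day, ep$per_day)
  expect_equal(ep2$total_excess, ep$total_excess)
  # constant panel -> all zeros
  dates <- seq(as.Date("2007-10-01"), as.Date("2007-11-15"), by = "day")
  ep0 <- excess_panel(constant_panel(c("A", "B"), dates, 2L), des)
  expect_true(all(ep0$excess$excess == 0))
  expect_equal(ep0$percent_excess, 0)
})

test_that("mean excess for mapping averages the exposed-day contrasts", {
  dates <- seq(as.Date("2007-10-01"), as.Date("2007-11-15"), by = "day")
  des3 <- study_design(exposed_dates = as.Date(c("2007-10-22", "2007-10-23",
                                                 "2007-10-24")))
  pn <- constant_panel("U1", dates, 1L)
  pn$count[pn$date %in% des3$exposed_dates] <- c(3L, 1L, 2L)
  ep <- excess_panel(pn, des3)
  expect_equal(unname(mean_excess_for_mapping(ep)), mean(c(2, 0, 1)))
  # single exposed day: identity
  des1 <- study_design(exposed_dates = as.Date("2007-10-22"))
  pn1 <- constant_panel("U1", dates, 1L)
  pn1$count[pn1$date == as.Date("2007-10-22")] <- 4L
  expect_equal(unname(mean_excess_for_mapping(excess_panel(pn1, des1))), 3)
  # sum/mean exchange: n_units * mean over units of per-unit means * n_days
  g <- gen_geometry(8, seed = 6)
  sim <- gen_count_panel(g, scenario_config(seed = 6))
  ep2 <- excess_panel(sim$panel, study_design())
  expect_equal(8 * mean(mean_excess_for_mapping(ep2)) * 5, ep2$total_excess)
})

test_that("null excess matches the analytic median-contrast bias", {
  # the median of 4 low-count Poisson controls lies below the mean, so the
  # contrast is positively biased under the null; the observed null mean
  # must match an independent Monte-Carlo oracle of E[Y - median(4)]
  g <- gen_geometry(108, seed = 15)
  sim <- gen_count_panel(g, scenario_config(seed = 16, plume_amplitude = 0))
  ep <- excess_panel(sim$panel, study_design())
  obs <- mean(ep$excess$excess)
  se <- sd(ep$excess$excess) / sqrt(nrow(ep$excess))

  # oracle: exposed days 2007-10-22..26 are Mon-Fri (dow multiplier 1.05)
  set.seed(17)
  lam <- sim$lambda * 1.05
  bias <- vapply(lam, function(l) {
    m <- apply(matrix(rpois(4 * 2000, l), 4), 2, sort)
    l - mean((m[2, ] + m[3, ]) / 2)
  }, numeric(1))
  expect_lt(abs(obs - mean(bias)), 3 * se)
  expect_gt(obs, 0)   # the bias is real and positive at these rates
})

test_that("period summary reproduces published headline percentages", {
  tabs <- published_excess_tables()
  tot <- tabs$totals
  pct <- function(id) {
    r <- tot[tot$period_id == id, ]
    percent_excess(r$printed_total_excess, r$total_count)$reported
  }
  expect_equal(pct("2007_oct22_26"), 30L)
  expect_equal(pct("2003_oct26_30"), 12L)
  expect_equal(pct("2000_oct22_26"), 8L)
  expect_equal(pct("2004_oct22_26"), 5L)
  # unrounded value retained: 96/325
  expect_equal(percent_excess(96, 325)$percent, 100 * 96 / 325)

  # internally consistent column sums
  pd <- tabs$per_day
  s <- function(id) period_summary(pd$excess[pd$period_id == id],
                                   total_count = tot$total_count[tot$period_id == id])
  expect_equal(s("2007_oct24_28")$total_excess, 58)
  expect_equal(s("2003_oct26_30")$total_excess, 30)

  # direct arithmetic and rounding conventions
  ps <- period_summary(c(6, 12, -1, 5, 8), total_count = 257)
  expect_equal(ps$total_excess, 30)
  expect_equal(ps$percent_reported, 12L)
  expect_equal(period_summary(0, total_count = 100)$percent_reported, 0L)
  expect_equal(percent_excess(59, 200)$reported, 30L)   # 29.5 rounds half away
  expect_error(percent_excess(5, 0), class = "firexcess_undefined_percent")
})
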