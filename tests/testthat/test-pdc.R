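test_that("compute_pdc matches hand-computed windows", {
  rx <- rx_table(c(0, 28, 56))
  expect_equal(compute_pdc(rx, study_window(0, 84)), 100)

  rx2 <- rx_table(c(0, 40))
  expect_equal(compute_pdc(rx2, study_window(0, 80)), 70) # 56 tablets / 80 d

  expect_equal(compute_pdc(rx_table(integer(0)), study_window(0, 365)), 0)
  expect_error(study_window(10, 10), "strictly greater")
})

test_that("compute_pdc agrees with the per-day tally oracle on random histories", {
  set.seed(401)
  for (i in 1:300) {
    cs <- random_rx_case()
    expect_equal(compute_pdc(cs$rx, study_window(cs$start, cs$end)),
                 pdc_oracle(cs$rx, cs$start, cs$end), tolerance = 1e-12)
  }
})

test_that("PDC is equivariant in tablet counts and additive over windows", {
  set.seed(402)
  for (i in 1:50) {
    cs <- random_rx_case()
    w <- study_window(cs$start, cs$end)
    doubled <- cs$rx
    doubled$n_tablets <- doubled$n_tablets * 2L
    expect_equal(compute_pdc(doubled, w), 2 * compute_pdc(cs$rx, w))

    mid <- cs$start + sample.int(cs$end - cs$start, 1L) - 1L
    if (mid > cs$start && mid < cs$end) {
      l1 <- mid - cs$start
      l2 <- cs$end - mid
      p1 <- compute_pdc(cs$rx, study_window(cs$start, mid))
      p2 <- compute_pdc(cs$rx, study_window(mid, cs$end))
      expect_equal(compute_pdc(cs$rx, w),
                   (p1 * l1 + p2 * l2) / (l1 + l2), tolerance = 1e-12)
    }
  }
})

test_that("first-year PDC applies the trailing-prescription window rules", {
  # trailing script at day 360 with no successor: dropped, window [0, 360)
  rx <- rx_table(c(seq(0, 330, by = 30), 360))
  r <- compute_pdc_year1(rx)
  expect_equal(r$pdc1, 336 / 360 * 100, tolerance = 1e-12)
  expect_true("trailing_script_dropped" %in% r$flags)

  # successor at day 370 extends the window to [0, 370)
  rx2 <- rx_table(c(seq(0, 336, by = 28), 370))
  r2 <- compute_pdc_year1(rx2)
  expect_equal(r2$pdc1, 364 / 370 * 100, tolerance = 1e-12)
  expect_length(r2$flags, 0L)

  # implausible oversupply is computed, not capped, and flagged
  rx3 <- rx_table(c(0, 10, 20, 400), tablets = c(300, 300, 300, 28))
  r3 <- compute_pdc_year1(rx3)
  expect_gt(r3$pdc1, 200)
  expect_true("pdc_gt_200" %in% r3$flags)

  # a single prescription has no observable coverage period
  r4 <- compute_pdc_year1(rx_table(0))
  expect_true(is.na(r4$pdc1))
  expect_true("pdc1_undefined" %in% r4$flags)
})

test_that("adherence categories partition PDC with the stated boundaries", {
  expect_equal(as.character(categorize_pdc(c(0, 49.9, 50, 72, 95, 95.1, 140))),
               c("<50", "<50", "50-95", "50-95", "50-95", ">95", ">95"))
  expect_error(categorize_pdc(-1), "negative")
  # piecewise-constant with exactly two breakpoints
  grid <- seq(0, 150, by = 0.1)
  expect_equal(sum(diff(as.integer(categorize_pdc(grid))) != 0), 2L)
})

test_that("interval PDC covers visit-to-visit windows", {
  rx <- rx_table(c(0, 28, 56, 84))
  ip <- compute_interval_pdc(rx, visit_days = c(56, 112))
  expect_equal(ip$pdc, c(100, 100))
  expect_equal(ip$start_day, c(0, 56))

  # an empty window has PDC 0
  ip2 <- compute_interval_pdc(rx_table(c(0, 28)), visit_days = c(60, 120, 180))
  expect_equal(ip2$pdc[3], 0)

  # a single window over year 1 without trailing-script complications
  rx3 <- rx_table(seq(0, 364, by = 28))
  expect_equal(compute_interval_pdc(rx3, visit_days = 365)$pdc,
               compute_pdc(rx3, study_window(0, 365)))

  expect_error(compute_interval_pdc(rx, visit_days = c(100, 50)),
               "strictly increasing")
})

test_that("cohort exclusions drop early deaths and implausible PDC", {
  series <- data.frame(patient_id = c("A", "B", "C", "D"),
                       pdc1 = c(80, 250, 95, NA))
  events <- data.frame(patient_id = c("A", "C"), date_day = c(89L, 91L),
                       event_type = "death")
  r <- apply_cohort_exclusions(series, events)
  expect_equal(r$report, list(died_lt_3mo = 1L, pdc_gt_200 = 1L))
  expect_setequal(r$series$patient_id, c("C", "D")) # death at 91 retained

  # no violations: identity
  r2 <- apply_cohort_exclusions(series[c(1, 3), ], events[0, ])
  expect_equal(r2$series, series[c(1, 3), ])
  expect_equal(r2$report, list(died_lt_3mo = 0L, pdc_gt_200 = 0L))
})
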