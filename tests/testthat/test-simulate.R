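test_that("scenario presets mirror the 13-year regime composition", {
  sc <- make_scenario_preset("mixed-13yr")
  expect_length(sc$regime_sequence, 13L)
  expect_equal(as.vector(table(sc$regime_sequence)[c("T1", "T2", "T3")]),
               c(3L, 5L, 5L))
  expect_equal(sc$years, 2006:2018)
  # regimes sit on the documented years
  expect_equal(sc$years[sc$regime_sequence == "T1"], c(2006L, 2008L, 2018L))
  expect_equal(sc$years[sc$regime_sequence == "T2"],
               c(2009L, 2011L, 2013L, 2015L, 2016L))

  expect_true(all(make_scenario_preset("T2-like")$regime_sequence == "T2"))
  expect_equal(sc$t2_arrival_advance, 4)
  expect_error(make_scenario_preset("T9-like"), "arg")
})

test_that("scenario invariants are enforced", {
  expect_error(scenario(sst_start = 18), "crossing always exists")
  expect_error(scenario(sst_end = 21), "crossing always exists")
  expect_error(scenario(run_size = 0), "run_size")
  expect_error(scenario(pulse_sd = 0), "pulse_sd")
  expect_error(scenario(regime_sequence = rep("T4", 13)), "unknown regime")
  expect_error(scenario(base_cross_day = c(CR1 = 100)), "0\\.\\.91")
})

test_that("noise-free SST crossings land exactly on the shifted target day", {
  base <- c(CR1 = 30, CR2 = 30, CR3 = 30, CR4 = 30, CR5 = 30, CR6 = 30)
  sc <- scenario(n_years = 3, regime_sequence = c("T1", "T2", "T3"),
                 base_cross_day = base, early_shift = 10, ns_offset = 8,
                 late_shift = 5, sst_noise_sd = 0)
  # T1: all regions 10 days early
  expect_equal(crossing_date(simulate_sst(sc, "CR1", 2006)), 20L)
  expect_equal(crossing_date(simulate_sst(sc, "CR6", 2006)), 20L)
  # T2: north early, south late by ns_offset
  expect_equal(crossing_date(simulate_sst(sc, "CR1", 2007)), 20L)
  expect_equal(crossing_date(simulate_sst(sc, "CR6", 2007)), 38L)
  # T3: all late
  expect_equal(crossing_date(simulate_sst(sc, "CR3", 2008)), 35L)
  expect_error(simulate_sst(sc, "CR1", 1999), "not in scenario")
})

test_that("the same seed reproduces a dataset bit-for-bit and streams are
           independent of which region-years are generated", {
  sc <- make_scenario_preset("mixed-13yr", seed = 99)
  a <- simulate_sst(sc, "CR2", 2010)
  b <- simulate_sst(sc, "CR2", 2010)
  expect_identical(a, b)

  ds1 <- simulate_dataset(sc)
  ds2 <- simulate_dataset(sc)
  expect_identical(ds1, ds2)

  # dropping a region leaves other regions' series untouched
  sc_sub <- make_scenario_preset("mixed-13yr", seed = 99)
  sc_sub$base_cross_day <- sc$base_cross_day[c("CR1", "CR2")]
  ds_sub <- simulate_dataset(sc_sub)
  expect_identical(ds_sub$sst$sst[ds_sub$sst$region == "CR2"],
                   ds1$sst$sst[ds1$sst$region == "CR2"])

  # different seed, different draws
  sc2 <- make_scenario_preset("mixed-13yr", seed = 100)
  expect_false(identical(simulate_sst(sc2, "CR2", 2010), a))
})

test_that("degenerate pulses put all catch on the centre day and the river
           pulse is a pure shift by the residence time", {
  sc <- flat_scenario(catch_noise = FALSE, arrival_jitter_sd = 0,
                      residence_jitter_sd = 0, pulse_sd = 1e-6)
  cc <- simulate_catch(sc, "CR1", 2006)
  ctr <- true_pulse_centers(sc, "CR1", "T1")
  expect_equal(which(cc$coastal > 0) - 1L, ctr$coastal)
  expect_equal(sum(cc$coastal), sc$run_size)
  expect_equal(mdmt(cc$coastal), ctr$coastal)
  expect_equal(mdmt(cc$riverine) - mdmt(cc$coastal), ctr$residence)

  # wide pulse, still noise-free: MDMT equals the centre exactly
  sc2 <- flat_scenario(catch_noise = FALSE, arrival_jitter_sd = 0,
                       residence_jitter_sd = 0)
  cc2 <- simulate_catch(sc2, "CR3", 2006)
  ctr2 <- true_pulse_centers(sc2, "CR3", "T1")
  expect_equal(mdmt(cc2$coastal), ctr2$coastal)
  expect_equal(mdmt(cc2$riverine) - mdmt(cc2$coastal), ctr2$residence)
})

test_that("mean recovered MDMT over Poisson replicates sits within half a
           day of the pulse centre", {
  devs <- vapply(1:200, function(s) {
    sc <- flat_scenario(seed = s, arrival_jitter_sd = 0,
                        residence_jitter_sd = 0)
    cc <- simulate_catch(sc, "CR2", 2006)
    mdmt(cc$coastal) - true_pulse_centers(sc, "CR2", "T1")$coastal
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.5)
})

test_that("no fish are created in the river", {
  sc <- make_scenario_preset("mixed-13yr", seed = 5)
  ds <- simulate_dataset(sc)
  tot <- merge(aggregate(catch ~ region + year, ds$coastal, sum),
               aggregate(catch ~ region + year, ds$riverine, sum),
               by = c("region", "year"))
  expect_true(all(tot$catch.y <= tot$catch.x))
  expect_true(all(ds$coastal$catch >= 0 & ds$riverine$catch >= 0))
  expect_true(all(ds$coastal$catch == round(ds$coastal$catch)))
})

test_that("widening ns_offset strictly widens the simulated T2 north-south
           crossing gap", {
  gap_at <- function(off) {
    sc <- scenario(n_years = 1, regime_sequence = "T2", ns_offset = off,
                   sst_noise_sd = 0)
    ds <- simulate_dataset(sc)
    cr <- crossing_table(ds$sst)
    reg <- default_registry()
    south <- cr$region %in% reg$id[reg$area == "south"]
    mean(cr$cross_day[south]) - mean(cr$cross_day[!south])
  }
  gaps <- vapply(c(2, 6, 10, 14), gap_at, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("out-of-window pulse centres are a scenario error", {
  expect_error(
    simulate_dataset(scenario(n_years = 1, regime_sequence = "T3",
                              base_cross_day = c(CR1 = 88), late_shift = 6,
                              sst_noise_sd = 0)),
    "window")
})

test_that("a dataset round-trips bit-for-bit through the long CSV", {
  sc <- make_scenario_preset("T2-like", seed = 3)
  ds <- simulate_dataset(sc)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  for (tab in c("sst", "coastal", "riverine"))
    expect_equal(back[[tab]], ds[[tab]][names(back[[tab]])],
                 ignore_attr = TRUE)
  expect_equal(back$truth$coastal_mdmt, ds$truth$coastal_mdmt)
})
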