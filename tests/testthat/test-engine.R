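# Engine-level behaviour on small worlds. These tests pin the compiled
# scheduler to the same contracts as the R-level rule functions.

test_that("identical config and seed give identical records", {
  cfg <- tiny_config(duration_days = 12)
  r1 <- run_simulation(cfg, seed = 77)
  r2 <- run_simulation(cfg, seed = 77)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$priming, r2$priming)
  expect_identical(r1$licensing, r2$licensing)
  expect_identical(r1$kills, r2$kills)
  expect_identical(r1$dc_census, r2$dc_census)
  r3 <- run_simulation(cfg, seed = 78)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("no CD4Th cells means no CD4Th1 effectors ever", {
  cfg <- tiny_config(duration_days = 15, n_cd4th_naive = 0L,
                     naive_influx_cd4th = 0)
  run <- run_simulation(cfg, seed = 3)
  expect_equal(max(population_series(run, "CD4Th1", "effector")$count), 0)
})

test_that("CD4Treg abrogation removes CD4Treg and all licensing", {
  cfg <- tiny_config(duration_days = 20, abrogate_cd4treg = TRUE)
  run <- run_simulation(cfg, seed = 5)
  for (st in c("naive", "partially_activated", "effector")) {
    expect_equal(max(population_series(run, "CD4Treg", st)$count), 0)
  }
  expect_equal(nrow(run$licensing), 0)
  # licensing mode + no CD4Treg: the Qa-1 gate stays shut, so no CD8Treg
  # priming events can occur in the whole run
  expect_equal(sum(run$priming$lineage == "CD8Treg"), 0)
})

test_that("the conservation ledger balances at every recording step", {
  cfg <- tiny_config(duration_days = 20, debug_conservation = TRUE)
  run <- run_simulation(cfg, seed = 9)
  expect_true(run$conservation_ok)
  # cumulative creation is never below removal
  expect_true(all(run$created >= run$removed))
})

test_that("counts are non-negative and event times lie inside the run", {
  cfg <- tiny_config(duration_days = 15)
  run <- run_simulation(cfg, seed = 21)
  expect_true(all(run$counts >= 0))
  horizon <- cfg$duration_days * 24
  for (log in list(run$priming$time, run$kills$time,
                   run$licensing$licensing_time, run$dc_census$time)) {
    if (length(log)) {
      expect_true(all(log >= 0 & log <= horizon))
    }
  }
  # licensing never precedes DC creation
  if (nrow(run$licensing)) {
    expect_true(all(run$licensing$licensing_time >=
                      run$licensing$creation_time))
  }
})

test_that("Qa-1 gating: CD8Treg priming only on already-licensed DCs", {
  cfg <- tiny_config(duration_days = 25)
  run <- run_simulation(cfg, seed = 13)
  pr <- run$priming[run$priming$lineage == "CD8Treg", ]
  lic <- run$licensing
  skip_if(nrow(pr) == 0, "no CD8Treg priming events in this small world")
  lic_time <- lic$licensing_time[match(pr$dc_id, lic$dc_id)]
  expect_false(anyNA(lic_time))
  expect_true(all(lic_time <= pr$time))
})

test_that("mutually exclusive mode yields zero dual-presenting DCs", {
  cfg <- tiny_config(duration_days = 25, mutex_mode = TRUE)
  for (s in 1:4) {
    run <- run_simulation(cfg, seed = s)
    expect_equal(sum(run$dc_census$presented_mbp == 1 &
                       run$dc_census$presented_tcr == 1), 0)
  }
})

test_that("run_batch wraps runs reproducibly and in seed order", {
  cfg <- tiny_config(duration_days = 8)
  one <- run_batch(cfg, n_runs = 1, base_seed = 42L)
  expect_equal(one$n_runs, 1)
  expect_identical(one$runs[[1]]$counts,
                   run_simulation(cfg, seed = 42)$counts)
  serial <- run_batch(cfg, n_runs = 2, base_seed = 5L)
  parallel <- run_batch(cfg, n_runs = 2, base_seed = 5L, parallel = TRUE)
  expect_identical(lapply(serial$runs, `[[`, "counts"),
                   lapply(parallel$runs, `[[`, "counts"))
  expect_equal(vapply(serial$runs, `[[`, 0L, "seed"), c(5L, 6L))
})

test_that("disabling CTL killing never lowers the median CD4Th1 curve", {
  with_kill <- run_batch(tiny_config(duration_days = 22),
                         n_runs = 10, base_seed = 31L)
  no_kill <- run_batch(tiny_config(duration_days = 22, p_kill = 0),
                       n_runs = 10, base_seed = 31L)
  for (run in no_kill$runs) expect_equal(nrow(run$kills), 0)
  mk <- median_curve(with_kill, "CD4Th1")$median_count
  m0 <- median_curve(no_kill, "CD4Th1")$median_count
  expect_true(all(m0 >= mk - 1e-9))
})

test_that("time series and event files round-trip with provenance", {
  run <- run_simulation(tiny_config(duration_days = 6), seed = 2)
  ts_path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(run, ts_path)
  back <- read_timeseries(ts_path)
  expect_equal(attr(back, "digest"), run$config_digest)
  expect_equal(attr(back, "seed"), run$seed)
  th1 <- population_series(run, "CD4Th1", "effector")
  th1_file <- aggregate(count ~ time_hours,
                        back[back$lineage == "CD4Th1" &
                               back$state == "effector", ], sum)
  got <- th1_file$count[match(th1$time_hours, th1_file$time_hours)]
  got[is.na(got)] <- 0  # zero rows are omitted from the file
  expect_equal(got, th1$count)
  ev_path <- withr::local_tempfile(fileext = ".jsonl")
  write_events(run, ev_path)
  lines <- readLines(ev_path)
  header <- jsonlite::fromJSON(lines[1])
  expect_equal(header$digest, run$config_digest)
  expect_equal(length(lines) - 1,
               nrow(run$priming) + nrow(run$licensing) + nrow(run$kills) +
                 nrow(run$dc_census))
})
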