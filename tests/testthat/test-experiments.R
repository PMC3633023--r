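test_that("experiment specs carry minimal, documented deltas", {
  ctrl <- experiment_spec("control")
  expect_equal(ctrl$deltas, list())
  mut <- experiment_spec("mutex")
  expect_equal(mut$deltas, list(mutex_mode = TRUE))
  q60 <- experiment_spec("qa1_delay_60")
  expect_true(q60$deltas$abrogate_cd4treg)
  expect_equal(q60$deltas$qa1_delay_hours, 60)
  q82 <- experiment_spec("qa1_delay_82")
  expect_equal(q82$deltas$qa1_delay_hours, 82)
  # the spatial arm refuses to run without its preliminary census
  expect_error(experiment_spec("spatial_relaxed"), "census_prelim")
  sp <- experiment_spec("spatial_relaxed", cd8_cap = 3)
  expect_equal(sp$deltas$occupancy_mode, "relaxed_cd8")
  expect_error(experiment_spec("nonsense"))
})

test_that("dc_presentation_census counts each DC once and sums to one", {
  one_dc <- make_run(dc_census = data.frame(
    time = 50, compartment = "Spleen", presented_mbp = 0L,
    presented_tcr = 0L, nb_cd4th_naive = 0L, nb_cd4th1 = 0L, nb_cd4th2 = 0L,
    nb_cd4treg = 0L, nb_cd8treg = 0L))
  cen <- dc_presentation_census(make_ensemble(list(one_dc)))
  expect_equal(unname(cen["none"]), 1)
  # 9 silent DCs and 1 dual presenter
  ten <- make_run(dc_census = data.frame(
    time = 1:10, compartment = "CLN",
    presented_mbp = c(rep(0L, 9), 1L), presented_tcr = c(rep(0L, 9), 1L),
    nb_cd4th_naive = 0L, nb_cd4th1 = 0L, nb_cd4th2 = 0L, nb_cd4treg = 0L,
    nb_cd8treg = 0L))
  cen10 <- dc_presentation_census(make_ensemble(list(ten)))
  expect_equal(unname(cen10["none"]), 0.9)
  expect_equal(unname(cen10["both"]), 0.1)
  expect_equal(sum(cen10), 1)
  expect_error(dc_presentation_census(make_ensemble(list(make_run()))),
               "census")
})

test_that("licensing_age_analysis matches hand-computed fixtures", {
  simple <- make_run(licensing = data.frame(
    dc_id = 1:3, creation_time = c(0, 0, 0),
    licensing_time = c(10, 20, 30)))
  out <- licensing_age_analysis(make_ensemble(list(simple)))
  expect_equal(out$overall_median, 20)
  # creation days 5, 5, 25, 25 with ages 80, 84, 58, 62
  split <- make_run(licensing = data.frame(
    dc_id = 1:4, creation_time = c(5, 5, 25, 25) * 24,
    licensing_time = c(5, 5, 25, 25) * 24 + c(80, 84, 58, 62)))
  res <- licensing_age_analysis(make_ensemble(list(split)), split_day = 20)
  expect_equal(res$median_before, 82)
  expect_equal(res$median_after, 60)
  expect_equal(res$overall_median, median(c(80, 84, 58, 62)))
  expect_error(licensing_age_analysis(make_ensemble(list(make_run()))),
               "licensing")
})

test_that("cd8_neighbour_cap applies the median / round-half-up / floor rule", {
  census_of <- function(counts) make_ensemble(list(make_run(
    dc_census = data.frame(
      time = seq_along(counts), compartment = "Spleen", presented_mbp = 0L,
      presented_tcr = 0L, nb_cd4th_naive = 0L, nb_cd4th1 = 0L,
      nb_cd4th2 = 0L, nb_cd4treg = 0L, nb_cd8treg = as.integer(counts)))))
  expect_equal(cd8_neighbour_cap(census_of(c(0, 1, 3))), 1L)
  # even-length median 3 rounds half-up to 3
  expect_equal(cd8_neighbour_cap(census_of(c(2, 2, 4, 6))), 3L)
  # half-up at .5: median 2.5 -> 3
  expect_equal(cd8_neighbour_cap(census_of(c(2, 3))), 3L)
  expect_warning(cap0 <- cd8_neighbour_cap(census_of(c(0, 0, 0))), "cap 1")
  expect_equal(cap0, 1L)
})

test_that("reduction_metrics compares ensemble medians of event totals", {
  mk <- function(n_prime, n_kill) make_run(
    priming = data.frame(time = seq_len(n_prime), lineage = "CD8Treg",
                         compartment = "Spleen", dc_id = 1L),
    kills = data.frame(time = seq_len(n_kill),
                       compartment = rep(c("CLN", "Spleen"),
                                         length.out = n_kill)))
  ctrl <- make_ensemble(list(mk(100, 200), mk(100, 200)))
  expect_equal(unname(reduction_metrics(ctrl, ctrl)), c(0, 0, 0))
  exp190 <- make_ensemble(list(mk(90, 190), mk(90, 190)))
  red <- reduction_metrics(exp190, ctrl)
  expect_equal(unname(red["cd8_priming_reduction"]), 10)
  expect_equal(unname(red["cd4th1_kill_reduction"]), 5)
  empty <- make_ensemble(list(make_run()))
  expect_error(reduction_metrics(empty, empty), "zero")
})

test_that("calibrate recovers a toy model's parameters within tolerance", {
  # reduced model: two observable metrics are noiseless functions of two
  # config fields; the search must find values inside the bands
  toy_targets <- list(
    m1 = list(value = 0.3, tol = 0.05,
              extract = function(obj) obj$m1),
    m2 = list(value = 120, tol = 15,
              extract = function(obj) obj$m2)
  )
  toy_eval <- function(cfg) {
    list(m1 = cfg$p_kill, m2 = cfg$eff_lifespan_th1)
  }
  out <- calibrate(
    search_space = list(p_kill = c(0, 1), eff_lifespan_th1 = c(50, 200)),
    targets = toy_targets, evaluate = toy_eval,
    n_candidates = 500, seed = 4L)
  expect_true(out$all_pass)
  expect_lt(abs(out$config$p_kill - 0.3), 0.05)
  expect_lt(abs(out$config$eff_lifespan_th1 - 120), 15)
  # with infinite tolerance the first candidate is accepted
  loose <- list(m1 = list(value = 0, tol = Inf,
                          extract = function(obj) obj$m1))
  first <- calibrate(search_space = list(p_kill = c(0, 1)),
                     targets = loose, evaluate = toy_eval,
                     n_candidates = 50, seed = 1L)
  expect_true(first$all_pass)
})

test_that("event_totals extracts per-run totals", {
  r <- make_run(
    priming = data.frame(time = 1:5,
                         lineage = c("CD8Treg", "CD8Treg", "CD4Treg",
                                     "CD4Th1", "CD8Treg"),
                         compartment = "Spleen", dc_id = 1L),
    kills = data.frame(time = 1:2, compartment = "CLN"),
    th1_apoptosis_total = 7)
  ens <- make_ensemble(list(r))
  expect_equal(event_totals(ens, "cd8_priming"), 3)
  expect_equal(event_totals(ens, "kills"), 2)
  expect_equal(event_totals(ens, "th1_apoptosis"), 7)
})
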