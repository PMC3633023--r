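test_that("polarization follows the cytokine milieu", {
  naive <- t_cell("CD4Th_naive_unpolarized")
  # degenerate milieu: type1 only
  for (i in 1:20) {
    expect_equal(polarize_cd4th(naive, c(type1 = 1, type2 = 0)), "CD4Th1")
  }
  # binomial check at p = 0.9
  set.seed(11)
  draws <- replicate(10000, polarize_cd4th(naive, c(type1 = 0.9, type2 = 0.1)))
  frac <- mean(draws == "CD4Th1")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac - 0.9), 3 * se)
  # polarization is a one-way commitment
  th1 <- t_cell("CD4Th1", state = "effector", effector_clock = 50)
  expect_error(polarize_cd4th(th1, c(type1 = 1, type2 = 0)),
               "already polarized")
  expect_error(polarize_cd4th(naive, c(type1 = 0, type2 = 0)), "milieu")
})

test_that("efferocytosis under mutually exclusive presentation locks to the first kind", {
  dc <- dc_state()
  corpse <- t_cell("CD4Th1", state = "apoptotic")
  # first corpse is TCR-derived: lock set, inventory counted
  r1 <- efferocytose(dc, corpse, mutex_mode = TRUE)
  expect_equal(unname(r1$dc$inventory["TCR_source"]), 1L)
  expect_equal(r1$dc$mutex_lock, "TCR_source")
  expect_equal(r1$corpse$state, "removed")
  # second corpse of the other kind is engulfed but never processed
  r2 <- efferocytose(r1$dc, "Neuron", mutex_mode = TRUE)
  expect_equal(unname(r2$dc$inventory["MBP_source"]), 0L)
  expect_equal(unname(r2$dc$inventory["TCR_source"]), 1L)
  # without the mutex both kinds are processed
  r3 <- efferocytose(dc, corpse, mutex_mode = FALSE)
  r4 <- efferocytose(r3$dc, "Neuron", mutex_mode = FALSE)
  expect_equal(unname(r4$dc$inventory), c(1L, 1L))
  # a removed corpse cannot be engulfed twice
  expect_error(efferocytose(dc, r1$corpse), "apoptotic")
  expect_error(efferocytose(dc, t_cell("CD4Th1", state = "naive")),
               "apoptotic")
})

test_that("presentation requires a mature DC and Qa-1 gates CDR1/2 display", {
  dc <- dc_state(maturity = "mature",
                 inventory = c(MBP_source = 0L, TCR_source = 1L))
  expect_error(derive_presentation(dc_state()), "mature")
  # empty inventory: nothing appears
  empty <- dc_state(maturity = "mature")
  expect_equal(derive_presentation(empty, 1, 1)$presented, character(0))
  # without Qa-1, QA1_CDR12 is never displayed however long we derive
  for (i in 1:30) {
    dc <- derive_presentation(dc, p_mbp = 1, p_tcr = 1)
    expect_false("QA1_CDR12" %in% dc$presented)
  }
  expect_true("MHCII_Fr3" %in% dc$presented)
  # once Qa-1 is on, the cross-presented complex appears with Fr3
  dc$qa1_expressed <- TRUE
  dc <- derive_presentation(dc)
  expect_true("QA1_CDR12" %in% dc$presented)
})

test_that("licensing records the first CD40-CD40L contact only", {
  dc <- dc_state(maturity = "mature",
                 inventory = c(MBP_source = 0L, TCR_source = 1L),
                 presented = "MHCII_Fr3", creation_time = 0)
  treg <- t_cell("CD4Treg", state = "effector", effector_clock = 60,
                 has_CD40L = TRUE)
  lic <- license_dc(dc, treg, t = 58)
  expect_true(lic$licensed)
  expect_true(lic$qa1_expressed)
  expect_equal(lic$licensing_time - lic$creation_time, 58)
  expect_true("QA1_CDR12" %in% lic$presented)
  # second contact leaves the licensing time untouched
  again <- license_dc(lic, treg, t = 90)
  expect_equal(again$licensing_time, 58)
  # preconditions: the licensing signal needs an armed effector CD4Treg
  naive_treg <- t_cell("CD4Treg")
  expect_error(license_dc(dc, naive_treg, 10), "effector CD4Treg")
  cd8 <- t_cell("CD8Treg", state = "effector", effector_clock = 60)
  expect_error(license_dc(dc, cd8, 10), "effector CD4Treg")
  no_fr3 <- dc_state(maturity = "mature")
  expect_error(license_dc(no_fr3, treg, 10), "MHCII-Fr3")
})

test_that("constitutive Qa-1 uses a closed lower bound on DC age", {
  pol <- qa1_policy("constitutive_after_delay", delay = 60)
  dc <- dc_state(maturity = "mature", creation_time = 0)
  expect_false(constitutive_qa1_update(dc, pol, t = 59.9)$qa1_expressed)
  expect_true(constitutive_qa1_update(dc, pol, t = 60)$qa1_expressed)
  expect_false(constitutive_qa1_update(dc, pol, t = 60)$licensed)
  expect_error(constitutive_qa1_update(dc, qa1_policy("licensing_required"),
                                       60), "licensing_required")
  expect_error(qa1_policy("constitutive_after_delay"), "delay")
})

test_that("priming advances maturity only at a cognate-presenting DC", {
  dc_mbp <- dc_state(maturity = "mature", polarization = "type1",
                     inventory = c(MBP_source = 1L, TCR_source = 0L),
                     presented = "MHCII_MBP")
  # a CD8Treg at a DC without QA1_CDR12 does not engage (no-op, no error)
  cd8 <- t_cell("CD8Treg")
  expect_equal(prime_t_cell(cd8, dc_mbp)$state, "naive")
  # an unpolarized CD4Th progresses naive -> partial -> effector and
  # polarizes at activation
  set.seed(1)
  th <- t_cell("CD4Th_naive_unpolarized")
  th <- prime_t_cell(th, dc_mbp, milieu = c(type1 = 1, type2 = 0))
  expect_equal(th$state, "partially_activated")
  th <- prime_t_cell(th, dc_mbp, milieu = c(type1 = 1, type2 = 0))
  expect_equal(th$state, "effector")
  expect_equal(th$lineage, "CD4Th1")
  expect_false(is.na(th$effector_clock))
})

test_that("CTL killing is selective for activated CD4Th1", {
  killer <- t_cell("CD8Treg", state = "effector", effector_clock = 50)
  target <- t_cell("CD4Th1", state = "effector", effector_clock = 20)
  expect_equal(cd8treg_kill(killer, target)$state, "apoptotic")
  th2 <- t_cell("CD4Th2", state = "effector", effector_clock = 20)
  expect_error(cd8treg_kill(killer, th2), "selective")
  expect_error(cd8treg_kill(t_cell("CD8Treg"), target), "effector CD8Treg")
})

test_that("lifecycle clocks drive activation-induced cell death", {
  eff <- t_cell("CD4Th1", state = "effector", effector_clock = 1)
  out <- step_lifecycle(eff, dt = 1)
  expect_equal(out$state, "apoptotic")
  still <- step_lifecycle(t_cell("CD4Th1", state = "effector",
                                 effector_clock = 10), dt = 1)
  expect_equal(still$state, "effector")
  expect_equal(still$effector_clock, 9)
  removed <- t_cell("CD4Th1")
  removed$state <- "removed"
  expect_error(step_lifecycle(removed), "removed")
})
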