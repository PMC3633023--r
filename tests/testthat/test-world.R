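test_that("standard occupancy caps total occupants", {
  full <- rep("CD4Treg", 4)
  expect_false(occupancy_allowed(full, 4, "CD8Treg"))
  expect_true(occupancy_allowed(full[1:3], 4, "CD8Treg"))
  expect_false(occupancy_allowed(full, 4, "CD4Treg"))
})

test_that("relaxed occupancy frees CD8Treg from CD4Treg competition only", {
  pol <- occupancy_policy("relaxed_cd8", cd8_cap = 3)
  full_of_treg4 <- rep("CD4Treg", 4)
  # a CD8Treg may enter a space full of CD4Treg
  expect_true(occupancy_allowed(full_of_treg4, 4, "CD8Treg", pol))
  # but only up to cd8_cap CD8Treg per space
  expect_false(occupancy_allowed(c(full_of_treg4, rep("CD8Treg", 3)), 4,
                                 "CD8Treg", pol))
  # every other lineage still obeys the standard rule
  expect_false(occupancy_allowed(full_of_treg4, 4, "CD4Treg", pol))
  expect_error(occupancy_policy("relaxed_cd8"), "cd8_cap")
})

test_that("migration edges match the compartment topology", {
  # recirculation open to all
  expect_true(migration_allowed("CD8Treg", "naive", "Circulation", "Spleen"))
  expect_true(migration_allowed("CD4Treg", "effector", "CLN", "Circulation"))
  # CNS entry is for effector CD4Th1 only
  expect_true(migration_allowed("CD4Th1", "effector", "Circulation", "CNS"))
  expect_false(migration_allowed("CD4Th1", "naive", "Circulation", "CNS"))
  expect_false(migration_allowed("CD8Treg", "effector", "Circulation", "CNS"))
  # apoptotic CD4Th1 drain from the CNS to the lymphoid compartments
  expect_true(migration_allowed("CD4Th1", "apoptotic", "CNS", "CLN"))
  expect_true(migration_allowed("CD4Th1", "apoptotic", "CNS", "Spleen"))
  # mature DCs leave the CNS for the CLN, never the reverse
  expect_true(migration_allowed("DendriticCell", "effector", "CNS", "CLN"))
  expect_false(migration_allowed("DendriticCell", "effector", "CLN", "CNS"))
})

test_that("neighbour census counts lineages around a DC", {
  expect_equal(unname(neighbour_census(character(0))), rep(0L, 5))
  cen <- neighbour_census(c("CD4Treg", "CD4Treg", "CD8Treg"))
  expect_equal(unname(cen[c("CD4Treg", "CD8Treg")]), c(2L, 1L))
  expect_error(neighbour_census("Microglia"), "T-cell")
})
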