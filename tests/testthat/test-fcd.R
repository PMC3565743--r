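test_that("discrepancy metric normalizes by the first response's range", {
  y <- sin(seq(0, 2 * pi, length.out = 100))
  expect_identical(fcdDiscrepancy(y, y), 0)
  expect_equal(fcdDiscrepancy(y, y + 0.1), 0.1 / diff(range(y)))
  # flat reference falls back to the absolute sup-norm
  expect_equal(fcdDiscrepancy(rep(2, 10), rep(2.5, 10)), 0.5)
})

test_that("an unscaled pair is trivially indistinguishable", {
  mod <- setActivityForm(chemotaxisModel("I"), "log")
  pair <- scaledStepPair(500, 100, 500, 100, stepTime = 50, horizon = 150)
  res <- runScaledPair(mod, pair)
  expect_equal(res$verdict@discrepancy, 0, tolerance = 1e-12)
  expect_true(res$verdict@isFCD)
})

test_that("scaled pairs must share a common fold", {
  expect_error(scaledStepPair(1000, 200, 500, 150), "scale factor")
  expect_equal(pairScaleFactor(scaledStepPair()), 2)
})

test_that("explicit methylation dependence destroys fold-change detection", {
  # negative control: a leak term -mLeak * m violates the requirement
  # that the methylation kinetics not depend explicitly on m
  leaky <- setActivityForm(chemotaxisModel("I", mLeak = 1e-3), "log")
  res <- runScaledPair(leaky)
  expect_false(res$verdict@isFCD)
  expect_gt(res$verdict@discrepancy, 1e-3)
  # and the same protocol on the intact model passes
  intact <- setActivityForm(chemotaxisModel("I"), "log")
  expect_true(runScaledPair(intact)$verdict@isFCD)
})

test_that("equivariance check rejects exact-activity models and p = 1 is exact", {
  mod <- chemotaxisModel("I")
  expect_error(equivarianceCheck(mod, ligandProgram(0, 100), 2),
               "log-regime")
  modLog <- setActivityForm(mod, "log")
  prog <- ligandProgram(c(0, 50), c(500, 100))
  tt <- seq(0, 150, 0.5)
  expect_lt(equivarianceCheck(modLog, prog, 1, times = tt), 1e-12)
})

test_that("FCD holds only for backgrounds inside the dissociation window", {
  mod <- chemotaxisModel("I")
  scan <- fcdRangeScan(mod, fold = 5, backgrounds = c(10, 500, 20000))
  expect_false(scan$is_fcd[scan$background_uM == 10])      # ~K_I and below
  expect_true(scan$is_fcd[scan$background_uM == 500])      # log regime
  expect_false(scan$is_fcd[scan$background_uM == 20000])   # above K_A
})

test_that("FCD bound factors reflect the internal-ligand attenuation", {
  expect_equal(fcdBoundFactor(chemotaxisModel("I")), 2.64)
  expect_equal(fcdBoundFactor(addMutation(chemotaxisModel("I"), "cheY4_5x")),
               7.92)
  expect_equal(fcdBoundFactor(chemotaxisModel("II")), 1)
  expect_equal(fcdBoundFactor(chemotaxisModel("III")), 1)
  expect_equal(fcdBoundFactor(addMutation(chemotaxisModel("I"), "cheB2_del")),
               2.64)
})

test_that("FCD implies Weber's law and propagates to downstream channels", {
  mod <- setActivityForm(chemotaxisModel("II"), "log")
  res <- runScaledPair(mod)
  expect_true(res$verdict@isFCD)
  f1 <- trajChannel(res$traj1, "f"); f2 <- trajChannel(res$traj2, "f")
  # equal extremal amplitudes (Weber) follow from full shape equality
  expect_equal(max(f1), max(f2), tolerance = 1e-6)
  expect_equal(min(f1), min(f2), tolerance = 1e-6)
  for (ch in c("a", "at", "A2p", "A34p", "Y3p", "Y4p", "Y6p", "B1p", "B2p"))
    expect_lt(fcdDiscrepancy(trajChannel(res$traj1, ch),
                             trajChannel(res$traj2, ch)), 1e-6)
})

test_that("verdicts are stable under solver-tolerance and grid refinement", {
  mod <- setActivityForm(chemotaxisModel("I"), "log")
  pair <- scaledStepPair(1000, 200, 500, 100, stepTime = 50, horizon = 200)
  v1 <- runScaledPair(mod, pair)$verdict
  modTight <- setActivityForm(
    chemotaxisModel("I", solver = list(rtol = 5e-11, atol = 5e-11)), "log")
  v2 <- runScaledPair(modTight, pair)$verdict
  v3 <- runScaledPair(mod, pair, by = 0.25)$verdict
  expect_true(v1@isFCD && v2@isFCD && v3@isFCD)
})

test_that("zeroing the CheB1 demethylation rate preserves adaptation and FCD", {
  # under the reference wiring CheB2-P covers both clusters, so the
  # membrane cluster still adapts with k_B1 = 0
  mod <- setActivityForm(chemotaxisModel("I"), "log")
  mod <- rsfcd:::.setModelParam(mod, "methylation.kB1", 0)
  expect_false(any(lostAdaptation(mod)))
  st <- lapply(c(100, 1000), function(L) attr(steadyState(mod, L), "a"))
  expect_lt(abs(st[[1]] - st[[2]]), 1e-6)
  expect_true(runScaledPair(mod)$verdict@isFCD)
})

test_that("unresolvable sweep paths raise a config error", {
  expect_error(robustnessSweep(chemotaxisModel("I"), "phospho.nonsense",
                               1, scaledStepPair()), "unresolvable")
  expect_error(robustnessSweep(chemotaxisModel("I"), "phospho.kDephos.Z9",
                               1, scaledStepPair()), "unresolvable")
})

test_that("mutant suite flags the structural loss of cytoplasmic adaptation", {
  mod <- setActivityForm(chemotaxisModel("I"), "log")
  pair <- scaledStepPair(1000, 200, 500, 100, stepTime = 50, horizon = 200)
  ms <- mutantFcdSuite(mod, pair, mutants = c("cheA2_del", "cheB2_del"))
  a2 <- ms[ms$mutant == "cheA2_del", ]
  expect_equal(a2$observable, "Y6p")
  expect_true(all(a2$is_fcd))
  expect_false(any(a2$adaptation_lost_cytoplasmic))
  b2 <- ms[ms$mutant == "cheB2_del", ]
  expect_true(all(b2$adaptation_lost_cytoplasmic))
  expect_false(any(b2$adaptation_lost_membrane))
  # membrane-driven channels still show (approximate) FCD
  expect_true(all(b2$is_fcd))
})

test_that("CheB2 deletion collapses the flagellar frequency but leaves a response", {
  mod <- addMutation(chemotaxisModel("I"), "cheB2_del")
  ss <- steadyState(mod, 500, allowDrift = TRUE)
  tr <- simulateTrajectory(mod, ligandProgram(c(0, 50), c(500, 100)),
                           seq(0, 200, 1), init = ss)
  f <- trajChannel(tr, "f")
  expect_lt(mean(f), 1)           # rotation near zero: saturated CheY6-P
  expect_gt(diff(range(trajChannel(tr, "Y3p"))), 0.01)  # membrane responds
})
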