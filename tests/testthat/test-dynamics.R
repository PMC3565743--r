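test_that("model I internal-ligand map attenuates by the CheY phospho load", {
  expect_equal(internalLigandModelI(100, 0, 0), 100)
  expect_equal(internalLigandModelI(100, 3.2, 13.2), 1000 / 26.4)
  # worst-case attenuation factor at the printed totals
  expect_equal(100 / internalLigandModelI(100, 3.2, 13.2), 2.64)
  expect_error(internalLigandModelI(-1, 0, 0), ">= 0")
})

test_that("model II filter is a first-order lag with the analytic step response", {
  expect_identical(internalLigandLagRHS(100, 100, 10), 0)
  expect_error(internalLigandLagRHS(1, 1, 0), "tauLt")
  # closed form of the step response via the full model II trajectory
  mod <- chemotaxisModel("II", tauLt = 10)
  ss <- steadyState(mod, 0)
  tr <- simulateTrajectory(mod, ligandProgram(c(0, 50), c(0, 100)),
                           times = seq(0, 110, 1), init = ss)
  Lt <- trajChannel(tr, "Lt")
  expect_equal(Lt[61], 100 * (1 - exp(-1)), tolerance = 1e-6)  # t = 10 s after step
  # confinement to [L_a, L_b)
  expect_true(all(Lt >= 0 & Lt < 100))
})

test_that("methylation kinetics are a negative integral-feedback loop", {
  mp <- methylationParams()
  conn <- demethConnectivity("I")
  d1 <- methylationRHS(1, 0.5, 2, 3, mp, conn)
  expect_equal(d1[["dm"]], -(mp@kB1 * 2 + mp@kB2 * 3))
  d0 <- methylationRHS(0, 0.5, 2, 3, mp, conn)
  expect_equal(d0[["dm"]], mp@kR)
  # model III wiring: CheB2-P no longer touches the membrane cluster
  d3 <- methylationRHS(1, 0.5, 2, 3, mp, demethConnectivity("III"))
  expect_equal(d3[["dm"]], -mp@kB1 * 2)
  # cytoplasmic cluster identical across wirings
  expect_equal(d1[["dmt"]], d3[["dmt"]])
})

test_that("phosphotransfer bookkeeping balances donors against acceptors", {
  pp <- phosphoParams()
  x0 <- c(A2p = 0, A34p = 0, Y3p = 0, Y4p = 0, Y6p = 0, B1p = 0, B2p = 0)
  expect_true(all(phosphoRHS(x0, 0, 0, pp) == 0))
  set.seed(11)
  for (i in 1:50) {
    x <- pp@totals[c("A2", "A34", "Y3", "Y4", "Y6", "B1", "B2")] *
      runif(7)
    names(x) <- c("A2p", "A34p", "Y3p", "Y4p", "Y6p", "B1p", "B2p")
    d <- phosphoRHS(x, runif(1), runif(1), pp)
    fl <- attr(d, "fluxes")
    # total phospho pool changes only by autophosphorylation minus
    # dephosphorylation: every transferred group is conserved
    expect_equal(sum(d), fl[["auto"]] - fl[["dephos"]], tolerance = 1e-12)
  }
  expect_error(phosphoRHS(x0 - 1, 0.5, 0.5, pp), "outside")
})

test_that("flagellar Hill output is an AND gate bounded by fMax", {
  fp <- flagellarParams()
  expect_equal(flagellarFrequency(0, 0, 0, fp), 8)
  expect_equal(flagellarFrequency(5, 5, 0, fp), 8)     # no CheY6-P
  expect_equal(flagellarFrequency(0, 0, 5, fp), 8)     # no CheY3/4-P
  # half-effect: V = q
  expect_equal(flagellarFrequency(1, 1, fp@q / 2, fp), 4)
  # strictly decreasing in each argument when the others are positive
  f <- flagellarFrequency(seq(0.1, 5, 0.1), 1, 2, fp)
  expect_true(all(diff(f) < 0))
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  for (v in c("I", "II", "III")) {
    mod <- chemotaxisModel(v)
    pc <- rsfcd:::.compileModel(mod)
    pc$L <- 150
    y0 <- steadyState(mod, 80)
    y0 <- unname(y0[rsfcd:::.stateNames(v)])
    tt <- seq(0, 50, 5)
    solC <- rsfcd:::.integrateSegment(y0, tt, pc, 1e-10, 1e-12)
    solR <- deSolve::lsoda(y0, tt, rsfcd:::.rhsDeSolve, pc,
                           rtol = 1e-10, atol = 1e-12)
    expect_equal(as.matrix(solC[, -1]), as.matrix(solR[, -1]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("steady state is a fixed point and satisfies the activity balance", {
  mod <- chemotaxisModel("I")
  ss <- steadyState(mod, 100)
  # fixed under 200 s of further integration
  tr <- simulateTrajectory(mod, ligandProgram(0, 100), seq(0, 200, 10),
                           init = ss)
  for (ch in c("m", "mt", "A2p", "Y6p", "f"))
    expect_lt(diff(range(trajChannel(tr, ch))), 1e-6)
  # algebraic identity from the methylation balance at equilibrium
  me <- mod@methylation
  aStar <- me@kR / (me@kR + me@kB1 * ss[["B1p"]] + me@kB2 * ss[["B2p"]])
  expect_equal(attr(ss, "a"), aStar, tolerance = 1e-8)
})

test_that("log-regime steady states adapt exactly across backgrounds", {
  for (v in c("I", "II", "III")) {
    mod <- setActivityForm(chemotaxisModel(v), "log")
    st <- lapply(c(50, 100, 500, 1000), function(L) steadyState(mod, L))
    a <- vapply(st, attr, numeric(1), "a")
    at <- vapply(st, attr, numeric(1), "at")
    f <- vapply(st, attr, numeric(1), "f")
    expect_lt(diff(range(a)), 1e-6)
    expect_lt(diff(range(at)), 1e-6)
    expect_lt(diff(range(f)), 1e-6)
    # adaptation holds when the demethylation wiring is swapped between
    # the reference and model III patterns, as the theory predicts
  }
  swapped <- chemotaxisModel("I")
  swapped@variant <- "III"    # model III wiring with model I-style params
  swapped <- setActivityForm(swapped, "log")
  a <- vapply(c(100, 1000), function(L) attr(steadyState(swapped, L), "a"),
              numeric(1))
  expect_lt(abs(diff(a)), 1e-6)
})

test_that("simulated trajectories respect physical bounds for random stimuli", {
  set.seed(23)
  tot <- phosphoParams()@totals
  for (i in 1:10) {
    v <- sample(c("I", "II", "III"), 1)
    mod <- chemotaxisModel(v)
    nSeg <- sample(2:4, 1)
    prog <- ligandProgram(times = c(0, sort(runif(nSeg - 1, 10, 290))),
                          levels = runif(nSeg, 0, 2000))
    tr <- simulateTrajectory(mod, prog, seq(0, 300, 2))
    for (sp in c("A2", "A34", "Y3", "Y4", "Y6", "B1", "B2")) {
      x <- trajChannel(tr, paste0(sp, "p"))
      expect_true(all(x >= -1e-9 & x <= tot[[sp]] + 1e-9))
    }
    expect_true(all(trajChannel(tr, "f") >= 0 & trajChannel(tr, "f") <= 8))
    for (ch in c("a", "at")) {
      p <- trajChannel(tr, ch)
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("the reference schedule adapts and is insensitive to solver tolerance", {
  mod <- chemotaxisModel("I")
  tt <- seq(0, 600, 1)
  tr <- simulateTrajectory(mod, ligandProgram(), tt)
  f <- trajChannel(tr, "f")
  # response returns to the pre-step level after each step
  expect_lt(abs(f[241] - f[1]), 1e-4)      # adapted before the 245 s step
  expect_lt(abs(f[601] - f[1]), 0.1)       # re-adapting after the 375 s step
  expect_gt(diff(range(f)), 1)             # but there was a real transient
  modTight <- chemotaxisModel("I", solver = list(rtol = 5e-11, atol = 5e-11))
  f2 <- trajChannel(simulateTrajectory(modTight, ligandProgram(), tt), "f")
  expect_lt(max(abs(f - f2)), 1e-4)
})

test_that("mutations rewrite the effective totals and adaptation structure", {
  mod <- chemotaxisModel("I")
  expect_equal(effectiveTotals(addMutation(mod, "cheA2_del"))[["A2"]], 0)
  expect_equal(effectiveTotals(addMutation(mod, "cheY4_5x"))[["Y4"]], 66)
  expect_error(addMutation(mod, "cheZ_del"))
  expect_false(any(lostAdaptation(mod)))
  # CheB2 is the only cytoplasmic demethylase: deleting it kills
  # cytoplasmic adaptation in every wiring
  expect_true(lostAdaptation(addMutation(mod, "cheB2_del"))[["cytoplasmic"]])
  expect_false(lostAdaptation(addMutation(mod, "cheB2_del"))[["membrane"]])
  # model III: CheB1 is the only membrane demethylase
  m3 <- chemotaxisModel("III")
  expect_true(lostAdaptation(addMutation(m3, "cheB2_del"))[["cytoplasmic"]])
  expect_error(steadyState(addMutation(mod, "cheB2_del"), 100),
               "no steady state")
})

test_that("cheA2 deletion leaves CheY6 driven by the cytoplasmic cluster only", {
  mod <- addMutation(chemotaxisModel("I"), "cheA2_del")
  ss <- steadyState(mod, 100)
  expect_equal(ss[["A2p"]], 0, tolerance = 1e-12)
  expect_equal(ss[["Y3p"]], 0, tolerance = 1e-9)
  expect_equal(ss[["Y4p"]], 0, tolerance = 1e-9)
  expect_gt(ss[["Y6p"]], 0.1)   # still phosphorylated via CheA3A4
  # flagellar AND gate is disengaged without CheY3/4-P
  expect_equal(attr(ss, "f"), 8, tolerance = 1e-6)
})
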