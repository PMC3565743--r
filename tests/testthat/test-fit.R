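test_that("RMSE has its closed forms", {
  expect_identical(rmseTrace(1:5, 1:5), 0)
  expect_equal(rmseTrace(rep(2.7, 10), rep(0, 10)), 2.7)
  expect_equal(rmseTrace(c(3, 4), c(0, 0)), 5 / sqrt(2))
  expect_error(rmseTrace(numeric(0), numeric(0)), "empty")
})

test_that("fit problems enforce bounds and carry the six free parameters", {
  tr <- data.frame(t_s = 0:10, f_hz = rep(4, 11))
  expect_error(fitProblem(tr, lower = c(methylation.kR = 2),
                          upper = c(methylation.kR = 1)), "lower < upper")
  pr <- fitProblem(tr)
  expect_named(pr@lower, c("methylation.kR", "methylation.kRt",
                           "methylation.kB1", "methylation.kB2",
                           "methylation.kB2t", "flagellar.q"))
})

test_that("annealing is deterministic with a monotone best-so-far trace", {
  tr <- generateTrace(assayConfig(seed = 12L, noiseSd = 0))
  pr <- fitProblem(tr, seed = 4L, nSA = 25L, polish = FALSE)
  f1 <- fitTrace(pr)
  f2 <- fitTrace(pr)
  expect_identical(f1@estimates, f2@estimates)
  expect_identical(f1@objectiveTrace, f2@objectiveTrace)
  expect_true(all(diff(f1@objectiveTrace) <= 0))
  expect_true(all(f1@estimates >= pr@lower & f1@estimates <= pr@upper))
})

test_that("scaling alpha with compensating rate scalings leaves the output unchanged", {
  mod <- chemotaxisModel("I", solver = list(rtol = 1e-12, atol = 1e-12))
  expect_lt(alphaScalingCheck(mod, eps = 2), 1e-8)
  expect_lt(alphaScalingCheck(mod, eps = 0.5,
                              program = ligandProgram(c(0, 100), c(50, 500)),
                              times = seq(0, 300, 1)), 1e-8)
})
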