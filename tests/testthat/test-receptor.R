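par <- receptorParams()   # N = 1, alpha = 2, m0 = 5, K_A = 3000, K_I = 18

test_that("ligand free energy has the closed-form limits and log-regime shape", {
  expect_identical(ligandFreeEnergy(0, par), 0)
  # saturation limit ln(K_A / K_I)
  expect_equal(ligandFreeEnergy(1e12, par), log(3000 / 18), tolerance = 1e-6)
  # at the geometric mean of the dissociation constants the exact form is
  # close to its log-regime approximation ln(L / K_I)
  Lg <- sqrt(18 * 3000)
  brute <- log((1 + Lg / 18) / (1 + Lg / 3000))
  expect_equal(ligandFreeEnergy(Lg, par), brute, tolerance = 1e-12)
  expect_lt(abs(ligandFreeEnergy(Lg, par) - log(Lg / 18)), 0.1)
  # strictly increasing
  L <- 10^seq(-2, 5, length.out = 200)
  expect_true(all(diff(ligandFreeEnergy(L, par)) > 0))
  expect_error(ligandFreeEnergy(-1, par), "L")
})

test_that("exact MWC activity matches a two-state partition-function oracle", {
  expect_equal(activityExact(5, 0, par), 0.5)
  set.seed(101)
  for (i in 1:1000) {
    p <- receptorParams(N = runif(1, 0.5, 20), alpha = runif(1, 0.5, 4),
                        m0 = runif(1, 0, 8), K_A = runif(1, 1000, 5000),
                        K_I = runif(1, 1, 100))
    m <- runif(1, -2, 12); L <- runif(1, 0, 5000)
    a <- activityExact(m, L, p)
    expect_equal(a, boltzmannActivityOracle(m, L, p), tolerance = 1e-12)
    # mathematically in (0, 1); extreme free-energy differences saturate
    # in double precision, so the closed bounds are asserted
    expect_true(a >= 0 && a <= 1)
  }
})

test_that("activity is monotone: decreasing in ligand, increasing in methylation", {
  L <- seq(0, 2000, length.out = 100)
  expect_true(all(diff(activityExact(5, L, par)) < 0))
  m <- seq(0, 10, length.out = 100)
  expect_true(all(diff(activityExact(m, 100, par)) > 0))
  expect_true(all(diff(activityLogRegime(m, 100, par)) > 0))
})

test_that("log-regime activity is exactly scale-equivariant", {
  set.seed(7)
  for (p in c(0.1, 2, 5, 100)) {
    m <- runif(5, 0, 10); L <- runif(5, 20, 2000)
    shift <- fcdMethylationShift(p, par@alpha)
    expect_equal(activityLogRegime(m + shift, p * L, par),
                 activityLogRegime(m, L, par), tolerance = 1e-14)
  }
  expect_equal(activityLogRegime(5, 18, par), 0.5)
  expect_error(activityLogRegime(5, 0, par), "log-regime")
})

test_that("log-regime approximation is accurate deep inside (K_I, K_A)", {
  L <- seq(180, 300, length.out = 50)   # [10 K_I, K_A / 10]
  m <- seq(0, 10, length.out = 41)
  grid <- expand.grid(m = m, L = L)
  err <- abs(activityExact(grid$m, grid$L, par) -
             activityLogRegime(grid$m, grid$L, par))
  expect_lt(max(err), 0.02)
  # pointwise 0.01 on the narrower comparison band
  expect_lt(max(abs(activityExact(5, L, par) - activityLogRegime(5, L, par))),
            0.01)
})

test_that("methylation shift has the closed form and composes additively", {
  expect_identical(fcdMethylationShift(1, 2), 0)
  expect_equal(fcdMethylationShift(5, 2), log(5) / 2)
  expect_equal(fcdMethylationShift(3, 2) + fcdMethylationShift(4, 2),
               fcdMethylationShift(12, 2))
  expect_error(fcdMethylationShift(0, 2), "p")
  expect_error(fcdMethylationShift(2, -1), "alpha")
})

test_that("receptor parameter invariants are enforced", {
  expect_error(receptorParams(K_A = 3, K_I = 18), "K_A > K_I")
  expect_error(receptorParams(N = 0), "N")
  expect_error(receptorParams(alpha = -2), "alpha")
})
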