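test_that("noise-free traces equal the simulated flagellar output", {
  cfg <- assayConfig(noiseSd = 0, seed = 3L)
  tr <- generateTrace(cfg)
  expect_equal(tr$f_hz, attr(tr, "noiseless"))
  expect_equal(nrow(tr), 601L)
  # adaptation of the noiseless trace across the two steps
  f0 <- attr(tr, "noiseless")
  expect_lt(abs(f0[241] - f0[600]), 0.1)
})

test_that("traces are reproducible and bounded in [0, 8] Hz", {
  cfg <- assayConfig(seed = 42L)
  t1 <- generateTrace(cfg)
  t2 <- generateTrace(cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$f_hz >= 0 & t1$f_hz <= 8))
  # a different seed gives a different noise draw
  t3 <- generateTrace(assayConfig(seed = 43L))
  expect_false(identical(t1$f_hz, t3$f_hz))
})

test_that("empirical noise level matches the configured standard deviation", {
  cfg <- assayConfig(seed = 5L, sampleRate = 20, noiseSd = 0.5)
  tr <- generateTrace(cfg)
  f0 <- attr(tr, "noiseless")
  interior <- f0 > 1.5 & f0 < 6.5 & tr$f_hz > 0 & tr$f_hz < 8  # unclipped
  expect_gt(sum(interior), 8e3)
  expect_equal(sd(tr$f_hz[interior] - f0[interior]), 0.5, tolerance = 0.05)
})

test_that("trace CSV I/O round-trips and validates its input", {
  cfg <- assayConfig(seed = 9L)
  tr <- generateTrace(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, path)
  back <- readTrace(path)
  expect_equal(back$t_s, tr$t_s, tolerance = 1e-12)
  expect_equal(back$f_hz, tr$f_hz, tolerance = 1e-12)

  bad1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,freq", "0,1"), bad1)
  expect_error(readTrace(bad1), "missing column")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,f_hz", "0,1", "2,1", "1,2"), bad2)
  expect_error(readTrace(bad2), "strictly increasing")

  bad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,f_hz", "0,1", "1,abc"), bad3)
  expect_error(readTrace(bad3), "non-numeric")
})
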