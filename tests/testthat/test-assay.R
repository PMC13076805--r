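test_that("initial velocity is the slope of the first interval", {
  expect_equal(initialVelocity(c(0, 1, 2), c(0, 100, 200)), 100)
  # three-minute read interval
  expect_equal(initialVelocity(c(0, 3), c(0, 300)), 100)
  expect_equal(initialVelocity(c(0, 3), c(50, 350),
                               background = c(50, 50)), 100)
  expect_equal(initialVelocity(c(0, 3, 6), c(5, 10, 310),
                               dropFirst = TRUE), 100)
  expect_error(initialVelocity(c(3, 0), c(0, 1)), "increasing")
})

test_that("noisy linear traces recover the true slope on average", {
  set.seed(211)
  v <- vapply(1:100, function(i) {
    t <- seq(0, 15, by = 3)
    initialVelocity(t, 50 * t + rnorm(length(t), 0, 5))
  }, numeric(1))
  expect_equal(mean(v), 50, tolerance = 3 * 5 * sqrt(2) / 3 / sqrt(100))
})

test_that("percent inhibition follows 100 - v_i/v_0 x 100", {
  expect_equal(as.numeric(percentInhibition(10, 10)), 0)
  expect_equal(as.numeric(percentInhibition(0, 10)), 100)
  expect_equal(as.numeric(percentInhibition(2.5, 10)), 75)
  expect_true(attr(percentInhibition(12, 10), "clipped"))
  expect_error(percentInhibition(1, 0), "positive")
})

test_that("noiseless 4PL curves are recovered exactly", {
  for (truth in list(c(ic50 = 1.35, h = 1),      # psysol 3 scale (uM)
                     c(ic50 = 42.7, h = 1.3))) { # extract scale (ug/mL)
    conc <- truth[["ic50"]] * 10^seq(-2, 2, length.out = 8)
    rem <- 100 / (1 + 10^((log10(conc) - log10(truth[["ic50"]])) *
                            truth[["h"]]))
    fit <- fit4PL(conc, rem)
    expect_true(fit$converged)
    expect_equal(fit$ic50, truth[["ic50"]], tolerance = 1e-6)
    expect_equal(fit$hill, truth[["h"]], tolerance = 1e-6)
    expect_true(fit$in_range)
  }
  expect_error(fit4PL(c(1, 2, 3), c(90, 50, 10)), "four distinct")
})

test_that("4PL recovery under 5% noise is unbiased within 10%", {
  set.seed(221)
  truth <- 1.35
  conc <- truth * 10^seq(-2, 2, length.out = 8)
  rem0 <- 100 / (1 + 10^(log10(conc) - log10(truth)))
  est <- vapply(1:100, function(i) {
    fit <- fit4PL(conc, rem0 + rnorm(length(conc), 0, 5))
    fit$ic50
  }, numeric(1))
  expect_lt(abs(stats::median(est, na.rm = TRUE) - truth) / truth, 0.10)
})

test_that("one-phase decay fits recover half-lives exactly and under noise", {
  grid <- c(0, 5, 10, 20, 40, 60, 120) / 60  # the assay's minute grid, in h
  grid <- c(grid, 4, 24)
  for (tau in c(6.7, 23.4)) {
    d <- genDecay(tau, times = grid, sigma = 0)
    fit <- fitDecay(d$time_h, d$remaining)
    expect_true(fit$converged)
    expect_equal(fit$half_life, tau, tolerance = 1e-6)
  }
  d <- genDecay(6.7, times = grid, sigma = 3, seed = 231)
  fit <- fitDecay(d$time_h, d$remaining)
  expect_lt(abs(fit$half_life - 6.7) / 6.7, 0.15)
  expect_error(fitDecay(c(0, 1, 2), c(10, 50, 90)), "increases")
})

test_that("extract ranking orders by potency with the documented sign", {
  extracts <- data.frame(extract = c("A", "B", "C", "D"),
                         ic50 = c(27.6, 42.7, 140.2, 208.4),
                         peptide_count = c(40, 30, 20, 10))
  r <- rankExtracts(extracts)
  expect_equal(r$table$extract, c("A", "B", "C", "D"))
  expect_equal(r$rho, -1)  # more peptides <-> lower IC50
  set.seed(241)
  rhos <- vapply(1:500, function(i) {
    e <- data.frame(extract = letters[1:8], ic50 = runif(8, 10, 200),
                    peptide_count = sample(5:50, 8))
    rankExtracts(e)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("plate-format assay data round-trips through the pipeline fit", {
  a <- genAssay(ic50 = 1.35, hill = 1,
                concentrations = 10^seq(-2, 2, length.out = 8) * 1.35,
                rfuSigma = 0, seed = 251)
  rep <- runPipeline(list(assay = a))
  expect_true(rep$ic50$converged)
  expect_equal(rep$ic50$ic50, 1.35, tolerance = 1e-6)
})
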