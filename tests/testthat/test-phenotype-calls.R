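# LPI computation, BH FDR, dual-criterion phenotype calls.

test_that("slow growers are excluded by the background cutoff", {
  expect_identical(excludeSlowGrowers(c(a = 0.1, b = 2.0), cutoff = 1.5), "b")
  expect_length(excludeSlowGrowers(c(a = 0.1, b = 2.0), cutoff = Inf), 0)
  # simulator oracle: planting 6.7% slow growers reproduces the fraction
  strains <- sprintf("g%04d", 1:1000)
  slow <- strains[1:67]
  ph <- simulatePhenotypes(strains, noiseSd = 0.05, seed = 8,
                           effects = data.frame(strain_id = slow,
                                                condition = "background",
                                                effect = 2.5))
  res <- scoreScreen(ph)
  expect_equal(sort(res$excluded), sort(slow))
  expect_equal(length(res$excluded) / length(strains), 0.067)
})

test_that("LPI arithmetic follows from condition means", {
  lpi <- computeLPI(c(2.0, 2.2, 2.4), c(0.1, 0.0, -0.1))
  expect_equal(lpi$mean, 2.2)
  expect_equal(lpi$replicates, c(2.0, 2.2, 2.4))
  expect_equal(computeLPI(c(1, 2), c(1, 2))$mean, 0)
  # antisymmetry of the mean under swapping the two media
  a <- c(1.1, 0.9, 1.0); b <- c(0.2, 0.1, 0.0)
  expect_equal(computeLPI(a, b)$mean, -computeLPI(b, a)$mean)
  expect_error(computeLPI(c(1), c(0, 0)), "missing data")
})

test_that("BH q-values match the direct step-up definition", {
  res <- bhFDR(0.005, alpha = 0.01)
  expect_equal(res$q, 0.005)
  expect_true(res$rejected)
  res <- bhFDR(c(0.001, 0.008, 0.039, 0.041), alpha = 0.05)
  expect_equal(res$q, c(0.004, 0.016, 0.041, 0.041))
  expect_true(all(res$rejected))
  expect_false(any(bhFDR(rep(1, 5), alpha = 0.05)$rejected))
  expect_error(bhFDR(c(0.1, 1.2)), "invalid input")
  # exhaustive small cases against the definition-level oracle
  set.seed(99)
  for (n in 1:8) {
    for (rep in 1:25) {
      p <- round(runif(n), 3)
      expect_equal(bhFDR(p)$q, bhOracle(p), tolerance = 1e-12)
    }
  }
  # q monotone non-decreasing in p order
  p <- runif(50)
  q <- bhFDR(p)$q
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("calls apply the dual criterion with a t-test oracle", {
  cfg <- callConfig()  # alpha 0.01, threshold 2.5
  # single record: t and p from the t distribution directly
  lpi <- data.frame(strain_id = "m1", condition = "metal",
                    lpi = c(2.8, 3.0, 3.2))
  out <- callPhenotypes(lpi, cfg)
  tOracle <- mean(lpi$lpi) / (sd(lpi$lpi) / sqrt(3))
  expect_equal(out$t_stat, tOracle)
  expect_equal(out$p_value, 2 * pt(-abs(tOracle), df = 2))
  expect_lt(out$p_value, 0.01)
  expect_equal(out$call, "sensitive")
  # all-zero replicates: no call
  out0 <- callPhenotypes(data.frame(strain_id = "m0", condition = "metal",
                                    lpi = c(0, 0, 0)), cfg)
  expect_equal(out0$call, "none")
  # significant but weak effect fails the strong-effect gate
  outW <- callPhenotypes(data.frame(strain_id = "mw", condition = "metal",
                                    lpi = c(2.0, 2.0, 2.0)), cfg)
  expect_equal(outW$p_value, 0)  # zero-variance, nonzero-mean convention
  expect_equal(outW$call, "none")
  # symmetric resistance
  outR <- callPhenotypes(data.frame(strain_id = "mr", condition = "metal",
                                    lpi = c(-2.8, -3.0, -3.2)), cfg)
  expect_equal(outR$call, "resistant")
  expect_equal(callPhenotypes(data.frame(strain_id = "mr", condition = "metal",
                                         lpi = c(-2.8, -3.0, -3.2)),
                              callConfig(symmetricResistance = FALSE))$call,
               "none")
})

test_that("excluded strains receive no call and calls ignore strain order", {
  lpi <- data.frame(
    strain_id = rep(c("a", "b", "c"), each = 3),
    condition = "metal",
    lpi = c(3.1, 2.9, 3.0, 0.1, -0.2, 0.05, 3.3, 3.2, 2.9))
  out <- callPhenotypes(lpi, callConfig(), excluded = "c")
  expect_equal(out$call[out$strain_id == "c"], "excluded")
  expect_equal(out$call[out$strain_id == "a"], "sensitive")
  shuffled <- lpi[sample(nrow(lpi)), ]
  out2 <- callPhenotypes(shuffled, callConfig(), excluded = "c")
  expect_equal(out2[order(out2$strain_id), ], out[order(out$strain_id), ])
})

test_that("null screens stay quiet and planted effects are recovered", {
  strains <- sprintf("n%04d", 1:500)
  falseFrac <- vapply(1:5, function(seed) {
    ph <- simulatePhenotypes(strains, noiseSd = 0.05, seed = seed)
    calls <- scoreScreen(ph)$calls
    mean(calls$call %in% c("sensitive", "resistant"))
  }, numeric(1))
  expect_lt(mean(falseFrac), 0.001)
  planted <- strains[1:20]
  power <- vapply(1:5, function(seed) {
    ph <- simulatePhenotypes(strains, noiseSd = 0.05, seed = 100 + seed,
                             effects = data.frame(strain_id = planted,
                                                  condition = "stressor",
                                                  effect = 3))
    calls <- scoreScreen(ph)$calls
    mean(calls$call[calls$strain_id %in% planted] == "sensitive")
  }, numeric(1))
  expect_gte(mean(power), 0.95)
})
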