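# Synthetic screen generator: logistic growth, layout geometry, ground truth.

test_that("logistic growth matches the closed form and its boundary cases", {
  # identity at t = 0 and constancy at r = 0
  expect_equal(logisticCurve(123, 1e6, 0.5, 0), 123)
  expect_equal(logisticCurve(1e4, 1e7, 0, c(0, 5, 50)), rep(1e4, 3))
  # direct formula evaluation at N0 = 1e4, K = 1e7, r = ln2/2, t = 10
  r <- log(2) / 2
  direct <- 1e7 * 1e4 * exp(r * 10) / (1e7 + 1e4 * (exp(r * 10) - 1))
  expect_equal(logisticCurve(1e4, 1e7, r, 10), direct)
  # monotone non-decreasing, bounded by K
  t <- seq(0, 72, by = 1 / 3)
  n <- logisticCurve(1e5, 1e7, log(2) / 2.5, t)
  expect_true(all(diff(n) >= 0))
  expect_true(all(n <= 1e7))
  expect_error(logisticCurve(-1, 1e7, 0.2, 1), "invalid parameter")
  expect_error(logisticCurve(1e4, 0, 0.2, 1), "invalid parameter")
})

test_that("layouts interleave controls at every fourth position", {
  lay <- makeLayout(screenConfig(), sprintf("y%04d", 1:1152))
  ctrl <- layoutControls(lay)
  expect_equal(sum(ctrl), 384)
  expect_equal(sum(!is.na(layoutStrains(lay)) & !ctrl), 1152)
  # all controls share the parity of the configured offset
  pos <- which(ctrl, arr.ind = TRUE) - 1L
  expect_true(all(pos[, 1] %% 2 == 0))
  expect_true(all(pos[, 2] %% 2 == 0))
  # a different parity offset moves the whole sub-grid
  lay2 <- makeLayout(screenConfig(controlOffset = c(1L, 0L)),
                     sprintf("y%04d", 1:1152))
  pos2 <- which(layoutControls(lay2), arr.ind = TRUE) - 1L
  expect_true(all(pos2[, 1] %% 2 == 1))
})

test_that("tiny layouts fill row-major and reject overflow", {
  cfg <- screenConfig(rows = 2, cols = 2)
  lay <- makeLayout(cfg, c("a", "b", "c"))
  expect_equal(sum(layoutControls(lay)), 1)
  df <- as.data.frame(lay)
  exp <- df[!df$is_control, ]
  # row-major: (0,1), (1,0), (1,1)
  expect_equal(exp$strain_id[order(exp$row, exp$col)], c("a", "b", "c"))
  expect_error(makeLayout(cfg, letters[1:4]), "capacity")
})

test_that("identical seeds reproduce the screen bit-for-bit; seeds differ", {
  cfg <- smallConfig()
  s1 <- simulateScreen(cfg, smallStrains)
  s2 <- simulateScreen(cfg, smallStrains)
  expect_identical(curveValues(screenCurves(s1)), curveValues(screenCurves(s2)))
  expect_identical(screenTruth(s1), screenTruth(s2))
  s3 <- simulateScreen(smallConfig(seed = 12), smallStrains)
  expect_false(identical(curveValues(screenCurves(s1)),
                         curveValues(screenCurves(s3))))
})

test_that("with zero noise and bias, estimated D equals baselineD * 2^effect", {
  cfg <- smallConfig(noiseSd = 0, biasAmplitude = 0, corruptionRate = 0,
                     effects = data.frame(strain_id = "s005",
                                          condition = "stressor", effect = 1))
  sim <- simulateScreen(cfg, smallStrains)
  est <- estimateDoublingTimes(qcCurves(screenCurves(sim)))
  lay <- do.call(rbind, lapply(screenLayouts(sim), as.data.frame))
  est <- merge(est, lay, by = c("plate_id", "row", "col"))
  tru <- screenTruth(sim)$effects
  eff <- rep(0, nrow(est))
  expi <- !est$is_control
  eff[expi] <- tru[cbind(est$strain_id[expi], est$condition[expi])]
  # logistic curvature inside the fit window keeps this to ~2%
  expect_true(all(abs(est$D_hours / (cfg@baselineD * 2^eff) - 1) < 0.03))
})

test_that("a null screen yields zero LPI everywhere", {
  cfg <- smallConfig(noiseSd = 0, corruptionRate = 0)
  sim <- simulateScreen(cfg, smallStrains)
  res <- analyzeScreen(screenCurves(sim), screenLayouts(sim), verbose = FALSE)
  expect_true(all(abs(res$calls$lpi_mean) < 0.05))
  expect_true(all(res$calls$call == "none"))
})

test_that("bias is additive and identical across plates of a screen", {
  cfg <- smallConfig(noiseSd = 0, corruptionRate = 0)
  sim <- simulateScreen(cfg, smallStrains)
  bias <- screenTruth(sim)$bias
  expect_equal(dim(bias), c(cfg@rows, cfg@cols))
  est <- estimateDoublingTimes(qcCurves(screenCurves(sim)))
  # same position on different plates: identical log2D (controls everywhere)
  byPlate <- split(est$log2D, est$plate_id)
  for (p in byPlate[-1]) expect_equal(p, byPlate[[1]], tolerance = 1e-10)
})

test_that("corruption flags approximately the configured fraction of curves", {
  # one larger plate so the binomial count is informative
  cfg <- screenConfig(rows = 32, cols = 48, duration = 12, nReplicates = 2,
                      corruptionRate = 0.003, seed = 5)
  sim <- simulateScreen(cfg, sprintf("z%04d", 1:1152))
  n <- nrow(screenCurves(sim))
  k <- nrow(screenTruth(sim)$corrupted)
  expect_gt(n, 6000)
  # within 4 sd of Binomial(n, 0.003)
  expect_lt(abs(k - n * 0.003), 4 * sqrt(n * 0.003 * 0.997))
  # and the corrupted curves are exactly the QC rejections
  qc <- qcCurves(screenCurves(sim))
  info <- colonyInfo(qc)
  rejected <- info[!info$qc_pass, c("plate_id", "row", "col")]
  corr <- screenTruth(sim)$corrupted
  keyR <- sort(paste(rejected$plate_id, rejected$row, rejected$col))
  keyC <- sort(paste(corr$plate_id, corr$row, corr$col))
  expect_equal(keyR, keyC)
})

test_that("a planted +3 effect propagates through the full pipeline, mean over seeds", {
  lpis <- vapply(1:20, function(seed) {
    cfg <- smallConfig(seed = seed, noiseSd = 0.05,
                       effects = data.frame(strain_id = "s010",
                                            condition = "stressor", effect = 3))
    sim <- simulateScreen(cfg, smallStrains)
    res <- analyzeScreen(screenCurves(sim), screenLayouts(sim), verbose = FALSE)
    res$calls$lpi_mean[res$calls$strain_id == "s010"]
  }, numeric(1))
  expect_lt(abs(mean(lpis) - 3), 0.2)
})

test_that("direct phenotype simulation reproduces requested effects and structure", {
  ph <- simulatePhenotypes(sprintf("p%02d", 1:40), noiseSd = 0.01, seed = 2,
                           effects = data.frame(strain_id = "p03",
                                                condition = "stressor",
                                                effect = 2))
  expect_equal(nrow(ph), 40 * 2 * 3)
  m <- with(ph[ph$condition == "stressor", ], tapply(log2D_norm, strain_id, mean))
  expect_lt(abs(m[["p03"]] - 2), 0.05)
  expect_lt(max(abs(m[names(m) != "p03"])), 0.05)
  # reproducible
  expect_identical(ph, simulatePhenotypes(sprintf("p%02d", 1:40), noiseSd = 0.01,
                                          seed = 2,
                                          effects = data.frame(strain_id = "p03",
                                                               condition = "stressor",
                                                               effect = 2)))
})
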