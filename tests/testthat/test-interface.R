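# File I/O and the end-to-end pipeline contract.

test_that("curves and layouts round-trip through TSV", {
  sim <- simulateScreen(smallConfig(nReplicates = 1), smallStrains)
  dir <- withr::local_tempdir()
  cf <- file.path(dir, "curves.tsv")
  lf <- file.path(dir, "layouts.tsv")
  writeCurves(screenCurves(sim), cf)
  writeLayouts(screenLayouts(sim), lf)
  back <- readCurves(cf)
  expect_equal(curveTimes(back), curveTimes(screenCurves(sim)))
  expect_equal(curveValues(back), curveValues(screenCurves(sim)),
               tolerance = 1e-12)
  expect_equal(colonyInfo(back)[c("plate_id", "row", "col")],
               colonyInfo(screenCurves(sim))[c("plate_id", "row", "col")])
  lays <- readLayouts(lf)
  expect_equal(names(lays), names(screenLayouts(sim)))
  expect_equal(layoutStrains(lays[[1]]),
               layoutStrains(screenLayouts(sim)[[1]]))
  expect_equal(layoutControls(lays[[1]]),
               layoutControls(screenLayouts(sim)[[1]]))
})

test_that("malformed curve files fail with informative errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("plate_id\trow\tcol\tvalue", "p\t0\t0\t1"), bad)
  expect_error(readCurves(bad), "missing column.*time_h")
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("plate_id\trow\tcol\ttime_h\tvalue",
               "p\t0\t0\t0\t1", "p\t0\t0\t0\t2"), dup)
  expect_error(readCurves(dup), "duplicate")
  nonnum <- file.path(dir, "nonnum.tsv")
  writeLines(c("plate_id\trow\tcol\ttime_h\tvalue",
               "p\t0\t0\t0\t1", "p\t0\t0\t0.33\toops"), nonnum)
  expect_error(readCurves(nonnum), "parse error.*value")
})

test_that("simulation truth round-trips through JSON", {
  sim <- simulateScreen(smallConfig(corruptionRate = 0.05), smallStrains)
  path <- withr::local_tempfile(fileext = ".json")
  writeTruth(screenTruth(sim), path)
  tru <- readTruth(path)
  expect_equal(tru$seed, screenTruth(sim)$seed)
  expect_equal(tru$bias, screenTruth(sim)$bias, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(nrow(tru$corrupted), nrow(screenTruth(sim)$corrupted))
})

test_that("the pipeline recovers planted hits with no extra calls", {
  planted <- smallStrains[seq(3, 60, 2)][1:15]
  cfg <- smallConfig(noiseSd = 0.05, seed = 21,
                     effects = data.frame(strain_id = planted,
                                          condition = "stressor", effect = 3))
  sim <- simulateScreen(cfg, smallStrains)
  dir <- withr::local_tempdir()
  writeCurves(screenCurves(sim), file.path(dir, "curves.tsv"))
  writeLayouts(screenLayouts(sim), file.path(dir, "layouts.tsv"))
  res <- runPipeline(file.path(dir, "curves.tsv"), file.path(dir, "layouts.tsv"),
                     file.path(dir, "out"), verbose = FALSE)
  calls <- res$calls
  hits <- calls$strain_id[calls$call == "sensitive"]
  expect_gte(length(intersect(hits, planted)), 14)
  expect_length(setdiff(hits, planted), 0)
  # stage outputs exist, are self-describing and re-readable
  est <- readTSV(file.path(dir, "out", "doubling_times.tsv"))
  expect_true(all(c("plate_id", "row", "col", "D_hours", "log2D") %in% names(est)))
  hitFile <- readGeneSet(file.path(dir, "out", "hits_stressor.txt"))
  expect_equal(sort(geneSetMembers(hitFile)), sort(toupper(hits)))
})

test_that("a null screen produces an empty hit list", {
  sim <- simulateScreen(smallConfig(seed = 33), smallStrains)
  res <- analyzeScreen(screenCurves(sim), screenLayouts(sim), verbose = FALSE)
  expect_false(any(res$calls$call %in% c("sensitive", "resistant")))
})

test_that("rerunning the pipeline is byte-identical", {
  sim <- simulateScreen(smallConfig(seed = 5), smallStrains)
  dir <- withr::local_tempdir()
  writeCurves(screenCurves(sim), file.path(dir, "curves.tsv"))
  writeLayouts(screenLayouts(sim), file.path(dir, "layouts.tsv"))
  for (run in c("out1", "out2"))
    runPipeline(file.path(dir, "curves.tsv"), file.path(dir, "layouts.tsv"),
                file.path(dir, run), verbose = FALSE)
  for (f in c("doubling_times.tsv", "normalized.tsv", "calls.tsv",
              "hits_stressor.txt")) {
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)))
  }
})
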