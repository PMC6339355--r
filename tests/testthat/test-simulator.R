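simContext <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      space <- lycopeneSpace()
      des <- selectDOptimal(space, modelSpec(space), nRuns = 88, seed = 17)
      cache <<- list(space = space, runs = labelledRuns(space, des),
                     truth = defaultGroundTruth(space))
    }
    cache
  }
})

test_that("the same seed reproduces the simulated table bitwise", {
  ctx <- simContext()
  a <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 3, seed = 42)
  b <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 3, seed = 42)
  expect_identical(a, b)
  c <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 3, seed = 43)
  expect_false(identical(a, c))
})

test_that("with no noise and no failures titres equal the linear predictor", {
  ctx <- simContext()
  truth <- noiselessTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 2, seed = 1)
  mu <- operonDesign:::truthPredictor(ctx$space, ctx$runs, truth)$mu
  expect_equal(tt$titre_mg_per_gdcw, rep(mu, each = 2), tolerance = 1e-12)
  expect_true(all(tt$detected))
  expect_true(all(tt$dcw_g > 0))
})

test_that("the end-to-end round trip recovers the truth coefficients exactly", {
  ctx <- simContext()
  truth <- noiselessTruth(ctx$space, betaProm = -0.55, betaRbs = c(0.1, 0, -0.35))
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 2)
  fit <- fitEffects(ctx$runs, tt, ctx$space, modelSpec(ctx$space))
  co <- coef(fit)
  expect_equal(unname(co["(Intercept)"]), truth@beta0, tolerance = 1e-9)
  expect_equal(unname(co["promoter"]), truth@betaProm, tolerance = 1e-9)
  expect_equal(unname(co["rbs_pos3"]), truth@betaRbs[3], tolerance = 1e-9)
  lv <- designFactors(ctx$space)[["gene_order"]]@levels
  for (j in 1:5) {
    expect_equal(unname(co[paste0("gene_order[", lv[j], "]")]),
                 unname(truth@gammaOrder[lv[j]]), tolerance = 1e-9)
  }
})

test_that("failure rate is non-decreasing in promoter rank", {
  ctx <- simContext()
  ## simulate on a balanced slice of the full factorial covering all 5 ranks
  configs <- enumerateConfigurations(ctx$space)
  slice <- configs[configs$rbs_pos1 == "rbsL" & configs$rbs_pos2 == "rbsL" &
                     configs$rbs_pos3 == "rbsL", ]
  slice$stitch_id <- sprintf("C%03d", seq_len(nrow(slice)))
  rates <- matrix(NA_real_, 40, 5)
  for (s in 1:40) {
    tt <- simulateTitres(ctx$space, slice, ctx$truth, replicates = 1,
                         seed = 500 + s)
    failedByCon <- !tapply(tt$dcw_g > 0, tt$stitch_id, any)
    byProm <- tapply(failedByCon[slice$stitch_id], slice$promoter, mean)
    lv <- designFactors(ctx$space)[["promoter"]]@levels
    rates[s, ] <- byProm[lv]
  }
  mean_rates <- colMeans(rates)
  expect_true(all(diff(mean_rates) > -0.05))   # monotone up to noise
  expect_gt(mean_rates[5], mean_rates[1])
})

test_that("failed constructs appear as no-growth rows matching the titre schema", {
  ctx <- simContext()
  tt <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 3, seed = 7)
  expect_identical(names(tt), c("stitch_id", "replicate", "dcw_g",
                                "titre_mg_per_gdcw", "detected"))
  failedRows <- tt[tt$dcw_g == 0, ]
  expect_true(all(is.na(failedRows$titre_mg_per_gdcw)))
  expect_true(all(!failedRows$detected))
  expect_identical(nrow(tt), 88L * 3L)
})

test_that("detected titres stay within the calibrated envelope", {
  ctx <- simContext()
  det <- unlist(lapply(1:25, function(s) {
    tt <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 3,
                         seed = 2000 + s)
    tt$titre_mg_per_gdcw[tt$detected]
  }))
  expect_gte(min(det), 0.05)   # the detection floor
  expect_gt(mean(det >= 0.05 & det <= 4.6), 0.99)
})

test_that("simulated raw measurements round-trip through quantification", {
  ctx <- simContext()
  std <- lycopeneStandards()
  curve <- fitStandardCurve(std$concentration_mg_per_ml, std$peak_area)
  meas <- simulateMeasurements(ctx$space, ctx$runs, ctx$truth, curve,
                               replicates = 2, seed = 11)
  direct <- simulateTitres(ctx$space, ctx$runs, ctx$truth, replicates = 2,
                           seed = 11)
  rec <- suppressWarnings(peakAreaToTitre(meas, curve))
  grown <- direct$dcw_g > 0
  expect_equal(rec$titre_mg_per_gdcw[grown],
               direct$titre_mg_per_gdcw[grown], tolerance = 1e-6)
  expect_equal(rec$dcw_g, direct$dcw_g, tolerance = 1e-12)
})

test_that("ground-truth validity is enforced", {
  ctx <- simContext()
  lv <- designFactors(ctx$space)[["gene_order"]]@levels
  badGamma <- setNames(rep(0.1, 6), lv)   # does not sum to zero
  expect_error(groundTruth(ctx$space, 1, 0, c(0, 0, 0), badGamma,
                           sigma = 0.1, alpha0 = 0, alpha1 = 0, lod = 0))
  expect_error(groundTruth(ctx$space, 1, 0, c(0, 0), setNames(numeric(6), lv),
                           sigma = 0.1, alpha0 = 0, alpha1 = 0, lod = 0),
               class = "configurationError")
})
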