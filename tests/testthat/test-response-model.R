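## Shared fixture: 88-run design on the demo space with labelled runs.
fittedContext <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      space <- lycopeneSpace()
      des <- selectDOptimal(space, modelSpec(space), nRuns = 88, seed = 17)
      cache <<- list(space = space, model = modelSpec(space),
                     runs = labelledRuns(space, des))
    }
    cache
  }
})

test_that("a noiseless linear truth is recovered to machine tolerance", {
  ctx <- fittedContext()
  truth <- noiselessTruth(ctx$space, betaProm = -0.5, betaRbs = c(0, 0, 0),
                          gamma = rep(0, 6))
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 1, seed = 1)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  expect_equal(unname(coef(fit)["(Intercept)"]), 2, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["promoter"]), -0.5, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["rbs_pos1"]), 0, tolerance = 1e-10)
})

test_that("41 producers under a p = 10 model leave 31 residual df", {
  ctx <- fittedContext()
  truth <- noiselessTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 2)
  ## fail 47 constructs spread across the design, keep 41 producers
  failed <- ctx$runs$stitch_id[c(seq(2, 88, by = 2), 1, 3, 5)]
  tt$detected[tt$stitch_id %in% failed] <- FALSE
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  expect_identical(fit@nObs, 41L)
  expect_identical(fit@residualDf, 31L)
})

test_that("observations spanning one promoter level alias the promoter term", {
  ctx <- fittedContext()
  truth <- noiselessTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 1, seed = 3)
  oneProm <- ctx$runs$stitch_id[ctx$runs$promoter == ctx$runs$promoter[1]]
  tt$detected[!tt$stitch_id %in% oneProm] <- FALSE
  expect_error(fitEffects(ctx$runs, tt, ctx$space, ctx$model),
               "promoter", class = "aliasingError")
})

test_that("too few producing observations is an infeasible fit", {
  ctx <- fittedContext()
  truth <- noiselessTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 1, seed = 4)
  tt$detected[-(1:5)] <- FALSE
  expect_error(fitEffects(ctx$runs, tt, ctx$space, ctx$model),
               class = "infeasibleFitError")
})

test_that("LogWorth is -log10(p), strictly decreasing, 2 at p = 0.01", {
  expect_identical(logWorth(0.01), 2)
  expect_identical(logWorth(1), 0)
  p <- sort(runif(50, 1e-10, 1))
  expect_true(all(diff(logWorth(p)) < 0 | diff(p) == 0))
  expect_identical(logWorth(1e-321), 320)  # capped under p underflow
  expect_error(logWorth(0))
})

test_that("the effect summary flags p = 0.01 at the significance boundary", {
  ctx <- fittedContext()
  truth <- groundTruth(ctx$space, beta0 = 2, betaProm = -0.5,
                       betaRbs = c(0.1, 0, -0.3),
                       gammaOrder = setNames(c(-0.5, 0.9, -0.6, 0.6, -0.7, 0.3),
                                             designFactors(ctx$space)[["gene_order"]]@levels),
                       sigma = 0.25, alpha0 = -50, alpha1 = 0, lod = 0)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 5)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  eff <- effectSummary(fit)
  expect_identical(names(eff),
                   c("factor", "df", "F", "p_value", "log_worth", "significant"))
  expect_true(all(diff(eff$log_worth) <= 0))      # sorted descending
  expect_identical(eff$significant, eff$log_worth > 2)
  expect_equal(eff$log_worth, -log10(eff$p_value), tolerance = 1e-12)
  ## boundary semantics: LogWorth exactly 2 is not "exceeds 2"
  expect_false(logWorth(0.01) > 2)
})

test_that("refitting data generated from a fit's own coefficients is idempotent", {
  ctx <- fittedContext()
  truth <- defaultGroundTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 6)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  ## regenerate noise-free from the fitted coefficients
  X <- encodeModelMatrix(ctx$space, ctx$runs, ctx$model)
  clean <- data.frame(stitch_id = ctx$runs$stitch_id, replicate = 1L,
                      dcw_g = 7e-4,
                      titre_mg_per_gdcw = as.numeric(X %*% coef(fit)),
                      detected = TRUE, stringsAsFactors = FALSE)
  refit <- fitEffects(ctx$runs, clean, ctx$space, ctx$model)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-9)
})

test_that("predicted optima agree with brute-force evaluation over all candidates", {
  ctx <- fittedContext()
  truth <- defaultGroundTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 7)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  preds <- predictOptimum(fit, ctx$space, topK = 3)
  configs <- enumerateConfigurations(ctx$space)
  Xall <- encodeModelMatrix(ctx$space, configs, ctx$model)
  brute <- as.numeric(Xall %*% coef(fit))
  expect_equal(max(brute), preds$predicted_titre[1], tolerance = 1e-12)
  bruteTop <- configs$config_index[order(brute, decreasing = TRUE)][1]
  expect_identical(preds$config_index[1], bruteTop)
  expect_true(all(diff(preds$rank) >= 0))
})

test_that("negative promoter and rbs3 effects put the weakest parts on top", {
  ctx <- fittedContext()
  truth <- defaultGroundTruth(ctx$space)  # betaProm, betaRbs3 < 0
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 8)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  top <- predictOptimum(fit, ctx$space, topK = 1)[1, ]
  facs <- designFactors(ctx$space)
  expect_identical(top$promoter, facs[["promoter"]]@levels[1])   # rank 1
  expect_identical(top$rbs_pos3, facs[["rbs_pos3"]]@levels[1])   # rank 1
})

test_that("order-symmetric truth produces tied co-optimal gene orders", {
  ctx <- fittedContext()
  lv <- designFactors(ctx$space)[["gene_order"]]@levels
  gamma <- setNames(numeric(6), lv)
  gamma[c("E-I-B", "B-I-E")] <- 0.8          # reversal-symmetric optimum
  gamma[c("E-B-I", "I-B-E")] <- -0.3
  gamma[c("B-E-I", "I-E-B")] <- -0.5
  truth <- noiselessTruth(ctx$space, betaProm = -0.4, betaRbs = c(0.2, 0.1, -0.3),
                          gamma = gamma)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 1, seed = 9)
  fit <- fitEffects(ctx$runs, tt, ctx$space, ctx$model)
  top <- predictOptimum(fit, ctx$space, topK = 1)
  expect_identical(nrow(top), 2L)
  expect_setequal(top$gene_order, c("E-I-B", "B-I-E"))
  expect_identical(unique(top$rank), 1L)
})

test_that("an intercept-only model predicts the same titre everywhere", {
  ctx <- fittedContext()
  m0 <- methods::new("ModelSpec", factorNames = character(),
                     interactions = list(), p = 1L)
  tt <- data.frame(stitch_id = ctx$runs$stitch_id, replicate = 1L,
                   dcw_g = 7e-4, titre_mg_per_gdcw = 1.4, detected = TRUE,
                   stringsAsFactors = FALSE)
  fit <- fitEffects(ctx$runs, tt, ctx$space, m0)
  preds <- predictOptimum(fit, ctx$space, topK = 1)
  expect_identical(nrow(preds), 810L)
  expect_identical(unique(preds$rank), 1L)
  expect_equal(unique(preds$predicted_titre), 1.4, tolerance = 1e-12)
})

test_that("the failure trend fit recovers a positive promoter slope", {
  ctx <- fittedContext()
  truth <- defaultGroundTruth(ctx$space)
  tt <- simulateTitres(ctx$space, ctx$runs, truth, replicates = 3, seed = 10)
  glmFit <- fitFailureModel(ctx$runs, tt, ctx$space)
  expect_gt(coef(glmFit)[["x_prom"]], 0)
})
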