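test_that("discrete-numeric ranks are coded linearly onto [-1, 1]", {
  space <- lycopeneSpace()
  configs <- enumerateConfigurations(space)
  X <- encodeModelMatrix(space, configs, modelSpec(space))
  expect_setequal(unique(X[, "promoter"]), c(-1, -0.5, 0, 0.5, 1))
  expect_setequal(unique(X[, "rbs_pos1"]), c(-1, 0, 1))
})

test_that("the main-effects model for the lycopene space has p = 10 columns", {
  space <- lycopeneSpace()
  m <- modelSpec(space)
  expect_identical(m@p, 10L)  # intercept + 4 numeric + (6-1) effects columns
  X <- encodeModelMatrix(space, enumerateConfigurations(space), m)
  expect_identical(ncol(X), 10L)
})

test_that("effects-coded categorical columns sum to zero over the balanced factorial", {
  space <- lycopeneSpace()
  X <- encodeModelMatrix(space, enumerateConfigurations(space), modelSpec(space))
  ordCols <- grep("^gene_order", colnames(X))
  expect_identical(length(ordCols), 5L)
  expect_true(all(abs(colSums(X[, ordCols])) < 1e-9))
  ## last level coded -1 in every column of its block
  lvl <- designFactors(space)[["gene_order"]]@levels
  lastRows <- enumerateConfigurations(space)$gene_order == lvl[6]
  expect_true(all(X[lastRows, ordCols] == -1))
})

test_that("single-level factors cannot enter the model", {
  lib <- tinyLibrary(nGenes = 1)
  space <- buildDesignSpace(lib)
  ## default model drops the single-level gene_order silently
  expect_false("gene_order" %in% modelSpec(space)@factorNames)
  badModel <- methods::new("ModelSpec", factorNames = c("promoter", "gene_order"),
                           interactions = list(), p = 3L)
  expect_error(encodeModelMatrix(space, enumerateConfigurations(space), badModel),
               "gene_order", class = "degenerateTermError")
})

test_that("a 2x2 factorial at n = 4 recovers the full factorial with det 64", {
  lib <- tinyLibrary(nProm = 2, nRbs = 2, nGenes = 1)
  space <- buildDesignSpace(lib)
  m <- modelSpec(space)
  expect_identical(m@p, 3L)
  des <- selectDOptimal(space, m, nRuns = 4, seed = 1, nStarts = 5)
  expect_identical(runIndices(des), 0:3)
  expect_equal(exp(logDet(des)), 64, tolerance = 1e-10)
  expect_equal(dEfficiency(des), 100, tolerance = 1e-10)
})

test_that("infeasible run counts are rejected", {
  space <- lycopeneSpace()
  expect_error(selectDOptimal(space, modelSpec(space), nRuns = 2, seed = 1),
               "p", class = "infeasibleDesignError")
})

test_that("D-efficiency is 100 for an orthogonal two-level design and errors when singular", {
  X <- cbind(1, c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_equal(dEfficiency(X), 100, tolerance = 1e-12)
  Xsing <- cbind(X, X[, 2])  # duplicated column
  expect_error(dEfficiency(Xsing), class = "singularDesignError")
})

test_that("D-efficiency of any valid design lies in (0, 100]", {
  space <- lycopeneSpace()
  configs <- enumerateConfigurations(space)
  X <- encodeModelMatrix(space, configs, modelSpec(space))
  set.seed(7)
  for (rep in 1:25) {
    idx <- sample.int(nrow(X), 40)
    eff <- tryCatch(dEfficiency(X[idx, ]), singularDesignError = function(e) NA)
    if (!is.na(eff)) {
      expect_gt(eff, 0)
      expect_lte(eff, 100 + 1e-9)
    }
  }
})

test_that("coordinate exchange attains the exhaustive-subset optimum on small candidate sets", {
  ## 2 promoters x 3 rbs levels: 6 candidates, p = 3, n = 4
  libA <- tinyLibrary(nProm = 2, nRbs = 3, nGenes = 1)
  spA <- buildDesignSpace(libA)
  mA <- modelSpec(spA)
  CA <- encodeModelMatrix(spA, enumerateConfigurations(spA), mA)
  oracleA <- exhaustiveDOptimal(CA, 4)
  desA <- selectDOptimal(spA, mA, nRuns = 4, seed = 11, nStarts = 20)
  expect_equal(logDet(desA), oracleA$logDet, tolerance = 1e-8)

  ## 4 promoters x 3 rbs levels: 12 candidates, p = 3, n = 6
  libB <- tinyLibrary(nProm = 4, nRbs = 3, nGenes = 1)
  spB <- buildDesignSpace(libB)
  mB <- modelSpec(spB)
  CB <- encodeModelMatrix(spB, enumerateConfigurations(spB), mB)
  oracleB <- exhaustiveDOptimal(CB, 6)
  desB <- selectDOptimal(spB, mB, nRuns = 6, seed = 23, nStarts = 20)
  expect_equal(logDet(desB), oracleB$logDet, tolerance = 1e-8)
})

test_that("the exchange search is reproducible and monotone", {
  space <- lycopeneSpace()
  m <- modelSpec(space)
  d1 <- selectDOptimal(space, m, nRuns = 20, seed = 5, nStarts = 3)
  d2 <- selectDOptimal(space, m, nRuns = 20, seed = 5, nStarts = 3)
  expect_identical(runIndices(d1), runIndices(d2))
  expect_identical(logDet(d1), logDet(d2))
  ## accepted log-dets never decrease
  expect_true(all(diff(d1@traceLogDet) > -1e-9))
})

test_that("the selected 88-run design beats 1000 seeded random designs", {
  space <- lycopeneSpace()
  m <- modelSpec(space)
  configs <- enumerateConfigurations(space)
  X <- encodeModelMatrix(space, configs, m)
  des <- selectDOptimal(space, m, nRuns = 88, seed = 17)
  ld <- function(idx) {
    d <- determinant(crossprod(X[idx, ]), logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }
  set.seed(99)
  randomBest <- max(vapply(1:1000, function(i) ld(sample.int(810, 88)),
                           numeric(1)))
  expect_gt(logDet(des), randomBest)
  expect_identical(length(unique(runIndices(des))), 88L)
})

test_that("allowReplicates permits repeated runs when n exceeds the candidates", {
  lib <- tinyLibrary(nProm = 2, nRbs = 2, nGenes = 1)
  space <- buildDesignSpace(lib)
  m <- modelSpec(space)
  expect_error(selectDOptimal(space, m, nRuns = 6, seed = 1),
               class = "infeasibleDesignError")
  des <- selectDOptimal(space, m, nRuns = 6, seed = 1, allowReplicates = TRUE)
  expect_identical(des@nRuns, 6L)
  expect_true(anyDuplicated(runIndices(des)) > 0)
})

test_that("the design table reports rank values for numeric factors and labels for gene order", {
  space <- lycopeneSpace()
  des <- selectDOptimal(space, modelSpec(space), nRuns = 12, seed = 2, nStarts = 2)
  tab <- designTable(des, space)
  expect_true(all(tab$promoter %in% 1:5))
  expect_true(all(tab$rbs_pos1 %in% 1:3))
  expect_true(all(tab$gene_order %in% designFactors(space)[["gene_order"]]@levels))
  expect_identical(tab$config_index, runIndices(des))
})
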