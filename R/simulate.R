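## Seeded titre simulator: synthetic screening outcomes with the statistical
## structure the effect analysis assumes.

#' Construct a ground truth for the titre simulator
#'
#' @param space the [DesignSpace-class] the truth refers to (fixes the
#'   gene-order level names and the number of RBS positions).
#' @param beta0 baseline titre, mg/g DCW.
#' @param betaProm coded-unit promoter effect.
#' @param betaRbs coded-unit effects, one per RBS position.
#' @param gammaOrder named sum-to-zero gene-order effects (names must be the
#'   space's gene-order levels).
#' @param sigma residual SD, mg/g DCW.
#' @param alpha0,alpha1 failure-logit intercept and promoter slope.
#' @param lod detection floor, mg/g DCW.
#' @param seed default simulation seed.
#' @return a [GroundTruth-class].
#' @export
groundTruth <- function(space, beta0, betaProm, betaRbs, gammaOrder,
                        sigma, alpha0, alpha1, lod, seed = 1L) {
  stopifnot(is(space, "DesignSpace"))
  facs <- designFactors(space)
  nRbs <- sum(grepl("^rbs_pos", names(facs)))
  if (length(betaRbs) != nRbs) {
    stopWithClass("configurationError", "betaRbs must have one entry per RBS position")
  }
  ordLevels <- facs[["gene_order"]]@levels
  if (!setequal(names(gammaOrder), ordLevels)) {
    stopWithClass("configurationError",
                  "gammaOrder names must be the gene-order levels")
  }
  methods::new("GroundTruth", beta0 = beta0, betaProm = betaProm,
               betaRbs = as.numeric(betaRbs),
               gammaOrder = gammaOrder[ordLevels], sigma = sigma,
               alpha0 = alpha0, alpha1 = alpha1, lod = lod,
               seed = as.integer(seed))
}

#' Default calibrated ground truth
#'
#' The shipped calibration emulates the screening campaign the package is
#' designed around: gene order dominates, promoter strength comes second and
#' the position-3 RBS third (both negative: weaker parts give more product),
#' the remaining RBS positions are null; titres span roughly 0.05-4.6 mg/g
#' DCW with a 0.05 mg/g detection floor; and assembly/growth failure becomes
#' more likely as promoter strength rises, with the failure-logit intercept
#' solved numerically so that the expected failure fraction over the extreme
#' coded promoter levels (the levels a D-optimal main-effects screen selects)
#' is 53%. These defaults are a calibration, not an estimate from data.
#'
#' @param space the [DesignSpace-class] (3-gene spaces get the canonical
#'   gene-order effect pattern; other sizes a centred spread).
#' @param failureRate target mean failure fraction (default 0.53).
#' @param seed default simulation seed.
#' @return a [GroundTruth-class].
#' @export
defaultGroundTruth <- function(space, failureRate = 0.53, seed = 1L) {
  facs <- designFactors(space)
  ordLevels <- facs[["gene_order"]]@levels
  k <- length(ordLevels)
  if (k == 6L) {
    gamma <- c(-0.5, 0.9, -0.6, 0.6, -0.7, 0.3)
  } else if (k == 1L) {
    gamma <- 0
  } else {
    gamma <- seq(-0.8, 0.8, length.out = k)
    gamma <- gamma - mean(gamma)
  }
  names(gamma) <- ordLevels
  nRbs <- sum(grepl("^rbs_pos", names(facs)))
  betaRbs <- rep(0, nRbs)
  if (nRbs >= 1L) betaRbs[nRbs] <- -0.35
  alpha1 <- 0.5
  alpha0 <- stats::uniroot(function(a0) {
    mean(stats::plogis(a0 + alpha1 * c(-1, 1))) - failureRate
  }, c(-10, 10))$root
  groundTruth(space, beta0 = 1.7, betaProm = -0.55, betaRbs = betaRbs,
              gammaOrder = gamma, sigma = 0.3, alpha0 = alpha0,
              alpha1 = alpha1, lod = 0.05, seed = seed)
}

## Linear predictor of the truth for a set of design runs (label columns).
truthPredictor <- function(space, design, truth) {
  facs <- designFactors(space)
  mu <- rep(truth@beta0, nrow(design))
  xProm <- factorBlock(facs[["promoter"]], design$promoter)[, 1L]
  mu <- mu + truth@betaProm * xProm
  rbsNames <- grep("^rbs_pos", names(facs), value = TRUE)
  for (i in seq_along(rbsNames)) {
    x <- factorBlock(facs[[rbsNames[i]]], design[[rbsNames[i]]])[, 1L]
    mu <- mu + truth@betaRbs[i] * x
  }
  if (length(truth@gammaOrder) > 1L) {
    mu <- mu + unname(truth@gammaOrder[design$gene_order])
  }
  list(mu = mu, xProm = xProm)
}

#' Simulate screening outcomes for a design
#'
#' Per run, assembly/growth failure is drawn from
#' `Bernoulli(plogis(alpha0 + alpha1 * x_prom))`; failed runs yield no
#' growth (zero dry cell weight, no titre). Surviving runs get, per
#' replicate, `titre = max(0, mu + Normal(0, sigma))` where `mu` is the
#' truth's linear predictor, flagged undetected below the detection floor.
#' Fully seeded: the same seed reproduces the table bitwise.
#'
#' @param space the [DesignSpace-class].
#' @param design data.frame of design runs with `stitch_id` and factor
#'   level-label columns (e.g. [designRuns()] after [assignStitchIds()]), or
#'   a [ReducedDesign-class] whose runs carry stitch IDs.
#' @param truth a [GroundTruth-class].
#' @param replicates biological replicates per construct (default 3).
#' @param seed simulation seed (default the truth's).
#' @return titre-record table: `stitch_id`, `replicate`, `dcw_g`,
#'   `titre_mg_per_gdcw`, `detected`.
#' @export
simulateTitres <- function(space, design, truth, replicates = 3L,
                           seed = truth@seed) {
  stopifnot(is(space, "DesignSpace"), is(truth, "GroundTruth"),
            replicates >= 1L)
  if (is(design, "ReducedDesign")) design <- designRuns(design)
  if (!"stitch_id" %in% names(design) || any(is.na(design$stitch_id))) {
    stopWithClass("validationError", "design runs must carry stitch IDs")
  }
  n <- nrow(design)
  pred <- truthPredictor(space, design, truth)
  set.seed(as.integer(seed))
  pFail <- stats::plogis(truth@alpha0 + truth@alpha1 * pred$xProm)
  failed <- stats::runif(n) < pFail
  od <- matrix(pmax(stats::rnorm(n * replicates, 2.0, 0.15), 0.2),
               n, replicates)
  eps <- matrix(stats::rnorm(n * replicates, 0, truth@sigma), n, replicates)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (failed[i]) {
      rows[[i]] <- data.frame(
        stitch_id = design$stitch_id[i], replicate = seq_len(replicates),
        dcw_g = 0, titre_mg_per_gdcw = NA_real_, detected = FALSE,
        stringsAsFactors = FALSE)
    } else {
      titre <- pmax(pred$mu[i] + eps[i, ], 0)
      rows[[i]] <- data.frame(
        stitch_id = design$stitch_id[i], replicate = seq_len(replicates),
        dcw_g = odToDcw(od[i, ], 1), titre_mg_per_gdcw = titre,
        detected = titre >= truth@lod & titre > 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate raw measurements (OD600 and LC peak areas)
#'
#' Emits pseudo-measurements by inverting the quantification formulas, so the
#' quantification stage itself can be exercised: peak area is
#' `slope * conc + intercept` where `conc = titre * dcw / extract volume`.
#' The 450 nm channel is emitted at a fixed 0.85 response ratio to 471 nm.
#'
#' @inheritParams simulateTitres
#' @param curve the [StandardCurve-class] whose formulas are inverted.
#' @return measurement table: `stitch_id`, `replicate`, `od600`,
#'   `peak_area_450`, `peak_area_471`, `culture_volume_mL`,
#'   `extract_volume_mL`.
#' @export
simulateMeasurements <- function(space, design, truth, curve,
                                 replicates = 3L, seed = truth@seed) {
  stopifnot(is(curve, "StandardCurve"))
  titres <- simulateTitres(space, design, truth, replicates, seed)
  od <- titres$dcw_g / (0.36 / 1000)
  titre <- ifelse(is.na(titres$titre_mg_per_gdcw), 0, titres$titre_mg_per_gdcw)
  conc <- titre * titres$dcw_g / 1
  area471 <- curve@slope * conc + curve@intercept
  data.frame(stitch_id = titres$stitch_id, replicate = titres$replicate,
             od600 = od, peak_area_450 = 0.85 * area471,
             peak_area_471 = area471, culture_volume_mL = 1,
             extract_volume_mL = 1, stringsAsFactors = FALSE)
}
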