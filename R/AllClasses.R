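## S4 classes for the design-build-test workflow.

#' PartLibrary: a validated collection of characterised parts
#'
#' Holds one row per biological part with its class, sequence, relative
#' strength (e.g. RPU measured against a reference constitutive promoter)
#' and, once assigned, its within-class strength rank (1 = weakest).
#'
#' @slot parts data.frame with columns `part_id`, `name`, `part_class`,
#'   `native_host`, `sequence`, `strength_value`, `strength_units`,
#'   `reference_standard`, `rank`.
#' @slot provenance list recording the source file and load time.
#' @export
setClass("PartLibrary",
         representation(parts = "data.frame", provenance = "list"),
         prototype(provenance = list()))

setValidity("PartLibrary", function(object) {
  p <- object@parts
  msgs <- character()
  need <- c(PART_COLUMNS, "rank")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  dup <- p$part_id[duplicated(p$part_id)]
  if (length(dup)) {
    msgs <- c(msgs, paste("duplicate part_id:", paste(unique(dup), collapse = ", ")))
  }
  badClass <- setdiff(unique(p$part_class), PART_CLASSES)
  if (length(badClass)) {
    msgs <- c(msgs, paste("unknown part_class:", paste(badClass, collapse = ", ")))
  }
  if (any(!is.na(p$strength_value) & p$strength_value < 0)) {
    msgs <- c(msgs, "strength_value must be >= 0")
  }
  noSeq <- p$part_class %in% SEQUENCE_REQUIRED & (is.na(p$sequence) | !nzchar(p$sequence))
  if (any(noSeq)) {
    msgs <- c(msgs, paste("empty sequence for part(s):",
                          paste(p$part_id[noSeq], collapse = ", ")))
  }
  ## ranks, where set, must be a subset of 1..k within each class
  for (cl in unique(p$part_class)) {
    r <- p$rank[p$part_class == cl]
    r <- r[!is.na(r)]
    if (length(r) && (any(r < 1L) || any(r > length(r)) || anyDuplicated(r))) {
      msgs <- c(msgs, paste0("ranks for class '", cl,
                             "' are not distinct values in 1..k"))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FactorSpec: one experimental factor of the design space
#'
#' @slot name factor name, e.g. `"promoter"` or `"gene_order"`.
#' @slot kind `"discrete_numeric"` (levels carry strength ranks) or
#'   `"categorical"`.
#' @slot levels ordered character vector of level labels.
#' @slot numericValues for discrete-numeric factors, the strictly increasing
#'   rank value of each level; `numeric(0)` otherwise.
#' @slot partMap named character vector mapping each level label to the
#'   part_id realising it (absent for the gene-order factor).
#' @export
setClass("FactorSpec",
         representation(name = "character", kind = "character",
                        levels = "character", numericValues = "numeric",
                        partMap = "character"),
         prototype(numericValues = numeric(0), partMap = character(0)))

setValidity("FactorSpec", function(object) {
  msgs <- character()
  if (length(object@levels) < 1L) msgs <- c(msgs, "factor needs >= 1 level")
  if (anyDuplicated(object@levels)) msgs <- c(msgs, "level labels must be unique")
  if (!object@kind %in% c("discrete_numeric", "categorical")) {
    msgs <- c(msgs, "kind must be 'discrete_numeric' or 'categorical'")
  }
  if (object@kind == "discrete_numeric") {
    v <- object@numericValues
    if (length(v) != length(object@levels)) {
      msgs <- c(msgs, "numericValues must match levels")
    } else if (length(v) > 1L && any(diff(v) <= 0)) {
      msgs <- c(msgs, "numericValues must be strictly increasing")
    }
  }
  if (length(object@partMap) &&
      !all(object@levels %in% names(object@partMap))) {
    msgs <- c(msgs, "partMap must cover every level")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' DesignSpace: the factor structure of an operon library
#'
#' @slot factors list of [FactorSpec-class] objects in definition order
#'   (promoter, one RBS factor per gene position, gene order).
#' @slot genes character vector of CDS part_ids in declared order.
#' @slot geneCodes single-letter codes used in gene-order level labels.
#' @slot orderPerms integer matrix, one row per gene-order level, giving the
#'   permutation of `genes` that the level places in positions 1..g.
#' @slot terminatorId,backboneId part_ids of the fixed elements.
#' @export
setClass("DesignSpace",
         representation(factors = "list", genes = "character",
                        geneCodes = "character", orderPerms = "matrix",
                        terminatorId = "character", backboneId = "character"))

setValidity("DesignSpace", function(object) {
  msgs <- character()
  if (!all(vapply(object@factors, is, logical(1), "FactorSpec"))) {
    msgs <- c(msgs, "factors must be FactorSpec objects")
  }
  nm <- vapply(object@factors, function(f) f@name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "factor names must be unique")
  g <- length(object@genes)
  if (g >= 1L && "gene_order" %in% nm) {
    ord <- object@factors[[match("gene_order", nm)]]
    if (length(ord@levels) != factorial(g)) {
      msgs <- c(msgs, "gene_order level count must equal (number of genes)!")
    }
  }
  if (length(object@geneCodes) != g) {
    msgs <- c(msgs, "geneCodes must match genes")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ModelSpec: the linear model used for design selection and effect screening
#'
#' @slot factorNames factors entering as main effects (discrete-numeric
#'   factors contribute one linear column; categorical factors an
#'   effects-coded block of k-1 columns).
#' @slot interactions list of length-2 character vectors naming two-factor
#'   interactions (columnwise products of the main-effect blocks).
#' @slot p total model column count including the intercept.
#' @export
setClass("ModelSpec",
         representation(factorNames = "character", interactions = "list",
                        p = "integer"),
         prototype(interactions = list()))

setValidity("ModelSpec", function(object) {
  if (object@p < 1L) return("p must be >= 1")
  TRUE
})

#' ReducedDesign: a D-optimal run subset of the candidate configurations
#'
#' @slot runIndices 0-based `config_index` values of the selected runs,
#'   sorted ascending.
#' @slot runs data.frame of the selected configurations (factor level labels
#'   plus `config_index`, and `stitch_id` once assigned).
#' @slot nRuns,candidateCount design size and candidate-set size.
#' @slot logDet log determinant of the information matrix X'X.
#' @slot dEfficiency 100 * det(X'X)^(1/p) / n, in (0, 100].
#' @slot seed,nStarts search reproducibility metadata.
#' @slot traceLogDet accepted log-det sequence of the winning search start
#'   (monotone non-decreasing).
#' @export
setClass("ReducedDesign",
         representation(runIndices = "integer", runs = "data.frame",
                        nRuns = "integer", candidateCount = "integer",
                        logDet = "numeric", dEfficiency = "numeric",
                        seed = "integer", nStarts = "integer",
                        traceLogDet = "numeric"))

setValidity("ReducedDesign", function(object) {
  msgs <- character()
  if (length(object@runIndices) != object@nRuns) {
    msgs <- c(msgs, "runIndices length must equal nRuns")
  }
  if (any(object@runIndices < 0L) ||
      any(object@runIndices > object@candidateCount - 1L)) {
    msgs <- c(msgs, "runIndices out of candidate range")
  }
  if (!is.finite(object@logDet)) msgs <- c(msgs, "information matrix is singular")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PlateLayout: source-plate locations of parts and reagents
#'
#' @slot layout data.frame with columns `plate_name`, `well`, `content_id`,
#'   `concentration`, `units`.
#' @slot format wells per plate (96 or 384).
#' @export
setClass("PlateLayout",
         representation(layout = "data.frame", format = "integer"))

setValidity("PlateLayout", function(object) {
  msgs <- character()
  need <- c("plate_name", "well", "content_id", "concentration", "units")
  missing <- setdiff(need, names(object@layout))
  if (length(missing)) {
    return(paste("missing layout column(s):", paste(missing, collapse = ", ")))
  }
  if (!object@format %in% c(96L, 384L)) msgs <- c(msgs, "format must be 96 or 384")
  ok <- object@layout$well %in% wellLabels(object@format)
  if (!all(ok)) {
    msgs <- c(msgs, paste("invalid well label(s):",
                          paste(unique(object@layout$well[!ok]), collapse = ", ")))
  }
  key <- paste(object@layout$plate_name, object@layout$well)
  if (anyDuplicated(key)) msgs <- c(msgs, "one content per well violated")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AssemblyConfig: volumes and plate settings for picklist planning
#'
#' Default transfer volumes are configuration placeholders (the protocol does
#' not prescribe them); droplet size 2.5 nL matches Echo-class acoustic
#' dispensers, and volumes are always rounded *up* to a droplet multiple so
#' molar targets are met or exceeded.
#'
#' @slot dropletNl droplet quantum in nL (default 2.5).
#' @slot partVolumeNl,linkerVolumeNl,mixVolumeNl requested volumes in nL.
#' @slot maxWellVolumeNl per-destination-well capacity in nL.
#' @slot partConcNM part plasmid working concentration (default 76 nM).
#' @slot linkerConcUM linker working concentration (default 1 uM).
#' @slot destinationPlate destination plate name.
#' @slot destinationFormat destination plate format (96 or 384).
#' @slot mixContentId content_id of the shared assembly master mix
#'   (`NA` to omit reagent transfers).
#' @export
setClass("AssemblyConfig",
         representation(dropletNl = "numeric", partVolumeNl = "numeric",
                        linkerVolumeNl = "numeric", mixVolumeNl = "numeric",
                        maxWellVolumeNl = "numeric", partConcNM = "numeric",
                        linkerConcUM = "numeric", destinationPlate = "character",
                        destinationFormat = "integer", mixContentId = "character"),
         prototype(dropletNl = 2.5, partVolumeNl = 25, linkerVolumeNl = 25,
                   mixVolumeNl = 500, maxWellVolumeNl = 12000,
                   partConcNM = 76, linkerConcUM = 1,
                   destinationPlate = "assembly_1", destinationFormat = 96L,
                   mixContentId = "master_mix"))

setValidity("AssemblyConfig", function(object) {
  vols <- c(object@dropletNl, object@partVolumeNl, object@linkerVolumeNl,
            object@mixVolumeNl, object@maxWellVolumeNl)
  if (any(!is.finite(vols)) || any(vols <= 0)) return("all volumes must be > 0")
  if (!object@destinationFormat %in% c(96L, 384L)) return("destination format must be 96 or 384")
  TRUE
})

#' Picklist: an ordered liquid-handler transfer plan
#'
#' @slot transfers data.frame with columns `source_plate`, `source_well`,
#'   `destination_plate`, `destination_well`, `volume_nl`.
#' @slot destinationTotals named numeric, total nL per destination well.
#' @slot dropletNl droplet quantum every volume is a multiple of.
#' @export
setClass("Picklist",
         representation(transfers = "data.frame",
                        destinationTotals = "numeric", dropletNl = "numeric"))

setValidity("Picklist", function(object) {
  t <- object@transfers
  need <- c("source_plate", "source_well", "destination_plate",
            "destination_well", "volume_nl")
  missing <- setdiff(need, names(t))
  if (length(missing)) {
    return(paste("missing transfer column(s):", paste(missing, collapse = ", ")))
  }
  if (nrow(t)) {
    if (any(t$volume_nl <= 0)) return("transfer volumes must be > 0")
    q <- t$volume_nl / object@dropletNl
    if (any(abs(q - round(q)) > 1e-9)) {
      return("transfer volumes must be droplet multiples")
    }
  }
  TRUE
})

#' StandardCurve: linear peak-area response to analyte concentration
#'
#' @slot slope peak-area units per (mg/mL); must be > 0 for a usable curve.
#' @slot intercept peak-area units at zero concentration.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nPoints number of calibration points.
#' @slot detectionFloor concentration (mg/mL) of the smallest nonzero
#'   standard; computed concentrations below it are flagged undetected.
#' @export
setClass("StandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", nPoints = "integer",
                        detectionFloor = "numeric"))

setValidity("StandardCurve", function(object) {
  if (object@nPoints < 2L) return("a standard curve needs >= 2 points")
  if (!is.finite(object@slope)) return("slope must be finite")
  TRUE
})

#' EffectFit: an ordinary least-squares fit of the effect model
#'
#' @slot coefficients named vector of coefficients in coded units.
#' @slot residualDf residual degrees of freedom (n - p).
#' @slot sigma2 residual variance estimate.
#' @slot model the [ModelSpec-class] fitted.
#' @slot nObs observations used (producing constructs only, by default the
#'   per-construct mean titre).
#' @slot X,y the coded model matrix and response retained for partial-F
#'   effect tests and prediction.
#' @slot termLabels model term of each X column.
#' @export
setClass("EffectFit",
         representation(coefficients = "numeric", residualDf = "integer",
                        sigma2 = "numeric", model = "ModelSpec",
                        nObs = "integer", X = "matrix", y = "numeric",
                        termLabels = "character"))

setValidity("EffectFit", function(object) {
  if (object@residualDf < 0L) return("residual df must be >= 0")
  if (is.finite(object@sigma2) && object@sigma2 < 0) return("sigma2 must be >= 0")
  TRUE
})

#' GroundTruth: generating model of the titre simulator
#'
#' Titres follow a linear model on the coded factors, truncated at zero and
#' censored at a detection floor; assembly/growth failure is Bernoulli with
#' a logit linear in the coded promoter strength (failures become more
#' frequent as promoter strength rises when `alpha1 > 0`).
#'
#' @slot beta0 baseline titre, mg/g DCW.
#' @slot betaProm coded-unit promoter effect.
#' @slot betaRbs coded-unit effects, one per RBS position.
#' @slot gammaOrder named sum-to-zero gene-order level effects.
#' @slot sigma residual SD, mg/g DCW.
#' @slot alpha0,alpha1 failure-logit intercept and promoter slope (alpha1 >= 0).
#' @slot lod detection floor, mg/g DCW.
#' @slot seed default simulation seed.
#' @export
setClass("GroundTruth",
         representation(beta0 = "numeric", betaProm = "numeric",
                        betaRbs = "numeric", gammaOrder = "numeric",
                        sigma = "numeric", alpha0 = "numeric",
                        alpha1 = "numeric", lod = "numeric", seed = "integer"),
         prototype(seed = 1L))

setValidity("GroundTruth", function(object) {
  msgs <- character()
  if (object@sigma < 0) msgs <- c(msgs, "sigma must be >= 0")
  if (object@lod < 0) msgs <- c(msgs, "lod must be >= 0")
  if (object@alpha1 < 0) msgs <- c(msgs, "alpha1 must be >= 0")
  if (length(object@gammaOrder) &&
      abs(sum(object@gammaOrder)) > 1e-8) {
    msgs <- c(msgs, "gammaOrder must sum to zero")
  }
  if (is.null(names(object@gammaOrder)) && length(object@gammaOrder)) {
    msgs <- c(msgs, "gammaOrder must be named by gene-order level")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "PartLibrary", function(object) {
  tab <- table(factor(object@parts$part_class, levels = PART_CLASSES))
  cat("PartLibrary with", nrow(object@parts), "parts\n")
  cat(" ", paste(names(tab)[tab > 0], tab[tab > 0], sep = ": ",
                 collapse = ", "), "\n")
  ranked <- sum(!is.na(object@parts$rank))
  cat("  ranked parts:", ranked, "\n")
})

setMethod("show", "DesignSpace", function(object) {
  cat("DesignSpace with", length(object@factors), "factors\n")
  for (f in object@factors) {
    cat(sprintf("  %s (%s): %d levels\n", f@name, f@kind, length(f@levels)))
  }
  cat("  configurations:",
      prod(vapply(object@factors, function(f) length(f@levels), numeric(1))), "\n")
})

setMethod("show", "ReducedDesign", function(object) {
  cat(sprintf("ReducedDesign: %d runs from %d candidates\n",
              object@nRuns, object@candidateCount))
  cat(sprintf("  log det(X'X) = %.4f, D-efficiency = %.2f%%\n",
              object@logDet, object@dEfficiency))
  cat(sprintf("  seed = %d, starts = %d\n", object@seed, object@nStarts))
})

setMethod("show", "Picklist", function(object) {
  cat(sprintf("Picklist: %d transfers to %d destination wells (droplet %.1f nL)\n",
              nrow(object@transfers), length(object@destinationTotals),
              object@dropletNl))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: area = %.4g * conc + %.4g (r^2 = %.4f, n = %d)\n",
              object@slope, object@intercept, object@rSquared, object@nPoints))
})

setMethod("show", "EffectFit", function(object) {
  cat(sprintf("EffectFit: %d observations, %d parameters, residual df = %d\n",
              object@nObs, length(object@coefficients), object@residualDf))
  cat(sprintf("  residual variance = %.4g\n", object@sigma2))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth titre model (mg/g DCW):\n")
  cat(sprintf("  beta0 = %.3g, betaProm = %.3g, betaRbs = (%s), sigma = %.3g\n",
              object@beta0, object@betaProm,
              paste(signif(object@betaRbs, 3), collapse = ", "), object@sigma))
  cat(sprintf("  failure logit: %.3g + %.3g * x_prom; lod = %.3g\n",
              object@alpha0, object@alpha1, object@lod))
})
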