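## Titre quantification: OD600 -> dry cell weight, standard curve,
## LC peak area -> mg product per g DCW.
##
## Units contract: concentrations mg/mL, volumes mL, DCW g, titre mg/g DCW.

#' Convert OD600 to dry cell weight
#'
#' Uses the fixed calibration DCW/OD = 0.36 g per litre per OD unit,
#' corrected for the culture volume: `0.36 * od600 * volume_mL / 1000` grams.
#' Linear and homogeneous in OD.
#'
#' @param od600 optical density at 600 nm (>= 0).
#' @param cultureVolumeMl culture volume in mL (default 1).
#' @return dry cell weight in grams.
#' @examples
#' odToDcw(1.0, 1000)  # 0.36 g for 1 L of OD 1.0 culture
#' @export
odToDcw <- function(od600, cultureVolumeMl = 1) {
  if (any(od600 < 0, na.rm = TRUE)) {
    stopWithClass("domainError", "od600 must be >= 0")
  }
  if (any(cultureVolumeMl <= 0)) {
    stopWithClass("domainError", "culture volume must be > 0")
  }
  0.36 * od600 * cultureVolumeMl / 1000
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of peak area on analyte concentration,
#' `area = slope * conc + intercept`. The detection floor is set to the
#' smallest nonzero standard concentration: computed sample concentrations
#' below it are flagged undetected.
#'
#' @param concentrations standard concentrations in mg/mL (>= 2 distinct).
#' @param areas corresponding peak areas.
#' @param zeroIntercept force the line through the origin.
#' @return a [StandardCurve-class].
#' @export
fitStandardCurve <- function(concentrations, areas, zeroIntercept = FALSE) {
  if (length(concentrations) != length(areas)) {
    stopWithClass("domainError", "concentrations and areas must match")
  }
  if (length(concentrations) < 2L || length(unique(concentrations)) < 2L) {
    stopWithClass("underdeterminedError",
                  "need at least 2 distinct standard concentrations")
  }
  df <- data.frame(conc = concentrations, area = areas)
  fit <- if (zeroIntercept) stats::lm(area ~ 0 + conc, data = df)
         else stats::lm(area ~ conc, data = df)
  co <- stats::coef(fit)
  slope <- unname(co[["conc"]])
  intercept <- if (zeroIntercept) 0 else unname(co[["(Intercept)"]])
  tss <- sum((areas - mean(areas))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  floorConc <- if (any(concentrations > 0)) min(concentrations[concentrations > 0]) else 0
  methods::new("StandardCurve", slope = slope, intercept = intercept,
               rSquared = r2, nPoints = length(concentrations),
               detectionFloor = floorConc)
}

#' Convert peak areas to titres in mg per g dry cell weight
#'
#' For each measurement row: concentration in the extract is
#' `(area - intercept) / slope` mg/mL; analyte mass is concentration times
#' extract volume; dry cell weight comes from [odToDcw()]; titre is mass over
#' DCW. Negative computed concentrations are clamped to zero with a warning
#' and flagged undetected, as are concentrations below the curve's detection
#' floor. The titre channel defaults to the 471 nm absorbance maximum.
#'
#' @param measurements data.frame with columns `stitch_id`, `replicate`,
#'   `od600`, `peak_area_450`, `peak_area_471` and optionally
#'   `culture_volume_mL`, `extract_volume_mL` (default 1 each).
#' @param curve a [StandardCurve-class] with positive slope.
#' @param channel `"471"` (default) or `"450"`.
#' @return data.frame of titre records: `stitch_id`, `replicate`, `dcw_g`,
#'   `titre_mg_per_gdcw`, `detected`.
#' @export
peakAreaToTitre <- function(measurements, curve, channel = c("471", "450")) {
  stopifnot(is(curve, "StandardCurve"))
  channel <- match.arg(channel)
  if (curve@slope <= 0) {
    stopWithClass("domainError", "standard curve slope must be > 0 to be usable")
  }
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  need <- c("stitch_id", "replicate", "od600", paste0("peak_area_", channel))
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stopWithClass("schemaError", "measurements lack column(s): ",
                  paste(missing, collapse = ", "))
  }
  if (!"culture_volume_mL" %in% names(m)) m$culture_volume_mL <- 1
  if (!"extract_volume_mL" %in% names(m)) m$extract_volume_mL <- 1
  if (any(m$culture_volume_mL <= 0) || any(m$extract_volume_mL <= 0)) {
    stopWithClass("domainError", "volumes must be > 0")
  }
  area <- m[[paste0("peak_area_", channel)]]
  conc <- (area - curve@intercept) / curve@slope
  neg <- conc < 0
  if (any(neg)) {
    warning(sum(neg), " measurement(s) below the curve intercept; ",
            "concentration clamped to 0 and flagged undetected")
    conc[neg] <- 0
  }
  dcw <- odToDcw(m$od600, m$culture_volume_mL)
  ## a signal above the detection floor with no biomass is contradictory;
  ## sub-floor traces at zero DCW are treated as blank wells
  bad <- dcw == 0 & conc >= curve@detectionFloor & conc > 0
  if (any(bad)) {
    stopWithClass("undefinedTitreError",
                  "nonzero peak area with zero dry cell weight for: ",
                  paste(unique(m$stitch_id[bad]), collapse = ", "))
  }
  mass <- conc * m$extract_volume_mL
  titre <- ifelse(dcw > 0, mass / dcw, 0)
  detected <- conc >= curve@detectionFloor & conc > 0 & dcw > 0
  data.frame(stitch_id = m$stitch_id, replicate = m$replicate,
             dcw_g = dcw, titre_mg_per_gdcw = titre, detected = detected,
             stringsAsFactors = FALSE)
}

#' Summarise screening outcomes
#'
#' Counts, per construct, whether it grew (any replicate with nonzero dry
#' cell weight) and whether it produced detectable product (any detected
#' replicate), and reports the failure rate to the nearest percent.
#'
#' @param titres titre-record table ([peakAreaToTitre()] or
#'   [simulateTitres()] output).
#' @return list with `n_constructs`, `producers`, `no_growth`, `no_product`,
#'   `failures` and `failure_pct`.
#' @export
summariseScreen <- function(titres) {
  need <- c("stitch_id", "dcw_g", "detected")
  missing <- setdiff(need, names(titres))
  if (length(missing)) {
    stopWithClass("schemaError", "titre table lacks column(s): ",
                  paste(missing, collapse = ", "))
  }
  grew <- tapply(titres$dcw_g > 0, titres$stitch_id, any)
  produced <- tapply(titres$detected, titres$stitch_id, any)
  n <- length(grew)
  producers <- sum(produced)
  noGrowth <- sum(!grew)
  noProduct <- sum(grew & !produced)
  failures <- n - producers
  list(n_constructs = n, producers = producers, no_growth = noGrowth,
       no_product = noProduct, failures = failures,
       failure_pct = round(100 * failures / n))
}
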