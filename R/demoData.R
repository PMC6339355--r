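## Bundled synthetic demonstration inputs for the lycopene operon workflow.

#' Synthetic lycopene demonstration part library
#'
#' Loads the bundled synthetic part library: five constitutive promoters of
#' low-to-medium relative strength (RPU against a reference constitutive
#' promoter), three RBS parts spanning low/medium/high strength, the three
#' carotenoid pathway CDSs (crtE, crtB, crtI), a terminator, three
#' RBS-carrying assembly linkers and a p15A backbone. Strength values and
#' sequences are fabricated placeholders for demonstration and testing; they
#' are not measurements.
#'
#' @param ranked rank the promoter and RBS classes before returning
#'   (default TRUE).
#' @return a [PartLibrary-class].
#' @export
lycopeneLibrary <- function(ranked = TRUE) {
  path <- system.file("extdata", "lycopene_demo_parts.csv",
                      package = "operonDesign")
  lib <- loadParts(path)
  if (ranked) {
    lib <- rankParts(lib, "promoter")
    lib <- rankParts(lib, "rbs")
  }
  lib
}

#' Demonstration source-plate layout
#'
#' @return a [PlateLayout-class] locating every demo part, linker and the
#'   assembly master mix on one 96-well source plate.
#' @export
lycopeneLayout <- function() {
  readPlateLayout(system.file("extdata", "lycopene_source_plates.csv",
                              package = "operonDesign"))
}

#' Demonstration lycopene standard curve data
#'
#' Synthetic calibration points (concentration in mg/mL vs LC peak area)
#' spanning the concentrations a screening extract produces.
#'
#' @return data.frame with columns `concentration_mg_per_ml`, `peak_area`.
#' @export
lycopeneStandards <- function() {
  utils::read.csv(system.file("extdata", "lycopene_standards.csv",
                              package = "operonDesign"),
                  stringsAsFactors = FALSE)
}

#' Default pipeline configuration for the lycopene demonstration
#'
#' @param outputDir directory the pipeline writes artifacts to.
#' @param seed design-selection seed; the simulation seed is derived as
#'   `seed + 1`.
#' @return configuration list accepted by [runPipeline()].
#' @export
lycopeneConfig <- function(outputDir = tempfile("operon_run_"), seed = 17L) {
  list(
    parts = system.file("extdata", "lycopene_demo_parts.csv",
                        package = "operonDesign"),
    layout = system.file("extdata", "lycopene_source_plates.csv",
                         package = "operonDesign"),
    genes = c("crtE", "crtB", "crtI"),
    gene_codes = c("E", "B", "I"),
    n_runs = 88L,
    n_starts = 10L,
    replicates = 3L,
    top_k = 5L,
    seeds = list(design = as.integer(seed), simulation = as.integer(seed) + 1L),
    output_dir = outputDir
  )
}
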