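## Programmatic fixtures shared across test files.

## A minimal valid part row.
partRow <- function(part_id, part_class, strength = NA_real_, rank = NA,
                    sequence = "ACGT", name = part_id) {
  data.frame(part_id = part_id, name = name, part_class = part_class,
             native_host = "E. coli", sequence = sequence,
             strength_value = strength, strength_units = "RPU",
             reference_standard = "ref", rank = rank,
             stringsAsFactors = FALSE)
}

## Write a part table (without the rank column unless asked) to a temp CSV.
writePartsCsv <- function(rows, keepRank = FALSE) {
  df <- do.call(rbind, rows)
  if (!keepRank) df$rank <- NULL
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

## A tiny complete library: nProm promoters, nRbs RBSs, genes CDSs,
## terminator + backbone (+ optional linkers), ranked.
tinyLibrary <- function(nProm = 2, nRbs = 2, nGenes = 2, linkers = FALSE) {
  rows <- list()
  for (i in seq_len(nProm)) {
    rows <- c(rows, list(partRow(paste0("p", i), "promoter", strength = i / 10)))
  }
  for (i in seq_len(nRbs)) {
    rows <- c(rows, list(partRow(paste0("r", i), "rbs", strength = i)))
  }
  for (i in seq_len(nGenes)) {
    rows <- c(rows, list(partRow(paste0("g", i), "cds",
                                 sequence = "ATGAAATAA")))
  }
  rows <- c(rows, list(partRow("t1", "terminator"),
                       partRow("bb", "backbone")))
  if (linkers) {
    for (i in seq_len(nRbs)) {
      rows <- c(rows, list(partRow(paste0("l", i), "linker")))
    }
  }
  lib <- loadParts(writePartsCsv(rows))
  lib <- rankParts(lib, "promoter")
  rankParts(lib, "rbs")
}

## The full demonstration space used throughout.
lycopeneSpace <- function() {
  buildDesignSpace(lycopeneLibrary(), genes = c("crtE", "crtB", "crtI"),
                   geneCodes = c("E", "B", "I"))
}

## Design runs with stitch IDs for a reduced design.
labelledRuns <- function(space, design) {
  cons <- assignStitchIds(configurationToConstruct(space, designRuns(design)))
  runs <- designRuns(design)
  runs$stitch_id <- cons$stitch_id[match(runs$config_index, cons$config_index)]
  runs
}

## Noise-free, failure-free ground truth for exact-recovery tests.
noiselessTruth <- function(space, betaProm = -0.5, betaRbs = c(0.2, -0.1, -0.3),
                           gamma = NULL) {
  ord <- designFactors(space)[["gene_order"]]@levels
  if (is.null(gamma)) {
    gamma <- seq(-0.5, 0.5, length.out = length(ord))
    gamma <- gamma - mean(gamma)
  }
  names(gamma) <- ord
  groundTruth(space, beta0 = 2, betaProm = betaProm, betaRbs = betaRbs,
              gammaOrder = gamma, sigma = 0, alpha0 = -50, alpha1 = 0,
              lod = 0, seed = 1L)
}
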