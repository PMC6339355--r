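## Part-library ingestion, ranking and export (the datasheet-to-DoE stage).

#' Load a part library from a CSV datasheet export
#'
#' Reads a comma-delimited, UTF-8 table of characterised parts with header
#' columns `part_id, name, part_class, native_host, sequence, strength_value,
#' strength_units, reference_standard` (an optional `rank` column is honoured
#' so that exported tables round-trip). Sequences are case-folded to upper
#' case and validated against the IUPAC nucleotide alphabet. Load order is
#' preserved.
#'
#' @param source path to the CSV file.
#' @return a validated [PartLibrary-class].
#' @examples
#' lib <- loadParts(system.file("extdata", "lycopene_demo_parts.csv",
#'                              package = "operonDesign"))
#' lib
#' @export
loadParts <- function(source) {
  if (!file.exists(source)) {
    stopWithClass("fileError", "part file not found: ", source)
  }
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(PART_COLUMNS, names(df))
  if (length(missing)) {
    stopWithClass("schemaError", "missing required column(s): ",
                  paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    stopWithClass("emptyLibraryError", "part file has no data rows: ", source)
  }
  badClass <- setdiff(unique(df$part_class), PART_CLASSES)
  if (length(badClass)) {
    stopWithClass("validationError", "unknown part_class value(s): ",
                  paste(badClass, collapse = ", "),
                  " (allowed: ", paste(PART_CLASSES, collapse = ", "), ")")
  }
  dup <- unique(df$part_id[duplicated(df$part_id)])
  if (length(dup)) {
    stopWithClass("validationError", "duplicate part_id: ",
                  paste(dup, collapse = ", "))
  }
  df$sequence <- normaliseSequence(df$sequence)
  df$strength_value <- suppressWarnings(as.numeric(df$strength_value))
  if ("rank" %in% names(df)) {
    df$rank <- suppressWarnings(as.integer(df$rank))
  } else {
    df$rank <- NA_integer_
  }
  df <- df[c(PART_COLUMNS, "rank")]
  rownames(df) <- NULL
  methods::new("PartLibrary", parts = df,
               provenance = list(source = source, loaded = Sys.time()))
}

#' Assign strength ranks within one part class
#'
#' Ranks every part of the class by its relative strength, with rank 1 the
#' weakest part. Ranks are a permutation of 1..k. Ties in strength are broken
#' lexicographically by `part_id` into distinct consecutive ranks (discrete
#' numeric factors need distinct values) and reported with a warning.
#'
#' @param library a [PartLibrary-class].
#' @param partClass the class to rank (`"promoter"`, `"rbs"`, ...).
#' @return the library with ranks assigned for that class.
#' @export
rankParts <- function(library, partClass) {
  stopifnot(is(library, "PartLibrary"))
  partClass <- match.arg(partClass, PART_CLASSES)
  p <- library@parts
  idx <- which(p$part_class == partClass)
  if (!length(idx)) {
    stopWithClass("validationError", "no parts of class '", partClass, "'")
  }
  s <- p$strength_value[idx]
  if (anyNA(s)) {
    stopWithClass("unrankedPartError",
                  "part(s) of class '", partClass, "' lack strength_value: ",
                  paste(p$part_id[idx][is.na(s)], collapse = ", "))
  }
  ties <- unique(s[duplicated(s)])
  if (length(ties)) {
    tied <- p$part_id[idx][s %in% ties]
    warning("strength ties broken by part_id for: ",
            paste(sort(tied), collapse = ", "))
  }
  ord <- order(s, p$part_id[idx])
  p$rank[idx[ord]] <- seq_along(idx)
  methods::new("PartLibrary", parts = p, provenance = library@provenance)
}

#' Export the ranked DoE-ready part table
#'
#' Writes one row per part with the full schema (including `rank`) so that
#' the file round-trips through [loadParts()] without information loss.
#' Export is refused while any promoter or RBS part is unranked, because the
#' downstream design stage treats those classes as discrete numeric factors.
#'
#' @param library a [PartLibrary-class].
#' @param destination output CSV path.
#' @return the destination path, invisibly.
#' @export
exportDoeTable <- function(library, destination) {
  stopifnot(is(library, "PartLibrary"))
  p <- library@parts
  need <- p$part_class %in% c("promoter", "rbs")
  unranked <- need & is.na(p$rank)
  if (any(unranked)) {
    stopWithClass("unrankedPartError",
                  "export refused, unranked promoter/rbs part(s): ",
                  paste(p$part_id[unranked], collapse = ", "))
  }
  utils::write.csv(p, destination, row.names = FALSE, quote = FALSE, na = "")
  invisible(destination)
}
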