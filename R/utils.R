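## Shared constants and small helpers.

## Recognised part classes for an operon toolkit.
PART_CLASSES <- c("promoter", "rbs", "cds", "terminator", "linker", "backbone")

## Part classes that must carry a non-empty DNA sequence.
SEQUENCE_REQUIRED <- c("promoter", "rbs", "cds", "terminator")

## IUPAC nucleotide alphabet (upper case).
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W",
               "K", "M", "B", "D", "H", "V", "N")

## Columns of the part-library CSV contract.
PART_COLUMNS <- c("part_id", "name", "part_class", "native_host", "sequence",
                  "strength_value", "strength_units", "reference_standard")

#' LogWorth transform of a p-value
#'
#' LogWorth is `-log10(p)`, the scale used for effect screening: a value
#' above 2 (p < 0.01) is treated as significant. Values are capped to guard
#' against p-value underflow.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param cap upper cap applied after the transform (default 320).
#' @return numeric vector of LogWorth values.
#' @examples
#' logWorth(c(0.01, 1))
#' @export
logWorth <- function(p, cap = 320) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  pmin(-log10(p), cap)
}

## Row-major well labels for a plate format (A1..A12, B1.. for 96).
wellLabels <- function(format = 96) {
  format <- as.integer(format)
  if (format == 96L) {
    as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  } else if (format == 384L) {
    as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
  } else {
    stop("unsupported plate format: ", format)
  }
}

## All permutations of 1..n in lexicographic order, one per row.
permutationsLex <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsLex(n - 1L)
  elems <- seq_len(n)
  blocks <- lapply(elems, function(i) {
    rest <- elems[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

## Validate a DNA sequence against the IUPAC alphabet; returns upper case.
normaliseSequence <- function(x) {
  x <- toupper(x)
  bad <- vapply(strsplit(x, ""), function(ch) {
    length(ch) > 0L && !all(ch %in% IUPAC_DNA)
  }, logical(1))
  if (any(bad)) {
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  x
}

## stop() with a condition class so callers can distinguish failure modes.
stopWithClass <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
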