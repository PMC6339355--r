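## Factor structure of the operon library and full-factorial enumeration.

#' Build the design space of an operon library
#'
#' Defines the experimental factors of the combinatorial operon: one
#' discrete-numeric promoter factor, one discrete-numeric RBS factor per gene
#' position, and a categorical gene-order factor whose levels are all
#' permutations of the gene list. Discrete-numeric levels are the ranked
#' parts, ordered by rank (1 = weakest). Each RBS level maps 1:1 to the
#' assembly linker that carries it.
#'
#' @param library a ranked [PartLibrary-class] containing at least one part
#'   of each of the classes promoter, rbs, cds, terminator and backbone.
#' @param genes character vector of CDS part_ids in declared pathway order;
#'   defaults to all CDS parts in load order.
#' @param geneCodes single-letter codes used to label gene-order levels
#'   (e.g. `c("E","B","I")`); defaults to `LETTERS` positions.
#' @param rbsLinkerMap named character vector mapping each rbs part_id to the
#'   linker part_id embedding it. Defaults to pairing rank-ordered RBS parts
#'   with linker parts in load order; if the library carries no linker parts
#'   the RBS part stands as its own linker-embedded element.
#' @return a [DesignSpace-class].
#' @export
buildDesignSpace <- function(library, genes = NULL, geneCodes = NULL,
                             rbsLinkerMap = NULL) {
  stopifnot(is(library, "PartLibrary"))
  p <- library@parts
  required <- c("promoter", "rbs", "cds", "terminator", "backbone")
  have <- unique(p$part_class)
  missing <- setdiff(required, have)
  if (length(missing)) {
    stopWithClass("configurationError", "library is missing part class(es): ",
                  paste(missing, collapse = ", "))
  }

  proms <- partsOfClass(library, "promoter")
  rbss <- partsOfClass(library, "rbs")
  if (anyNA(proms$rank) || anyNA(rbss$rank)) {
    stopWithClass("configurationError",
                  "promoter and rbs parts must be ranked before the design space is built")
  }

  if (is.null(genes)) genes <- partsOfClass(library, "cds")$part_id
  g <- length(genes)
  if (g < 1L) stopWithClass("configurationError", "at least one gene is required")
  if (!all(genes %in% p$part_id[p$part_class == "cds"])) {
    stopWithClass("configurationError", "genes must be cds part_ids in the library")
  }
  if (is.null(geneCodes)) geneCodes <- LETTERS[seq_len(g)]
  if (length(geneCodes) != g || anyDuplicated(geneCodes)) {
    stopWithClass("configurationError", "geneCodes must be distinct, one per gene")
  }

  linkers <- partsOfClass(library, "linker")$part_id
  rbsByRank <- rbss$part_id[order(rbss$rank)]
  if (is.null(rbsLinkerMap)) {
    if (length(linkers) == nrow(rbss)) {
      rbsLinkerMap <- stats::setNames(linkers, rbsByRank)
    } else if (length(linkers) == 0L) {
      rbsLinkerMap <- stats::setNames(rbsByRank, rbsByRank)
    } else {
      stopWithClass("configurationError",
                    "cannot pair ", nrow(rbss), " rbs parts with ",
                    length(linkers), " linkers; supply rbsLinkerMap")
    }
  }
  if (!all(rbsByRank %in% names(rbsLinkerMap))) {
    stopWithClass("configurationError", "rbsLinkerMap must cover every rbs part")
  }

  promByRank <- proms$part_id[order(proms$rank)]
  promoterFactor <- methods::new(
    "FactorSpec", name = "promoter", kind = "discrete_numeric",
    levels = promByRank, numericValues = as.numeric(sort(proms$rank)),
    partMap = stats::setNames(promByRank, promByRank))

  rbsFactors <- lapply(seq_len(g), function(i) {
    methods::new("FactorSpec", name = paste0("rbs_pos", i),
                 kind = "discrete_numeric",
                 levels = rbsByRank, numericValues = as.numeric(sort(rbss$rank)),
                 partMap = rbsLinkerMap[rbsByRank])
  })

  perms <- permutationsLex(g)
  orderLabels <- apply(perms, 1L, function(ix) paste(geneCodes[ix], collapse = "-"))
  orderFactor <- methods::new("FactorSpec", name = "gene_order",
                              kind = "categorical", levels = orderLabels)
  rownames(perms) <- orderLabels

  term <- partsOfClass(library, "terminator")$part_id[1L]
  backbone <- partsOfClass(library, "backbone")$part_id[1L]

  methods::new("DesignSpace",
               factors = c(list(promoterFactor), rbsFactors, list(orderFactor)),
               genes = genes, geneCodes = geneCodes, orderPerms = perms,
               terminatorId = term, backboneId = backbone)
}

#' Enumerate every configuration of a design space
#'
#' Produces the full factorial: one row per combination of factor levels,
#' ordered lexicographically in factor-definition order (the first factor
#' varies slowest), with a dense 0-based `config_index`.
#'
#' @param space a [DesignSpace-class].
#' @return data.frame with one character column per factor (level labels)
#'   plus `config_index`.
#' @export
enumerateConfigurations <- function(space) {
  stopifnot(is(space, "DesignSpace"))
  lvls <- lapply(space@factors, function(f) f@levels)
  names(lvls) <- vapply(space@factors, function(f) f@name, character(1))
  ## expand.grid varies the first column fastest; reverse for lexicographic
  ## order in factor-definition order.
  grid <- expand.grid(rev(lvls), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  stopifnot(nrow(grid) == prod(vapply(lvls, length, numeric(1))))
  grid$config_index <- seq_len(nrow(grid)) - 1L
  rownames(grid) <- NULL
  grid
}

#' Realise configurations as ordered constructs
#'
#' Maps each configuration to the ordered DNA elements of a BASIC-style
#' assembly: `[promoter, linker(rbs1), cds_1, linker(rbs2), cds_2, ...,
#' terminator]` plus the backbone, where the gene-order level decides which
#' CDS occupies each position and each RBS level contributes the linker that
#' carries it.
#'
#' @param space a [DesignSpace-class].
#' @param configurations data.frame of configurations as returned by
#'   [enumerateConfigurations()] (any subset of rows).
#' @return data.frame with `config_index`, `stitch_id` (unset), `promoter`,
#'   `linker_1`, `cds_1`, ..., `terminator`, `backbone` columns of part_ids.
#' @export
configurationToConstruct <- function(space, configurations) {
  stopifnot(is(space, "DesignSpace"))
  cfg <- as.data.frame(configurations, stringsAsFactors = FALSE)
  facs <- designFactors(space)
  need <- names(facs)
  if (!all(need %in% names(cfg))) {
    stopWithClass("mappingError", "configurations lack factor column(s): ",
                  paste(setdiff(need, names(cfg)), collapse = ", "))
  }
  for (nm in need) {
    bad <- setdiff(unique(cfg[[nm]]), facs[[nm]]@levels)
    if (length(bad)) {
      stopWithClass("mappingError", "level(s) not defined for factor '", nm,
                    "': ", paste(bad, collapse = ", "))
    }
  }
  g <- length(space@genes)
  n <- nrow(cfg)
  out <- data.frame(config_index = if ("config_index" %in% names(cfg))
    cfg$config_index else seq_len(n) - 1L,
    stitch_id = NA_character_, stringsAsFactors = FALSE)
  promMap <- facs[["promoter"]]@partMap
  out$promoter <- unname(promMap[cfg$promoter])
  perms <- space@orderPerms
  for (i in seq_len(g)) {
    rbsName <- paste0("rbs_pos", i)
    linkMap <- facs[[rbsName]]@partMap
    out[[paste0("linker_", i)]] <- unname(linkMap[cfg[[rbsName]]])
    sel <- perms[cfg$gene_order, i]
    out[[paste0("cds_", i)]] <- space@genes[sel]
  }
  out$terminator <- space@terminatorId
  out$backbone <- space@backboneId
  ## reorder columns into assembly template order
  elem <- c("promoter",
            as.vector(rbind(paste0("linker_", seq_len(g)),
                            paste0("cds_", seq_len(g)))),
            "terminator", "backbone")
  out[c("config_index", "stitch_id", elem)]
}

## Element column names of a construct table for a g-gene operon,
## in transfer/template order.
constructElementColumns <- function(g) {
  c("promoter",
    as.vector(rbind(paste0("linker_", seq_len(g)), paste0("cds_", seq_len(g)))),
    "terminator", "backbone")
}
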