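## Build coordination: stitch IDs, source-plate lookup, picklist planning.

#' Assign stitch IDs to constructs
#'
#' Gives every construct a unique, zero-padded identifier in `config_index`
#' order (`S001`, `S002`, ...). Re-running on an already fully labelled table
#' returns it unchanged (idempotent); partial labelling or duplicate
#' pre-existing IDs is a collision error.
#'
#' @param constructs construct table from [configurationToConstruct()].
#' @param prefix ID prefix (default `"S"`).
#' @return the construct table with `stitch_id` filled in.
#' @export
assignStitchIds <- function(constructs, prefix = "S") {
  stopifnot(is.data.frame(constructs), nrow(constructs) > 0L)
  ids <- constructs$stitch_id
  if (all(!is.na(ids))) {
    if (anyDuplicated(ids)) {
      stopWithClass("collisionError", "pre-existing stitch IDs collide: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    return(constructs)
  }
  if (any(!is.na(ids))) {
    stopWithClass("collisionError",
                  "constructs are partially labelled; clear stitch_id or label all")
  }
  n <- nrow(constructs)
  width <- max(3L, nchar(as.character(n)))
  ord <- order(constructs$config_index)
  constructs$stitch_id[ord] <- sprintf(paste0(prefix, "%0", width, "d"),
                                       seq_len(n))
  constructs
}

#' Read a source-plate layout CSV
#'
#' Expects columns `plate_name, well, content_id, concentration, units`.
#'
#' @param path CSV path.
#' @param format wells per source plate (96 or 384).
#' @return a [PlateLayout-class].
#' @export
readPlateLayout <- function(path, format = 96) {
  if (!file.exists(path)) stopWithClass("fileError", "layout file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods::new("PlateLayout", layout = df, format = as.integer(format))
}

#' Construct an assembly configuration
#'
#' @param dropletNl droplet quantum in nL.
#' @param partVolumeNl,linkerVolumeNl,mixVolumeNl requested volumes in nL.
#' @param maxWellVolumeNl destination well capacity in nL.
#' @param partConcNM,linkerConcUM working concentrations.
#' @param destinationPlate destination plate name.
#' @param destinationFormat destination plate format (96 or 384).
#' @param mixContentId content_id of the shared master mix, or `NA` to omit.
#' @return an [AssemblyConfig-class].
#' @export
assemblyConfig <- function(dropletNl = 2.5, partVolumeNl = 25,
                           linkerVolumeNl = 25, mixVolumeNl = 500,
                           maxWellVolumeNl = 12000, partConcNM = 76,
                           linkerConcUM = 1, destinationPlate = "assembly_1",
                           destinationFormat = 96,
                           mixContentId = "master_mix") {
  methods::new("AssemblyConfig", dropletNl = dropletNl,
               partVolumeNl = partVolumeNl, linkerVolumeNl = linkerVolumeNl,
               mixVolumeNl = mixVolumeNl, maxWellVolumeNl = maxWellVolumeNl,
               partConcNM = partConcNM, linkerConcUM = linkerConcUM,
               destinationPlate = destinationPlate,
               destinationFormat = as.integer(destinationFormat),
               mixContentId = as.character(mixContentId))
}

## Round a volume UP to the next droplet multiple.
quantiseVolume <- function(v, droplet) {
  ceiling(v / droplet - 1e-9) * droplet
}

#' Plan the assembly picklist for a set of constructs
#'
#' Allocates one destination well per construct (row-major fill: A1, A2, ...)
#' and emits one transfer per DNA element plus one for the shared master mix,
#' looking each content_id up on the source plates. Volumes are rounded up to
#' the droplet quantum. The plan is a pure function of its inputs: repeated
#' calls give identical picklists.
#'
#' @param constructs labelled construct table ([assignStitchIds()]).
#' @param layout a [PlateLayout-class] of source plates.
#' @param config an [AssemblyConfig-class].
#' @return a [Picklist-class].
#' @export
planAssembly <- function(constructs, layout, config = assemblyConfig()) {
  stopifnot(is.data.frame(constructs), is(layout, "PlateLayout"),
            is(config, "AssemblyConfig"))
  if (any(is.na(constructs$stitch_id))) {
    stopWithClass("validationError", "constructs must carry stitch IDs")
  }
  g <- sum(grepl("^cds_", names(constructs)))
  elemCols <- constructElementColumns(g)
  lay <- layout@layout
  lookup <- function(contentId, stitchId) {
    hit <- which(lay$content_id == contentId)
    if (!length(hit)) {
      stopWithClass("provenanceError", "part '", contentId, "' for construct ",
                    stitchId, " not found on any source plate")
    }
    lay[hit[1L], c("plate_name", "well")]
  }
  destWells <- wellLabels(config@destinationFormat)
  n <- nrow(constructs)
  if (n > length(destWells)) {
    stopWithClass("capacityError", n, " constructs exceed the ",
                  length(destWells), "-well destination plate")
  }
  ord <- order(constructs$stitch_id)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    sid <- constructs$stitch_id[i]
    dest <- destWells[k]
    contents <- unlist(constructs[i, elemCols], use.names = TRUE)
    vols <- ifelse(grepl("^linker_", names(contents)),
                   config@linkerVolumeNl, config@partVolumeNl)
    if (!is.na(config@mixContentId) && nzchar(config@mixContentId)) {
      contents <- c(contents, mix = config@mixContentId)
      vols <- c(vols, config@mixVolumeNl)
    }
    src <- do.call(rbind, lapply(unname(contents), lookup, stitchId = sid))
    rows[[k]] <- data.frame(
      source_plate = src$plate_name, source_well = src$well,
      destination_plate = config@destinationPlate, destination_well = dest,
      volume_nl = quantiseVolume(vols, config@dropletNl),
      stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, rows)
  rownames(tr) <- NULL
  totals <- tapply(tr$volume_nl, tr$destination_well, sum)
  over <- totals > config@maxWellVolumeNl
  if (any(over)) {
    stopWithClass("capacityError", "destination well(s) over capacity: ",
                  paste(names(totals)[over], collapse = ", "))
  }
  methods::new("Picklist", transfers = tr,
               destinationTotals = stats::setNames(as.numeric(totals), names(totals)),
               dropletNl = config@dropletNl)
}

PICKLIST_HEADER <- paste("Source Plate Name", "Source Well",
                         "Destination Plate Name", "Destination Well",
                         "Transfer Volume", sep = ",")

#' Write a picklist CSV
#'
#' Emits the instrument dialect: header
#' `Source Plate Name,Source Well,Destination Plate Name,Destination Well,Transfer Volume`,
#' volumes in nL, rows in transfer order. An empty picklist produces a
#' header-only file with a warning.
#'
#' @param picklist a [Picklist-class].
#' @param destination output path.
#' @return the destination path, invisibly.
#' @export
writePicklist <- function(picklist, destination) {
  stopifnot(is(picklist, "Picklist"))
  tr <- picklist@transfers
  if (nrow(tr) == 0L) {
    warning("picklist is empty; writing header only")
    writeLines(PICKLIST_HEADER, destination)
    return(invisible(destination))
  }
  vol <- format(tr$volume_nl, trim = TRUE, scientific = FALSE,
                drop0trailing = TRUE)
  lines <- paste(tr$source_plate, tr$source_well, tr$destination_plate,
                 tr$destination_well, vol, sep = ",")
  writeLines(c(PICKLIST_HEADER, lines), destination)
  invisible(destination)
}

#' Read a picklist CSV written by [writePicklist()]
#'
#' @param path picklist path.
#' @return data.frame with the five picklist columns.
#' @export
readPicklist <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- strsplit(PICKLIST_HEADER, ",")[[1]]
  if (!identical(names(df), expected)) {
    stopWithClass("schemaError", "not a picklist file: ", path)
  }
  df
}
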