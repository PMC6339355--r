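## Coded model matrices: linear terms for discrete-numeric factors,
## sum-to-zero (effects) coding for categorical factors.

#' Specify the linear effect model for a design space
#'
#' The default screening model carries an intercept plus one main effect per
#' factor: discrete-numeric factors enter as a single linear column on coded
#' ranks, categorical factors as an effects-coded block (k levels give k-1
#' columns, with the last level coded -1 in every column so effects sum to
#' zero). Optional two-factor interactions are the columnwise products of the
#' two main-effect blocks. Single-level factors carry no information and are
#' dropped from the default model; requesting one explicitly is an error at
#' encoding time.
#'
#' @param space a [DesignSpace-class].
#' @param factors factor names to include as main effects; default all
#'   factors with more than one level.
#' @param interactions list of length-2 character vectors of factor names.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(space, factors = NULL, interactions = list()) {
  stopifnot(is(space, "DesignSpace"))
  facs <- designFactors(space)
  if (is.null(factors)) {
    factors <- names(facs)[vapply(facs, function(f) length(f@levels) > 1L,
                                  logical(1))]
  }
  unknown <- setdiff(factors, names(facs))
  if (length(unknown)) {
    stopWithClass("configurationError", "unknown factor(s): ",
                  paste(unknown, collapse = ", "))
  }
  ncols <- function(nm) {
    f <- facs[[nm]]
    if (f@kind == "discrete_numeric") 1L else length(f@levels) - 1L
  }
  p <- 1L + sum(vapply(factors, ncols, integer(1)))
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% factors)) {
      stopWithClass("configurationError",
                    "interactions must pair two modelled factors")
    }
    p <- p + ncols(ia[1L]) * ncols(ia[2L])
  }
  methods::new("ModelSpec", factorNames = factors, interactions = interactions,
               p = as.integer(p))
}

## Coded columns of one factor for a vector of level labels.
## Numeric: x = 2 (r - r_min) / (r_max - r_min) - 1 on the rank values.
## Categorical: k-1 indicator columns, last level coded -1 everywhere.
factorBlock <- function(f, labels) {
  i <- match(labels, f@levels)
  if (anyNA(i)) {
    stopWithClass("mappingError", "level(s) not defined for factor '",
                  f@name, "': ", paste(unique(labels[is.na(i)]), collapse = ", "))
  }
  if (f@kind == "discrete_numeric") {
    r <- f@numericValues
    if (length(r) < 2L || max(r) == min(r)) {
      stopWithClass("degenerateTermError", "factor '", f@name,
                    "' has a single level and cannot enter the model")
    }
    x <- matrix(2 * (r[i] - min(r)) / (max(r) - min(r)) - 1, ncol = 1L)
    colnames(x) <- f@name
    x
  } else {
    k <- length(f@levels)
    if (k < 2L) {
      stopWithClass("degenerateTermError", "factor '", f@name,
                    "' has a single level and cannot enter the model")
    }
    x <- matrix(0, length(i), k - 1L,
                dimnames = list(NULL, paste0(f@name, "[", f@levels[-k], "]")))
    for (j in seq_len(k - 1L)) x[i == j, j] <- 1
    x[i == k, ] <- -1
    x
  }
}

#' Encode the coded model matrix for a set of configurations
#'
#' @param space a [DesignSpace-class].
#' @param configurations data.frame with one level-label column per factor.
#' @param model a [ModelSpec-class] from [modelSpec()].
#' @return numeric matrix with `model@p` columns; attribute `"term"` labels
#'   each column with the model term it belongs to.
#' @export
encodeModelMatrix <- function(space, configurations, model) {
  stopifnot(is(space, "DesignSpace"), is(model, "ModelSpec"))
  cfg <- as.data.frame(configurations, stringsAsFactors = FALSE)
  facs <- designFactors(space)
  n <- nrow(cfg)
  blocks <- list(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  terms <- "(Intercept)"
  main <- list()
  for (nm in model@factorNames) {
    if (!nm %in% names(cfg)) {
      stopWithClass("mappingError", "configurations lack factor column '", nm, "'")
    }
    b <- factorBlock(facs[[nm]], cfg[[nm]])
    main[[nm]] <- b
    blocks <- c(blocks, list(b))
    terms <- c(terms, rep(nm, ncol(b)))
  }
  for (ia in model@interactions) {
    a <- main[[ia[1L]]]; b <- main[[ia[2L]]]
    cols <- list()
    nms <- character()
    for (j in seq_len(ncol(a))) {
      for (k in seq_len(ncol(b))) {
        cols <- c(cols, list(a[, j] * b[, k]))
        nms <- c(nms, paste0(colnames(a)[j], ":", colnames(b)[k]))
      }
    }
    m <- do.call(cbind, cols)
    colnames(m) <- nms
    blocks <- c(blocks, list(m))
    terms <- c(terms, rep(paste(ia, collapse = ":"), ncol(m)))
  }
  X <- do.call(cbind, blocks)
  stopifnot(ncol(X) == model@p)
  attr(X, "term") <- terms
  X
}
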