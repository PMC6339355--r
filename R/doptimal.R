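## D-optimal run selection by coordinate (row) exchange over the full
## candidate list, best of several random starts.

dEfficiencyFromMatrix <- function(X) {
  p <- ncol(X)
  n <- nrow(X)
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus)) {
    stopWithClass("singularDesignError",
                  "design information matrix is singular; D-efficiency undefined")
  }
  100 * exp(as.numeric(d$modulus) / p) / n
}

logDetInfo <- function(X) {
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

## One exchange search from a starting index set. Returns list(idx, logDet,
## trace). Monotone: a row swap is accepted only if it improves det(X'X) by
## a relative factor > tol.
exchangeSearch <- function(C, idx, allowReplicates, maxPasses, tol) {
  n <- length(idx)
  X <- C[idx, , drop = FALSE]
  M <- crossprod(X)
  Minv <- solve(M)
  ld <- logDetInfo(X)
  trace <- ld
  for (pass in seq_len(maxPasses)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      xi <- X[i, ]
      di <- drop(crossprod(xi, Minv %*% xi))
      B <- C %*% Minv
      dj <- rowSums(B * C)
      dij <- drop(B %*% xi)
      ## determinant ratio after swapping row i for candidate j
      ratio <- (1 - di) * (1 + dj) + dij^2
      if (!allowReplicates) ratio[idx[-i]] <- -Inf
      j <- which.max(ratio)
      if (ratio[j] > 1 + tol) {
        idx[i] <- j
        xj <- C[j, ]
        M <- M - tcrossprod(xi) + tcrossprod(xj)
        Minv <- solve(M)
        X[i, ] <- xj
        ld <- ld + log(ratio[j])
        trace <- c(trace, ld)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ## recompute exactly to shed accumulated rounding
  ld <- logDetInfo(X)
  trace[length(trace)] <- ld
  list(idx = idx, logDet = ld, trace = trace)
}

#' Select a D-optimal reduced design by coordinate exchange
#'
#' Reduces the full factorial candidate set to `nRuns` runs maximising
#' det(X'X) of the coded model matrix. For each of `nStarts` random starting
#' designs, every design row in turn is tested against every candidate row
#' and swapped for the best replacement whenever the determinant improves
#' (relative improvement > 1e-9); sweeps repeat until a full pass makes no
#' change (at most 50 passes). The best start wins. Runs are distinct by
#' default; `allowReplicates = TRUE` permits repeated runs. Reproducible
#' given `(seed, nStarts)`.
#'
#' @param space a [DesignSpace-class].
#' @param model a [ModelSpec-class]; `nRuns` must be at least `model@p`.
#' @param nRuns number of runs to select.
#' @param seed integer seed for the random starts.
#' @param nStarts number of random starts (default 10).
#' @param allowReplicates permit duplicate runs (default FALSE).
#' @param maxPasses sweep limit per start (default 50).
#' @param tol relative determinant improvement needed to accept a swap.
#' @return a [ReducedDesign-class].
#' @examples
#' lib <- lycopeneLibrary()
#' space <- buildDesignSpace(lib, genes = c("crtE", "crtB", "crtI"),
#'                           geneCodes = c("E", "B", "I"))
#' des <- selectDOptimal(space, modelSpec(space), nRuns = 88, seed = 17)
#' des
#' @export
selectDOptimal <- function(space, model, nRuns, seed, nStarts = 10L,
                           allowReplicates = FALSE, maxPasses = 50L,
                           tol = 1e-9) {
  stopifnot(is(space, "DesignSpace"), is(model, "ModelSpec"))
  nRuns <- as.integer(nRuns)
  if (nRuns < model@p) {
    stopWithClass("infeasibleDesignError", "nRuns (", nRuns,
                  ") must be at least the model column count p (", model@p, ")")
  }
  configs <- enumerateConfigurations(space)
  C <- encodeModelMatrix(space, configs, model)
  N <- nrow(C)
  if (!allowReplicates && nRuns > N) {
    stopWithClass("infeasibleDesignError",
                  "nRuns exceeds the candidate count without replicates")
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nStarts)) {
    idx <- NULL
    for (try in seq_len(100L)) {
      cand <- if (allowReplicates) sample.int(N, nRuns, replace = TRUE)
              else sample.int(N, nRuns)
      if (is.finite(logDetInfo(C[cand, , drop = FALSE]))) {
        idx <- cand
        break
      }
    }
    if (is.null(idx)) {
      stopWithClass("singularDesignError",
                    "no nonsingular starting design found in 100 draws")
    }
    res <- exchangeSearch(C, idx, allowReplicates, maxPasses, tol)
    if (is.null(best) || res$logDet > best$logDet) best <- res
  }
  runIdx <- sort(best$idx)
  X <- C[runIdx, , drop = FALSE]
  runs <- configs[runIdx, , drop = FALSE]
  rownames(runs) <- NULL
  methods::new("ReducedDesign",
               runIndices = as.integer(runIdx - 1L), runs = runs,
               nRuns = nRuns, candidateCount = as.integer(N),
               logDet = logDetInfo(X), dEfficiency = dEfficiencyFromMatrix(X),
               seed = as.integer(seed), nStarts = as.integer(nStarts),
               traceLogDet = best$trace)
}

#' Exhaustive D-optimal search over all run subsets
#'
#' Brute-force reference for small candidate sets: evaluates det(X'X) for
#' every distinct `nRuns`-subset of the candidates and returns the maximum
#' log determinant. Intended as an independent check of the exchange search;
#' infeasible beyond a few thousand subsets.
#'
#' @param C coded candidate model matrix.
#' @param nRuns subset size.
#' @return list with `logDet` (the maximum) and `idx` (one maximising subset).
#' @export
exhaustiveDOptimal <- function(C, nRuns) {
  N <- nrow(C)
  stopifnot(nRuns <= N)
  combs <- utils::combn(N, nRuns)
  bestLd <- -Inf
  bestIdx <- NULL
  for (j in seq_len(ncol(combs))) {
    ld <- logDetInfo(C[combs[, j], , drop = FALSE])
    if (ld > bestLd) {
      bestLd <- ld
      bestIdx <- combs[, j]
    }
  }
  list(logDet = bestLd, idx = bestIdx)
}

#' Export a reduced design as a plain factor table
#'
#' One row per selected run with the rank value of each discrete-numeric
#' factor, the label of each categorical factor, `config_index` and
#' `stitch_id` (if assigned) -- importable by DoE software as a factor table.
#'
#' @param design a [ReducedDesign-class].
#' @param space the [DesignSpace-class] the design was selected from.
#' @return data.frame.
#' @export
designTable <- function(design, space) {
  stopifnot(is(design, "ReducedDesign"), is(space, "DesignSpace"))
  runs <- design@runs
  out <- data.frame(row.names = seq_len(nrow(runs)))
  for (f in space@factors) {
    if (f@kind == "discrete_numeric") {
      out[[f@name]] <- f@numericValues[match(runs[[f@name]], f@levels)]
    } else {
      out[[f@name]] <- runs[[f@name]]
    }
  }
  out$config_index <- runs$config_index
  out$stitch_id <- if ("stitch_id" %in% names(runs)) runs$stitch_id else NA_character_
  out
}
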