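## Least-squares effect screening with partial-F LogWorth statistics, and
## prediction of the titre-maximising configuration.

## QR fit returning coefficients and RSS; errors on rank deficiency with the
## aliased columns named.
qrFit <- function(X, y, onAliased = c("error", "silent")) {
  onAliased <- match.arg(onAliased)
  q <- qr(X)
  if (q$rank < ncol(X) && onAliased == "error") {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stopWithClass("aliasingError",
                  "model matrix is rank deficient; confounded column(s): ",
                  paste(aliased, collapse = ", "))
  }
  co <- qr.coef(q, y)
  fitted <- qr.fitted(q, y)
  list(coef = co, rss = sum((y - fitted)^2), rank = q$rank)
}

#' Fit the least-squares effect model to observed titres
#'
#' Joins the selected design runs to titre records on `stitch_id`, keeps
#' producing constructs only (failed assemblies and undetected product are
#' excluded, as the screening analysis models producers), reduces replicates
#' to the per-construct mean titre by default, and fits ordinary least
#' squares on the coded model matrix.
#'
#' @param design data.frame of design runs: `stitch_id` plus one level-label
#'   column per factor (e.g. [designRuns()] after stitch assignment).
#' @param titres titre-record table with `stitch_id`, `titre_mg_per_gdcw`,
#'   `detected`.
#' @param space the [DesignSpace-class].
#' @param model a [ModelSpec-class].
#' @param perReplicate fit one observation per detected replicate instead of
#'   per-construct means.
#' @return an [EffectFit-class].
#' @export
fitEffects <- function(design, titres, space, model, perReplicate = FALSE) {
  stopifnot(is(space, "DesignSpace"), is(model, "ModelSpec"))
  obs <- titres[titres$detected & !is.na(titres$titre_mg_per_gdcw), , drop = FALSE]
  if (!perReplicate && nrow(obs)) {
    agg <- stats::aggregate(titre_mg_per_gdcw ~ stitch_id, data = obs, FUN = mean)
    obs <- agg
  }
  merged <- merge(obs, design, by = "stitch_id", sort = TRUE)
  n <- nrow(merged)
  if (n < model@p) {
    stopWithClass("infeasibleFitError", n,
                  " producing observation(s) for a model with p = ", model@p)
  }
  X <- encodeModelMatrix(space, merged, model)
  y <- merged$titre_mg_per_gdcw
  fit <- qrFit(X, y, onAliased = "error")
  df <- n - model@p
  sigma2 <- if (df > 0L) fit$rss / df else NA_real_
  methods::new("EffectFit",
               coefficients = stats::setNames(as.numeric(fit$coef), colnames(X)),
               residualDf = as.integer(df), sigma2 = sigma2, model = model,
               nObs = as.integer(n), X = X, y = y,
               termLabels = attr(X, "term"))
}

#' Effect summary: partial F tests and LogWorth per model term
#'
#' For each factor (and interaction) in the model, compares the full fit with
#' the fit dropping that term's columns (a Type-III-style partial F test
#' under sum-to-zero coding, matching DoE effect-summary semantics). LogWorth
#' is `-log10(p)`, capped at 320; a term is flagged significant when LogWorth
#' strictly exceeds 2 (p < 0.01). Rows are sorted by LogWorth descending.
#'
#' @param fit an [EffectFit-class] with residual df >= 1.
#' @return data.frame with columns `factor`, `df`, `F`, `p_value`,
#'   `log_worth`, `significant`.
#' @export
effectSummary <- function(fit) {
  stopifnot(is(fit, "EffectFit"))
  if (fit@residualDf < 1L) {
    stopWithClass("infeasibleFitError",
                  "effect tests need residual df >= 1")
  }
  terms <- setdiff(unique(fit@termLabels), "(Intercept)")
  fullRss <- sum((fit@y - fit@X %*% fit@coefficients)^2)
  sigma2 <- fullRss / fit@residualDf
  zeroVar <- sigma2 <= 1e-25
  if (zeroVar) {
    warning("residual variance is zero; p-values reported at the LogWorth cap")
  }
  rows <- lapply(terms, function(tm) {
    keep <- fit@termLabels != tm
    red <- qrFit(fit@X[, keep, drop = FALSE], fit@y, onAliased = "silent")
    q <- sum(!keep)
    if (zeroVar) {
      p <- 10^(-320)
      Fstat <- Inf
    } else {
      Fstat <- ((red$rss - fullRss) / q) / sigma2
      Fstat <- max(Fstat, 0)
      p <- stats::pf(Fstat, q, fit@residualDf, lower.tail = FALSE)
      p <- min(max(p, 10^(-320)), 1)
    }
    lw <- logWorth(p)
    data.frame(factor = tm, df = q, F = Fstat, p_value = p, log_worth = lw,
               significant = lw > 2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$log_worth, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the titre-maximising configurations
#'
#' Evaluates the fitted linear predictor for every configuration in the
#' design space and returns the top-ranked ones. Ranks are dense over the
#' whole candidate set; predictions equal within numerical tolerance share a
#' rank and are all reported, so a tie at rank 1 returns every co-optimum.
#'
#' @param fit an [EffectFit-class].
#' @param space the [DesignSpace-class].
#' @param topK number of ranks to return (default 5).
#' @return data.frame of configurations with `predicted_titre` and `rank`,
#'   all rows whose rank is at most `topK`.
#' @export
predictOptimum <- function(fit, space, topK = 5L) {
  stopifnot(is(fit, "EffectFit"), is(space, "DesignSpace"))
  configs <- enumerateConfigurations(space)
  X <- encodeModelMatrix(space, configs, fit@model)
  pred <- as.numeric(X %*% fit@coefficients)
  ord <- order(pred, decreasing = TRUE)
  v <- pred[ord]
  tol <- 1e-8 * max(1, diff(range(v)))
  newGroup <- c(TRUE, (v[-length(v)] - v[-1L]) > tol)
  rank <- cumsum(newGroup)
  out <- configs[ord, , drop = FALSE]
  out$predicted_titre <- v
  out$rank <- rank
  out <- out[out$rank <= topK, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Logistic fit of assembly/growth failure against promoter strength
#'
#' Quantifies the observed trend that stronger promoters fail more often:
#' fits `failed ~ coded promoter strength` by logistic regression over the
#' screened constructs.
#'
#' @param design data.frame of design runs with `stitch_id` and factor
#'   level-label columns.
#' @param titres titre-record table; a construct counts as failed when no
#'   replicate has detectable product.
#' @param space the [DesignSpace-class].
#' @return a `glm` object (binomial family).
#' @export
fitFailureModel <- function(design, titres, space) {
  stopifnot(is(space, "DesignSpace"))
  produced <- tapply(titres$detected, titres$stitch_id, any)
  df <- data.frame(stitch_id = names(produced),
                   failed = as.numeric(!produced), stringsAsFactors = FALSE)
  merged <- merge(df, design, by = "stitch_id")
  prom <- designFactors(space)[["promoter"]]
  merged$x_prom <- factorBlock(prom, merged$promoter)[, 1L]
  stats::glm(failed ~ x_prom, family = stats::binomial(), data = merged)
}
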