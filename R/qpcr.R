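#' Relative gene expression from a Ct table (delta-delta-Ct)
#'
#' Computes the fold expression of a target gene relative to a reference
#' (housekeeping, e.g. 16S rRNA) gene across groups, against a calibrator
#' group: `dCt_g = Ct_target,g - Ct_ref,g` and
#' `fold_g = efficiency^-(dCt_g - dCt_calibrator)`. With `efficiency = 2`
#' (perfect doubling, the default) this is the classical 2^-ddCt method; the
#' efficiency is exposed as a parameter for Pfaffl-style correction.
#'
#' @param table Data frame with columns `sample`, `group`, `gene`
#'   (values `"target"` / `"reference"`), `ct` (cycles), `replicate`.
#'   Rows with non-finite Ct are rejected with a message.
#' @param calibrator Group label serving as the fold-1 baseline.
#' @param efficiency Amplification factor per cycle, in `(1, 2]`.
#' @param aggregation `"replicate"` (default): pair target and reference Ct
#'   by replicate index within each group, compute a fold per replicate
#'   against the calibrator's mean dCt, then average; falls back to
#'   `"mean_ct"` (group-mean Ct) for any group whose replicate counts
#'   differ between genes.
#' @return Data frame with one row per group: `group`, `fold`, `sd`
#'   (dispersion of replicate folds, `NA` under mean-Ct aggregation), `n`.
#'   The calibrator's fold is 1 by construction at zero noise.
#' @export
relative_expression <- function(table, calibrator,
                                efficiency = 2,
                                aggregation = c("replicate", "mean_ct")) {
  aggregation <- match.arg(aggregation)
  req <- c("sample", "group", "gene", "ct", "replicate")
  if (!all(req %in% names(table)))
    stop("Ct table must have columns: ", paste(req, collapse = ", "))
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  bad <- !is.finite(table$ct)
  if (any(bad)) {
    message(sum(bad), " row(s) with non-finite Ct rejected")
    table <- table[!bad, , drop = FALSE]
  }
  groups <- unique(table$group)
  if (!calibrator %in% groups)
    stop("calibrator group '", calibrator, "' not present in the table")
  dct_of <- function(g) {
    tg <- table[table$group == g & table$gene == "target", , drop = FALSE]
    rf <- table[table$group == g & table$gene == "reference", , drop = FALSE]
    if (nrow(rf) == 0L)
      stop("group '", g, "' is missing reference-gene measurements")
    if (nrow(tg) == 0L)
      stop("group '", g, "' is missing target-gene measurements")
    if (aggregation == "replicate" && nrow(tg) == nrow(rf)) {
      tg <- tg[order(tg$replicate), ]
      rf <- rf[order(rf$replicate), ]
      tg$ct - rf$ct
    } else {
      mean(tg$ct) - mean(rf$ct)     # mean-Ct fallback
    }
  }
  dct_cal <- mean(dct_of(calibrator))
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- dct_of(g)
    folds <- efficiency^-(d - dct_cal)
    data.frame(group = g, fold = mean(folds),
               sd = if (length(folds) > 1) stats::sd(folds) else NA_real_,
               n = length(folds), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
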