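# Cross-method comparison: category cross-tabulations, overall and per-class
# concordance percentages, and the fine ratio bins used for equivocal-range
# analyses.

#' Concordance between a reference and a test categorisation
#'
#' Cross-tabulates reference against test calls and reports the percentage
#' of cases on the diagonal, overall and per reference class. Cases with a
#' missing call on either side (e.g. QC-rejected cases) are excluded and
#' reported in `n_excluded`.
#'
#' @param reference,test character vectors of equal length over the same
#'   category alphabet.
#' @param levels category levels in display order; defaults to the standard
#'   amplification categories when applicable, otherwise the sorted union.
#' @return an object of class `concordance_report`: list with `table`
#'   (reference rows x test columns), `overall_pct`, `per_class_pct`, `n`,
#'   `n_excluded`.
#' @export
concordance <- function(reference, test, levels = NULL) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length", call. = FALSE)
  keep <- !is.na(reference) & !is.na(test)
  n_excluded <- sum(!keep)
  reference <- as.character(reference[keep])
  test <- as.character(test[keep])
  if (length(reference) == 0)
    stop("no scorable cases", call. = FALSE)
  if (is.null(levels)) {
    std <- c("nonamplified", "equivocal", "amplified")
    obs <- unique(c(reference, test))
    levels <- if (all(obs %in% std)) std else sort(obs)
  }
  bad <- setdiff(unique(c(reference, test)), levels)
  if (length(bad))
    stop("categories outside the level set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tab <- table(reference = factor(reference, levels),
               test = factor(test, levels))
  n <- sum(tab)
  overall <- 100 * sum(diag(tab)) / n
  row_n <- rowSums(tab)
  per_class <- ifelse(row_n > 0, 100 * diag(tab) / row_n, NA_real_)
  structure(list(table = tab, overall_pct = overall,
                 per_class_pct = setNames(as.numeric(per_class), levels),
                 n = n, n_excluded = n_excluded),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance: %d cases%s>\n", x$n,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  print(x$table)
  cat(sprintf("overall: %.1f%%\n", x$overall_pct))
  pc <- x$per_class_pct[!is.na(x$per_class_pct)]
  if (length(pc))
    cat(paste(sprintf("  %s: %.1f%%", names(pc), pc), collapse = "\n"), "\n")
  invisible(x)
}

#' Bin a HER2/CEP17 ratio into the fine equivocal-range bins
#'
#' The four bins used when dissecting borderline cases: below the equivocal
#' band, the lower and upper halves of the band (split at the treatment
#' eligibility cutoff 2.0, with 2.2 included in the upper bin), and above
#' the band. The bins partition `[0, Inf)`.
#'
#' @param ratio nonnegative finite ratio(s); vectorised.
#' @return a character vector with values among `"<1.8"`, `">=1.8-<2.0"`,
#'   `"2.0-2.2"`, `">2.2"`.
#' @export
bin_ratio <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio < 0))
    stop("ratio must be finite and nonnegative", call. = FALSE)
  ifelse(ratio < 1.8, "<1.8",
  ifelse(ratio < 2.0, ">=1.8-<2.0",
  ifelse(ratio <= 2.2, "2.0-2.2", ">2.2")))
}
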