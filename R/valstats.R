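#' Build a 2x2 confusion table
#'
#' Cross-tabulates observed vs predicted relapse status. The positive label
#' is `"relapsed"` (or `TRUE`).
#'
#' @param observed,predicted Vectors of labels, or pass `tp`, `fn`, `fp`,
#'   `tn` directly.
#' @param tp,fn,fp,tn Cell counts (observed relapse predicted relapse,
#'   observed relapse predicted non-relapse, observed non-relapse predicted
#'   relapse, observed non-relapse predicted non-relapse).
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(observed = NULL, predicted = NULL,
                            tp = NULL, fn = NULL, fp = NULL, tn = NULL) {
  if (!is.null(observed)) {
    o <- as_binary_outcome(observed) == 1
    p <- as_binary_outcome(predicted) == 1
    tp <- sum(o & p); fn <- sum(o & !p); fp <- sum(!o & p); tn <- sum(!o & !p)
  }
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) abort("Confusion cells must be >= 0.")
  structure(as.list(cells), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("Observed relapse", "Observed non-relapse"),
                              c("Pred. relapse", "Pred. non-relapse")))
  print(m)
  invisible(x)
}

# half-up rounding to integer percent, matching printed "7/8 (88%)" style
percent_half_up <- function(x) floor(100 * x + 0.5)

#' Sensitivity and specificity of a confusion table
#'
#' Exact fractions plus half-up-rounded integer percentages. A zero row
#' total leaves the corresponding metric `NaN` and flags the result.
#'
#' @param t A [confusion_table()].
#' @return Tibble `sensitivity`, `specificity`, `sensitivity_pct`,
#'   `specificity_pct`, `flagged`.
#' @export
confusion_metrics <- function(t) {
  sens <- if (t$tp + t$fn > 0) t$tp / (t$tp + t$fn) else NaN
  spec <- if (t$tn + t$fp > 0) t$tn / (t$tn + t$fp) else NaN
  tibble(sensitivity = sens, specificity = spec,
         sensitivity_pct = percent_half_up(sens),
         specificity_pct = percent_half_up(spec),
         flagged = is.nan(sens) || is.nan(spec))
}

#' Odds ratio with Woolf confidence interval
#'
#' For a binary predictor the unconditional-logistic-regression odds ratio
#' equals the cross-product ratio `(tp * tn) / (fn * fp)`; the 95% CI is
#' Woolf's (log-OR +/- 1.96 * SE with SE the square root of the summed
#' reciprocal cells) and the p-value is the Wald test of the log-OR. When
#' any cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied and the result flagged; two zero cells in one margin leave the
#' OR undefined.
#'
#' @param t A [confusion_table()].
#' @return Tibble `or_value`, `ci_low`, `ci_high`, `p_value`, `corrected`,
#'   `flagged`.
#' @export
odds_ratio <- function(t) {
  cells <- c(t$tp, t$fn, t$fp, t$tn)
  if ((t$tp + t$fn) == 0 || (t$fp + t$tn) == 0 ||
      (t$tp + t$fp) == 0 || (t$fn + t$tn) == 0) {
    return(tibble(or_value = NaN, ci_low = NaN, ci_high = NaN,
                  p_value = NaN, corrected = FALSE, flagged = TRUE))
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- 2 * pnorm(-abs(log(or)) / se)
  tibble(or_value = or, ci_low = ci[1], ci_high = ci[2], p_value = p,
         corrected = corrected, flagged = corrected)
}

#' @export
tidy.confusion_table <- function(x, ...) {
  dplyr::bind_cols(tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn),
                   confusion_metrics(x)[, 1:4], odds_ratio(x)[, 1:4])
}

#' Delta-Ct relative expression level
#'
#' Relative level of a gene against the reference gene (miR-16) in the same
#' sample: `2^(ct_ref - ct_gene)`; each PCR cycle is a doubling.
#'
#' @param ct_gene,ct_ref Finite threshold-cycle values (vectorized).
#' @return Relative levels.
#' @export
pcr_relative_level <- function(ct_gene, ct_ref) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_ref))) {
    abort("Ct values must be finite.")
  }
  2^(ct_ref - ct_gene)
}

#' miR-16-normalized log2 qPCR feature table
#'
#' Converts a long Ct table to a wide per-sample feature table of log2
#' relative levels (`ct_ref - ct_gene`) against the reference gene.
#'
#' @param pcr Long tibble `sample`, `gene`, `ct`.
#' @param genes Genes to keep as features.
#' @param reference Reference gene id (default `hsa-miR-16`).
#' @return Wide tibble: `sample` plus one log2-relative-level column per
#'   gene.
#' @export
pcr_features <- function(pcr, genes, reference = "hsa-miR-16") {
  if (!reference %in% pcr$gene) abort("Reference gene absent from Ct table.")
  wide <- tidyr::pivot_wider(pcr, names_from = "gene", values_from = "ct")
  if (!all(genes %in% names(wide))) abort("Requested gene absent from Ct table.")
  if (any(!is.finite(wide[[reference]]))) {
    abort("Reference gene Ct missing for some samples.")
  }
  out <- tibble(sample = wide$sample)
  for (g in genes) out[[g]] <- wide[[reference]] - wide[[g]]
  out
}

#' Welch t-test between two groups of log2 relative levels
#'
#' Two-sided unequal-variance t-test, reporting group means and standard
#' errors of the mean. Degenerate zero-variance groups with equal means
#' give `t = 0, p = 1`.
#'
#' @param values_g1,values_g2 Numeric vectors (>= 2 values each).
#' @return Tibble `t`, `p_value`, `mean_g1`, `mean_g2`, `sem_g1`, `sem_g2`.
#' @export
group_t_test <- function(values_g1, values_g2) {
  if (length(values_g1) < 2 || length(values_g2) < 2) {
    abort("Each group needs >= 2 values.")
  }
  ht <- tryCatch(t.test(values_g1, values_g2), error = function(e) NULL)
  if (is.null(ht)) {
    equal <- isTRUE(all.equal(mean(values_g1), mean(values_g2)))
    ht <- list(statistic = if (equal) 0 else Inf,
               p.value = if (equal) 1 else 0)
  }
  tibble(t = unname(ht$statistic), p_value = ht$p.value,
         mean_g1 = mean(values_g1), mean_g2 = mean(values_g2),
         sem_g1 = sd(values_g1) / sqrt(length(values_g1)),
         sem_g2 = sd(values_g2) / sqrt(length(values_g2)))
}

#' Pearson correlation between sequencing and qPCR measurements
#'
#' Pearson r between per-sample normalized log2 sequencing counts and log2
#' qPCR relative levels, with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom. Zero variance on either side leaves the result
#' `NaN`, flagged.
#'
#' @param log2_counts,pcr_log2_levels Paired per-sample values (n >= 3).
#' @return Tibble `r`, `p_value`, `n`, `flagged`.
#' @export
seq_pcr_correlation <- function(log2_counts, pcr_log2_levels) {
  if (length(log2_counts) != length(pcr_log2_levels)) {
    abort("Paired vectors must have equal length.")
  }
  n <- length(log2_counts)
  if (n < 3) abort("Need at least 3 paired samples.")
  if (sd(log2_counts) == 0 || sd(pcr_log2_levels) == 0) {
    warn("Zero variance; correlation undefined.")
    return(tibble(r = NaN, p_value = NaN, n = n, flagged = TRUE))
  }
  ht <- cor.test(log2_counts, pcr_log2_levels, method = "pearson")
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = n,
         flagged = FALSE)
}
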