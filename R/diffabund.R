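#' Log2 fold difference of two group means
#'
#' `log2(mean_g1 / mean_g2)` on (normalized) group-mean counts. A zero mean
#' yields a signed infinity and a `fold_defined = FALSE` flag rather than a
#' pseudo-count fold; both means zero yield `NaN`, flagged.
#'
#' @param mean_g1,mean_g2 Non-negative group means (vectorized).
#' @return Tibble `log2_fold`, `fold_defined`.
#' @export
group_log2_fold <- function(mean_g1, mean_g2) {
  if (any(mean_g1 < 0) || any(mean_g2 < 0)) abort("Means must be >= 0.")
  lf <- suppressWarnings(log2(mean_g1 / mean_g2))
  tibble(log2_fold = lf, fold_defined = is.finite(lf))
}

# Scale sample columns to the geometric-mean library size and round
# half-up, giving the integer pseudo-counts the exact test conditions on.
equalize_libraries <- function(m) {
  depth <- colSums(m)
  if (any(depth == 0)) abort("Sample with zero total counts.")
  target <- exp(mean(log(depth)))
  floor(sweep(m, 2, target / depth, `*`) + 0.5)
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the summed conditional NB log-likelihood over genes (given each
#' group's total, after scaling all samples to the common geometric-mean
#' library size) for a single dispersion phi shared by all genes, the
#' variance model being `mu + phi * mu^2`. The estimate is clamped to
#' `[1e-6, 10]`.
#'
#' @param counts Count tibble.
#' @param groups Vector of group labels, one per sample column.
#' @return Dispersion phi (scalar).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  m <- counts_to_matrix(counts)
  if (length(groups) != ncol(m)) abort("One group label per sample needed.")
  if (all(m == 0)) abort("All-zero count matrix.")
  eq <- equalize_libraries(m)
  keep <- rowSums(eq) > 0
  eq <- eq[keep, , drop = FALSE]
  gidx <- split(seq_along(groups), groups)
  gidx <- gidx[vapply(gidx, length, 1L) >= 2]
  if (!length(gidx)) abort("Need a group with >= 2 samples.")
  cond_ll <- function(phi) {
    r <- 1 / phi
    tot <- 0
    for (idx in gidx) {
      y <- eq[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      tot <- tot + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                         lgamma(n * r) - lgamma(z + n * r))
    }
    tot
  }
  opt <- optimize(function(lp) cond_ll(exp(lp)),
                  interval = log(c(1e-6, 10)), maximum = TRUE, tol = 1e-6)
  # prefer a clamp when the boundary is at least as good
  cand <- c(exp(opt$maximum), 1e-6, 10)
  ll <- vapply(cand, cond_ll, numeric(1))
  cand[which.max(ll)]
}

# Exact two-sided p for group sums s1, s2 (n1, n2 samples) under a common
# NB mean, conditioning on the total. The conditional law of s1 given
# s1 + s2 = T is Beta-Binomial(T, n1/phi, n2/phi); two-sidedness doubles
# the smaller tail (observation included), capped at 1. Totals above
# `exact_limit` use the beta large-count limit with continuity correction.
nb_exact_p <- function(s1, s2, n1, n2, phi, exact_limit = 1e5) {
  tt <- s1 + s2
  if (tt == 0) return(1)
  if (phi < 1e-10) {                      # Poisson limit: binomial split
    pr <- n1 / (n1 + n2)
    lo <- pbinom(s1, tt, pr)
    hi <- 1 - pbinom(s1 - 1, tt, pr)
    return(min(1, 2 * min(lo, hi)))
  }
  r1 <- n1 / phi
  r2 <- n2 / phi
  if (tt <= exact_limit) {
    a <- 0:tt
    lp <- lgamma(a + r1) - lgamma(a + 1) + lgamma(tt - a + r2) -
      lgamma(tt - a + 1)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    lo <- sum(p[a <= s1])
    hi <- sum(p[a >= s1])
  } else {
    # symmetric continuity convention: the upper tail is the lower tail of
    # the swapped problem, so group relabelling preserves p exactly
    lo <- pbeta((s1 + 0.5) / (tt + 1), r1, r2)
    hi <- pbeta((s2 + 0.5) / (tt + 1), r2, r1)
  }
  min(1, 2 * min(lo, hi))
}

#' Negative-binomial exact test for two groups
#'
#' Two-sided exact test of equal means for overdispersed counts,
#' conditioning on the combined total of the two groups' sums under an NB
#' model with common dispersion `phi`. Counts are expected to be
#' library-size-equalized integer pseudo-counts (see
#' [differential_table()], which handles equalization). Two-sidedness is by
#' doubling the smaller tail, capped at 1.
#'
#' @param counts_g1,counts_g2 Non-negative integer count vectors.
#' @param phi Common dispersion (>= 0).
#' @return The p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_g1, counts_g2, phi) {
  if (any(counts_g1 < 0) || any(counts_g2 < 0)) {
    abort("Counts must be non-negative.")
  }
  if (phi < 0) abort("`phi` must be >= 0.")
  nb_exact_p(sum(counts_g1), sum(counts_g2),
             length(counts_g1), length(counts_g2), phi)
}

#' Negative-binomial GLM likelihood-ratio test for one gene
#'
#' Fits a log-linear NB model at fixed dispersion (via iteratively
#' reweighted least squares) with log library sizes as offsets, and tests
#' the two-level group term against the adjustment-only null with a 1-df
#' chi-squared likelihood-ratio test. When the group indicator is aliased
#' with the adjustment covariate (perfect confounding), or the fit fails to
#' converge, the result is flagged and `p` is `NaN`.
#'
#' @param y Integer counts for one gene.
#' @param group Two-level factor/logical of interest.
#' @param adjust Optional adjustment factor (e.g. NCT regimen).
#' @param offset_log Log effective library sizes (defaults to 0).
#' @param phi Fixed NB dispersion (> 0; use a small value such as 1e-8 for
#'   a Poisson-like fit).
#' @return Tibble `p_value`, `lrt_stat`, `flagged`.
#' @export
nb_glm_lrt <- function(y, group, adjust = NULL, offset_log = NULL,
                       phi = 0.1) {
  group <- factor(group)
  if (nlevels(group) != 2) abort("`group` must have exactly 2 levels.")
  offset_log <- offset_log %||% rep(0, length(y))
  dat <- data.frame(y = y, group = group)
  full_rhs <- "group"
  null_rhs <- "1"
  if (!is.null(adjust)) {
    dat$adjust <- factor(adjust)
    X <- stats::model.matrix(~ group + adjust, dat)
    if (qr(X)$rank < ncol(X)) {
      return(tibble(p_value = NaN, lrt_stat = NaN, flagged = TRUE))
    }
    full_rhs <- "group + adjust"
    null_rhs <- "adjust"
  }
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- tryCatch({
    f1 <- glm(stats::reformulate(full_rhs, "y"), family = fam, data = dat,
              offset = offset_log, control = list(maxit = 100))
    f0 <- glm(stats::reformulate(null_rhs, "y"), family = fam, data = dat,
              offset = offset_log, control = list(maxit = 100))
    list(f1 = f1, f0 = f0)
  }, error = function(e) NULL)
  if (is.null(fit) || !fit$f1$converged || !fit$f0$converged) {
    return(tibble(p_value = NaN, lrt_stat = NaN, flagged = TRUE))
  }
  stat <- fit$f0$deviance - fit$f1$deviance
  tibble(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         lrt_stat = stat, flagged = FALSE)
}

#' Benjamini-Hochberg step-up false-discovery rates
#'
#' `q_i = min_{j >= i} m * p_(j) / j` on the sorted p-values, mapped back to
#' the input order (identical to `p.adjust(method = "BH")`, asserted in the
#' test suite against the definitional step-up).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential-abundance table for a two-level clinical contrast
#'
#' For each gene, reports the group means of the quantile-normalized
#' (pre-log) counts, their log2 fold difference, a p-value from the NB
#' exact test on library-size-equalized raw counts (or, when `adjust` is
#' given, from the NB-GLM likelihood-ratio test with log library offsets),
#' and the BH FDR. Rows are sorted by p-value, ties broken by gene id.
#'
#' @param counts Raw count tibble (already filtered to the analysis set).
#' @param metadata Cohort metadata tibble with a `sample` column matching
#'   the count columns.
#' @param contrast Name of a two-level metadata column; for logical
#'   columns group 1 is `TRUE`, otherwise the first sorted level unless
#'   `level_g1` is given.
#' @param adjust Optional metadata column to adjust for (e.g. `regimen`).
#' @param phi Common dispersion; estimated from the data when `NULL`.
#' @param level_g1 Optional explicit level defining group 1.
#' @return Tibble of class `circmir_da`: `gene`, `mean_g1`, `mean_g2`,
#'   `log2_fold`, `p_value`, `fdr` (plus `fold_defined`, `flagged`).
#' @export
differential_table <- function(counts, metadata, contrast, adjust = NULL,
                               phi = NULL, level_g1 = NULL) {
  m <- counts_to_matrix(counts)
  meta <- metadata[match(colnames(m), metadata$sample), , drop = FALSE]
  if (any(is.na(meta$sample))) abort("Metadata missing for some samples.")
  v <- meta[[contrast]]
  if (is.null(v)) abort(paste0("No metadata column '", contrast, "'."))
  g1_level <- level_g1 %||% if (is.logical(v)) TRUE else sort(unique(v))[1]
  in_g1 <- v == g1_level
  lv <- unique(v[!is.na(v)])
  if (length(lv) != 2) abort("`contrast` must have exactly 2 levels.")
  if (sum(in_g1) < 2 || sum(!in_g1) < 2) {
    abort("Each contrast level needs >= 2 samples.")
  }
  norm <- counts_to_matrix(quantile_normalize(counts, log2 = FALSE))
  mean_g1 <- rowMeans(norm[, in_g1, drop = FALSE])
  mean_g2 <- rowMeans(norm[, !in_g1, drop = FALSE])
  fold <- group_log2_fold(mean_g1, mean_g2)
  if (is.null(phi)) phi <- estimate_common_dispersion(counts, in_g1)
  if (is.null(adjust)) {
    eq <- equalize_libraries(m)
    res <- purrr::map_dfr(seq_len(nrow(eq)), function(i) {
      tibble(p_value = nb_exact_test(eq[i, in_g1], eq[i, !in_g1], phi),
             flagged = FALSE)
    })
  } else {
    adj <- meta[[adjust]]
    if (is.null(adj)) abort(paste0("No metadata column '", adjust, "'."))
    off <- log(colSums(m))
    res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
      r <- nb_glm_lrt(m[i, ], in_g1, adjust = adj, offset_log = off,
                      phi = phi)
      tibble(p_value = r$p_value, flagged = r$flagged)
    })
  }
  out <- tibble(gene = rownames(m), mean_g1 = mean_g1, mean_g2 = mean_g2,
                log2_fold = fold$log2_fold, fold_defined = fold$fold_defined,
                p_value = res$p_value, flagged = res$flagged)
  ok <- !is.nan(out$p_value)
  out$fdr <- NA_real_
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  attr(out, "contrast") <- contrast
  attr(out, "level_g1") <- as.character(g1_level)
  attr(out, "phi") <- phi
  class(out) <- c("circmir_da", class(out))
  out
}
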