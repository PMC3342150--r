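#' @name counts-helpers
#' @title Convert between count tibbles and matrices
#' @description A count table is a tibble whose first column `gene` holds
#'   gene ids and whose remaining columns are numeric per-sample values.
#'   These helpers convert to and from a plain matrix with gene rownames.
#' @param counts A count tibble.
#' @param m A numeric matrix with gene rownames and sample colnames.
#' @return A matrix, or a tibble, respectively.
NULL

#' @rdname counts-helpers
#' @export
counts_to_matrix <- function(counts) {
  stopifnot("gene" %in% names(counts))
  if (anyDuplicated(counts$gene)) abort("Duplicate gene ids.")
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  if (any(is.na(m))) abort("Missing values in count table.")
  m
}

#' @rdname counts-helpers
#' @export
matrix_to_counts <- function(m) {
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

#' Detectability filter
#'
#' Keeps genes seen (count >= 1) in at least `min_samples` samples —
#' the rule under which a circulating miRNA is deemed detectable when
#' observed in at least 2 patients.
#'
#' @param counts Count tibble.
#' @param min_samples Minimum number of samples with a nonzero count.
#' @return Filtered count tibble; sample columns unchanged.
#' @export
detectability_filter <- function(counts, min_samples = 2L) {
  if (min_samples < 1) abort("`min_samples` must be >= 1.")
  m <- counts_to_matrix(counts)
  counts[rowSums(m >= 1) >= min_samples, , drop = FALSE]
}

#' Abundance filter
#'
#' Keeps genes with counts strictly greater than `min_count` in at least
#' `ceiling(min_fraction * n_samples)` samples — the "counts of > 50 in at
#' least 10% of the samples" analysis-set rule.
#'
#' @param counts Count tibble.
#' @param min_count Count threshold (strict inequality).
#' @param min_fraction Minimum fraction of samples, in (0, 1].
#' @return Filtered count tibble.
#' @export
abundance_filter <- function(counts, min_count = 50L, min_fraction = 0.10) {
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1].")
  }
  m <- counts_to_matrix(counts)
  need <- ceiling(min_fraction * ncol(m))
  counts[rowSums(m > min_count) >= need, , drop = FALSE]
}

# Core quantile normalization on a matrix (pre-log). Each column is mapped
# rank-wise onto the across-column mean of order statistics; ties within a
# column receive the mean of their tied reference quantiles.
quantile_normalize_matrix <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "min")
    run <- table(r)                      # tie-group sizes keyed by min-rank
    starts <- as.integer(names(run))
    mapped <- vapply(seq_along(starts), function(k) {
      mean(ref[starts[k]:(starts[k] + run[k] - 1L)])
    }, numeric(1))
    out[, j] <- mapped[match(r, starts)]
  }
  out
}

#' Quantile normalization with log2 transform
#'
#' Quantile-normalizes the sample columns (rank-based mapping onto the
#' across-column mean of order statistics; ties within a column receive the
#' mean of their tied reference quantiles) and then applies
#' `log2(x + 1)`. Set `log2 = FALSE` to obtain the pre-log normalized
#' values whose per-column multisets are identical.
#'
#' @param counts Count tibble with >= 2 sample columns (a single sample is
#'   passed through with a warning).
#' @param log2 Apply the `log2(x + 1)` transform (default `TRUE`).
#' @return Normalized tibble on the same gene/sample axes.
#' @export
quantile_normalize <- function(counts, log2 = TRUE) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2) {
    warn("Single sample: quantile normalization is the identity.")
  } else {
    m <- quantile_normalize_matrix(m)
  }
  if (log2) m <- log2(m + 1)
  matrix_to_counts(m)
}

#' Rank genes by across-sample abundance
#'
#' Orders genes by decreasing across-sample mean, reporting the mean and
#' range per gene — the ranking behind "top 100 miRNAs with the highest
#' quantities in circulation" displays.
#'
#' @param counts Count or normalized tibble.
#' @param top_n Number of genes to return (all when larger than the gene
#'   count).
#' @return Tibble `gene`, `mean`, `min`, `max`, sorted by decreasing mean
#'   (gene id breaks ties).
#' @export
rank_by_abundance <- function(counts, top_n = 100L) {
  if (top_n < 1) abort("`top_n` must be >= 1.")
  m <- counts_to_matrix(counts)
  out <- tibble(gene = rownames(m), mean = unname(rowMeans(m)),
                min = unname(apply(m, 1, min)),
                max = unname(apply(m, 1, max)))
  out <- out[order(-out$mean, out$gene), , drop = FALSE]
  head(out, top_n)
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of sample columns with distance
#' `1 - Pearson correlation` and average linkage. Columns are put in sample-id
#' order first so equal-distance merges resolve deterministically. A
#' zero-variance column has undefined correlations; its distances are set
#' to the maximum (2) with a warning.
#'
#' @param norm Normalized tibble (>= 2 samples).
#' @return An object of class `hclust`.
#' @seealso [write_dendrogram_newick()] to serialize the tree.
#' @export
cluster_samples <- function(norm) {
  m <- counts_to_matrix(norm)
  if (ncol(m) < 2) abort("Need at least 2 samples to cluster.")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2, sd)
  cc <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warn("Zero-variance sample column(s); treating their distances as maximal.")
    cc[is.na(cc)] <- -1
    diag(cc) <- 1
  }
  hclust(as.dist(1 - cc), method = "average")
}

#' Serialize a sample dendrogram as Newick
#'
#' @param hc An `hclust` object from [cluster_samples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
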