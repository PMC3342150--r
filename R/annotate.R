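#' Size-select reads
#'
#' Retains reads whose sequence length lies in `[min_len, max_len]`
#' inclusive, mimicking the 15-52 nt size selection applied to serum
#' small-RNA libraries. Input order is preserved.
#'
#' @param reads Tibble with at least `read_id` and `sequence` columns.
#' @param min_len,max_len Inclusive length bounds.
#' @return The filtered tibble.
#' @export
size_select <- function(reads, min_len = 15L, max_len = 52L) {
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

normalize_seq <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

#' Assign reads to small-RNA reference entries
#'
#' A read is assigned when it is an exact contiguous substring of at least
#' one reference sequence (after U-to-T normalization). When a read matches
#' entries of several classes the class is chosen by a fixed priority
#' (miRNA > tRNA > rRNA > scRNA > snRNA > snoRNA > other); within the
#' winning class the lexicographically smallest entry id is reported and
#' `ambiguous` is set when more than one entry of that class matches. Reads
#' containing characters outside A/C/G/T/U/N, or matching nothing, are
#' `unassigned`. Reads outside `[min_len, max_len]` are `size_excluded` and
#' not matched.
#'
#' @param reads Tibble with `read_id` and `sequence` columns (a ReadSet).
#' @param ref Reference tibble from [make_reference()] or
#'   [read_reference_fasta()].
#' @param min_len,max_len Size-selection bounds applied before matching.
#' @return A tibble with one row per input read: `read_id`, `status`
#'   (`assigned`/`unassigned`/`size_excluded`), `class`, `entry_id`,
#'   `ambiguous`.
#' @export
assign_reads <- function(reads, ref, min_len = 15L, max_len = 52L) {
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), status = character(),
                  class = character(), entry_id = character(),
                  ambiguous = logical()))
  }
  if (any(!nzchar(reads$sequence))) abort("Empty read sequence.")
  seqs <- normalize_seq(reads$sequence)
  len <- nchar(seqs)
  n <- length(seqs)
  status <- rep("unassigned", n)
  class <- rep(NA_character_, n)
  entry_id <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)

  size_ok <- len >= min_len & len <= max_len
  status[!size_ok] <- "size_excluded"
  alphabet_ok <- !grepl("[^ACGTN]", seqs)
  candidate <- size_ok & alphabet_ok

  if (nrow(ref) > 0 && any(candidate)) {
    ord <- order(match(as.character(ref$class), RNA_CLASSES), ref$id)
    ref_seq <- normalize_seq(ref$sequence[ord])
    ref_id <- ref$id[ord]
    ref_class <- as.character(ref$class)[ord]
    idx <- which(candidate)
    for (k in seq_along(ref_seq)) {
      hit <- idx[stringr::str_detect(ref_seq[k],
                                     stringr::fixed(seqs[idx]))]
      if (!length(hit)) next
      new <- hit[status[hit] != "assigned"]
      again <- hit[status[hit] == "assigned" & class[hit] == ref_class[k]]
      if (length(new)) {
        status[new] <- "assigned"
        class[new] <- ref_class[k]
        entry_id[new] <- ref_id[k]
      }
      if (length(again)) ambiguous[again] <- TRUE
    }
  }
  tibble(read_id = reads$read_id, status = status, class = class,
         entry_id = entry_id, ambiguous = ambiguous)
}

#' Assign a single read
#'
#' Scalar convenience wrapper around [assign_reads()] without size
#' selection (the sequence must be non-empty).
#'
#' @param sequence A single read sequence.
#' @param ref Reference tibble.
#' @return One-row assignment tibble (see [assign_reads()]).
#' @export
assign_read <- function(sequence, ref) {
  if (length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  assign_reads(tibble(read_id = "read", sequence = sequence), ref,
               min_len = 1L, max_len = .Machine$integer.max)
}

#' Count miRNAs and summarize small-RNA composition for one sample
#'
#' Tallies assigned reads per mature-miRNA entry and the per-class fractions
#' of assigned reads. Composition fractions are computed over assigned reads
#' only; with zero assigned reads the fractions are `NaN` and flagged.
#'
#' @param assignments Assignment tibble from [assign_reads()] for one
#'   sample.
#' @param gene_universe Optional character vector of miRNA ids to report
#'   (absent ids get count 0); defaults to the ids seen in `assignments`.
#' @return A list with `counts` (tibble `gene`, `count`) and `composition`
#'   (tibble `class`, `n_reads`, `fraction`, plus attributes `n_total`,
#'   `n_assigned`, `n_unassigned`, `n_size_excluded`).
#' @export
count_sample <- function(assignments, gene_universe = NULL) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  mir <- asg[asg$class == "miRNA", , drop = FALSE]
  genes <- gene_universe %||% sort(unique(mir$entry_id))
  cnt <- table(factor(mir$entry_id, levels = genes))
  counts <- tibble(gene = genes, count = as.integer(cnt))
  n_assigned <- nrow(asg)
  comp_n <- table(factor(asg$class, levels = RNA_CLASSES))
  composition <- tibble(
    class = RNA_CLASSES,
    n_reads = as.integer(comp_n),
    fraction = if (n_assigned > 0) as.numeric(comp_n) / n_assigned
               else rep(NaN, length(RNA_CLASSES))
  )
  attr(composition, "n_total") <- nrow(assignments)
  attr(composition, "n_assigned") <- n_assigned
  attr(composition, "n_unassigned") <-
    sum(assignments$status == "unassigned")
  attr(composition, "n_size_excluded") <-
    sum(assignments$status == "size_excluded")
  list(counts = counts, composition = composition)
}

#' Combine per-sample counts into a count matrix
#'
#' @param sample_counts Named list of per-sample count tibbles (`gene`,
#'   `count`), names are sample ids. Genes absent from a sample get 0.
#' @return Count tibble: `gene` column plus one integer column per sample.
#' @export
build_count_matrix <- function(sample_counts) {
  ids <- names(sample_counts)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("`sample_counts` must be a named list with unique sample ids.")
  }
  genes <- sort(unique(unlist(lapply(sample_counts, `[[`, "gene"))))
  out <- tibble(gene = genes)
  for (s in ids) {
    v <- setNames(sample_counts[[s]]$count, sample_counts[[s]]$gene)
    out[[s]] <- as.integer(ifelse(is.na(v[genes]), 0L, v[genes]))
  }
  out
}

#' Annotate a set of samples end to end
#'
#' Runs size selection, read assignment and counting for each sample's
#' reads and assembles the miRNA count matrix plus per-sample composition
#' summaries.
#'
#' @param read_sets Named list of read tibbles (one per sample).
#' @param ref Reference tibble.
#' @param min_len,max_len Size-selection bounds.
#' @return A list with `counts` (count tibble), `composition` (long tibble
#'   `sample`, `class`, `n_reads`, `fraction`) and `assignments` (named
#'   list of assignment tibbles).
#' @export
annotate_samples <- function(read_sets, ref, min_len = 15L, max_len = 52L) {
  if (is.null(names(read_sets))) abort("`read_sets` must be named.")
  genes <- sort(ref$id[ref$class == "miRNA"])
  asg <- lapply(read_sets, assign_reads, ref = ref,
                min_len = min_len, max_len = max_len)
  per <- lapply(asg, count_sample, gene_universe = genes)
  comp <- purrr::imap_dfr(per, function(p, s) {
    dplyr::mutate(p$composition, sample = s, .before = 1)
  })
  list(counts = build_count_matrix(lapply(per, `[[`, "counts")),
       composition = comp, assignments = asg)
}
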