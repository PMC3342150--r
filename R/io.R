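# File readers/writers. Sequence formats go through Biostrings; tables
# through readr (TSV throughout, gene rows x sample columns). Every writer
# prepends a comment header with the package version, a config hash and the
# seed when one is supplied.

output_header <- function(seed = NULL, params = list()) {
  h <- rlang::hash(list(params = params, seed = seed))
  c(paste0("# circmir ", as.character(utils::packageVersion("circmir"))),
    paste0("# config_hash=", h),
    paste0("# seed=", if (is.null(seed)) "NA" else seed))
}

write_tsv_with_header <- function(x, path, seed = NULL, params = list()) {
  writeLines(output_header(seed, params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, ...)
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    abort(paste0("Malformed TSV '", path, "': ", pr$expected[1],
                 " at line ", pr$row[1], "."))
  }
  out
}

#' Read and write a class-tagged small-RNA reference FASTA
#'
#' The class is carried on the description line as `id class=<class>`.
#'
#' @param path File path (gzip transparently handled on read).
#' @param ref Reference tibble (`id`, `class`, `sequence`).
#' @return `read_reference_fasta()` returns the reference tibble;
#'   the writer returns `path` invisibly.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  cls <- ifelse(grepl("class=", nm), sub(".*class=(\\S+).*", "\\1", nm),
                "other")
  if (anyDuplicated(id)) abort("Duplicate reference ids in FASTA.")
  bad <- setdiff(unique(cls), RNA_CLASSES)
  if (length(bad)) abort(paste0("Unknown class tag: ", bad[1]))
  tibble(id = id, class = factor(cls, levels = RNA_CLASSES),
         sequence = unname(as.character(ss)))
}

#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$sequence)
  names(ss) <- paste0(ref$id, " class=", as.character(ref$class))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write small-RNA reads (FASTA/FASTQ)
#'
#' FASTQ records are written with a uniform dummy quality (`I`). A
#' truncated FASTQ (record count not a multiple of 4 lines) is rejected
#' with the index of the offending record.
#'
#' @param path File path; format inferred from the extension
#'   (`.fastq`/`.fq` vs `.fasta`/`.fa`), gzip suffix allowed.
#' @param reads Read tibble (`read_id`, `sequence`).
#' @return `read_reads()` returns a tibble `read_id`, `sequence`; writers
#'   return `path` invisibly.
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path)
  if (fastq) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) %% 4 != 0) {
      abort(paste0("Truncated FASTQ: record ", length(lines) %/% 4 + 1,
                   " is incomplete."))
    }
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    ss <- Biostrings::readDNAStringSet(path)
  }
  tibble(read_id = sub("\\s.*$", "", names(ss)),
         sequence = unname(as.character(ss)))
}

#' @rdname read_reads
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname read_reads
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write count matrices as TSV
#'
#' Genes as rows (first column `gene`), samples as columns. Reading
#' validates uniqueness of ids and integrality of counts, naming the
#' offending line.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @param seed,params Recorded in the output comment header.
#' @return The count tibble, or `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  out <- read_tsv_quiet(path)
  if (names(out)[1] != "gene") abort("First column must be 'gene'.")
  if (anyDuplicated(out$gene)) {
    abort(paste0("Duplicate gene id '", out$gene[anyDuplicated(out$gene)],
                 "' in ", path, "."))
  }
  for (j in setdiff(names(out), "gene")) {
    v <- out[[j]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)) || any(v < 0)) {
      bad <- which(!is.finite(v) | v != floor(v) | v < 0)[1]
      abort(paste0("Non-integer or negative count in column '", j,
                   "', data line ", bad, "."))
    }
    out[[j]] <- as.integer(v)
  }
  out
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path, seed = NULL, params = list()) {
  write_tsv_with_header(counts, path, seed, params)
}

metadata_logical_cols <- c("er", "pr", "her2", "inflammatory")

#' Read and write cohort metadata as TSV
#'
#' Serialization follows the study vocabulary: receptor statuses as
#' `+`/`-`, response as `pCR`/`non-pCR`, relapse as
#' `relapsed`/`non-relapsed`; missing values are empty cells.
#'
#' @param path File path.
#' @param metadata Metadata tibble (see [simulate_cohort()]).
#' @param seed,params Recorded in the output comment header.
#' @return The metadata tibble, or `path` invisibly.
#' @export
read_metadata_tsv <- function(path) {
  out <- read_tsv_quiet(path, col_types = readr::cols(
    .default = readr::col_character(),
    follow_up_years = readr::col_double()))
  if (anyDuplicated(out$sample)) abort("Duplicate sample ids in metadata.")
  for (cl in intersect(metadata_logical_cols, names(out))) {
    v <- out[[cl]]
    if (cl == "inflammatory" && all(v %in% c("TRUE", "FALSE", NA))) {
      out[[cl]] <- as.logical(v)
    } else {
      if (any(!v %in% c("+", "-", NA))) {
        abort(paste0("Column '", cl, "' must be '+'/'-'."))
      }
      out[[cl]] <- v == "+"
    }
  }
  if ("relapse" %in% names(out)) {
    if (any(!out$relapse %in% c("relapsed", "non-relapsed", NA))) {
      abort("Column 'relapse' must be 'relapsed'/'non-relapsed'.")
    }
    out$relapse <- out$relapse == "relapsed"
  }
  if ("pcr_status" %in% names(out) &&
      any(!out$pcr_status %in% c("pCR", "non-pCR", NA))) {
    abort("Column 'pcr_status' must be 'pCR'/'non-pCR'.")
  }
  out
}

#' @rdname read_metadata_tsv
#' @export
write_metadata_tsv <- function(metadata, path, seed = NULL, params = list()) {
  out <- metadata
  for (cl in intersect(c("er", "pr", "her2"), names(out))) {
    out[[cl]] <- ifelse(out[[cl]], "+", "-")
  }
  if ("relapse" %in% names(out)) {
    out$relapse <- ifelse(out$relapse, "relapsed", "non-relapsed")
  }
  write_tsv_with_header(out, path, seed, params)
}

#' Read and write long qPCR Ct tables as TSV
#'
#' @param path File path.
#' @param pcr Tibble `sample`, `gene`, `ct`.
#' @param seed,params Recorded in the output comment header.
#' @return The Ct tibble, or `path` invisibly.
#' @export
read_pcr_tsv <- function(path) {
  out <- read_tsv_quiet(path)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(out))) {
    abort("PCR table needs columns sample, gene, ct.")
  }
  out
}

#' @rdname read_pcr_tsv
#' @export
write_pcr_tsv <- function(pcr, path, seed = NULL, params = list()) {
  write_tsv_with_header(pcr, path, seed, params)
}

#' Cross-file consistency validation
#'
#' Checks that every metadata sample appears in the count matrix and vice
#' versa (and likewise for an optional Ct table), before any computation.
#'
#' @param counts Count tibble.
#' @param metadata Metadata tibble.
#' @param pcr Optional Ct tibble.
#' @return `TRUE` invisibly; aborts listing the mismatched ids otherwise.
#' @export
validate_cohort <- function(counts, metadata, pcr = NULL) {
  cs <- setdiff(names(counts), "gene")
  miss <- c(setdiff(metadata$sample, cs), setdiff(cs, metadata$sample))
  if (!is.null(pcr)) miss <- c(miss, setdiff(unique(pcr$sample), cs))
  if (length(miss)) {
    abort(paste0("Sample ids not shared across inputs: ",
                 paste(unique(miss), collapse = ", ")))
  }
  invisible(TRUE)
}
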