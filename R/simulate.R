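#' Default small-RNA class mixture of serum sequencing reads
#'
#' Read-class proportions typical of serum small-RNA libraries: roughly half
#' miRNA, a large tRNA fraction, smaller scRNA/rRNA/snRNA/snoRNA fractions,
#' and a remainder of other annotated species. Fractions sum to 1.
#'
#' @return Named numeric vector of per-class read fractions.
#' @export
default_class_mixture <- function() {
  c(miRNA = 0.50, tRNA = 0.28, scRNA = 0.088, rRNA = 0.044,
    snRNA = 0.006, snoRNA = 0.004, other = 0.078)
}

# Length ranges (nt) per class used when generating reference entries.
# Mature miRNAs are 18-25 nt; the other classes get compact desk-scale
# surrogates of their usual sizes.
default_length_ranges <- function() {
  list(miRNA = c(18L, 25L), tRNA = c(70L, 90L), rRNA = c(90L, 150L),
       scRNA = c(80L, 120L), snRNA = c(60L, 110L), snoRNA = c(60L, 100L),
       other = c(40L, 80L))
}

random_dna <- function(n, lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a class-tagged small-RNA mini-reference
#'
#' Builds a synthetic reference of small-RNA sequences with unique ids and
#' pairwise-distinct sequences across all classes. The miRNA class always
#' contains entries named `hsa-miR-375`, `hsa-miR-122` and `hsa-miR-16`
#' (the marker genes and the qPCR reference gene), provided at least three
#' miRNA entries are requested. Deterministic for a fixed seed.
#'
#' @param n_per_class Named integer vector, entries per class (classes among
#'   `miRNA`, `tRNA`, `rRNA`, `scRNA`, `snRNA`, `snoRNA`, `other`).
#' @param length_ranges Named list of `c(min, max)` sequence lengths per
#'   class; defaults cover typical sizes of each class.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `class`, `sequence`.
#' @examples
#' ref <- make_reference(c(miRNA = 10, tRNA = 4), seed = 1)
#' table(ref$class)
#' @export
make_reference <- function(n_per_class,
                           length_ranges = default_length_ranges(),
                           seed = 1L) {
  if (is.null(names(n_per_class)) || any(names(n_per_class) %ni% RNA_CLASSES)) {
    abort("`n_per_class` must be named with known small-RNA classes.")
  }
  if (any(n_per_class < 0)) abort("`n_per_class` values must be >= 0.")
  for (cl in names(n_per_class)) {
    lr <- length_ranges[[cl]]
    if (is.null(lr) || length(lr) != 2 || lr[1] > lr[2] || lr[1] < 1) {
      abort(paste0("Impossible or missing length range for class '", cl, "'."))
    }
  }
  named_mirs <- c("hsa-miR-375", "hsa-miR-122", "hsa-miR-16")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(names(n_per_class), function(cl) {
      n <- n_per_class[[cl]]
      if (n == 0) return(tibble(id = character(), class = character(),
                                sequence = character()))
      lr <- length_ranges[[cl]]
      ids <- if (cl == "miRNA") {
        c(named_mirs[seq_len(min(n, 3))],
          if (n > 3) sprintf("hsa-miR-sim%03d", seq_len(n - 3)))
      } else {
        sprintf("%s-sim%03d", cl, seq_len(n))
      }
      lens <- sample(seq(lr[1], lr[2]), n, replace = TRUE)
      tibble(id = ids, class = cl, sequence = random_dna(n, lens))
    })
    # regenerate colliding sequences until all are pairwise distinct
    while (anyDuplicated(out$sequence) > 0) {
      dup <- duplicated(out$sequence)
      out$sequence[dup] <- random_dna(sum(dup), nchar(out$sequence[dup]))
    }
    out$class <- factor(out$class, levels = RNA_CLASSES)
    out[order(match(out$class, RNA_CLASSES), out$id), , drop = FALSE]
  })
}

#' Simulate small-RNA reads from a reference
#'
#' Draws each read's class from the given mixture, picks a reference entry
#' of that class uniformly, and takes an exact contiguous substring whose
#' length falls in `len_range` (the whole entry when it is shorter than the
#' minimum). True source entries are kept in a `source_id` column for
#' truth-checking; the annotation module never sees it.
#'
#' @param ref Reference tibble from [make_reference()].
#' @param mixture Named per-class fractions summing to 1; classes must exist
#'   in `ref`.
#' @param n_reads Number of reads (> 0).
#' @param len_range Integer `c(min, max)` read length.
#' @param seed Integer seed.
#' @return A tibble with columns `read_id`, `sequence`, `source_id`.
#' @export
simulate_reads <- function(ref, mixture = default_class_mixture(),
                           n_reads, len_range = c(15L, 52L), seed = 1L) {
  if (n_reads <= 0) abort("`n_reads` must be positive.")
  if (abs(sum(mixture) - 1) > 1e-9) abort("`mixture` fractions must sum to 1.")
  missing_cls <- setdiff(names(mixture)[mixture > 0], as.character(ref$class))
  if (length(missing_cls)) {
    abort(paste0("Mixture classes absent from reference: ",
                 paste(missing_cls, collapse = ", ")))
  }
  withr::with_seed(seed, {
    cls <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
    idx_by_class <- split(seq_len(nrow(ref)), as.character(ref$class))
    src <- integer(n_reads)
    for (cl in unique(cls)) {
      sel <- which(cls == cl)
      pool <- idx_by_class[[cl]]
      src[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    }
    entry_seq <- ref$sequence[src]
    entry_len <- nchar(entry_seq)
    max_len <- pmin(len_range[2], entry_len)
    min_len <- pmin(len_range[1], entry_len)
    len <- min_len + floor(runif(n_reads) * (max_len - min_len + 1))
    start <- 1L + floor(runif(n_reads) * (entry_len - len + 1))
    tibble(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      sequence = substr(entry_seq, start, start + len - 1L),
      source_id = ref$id[src]
    )
  })
}

#' Simulation settings for a synthetic serum cohort
#'
#' Assembles and validates the generative settings used by
#' [simulate_cohort()]. Defaults reproduce the structure of a 42-patient
#' neoadjuvant-chemotherapy cohort: 11/42 metastatic relapses, 23/42 HER2+
#' (all on the trastuzumab-containing regimen C; the rest split 7 to regimen
#' A and 12 to regimen B), pathologic complete response in 12/23 HER2+ and
#' 2/19 HER2- patients, 21/42 ER+, 14/42 PR+, and 10/42 inflammatory cases.
#' The default planted effects are the two relapse markers: miR-375 lower in
#' relapse (-1.90 log2) and miR-122 higher (+1.35 log2); miR-16 never
#' carries an effect.
#'
#' @param n_samples Cohort size (>= 4).
#' @param relapse_fraction Fraction of relapsing patients, in (0, 1).
#' @param class_mixture Named per-class read fractions summing to 1.
#' @param planted_effects Tibble with columns `gene`, `covariate`,
#'   `log2_effect`; covariates among `relapse`, `pcr`, `er`, `pr`, `her2`,
#'   `inflammatory`. The effect multiplies a gene's mean by
#'   `2^log2_effect` in samples where the covariate is positive.
#' @param dispersion Negative-binomial dispersion phi (> 0); variance is
#'   `mu + phi * mu^2`.
#' @param mean_library_size Mean per-sample read depth.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 42L,
                       relapse_fraction = 11 / 42,
                       class_mixture = default_class_mixture(),
                       planted_effects = default_planted_effects(),
                       dispersion = 0.1,
                       mean_library_size = 5e5,
                       seed = 1L) {
  if (n_samples < 4) abort("`n_samples` must be >= 4.")
  if (relapse_fraction <= 0 || relapse_fraction >= 1) {
    abort("`relapse_fraction` must lie strictly between 0 and 1.")
  }
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    abort("`class_mixture` fractions must sum to 1.")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  planted_effects <- as_tibble(planted_effects)
  req <- c("gene", "covariate", "log2_effect")
  if (!all(req %in% names(planted_effects))) {
    abort("`planted_effects` needs columns gene, covariate, log2_effect.")
  }
  structure(list(n_samples = as.integer(n_samples),
                 relapse_fraction = relapse_fraction,
                 class_mixture = class_mixture,
                 planted_effects = planted_effects,
                 dispersion = dispersion,
                 mean_library_size = mean_library_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_effects <- function() {
  tibble(gene = c("hsa-miR-375", "hsa-miR-122"),
         covariate = c("relapse", "relapse"),
         log2_effect = c(-1.90, 1.35))
}

sim_covariates <- c("relapse", "pcr", "er", "pr", "her2", "inflammatory")

# Exact-count label assignment: k positives among n, randomly placed.
draw_labels <- function(n, k) {
  out <- rep(FALSE, n)
  out[sample.int(n, k)] <- TRUE
  out
}

#' Simulate a clinical cohort with planted miRNA effects
#'
#' Generates per-sample clinical metadata mirroring a locally advanced
#' breast-cancer NCT cohort and a miRNA x sample count matrix. Counts for
#' gene i in sample j are NB(mu_ij, size = 1/phi) with
#' `mu_ij = library_size_j * abundance_i * 2^(sum of planted effects active
#' in sample j)`. Library sizes are log-normal around the configured mean
#' (sigma = 0.3 on the log scale) and baseline relative abundances are
#' log-normal so a few genes dominate; the marker genes miR-122, miR-16 and
#' miR-375 are pinned to high-abundance quantiles, mirroring their reported
#' circulating abundance. Deterministic per seed.
#'
#' @param cfg A [sim_config()].
#' @param ref Reference tibble; its miRNA entries define the gene universe.
#' @return A list with `counts` (tibble: `gene` column + one numeric column
#'   per sample) and `metadata` (one row per sample).
#' @export
simulate_cohort <- function(cfg = sim_config(), ref) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- ref$id[ref$class == "miRNA"]
  if (length(genes) < 2) abort("Reference must contain at least 2 miRNAs.")
  bad <- setdiff(cfg$planted_effects$gene, genes)
  if (length(bad)) {
    abort(paste0("Planted-effect genes absent from reference: ",
                 paste(bad, collapse = ", ")))
  }
  bad_cov <- setdiff(cfg$planted_effects$covariate, sim_covariates)
  if (length(bad_cov)) {
    abort(paste0("Unknown covariate in planted_effects: ",
                 paste(bad_cov, collapse = ", ")))
  }
  if (any(cfg$planted_effects$gene == "hsa-miR-16")) {
    abort("hsa-miR-16 is the qPCR reference gene and must carry no effect.")
  }
  n <- cfg$n_samples
  withr::with_seed(cfg$seed, {
    meta <- simulate_metadata(n, cfg$relapse_fraction)
    libsize <- rlnorm(n, log(cfg$mean_library_size) - 0.3^2 / 2, 0.3)
    ab <- rlnorm(length(genes), meanlog = 0, sdlog = 1.5)
    names(ab) <- genes
    # pin marker/reference genes to high abundance
    pin <- c("hsa-miR-122" = 0.95, "hsa-miR-16" = 0.85, "hsa-miR-375" = 0.80)
    for (g in names(pin)) {
      if (g %in% genes) ab[g] <- as.numeric(quantile(ab, pin[[g]]))
    }
    ab <- ab / sum(ab)
    log2fc <- matrix(0, nrow = length(genes), ncol = n,
                     dimnames = list(genes, meta$sample))
    cov_ind <- list(relapse = meta$relapse,
                    pcr = !is.na(meta$pcr_status) & meta$pcr_status == "pCR",
                    er = meta$er, pr = meta$pr, her2 = meta$her2,
                    inflammatory = meta$inflammatory)
    for (k in seq_len(nrow(cfg$planted_effects))) {
      pe <- cfg$planted_effects[k, ]
      log2fc[pe$gene, ] <- log2fc[pe$gene, ] +
        pe$log2_effect * as.numeric(cov_ind[[pe$covariate]])
    }
    mu <- outer(ab, libsize) * 2^log2fc
    dimnames(mu) <- list(genes, meta$sample)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = length(genes), dimnames = dimnames(mu))
    list(counts = matrix_to_counts(counts), metadata = meta)
  })
}

simulate_metadata <- function(n, relapse_fraction) {
  frac <- function(k42) round(n * k42 / 42)
  her2 <- draw_labels(n, frac(23))
  regimen <- ifelse(her2, "C", NA)
  neg <- which(!her2)
  regimen[neg] <- ifelse(draw_labels(length(neg),
                                     round(length(neg) * 7 / 19)), "A", "B")
  pcr <- rep(FALSE, n)
  pos <- which(her2)
  pcr[pos] <- draw_labels(length(pos), round(length(pos) * 12 / 23))
  pcr[neg] <- draw_labels(length(neg), round(length(neg) * 2 / 19))
  er <- draw_labels(n, frac(21))
  pr <- rep(FALSE, n)
  erp <- which(er)
  if (length(erp)) pr[erp] <- draw_labels(length(erp),
                                          min(length(erp), frac(14)))
  tibble(
    sample = sprintf("S%02d", seq_len(n)),
    cohort = "training",
    er = er, pr = pr, her2 = her2,
    inflammatory = draw_labels(n, frac(10)),
    regimen = regimen,
    pcr_status = ifelse(pcr, "pCR", "non-pCR"),
    relapse = draw_labels(n, max(1L, round(n * relapse_fraction))),
    follow_up_years = round(runif(n, 2, 5), 1)
  )
}

#' Simulate qPCR Ct values from normalized sequencing counts
#'
#' Generates threshold-cycle (Ct) values linearly related to the log2
#' normalized sequencing signal, `Ct = intercept - slope * log2value +
#' noise`, so that -Ct correlates positively with sequencing abundance as
#' observed when qPCR is run on the same serum RNA extracts.
#'
#' @param norm Normalized matrix tibble (`gene` column + sample columns) on
#'   the log2 scale.
#' @param genes Genes to assay; must be present in `norm` (include
#'   `hsa-miR-16` when the table will be miR-16-normalized downstream).
#' @param noise_sd Gaussian noise SD on the Ct scale.
#' @param intercept,slope Calibration line; `slope` must be > 0.
#' @param seed Integer seed.
#' @return Long tibble with columns `sample`, `gene`, `ct`.
#' @export
simulate_pcr <- function(norm, genes, noise_sd = 0.5,
                         intercept = 36, slope = 1, seed = 1L) {
  if (slope <= 0) abort("`slope` must be > 0.")
  missing <- setdiff(genes, norm$gene)
  if (length(missing)) {
    abort(paste0("Genes absent from normalized matrix: ",
                 paste(missing, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(norm[norm$gene %in% genes, ],
                              -"gene", names_to = "sample",
                              values_to = "log2value")
  withr::with_seed(seed, {
    tibble(sample = long$sample, gene = long$gene,
           ct = intercept - slope * long$log2value +
             rnorm(nrow(long), 0, noise_sd))
  })
}
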