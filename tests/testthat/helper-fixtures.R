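# Shared fixtures, all generated in code.

tiny_reference <- function(seed = 11L) {
  make_reference(c(miRNA = 10L, tRNA = 4L, rRNA = 3L, scRNA = 3L,
                   snRNA = 2L, snoRNA = 2L, other = 2L), seed = seed)
}

default_pipeline_reference <- function(seed = 1L) {
  make_reference(c(miRNA = 40L, tRNA = 8L, rRNA = 4L, scRNA = 4L,
                   snRNA = 3L, snoRNA = 3L, other = 4L), seed = seed)
}

random_count_tibble <- function(n_genes, n_samples, seed = 1L,
                                lambda = 40) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    matrix_to_counts(m)
  })
}

# Brute-force assignment oracle: exhaustive (read, entry) substring scan
# with the priority/lexicographic rule applied by hand.
oracle_assign <- function(sequence, ref) {
  s <- gsub("U", "T", toupper(sequence))
  if (grepl("[^ACGTN]", s)) {
    return(list(status = "unassigned", class = NA, entry_id = NA,
                ambiguous = FALSE))
  }
  hits <- vapply(seq_len(nrow(ref)), function(k) {
    grepl(s, gsub("U", "T", toupper(ref$sequence[k])), fixed = TRUE)
  }, logical(1))
  if (!any(hits)) {
    return(list(status = "unassigned", class = NA, entry_id = NA,
                ambiguous = FALSE))
  }
  classes <- as.character(ref$class)[hits]
  prio <- c("miRNA", "tRNA", "rRNA", "scRNA", "snRNA", "snoRNA", "other")
  win <- prio[min(match(classes, prio))]
  ids <- sort(ref$id[hits][classes == win])
  list(status = "assigned", class = win, entry_id = ids[1],
       ambiguous = length(ids) > 1)
}

# Brute-force conditional NB two-sided p (doubling the smaller tail) by
# direct convolution of the two group-sum NB laws.
oracle_nb_exact <- function(s1, s2, n1, n2, phi) {
  tt <- s1 + s2
  if (tt == 0) return(1)
  mu <- tt / (n1 + n2)
  a <- 0:tt
  pr <- dnbinom(a, size = n1 / phi, mu = n1 * mu) *
    dnbinom(tt - a, size = n2 / phi, mu = n2 * mu)
  pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[a <= s1]), sum(pr[a >= s1])))
}

# Brute-force logistic likelihood grid over (intercept, slope), refined
# in stages down to a 5e-4 step.
grid_mle <- function(x, y) {
  scan <- function(b0, b1) {
    best <- c(NA, NA)
    best_ll <- -Inf
    for (a in b0) {
      eta <- a + outer(x, b1)
      ll <- colSums(y * eta - log1p(exp(eta)))
      k <- which.max(ll)
      if (ll[k] > best_ll) {
        best_ll <- ll[k]
        best <- c(a, b1[k])
      }
    }
    best
  }
  b <- scan(seq(-6, 6, by = 0.02), seq(-8, 8, by = 0.02))
  b <- scan(seq(b[1] - 0.05, b[1] + 0.05, by = 0.002),
            seq(b[2] - 0.05, b[2] + 0.05, by = 0.002))
  scan(seq(b[1] - 0.005, b[1] + 0.005, by = 5e-4),
       seq(b[2] - 0.005, b[2] + 0.005, by = 5e-4))
}

# Definitional BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(m * p[o][i:m] / (i:m))
  }
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

signature_cohort <- function(seed, n_samples = 42L) {
  ref <- default_pipeline_reference(seed = 1L)
  sim <- simulate_cohort(sim_config(n_samples = n_samples, seed = seed),
                         ref)
  filtered <- sim$counts |>
    detectability_filter() |>
    abundance_filter()
  norm <- quantile_normalize(filtered)
  list(ref = ref, counts = sim$counts, metadata = sim$metadata,
       filtered = filtered, norm = norm)
}

signature_features <- function(norm, metadata,
                               genes = c("hsa-miR-375", "hsa-miR-122")) {
  feat <- norm[norm$gene %in% genes, ] |>
    tidyr::pivot_longer(-gene, names_to = "sample") |>
    tidyr::pivot_wider(names_from = gene)
  feat$relapse <- metadata$relapse[match(feat$sample, metadata$sample)]
  feat
}
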