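test_that("group log2 fold reproduces printed group-mean ratios", {
  expect_equal(round(group_log2_fold(32629, 4014)$log2_fold, 2), 3.02)
  expect_equal(round(group_log2_fold(989, 239)$log2_fold, 2), 2.05)
  expect_equal(group_log2_fold(7, 7)$log2_fold, 0)
  zr <- group_log2_fold(5, 0)
  expect_true(is.infinite(zr$log2_fold) && !zr$fold_defined)
  both <- group_log2_fold(0, 0)
  expect_true(is.nan(both$log2_fold) && !both$fold_defined)
  expect_error(group_log2_fold(-1, 2), ">= 0")
})

test_that("common dispersion is recovered from simulated counts", {
  withr::with_seed(101, {
    mu <- rep(rlnorm(200, log(80), 1), each = 20)
    pois <- matrix(rpois(200 * 20, mu), nrow = 200, byrow = TRUE,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("S%02d", 1:20)))
    nb <- matrix(rnbinom(200 * 20, mu = mu, size = 1 / 0.3), nrow = 200,
                 byrow = TRUE, dimnames = dimnames(pois))
  })
  grp <- rep(c("a", "b"), each = 10)
  expect_lte(estimate_common_dispersion(matrix_to_counts(pois), grp), 0.05)
  phi_nb <- estimate_common_dispersion(matrix_to_counts(nb), grp)
  expect_gte(phi_nb, 0.2)
  expect_lte(phi_nb, 0.45)

  ident <- matrix(rep(c(5L, 9L, 40L), 2), ncol = 2,
                  dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_equal(estimate_common_dispersion(matrix_to_counts(ident),
                                          c("a", "a")), 1e-6)
  zeros <- matrix(0L, 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(estimate_common_dispersion(matrix_to_counts(zeros),
                                          c("a", "a")), "zero")
})

test_that("NB exact test matches brute-force conditional enumeration", {
  # balanced observation -> p = 1
  expect_equal(nb_exact_test(c(3, 2), c(2, 3), phi = 0.2), 1)
  # label-swap symmetry
  withr::with_seed(7, {
    y1 <- rpois(4, 9); y2 <- rpois(3, 12)
  })
  expect_equal(nb_exact_test(y1, y2, 0.15), nb_exact_test(y2, y1, 0.15))

  # exhaustive small-total grid against the convolution oracle
  for (phi in c(0.05, 0.1, 0.5)) {
    for (s1 in c(0, 2, 7, 15)) {
      for (s2 in c(1, 5, 15)) {
        if (s1 + s2 > 30) next
        got <- nb_exact_test(c(s1, 0), c(s2), phi)
        want <- oracle_nb_exact(s1, s2, 2, 1, phi)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
  expect_error(nb_exact_test(c(-1, 2), c(1), 0.1), "non-negative")
})

test_that("NB exact test approaches the conditional binomial as phi -> 0", {
  for (s1 in 0:10) {
    for (s2 in c(0, 3, 9)) {
      if (s1 + s2 > 20 || s1 + s2 == 0) next
      tt <- s1 + s2
      lo <- pbinom(s1, tt, 0.5)
      hi <- 1 - pbinom(s1 - 1, tt, 0.5)
      binom_p <- min(1, 2 * min(lo, hi))
      expect_lt(abs(nb_exact_test(c(s1, 0), c(s2, 0), phi = 1e-8) -
                      binom_p), 1e-6)
    }
  }
})

test_that("large-count path is consistent with the exact path", {
  # straddle the enumeration cutoff: beta approximation should agree
  # closely with exact enumeration where both are computable
  p_exact <- circmir:::nb_exact_p(30000, 28000, 5, 5, 0.1,
                                  exact_limit = 1e5)
  p_beta <- circmir:::nb_exact_p(30000, 28000, 5, 5, 0.1, exact_limit = 1)
  expect_equal(p_exact, p_beta, tolerance = 0.02)
})

test_that("NB GLM LRT is calibrated under the null and matches Poisson", {
  withr::with_seed(55, {
    n <- 10
    grp <- rep(c(FALSE, TRUE), each = n / 2)
    pvals <- vapply(seq_len(1000), function(i) {
      y <- rnbinom(n, mu = 60, size = 1 / 0.1)
      nb_glm_lrt(y, grp, phi = 0.1)$p_value
    }, numeric(1))
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)

  # Poisson limit equals the ordinary Poisson GLM likelihood-ratio test
  withr::with_seed(56, {
    y <- rpois(10, 25)
    g <- rep(c(FALSE, TRUE), 5)
  })
  ours <- nb_glm_lrt(y, g, phi = 1e-8)
  f1 <- glm(y ~ g, family = poisson())
  f0 <- glm(y ~ 1, family = poisson())
  p_pois <- pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE)
  expect_equal(ours$p_value, p_pois, tolerance = 1e-6)

  # perfect confounding of group and adjustment is flagged
  conf <- nb_glm_lrt(y, g, adjust = ifelse(g, "A", "B"), phi = 0.1)
  expect_true(conf$flagged)
  expect_true(is.nan(conf$p_value))
})

test_that("BH FDR equals the definitional step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- runif(sample(3:50, 1))^sample(1:3, 1)
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
      # invariance to input order
      o <- sample(length(p))
      expect_equal(bh_fdr(p[o]), oracle_bh(p)[o], tolerance = 1e-12)
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential tables are order-invariant and sign-symmetric", {
  co <- signature_cohort(seed = 61, n_samples = 20L)
  da <- differential_table(co$filtered, co$metadata, "relapse")
  expect_true(all(diff(da$p_value) >= 0))
  # monotone-consistent BH over the result set
  expect_equal(da$fdr, bh_fdr(da$p_value), ignore_attr = TRUE)
  expect_true(all(diff(da$fdr) >= -1e-12))

  # swapped contrast: folds negate, p-values unchanged
  swapped <- differential_table(co$filtered, co$metadata, "relapse",
                                level_g1 = FALSE)
  m <- match(da$gene, swapped$gene)
  expect_equal(swapped$log2_fold[m], -da$log2_fold, tolerance = 1e-9)
  expect_equal(swapped$p_value[m], da$p_value, tolerance = 1e-12)

  # permuting sample columns leaves the table unchanged
  perm_cols <- withr::with_seed(62,
    sample(setdiff(names(co$filtered), "gene")))
  perm <- co$filtered[, c("gene", perm_cols)]
  da2 <- differential_table(perm, co$metadata, "relapse")
  expect_equal(tidy(da2), tidy(da), tolerance = 1e-12)

  md <- co$metadata
  md$relapse <- c(TRUE, rep(FALSE, nrow(md) - 1))
  expect_error(differential_table(co$filtered, md, "relapse"),
               ">= 2 samples")
})

test_that("null contrasts produce roughly uniform p-values", {
  ref <- tiny_reference()
  null_effects <- tibble::tibble(gene = character(), covariate = character(),
                                 log2_effect = numeric())
  ps <- unlist(lapply(1:6, function(s) {
    sim <- simulate_cohort(sim_config(n_samples = 24L,
                                      planted_effects = null_effects,
                                      mean_library_size = 5e4, seed = s),
                           ref)
    da <- differential_table(detectability_filter(sim$counts),
                             sim$metadata, "relapse")
    da$p_value
  }))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("dispersion estimate agrees loosely with edgeR's qCML", {
  co <- signature_cohort(seed = 71, n_samples = 16L)
  grp <- co$metadata$relapse
  ours <- estimate_common_dispersion(co$filtered, grp)
  dge <- edgeR::DGEList(counts = counts_to_matrix(co$filtered),
                        group = grp)
  theirs <- edgeR::estimateCommonDisp(dge)$common.dispersion
  expect_lt(abs(log(ours / theirs)), log(2))  # same scale, within 2-fold
})
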