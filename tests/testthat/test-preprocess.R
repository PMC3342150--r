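test_that("detectability filter keeps genes seen in >= 2 patients", {
  m <- matrix(c(5, 0, 0, 0,
                3, 2, 0, 0,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("once", "twice", "never"),
                              paste0("S", 1:4)))
  kept <- detectability_filter(matrix_to_counts(m))
  expect_equal(kept$gene, "twice")

  rc <- random_count_tibble(50, 10, seed = 3, lambda = 0.6)
  got <- detectability_filter(rc)
  mm <- counts_to_matrix(rc)
  brute <- rownames(mm)[vapply(seq_len(nrow(mm)), function(i) {
    sum(mm[i, ] >= 1) >= 2
  }, logical(1))]
  expect_equal(got$gene, brute)
})

test_that("abundance filter uses a strict count threshold and ceil fraction", {
  m <- matrix(50L, nrow = 2, ncol = 10,
              dimnames = list(c("boundary", "over"), paste0("S", 1:10)))
  m["over", 1] <- 51L
  kept <- abundance_filter(matrix_to_counts(m))
  # 51 in one of ten samples passes (1 >= ceil(0.1*10)); 50 everywhere fails
  expect_equal(kept$gene, "over")

  rc <- random_count_tibble(60, 7, seed = 5, lambda = 45)
  got <- abundance_filter(rc, min_count = 50, min_fraction = 0.25)
  mm <- counts_to_matrix(rc)
  brute <- rownames(mm)[vapply(seq_len(nrow(mm)), function(i) {
    sum(mm[i, ] > 50) >= ceiling(0.25 * ncol(mm))
  }, logical(1))]
  expect_equal(got$gene, brute)
  expect_error(abundance_filter(rc, min_fraction = 0), "min_fraction")
})

test_that("quantile normalization matches the hand-worked oracle", {
  m <- matrix(c(5, 4, 3,
                2, 1, 4,
                3, 4, 6,
                4, 2, 8), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:3)))
  # sorted columns: (2,3,4,5), (1,2,4,4), (3,4,6,8); reference quantiles
  # (2, 3, 14/3, 17/3); S2's tied 4s take the mean of ranks 3-4.
  q <- c(2, 3, 14 / 3, 17 / 3)
  expected <- cbind(S1 = c(q[4], q[1], q[2], q[3]),
                    S2 = c(mean(q[3:4]), q[1], mean(q[3:4]), q[2]),
                    S3 = c(q[1], q[2], q[3], q[4]))
  got <- quantile_normalize(matrix_to_counts(m), log2 = FALSE)
  expect_equal(unname(counts_to_matrix(got)), unname(expected),
               tolerance = 1e-12)
  logged <- quantile_normalize(matrix_to_counts(m))
  expect_equal(counts_to_matrix(logged), log2(counts_to_matrix(got) + 1),
               tolerance = 1e-12)
})

test_that("quantile normalization invariants hold", {
  # tie-free columns: exact column-multiset identity and idempotence
  # (with within-column ties both hold only up to tie-averaging)
  tiefree <- withr::with_seed(9, {
    matrix(sample.int(5000, 30 * 6), nrow = 30,
           dimnames = list(sprintf("g%02d", 1:30), sprintf("S%02d", 1:6)))
  })
  norm <- quantile_normalize(matrix_to_counts(tiefree), log2 = FALSE)
  nm <- counts_to_matrix(norm)
  ref_sorted <- sort(nm[, 1])
  for (j in 2:ncol(nm)) expect_equal(sort(nm[, j]), ref_sorted,
                                     ignore_attr = TRUE)
  # idempotence on pre-log output
  again <- quantile_normalize(norm, log2 = FALSE)
  expect_equal(counts_to_matrix(again), nm, tolerance = 1e-9)

  # two identical columns stay identical and equal log2(x+1)
  two <- matrix(c(7, 1, 4, 7, 1, 4), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("A", "B")))
  nt <- counts_to_matrix(quantile_normalize(matrix_to_counts(two)))
  expect_equal(nt[, "A"], nt[, "B"])
  expect_equal(unname(nt[, "A"]), unname(log2(two[, 1] + 1)))

  # a column that permutes another yields the same value multiset
  pm <- matrix(c(1, 5, 9, 9, 1, 5), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("A", "B")))
  np <- counts_to_matrix(quantile_normalize(matrix_to_counts(pm),
                                            log2 = FALSE))
  expect_equal(sort(np[, "A"]), sort(np[, "B"]), ignore_attr = TRUE)

  # agreement with limma on tie-free data
  tf <- matrix(c(sample(1:30), sample(31:60)), ncol = 2,
               dimnames = list(paste0("g", 1:30), c("A", "B")))
  ours <- counts_to_matrix(quantile_normalize(matrix_to_counts(tf),
                                              log2 = FALSE))
  theirs <- limma::normalizeQuantiles(tf)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-9)

  expect_warning(quantile_normalize(random_count_tibble(5, 1, seed = 1)),
                 "Single sample")
})

test_that("abundance ranking equals a brute-force sort on means", {
  m <- matrix(c(1000, 900, 1, 2, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("dominant", "tiny", "mid"), c("A", "B")))
  rk <- rank_by_abundance(matrix_to_counts(m))
  expect_equal(rk$gene[1], "dominant")
  expect_equal(nrow(rk), 3)  # top_n larger than gene count returns all

  rc <- random_count_tibble(40, 5, seed = 13)
  got <- rank_by_abundance(rc, top_n = 40)
  mm <- counts_to_matrix(rc)
  mns <- rowMeans(mm)
  brute <- names(mns)[order(-mns, names(mns))]
  expect_equal(got$gene, brute)
  expect_equal(got$mean, unname(mns[brute]))
  expect_equal(got$min, unname(apply(mm, 1, min)[brute]))
})

test_that("sample clustering uses 1 - Pearson with average linkage", {
  withr::with_seed(17, {
    base <- matrix(rnorm(40 * 5, 8, 2), nrow = 40,
                   dimnames = list(paste0("g", 1:40), paste0("S", 1:5)))
  })
  base[, "S4"] <- base[, "S2"]  # duplicated sample pair
  hc <- cluster_samples(matrix_to_counts(base))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("S2", "S4"))

  # 3-sample brute-force check of merge order and heights
  withr::with_seed(18, {
    m3 <- matrix(rnorm(30 * 3, 5), nrow = 30,
                 dimnames = list(paste0("g", 1:30), c("A", "B", "C")))
  })
  d <- 1 - cor(m3)
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  dv <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  hc3 <- cluster_samples(matrix_to_counts(m3))
  expect_equal(hc3$height[1], min(dv), tolerance = 1e-12)
  merged <- pairs[[which.min(dv)]]
  expect_setequal(hc3$labels[-hc3$merge[1, ]], merged)
  # average linkage: final height is the mean of the two cross distances
  rest <- setdiff(c("A", "B", "C"), merged)
  expect_equal(hc3$height[2], mean(d[rest, merged]), tolerance = 1e-12)
})

test_that("clustering recovers planted sample groups", {
  ref <- tiny_reference()
  eff <- tibble::tibble(
    gene = c("hsa-miR-375", "hsa-miR-122", "hsa-miR-16"),
    covariate = "er", log2_effect = c(3, -3, 2.5))
  eff <- eff[eff$gene != "hsa-miR-16", ]
  extra <- tibble::tibble(gene = paste0("hsa-miR-sim00", 1:7),
                          covariate = "er",
                          log2_effect = rep(c(2.5, -2.5), length.out = 7))
  cfg <- sim_config(n_samples = 16L, planted_effects = rbind(eff, extra),
                    seed = 23)
  sim <- simulate_cohort(cfg, ref)
  norm <- quantile_normalize(detectability_filter(sim$counts))
  hc <- cluster_samples(norm)
  k2 <- stats::cutree(hc, k = 2)
  truth <- sim$metadata$er[match(names(k2), sim$metadata$sample)]
  agree <- max(mean((k2 == 1) == truth), mean((k2 == 2) == truth))
  expect_gte(agree, 0.9)
})

test_that("zero-variance sample columns are handled with a warning", {
  m <- matrix(c(1, 2, 3, 4, 4, 4, 2, 1, 5), ncol = 3,
              dimnames = list(paste0("g", 1:3), c("A", "B", "C")))
  expect_warning(hc <- cluster_samples(matrix_to_counts(m)),
                 "Zero-variance")
  expect_s3_class(hc, "hclust")
})
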