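test_that("three pure dosage groups land on three equally spaced PC1 points", {
  # 6 specimens in three groups with rows all-0 / all-1 / all-2
  g <- rbind(matrix(0L, 2, 10), matrix(1L, 2, 10), matrix(2L, 2, 10))
  sites <- data.frame(contig = "3R", pos = 1:10 * 100, ref = "A", alt = "G")
  vm <- variant_matrix(g, sites, paste0("s", 1:6))
  pca <- run_local_pca(vm)
  pc1 <- pca$scores[, "PC1"]
  centers <- tapply(pc1, rep(1:3, each = 2), mean)
  centers <- sort(centers)
  # within-group collapse and equal spacing of the three group positions
  expect_lt(max(tapply(pc1, rep(1:3, each = 2), stats::sd)), 1e-8)
  expect_equal(unname(centers[3] - centers[2]),
               unname(centers[2] - centers[1]), tolerance = 1e-8)
  expect_lt(pca$var_frac[2], 1e-8)
})

test_that("a matrix without polymorphism is rejected", {
  g <- matrix(1L, 5, 4)
  sites <- data.frame(contig = "3R", pos = 1:4 * 10, ref = "A", alt = "G")
  vm <- variant_matrix(g, sites, paste0("s", 1:5))
  expect_error(run_local_pca(vm), "no polymorphism")
  expect_error(run_local_pca(variant_matrix(g[1:2, ], sites,
                                            c("a", "b"))),
               "at least 3 specimens")
})

test_that("on a simulated cohort PC1 dominates PC2", {
  sim <- small_cohort(seed = 3)
  pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
  expect_gt(pca$var_frac[1], pca$var_frac[2])
  expect_true(all(pca$var_frac >= 0 & pca$var_frac <= 1))
})

test_that("anchored stripes are labelled 0/1/2 and match simulation truth", {
  sim <- small_cohort(seed = 4)
  pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
  res <- classify_stripes(pca, sim$anchors, "3Ra")
  expect_equal(sort(res$model$labels), 0:2)
  conf <- res$calls$conforming
  acc <- mean(res$calls$genotype[conf] ==
                sim$truth$genotype[res$calls$specimen[conf]])
  expect_gte(acc, 0.99)
  # middle stripe (by centre order) is the heterokaryotype
  expect_equal(res$model$labels[2], 1L)
})

test_that("PCA sign indeterminacy does not change genotype calls", {
  sim <- small_cohort(seed = 5, n = 90, sites = 200)
  pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
  res1 <- classify_stripes(pca, sim$anchors, "3Ra")
  flipped <- pca
  flipped$scores[, "PC1"] <- -flipped$scores[, "PC1"]
  res2 <- classify_stripes(flipped, sim$anchors, "3Ra")
  expect_identical(res1$calls$genotype, res2$calls$genotype)
  expect_identical(res1$calls$conforming, res2$calls$conforming)
})

test_that("stripe labels are monotone along PC1", {
  for (seed in 6:9) {
    sim <- small_cohort(seed = seed, n = 80, sites = 150)
    pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
    res <- classify_stripes(pca, sim$anchors, "3Ra")
    lab <- res$model$labels[!is.na(res$model$labels)]
    expect_true(!is.unsorted(lab) || !is.unsorted(rev(lab)))
  }
})

test_that("a fixed cohort forms a single stripe called from its anchors", {
  sim <- small_cohort(seed = 10, q = 0, n = 40, sites = 100)
  pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
  res <- classify_stripes(pca, sim$anchors, "3Ra")
  expect_equal(res$model$diagnostics$n_stripes, 1)
  expect_true(all(res$calls$genotype[res$calls$conforming] == 0L))
})

test_that("a specimen midway between stripes is flagged non-conforming", {
  pc1 <- c(rep(-10, 10), rep(0, 10), rep(10, 10), 5)  # one midway point
  specimens <- c(paste0("s", 1:30), "odd")
  pca <- structure(list(specimens = specimens,
                        scores = cbind(PC1 = pc1, PC2 = 0),
                        var_frac = c(0.9, 0.05)),
                   class = "pca_result")
  anchors <- anchor_set(c("s1", "s21"), c(0L, 2L))
  res <- classify_stripes(pca, anchors, "inv")
  odd <- res$calls[res$calls$specimen == "odd", ]
  expect_false(odd$conforming)
  expect_true(is.na(odd$genotype))
  # everyone sitting on a stripe centre is conforming and called
  others <- res$calls[res$calls$specimen != "odd", ]
  expect_true(all(others$conforming))
  expect_equal(as.integer(tapply(others$genotype, rep(0:2, each = 10),
                                 unique)),
               c(0L, 1L, 2L))
})

test_that("stripe labelling uses anchor majority and reports the minority", {
  pc1 <- c(rep(-5, 8), rep(0, 8), rep(5, 8))
  specimens <- paste0("s", 1:24)
  pca <- structure(list(specimens = specimens,
                        scores = cbind(PC1 = pc1, PC2 = 0),
                        var_frac = c(0.8, 0.1)),
                   class = "pca_result")
  # left stripe: 3 anchors vote 0, 1 votes 2 (cytogenetic error)
  anchors <- anchor_set(c("s1", "s2", "s3", "s4", "s17"),
                        c(0L, 0L, 0L, 2L, 2L))
  res <- classify_stripes(pca, anchors, "inv")
  expect_equal(res$model$labels, c(0L, 1L, 2L))
  expect_equal(res$model$anchor_mismatches, "s4")
})

test_that("conflicting or absent anchor labels raise errors", {
  pc1 <- c(rep(-5, 6), rep(0, 6), rep(5, 6))
  pca <- structure(list(specimens = paste0("s", 1:18),
                        scores = cbind(PC1 = pc1, PC2 = 0),
                        var_frac = c(0.8, 0.1)),
                   class = "pca_result")
  # both outer stripes labelled 0
  expect_error(classify_stripes(pca, anchor_set(c("s1", "s13"), c(0L, 0L))),
               "anchor conflict")
  # tied vote inside one stripe
  expect_error(classify_stripes(pca, anchor_set(c("s1", "s2"), c(0L, 2L))),
               "anchor conflict")
  # only the middle stripe anchored: outer orientation unresolvable
  expect_error(classify_stripes(pca, anchor_set("s7", 1L)),
               "insufficient anchors")
})

test_that("removing non-anchor specimens keeps anchored stripe labels", {
  sim <- small_cohort(seed = 13, n = 100, sites = 200)
  vm <- filter_biallelic_mac(sim$matrix)
  pca <- run_local_pca(vm)
  res_full <- classify_stripes(pca, sim$anchors, "3Ra")
  # drop a third of the non-anchor specimens and re-run
  non_anchor <- setdiff(vm$specimens, sim$anchors$specimen)
  drop <- non_anchor[seq_len(floor(length(non_anchor) / 3))]
  keep <- !(vm$specimens %in% drop)
  vm2 <- variant_matrix(vm$geno[keep, , drop = FALSE], vm$sites,
                        vm$specimens[keep])
  res_sub <- classify_stripes(run_local_pca(vm2), sim$anchors, "3Ra")
  common <- intersect(res_full$calls$specimen, res_sub$calls$specimen)
  g1 <- res_full$calls$genotype[match(common, res_full$calls$specimen)]
  g2 <- res_sub$calls$genotype[match(common, res_sub$calls$specimen)]
  conf <- res_full$calls$conforming[match(common, res_full$calls$specimen)] &
    res_sub$calls$conforming[match(common, res_sub$calls$specimen)]
  expect_true(all(g1[conf] == g2[conf]))
})

test_that("outlier specimens from an offset population are flagged", {
  sim <- small_cohort(seed = 14, n = 150, sites = 400, n_outliers = 6,
                      outlier_offset = 0.5)
  pca <- run_local_pca(filter_biallelic_mac(sim$matrix))
  res <- classify_stripes(pca, sim$anchors, "3Ra")
  flagged <- res$calls$specimen[!res$calls$conforming]
  expect_gt(length(intersect(flagged, sim$truth$outliers)), 0)
})
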