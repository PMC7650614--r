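pca_calls_from <- function(genotypes, specimens = names(genotypes),
                           conforming = TRUE) {
  karyotype_calls(specimens, "inv", genotypes, "PCA", conforming)
}

test_that("tag concordance uses jointly called, conforming specimens", {
  # 10 comparable specimens, 8 equal: at the 80% rule boundary
  pc <- pca_calls_from(stats::setNames(c(rep(0L, 5), rep(2L, 5)),
                                       paste0("s", 1:10)))
  snp <- stats::setNames(c(rep(0L, 4), 2L, rep(2L, 4), 0L), paste0("s", 1:10))
  r <- tag_concordance(snp, pc)
  expect_equal(r$concordance, 0.8)
  expect_equal(r$n_compared, 10L)

  # perfect tag
  r2 <- tag_concordance(stats::setNames(c(rep(0L, 5), rep(2L, 5)),
                                        paste0("s", 1:10)), pc)
  expect_equal(r2$concordance, 1.0)

  # missing SNP call and non-conforming PCA call shrink the denominator:
  # of 6 specimens, 1 missing SNP + 1 non-conforming leave n = 4, 3 equal
  pc6 <- karyotype_calls(paste0("s", 1:6), "inv",
                         c(0L, 0L, 1L, 1L, 2L, 2L), "PCA",
                         conforming = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  snp6 <- stats::setNames(c(0L, NA, 1L, 1L, 0L, 2L), paste0("s", 1:6))
  r3 <- tag_concordance(snp6, pc6)
  expect_equal(r3$n_compared, 4L)
  expect_equal(r3$concordance, 0.75)

  # empty denominator: undefined, not zero
  r4 <- tag_concordance(stats::setNames(NA_integer_, "s1"), pc)
  expect_true(is.na(r4$concordance))
  expect_equal(r4$n_compared, 0L)
})

test_that("concordance is invariant to specimen order", {
  set.seed(42)
  specimens <- paste0("s", 1:30)
  pc <- pca_calls_from(stats::setNames(sample(0:2, 30, TRUE), specimens))
  snp <- stats::setNames(sample(c(0:2, NA), 30, TRUE), specimens)
  r1 <- tag_concordance(snp, pc)
  perm <- sample(30)
  r2 <- tag_concordance(snp[perm], pc[sample(30), ])
  expect_equal(r1, r2)
})

test_that("ascertainment keeps >= 0.80 concordant sites, fixed polarity", {
  n <- 40
  specimens <- paste0("s", 1:n)
  pca_g <- stats::setNames(rep(0:2, length.out = n), specimens)
  pc <- pca_calls_from(pca_g)
  # site 1: identical to PCA genotypes; site 2: reversed polarity (2 - g);
  # site 3: exactly 80% agreement; site 4: 50% agreement
  g1 <- pca_g
  g2 <- 2L - pca_g
  g3 <- pca_g; flip <- 1:8          # 8/40 disagree -> exactly 0.80
  g3[flip] <- (pca_g[flip] + 1L) %% 3L
  g4 <- pca_g; g4[1:20] <- (pca_g[1:20] + 1L) %% 3L
  vm <- variant_matrix(cbind(g1, g2, g3, g4),
                       data.frame(contig = "3R", pos = c(100, 300, 500, 700),
                                  ref = "A", alt = "G"), specimens)
  cand <- ascertain_tags(vm, pc, karyotag_thresholds(), "3Ra")
  # reversed polarity still agrees for heterozygotes (2 - 1 = 1): 13 of 40
  expect_equal(cand$concordance, c(1.0, 13 / 40, 0.8, 0.5))
  # boundary 0.80 passes ("at least 80%"); reversed polarity is never
  # flipped into a pass but is reported as a diagnostic
  expect_equal(cand$pass_concordance, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cand$would_pass_flipped, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("a tiny denominator invalidates an otherwise perfect tag", {
  specimens <- paste0("s", 1:30)
  pc <- pca_calls_from(stats::setNames(rep(0:2, each = 10), specimens))
  g <- stats::setNames(rep(c(0L, NA, NA), each = 10), specimens)
  vm <- variant_matrix(matrix(g, ncol = 1),
                       data.frame(contig = "3R", pos = 10, ref = "A",
                                  alt = "G"), specimens)
  cand <- ascertain_tags(vm, pc)  # n_compared = 10 < 20
  expect_equal(cand$concordance, 1.0)
  expect_false(cand$pass_concordance)
})

test_that("neighbour filter removes candidates with close polymorphisms", {
  specimens <- paste0("s", 1:4)
  pos <- c(100, 112, 200, 231, 400)
  vm <- variant_matrix(matrix(1L, 4, 5),
                       data.frame(contig = "3R", pos = pos, ref = "A",
                                  alt = "G"), specimens)
  cand <- data.frame(inversion = "3Ra", contig = "3R",
                     pos = c(100, 200, 400), ref = "A", alt = "G",
                     concordance = 1, n_compared = 4,
                     pass_concordance = TRUE, would_pass_flipped = FALSE,
                     pass_neighbor = NA, pass = TRUE,
                     stringsAsFactors = FALSE)
  class(cand) <- c("tag_candidates", "data.frame")
  out <- assay_neighbor_filter(cand, vm)
  # neighbour at distance 12 removes; nearest at 31 retains (<= 30 rule);
  # isolated site retains
  expect_equal(out$pass_neighbor, c(FALSE, TRUE, TRUE))
  log <- attr(out, "neighbor_log")
  expect_equal(log$candidate_pos, 100)
  expect_equal(log$neighbor_pos, 112)
  expect_equal(log$distance, 12)
})

test_that("neighbour filter equals a brute-force all-pairs scan", {
  set.seed(7)
  for (rep in 1:5) {
    pos <- sort(sample(1:2000, 40))
    vm <- variant_matrix(matrix(1L, 3, 40),
                         data.frame(contig = "3R", pos = pos, ref = "A",
                                    alt = "G"), paste0("s", 1:3))
    cand <- data.frame(inversion = "i", contig = "3R", pos = pos,
                       ref = "A", alt = "G", concordance = 1,
                       n_compared = 3, pass_concordance = TRUE,
                       would_pass_flipped = FALSE, pass_neighbor = NA,
                       pass = TRUE, stringsAsFactors = FALSE)
    class(cand) <- c("tag_candidates", "data.frame")
    out <- assay_neighbor_filter(cand, vm)
    bf <- vapply(pos, function(p) {
      !any(abs(pos - p) <= 30 & pos != p)
    }, TRUE)
    expect_equal(out$pass_neighbor, bf)
  }
})

test_that("mean concordance of inside sites rises with divergence", {
  mean_conc <- vapply(c(0.2, 0.6, 1.0), function(d) {
    vals <- vapply(1:3, function(seed) {
      sim <- small_cohort(seed = seed, n = 80, sites = 120, d = d, miss = 0)
      pc <- karyotype_calls(names(sim$truth$genotype), "3Ra",
                            sim$truth$genotype, "PCA", TRUE)
      cand <- ascertain_tags(sim$matrix, pc)
      mean(cand$concordance)
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_conc) > 0))
})

test_that("at full divergence every site tags perfectly without missingness", {
  sim <- small_cohort(seed = 21, n = 60, sites = 80, d = 1, miss = 0)
  pc <- karyotype_calls(names(sim$truth$genotype), "3Ra",
                        sim$truth$genotype, "PCA", TRUE)
  cand <- ascertain_tags(sim$matrix, pc)
  expect_true(all(cand$concordance == 1))
  expect_true(all(cand$pass_concordance))
})
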