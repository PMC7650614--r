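# Fixtures are built in code at test time; nothing binary is stored.

# write a small VCF: `sites` has contig/pos/ref/alt (alt may be multiallelic
# or indel strings to exercise filters); `gt` is a character matrix of GT
# strings, sites x specimens
write_test_vcf <- function(path, sites, gt,
                           specimens = paste0("s", seq_len(ncol(gt)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", specimens), collapse = "\t"))
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$contig[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  path
}

# genotype matrix -> GT strings (sites x specimens), NA -> ./.
geno_to_gt <- function(geno_t) {
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  out <- matrix("./.", nrow(geno_t), ncol(geno_t))
  ok <- !is.na(geno_t)
  out[ok] <- code[as.character(geno_t[ok])]
  out
}

# independent brute-force oracle: mean of called tags binned at 2/3, 4/3
bf_call_inversion <- function(tags) {
  called <- tags[!is.na(tags)]
  if (length(called) == 0) return(list(mean = NA_real_, g = NA_integer_))
  m <- sum(called) / length(called)
  g <- if (m <= 2 / 3) 0L else if (m <= 4 / 3) 1L else 2L
  list(mean = m, g = g)
}

# independent brute-force oracle for the tag-then-specimen QC filters
bf_qc <- function(m, min_rate = 0.8) {
  keep_t <- apply(m, 2, function(col) mean(!is.na(col)) >= min_rate)
  m2 <- m[, keep_t, drop = FALSE]
  keep_s <- apply(m2, 1, function(row) {
    if (ncol(m2) == 0) FALSE else mean(!is.na(row)) >= min_rate
  })
  m2[keep_s, , drop = FALSE]
}

# independent brute-force oracle for the count-ratio genotyper
bf_ratio_genotype <- function(c1, c2) {
  if (c1 + c2 <= 10) return(NA_integer_)
  if (c2 == 0) r <- Inf else r <- c1 / c2
  if (c1 == 0) r <- 0
  if (r >= 10) return(0L)
  if (r <= 0.1) return(2L)
  if (r >= 0.2 && r <= 5) return(1L)
  NA_integer_
}

# small simulated cohort shared across tests
small_cohort <- function(seed = 1, n = 120, sites = 300, q = 0.4, d = 0.8,
                         miss = 0.05, ...) {
  simulate_inversion_cohort(sim_config(n_specimens = n, n_sites = sites,
                                       inv_freq = q, divergence = d,
                                       missing_rate = miss, seed = seed, ...))
}
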