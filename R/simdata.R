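#' Configuration for the synthetic inversion cohort simulator
#'
#' The simulator emulates the minimal statistical structure the karyotyping
#' method relies on: inside an inversion, suppressed recombination keeps the
#' two orientations diverged, so each site carries orientation-specific
#' alternate-allele frequencies separated by a divergence `d`; specimens
#' draw two orientation chromosomes at the inversion frequency `q`
#' (Hardy-Weinberg), alleles are independent given orientation (no
#' background linkage disequilibrium), genotype missingness is uniform, a
#' subset of specimens is karyotyped as anchors (with an optional
#' cytogenetic error rate), and amplicon read counts per locus follow a
#' Poisson depth model with per-read probe corruption.
#'
#' @param n_specimens Cohort size (>= 3). Default 300.
#' @param n_sites Sites inside the inversion. Default 1000.
#' @param inv_freq Inversion (inverted-orientation) frequency q in [0,1].
#'   Default 0.4.
#' @param divergence Per-site allele-frequency separation d in [0,1]
#'   between orientations. Default 0.8.
#' @param beta_shape Shape of the symmetric Beta distribution the base
#'   allele frequency is drawn from (rescaled into [d/2, 1 - d/2] so the
#'   two orientation frequencies stay in [0,1]). Default 0.8.
#' @param missing_rate Per-genotype missingness. Default 0.05.
#' @param anchor_fraction Fraction of specimens with a cytogenetic
#'   karyotype. Default 0.2.
#' @param anchor_error Probability an anchor's cytogenetic genotype is
#'   mis-scored (replaced by a different genotype). Default 0.
#' @param n_outliers Number of specimens drawn from a second, offset
#'   population (creates non-conforming specimens). Default 0.
#' @param outlier_offset Allele-frequency offset of the outlier population.
#'   Default 0.35.
#' @param depth_mean Mean Poisson read depth per locus. Default 100.
#' @param read_error Per-read probe-corruption probability. Default 0.005.
#' @param inversion An [inversion_def] giving the simulated span; default
#'   the 3Ra span.
#' @param seed Mandatory integer seed; every draw is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_specimens = 300L, n_sites = 1000L,
                       inv_freq = 0.4, divergence = 0.8,
                       beta_shape = 0.8, missing_rate = 0.05,
                       anchor_fraction = 0.2, anchor_error = 0,
                       n_outliers = 0L, outlier_offset = 0.35,
                       depth_mean = 100, read_error = 0.005,
                       inversion = funestus_inversions()[["3Ra"]],
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  probs <- c(inv_freq, divergence, missing_rate, anchor_fraction,
             anchor_error, read_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (n_specimens < 3) stop("need at least 3 specimens")
  structure(list(n_specimens = as.integer(n_specimens),
                 n_sites = as.integer(n_sites),
                 inv_freq = inv_freq, divergence = divergence,
                 beta_shape = beta_shape, missing_rate = missing_rate,
                 anchor_fraction = anchor_fraction,
                 anchor_error = anchor_error,
                 n_outliers = as.integer(n_outliers),
                 outlier_offset = outlier_offset,
                 depth_mean = depth_mean, read_error = read_error,
                 inversion = inversion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an inversion-polymorphic cohort with full truth
#'
#' Each specimen draws two orientation chromosomes Bernoulli(q); each site
#' gets a base alternate-allele frequency from a rescaled symmetric Beta
#' and orientation frequencies `base - d/2` (standard) and `base + d/2`
#' (inverted), so the separation is exactly `d`; per-chromosome alleles are
#' drawn independently given orientation and summed to a genotype;
#' missingness is applied uniformly; anchors are sampled and corrupted at
#' the anchor error rate. Optional outlier specimens draw alleles from a
#' third, offset frequency vector regardless of orientation, producing the
#' off-stripe points the conformity check is designed to catch.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (a [variant_matrix]), `anchors` (an
#'   [anchor_set()]), and `truth`: per-specimen true genotype, the
#'   pre-missingness genotype matrix `geno_full`, orientation frequencies
#'   `p_std` / `p_inv`, site positions, and the outlier specimen ids.
#' @export
simulate_inversion_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_specimens; L <- config$n_sites
  d <- config$divergence; q <- config$inv_freq
  inv <- config$inversion

  span <- inv$end - inv$start
  if (L > span) stop("more sites than positions in the inversion span")
  pos <- sort(sample.int(span + 1, L)) + inv$start - 1
  base <- stats::rbeta(L, config$beta_shape, config$beta_shape)
  base <- d / 2 + base * (1 - d)
  p_std <- base - d / 2
  p_inv <- base + d / 2

  specimens <- sprintf("sim%03d", seq_len(n))
  chrom1 <- stats::rbinom(n, 1, q)
  chrom2 <- stats::rbinom(n, 1, q)
  true_geno <- chrom1 + chrom2
  names(true_geno) <- specimens

  draw_alleles <- function(orient) {
    p <- ifelse(orient == 1, 1, 0) %o% p_inv + ifelse(orient == 0, 1, 0) %o% p_std
    matrix(stats::rbinom(n * L, 1, as.vector(p)), n, L)
  }
  geno_full <- draw_alleles(chrom1) + draw_alleles(chrom2)

  outliers <- character(0)
  if (config$n_outliers > 0) {
    oidx <- seq_len(min(config$n_outliers, n))
    outliers <- specimens[oidx]
    shift <- sample(c(-1, 1), L, replace = TRUE) * config$outlier_offset
    p_out <- pmin(pmax(base + shift, 0), 1)
    for (i in oidx) {
      geno_full[i, ] <- stats::rbinom(L, 2, p_out)
    }
  }

  geno <- geno_full
  miss <- matrix(stats::runif(n * L) < config$missing_rate, n, L)
  geno[miss] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  sites <- data.frame(contig = inv$contig, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  vm <- variant_matrix(geno, sites, specimens)

  n_anchor <- round(config$anchor_fraction * n)
  anchor_ids <- sort(sample(specimens, n_anchor))
  anchor_geno <- true_geno[anchor_ids]
  err <- stats::runif(n_anchor) < config$anchor_error
  if (any(err)) {
    anchor_geno[err] <- vapply(anchor_geno[err], function(g) {
      sample(setdiff(0:2, g), 1)
    }, 0)
  }
  anchors <- anchor_set(anchor_ids, anchor_geno)

  list(matrix = vm,
       anchors = anchors,
       truth = list(genotype = true_geno,
                    geno_full = geno_full,
                    p_std = p_std, p_inv = p_inv,
                    positions = pos,
                    outliers = outliers))
}

#' Design synthetic probe assays for a set of tag sites
#'
#' Builds, for each tag site, a pair of probe oligomers embedded in a
#' random flanking context, differing only at the central (tag) base:
#' probe 1 carries the reference base, probe 2 the alternate. Contexts are
#' drawn to be unique across loci. These are synthetic stand-ins for
#' laboratory assay designs and are suitable for simulation and testing.
#'
#' @param sites Data frame with columns contig, pos, ref, alt (and
#'   optionally inversion); e.g. passing rows of a `tag_candidates` table.
#' @param probe_len Odd probe length, default 21.
#' @param seed Integer seed for the flank draw.
#' @return A [locus_assays()] table, locus names `contig_pos`.
#' @export
design_probe_assays <- function(sites, probe_len = 21L, seed = 1L) {
  stopifnot(probe_len %% 2 == 1)
  set.seed(seed)
  half <- (probe_len - 1) / 2
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  repeat {
    left <- vapply(seq_len(n), function(i)
      paste(sample(bases, half, replace = TRUE), collapse = ""), "")
    right <- vapply(seq_len(n), function(i)
      paste(sample(bases, half, replace = TRUE), collapse = ""), "")
    if (!anyDuplicated(paste(left, right))) break
  }
  inv <- if ("inversion" %in% names(sites)) sites$inversion else "inv"
  locus_assays(locus = paste0(sites$contig, "_", sites$pos),
               inversion = inv,
               probe1 = paste0(left, sites$ref, right),
               probe2 = paste0(left, sites$alt, right),
               contig = sites$contig, pos = sites$pos,
               ref = sites$ref, alt = sites$alt)
}

#' Simulate amplicon reads for assayed tag loci
#'
#' For each (specimen, locus), a Poisson(depth_mean) number of reads is
#' drawn; each read carries the allele-1 or allele-2 probe according to the
#' specimen's true tag genotype (heterozygotes: each read picks an allele
#' with probability 1/2), embedded between short fixed adapters; with
#' probability `read_error` the probe is corrupted at one position,
#' yielding an unassigned read.
#'
#' @param cohort Output of [simulate_inversion_cohort()] (its truth table
#'   supplies the per-locus true genotypes).
#' @param assays A [locus_assays()] table whose `pos` values reference
#'   simulated sites.
#' @param config The [sim_config()] used for the cohort.
#' @return Named list (by specimen) of character vectors of read
#'   sequences; attribute `true_tag_geno` holds the specimen x locus truth
#'   matrix.
#' @export
simulate_amplicon_reads <- function(cohort, assays, config) {
  stopifnot(inherits(assays, "locus_assays"))
  set.seed(config$seed + 77003L)
  site_idx <- match(assays$pos, cohort$truth$positions)
  if (anyNA(site_idx)) {
    stop("assay locus without a simulated truth entry: ",
         paste(assays$locus[is.na(site_idx)], collapse = ", "))
  }
  specimens <- cohort$matrix$specimens
  truth <- cohort$truth$geno_full[, site_idx, drop = FALSE]
  colnames(truth) <- assays$locus
  rownames(truth) <- specimens
  adapter5 <- "ACGTTGCA"; adapter3 <- "TGCAACGT"
  bases <- c("A", "C", "G", "T")

  reads <- vector("list", length(specimens))
  names(reads) <- specimens
  for (i in seq_along(specimens)) {
    rs <- character(0)
    for (j in seq_len(nrow(assays))) {
      depth <- stats::rpois(1, config$depth_mean)
      if (depth == 0) next
      g <- truth[i, j]
      alt_read <- switch(as.character(g),
                         `0` = rep(FALSE, depth),
                         `1` = stats::runif(depth) < 0.5,
                         `2` = rep(TRUE, depth))
      probe <- ifelse(alt_read, assays$probe2[j], assays$probe1[j])
      corrupt <- stats::runif(depth) < config$read_error
      if (any(corrupt)) {
        probe[corrupt] <- vapply(probe[corrupt], function(p) {
          k <- sample.int(nchar(p), 1)
          b <- substr(p, k, k)
          substr(p, k, k) <- sample(setdiff(bases, b), 1)
          p
        }, "")
      }
      rs <- c(rs, paste0(adapter5, probe, adapter3))
    }
    reads[[i]] <- rs
  }
  attr(reads, "true_tag_geno") <- truth
  reads
}

#' Write per-specimen reads as FASTQ files
#'
#' One file per specimen, named `<specimen>.fastq`, uniform quality.
#'
#' @param reads Named list of character vectors (see
#'   [simulate_amplicon_reads()]).
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths.
#' @export
write_fastq_per_specimen <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(reads))
  names(paths) <- names(reads)
  for (s in names(reads)) {
    rs <- reads[[s]]
    path <- file.path(dir, paste0(s, ".fastq"))
    if (length(rs) > 0) {
      qual <- vapply(nchar(rs), function(n)
        paste(rep("I", n), collapse = ""), "")
      writeLines(as.vector(rbind(paste0("@", s, "_read", seq_along(rs)),
                                 rs, "+", qual)), path)
    } else {
      file.create(path)
    }
    paths[s] <- path
  }
  paths
}
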