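#' Define allele-specific probe assays for tag loci
#'
#' Each locus is scored by two short probe oligomers spanning the tag SNP:
#' one containing the reference (allele 1) base, one the alternate
#' (allele 2) base. A read supports an allele when it contains the probe as
#' an exact substring (forward strand only; assay orientation is fixed by
#' the panel design).
#'
#' @param locus Character vector of unique locus names.
#' @param inversion Inversion name per locus.
#' @param probe1,probe2 Allele-1 (reference) and allele-2 (alternate)
#'   probe sequences; non-empty, unequal within a locus.
#' @param contig,pos,ref,alt Optional genomic link to the tag site.
#' @return A `locus_assays` data frame.
#' @export
locus_assays <- function(locus, inversion, probe1, probe2,
                         contig = NA_character_, pos = NA_real_,
                         ref = NA_character_, alt = NA_character_) {
  if (length(locus) == 0) stop("empty assay list")
  if (anyDuplicated(locus)) stop("duplicate locus names")
  probe1 <- toupper(probe1); probe2 <- toupper(probe2)
  if (any(!nzchar(probe1)) || any(!nzchar(probe2))) {
    stop("probes must be non-empty")
  }
  if (any(probe1 == probe2)) stop("probe1 and probe2 must differ")
  structure(data.frame(locus = as.character(locus),
                       inversion = as.character(inversion),
                       probe1 = probe1, probe2 = probe2,
                       contig = contig, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
            class = c("locus_assays", "data.frame"))
}

#' Read assay definitions from TSV
#' @param path TSV with columns locus, inversion, probe1, probe2 and
#'   optionally contig, pos, ref, alt.
#' @return A `locus_assays` data frame.
#' @export
read_assay_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  locus_assays(df$locus, df$inversion, df$probe1, df$probe2,
               contig = if ("contig" %in% names(df)) df$contig else NA,
               pos = if ("pos" %in% names(df)) df$pos else NA,
               ref = if ("ref" %in% names(df)) df$ref else NA,
               alt = if ("alt" %in% names(df)) df$alt else NA)
}

#' Count allele-specific amplicon reads per specimen and locus
#'
#' For each read, every probe of every locus is tested for exact substring
#' occurrence. A read matching exactly one probe of exactly one locus
#' increments that allele's count; a read matching probes of more than one
#' locus, or both probes of one locus, is discarded as ambiguous; a read
#' matching no probe is tallied as unassigned. Each read counts at most
#' once.
#'
#' @param reads Either a named list of character vectors of read sequences
#'   (one element per specimen) or a named character vector of FASTQ file
#'   paths (names are specimen ids; plain or gzipped).
#' @param assays A [locus_assays()] data frame.
#' @return An `allele_counts` data frame with one row per
#'   (specimen, locus): columns specimen, locus, inversion, count1, count2,
#'   plus per-specimen tallies in the `read_summary` attribute (n_reads,
#'   n_ambiguous, n_unassigned).
#' @export
count_alleles <- function(reads, assays) {
  stopifnot(inherits(assays, "locus_assays"))
  if (is.character(reads)) {
    paths <- reads
    reads <- lapply(paths, function(p) {
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
    })
    names(reads) <- names(paths)
  }
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    stop("reads must be named by specimen")
  }
  n_loci <- nrow(assays)
  probes <- c(assays$probe1, assays$probe2)  # locus-major: 1..n then n+1..2n
  out <- vector("list", length(reads))
  summ <- data.frame(specimen = names(reads), n_reads = 0L,
                     n_ambiguous = 0L, n_unassigned = 0L,
                     stringsAsFactors = FALSE)
  for (s in seq_along(reads)) {
    rs <- toupper(reads[[s]])
    hits <- matrix(FALSE, nrow = length(rs), ncol = 2L * n_loci)
    for (p in seq_along(probes)) {
      hits[, p] <- grepl(probes[p], rs, fixed = TRUE)
    }
    locus_hit <- hits[, seq_len(n_loci), drop = FALSE] |
      hits[, n_loci + seq_len(n_loci), drop = FALSE]
    n_locus_hits <- rowSums(locus_hit)
    both_probes <- rowSums(hits[, seq_len(n_loci), drop = FALSE] &
                           hits[, n_loci + seq_len(n_loci), drop = FALSE]) > 0
    ambiguous <- n_locus_hits > 1 | both_probes
    unassigned <- n_locus_hits == 0
    usable <- !ambiguous & !unassigned
    count1 <- colSums(hits[usable, seq_len(n_loci), drop = FALSE])
    count2 <- colSums(hits[usable, n_loci + seq_len(n_loci), drop = FALSE])
    out[[s]] <- data.frame(specimen = names(reads)[s],
                           locus = assays$locus,
                           inversion = assays$inversion,
                           count1 = as.integer(count1),
                           count2 = as.integer(count2),
                           stringsAsFactors = FALSE)
    summ$n_reads[s] <- length(rs)
    summ$n_ambiguous[s] <- sum(ambiguous)
    summ$n_unassigned[s] <- sum(unassigned)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "read_summary") <- summ
  class(res) <- c("allele_counts", "data.frame")
  res
}

#' Convert allele read counts to a tag-SNP genotype
#'
#' Applies the GT-seq ratio rules: with total reads
#' `count1 + count2 > min_total_reads` (strictly), the ratio
#' `r = count1 / count2` is called homozygous allele 1 (genotype 0) when
#' `r >= ratio_hom1`, homozygous allele 2 (genotype 2) when
#' `r <= ratio_hom2`, heterozygous (genotype 1) when
#' `het_low <= r <= het_high`, and left uncalled (`NA`) in the ambiguous
#' bands between. Totals at or below `min_total_reads` are uncalled.
#' Genotypes count alternate (allele 2) dose. Vectorised.
#'
#' @param count1,count2 Non-negative integer vectors of allele-1 and
#'   allele-2 read counts.
#' @param thresholds A [karyotag_thresholds] object.
#' @return Integer vector of genotypes in {0,1,2,NA}.
#' @export
call_genotype_from_counts <- function(count1, count2,
                                      thresholds = karyotag_thresholds()) {
  if (any(count1 < 0, na.rm = TRUE) || any(count2 < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  total <- count1 + count2
  r <- ifelse(count2 == 0, Inf, count1 / count2)
  r[count1 == 0] <- 0
  g <- rep(NA_integer_, length(total))
  g[r >= thresholds$ratio_hom1] <- 0L
  g[r <= thresholds$ratio_hom2] <- 2L
  g[r >= thresholds$het_low & r <= thresholds$het_high] <- 1L
  g[total <= thresholds$min_total_reads] <- NA_integer_
  g
}

#' Genotype an allele-count table into a tag genotype matrix
#'
#' @param counts An `allele_counts` data frame from [count_alleles()] (or
#'   any data frame with specimen, locus, inversion, count1, count2).
#' @param thresholds A [karyotag_thresholds] object.
#' @param method Platform label for the resulting matrix ("AS" or "OA").
#' @return A [tag_genotype_matrix()].
#' @export
genotype_allele_counts <- function(counts,
                                   thresholds = karyotag_thresholds(),
                                   method = "AS") {
  g <- call_genotype_from_counts(counts$count1, counts$count2, thresholds)
  specimens <- unique(counts$specimen)
  loci <- unique(counts$locus)
  m <- matrix(NA_integer_, length(specimens), length(loci),
              dimnames = list(specimens, loci))
  m[cbind(match(counts$specimen, specimens), match(counts$locus, loci))] <- g
  inv <- counts$inversion[match(loci, counts$locus)]
  tag_genotype_matrix(m, tag_inversion = inv, method = method)
}
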