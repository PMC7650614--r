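#' Specimen-by-site genotype matrix of alternate-allele counts
#'
#' The central container for within-inversion SNP genotypes. Genotypes are
#' coded 0, 1 or 2 as the count of alternate alleles at a biallelic site;
#' uncalled or half-called genotypes are `NA`. Rows are specimens, columns
#' are sites.
#'
#' @param geno Integer matrix, specimens x sites, values in {0,1,2,NA}.
#' @param sites Data frame with columns contig, pos (1-based), ref, alt;
#'   one row per column of `geno`, positions strictly increasing within a
#'   contig.
#' @param specimens Character vector of specimen identifiers, one per row
#'   of `geno`.
#' @return A `variant_matrix` object.
#' @export
variant_matrix <- function(geno, sites, specimens = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(specimens)) stop("specimen identifiers required")
  stopifnot(nrow(geno) == length(specimens),
            ncol(geno) == nrow(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("site positions must be strictly increasing within contig ", ctg)
    }
  }
  rownames(geno) <- specimens
  if (ncol(geno) > 0) colnames(geno) <- paste0(sites$contig, ":", sites$pos)
  structure(list(geno = geno,
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 specimens = as.character(specimens)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d specimens x %d sites, %.1f%% missing\n",
              length(x$specimens), nrow(x$sites),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) dim(x$geno)

# parse diploid GT strings ("0/1", "1|0", "./.", ...) to alt-allele counts
parse_gt_diploid <- function(gt, record_id) {
  gt <- sub(":.*$", "", gt)
  gt[is.na(gt) | gt == "."] <- "./."
  parts <- strsplit(gt, "[/|]")
  n_all <- lengths(parts)
  if (any(n_all != 2)) {
    stop("mixed-ploidy genotype in record ", record_id,
         " (expected diploid calls)")
  }
  al <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  a1 <- suppressWarnings(as.integer(al[, 1]))
  a2 <- suppressWarnings(as.integer(al[, 2]))
  out <- a1 + a2
  out[is.na(a1) | is.na(a2)] <- NA_integer_  # uncalled or half-called
  if (any(out > 2, na.rm = TRUE)) {
    stop("non-biallelic allele index in record ", record_id)
  }
  out
}

#' Load within-inversion SNP genotypes from a VCF
#'
#' Reads a VCF, restricts records to the inversion's breakpoint span
#' (boundary-inclusive at both ends), removes records overlapping an
#' optional site mask, drops multiallelic and non-SNP records, and encodes
#' diploid genotypes as alternate-allele counts. Multiallelic records are
#' dropped rather than decomposed: downstream ascertainment assumes one
#' alternate allele per site.
#'
#' @param vcf_source Path to a VCF (v4.x) file, plain or gzipped.
#' @param inversion An [inversion_def]; only sites on its contig with
#'   `start <= pos <= end` are retained.
#' @param mask Optional `site_mask` of intervals to exclude (BED dialect,
#'   0-based half-open).
#' @return A [variant_matrix] with the full specimen list; zero sites if no
#'   record overlaps the span.
#' @export
load_variant_matrix <- function(vcf_source, inversion, mask = NULL) {
  stopifnot(inherits(inversion, "inversion_def"))
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_source, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_source, "': ",
                             conditionMessage(e))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  specimens <- colnames(vcf@gt)[-1]
  if (is.null(specimens)) stop("VCF has no genotype columns")
  pos <- as.numeric(fix$POS)

  keep <- fix$CHROM == inversion$contig &
    pos >= inversion$start & pos <= inversion$end
  # biallelic SNPs only: single-base REF and single-base ALT, no comma
  keep <- keep & nchar(fix$REF) == 1 & !is.na(fix$ALT) &
    !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!is.null(mask) && any(keep)) {
    keep[keep] <- !mask_covers(mask, fix$CHROM[keep], pos[keep])
  }

  idx <- which(keep)
  idx <- idx[order(pos[idx])]
  sites <- data.frame(contig = fix$CHROM[idx], pos = pos[idx],
                      ref = fix$REF[idx], alt = fix$ALT[idx],
                      stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nrow = length(specimens), ncol = length(idx))
  if (length(idx) > 0) {
    gt <- vcf@gt[idx, -1, drop = FALSE]
    for (j in seq_along(idx)) {
      rec_id <- paste0(sites$contig[j], ":", sites$pos[j])
      geno[, j] <- parse_gt_diploid(gt[j, ], rec_id)
    }
  }
  variant_matrix(geno, sites, specimens)
}

#' Keep biallelic sites with minor-allele count at or above a threshold
#'
#' The minor-allele count (MAC) at a site is the number of chromosomes
#' carrying the rarer allele, counted over called genotypes only: with
#' `n` called diploid specimens and `a` alternate alleles among them,
#' MAC = min(a, 2n - a). Sites with MAC below `thresholds$min_mac` are
#' removed; the specimen list is unchanged. Idempotent.
#'
#' @param matrix A [variant_matrix].
#' @param thresholds A [karyotag_thresholds] object.
#' @return A filtered [variant_matrix].
#' @export
filter_biallelic_mac <- function(matrix, thresholds = karyotag_thresholds()) {
  stopifnot(inherits(matrix, "variant_matrix"))
  mac <- site_mac(matrix)
  keep <- mac >= thresholds$min_mac
  variant_matrix(matrix$geno[, keep, drop = FALSE],
                 matrix$sites[keep, , drop = FALSE],
                 matrix$specimens)
}

#' Per-site minor-allele count over called genotypes
#' @param matrix A [variant_matrix].
#' @return Integer vector, one MAC per site.
#' @export
site_mac <- function(matrix) {
  g <- matrix$geno
  alt <- colSums(g, na.rm = TRUE)
  called <- colSums(!is.na(g))
  as.integer(pmin(alt, 2L * called - alt))
}

#' Write a variant matrix as a minimal VCF
#'
#' Emits a VCF v4.2 file with GT-only genotype fields so that matrices
#' (including simulated cohorts) round-trip through standard VCF tooling.
#'
#' @param matrix A [variant_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "variant_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=karyotag",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$specimens), collapse = "\t")
  )
  lines <- character(nrow(matrix$sites))
  for (j in seq_len(nrow(matrix$sites))) {
    g <- matrix$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    lines[j] <- paste(c(matrix$sites$contig[j],
                        format(matrix$sites$pos[j], scientific = FALSE),
                        ".", matrix$sites$ref[j], matrix$sites$alt[j],
                        ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Export / import a variant matrix as TSV
#'
#' Specimen rows, site columns named `contig:pos:ref:alt`, genotype symbols
#' 0/1/2/NA. Useful for small fixtures and spreadsheets.
#'
#' @param matrix A [variant_matrix].
#' @param path File path.
#' @return `path` (write) or a [variant_matrix] (read).
#' @export
write_variant_tsv <- function(matrix, path) {
  df <- as.data.frame(matrix$geno)
  colnames(df) <- paste(matrix$sites$contig, matrix$sites$pos,
                        matrix$sites$ref, matrix$sites$alt, sep = ":")
  df <- cbind(specimen = matrix$specimens, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  specimens <- as.character(df$specimen)
  df$specimen <- NULL
  parts <- strsplit(colnames(df), ":", fixed = TRUE)
  sites <- data.frame(contig = vapply(parts, `[`, "", 1),
                      pos = as.numeric(vapply(parts, `[`, "", 2)),
                      ref = vapply(parts, `[`, "", 3),
                      alt = vapply(parts, `[`, "", 4),
                      stringsAsFactors = FALSE)
  variant_matrix(as.matrix(df), sites, specimens)
}
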