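#' Concordance of one SNP's genotypes with PCA-imputed inversion genotypes
#'
#' A useful tag SNP has an alternate-allele count that equals the number of
#' inverted chromosomes in nearly every specimen. Concordance is the
#' fraction of specimens, among those with both a called SNP genotype and a
#' conforming PCA genotype, whose two values are equal. With an empty
#' denominator the concordance is undefined and returned as `NA`, never 0.
#'
#' @param site_genotypes Named integer vector of alternate-allele counts
#'   (names are specimen ids; `NA` = uncalled).
#' @param pca_calls A [karyotype_calls] data frame with method "PCA";
#'   non-conforming or missing calls are excluded from the denominator.
#' @return List with `concordance` (fraction or `NA`) and `n_compared`.
#' @export
tag_concordance <- function(site_genotypes, pca_calls) {
  pc <- pca_calls[pca_calls$method == "PCA" & !is.na(pca_calls$genotype), ,
                  drop = FALSE]
  if ("conforming" %in% names(pc)) {
    pc <- pc[is.na(pc$conforming) | pc$conforming, , drop = FALSE]
  }
  common <- intersect(names(site_genotypes)[!is.na(site_genotypes)],
                      pc$specimen)
  n <- length(common)
  if (n == 0) return(list(concordance = NA_real_, n_compared = 0L))
  eq <- site_genotypes[common] == pc$genotype[match(common, pc$specimen)]
  list(concordance = sum(eq) / n, n_compared = n)
}

#' Score every site as a candidate tag SNP
#'
#' Computes, for each site in a MAC-filtered matrix, the concordance of its
#' alternate-allele count with the PCA-imputed inversion genotype.
#' Candidates are sites whose concordance meets `tag_concordance_min`
#' (ties at the threshold pass) with at least `min_n_compared` jointly
#' genotyped specimens. Polarity is never flipped: the reference assembly
#' carries the un-inverted arrangement, so the alternate allele must align
#' with inverted dose; a site whose reference allele tracks the inversion
#' simply fails. A diagnostic column reports sites that would have passed
#' with flipped polarity.
#'
#' @param matrix A MAC-filtered [variant_matrix].
#' @param pca_calls A [karyotype_calls] data frame with method "PCA".
#' @param thresholds A [karyotag_thresholds] object.
#' @param inversion_name Label recorded with the candidates.
#' @return A `tag_candidates` data frame: contig, pos, ref, alt,
#'   concordance, n_compared, pass_concordance, would_pass_flipped,
#'   pass_neighbor (NA until [assay_neighbor_filter()] runs), pass.
#' @export
ascertain_tags <- function(matrix, pca_calls,
                           thresholds = karyotag_thresholds(),
                           inversion_name = "inv") {
  stopifnot(inherits(matrix, "variant_matrix"))
  pc <- pca_calls[pca_calls$method == "PCA" & !is.na(pca_calls$genotype), ,
                  drop = FALSE]
  if ("conforming" %in% names(pc)) {
    pc <- pc[is.na(pc$conforming) | pc$conforming, , drop = FALSE]
  }
  if (nrow(pc) == 0) stop("no conforming PCA calls to score against")

  n_sites <- nrow(matrix$sites)
  conc <- numeric(n_sites); ncmp <- integer(n_sites); flip <- numeric(n_sites)
  for (j in seq_len(n_sites)) {
    g <- matrix$geno[, j]
    names(g) <- matrix$specimens
    r <- tag_concordance(g, pc)
    conc[j] <- r$concordance
    ncmp[j] <- r$n_compared
    rf <- tag_concordance(2L - g, pc)
    flip[j] <- rf$concordance
  }
  pass_conc <- !is.na(conc) & conc >= thresholds$tag_concordance_min &
    ncmp >= thresholds$min_n_compared
  would_flip <- !pass_conc & !is.na(flip) &
    flip >= thresholds$tag_concordance_min &
    ncmp >= thresholds$min_n_compared
  out <- data.frame(inversion = inversion_name,
                    contig = matrix$sites$contig,
                    pos = matrix$sites$pos,
                    ref = matrix$sites$ref,
                    alt = matrix$sites$alt,
                    concordance = conc,
                    n_compared = ncmp,
                    pass_concordance = pass_conc,
                    would_pass_flipped = would_flip,
                    pass_neighbor = NA,
                    pass = pass_conc,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tag_candidates", "data.frame")
  out
}

#' Assay-design neighbourhood filter
#'
#' Marker assays (hybridisation probes, locus-specific primers) fail when
#' another polymorphism sits close to the tag. A candidate is removed when
#' any other segregating site of the MAC-filtered matrix lies within
#' `neighbor_window` bases of it on the same contig (distance <= window,
#' inclusive). Each removal is recorded with the offending neighbour.
#'
#' @param candidates A `tag_candidates` data frame from [ascertain_tags()].
#' @param matrix The MAC-filtered [variant_matrix] defining segregating
#'   sites in the candidates' neighbourhoods.
#' @param thresholds A [karyotag_thresholds] object.
#' @return The candidates with `pass_neighbor` filled, `pass` updated, and
#'   a `neighbor_log` attribute (data frame candidate pos, neighbour pos,
#'   distance) listing removals.
#' @export
assay_neighbor_filter <- function(candidates, matrix,
                                  thresholds = karyotag_thresholds()) {
  w <- thresholds$neighbor_window
  pass <- rep(TRUE, nrow(candidates))
  log_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    same <- matrix$sites$contig == candidates$contig[i]
    d <- abs(matrix$sites$pos[same] - candidates$pos[i])
    hit <- which(d <= w & d > 0)
    if (length(hit) > 0) {
      pass[i] <- FALSE
      pos_same <- matrix$sites$pos[same]
      log_rows[[length(log_rows) + 1]] <-
        data.frame(candidate_pos = candidates$pos[i],
                   neighbor_pos = pos_same[hit],
                   distance = d[hit])
    }
  }
  candidates$pass_neighbor <- pass
  candidates$pass <- candidates$pass_concordance & pass
  attr(candidates, "neighbor_log") <-
    if (length(log_rows) > 0) do.call(rbind, log_rows)
    else data.frame(candidate_pos = numeric(0), neighbor_pos = numeric(0),
                    distance = numeric(0))
  candidates
}

#' Assemble the final tag panel
#'
#' @param candidates A `tag_candidates` data frame with all filters applied.
#' @return A `tag_panel`: the passing candidates, positions unique, sorted
#'   by position, with provenance attributes.
#' @export
tag_panel <- function(candidates) {
  panel <- candidates[candidates$pass %in% TRUE, , drop = FALSE]
  if (anyDuplicated(panel[c("contig", "pos")])) {
    stop("duplicate positions in tag panel")
  }
  panel <- panel[order(panel$contig, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("tag_panel", class(candidates))
  panel
}
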