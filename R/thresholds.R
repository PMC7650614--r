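#' Pipeline thresholds
#'
#' Bundles every tunable cut-off used across the pipeline in one object so
#' that a run's parameters can be recorded and overridden coherently.
#'
#' @param min_mac Minimum minor-allele count for a site to be retained
#'   (sites with MAC below this are removed); counted over called
#'   chromosomes only. Default 4.
#' @param tag_concordance_min Minimum fraction of specimens whose tag-SNP
#'   genotype must equal the PCA-imputed inversion genotype for the site to
#'   qualify as a candidate tag ("at least 80 percent" rule). Default 0.80.
#' @param call_rate_min Minimum call rate for tag-SNP and specimen QC;
#'   entries strictly below this are dropped. Default 0.80.
#' @param bin_edges Upper edges of the genotype-0 and genotype-1 bins for
#'   the multilocus mean alternate-allele count. Defaults are exact thirds
#'   \code{c(2/3, 4/3)}; both edges are inclusive in their lower bin.
#' @param strict_printed_bins If \code{TRUE}, use the two-decimal edges
#'   0.67 / 1.33 verbatim instead of exact thirds (audit mode).
#' @param min_total_reads Total allele-1 + allele-2 read count that must be
#'   exceeded (strictly) before a ratio genotype is attempted. Default 10.
#' @param neighbor_window Distance in bases within which another segregating
#'   site disqualifies a candidate tag for assay design (inclusive).
#'   Default 30.
#' @param ratio_hom1,ratio_hom2 Allele-1/allele-2 count-ratio cut-offs for
#'   homozygous calls: ratio >= \code{ratio_hom1} gives homozygous allele 1
#'   (genotype 0), ratio <= \code{ratio_hom2} gives homozygous allele 2
#'   (genotype 2). Defaults 10 and 0.1, inherited from the GT-seq
#'   genotyping pipeline.
#' @param het_low,het_high Ratio band called heterozygous (genotype 1),
#'   inclusive. Defaults 0.2 and 5 (inherited as above); ratios falling in
#'   the ambiguous bands between the homozygote and heterozygote cut-offs
#'   are left uncalled.
#' @param min_n_compared Minimum number of jointly genotyped specimens for
#'   a tag concordance estimate to be considered valid. Default 20.
#' @param conformity_alpha A specimen is non-conforming when its distance to
#'   its stripe centre exceeds \code{conformity_alpha} times half the
#'   minimum inter-centre gap. Default 0.8.
#' @param equidist_max Maximum tolerated deviation of the middle stripe
#'   centre from the midpoint of the outer centres, as a fraction of the
#'   outer gap. Default 0.25.
#' @param spread_max Maximum tolerated within-stripe standard deviation, as
#'   a fraction of the minimum inter-centre gap. Default 0.30.
#' @param pc2_outlier_mult A specimen is non-conforming when its PC2
#'   deviation from the cohort median exceeds this multiple of the robust
#'   PC2 spread (MAD, floored at 1 percent of the PC1 standard deviation);
#'   catches specimens displaced off the stripe axis by residual population
#'   structure. Default 6.
#'
#' @return An object of class \code{karyotag_thresholds} (a named list).
#' @export
karyotag_thresholds <- function(min_mac = 4L,
                                tag_concordance_min = 0.80,
                                call_rate_min = 0.80,
                                bin_edges = c(2 / 3, 4 / 3),
                                strict_printed_bins = FALSE,
                                min_total_reads = 10L,
                                neighbor_window = 30L,
                                ratio_hom1 = 10,
                                ratio_hom2 = 0.1,
                                het_low = 0.2,
                                het_high = 5,
                                min_n_compared = 20L,
                                conformity_alpha = 0.8,
                                equidist_max = 0.25,
                                spread_max = 0.30,
                                pc2_outlier_mult = 6) {
  stopifnot(min_mac >= 0,
            tag_concordance_min > 0, tag_concordance_min <= 1,
            call_rate_min > 0, call_rate_min <= 1,
            length(bin_edges) == 2, bin_edges[1] < bin_edges[2],
            bin_edges[1] >= 0, bin_edges[2] <= 2,
            min_total_reads >= 0, neighbor_window >= 0,
            ratio_hom2 < het_low, het_high < ratio_hom1)
  th <- list(min_mac = as.integer(min_mac),
             tag_concordance_min = tag_concordance_min,
             call_rate_min = call_rate_min,
             bin_edges = bin_edges,
             strict_printed_bins = isTRUE(strict_printed_bins),
             min_total_reads = as.integer(min_total_reads),
             neighbor_window = as.integer(neighbor_window),
             ratio_hom1 = ratio_hom1,
             ratio_hom2 = ratio_hom2,
             het_low = het_low,
             het_high = het_high,
             min_n_compared = as.integer(min_n_compared),
             conformity_alpha = conformity_alpha,
             equidist_max = equidist_max,
             spread_max = spread_max,
             pc2_outlier_mult = pc2_outlier_mult)
  class(th) <- "karyotag_thresholds"
  th
}

#' @export
print.karyotag_thresholds <- function(x, ...) {
  cat("karyotag thresholds:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
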