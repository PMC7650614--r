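#' Tag genotype matrix (specimens x tags)
#'
#' Holds pre-called tag-SNP genotypes from one assay platform — amplicon
#' sequencing ("AS") or array hybridisation ("OA") — as alternate-allele
#' counts with each tag annotated by the inversion it belongs to. Methods
#' are never mixed within one matrix.
#'
#' @param geno Integer matrix, specimens x tags, values {0,1,2,NA}; row
#'   names are specimen ids, column names are tag ids.
#' @param tag_inversion Character vector, inversion name per tag column.
#' @param method Platform label, "AS" or "OA".
#' @return A `tag_genotype_matrix` object.
#' @export
tag_genotype_matrix <- function(geno, tag_inversion, method = "AS") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(ncol(geno) == length(tag_inversion),
            method %in% c("AS", "OA"),
            nrow(geno) == 0 || !is.null(rownames(geno)),
            ncol(geno) == 0 || !is.null(colnames(geno)))
  if (any(!(geno %in% c(0L, 1L, 2L) | is.na(geno)))) {
    stop("tag genotypes must be 0, 1, 2 or NA")
  }
  structure(list(geno = geno,
                 tag_inversion = as.character(tag_inversion),
                 method = method),
            class = "tag_genotype_matrix")
}

#' @export
print.tag_genotype_matrix <- function(x, ...) {
  cat(sprintf("tag_genotype_matrix (%s): %d specimens x %d tags (%s)\n",
              x$method, nrow(x$geno), ncol(x$geno),
              paste(sprintf("%s: %d", names(table(x$tag_inversion)),
                            table(x$tag_inversion)), collapse = ", ")))
  invisible(x)
}

#' Read a tag genotype matrix from CSV/TSV
#'
#' Expects specimen rows and tag columns with values 0/1/2/NA; tag-to-
#' inversion assignment comes either from a `tag_info` table (tag,
#' inversion) or from column names of the form `inversion.tag`.
#'
#' @param path CSV or TSV path (delimiter inferred from extension).
#' @param tag_info Optional data frame with columns `tag`, `inversion`.
#' @param method Platform label ("AS" or "OA").
#' @return A [tag_genotype_matrix()].
#' @export
read_tag_matrix <- function(path, tag_info = NULL, method = "AS") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.null(tag_info)) {
    inv <- tag_info$inversion[match(colnames(m), tag_info$tag)]
    if (anyNA(inv)) stop("tags missing from tag_info: ",
                         paste(colnames(m)[is.na(inv)], collapse = ", "))
  } else {
    inv <- sub("\\..*$", "", colnames(m))
  }
  tag_genotype_matrix(m, inv, method)
}

#' Drop tags with low call rate
#'
#' A tag's call rate is the fraction of specimens with a genotype call at
#' that tag; tags with call rate strictly below `call_rate_min` are
#' eliminated from the panel. This filter runs before the specimen filter
#' (the order is part of the QC definition).
#'
#' @param matrix A [tag_genotype_matrix()].
#' @param thresholds A [karyotag_thresholds] object.
#' @return List with `matrix` (filtered) and `dropped` (data frame tag,
#'   inversion, call_rate for each removed tag).
#' @export
filter_tags_by_call_rate <- function(matrix,
                                     thresholds = karyotag_thresholds()) {
  stopifnot(inherits(matrix, "tag_genotype_matrix"))
  if (nrow(matrix$geno) == 0) stop("empty tag genotype matrix")
  rate <- colMeans(!is.na(matrix$geno))
  keep <- rate >= thresholds$call_rate_min
  dropped <- data.frame(tag = colnames(matrix$geno)[!keep],
                        inversion = matrix$tag_inversion[!keep],
                        call_rate = rate[!keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = tag_genotype_matrix(matrix$geno[, keep, drop = FALSE],
                                    matrix$tag_inversion[keep],
                                    matrix$method),
       dropped = dropped)
}

#' Drop specimens with low call rate
#'
#' A specimen's call rate is the fraction of retained tags (over the whole
#' multi-inversion panel) called in that specimen; specimens strictly
#' below `call_rate_min` are excluded. Apply after
#' [filter_tags_by_call_rate()].
#'
#' @param matrix A tag-filtered [tag_genotype_matrix()].
#' @param thresholds A [karyotag_thresholds] object.
#' @return List with `matrix` (filtered) and `dropped` (data frame
#'   specimen, call_rate).
#' @export
filter_specimens_by_call_rate <- function(matrix,
                                          thresholds = karyotag_thresholds()) {
  stopifnot(inherits(matrix, "tag_genotype_matrix"))
  if (ncol(matrix$geno) == 0) stop("empty panel after QC")
  rate <- rowMeans(!is.na(matrix$geno))
  keep <- rate >= thresholds$call_rate_min
  dropped <- data.frame(specimen = rownames(matrix$geno)[!keep],
                        call_rate = rate[!keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = tag_genotype_matrix(matrix$geno[keep, , drop = FALSE],
                                    matrix$tag_inversion,
                                    matrix$method),
       dropped = dropped)
}

#' Bin a mean alternate-allele count into an inversion genotype
#'
#' @param mean_alt Numeric vector of mean alternate-allele counts in [0,2].
#' @param thresholds A [karyotag_thresholds] object; with
#'   `strict_printed_bins` the two-decimal edges 0.67/1.33 replace the
#'   exact thirds.
#' @return Integer vector in {0,1,2,NA}.
#' @export
bin_mean_alt <- function(mean_alt, thresholds = karyotag_thresholds()) {
  edges <- if (thresholds$strict_printed_bins) c(0.67, 1.33)
           else thresholds$bin_edges
  out <- rep(NA_integer_, length(mean_alt))
  ok <- !is.na(mean_alt)
  out[ok & mean_alt <= edges[1]] <- 0L
  out[ok & mean_alt > edges[1] & mean_alt <= edges[2]] <- 1L
  out[ok & mean_alt > edges[2]] <- 2L
  out
}

#' Multilocus inversion genotype from one specimen's tag genotypes
#'
#' Averages the alternate-allele counts over the called tags of one
#' inversion and bins the average: means at or below 2/3 give genotype 0,
#' above 2/3 up to 4/3 give 1, above 4/3 give 2 (edges from
#' `thresholds$bin_edges`). With no called tag the genotype is `NA`.
#'
#' @param tag_genotypes Integer vector of one specimen's tag genotypes for
#'   one inversion ({0,1,2,NA}).
#' @param thresholds A [karyotag_thresholds] object.
#' @return List with `mean_alt`, `genotype`, `n_called`.
#' @export
call_inversion_genotype <- function(tag_genotypes,
                                    thresholds = karyotag_thresholds()) {
  called <- tag_genotypes[!is.na(tag_genotypes)]
  if (length(called) == 0) {
    return(list(mean_alt = NA_real_, genotype = NA_integer_, n_called = 0L))
  }
  m <- mean(called)
  list(mean_alt = m, genotype = bin_mean_alt(m, thresholds),
       n_called = length(called))
}

#' QC-filter a tag matrix and call every specimen at every inversion
#'
#' Runs the two call-rate filters in their fixed order (tags first, then
#' specimens, with specimen rates computed over the whole retained panel),
#' then produces one multilocus inversion genotype per retained specimen
#' and inversion.
#'
#' @param matrix A [tag_genotype_matrix()].
#' @param thresholds A [karyotag_thresholds] object.
#' @return List with `calls` (a [karyotype_calls] data frame carrying
#'   `mean_alt` and the matrix's method tag), `n_tags_called` (data frame
#'   specimen, inversion, n), `dropped_tags`, `dropped_specimens`.
#' @export
call_inversions <- function(matrix, thresholds = karyotag_thresholds()) {
  tf <- filter_tags_by_call_rate(matrix, thresholds)
  sf <- filter_specimens_by_call_rate(tf$matrix, thresholds)
  m <- sf$matrix
  if (nrow(m$geno) == 0) {
    empty <- karyotype_calls(character(0), character(0), integer(0),
                             character(0), conforming = logical(0),
                             mean_alt = numeric(0))
    return(list(calls = empty,
                n_tags_called = data.frame(specimen = character(0),
                                           inversion = character(0),
                                           n_tags_called = integer(0)),
                dropped_tags = tf$dropped,
                dropped_specimens = sf$dropped))
  }
  rows <- list()
  for (inv in unique(m$tag_inversion)) {
    sub <- m$geno[, m$tag_inversion == inv, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- call_inversion_genotype(sub[i, ], thresholds)
      rows[[length(rows) + 1]] <-
        data.frame(specimen = rownames(sub)[i], inversion = inv,
                   genotype = r$genotype, method = m$method,
                   conforming = NA, mean_alt = r$mean_alt,
                   n_tags_called = r$n_called,
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  calls <- karyotype_calls(df$specimen, df$inversion, df$genotype,
                           df$method, df$conforming, df$mean_alt)
  list(calls = calls,
       n_tags_called = df[c("specimen", "inversion", "n_tags_called")],
       dropped_tags = tf$dropped,
       dropped_specimens = sf$dropped)
}
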