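#' Format a fraction as a percentage rounded half-away-from-zero
#'
#' Counts always accompany percentages in reports; this helper only
#' controls the printed style (one decimal by default, ties rounded away
#' from zero rather than to even).
#'
#' @param x Numeric fractions.
#' @param digits Decimal places, default 1.
#' @return Numeric percentages.
#' @export
percent_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * 100 * scale + 0.5) / scale
}

categorize_three_way <- function(cyt, as_, oa) {
  if (is.na(cyt) || is.na(as_) || is.na(oa)) return("MISSING_ANY")
  if (cyt == as_ && as_ == oa) return("ALL_CONCORDANT")
  if (as_ == oa) return("CYT_VS_MOLECULAR")      # CYT disagrees
  if (cyt == as_) return("OA_DISCORDANT")        # OA the odd one out
  if (cyt == oa) return("AS_DISCORDANT")         # AS the odd one out
  "ALL_DISCORDANT"
}

#' Pairwise mismatch rate between two call sets
#'
#' The fraction of specimens, among those with non-missing calls in both
#' sets (matched by specimen and inversion), whose two genotypes differ.
#' Symmetric in its arguments.
#'
#' @param calls_a,calls_b [karyotype_calls] data frames (one method each).
#' @return List with `n_mismatch`, `n_compared`, `fraction`.
#' @export
mismatch_rate <- function(calls_a, calls_b) {
  a <- calls_a[!is.na(calls_a$genotype), , drop = FALSE]
  b <- calls_b[!is.na(calls_b$genotype), , drop = FALSE]
  key_a <- paste(a$specimen, a$inversion, sep = "\r")
  key_b <- paste(b$specimen, b$inversion, sep = "\r")
  common <- intersect(key_a, key_b)
  if (length(common) == 0) {
    stop("no jointly called specimens between the two call sets")
  }
  ga <- a$genotype[match(common, key_a)]
  gb <- b$genotype[match(common, key_b)]
  n_mis <- sum(ga != gb)
  list(n_mismatch = n_mis, n_compared = length(common),
       fraction = n_mis / length(common))
}

#' Multi-method concordance summary
#'
#' Compares inversion genotype calls across methods per specimen and
#' inversion. With the three methods CYT, AS and OA present, specimens
#' with complete data are assigned one of the categories ALL_CONCORDANT
#' (all three equal), CYT_VS_MOLECULAR (AS = OA differing from CYT),
#' OA_DISCORDANT (CYT = AS differing from OA), AS_DISCORDANT (CYT = OA
#' differing from AS) and ALL_DISCORDANT; specimens lacking any call are
#' MISSING_ANY (they remain countable in pairwise comparisons). All
#' pairwise mismatch/concordance rates are reported with numerator and
#' denominator.
#'
#' @param calls A [karyotype_calls] data frame (or rbind of several)
#'   holding calls from two or more methods.
#' @param methods Methods to compare, default all present; unknown labels
#'   are an error.
#' @return A `concordance_summary`: list with `per_specimen` (specimen,
#'   inversion, category), `three_way` (per-inversion category counts and
#'   fractions over complete-data specimens) when CYT/AS/OA are all
#'   supplied, and `pairwise` (per-inversion method pair, n_agree,
#'   n_compared, concordance, percent).
#' @export
concordance_summary <- function(calls, methods = NULL) {
  stopifnot(is.data.frame(calls))
  present <- unique(calls$method)
  if (is.null(methods)) methods <- present
  bad <- setdiff(methods, c("CYT", "PCA", "OA", "AS"))
  if (length(bad) > 0) stop("unknown method label: ", paste(bad, collapse = ", "))
  if (length(methods) < 2) stop("need at least 2 methods to compare")
  calls <- calls[calls$method %in% methods, , drop = FALSE]

  wide <- function(inv) {
    sub <- calls[calls$inversion == inv, , drop = FALSE]
    specimens <- unique(sub$specimen)
    w <- matrix(NA_integer_, length(specimens), length(methods),
                dimnames = list(specimens, methods))
    idx <- cbind(match(sub$specimen, specimens), match(sub$method, methods))
    w[idx] <- sub$genotype
    w
  }

  inversions <- unique(calls$inversion)
  per_specimen <- list(); three_way <- list(); pairwise <- list()
  for (inv in inversions) {
    w <- wide(inv)
    if (all(c("CYT", "AS", "OA") %in% methods)) {
      cat3 <- vapply(seq_len(nrow(w)), function(i) {
        categorize_three_way(w[i, "CYT"], w[i, "AS"], w[i, "OA"])
      }, "")
      per_specimen[[inv]] <- data.frame(specimen = rownames(w),
                                        inversion = inv, category = cat3,
                                        stringsAsFactors = FALSE)
      complete <- cat3 != "MISSING_ANY"
      denom <- sum(complete)
      lev <- c("ALL_CONCORDANT", "CYT_VS_MOLECULAR", "OA_DISCORDANT",
               "AS_DISCORDANT", "ALL_DISCORDANT")
      cnt <- vapply(lev, function(l) sum(cat3 == l), 0L)
      three_way[[inv]] <- data.frame(
        inversion = inv, category = c(lev, "MISSING_ANY"),
        count = c(cnt, sum(!complete)),
        denominator = c(rep(denom, length(lev)), nrow(w)),
        fraction = c(if (denom > 0) cnt / denom else rep(NA_real_, length(lev)),
                     sum(!complete) / nrow(w)),
        stringsAsFactors = FALSE)
      three_way[[inv]]$percent <- percent_half_away(three_way[[inv]]$fraction)
    }
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    for (p in pairs) {
      ok <- !is.na(w[, p[1]]) & !is.na(w[, p[2]])
      n <- sum(ok)
      agree <- sum(w[ok, p[1]] == w[ok, p[2]])
      pairwise[[length(pairwise) + 1]] <- data.frame(
        inversion = inv, method_a = p[1], method_b = p[2],
        n_agree = agree, n_compared = n,
        concordance = if (n > 0) agree / n else NA_real_,
        percent = if (n > 0) percent_half_away(agree / n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(per_specimen = do.call(rbind, per_specimen),
                 three_way = do.call(rbind, three_way),
                 pairwise = do.call(rbind, pairwise)),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("concordance summary\n")
  if (!is.null(x$three_way)) {
    cat("three-way categories:\n")
    for (i in seq_len(nrow(x$three_way))) {
      r <- x$three_way[i, ]
      cat(sprintf("  %-4s %-18s %d/%d (%.1f%%)\n", r$inversion, r$category,
                  r$count, r$denominator, r$percent))
    }
  }
  cat("pairwise concordance:\n")
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %-4s %s vs %s: %d/%d (%.1f%%)\n", r$inversion,
                r$method_a, r$method_b, r$n_agree, r$n_compared, r$percent))
  }
  invisible(x)
}

#' Write the per-specimen category table (heat-map source)
#' @param summary A `concordance_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_category_tsv <- function(summary, path) {
  if (is.null(summary$per_specimen)) stop("no three-way categories computed")
  utils::write.table(summary$per_specimen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
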