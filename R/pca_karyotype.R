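#' Principal component analysis of a within-inversion genotype matrix
#'
#' Suppressed recombination inside a polymorphic inversion makes the two
#' orientations behave as diverged sub-populations; PCA of the genotype
#' matrix restricted to the inversion then separates specimens into three
#' collinear clusters ("stripes") along the leading component: the two
#' homokaryotype clusters flanking the heterokaryotype cluster.
#'
#' Missing genotypes are replaced by the per-site mean of called genotypes
#' (keeps every specimen in the decomposition); sites are centred but not
#' variance-scaled. The decomposition is exact and deterministic (SVD); the
#' usual PCA sign indeterminacy is harmless downstream because stripe
#' labelling is anchored, not sign-based.
#'
#' @param matrix A [variant_matrix] with at least 3 specimens and at least
#'   2 polymorphic sites.
#' @return A `pca_result`: list with `specimens`, `scores` (n x 2 matrix,
#'   PC1 and PC2) and `var_frac` (variance fractions of PC1 and PC2).
#' @export
run_local_pca <- function(matrix) {
  stopifnot(inherits(matrix, "variant_matrix"))
  g <- matrix$geno
  if (nrow(g) < 3) stop("PCA requires at least 3 specimens")
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- mu[j]
  }
  g <- sweep(g, 2, colMeans(g))
  total_var <- sum(g^2)
  if (!is.finite(total_var) || total_var < 1e-12) {
    stop("no polymorphism: genotype matrix has zero variance")
  }
  poly <- sum(colSums(g^2) > 1e-12)
  if (poly < 2) stop("PCA requires at least 2 polymorphic sites")
  sv <- svd(g, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2, 2)
  colnames(scores) <- c("PC1", "PC2")
  rownames(scores) <- matrix$specimens
  structure(list(specimens = matrix$specimens,
                 scores = scores,
                 var_frac = sv$d[1:2]^2 / sum(sv$d^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("local PCA of %d specimens: PC1 %.1f%%, PC2 %.1f%% variance\n",
              length(x$specimens), 100 * x$var_frac[1], 100 * x$var_frac[2]))
  invisible(x)
}

#' Build an anchor set of cytogenetically karyotyped specimens
#'
#' @param specimen Character vector of specimen identifiers.
#' @param genotype Integer vector of cytogenetic inversion genotypes in
#'   {0,1,2}; `NA` entries are ignored at use.
#' @return An `anchor_set` data frame.
#' @export
anchor_set <- function(specimen, genotype) {
  stopifnot(length(specimen) == length(genotype))
  genotype <- as.integer(genotype)
  if (any(!(genotype %in% c(0L, 1L, 2L) | is.na(genotype)))) {
    stop("anchor genotypes must be 0, 1, 2 or NA")
  }
  structure(data.frame(specimen = as.character(specimen),
                       genotype = genotype,
                       stringsAsFactors = FALSE),
            class = c("anchor_set", "data.frame"))
}

#' Read an anchor table (TSV: specimen, inversion, genotype)
#'
#' @param path TSV path with columns `specimen`, `inversion`, `genotype`.
#' @param inversion Optional inversion name to subset on.
#' @return An `anchor_set`.
#' @export
read_anchor_tsv <- function(path, inversion = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(inversion) && "inversion" %in% names(df)) {
    df <- df[df$inversion == inversion, , drop = FALSE]
  }
  anchor_set(df$specimen, df$genotype)
}

# deterministic 1-D k-means on PC1: Lloyd iterations from centres at the
# minimum, median and maximum; k collapses when initial centres coincide
kmeans_1d <- function(x, k = 3L, max_iter = 100L) {
  init <- switch(k, min(x),
                 c(min(x), max(x)),
                 c(min(x), stats::median(x), max(x)))
  centers <- sort(unique(init))
  repeat {
    d <- abs(outer(x, centers, "-"))
    assign <- max.col(-d, ties.method = "first")
    new_centers <- vapply(seq_along(centers),
                          function(i) if (any(assign == i)) mean(x[assign == i])
                                      else NA_real_,
                          0)
    occupied <- !is.na(new_centers)
    new_centers <- new_centers[occupied]
    if (length(new_centers) == length(centers) &&
        max(abs(new_centers - centers)) < 1e-10) {
      centers <- new_centers
      break
    }
    centers <- sort(new_centers)
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) break
  }
  d <- abs(outer(x, centers, "-"))
  assign <- max.col(-d, ties.method = "first")
  list(centers = centers, assign = assign)
}

# choose the largest k (3, 2, 1) whose fitted stripes are genuinely
# separated: every adjacent pair of centres must be more than twice the sum
# of the two within-stripe standard deviations apart. A cohort fixed (or
# nearly fixed) for one arrangement spreads PC1 continuously and collapses
# to a single stripe here rather than being cut into artificial clusters.
choose_stripes <- function(x) {
  for (k in c(3L, 2L)) {
    km <- kmeans_1d(x, k)
    if (length(km$centers) < k) next
    sds <- vapply(seq_along(km$centers), function(s) {
      xs <- x[km$assign == s]
      if (length(xs) > 1) stats::sd(xs) else 0
    }, 0)
    gaps <- diff(km$centers)
    if (all(gaps > 2 * (sds[-length(sds)] + sds[-1]))) return(km)
  }
  kmeans_1d(x, 1L)
}

#' Classify specimens into stripes and label them with anchor karyotypes
#'
#' Partitions specimens into at most three stripes along PC1 (deterministic
#' 1-D 3-means initialised at the minimum, median and maximum), labels each
#' stripe by majority vote of the cytogenetically karyotyped anchors it
#' contains, infers unlabelled stripes when exactly one monotone
#' arrangement of 0,1,2 along PC1 is consistent, and flags non-conforming
#' specimens.
#'
#' A specimen is non-conforming when its distance to its stripe centre
#' exceeds `conformity_alpha` x half the minimum inter-centre gap, or when
#' its stripe fails a shape diagnostic (middle centre deviating from the
#' outer midpoint by more than `equidist_max` of the outer gap; within-
#' stripe standard deviation above `spread_max` of the minimum gap).
#' Non-conforming specimens receive genotype `NA`.
#'
#' @param pca A `pca_result` from [run_local_pca()].
#' @param anchors An [anchor_set()]; anchors must include at least one
#'   specimen falling in an outer stripe.
#' @param inversion_name Label recorded in the returned call set.
#' @param thresholds A [karyotag_thresholds] object.
#' @return List with `model` (a `stripe_model`: centres, per-stripe labels,
#'   assignments, diagnostics) and `calls` (a [karyotype_calls] data frame,
#'   method "PCA").
#' @export
classify_stripes <- function(pca, anchors, inversion_name = "inv",
                             thresholds = karyotag_thresholds()) {
  stopifnot(inherits(pca, "pca_result"), inherits(anchors, "anchor_set"))
  x <- pca$scores[, "PC1"]
  km <- choose_stripes(x)
  centers <- km$centers
  assign <- km$assign
  k <- length(centers)

  anc <- anchors[!is.na(anchors$genotype), , drop = FALSE]
  missing_anchors <- setdiff(anc$specimen, pca$specimens)
  if (length(missing_anchors) > 0) {
    warning("anchors absent from genotype matrix: ",
            paste(missing_anchors, collapse = ", "))
    anc <- anc[anc$specimen %in% pca$specimens, , drop = FALSE]
  }
  if (nrow(anc) == 0) stop("insufficient anchors: no usable anchor specimens")

  # majority vote per stripe; ties are an error, not an arbitrary pick
  labels <- rep(NA_integer_, k)
  mismatch <- character(0)
  anc_stripe <- assign[match(anc$specimen, pca$specimens)]
  for (s in seq_len(k)) {
    votes <- anc$genotype[anc_stripe == s]
    if (length(votes) == 0) next
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      stop("anchor conflict: tied anchor vote in stripe ", s)
    }
    labels[s] <- as.integer(names(tab)[1])
    losers <- anc$specimen[anc_stripe == s &
                           anc$genotype != labels[s]]
    mismatch <- c(mismatch, losers)
  }
  labels <- infer_stripe_labels(labels, k)
  if (k >= 2 && all(is.na(labels) | labels == 1L)) {
    stop("insufficient anchors: no outer stripe could be labelled")
  }

  # diagnostics
  gaps <- diff(centers)
  min_gap <- if (k > 1) min(gaps) else Inf
  equidist_dev <- if (k == 3) {
    abs(centers[2] - mean(centers[c(1, 3)])) / (centers[3] - centers[1])
  } else 0
  spread <- vapply(seq_len(k), function(s) {
    xs <- x[assign == s]
    if (length(xs) > 1) stats::sd(xs) else 0
  }, 0)

  conforming <- rep(TRUE, length(x))
  # off-axis outliers: residual structure displaces specimens along PC2
  pc2 <- pca$scores[, "PC2"]
  pc2_scale <- max(stats::mad(pc2), 0.01 * stats::sd(x))
  if (is.finite(pc2_scale) && pc2_scale > 0) {
    conforming <- conforming &
      abs(pc2 - stats::median(pc2)) <= thresholds$pc2_outlier_mult * pc2_scale
  }
  if (k > 1) {
    dist_to_center <- abs(x - centers[assign])
    conforming <- conforming &
      dist_to_center <= thresholds$conformity_alpha * min_gap / 2
    if (equidist_dev > thresholds$equidist_max) {
      conforming[assign == 2] <- FALSE
    }
    bad_spread <- which(spread > thresholds$spread_max * min_gap)
    for (s in bad_spread) conforming[assign == s] <- FALSE
  }

  genotype <- labels[assign]
  genotype[!conforming] <- NA_integer_

  model <- structure(list(centers = centers,
                          labels = labels,
                          assign = assign,
                          specimens = pca$specimens,
                          diagnostics = list(min_gap = min_gap,
                                             equidist_dev = equidist_dev,
                                             spread = spread,
                                             n_stripes = k),
                          anchor_mismatches = mismatch),
                     class = "stripe_model")
  calls <- karyotype_calls(specimen = pca$specimens,
                           inversion = inversion_name,
                           genotype = genotype,
                           method = "PCA",
                           conforming = conforming)
  list(model = model, calls = calls)
}

# fill NA stripe labels when exactly one monotone 0,1,2 arrangement fits
infer_stripe_labels <- function(labels, k) {
  if (!anyNA(labels)) {
    check_monotone_labels(labels)
    return(labels)
  }
  candidates <- list()
  perms <- if (k == 3) list(0:2, 2:0)
           else if (k == 2) list(c(0L, 1L), c(1L, 2L), c(0L, 2L),
                                 c(2L, 1L), c(1L, 0L), c(2L, 0L))
           else lapply(0:2, function(g) g)
  for (p in perms) {
    if (all(is.na(labels) | labels == p)) candidates <- c(candidates, list(p))
  }
  if (length(candidates) == 0) {
    stop("anchor conflict: anchor labels admit no monotone 0,1,2 arrangement")
  }
  if (length(candidates) == 1) return(as.integer(candidates[[1]]))
  labels  # ambiguous: leave unlabelled stripes NA
}

check_monotone_labels <- function(labels) {
  lab <- labels[!is.na(labels)]
  if (length(lab) > 1 && is.unsorted(lab) && is.unsorted(rev(lab))) {
    stop("anchor conflict: stripe labels not monotone along PC1")
  }
  if (anyDuplicated(lab)) {
    stop("anchor conflict: two stripes share the same anchor label")
  }
  invisible(labels)
}

#' @export
print.stripe_model <- function(x, ...) {
  cat(sprintf("stripe model: %d stripe(s), centres %s, labels %s\n",
              x$diagnostics$n_stripes,
              paste(signif(x$centers, 3), collapse = " / "),
              paste(ifelse(is.na(x$labels), "?", x$labels), collapse = " / ")))
  invisible(x)
}

#' Per-specimen inversion genotype calls with method provenance
#'
#' @param specimen,inversion,genotype,method Vectors (recycled to common
#'   length): specimen id, inversion name, genotype in {0,1,2,NA}, method
#'   tag in {"CYT","PCA","OA","AS"}.
#' @param conforming Logical PCA-conformity flag (`NA` for other methods).
#' @param mean_alt Mean alternate-allele count (multilocus calls only).
#' @return A `karyotype_calls` data frame.
#' @export
karyotype_calls <- function(specimen, inversion, genotype, method,
                            conforming = NA, mean_alt = NA_real_) {
  method <- as.character(method)
  bad <- setdiff(unique(method), c("CYT", "PCA", "OA", "AS"))
  if (length(bad) > 0) stop("unknown method label: ", paste(bad, collapse = ", "))
  df <- data.frame(specimen = as.character(specimen),
                   inversion = as.character(inversion),
                   genotype = as.integer(genotype),
                   method = method,
                   conforming = conforming,
                   mean_alt = mean_alt,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("specimen", "inversion", "method")])) {
    stop("duplicate (specimen, inversion, method) call")
  }
  class(df) <- c("karyotype_calls", "data.frame")
  df
}
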