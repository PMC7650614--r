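#' Read / write karyotype call tables
#'
#' Calls are exchanged as TSV with columns specimen, inversion, genotype
#' (0/1/2/NA) and method; optional columns conforming and mean_alt are
#' preserved.
#'
#' @param calls A [karyotype_calls] data frame.
#' @param path TSV path.
#' @param method Method label to assign when the file lacks a method
#'   column.
#' @return `path` (write) or a [karyotype_calls] data frame (read).
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path, method = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(df$method)) {
    if (is.null(method)) stop("file has no method column; supply `method`")
    df$method <- method
  }
  karyotype_calls(df$specimen, df$inversion, df$genotype, df$method,
                  conforming = if ("conforming" %in% names(df)) df$conforming
                               else NA,
                  mean_alt = if ("mean_alt" %in% names(df)) df$mean_alt
                             else NA_real_)
}
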