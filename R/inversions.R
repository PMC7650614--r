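#' Define an inversion by its breakpoint span
#'
#' An inversion is identified by a label (for example "2Ra"), the
#' chromosome-arm contig it sits on, and the 1-based inclusive genomic
#' coordinates of its (approximate) breakpoints. Breakpoint coordinates are
#' treated as exact configuration values; no refinement is attempted.
#'
#' @param name Inversion label, e.g. "3Ra".
#' @param contig Contig / chromosome-arm identifier as used in the VCF.
#' @param start,end 1-based inclusive breakpoint coordinates; `start < end`.
#' @return An `inversion_def` object.
#' @examples
#' inversion_def("3Ra", "3R", 1866360, 11289547)
#' @export
inversion_def <- function(name, contig, start, end) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.character(contig), length(contig) == 1, nzchar(contig))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start >= end) {
    stop("inversion '", name, "': start must be < end")
  }
  structure(list(name = name, contig = contig,
                 start = start, end = end),
            class = "inversion_def")
}

#' @export
print.inversion_def <- function(x, ...) {
  cat(sprintf("inversion %s  %s:%s-%s (1-based inclusive)\n",
              x$name, x$contig,
              format(x$start, big.mark = ","),
              format(x$end, big.mark = ",")))
  invisible(x)
}

#' Breakpoint spans of the three An. funestus inversions
#'
#' Returns the approximate breakpoint spans of the polymorphic inversions
#' 2Ra, 3Ra and 3Rb on the AfunF3 assembly, the configuration used
#' throughout the package examples. Coordinates are approximate: the
#' breakpoints have not been characterised molecularly and derive from
#' markers physically mapped to the polytene-chromosome photomap.
#'
#' @return Named list of [inversion_def] objects.
#' @export
funestus_inversions <- function() {
  list(
    `2Ra` = inversion_def("2Ra", "2R", 25967767, 33984223),
    `3Ra` = inversion_def("3Ra", "3R", 1866360, 11289547),
    `3Rb` = inversion_def("3Rb", "3R", 20512400, 33000000)
  )
}

#' Read inversion definitions from a YAML configuration file
#'
#' The file holds a top-level `inversions` list (or is itself a list) of
#' entries with fields `name`, `contig`, `start`, `end`.
#'
#' @param path Path to a YAML file.
#' @return Named list of [inversion_def] objects.
#' @export
read_inversion_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$inversions)) cfg <- cfg$inversions
  if (length(cfg) == 0) stop("no inversions defined in ", path)
  defs <- lapply(cfg, function(e) {
    inversion_def(e$name, e$contig, e$start, e$end)
  })
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(names(defs))) {
    stop("duplicate inversion names in ", path)
  }
  defs
}

#' Read a site mask from a BED file
#'
#' BED intervals are 0-based half-open, the standard dialect; they are kept
#' in that form and converted to 1-based positions only at the point of
#' use. Sites whose position falls inside a mask interval are excluded at
#' load time.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A `site_mask` object: data frame with columns contig, start, end.
#' @export
read_site_mask <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end")[1:3],
                           colClasses = c("character", "numeric", "numeric"))
  site_mask(bed$contig, bed$start, bed$end)
}

#' Construct a site mask from interval vectors
#'
#' @param contig Character vector of contig names.
#' @param start,end Numeric vectors; 0-based half-open spans (`end > start`).
#' @return A `site_mask` object.
#' @export
site_mask <- function(contig, start, end) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(start < 0) || any(end <= start)) {
    stop("mask intervals must satisfy start >= 0 and end > start")
  }
  structure(data.frame(contig = as.character(contig),
                       start = as.numeric(start),
                       end = as.numeric(end),
                       stringsAsFactors = FALSE),
            class = c("site_mask", "data.frame"))
}

# TRUE for 1-based positions covered by the mask
mask_covers <- function(mask, contig, pos) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (contig == mask$contig[i] &
                  pos > mask$start[i] & pos <= mask$end[i])
  }
  hit
}
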