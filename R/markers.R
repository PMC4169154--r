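#' Marker map
#'
#' Validates and classes a marker map. Positions are 1-based bp; both bp and
#' cM are required and must be strictly increasing within a chromosome (no
#' bp<->cM conversion is ever inferred).
#'
#' @param x data.frame with columns \code{marker}, \code{chr}, \code{bp},
#'   \code{cM}. \code{chr} is a label: autosomes \code{"1"}..\code{"19"} or
#'   \code{"X"} for the mouse, but any labels are accepted.
#' @return The data.frame, classed \code{marker_map}, rows ordered by
#'   chromosome (in order of first appearance) then position.
#' @export
marker_map <- function(x) {
  need <- c("marker", "chr", "bp", "cM")
  if (!all(need %in% names(x)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$marker <- as.character(x$marker)
  x$chr <- as.character(x$chr)
  if (anyDuplicated(x$marker)) stop("marker ids must be unique")
  if (any(x$bp < 1)) stop("bp positions must be >= 1")
  if (any(x$cM < 0)) stop("cM positions must be non-negative")
  chr_order <- unique(x$chr)
  x <- x[order(match(x$chr, chr_order), x$bp), ]
  for (cc in chr_order) {
    i <- x$chr == cc
    if (any(diff(x$bp[i]) <= 0) || any(diff(x$cM[i]) <= 0))
      stop("positions must be strictly increasing in both bp and cM on chr ", cc)
  }
  rownames(x) <- NULL
  class(x) <- c("marker_map", "data.frame")
  x
}

# Approximate mouse autosome lengths (synthetic stand-in for a real array
# map): genetic lengths in cM and physical lengths in Mb for chr 1..19.
mouse_chr_lengths <- function() {
  list(
    cM = c(98, 103, 82, 88, 90, 79, 89, 76, 75, 77,
           88, 64, 67, 66, 59, 57, 61, 59, 57),
    Mb = c(195, 182, 160, 157, 152, 150, 145, 129, 125, 131,
           122, 120, 120, 125, 104, 98, 95, 91, 61)
  )
}

#' Simulate a genome-wide marker map
#'
#' Builds a synthetic marker map over the 19 mouse autosomes (approximate
#' chromosome lengths), with markers equally spaced in cM per chromosome and
#' bp interpolated at the chromosome-specific Mb/cM rate. Markers are
#' allocated to chromosomes proportionally to genetic length.
#'
#' @param n_markers Total number of markers (default 500, the scaled-down
#'   simulation default).
#' @param chromosomes Indices of autosomes to include (default 1:19).
#' @return A \code{\link{marker_map}}.
#' @export
sim_marker_map <- function(n_markers = 500, chromosomes = 1:19) {
  len <- mouse_chr_lengths()
  cml <- len$cM[chromosomes]
  mbl <- len$Mb[chromosomes]
  n_per <- pmax(2L, round(n_markers * cml / sum(cml)))
  out <- vector("list", length(chromosomes))
  for (k in seq_along(chromosomes)) {
    m <- n_per[k]
    cm <- seq(cml[k] / (2 * m), cml[k] * (1 - 1 / (2 * m)), length.out = m)
    bp <- round(cm / cml[k] * mbl[k] * 1e6)
    out[[k]] <- data.frame(
      marker = sprintf("M%02d_%04d", chromosomes[k], seq_len(m)),
      chr = as.character(chromosomes[k]), bp = bp, cM = cm)
  }
  marker_map(do.call(rbind, out))
}

#' Read / write a marker map CSV
#'
#' Schema: columns \code{marker,chr,bp,cM}. Validation errors name the
#' offending chromosome.
#'
#' @param path File path.
#' @return \code{read_marker_map}: a \code{\link{marker_map}}.
#' @export
read_marker_map <- function(path) {
  marker_map(utils::read.csv(path, colClasses = c(chr = "character")))
}

#' @param map A \code{\link{marker_map}}.
#' @rdname read_marker_map
#' @export
write_marker_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
}

# split a map into per-chromosome row indices, preserving order
map_chr_index <- function(map) split(seq_len(nrow(map)), map$chr)[unique(map$chr)]

# autosome labels of a map (everything except X/Y/M)
autosomes_of <- function(map) setdiff(unique(map$chr), c("X", "Y", "M", "MT"))
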