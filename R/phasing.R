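# Phasing of marginal diplotype reconstructions: assign each marker's
# unordered founder pair to two haplotype strands so as to minimize the total
# number of strand switches (dynamic programming), and count recombination
# events from the phased strands. Breakpoints are placed at the bp midpoint
# between flanking markers.

# phase one chromosome: st = state indices along markers, pairs = S x 2
# returns list(h1, h2) of founder indices minimizing strand switches
phase_chromosome <- function(st, pairs) {
  m <- length(st)
  a <- pairs[st, 1]; b <- pairs[st, 2]
  if (m == 1) return(list(h1 = a, h2 = b))
  # orientation 1: (a,b); orientation 2: (b,a)
  cost <- matrix(0, m, 2)
  back <- matrix(1L, m, 2)
  for (j in 2:m) {
    for (o in 1:2) {
      c1 <- if (o == 1) a[j] else b[j]
      c2 <- if (o == 1) b[j] else a[j]
      step <- c(cost[j - 1, 1] + (a[j - 1] != c1) + (b[j - 1] != c2),
                cost[j - 1, 2] + (b[j - 1] != c1) + (a[j - 1] != c2))
      back[j, o] <- which.min(step)  # ties -> orientation 1
      cost[j, o] <- min(step)
    }
  }
  o <- which.min(cost[m, ])
  orient <- integer(m)
  orient[m] <- o
  for (j in m:2) orient[j - 1] <- back[j, orient[j]]
  h1 <- ifelse(orient == 1, a, b)
  h2 <- ifelse(orient == 1, b, a)
  list(h1 = h1, h2 = h2)
}

#' Phase a marginal reconstruction
#'
#' Splits each sample's per-marker maximum-probability diplotypes into two
#' founder haplotype strands by minimizing the total number of strand
#' switches (recombination events) along each chromosome. The unordered pair
#' at every marker is preserved. Breakpoints are reported at the bp midpoint
#' between the flanking markers.
#'
#' @param state n x M integer state matrix
#'   (\code{\link{marginal_reconstruction}} or truth).
#' @param map The \code{\link{marker_map}}.
#' @param states A \code{\link{diplotype_states}}.
#' @return Object of class \code{phased_reconstruction}: list with n x M
#'   founder-index matrices \code{h1}, \code{h2}, a \code{breakpoints}
#'   data.frame (sample, chr, strand, bp), and \code{map}.
#' @export
phase_reconstruction <- function(state, map, states) {
  n <- nrow(state); m <- ncol(state)
  stopifnot(m == nrow(map))
  idx <- map_chr_index(map)
  h1 <- h2 <- matrix(0L, n, m, dimnames = dimnames(state))
  bks <- list()
  for (cc in names(idx)) {
    j <- idx[[cc]]
    mid <- (map$bp[j][-length(j)] + map$bp[j][-1]) / 2
    for (i in seq_len(n)) {
      ph <- phase_chromosome(state[i, j], states$pairs)
      h1[i, j] <- ph$h1; h2[i, j] <- ph$h2
      for (strand in 1:2) {
        hv <- if (strand == 1) ph$h1 else ph$h2
        w <- which(diff(hv) != 0)
        if (length(w))
          bks[[length(bks) + 1L]] <- data.frame(
            sample = i, chr = cc, strand = strand, bp = mid[w])
      }
    }
  }
  bk <- if (length(bks)) do.call(rbind, bks)
        else data.frame(sample = integer(), chr = character(),
                        strand = integer(), bp = numeric())
  structure(list(h1 = h1, h2 = h2, breakpoints = bk, map = map),
            class = "phased_reconstruction")
}

#' @export
print.phased_reconstruction <- function(x, ...) {
  cat("Phased reconstruction:", nrow(x$h1), "samples x", ncol(x$h1),
      "markers;", nrow(x$breakpoints), "strand breakpoints\n")
  invisible(x)
}

#' Count recombination events per sample
#'
#' Sums strand switches over both phased haplotypes across autosomes.
#'
#' @param phased A \code{\link{phase_reconstruction}} result.
#' @param chromosomes Chromosomes to include (default: autosomes of the map).
#' @return Integer vector of event counts, one per sample.
#' @export
count_recombinations <- function(phased, chromosomes = NULL) {
  map <- phased$map
  if (is.null(chromosomes)) chromosomes <- autosomes_of(map)
  idx <- map_chr_index(map)
  n <- nrow(phased$h1)
  out <- integer(n)
  for (cc in chromosomes) {
    j <- idx[[cc]]
    out <- out + rowSums(phased$h1[, j[-1], drop = FALSE] !=
                           phased$h1[, j[-length(j)], drop = FALSE]) +
                 rowSums(phased$h2[, j[-1], drop = FALSE] !=
                           phased$h2[, j[-length(j)], drop = FALSE])
  }
  out
}
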