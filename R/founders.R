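#' Founder panel
#'
#' Defines the set of inbred founder strains of a multiparent outbred
#' population. The Diversity Outbred default is eight founders coded
#' \code{A}--\code{H} (A/J, C57BL/6J, 129S1/SvImJ, NOD/ShiLtJ, NZO/HlLtJ,
#' CAST/EiJ, PWK/PhJ, WSB/EiJ).
#'
#' @param labels Character vector of unique single-token founder codes
#'   (length >= 2). Defaults to \code{LETTERS[1:8]}.
#' @param names Optional display names, same length as \code{labels}.
#' @return An object of class \code{founder_panel}: a character vector of
#'   codes with a \code{names} attribute holding display strings.
#' @examples
#' founder_panel()            # the 8 DO founders
#' founder_panel(LETTERS[1:4])
#' @export
founder_panel <- function(labels = LETTERS[1:8], names = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a founder panel needs at least 2 founders")
  if (anyDuplicated(labels)) stop("founder labels must be unique")
  if (is.null(names)) names <- labels
  if (length(names) != length(labels)) stop("'names' must match 'labels' in length")
  structure(labels, names = names, class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel with", length(x), "founders:",
      paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the diplotype state space
#'
#' A diplotype is the unordered pair of founder haplotypes carried at a locus.
#' With F founders there are F(F+1)/2 states: F homozygous plus F(F-1)/2
#' heterozygous (36 = 8 + 28 for the DO). The ordering is fixed and
#' deterministic: all homozygotes in founder order first, then heterozygotes
#' in lexicographic order (AB, AC, ..., AH, BC, ...). All probability and
#' dosage arrays in the package use this ordering.
#'
#' @param panel A \code{\link{founder_panel}} (or a character vector of
#'   founder codes).
#' @return Object of class \code{diplotype_states}: a list with
#'   \describe{
#'     \item{founders}{the founder codes}
#'     \item{pairs}{S x 2 integer matrix of founder indices (first <= second)}
#'     \item{labels}{two-letter state labels, e.g. \code{"AA"}, \code{"BC"}}
#'     \item{N}{S x F matrix of founder allele counts N_h(s), each row
#'       summing to 2}
#'     \item{homozygous}{logical vector, TRUE for the F homozygous states}
#'   }
#' @examples
#' s <- diplotype_states(founder_panel())
#' nrow(s$pairs)  # 36
#' @export
diplotype_states <- function(panel = founder_panel()) {
  if (!inherits(panel, "founder_panel")) panel <- founder_panel(panel)
  f <- length(panel)
  hom <- cbind(seq_len(f), seq_len(f))
  het <- which(upper.tri(matrix(0, f, f)), arr.ind = TRUE)
  het <- het[order(het[, "row"], het[, "col"]), , drop = FALSE]
  pairs <- rbind(hom, cbind(het[, "row"], het[, "col"]))
  dimnames(pairs) <- NULL
  s <- nrow(pairs)
  labels <- paste0(unclass(panel)[pairs[, 1]], unclass(panel)[pairs[, 2]])
  N <- matrix(0L, s, f, dimnames = list(labels, unclass(panel)))
  for (k in seq_len(s)) {
    N[k, pairs[k, 1]] <- N[k, pairs[k, 1]] + 1L
    N[k, pairs[k, 2]] <- N[k, pairs[k, 2]] + 1L
  }
  structure(list(founders = unclass(panel), pairs = pairs, labels = labels,
                 N = N, homozygous = pairs[, 1] == pairs[, 2]),
            class = "diplotype_states")
}

#' @export
print.diplotype_states <- function(x, ...) {
  cat("Diplotype state space:", length(x$labels), "states (",
      sum(x$homozygous), "homozygous,", sum(!x$homozygous),
      "heterozygous ) over", length(x$founders), "founders\n")
  invisible(x)
}

#' Founder allele count within a diplotype state
#'
#' N_h(s): how many of the two alleles of diplotype s derive from founder h.
#' For example N_C(CC) = 2, N_C(BC) = 1, N_C(BB) = 0.
#'
#' @param states A \code{\link{diplotype_states}} object.
#' @param founder Founder code (e.g. \code{"C"}) or index.
#' @param state State label (e.g. \code{"BC"}) or index.
#' @return Integer in 0, 1, 2.
#' @export
founder_count <- function(states, founder, state) {
  stopifnot(inherits(states, "diplotype_states"))
  if (is.character(founder)) {
    founder <- match(founder, states$founders)
    if (anyNA(founder)) stop("unknown founder code")
  } else if (any(founder < 1 | founder > length(states$founders))) {
    stop("founder index out of range")
  }
  if (is.character(state)) {
    state <- match(state, states$labels)
    if (anyNA(state)) stop("unknown diplotype state")
  } else if (any(state < 1 | state > length(states$labels))) {
    stop("state index out of range")
  }
  states$N[cbind(state, founder)]
}

#' Expected genotype call for each diplotype state at a marker
#'
#' Given the biallelic founder genotypes at a marker (1 = reference/A allele,
#' 0 = alternate/B allele), returns the genotype call A/H/B expected for each
#' diplotype state: both alleles reference -> A, both alternate -> B,
#' mixed -> H.
#'
#' @param founder_alleles Numeric/integer vector of length F with values
#'   0 or 1 (1 = founder carries the reference allele). \code{NA} triggers a
#'   missing-data error.
#' @param states A \code{\link{diplotype_states}} object.
#' @return Character vector of length S with values in \code{c("A","H","B")},
#'   named by state label.
#' @export
expected_genotype <- function(founder_alleles, states) {
  stopifnot(inherits(states, "diplotype_states"))
  f <- length(states$founders)
  if (length(founder_alleles) != f)
    stop("need one allele per founder (", f, ")")
  if (anyNA(founder_alleles))
    stop("missing founder allele: founder genotype required for every founder")
  if (!all(founder_alleles %in% c(0, 1)))
    stop("founder alleles must be 0 (alternate) or 1 (reference)")
  nref <- founder_alleles[states$pairs[, 1]] + founder_alleles[states$pairs[, 2]]
  g <- c("B", "H", "A")[nref + 1]
  names(g) <- states$labels
  g
}
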