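# Diplotype transition model: two independent per-haplotype ancestry chains.
# Along one haplotype, over genetic distance d (Morgans) the chain switches
# ancestry with probability 1 - exp(-lambda * d) and then lands uniformly on
# the F founders; lambda grows linearly with outbreeding generation. The
# 36-state diplotype transition matrix is the convolution of the two
# haplotype chains collapsed to unordered pairs.

#' Per-haplotype ancestry switch intensity
#'
#' lambda(G) = events_per_gen * G / (2 * L * (1 - 1/F)) per Morgan, calibrated
#' so the expected number of observable ancestry junctions per diploid genome
#' (both haplotypes, genome length L Morgans) at generation G equals
#' \code{events_per_gen * G}. The default calibration constant 23.9 is the
#' theoretical autosomal accumulation rate per DO generation; it is exposed
#' because it depends on the pre-outbreeding history of the founders.
#'
#' @param gen Outbreeding generation.
#' @param L_morgan Genome (autosome) genetic length in Morgans.
#' @param n_founders F.
#' @param events_per_gen Calibration constant: expected new autosomal
#'   recombination events per generation.
#' @return Switch intensity per Morgan.
#' @export
switch_rate <- function(gen, L_morgan, n_founders = 8, events_per_gen = 23.9) {
  events_per_gen * gen / (2 * L_morgan * (1 - 1 / n_founders))
}

# F x F haplotype ancestry transition over d Morgans
haplotype_transition <- function(d, lambda, n_founders) {
  stay <- exp(-lambda * d)
  matrix((1 - stay) / n_founders, n_founders, n_founders) +
    diag(stay, n_founders)
}

#' Diplotype transition matrix between two loci
#'
#' @param d Genetic distance in Morgans (>= 0); \code{d = 0} gives the
#'   identity matrix.
#' @param lambda Per-haplotype switch intensity (\code{\link{switch_rate}}).
#' @param states A \code{\link{diplotype_states}}.
#' @return S x S stochastic matrix in the fixed state order.
#' @export
diplotype_transition <- function(d, lambda, states) {
  f <- length(states$founders)
  P <- haplotype_transition(d, lambda, f)
  a <- states$pairs[, 1]; b <- states$pairs[, 2]
  # unordered source (a,b) -> unordered target (c,d):
  # P(a->c)P(b->d) + P(a->d)P(b->c), halved for homozygous targets (c = d)
  Tm <- P[a, states$pairs[, 1]] * P[b, states$pairs[, 2]] +
        P[a, states$pairs[, 2]] * P[b, states$pairs[, 1]]
  Tm[, states$homozygous] <- Tm[, states$homozygous] / 2
  dimnames(Tm) <- list(states$labels, states$labels)
  Tm
}

#' Equilibrium diplotype distribution
#'
#' Random-union-of-gametes equilibrium: 1/F^2 for each homozygote, 2/F^2 for
#' each heterozygote (1/64 and 1/32 for F = 8).
#'
#' @param states A \code{\link{diplotype_states}}.
#' @export
diplotype_equilibrium <- function(states) {
  f <- length(states$founders)
  p <- ifelse(states$homozygous, 1 / f^2, 2 / f^2)
  names(p) <- states$labels
  p
}

#' Build the transition model along a marker map
#'
#' One transition matrix per adjacent marker pair per chromosome. Matrices
#' for repeated inter-marker distances are shared.
#'
#' @param map A \code{\link{marker_map}}.
#' @param gen Outbreeding generation of the genotyped cohort.
#' @param states A \code{\link{diplotype_states}}.
#' @param events_per_gen Calibration constant, see \code{\link{switch_rate}}.
#' @param genome_length_morgan Genetic length over which
#'   \code{events_per_gen} accumulates (default: the full mouse autosomal
#'   genome, ~14.35 Morgans), NOT the span of \code{map} -- the switch
#'   intensity per Morgan is intrinsic and must not change when only part of
#'   the genome is genotyped.
#' @return Object of class \code{transition_model}: per chromosome a list
#'   with \code{d} (Morgans between adjacent markers) and \code{T} (list of
#'   S x S matrices); attributes \code{lambda}, \code{gen}.
#' @export
build_transitions <- function(map, gen, states, events_per_gen = 23.9,
                              genome_length_morgan = sum(mouse_chr_lengths()$cM) / 100) {
  idx <- map_chr_index(map)
  lambda <- switch_rate(gen, genome_length_morgan, length(states$founders),
                        events_per_gen)
  cache <- new.env(parent = emptyenv())
  get_T <- function(d) {
    key <- sprintf("%.10g", d)
    if (is.null(cache[[key]])) cache[[key]] <- diplotype_transition(d, lambda, states)
    cache[[key]]
  }
  out <- lapply(idx, function(j) {
    d <- diff(map$cM[j]) / 100
    if (any(d <= 0)) stop("non-monotone genetic map")
    list(d = d, T = lapply(d, get_T))
  })
  structure(out, class = "transition_model", lambda = lambda, gen = gen)
}
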