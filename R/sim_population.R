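# Breeding simulator for Diversity-Outbred-style populations.
#
# A haplotype is a founder mosaic stored run-length style:
#   list(ends = numeric cM right endpoints (last = chromosome length),
#        founder = integer founder index per segment)
# Meiosis is a no-interference (Poisson) crossover process on the cM map;
# chiasma count per gamete ~ Poisson(L/100), no obligate crossover.

new_haplotype <- function(L, founder) list(ends = L, founder = as.integer(founder))

# random founder mosaic: Poisson junctions at `density` per Morgan, uniform
# ancestry with forced change at each junction (observable density = density)
random_mosaic <- function(L, density, f) {
  nj <- stats::rpois(1L, density * L / 100)
  if (nj == 0L) return(new_haplotype(L, sample.int(f, 1L)))
  ends <- c(sort(stats::runif(nj, 0, L)), L)
  fdr <- integer(nj + 1L)
  fdr[1] <- sample.int(f, 1L)
  for (k in seq_len(nj))
    fdr[k + 1L] <- sample(seq_len(f)[-fdr[k]], 1L)
  list(ends = ends, founder = fdr)
}

# recombine a parent's two haplotypes into one gamete
meiosis <- function(h1, h2, L) {
  nx <- stats::rpois(1L, L / 100)
  strand <- sample.int(2L, 1L)
  if (nx == 0L) return(if (strand == 1L) h1 else h2)
  bounds <- c(0, sort(stats::runif(nx, 0, L)), L)
  hl <- list(h1, h2)
  ends <- numeric(0); fdr <- integer(0)
  for (k in seq_len(nx + 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    h <- hl[[strand]]
    ia <- findInterval(a, h$ends) + 1L
    ib <- sum(h$ends < b) + 1L
    ib <- min(ib, length(h$ends))
    seg_ends <- h$ends[ia:ib]
    seg_ends[length(seg_ends)] <- b
    ends <- c(ends, seg_ends)
    fdr <- c(fdr, h$founder[ia:ib])
    strand <- 3L - strand
  }
  # merge adjacent segments with identical ancestry
  keep <- c(diff(fdr) != 0L, TRUE)
  list(ends = ends[keep], founder = fdr[keep])
}

#' Simulate a Diversity-Outbred-style population
#'
#' Breeds a randomized outbreeding population from an F-founder panel:
#' generation 1 individuals carry two pure founder haplotypes (a random
#' distinct founder pair, approximating the pre-CC seeding), and each later
#' generation is produced by random non-sibling mating among a fixed number of
#' breeding pairs with Poisson (no-interference) crossovers on the cM map.
#' The returned cohort is the offspring generation \code{gen}.
#'
#' @param map A \code{\link{marker_map}}; chromosome genetic lengths are taken
#'   as the span of the map (plus the mean marker spacing as margin).
#' @param n_ind Cohort size returned at generation \code{gen} (default 500).
#' @param n_pairs Number of breeding pairs maintained per generation
#'   (default 175, the DO design).
#' @param gen Outbreeding generation of the returned cohort (>= 1).
#' @param panel \code{\link{founder_panel}}.
#' @param g1_density Ancestry-junction density (per Morgan, per haplotype) of
#'   the generation-1 seed haplotypes. The default emulates the pre-CC funnel
#'   history: \code{events_per_gen / (2 L)} junctions per Morgan, so each G1
#'   haplotype is already a fine founder mosaic and founder frequencies start
#'   balanced. Set to 0 for pure-founder (F1-style) seeding, in which case
#'   every G1 individual is heterozygous at every locus.
#' @param events_per_gen Calibration constant for the default
#'   \code{g1_density} (theoretical autosomal events per generation, 23.9).
#' @param seed Optional integer seed (\code{set.seed} is called when given).
#' @return Object of class \code{do_population}: list with
#'   \code{individuals} (each a per-chromosome list of haplotype mosaics
#'   \code{h1}, \code{h2}), \code{chr}, \code{L} (cM lengths),
#'   \code{generation}, \code{founders}.
#' @export
sim_do_population <- function(map, n_ind = 500, n_pairs = 175, gen = 8,
                              panel = founder_panel(), g1_density = NULL,
                              events_per_gen = 23.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(map) == 0) stop("empty marker map")
  stopifnot(n_pairs >= 1, gen >= 1)
  f <- length(panel)
  chrs <- unique(map$chr)
  L <- vapply(chrs, function(cc) {
    cm <- map$cM[map$chr == cc]
    max(cm) + mean(diff(cm)) / 2
  }, 0)
  names(L) <- chrs
  nchr <- length(chrs)
  if (is.null(g1_density)) g1_density <- events_per_gen / (2 * sum(L) / 100)

  make_g1 <- function(n) {
    lapply(seq_len(n), function(i) {
      if (g1_density <= 0) {
        fp <- sample.int(f, 2L)  # distinct founders, F1-style
        lapply(L, function(l) list(h1 = new_haplotype(l, fp[1]),
                                   h2 = new_haplotype(l, fp[2])))
      } else {
        lapply(L, function(l) list(h1 = random_mosaic(l, g1_density, f),
                                   h2 = random_mosaic(l, g1_density, f)))
      }
    })
  }
  offspring <- function(pa, ma) {
    lapply(seq_len(nchr), function(cc) {
      list(h1 = meiosis(pa[[cc]]$h1, pa[[cc]]$h2, L[cc]),
           h2 = meiosis(ma[[cc]]$h1, ma[[cc]]$h2, L[cc]))
    })
  }
  # pair 2*n_pairs individuals avoiding full siblings where possible
  pair_up <- function(fam) {
    n <- length(fam)
    for (try in 1:50) {
      perm <- sample.int(n)
      a <- perm[seq(1, n, by = 2)]; b <- perm[seq(2, n, by = 2)]
      if (!any(fam[a] == fam[b] & fam[a] != 0L)) break
    }
    cbind(a, b)
  }

  inds <- make_g1(2L * n_pairs)
  fam <- rep(0L, 2L * n_pairs)  # 0 = unrelated seed stock
  g <- 1L
  while (g < gen) {
    prs <- pair_up(fam)
    last <- (g == gen - 1L)
    n_off <- if (last) n_ind else 2L * n_pairs
    # breeding generations: two offspring per pair; cohort: random pairs
    pair_of <- if (last) sample.int(nrow(prs), n_off, replace = TRUE)
               else rep(seq_len(nrow(prs)), length.out = n_off)
    inds <- lapply(pair_of, function(p)
      offspring(inds[[prs[p, 1]]], inds[[prs[p, 2]]]))
    fam <- pair_of
    g <- g + 1L
  }
  if (gen == 1L) {
    inds <- inds[rep_len(seq_along(inds), n_ind)]
    fam <- rep_len(fam, n_ind)
  }
  structure(list(individuals = inds, chr = chrs, L = L, generation = gen,
                 founders = panel, n_pairs = n_pairs, family = fam),
            class = "do_population")
}

#' @export
print.do_population <- function(x, ...) {
  cat("Simulated outbred population: ", length(x$individuals),
      " individuals at generation G", x$generation, ", ",
      length(x$chr), " chromosomes, ", length(x$founders),
      " founders\n", sep = "")
  invisible(x)
}

# founder index at given cM positions along one haplotype mosaic
haplo_at <- function(h, pos) h$founder[findInterval(pos, h$ends) + 1L]

#' True diplotypes of a simulated population at map markers
#'
#' @param pop A \code{\link{sim_do_population}} result.
#' @param map The \code{\link{marker_map}} used to simulate (or any map with
#'   the same chromosomes).
#' @param states A \code{\link{diplotype_states}} for the population's panel.
#' @return List with n x M integer matrices \code{h1}, \code{h2} (founder
#'   index per haplotype) and \code{state} (diplotype state index in the fixed
#'   state ordering).
#' @export
true_diplotypes <- function(pop, map, states = diplotype_states(pop$founders)) {
  n <- length(pop$individuals)
  m <- nrow(map)
  f <- length(states$founders)
  smat <- matrix(0L, f, f)  # (a,b) -> state index, symmetric
  smat[states$pairs] <- seq_along(states$labels)
  smat[states$pairs[, c(2, 1)]] <- seq_along(states$labels)
  h1 <- h2 <- matrix(0L, n, m)
  idx <- map_chr_index(map)
  for (cc in seq_along(pop$chr)) {
    j <- idx[[pop$chr[cc]]]
    pos <- map$cM[j]
    for (i in seq_len(n)) {
      ind <- pop$individuals[[i]][[cc]]
      h1[i, j] <- haplo_at(ind$h1, pos)
      h2[i, j] <- haplo_at(ind$h2, pos)
    }
  }
  state <- matrix(smat[cbind(as.vector(h1), as.vector(h2))], n, m)
  rownames(state) <- rownames(h1) <- rownames(h2) <-
    sprintf("ind%04d", seq_len(n))
  colnames(state) <- colnames(h1) <- colnames(h2) <- map$marker
  list(h1 = h1, h2 = h2, state = state)
}

#' Per-founder genome share of each individual
#'
#' Fraction of each individual's diploid genome (cM-length weighted, over both
#' haplotypes and all chromosomes) inherited from each founder. At breeding
#' equilibrium each founder's expected share is 1/F (12.5\% in the DO).
#'
#' @inheritParams true_diplotypes
#' @return n x F matrix of shares; rows sum to 1.
#' @export
founder_shares <- function(pop) {
  f <- length(pop$founders)
  n <- length(pop$individuals)
  out <- matrix(0, n, f, dimnames = list(NULL, unclass(pop$founders)))
  tot <- 2 * sum(pop$L)
  for (i in seq_len(n)) {
    acc <- numeric(f)
    for (cc in seq_along(pop$chr)) {
      for (h in c("h1", "h2")) {
        hp <- pop$individuals[[i]][[cc]][[h]]
        len <- diff(c(0, hp$ends))
        acc <- acc + vapply(seq_len(f), function(k) sum(len[hp$founder == k]), 0)
      }
    }
    out[i, ] <- acc / tot
  }
  out
}

#' Diplotype state frequencies across a population
#'
#' Tabulates diplotype frequencies over all (individual, marker) cells. At DO
#' equilibrium each heterozygous state occurs at frequency 1/32 and each
#' homozygous state at 1/64.
#'
#' @param state n x M integer state matrix (from \code{\link{true_diplotypes}})
#'   or an n x M x S probability array, in which case expected frequencies are
#'   used.
#' @param states A \code{\link{diplotype_states}}.
#' @return Named numeric vector of per-state frequencies summing to 1.
#' @export
diplotype_freq <- function(state, states) {
  s <- length(states$labels)
  if (is.array(state) && length(dim(state)) == 3) {
    fr <- apply(state, 3, sum)
    fr <- fr / sum(fr)
  } else {
    if (length(state) == 0) stop("empty population")
    fr <- tabulate(as.integer(state), nbins = s) / length(state)
  }
  names(fr) <- states$labels
  fr
}

#' Realized recombination breakpoints per individual
#'
#' Counts ancestry junctions in the true simulated mosaics (both haplotypes,
#' all chromosomes in the population -- autosomes, for the default simulated
#' maps).
#'
#' @inheritParams founder_shares
#' @return Integer vector, one count per individual.
#' @export
true_breakpoints <- function(pop) {
  vapply(pop$individuals, function(ind) {
    sum(vapply(ind, function(ch)
      (length(ch$h1$ends) - 1L) + (length(ch$h2$ends) - 1L), 0L))
  }, 0L)
}
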