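# Founder allelic dosages and genome-wide SNP imputation.
#
# d_ij(h) = sum_s p_ij(s) N_h(s): expected count of alleles from founder h,
# summing to 2 over founders. SNP dosage g_ij = sum_h d_ij(h) G_j(h) with
# G_j(h) the indicator that founder h carries the reference allele; SNPs with
# identical strain distribution patterns (SDPs) within an inter-marker
# interval share one dosage column (and one regression) via SDP collapsing.

#' Founder allelic dosage from diplotype probabilities
#'
#' @param probs n x M x S posterior array or a \code{diplotype_fit}.
#' @param states A \code{\link{diplotype_states}}.
#' @return n x M x F array of dosages d_ij(h); each (sample, marker) slice
#'   sums to 2.
#' @export
founder_dosage <- function(probs, states) {
  if (inherits(probs, "diplotype_fit")) probs <- probs$probs
  d <- dim(probs)
  stopifnot(length(d) == 3, d[3] == nrow(states$N))
  flat <- matrix(probs, d[1] * d[2], d[3]) %*% states$N
  dn <- dimnames(probs)
  array(flat, c(d[1], d[2], ncol(states$N)),
        dimnames = list(dn[[1]], dn[[2]], colnames(states$N)))
}

# one-hot diplotype probability array from an integer state matrix
state_probs <- function(state, states) {
  n <- nrow(state); m <- ncol(state); s <- nrow(states$N)
  dn <- dimnames(state)
  arr <- array(0, c(n, m, s), dimnames = list(dn[[1]], dn[[2]], states$labels))
  arr[cbind(rep(seq_len(n), m), rep(seq_len(m), each = n), as.vector(state))] <- 1
  arr
}

#' Founder dosage from a hard state assignment
#'
#' One-hot dosages (values in 0/1/2) from an integer diplotype state matrix
#' (simulated truth or a marginal reconstruction); equivalent to
#' \code{\link{founder_dosage}} on a point-mass probability array.
#'
#' @param state n x M integer state matrix.
#' @param states A \code{\link{diplotype_states}}.
#' @return n x M x F dosage array.
#' @export
dosage_from_states <- function(state, states) {
  n <- nrow(state); m <- ncol(state)
  flat <- states$N[as.integer(state), , drop = FALSE]
  dn <- dimnames(state)
  array(as.numeric(flat), c(n, m, ncol(states$N)),
        dimnames = list(dn[[1]], dn[[2]], colnames(states$N)))
}

#' Interval-averaged diplotype probabilities at a SNP position
#'
#' The diplotype probability vector at an ungenotyped SNP is the unweighted
#' mean of the two flanking markers' posteriors; before the first or after
#' the last marker of the chromosome, the nearest marker's posterior is used.
#'
#' @param probs n x M x S posterior array.
#' @param map The \code{\link{marker_map}} (M rows).
#' @param chr Chromosome label of the SNP.
#' @param bp SNP position (bp).
#' @return n x S matrix of probabilities.
#' @export
interval_average <- function(probs, map, chr, bp) {
  j <- which(map$chr == chr)
  if (!length(j)) stop("SNP chromosome '", chr, "' not in the marker map")
  pos <- map$bp[j]
  k <- findInterval(bp, pos)
  if (k == 0) return(matrix(probs[, j[1], ], nrow = dim(probs)[1]))
  if (k >= length(j)) return(matrix(probs[, j[length(j)], ], nrow = dim(probs)[1]))
  if (pos[k] == bp) return(matrix(probs[, j[k], ], nrow = dim(probs)[1]))
  (matrix(probs[, j[k], ], nrow = dim(probs)[1]) +
     matrix(probs[, j[k + 1], ], nrow = dim(probs)[1])) / 2
}

#' Strain distribution patterns of a founder SNP table
#'
#' Encodes each SNP's pattern of reference-allele carriage across the F
#' founders as an integer in 0..2^F - 1 (bit h set = founder h carries the
#' reference allele). Monomorphic patterns (0 or 2^F - 1) are flagged.
#'
#' @param snps A \code{\link{sim_founder_snps}}-style data.frame: columns
#'   \code{snp}, \code{chr}, \code{bp}, then one 0/1 column per founder.
#' @param panel A \code{\link{founder_panel}}.
#' @return Integer vector of SDP codes with attribute \code{monomorphic}.
#' @export
snp_sdp <- function(snps, panel = founder_panel()) {
  al <- as.matrix(snps[, unclass(panel), drop = FALSE])
  code <- as.integer(al %*% 2^(seq_along(panel) - 1))
  attr(code, "monomorphic") <- code %in% c(0L, 2L^length(panel) - 1L)
  code
}

#' Collapse SNPs with identical SDPs within inter-marker intervals
#'
#' SNPs falling in the same half-open interval [left marker, right marker)
#' and sharing a strain distribution pattern have identical imputed dosages,
#' so one regression per group suffices; results are broadcast back to the
#' member SNPs.
#'
#' @inheritParams snp_sdp
#' @param map The \code{\link{marker_map}}.
#' @return Integer vector of group ids (1..G) parallel to the SNP rows.
#' @export
collapse_sdp <- function(snps, map, panel = founder_panel()) {
  sdp <- snp_sdp(snps, panel)
  iv <- integer(nrow(snps))
  for (cc in unique(snps$chr)) {
    j <- which(map$chr == cc)
    w <- which(snps$chr == cc)
    iv[w] <- findInterval(snps$bp[w], map$bp[j])
  }
  key <- paste(snps$chr, iv, sdp)
  as.integer(factor(key, levels = unique(key)))
}

#' Imputed SNP dosages
#'
#' Probabilistic imputation of biallelic genotypes genome-wide: the founder
#' dosage at each SNP is the interval average of the flanking markers'
#' dosages and the reference-allele dosage is g = sum_h d(h) G(h), in [0, 2].
#' Computed once per SDP group.
#'
#' @param dosage n x M x F founder dosage array (\code{\link{founder_dosage}}).
#' @param snps Founder SNP table (see \code{\link{snp_sdp}}).
#' @param map The \code{\link{marker_map}}.
#' @param panel A \code{\link{founder_panel}}.
#' @param collapse If TRUE (default) compute one column per SDP group and
#'   broadcast; otherwise one column per SNP.
#' @return List of class \code{snp_dosage}: \code{g} (n x G matrix),
#'   \code{snps} (table with \code{group} column), \code{group_snp} (a
#'   representative SNP row per group), \code{monomorphic} (per-group flag;
#'   monomorphic groups carry constant g and are excluded from scans).
#' @export
impute_snp_dosage <- function(dosage, snps, map, panel = founder_panel(),
                              collapse = TRUE) {
  n <- dim(dosage)[1]; m <- dim(dosage)[2]; f <- dim(dosage)[3]
  stopifnot(m == nrow(map))
  grp <- if (collapse) collapse_sdp(snps, map, panel) else seq_len(nrow(snps))
  rep_row <- match(seq_len(max(grp)), grp)
  al <- as.matrix(snps[, unclass(panel), drop = FALSE])
  sdp <- snp_sdp(snps, panel)
  g <- matrix(0, n, length(rep_row))
  idx <- map_chr_index(map)
  for (k in seq_along(rep_row)) {
    r <- rep_row[k]
    j <- idx[[as.character(snps$chr[r])]]
    pos <- map$bp[j]
    iv <- findInterval(snps$bp[r], pos)
    dsn <- if (iv == 0) matrix(dosage[, j[1], ], n, f)
      else if (iv >= length(j)) matrix(dosage[, j[length(j)], ], n, f)
      else (matrix(dosage[, j[iv], ], n, f) +
              matrix(dosage[, j[iv + 1], ], n, f)) / 2
    g[, k] <- dsn %*% al[r, ]
  }
  colnames(g) <- snps$snp[rep_row]
  out_snps <- snps
  out_snps$group <- grp
  structure(list(g = g, snps = out_snps,
                 group_snp = snps[rep_row, c("snp", "chr", "bp")],
                 monomorphic = attr(sdp, "monomorphic")[rep_row]),
            class = "snp_dosage")
}

#' Impute a diploid genome from a phased marginal reconstruction
#'
#' Each SNP inherits one founder allele per haplotype strand from the founder
#' covering the SNP's interval (nearest marker's founder before the first /
#' after the last marker, flagged).
#'
#' @param phased A \code{\link{phase_reconstruction}} result.
#' @param snps Founder SNP table.
#' @param panel A \code{\link{founder_panel}}.
#' @return List: \code{g} (n x nSNP integer allele-count matrix in 0..2),
#'   \code{flagged} (SNPs outside the marker span).
#' @export
impute_marginal_genome <- function(phased, snps, panel = founder_panel()) {
  map <- phased$map
  n <- nrow(phased$h1)
  al <- as.matrix(snps[, unclass(panel), drop = FALSE])
  g <- matrix(0L, n, nrow(snps), dimnames = list(rownames(phased$h1), snps$snp))
  flagged <- logical(nrow(snps))
  idx <- map_chr_index(map)
  for (cc in unique(snps$chr)) {
    j <- idx[[as.character(cc)]]
    w <- which(snps$chr == cc)
    iv <- findInterval(snps$bp[w], map$bp[j])
    flagged[w] <- iv == 0 | iv >= length(j)
    # nearest-marker rule: use left marker inside the span, clamp at the ends
    jm <- j[pmin(pmax(iv, 1), length(j))]
    for (q in seq_along(w)) {
      a1 <- al[w[q], ][phased$h1[, jm[q]]]
      a2 <- al[w[q], ][phased$h2[, jm[q]]]
      g[, w[q]] <- as.integer(a1 + a2)
    }
  }
  list(g = g, flagged = flagged)
}
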