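# Kinship as expected founder-allele sharing: per marker, the cosine
# similarity of the two samples' F-dimensional dosage vectors, averaged over
# markers. Self-similarity is 1 by construction. The matrix is not forced
# positive semidefinite; the mixed-model solver clamps/jitters if a
# factorization requires it.

# normalized dosage unfolded to n x (M*F); markers with a zero dosage vector
# are dropped with a warning. Returns list(B, keep).
normalized_dosage <- function(dosage) {
  n <- dim(dosage)[1]; m <- dim(dosage)[2]; f <- dim(dosage)[3]
  flat <- matrix(dosage, n * m, f)
  nrm2 <- rowSums(flat * flat)
  zero <- matrix(nrm2 == 0, n, m)
  keep <- which(!apply(zero, 2, any))
  if (length(keep) < m)
    warning(m - length(keep), " marker(s) skipped: zero dosage vector")
  if (!length(keep)) stop("no usable markers for kinship")
  flat <- flat / sqrt(pmax(nrm2, 1e-300))
  dn <- array(flat, c(n, m, f))[, keep, , drop = FALSE]
  list(B = matrix(dn, n, length(keep) * f), keep = keep)
}

#' Kinship matrix from founder dosages
#'
#' Expected founder-allele sharing between samples i and e:
#' \deqn{k_{ie} = \frac{1}{M} \sum_j \frac{\sum_h d_{ij}(h) d_{ej}(h)}
#'   {\sqrt{\sum_h d_{ij}(h)^2} \sqrt{\sum_h d_{ej}(h)^2}}}
#' i.e. the per-marker cosine similarity of dosage vectors averaged over the
#' M markers. The diagonal is exactly 1.
#'
#' @param dosage n x M x F founder dosage array (\code{\link{founder_dosage}}).
#' @param map Optional \code{\link{marker_map}}; required when excluding a
#'   chromosome.
#' @param exclude_chr Optional chromosome label to omit
#'   (leave-one-chromosome-out member).
#' @return n x n symmetric matrix of class \code{kinship} with attribute
#'   \code{n_markers}.
#' @seealso \code{\link{loco_kinship}} for the full LOCO list.
#' @export
calc_kinship <- function(dosage, map = NULL, exclude_chr = NULL) {
  if (!is.null(exclude_chr)) {
    if (is.null(map)) stop("'map' is required to exclude a chromosome")
    keep <- which(map$chr != exclude_chr)
    if (!length(keep)) stop("no markers left after excluding chr ", exclude_chr)
    dosage <- dosage[, keep, , drop = FALSE]
  }
  nd <- normalized_dosage(dosage)
  mm <- length(nd$keep)
  K <- tcrossprod(nd$B) / mm
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  structure(K, n_markers = mm, class = c("kinship", "matrix", "array"))
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome, the kinship computed from all markers NOT on that
#' chromosome, so that a scanned locus never contributes to its own polygenic
#' correction (avoids proximal contamination).
#'
#' @inheritParams calc_kinship
#' @param map The \code{\link{marker_map}} (required).
#' @return Named list of \code{kinship} matrices, one per chromosome, class
#'   \code{loco_kinship}.
#' @export
loco_kinship <- function(dosage, map) {
  n <- dim(dosage)[1]
  idx <- map_chr_index(map)
  nd <- normalized_dosage(dosage)
  keep <- nd$keep
  f <- dim(dosage)[3]
  per <- lapply(idx, function(j) {
    cols <- which(keep %in% j)
    if (!length(cols)) return(list(S = matrix(0, n, n), m = 0L))
    cols_full <- as.vector(outer(cols, (seq_len(f) - 1) * length(keep), "+"))
    list(S = tcrossprod(nd$B[, cols_full, drop = FALSE]), m = length(cols))
  })
  Stot <- Reduce(`+`, lapply(per, `[[`, "S"))
  mtot <- sum(vapply(per, `[[`, 0L, "m"))
  out <- lapply(names(idx), function(cc) {
    S <- (Stot - per[[cc]]$S) / (mtot - per[[cc]]$m)
    dimnames(S) <- list(rownames(dosage), rownames(dosage))
    structure(S, n_markers = mtot - per[[cc]]$m,
              class = c("kinship", "matrix", "array"))
  })
  names(out) <- names(idx)
  structure(out, class = "loco_kinship")
}
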