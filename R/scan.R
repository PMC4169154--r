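# Genome scans by regression on diplotype probabilities, founder dosages, or
# imputed SNP dosages, with the polygenic kinship correction. Variance
# components come from the null fit and are held fixed along the genome;
# each locus is tested by a likelihood ratio on the rotated, weighted data:
# LOD = (n/2) log10(RSS0/RSS1), -log10(p) from the chi-square with the
# model's degrees of freedom (35 full, 7 additive haplotype, 1 additive SNP).

# rotate a matrix into the null fit's eigenbasis and apply sqrt-weights
rotate_weight <- function(fit, M) {
  if (!is.null(fit$U)) M <- crossprod(fit$U, M)
  M * sqrt(fit$weights)
}

# per-locus regression loop: Gw holds k columns per locus in locus-fastest
# layout (column (h-1)*m + l is predictor h of locus l)
scan_rss_loop <- function(Xw, yw, Gw, m, k, keep_coef = TRUE) {
  n <- nrow(Xw); p <- ncol(Xw)
  rss <- numeric(m)
  cf <- if (keep_coef) matrix(NA_real_, m, k) else NULL
  Xl <- cbind(Xw, matrix(0, n, k))
  for (l in seq_len(m)) {
    Xl[, p + seq_len(k)] <- Gw[, (seq_len(k) - 1L) * m + l]
    f <- stats::lm.fit(Xl, yw)
    rss[l] <- sum(f$residuals^2)
    if (keep_coef) cf[l, ] <- f$coefficients[p + seq_len(k)]
  }
  list(rss = rss, coef = cf)
}

lod_from_rss <- function(rss0, rss1, n) {
  pmax(n / 2 * log10(pmax(rss0, 1e-300) / pmax(rss1, 1e-300)), 0)
}

neglog10p_from_lod <- function(lod, df) {
  -stats::pchisq(2 * log(10) * lod, df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Genome scan
#'
#' Scans the genome under one of three regression models: \code{"full"}
#' (unconstrained regression on the 36 diplotype state probabilities, 35 df),
#' \code{"haplotype"} (additive founder-dosage model, 7 df) or \code{"snp"}
#' (additive imputed-SNP dosage, 1 df). The polygenic covariance is fixed
#' from the null fit; with a \code{\link{loco_kinship}} list the null model
#' is refit per chromosome with that chromosome's markers left out of the
#' kinship.
#'
#' One aliased genotype column is dropped by construction (dosages sum to 2,
#' probabilities to 1, both confounded with the intercept), giving the stated
#' degrees of freedom. A constant locus predictor yields LOD 0, not an error.
#'
#' @param pheno Numeric phenotype vector.
#' @param geno Model-dependent genotypes: \code{"haplotype"} an n x M x F
#'   dosage array (\code{\link{founder_dosage}}); \code{"full"} an
#'   n x M x S probability array (or n x M integer state matrix, expanded
#'   internally); \code{"snp"} an \code{\link{impute_snp_dosage}} object.
#' @param map The \code{\link{marker_map}} (ignored for \code{"snp"}, which
#'   carries its own positions).
#' @param kinship NULL (plain linear model), an n x n kinship matrix, or a
#'   \code{\link{loco_kinship}} list.
#' @param covar Covariates passed to \code{\link{fit_polygenic}}.
#' @param model Regression model.
#' @param states \code{\link{diplotype_states}}; required when \code{geno}
#'   is a state matrix.
#' @param keep_coef Store per-locus genotype coefficients (default TRUE
#'   except for \code{"snp"}).
#' @return Object of class \code{qtl_scan}: a data.frame with columns
#'   \code{locus}, \code{chr}, \code{bp}, \code{lod}, \code{neglog10p}, with
#'   attributes \code{model}, \code{df}, \code{h2} (per chromosome if LOCO),
#'   \code{coef} (loci x k matrix of locus coefficients).
#' @export
qtl_scan <- function(pheno, geno, map = NULL, kinship = NULL, covar = NULL,
                     model = c("haplotype", "full", "snp"), states = NULL,
                     keep_coef = NULL) {
  model <- match.arg(model)
  if (is.null(keep_coef)) keep_coef <- model != "snp"
  loco <- inherits(kinship, "loco_kinship")
  if (model == "snp") return(scan_snp(pheno, geno, kinship, covar, loco))

  if (length(dim(geno)) == 2) {  # integer state matrix: expand
    if (is.null(states)) stop("'states' required to expand a state matrix")
    geno <- if (model == "full") state_probs(geno, states)
            else dosage_from_states(geno, states)
  }
  stopifnot(length(dim(geno)) == 3, !is.null(map), dim(geno)[2] == nrow(map))
  n <- dim(geno)[1]; m <- dim(geno)[2]; k_all <- dim(geno)[3]
  k <- k_all - 1L  # drop one aliased column
  df <- k
  idx <- map_chr_index(map)
  global_fit <- if (!loco) fit_polygenic(pheno, kinship, covar) else NULL
  lod <- numeric(m); cf <- if (keep_coef) matrix(NA_real_, m, k_all) else NULL
  h2 <- c()
  Gflat <- matrix(geno, n, m * k_all)
  for (cc in names(idx)) {
    j <- idx[[cc]]
    fit <- if (loco) fit_polygenic(pheno, kinship[[cc]], covar) else global_fit
    h2[cc] <- fit$h2
    keep <- fit$keep
    cols <- as.vector(outer(j, (seq_len(k) - 1L) * m, "+"))  # drop last slice
    Gw <- rotate_weight(fit, Gflat[keep, cols, drop = FALSE])
    Xw <- fit$Xrot * sqrt(fit$weights)
    yw <- fit$yrot * sqrt(fit$weights)
    rss0 <- sum(stats::lm.fit(Xw, yw)$residuals^2)
    sc <- scan_rss_loop(Xw, yw, Gw, length(j), k, keep_coef)
    lod[j] <- lod_from_rss(rss0, sc$rss, fit$n)
    if (keep_coef) cf[j, ] <- cbind(sc$coef, 0)  # dropped column = reference 0
  }
  if (keep_coef && !is.null(dimnames(geno)[[3]]))
    colnames(cf) <- dimnames(geno)[[3]]
  out <- data.frame(locus = map$marker, chr = map$chr, bp = map$bp,
                    lod = lod, neglog10p = neglog10p_from_lod(lod, df))
  structure(out, model = model, df = df, h2 = h2, coef = cf,
            class = c("qtl_scan", "data.frame"))
}

# additive SNP model: vectorized 1-df regressions per SDP group
scan_snp <- function(pheno, snp_dos, kinship, covar, loco) {
  stopifnot(inherits(snp_dos, "snp_dosage"))
  g <- snp_dos$g
  info <- snp_dos$group_snp
  mono <- snp_dos$monomorphic
  ngrp <- ncol(g)
  lodg <- numeric(ngrp)
  chrs <- unique(info$chr)
  global_fit <- if (!loco) fit_polygenic(pheno, kinship, covar) else NULL
  for (cc in chrs) {
    w <- which(info$chr == cc & !mono)
    if (!length(w)) next
    fit <- if (loco) fit_polygenic(pheno, kinship[[cc]], covar) else global_fit
    Xw <- fit$Xrot * sqrt(fit$weights)
    yw <- fit$yrot * sqrt(fit$weights)
    Gw <- rotate_weight(fit, g[fit$keep, w, drop = FALSE])
    Q <- qr.Q(qr(Xw))
    yres <- yw - Q %*% crossprod(Q, yw)
    Gres <- Gw - Q %*% crossprod(Q, Gw)
    rss0 <- sum(yres^2)
    den <- colSums(Gres^2)
    num <- as.vector(crossprod(Gres, yres))^2
    rss1 <- rss0 - ifelse(den > 1e-10, num / pmax(den, 1e-300), 0)
    lodg[w] <- lod_from_rss(rss0, rss1, fit$n)
  }
  # broadcast group results to member SNPs
  grp <- snp_dos$snps$group
  out <- data.frame(locus = snp_dos$snps$snp, chr = snp_dos$snps$chr,
                    bp = snp_dos$snps$bp, lod = lodg[grp],
                    neglog10p = neglog10p_from_lod(lodg[grp], 1))
  structure(out, model = "snp", df = 1, h2 = NULL, coef = NULL,
            group_lod = lodg, class = c("qtl_scan", "data.frame"))
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("Genome scan (", attr(x, "model"), " model, ", attr(x, "df"),
      " df): ", nrow(x), " loci\n", sep = "")
  pk <- x[which.max(x$lod), ]
  cat("peak: ", pk$locus, " (chr ", pk$chr, ", ",
      round(pk$bp / 1e6, 2), " Mb)  LOD = ", round(pk$lod, 2), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, threshold = NULL, ...) {
  sp <- split(seq_len(nrow(object)), object$chr)
  pk <- do.call(rbind, lapply(sp, function(i) object[i[which.max(object$lod[i])], ]))
  pk <- pk[order(-pk$lod), ]
  if (!is.null(threshold)) pk <- pk[pk$lod >= threshold, ]
  rownames(pk) <- NULL
  pk
}

#' Locus with maximum LOD
#'
#' @param scan A \code{\link{qtl_scan}}.
#' @param chr Optional chromosome restriction.
#' @return One-row data.frame.
#' @export
max_scan <- function(scan, chr = NULL) {
  s <- if (is.null(chr)) scan else scan[scan$chr %in% chr, ]
  s[which.max(s$lod), ]
}

#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  chr <- unique(x$chr)
  off <- 0; pos <- numeric(nrow(x)); mid <- numeric(length(chr))
  for (k in seq_along(chr)) {
    i <- x$chr == chr[k]
    pos[i] <- x$bp[i] + off
    mid[k] <- off + mean(range(x$bp[i]))
    off <- off + max(x$bp[i]) + 1e6
  }
  col <- rep(c("#3B528B", "#5DC863"), length.out = length(chr))
  graphics::plot(pos, x$lod, type = "n", xaxt = "n", xlab = "Chromosome",
                 ylab = "LOD", ...)
  for (k in seq_along(chr)) {
    i <- x$chr == chr[k]
    graphics::lines(pos[i], x$lod[i], col = col[k])
  }
  graphics::axis(1, at = mid, labels = chr, tick = FALSE)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red")
  invisible(x)
}

#' Centered founder allele effects at a locus
#'
#' Re-expresses the additive haplotype model's eight founder coefficients at
#' a locus with mean zero across founders (the display convention for founder
#' effect plots). Centering is idempotent.
#'
#' @param scan A \code{\link{qtl_scan}} run with \code{model = "haplotype"}
#'   and \code{keep_coef = TRUE}.
#' @param locus Marker id or row index.
#' @return Named numeric vector of F centered effects.
#' @export
founder_effects <- function(scan, locus) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (attr(scan, "model") != "haplotype")
    stop("founder effects require the additive haplotype model")
  cf <- attr(scan, "coef")
  if (is.null(cf)) stop("scan was run with keep_coef = FALSE")
  i <- if (is.character(locus)) match(locus, scan$locus) else locus
  if (is.na(i) || i < 1 || i > nrow(scan)) stop("unknown locus")
  b <- cf[i, ]
  b[is.na(b)] <- 0
  b - mean(b)
}
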