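# Genome-wide significance: Bonferroni thresholds, permutation thresholds
# (the permuted scans are fit WITHOUT the kinship term -- a plain linear
# model -- which yields conservative thresholds for the mixed-model scan
# despite the population structure), and 95% Bayesian credible support
# intervals on the 10^LOD-transformed curve.

#' Bonferroni genome-wide threshold
#'
#' -log10(alpha / n_tests). With the 7664 retained array markers at
#' alpha = 0.05 this gives 5.2; with 57,977 markers, 6.06.
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Genome-wide significance level in (0, 1).
#' @return Threshold on the -log10(p) scale.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  -log10(alpha / n_tests)
}

# multi-phenotype OLS genome scan; returns per-phenotype maximum LOD over
# the given loci. Y is n x P; intercept-only fixed effects.
ols_max_lod <- function(Y, geno, map, model, snp_dos = NULL, loci = NULL) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  if (model == "snp") {
    g <- snp_dos$g
    w <- which(!snp_dos$monomorphic &
                 snp_dos$group_snp$chr %in% autosomes_of(map))
    Gc <- sweep(g[, w, drop = FALSE], 2, colMeans(g[, w, drop = FALSE]))
    den <- colSums(Gc^2)
    red <- crossprod(Gc, Yc)^2 / pmax(den, 1e-300)  # groups x P reductions
    best <- apply(red, 2, max)
    return(lod_from_rss(rss0, rss0 - best, n))
  }
  m <- dim(geno)[2]; k_all <- dim(geno)[3]; k <- k_all - 1L
  Gflat <- matrix(geno, n, m * k_all)
  if (is.null(loci)) loci <- which(map$chr %in% autosomes_of(map))
  best_red <- numeric(ncol(Y))
  one <- matrix(1, n, 1)
  for (l in loci) {
    Xl <- cbind(one, Gflat[, (seq_len(k) - 1L) * m + l, drop = FALSE])
    Q <- qr.Q(qr(Xl))
    best_red <- pmax(best_red, colSums(crossprod(Q, Yc)^2))
  }
  lod_from_rss(rss0, rss0 - best_red, n)
}

#' Permutation genome-wide threshold
#'
#' Permutes phenotype rows (together with their covariates, as a unit),
#' rescans each permuted set with a plain linear model (no kinship term) and
#' retains the maximum LOD across autosomal loci; the threshold is the
#' empirical (1 - alpha) quantile of the maxima.
#'
#' @param pheno Numeric phenotype vector.
#' @param geno Genotypes as in \code{\link{qtl_scan}} for the chosen model.
#' @param map The \code{\link{marker_map}}.
#' @param covar Optional covariates (forces the slower per-permutation loop).
#' @param model \code{"haplotype"}, \code{"full"} or \code{"snp"}.
#' @param n_perm Number of permutations (default 1000; < 10 is refused).
#' @param alpha Significance level(s) for the reported threshold.
#' @param seed Optional integer seed.
#' @return Object of class \code{perm_thresholds}: \code{maxima} (length
#'   \code{n_perm}), \code{threshold} (named by alpha, LOD scale),
#'   \code{alpha}, \code{model}, \code{df}.
#' @export
perm_threshold <- function(pheno, geno, map, covar = NULL,
                           model = c("haplotype", "full", "snp"),
                           n_perm = 1000, alpha = 0.05, seed = NULL) {
  model <- match.arg(model)
  if (n_perm < 10) stop("fewer than 10 permutations is not meaningful")
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(pheno)
  n <- length(y)
  auto <- autosomes_of(map)
  if (is.null(covar)) {
    P <- matrix(0, n, n_perm)
    for (p in seq_len(n_perm)) P[, p] <- y[sample.int(n)]
    maxima <- if (model == "snp")
      ols_max_lod(P, NULL, map, "snp", snp_dos = geno)
    else ols_max_lod(P, geno, map, model)
  } else {
    maxima <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      o <- sample.int(n)
      sc <- qtl_scan(y[o], geno, map, kinship = NULL,
                     covar = as.data.frame(covar)[o, , drop = FALSE],
                     model = model, keep_coef = FALSE)
      maxima[p] <- max(sc$lod[sc$chr %in% auto])
    }
  }
  thr <- stats::quantile(maxima, 1 - alpha, names = FALSE)
  names(thr) <- paste0("alpha=", alpha)
  df <- switch(model, haplotype = 7, full = 35, snp = 1)
  structure(list(maxima = maxima, threshold = thr, alpha = alpha,
                 model = model, df = df, n_perm = n_perm),
            class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat("Permutation thresholds (", x$n_perm, " permutations, ", x$model,
      " model, no kinship term)\n", sep = "")
  for (i in seq_along(x$threshold))
    cat("  ", names(x$threshold)[i], ": LOD ", round(x$threshold[i], 3),
        "\n", sep = "")
  invisible(x)
}

#' Bayesian credible support interval for a QTL
#'
#' Transforms the chromosome's LOD curve to 10^LOD, integrates it with
#' trapezoids between marker positions, and returns the smallest contiguous
#' region containing the peak whose transformed area reaches the coverage
#' level. \code{method = "peak"} (default) expands greedily from the peak
#' toward the higher-area neighbor; \code{method = "hpd"} adds intervals in
#' decreasing area order and keeps the contiguous run containing the peak.
#'
#' @param scan A \code{\link{qtl_scan}} (or data.frame with \code{chr},
#'   \code{bp}, \code{lod}).
#' @param chr Chromosome to localize on (default: chromosome of the global
#'   LOD peak).
#' @param level Coverage level (default 0.95).
#' @param method Interval construction rule.
#' @return Object of class \code{support_interval}: \code{chr}, \code{lo_bp},
#'   \code{hi_bp}, \code{level}, \code{peak_bp}, \code{peak_lod},
#'   \code{whole_chromosome} flag.
#' @export
credible_interval <- function(scan, chr = NULL, level = 0.95,
                              method = c("peak", "hpd")) {
  method <- match.arg(method)
  if (is.null(chr)) chr <- scan$chr[which.max(scan$lod)]
  s <- scan[scan$chr == chr, ]
  s <- s[order(s$bp), ]
  m <- nrow(s)
  if (m < 2) stop("need at least 2 markers on the chromosome")
  h <- 10^(s$lod - max(s$lod))  # rescaled for numerical stability
  areas <- diff(s$bp) * (h[-1] + h[-m]) / 2
  total <- sum(areas)
  pk <- which.max(s$lod)
  whole <- FALSE
  if (all(s$lod == 0) || total <= 0) {
    lo <- 1; hi <- m; whole <- TRUE
  } else if (method == "peak") {
    lo <- hi <- pk
    acc <- 0
    while (acc < level * total && (lo > 1 || hi < m)) {
      left <- if (lo > 1) areas[lo - 1] else -Inf
      right <- if (hi < m) areas[hi] else -Inf
      if (left >= right) { lo <- lo - 1; acc <- acc + left }
      else { hi <- hi + 1; acc <- acc + right }
    }
  } else {
    ord <- order(areas, decreasing = TRUE)
    sel <- logical(m - 1)
    acc <- 0
    for (i in ord) {
      sel[i] <- TRUE
      acc <- acc + areas[i]
      if (acc >= level * total) break
    }
    # contiguous run of selected intervals containing the peak
    lo <- min(pk, m - 1)
    while (lo > 1 && sel[lo - 1]) lo <- lo - 1
    hi <- max(pk - 1, 1)
    while (hi < m - 1 && sel[hi + 1]) hi <- hi + 1
    hi <- hi + 1
    if (!sel[min(pk, m - 1)] && !sel[max(pk - 1, 1)]) { lo <- pk; hi <- pk }
  }
  structure(list(chr = chr, lo_bp = s$bp[lo], hi_bp = s$bp[hi],
                 level = level, peak_bp = s$bp[pk], peak_lod = s$lod[pk],
                 whole_chromosome = whole),
            class = "support_interval")
}

#' @export
print.support_interval <- function(x, ...) {
  cat("QTL support interval (", 100 * x$level, "% credible): chr ", x$chr,
      " ", round(x$lo_bp / 1e6, 2), "-", round(x$hi_bp / 1e6, 2),
      " Mb (peak LOD ", round(x$peak_lod, 2), " at ",
      round(x$peak_bp / 1e6, 2), " Mb)",
      if (x$whole_chromosome) " [flat curve: whole chromosome]", "\n", sep = "")
  invisible(x)
}
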