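# Power and type-I-error simulation studies, scaled-down by default
# (500-marker genomes, a fixed simulated G8 genome pool standing in for real
# reconstructions, a few hundred replicates). Phenotype per replicate:
# QTL effect (+a / -a on the two homozygote classes, 0 heterozygotes)
# + polygenic term ~ MVN(0, kinship) + iid N(0,1) error. Detection: max LOD
# exceeds the sample-size-specific threshold (from null scans of iid N(0,1)
# phenotypes fit without the kinship term) AND lies within 5 Mb of the truth.

# normal-equation RSS with ridge fallback for (near-)aliased designs
fast_rss <- function(X, y) {
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-8 * mean(diag(XtX)) + 1e-12
    R <- chol(XtX + diag(ridge, ncol(X)))
  }
  b <- backsolve(R, forwardsolve(t(R), Xty))
  max(sum(y^2) - sum(b * Xty), 0)
}

#' Simulated genome pool for power studies
#'
#' Builds the fixed infrastructure shared by all simulation cells: a
#' synthetic marker map, a simulated DO cohort at the requested generation
#' (the genome pool), true diplotype states and founder dosages at the
#' markers, the pool kinship matrix, and an imputed-SNP dosage set from a
#' synthetic founder SNP table.
#'
#' @param n_pool Pool size (default 1000; replicates draw samples from it).
#' @param gen Outbreeding generation (default 8).
#' @param n_markers Markers genome-wide (default 500, scaled down).
#' @param n_pairs Breeding pairs (default 175).
#' @param snps_per_interval Founder SNPs simulated per marker interval.
#' @param panel A \code{\link{founder_panel}}.
#' @param seed Optional integer seed.
#' @return Object of class \code{power_pool}: \code{map}, \code{states},
#'   \code{state} (pool x M truth), \code{dosage} (pool x M x F), \code{K}
#'   (pool kinship), \code{snp_dos} (\code{\link{impute_snp_dosage}}),
#'   \code{minor_count} (minor-allele founder count per SDP group),
#'   \code{shares} (pool founder shares).
#' @export
power_pool <- function(n_pool = 1000, gen = 8, n_markers = 500,
                       n_pairs = 175, snps_per_interval = 4,
                       panel = founder_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- sim_marker_map(n_markers)
  states <- diplotype_states(panel)
  pop <- sim_do_population(map, n_ind = n_pool, n_pairs = n_pairs, gen = gen)
  truth <- true_diplotypes(pop, map, states)
  D <- dosage_from_states(truth$state, states)
  K <- calc_kinship(D)
  snps <- sim_founder_snps(map, per_interval = snps_per_interval, panel = panel)
  snp_dos <- impute_snp_dosage(D, snps, map, panel)
  al <- as.matrix(snps[, unclass(panel)])
  rep_row <- match(seq_len(max(snp_dos$snps$group)), snp_dos$snps$group)
  minor_count <- rowSums(al[rep_row, , drop = FALSE] == 0)
  structure(list(map = map, states = states, state = truth$state,
                 dosage = D, K = K, snp_dos = snp_dos,
                 minor_count = minor_count, shares = founder_shares(pop),
                 gen = gen, panel = panel),
            class = "power_pool")
}

#' @export
print.power_pool <- function(x, ...) {
  cat("Simulated genome pool: ", nrow(x$state), " G", x$gen, " genomes, ",
      nrow(x$map), " markers, ", ncol(x$snp_dos$g), " SDP groups\n", sep = "")
  invisible(x)
}

#' Null-scan genome-wide LOD threshold for a simulation cell
#'
#' Determined once per sample size: the (1 - alpha) quantile of the maximum
#' autosomal LOD over scans of phenotypes drawn iid from N(0, 1), fit by a
#' plain linear model (no kinship term) on a fixed draw of n pool genomes.
#'
#' @param pool A \code{\link{power_pool}}.
#' @param n Sample size of the cell.
#' @param model Scan model.
#' @param n_null Number of null phenotypes (default 300, scaled down from
#'   1000).
#' @param alpha Genome-wide level (default 0.05).
#' @param seed Optional integer seed.
#' @return List of class \code{scan_threshold}: \code{threshold} (LOD),
#'   \code{maxima}, \code{model}, \code{n}, \code{alpha}.
#' @export
scan_threshold <- function(pool, n, model = c("haplotype", "full", "snp"),
                           n_null = 300, alpha = 0.05, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(pool$state), n)
  Y <- matrix(stats::rnorm(n * n_null), n, n_null)
  maxima <- if (model == "snp") {
    sub <- pool$snp_dos
    sub$g <- sub$g[idx, , drop = FALSE]
    ols_max_lod(Y, NULL, pool$map, "snp", snp_dos = sub)
  } else if (model == "haplotype") {
    ols_max_lod(Y, pool$dosage[idx, , , drop = FALSE], pool$map, "haplotype")
  } else {
    ols_max_full(Y, pool$state[idx, , drop = FALSE], pool$states)
  }
  structure(list(threshold = stats::quantile(maxima, 1 - alpha, names = FALSE),
                 maxima = maxima, model = model, n = n, alpha = alpha),
            class = "scan_threshold")
}

# multi-phenotype OLS max-LOD for the full model via one-hot group sums
ols_max_full <- function(Y, SI, states) {
  n <- nrow(Y); m <- ncol(SI)
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  best <- numeric(ncol(Y))
  for (l in seq_len(m)) {
    f <- factor(SI[, l])
    gs <- rowsum(Yc, f)                      # per-state sums
    cnt <- tabulate(as.integer(f))
    best <- pmax(best, colSums(gs^2 / cnt))  # fitted SS of group means
  }
  lod_from_rss(rss0, rss0 - best, n)
}

# mixed-model LOD curves for one replicate, by model ---------------------

mixed_scan_haplo_lod <- function(fit, Dflat, m, f) {
  k <- f - 1L
  Gw <- rotate_weight(fit, Dflat[fit$keep, seq_len(m * k), drop = FALSE])
  Xw <- fit$Xrot * sqrt(fit$weights)
  yw <- fit$yrot * sqrt(fit$weights)
  rss0 <- sum(stats::lm.fit(Xw, yw)$residuals^2)
  sc <- scan_rss_loop(Xw, yw, Gw, m, k, keep_coef = FALSE)
  lod_from_rss(rss0, sc$rss, fit$n)
}

mixed_scan_full_lod <- function(fit, SI, n_states) {
  m <- ncol(SI)
  Uw <- if (is.null(fit$U)) NULL else fit$U
  sw <- sqrt(fit$weights)
  Xw <- fit$Xrot * sw
  yw <- fit$yrot * sw
  rss0 <- sum(stats::lm.fit(Xw, yw)$residuals^2)
  rss <- numeric(m)
  for (l in seq_len(m)) {
    if (is.null(Uw)) {
      Xl <- cbind(Xw, state_cols(SI[, l], n_states) * sw)
    } else {
      rs <- t(rowsum(Uw, SI[, l])) * sw   # rotated one-hot state columns
      Xl <- cbind(Xw, rs)
    }
    rss[l] <- fast_rss(Xl, yw)
  }
  lod_from_rss(rss0, rss, fit$n)
}

state_cols <- function(si, n_states) {
  n <- length(si)
  x <- matrix(0, n, length(unique(si)))
  x[cbind(seq_len(n), match(si, sort(unique(si))))] <- 1
  x
}

mixed_scan_snp_lod <- function(fit, g) {
  Xw <- fit$Xrot * sqrt(fit$weights)
  yw <- fit$yrot * sqrt(fit$weights)
  Gw <- rotate_weight(fit, g[fit$keep, , drop = FALSE])
  Q <- qr.Q(qr(Xw))
  yres <- yw - Q %*% crossprod(Q, yw)
  Gres <- Gw - Q %*% crossprod(Q, Gw)
  rss0 <- sum(yres^2)
  den <- colSums(Gres^2)
  num <- as.vector(crossprod(Gres, yres))^2
  rss1 <- rss0 - ifelse(den > 1e-10, num / pmax(den, 1e-300), 0)
  lod_from_rss(rss0, rss1, fit$n)
}

#' QTL effect size for a target variance-explained share
#'
#' Inverts the Hardy-Weinberg variance decomposition of the simulated QTL
#' term (+a, 0, -a on the three genotype classes; allele frequency
#' p = maf/F): Var_QTL = a^2 (q^2 + p^2 - (q^2 - p^2)^2). Returns the effect
#' a such that Var_QTL / (Var_QTL + background_var) equals \code{share}.
#'
#' @param share Target QTL share of total phenotypic variance in (0, 1).
#' @param maf Number of founders carrying the minor allele (1..F/2).
#' @param n_founders F (default 8).
#' @param background_var Polygenic + error variance (default 2).
#' @return Effect size in standardized units.
#' @export
effect_for_pve <- function(share, maf, n_founders = 8, background_var = 2) {
  stopifnot(share > 0, share < 1)
  p <- maf / n_founders; q <- 1 - p
  coefv <- q^2 + p^2 - (q^2 - p^2)^2
  sqrt(share * background_var / (1 - share) / coefv)
}

#' Run one power-simulation cell
#'
#' Per replicate: draw n genomes from the pool, pick a causal SNP (uniformly
#' among SDP groups with the requested minor-allele founder count), build the
#' phenotype (QTL + MVN polygenic with kinship covariance + iid error), run
#' the kinship-adjusted scan(s), and score detection when the maximum
#' autosomal LOD exceeds the cell threshold and falls within
#' \code{window_mb} of the true locus.
#'
#' @param pool A \code{\link{power_pool}}.
#' @param n Sample size.
#' @param maf Minor-allele founder count (1..4).
#' @param effect QTL effect in standardized units.
#' @param thresholds Named list/vector of LOD thresholds by model (from
#'   \code{\link{scan_threshold}}); its names select the models run.
#' @param n_reps Replicates (default 200, scaled down from 1000).
#' @param window_mb Detection window around the truth (default 5 Mb).
#' @param seed Optional integer seed.
#' @return Object of class \code{power_result}: \code{power} (named by
#'   model), \code{detect} (reps x models logical), \code{mean_pve}
#'   (mean realized QTL variance share), \code{mean_ci_width_mb} (mean 95\%
#'   support-interval width over detected haplotype-scan replicates, NA if
#'   none), plus the cell parameters.
#' @export
power_cell <- function(pool, n, maf, effect, thresholds, n_reps = 200,
                       window_mb = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  models <- names(thresholds)
  stopifnot(length(models) > 0, all(models %in% c("haplotype", "full", "snp")))
  npool <- nrow(pool$state)
  m <- nrow(pool$map)
  f <- length(pool$states$founders)
  cand <- which(pool$minor_count == maf)
  if (!length(cand)) stop("no SDP group with minor-allele count ", maf)
  al <- as.matrix(pool$snp_dos$snps[, unclass(pool$panel)])
  rep_row <- match(seq_len(max(pool$snp_dos$snps$group)), pool$snp_dos$snps$group)
  grp_chr <- pool$snp_dos$group_snp$chr
  grp_bp <- pool$snp_dos$group_snp$bp
  # founder-major flat dosage (drop-last-founder columns are the first (F-1)M)
  Dflat_all <- matrix(pool$dosage, npool, m * f)
  detect <- matrix(FALSE, n_reps, length(models),
                   dimnames = list(NULL, models))
  pve <- numeric(n_reps)
  ciw <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(npool, n)
    Ksub <- pool$K[idx, idx]
    ed <- eigen(Ksub, symmetric = TRUE)
    cs <- sample(cand, 1)
    qtl_chr <- grp_chr[cs]
    jchr <- which(pool$map$chr == qtl_chr)
    jq <- jchr[which.min(abs(pool$map$bp[jchr] - grp_bp[cs]))]
    # the genotype is taken from the diplotype at the nearest marker, so the
    # effective simulated QTL location is that marker
    qtl_bp <- pool$map$bp[jq]
    minor <- which(al[rep_row[cs], ] == 0)
    ph <- sim_phenotype(pool$state[idx, jq], minor, effect, pool$states,
                        kinship = structure(Ksub, eigen = ed))
    pve[r] <- ph$var_explained
    fit <- fit_polygenic(ph$y, Ksub, eigen_K = ed)
    for (mod in models) {
      lods <- switch(mod,
        haplotype = mixed_scan_haplo_lod(fit, Dflat_all[idx, , drop = FALSE], m, f),
        full = mixed_scan_full_lod(fit, pool$state[idx, , drop = FALSE],
                                   nrow(pool$states$N)),
        snp = mixed_scan_snp_lod(fit, pool$snp_dos$g[idx, , drop = FALSE]))
      pos <- if (mod == "snp") grp_bp else pool$map$bp
      chrv <- if (mod == "snp") grp_chr else pool$map$chr
      pk <- which.max(lods)
      hit <- lods[pk] > thresholds[[mod]] &&
        chrv[pk] == qtl_chr && abs(pos[pk] - qtl_bp) <= window_mb * 1e6
      detect[r, mod] <- hit
      if (mod == "haplotype" && hit) {
        sc <- data.frame(chr = pool$map$chr, bp = pool$map$bp, lod = lods)
        ci <- credible_interval(sc, chr = qtl_chr)
        ciw[r] <- (ci$hi_bp - ci$lo_bp) / 1e6
      }
    }
  }
  structure(list(power = colMeans(detect), detect = detect,
                 mean_pve = mean(pve), mean_ci_width_mb =
                   if (all(is.na(ciw))) NA_real_ else mean(ciw, na.rm = TRUE),
                 n = n, maf = maf, effect = effect, n_reps = n_reps,
                 thresholds = thresholds, window_mb = window_mb),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Power cell: n = ", x$n, ", MAF ", x$maf, "/8, effect ", x$effect,
      " SD, ", x$n_reps, " replicates\n", sep = "")
  for (mod in names(x$power))
    cat("  ", format(mod, width = 10), " power = ",
        sprintf("%.3f", x$power[mod]), "\n", sep = "")
  cat("  mean variance explained: ", sprintf("%.1f%%", 100 * x$mean_pve),
      "\n", sep = "")
  invisible(x)
}

#' Run one type-I-error simulation cell
#'
#' Null phenotypes (iid Gaussian by default, or polygenic + error) are mapped
#' with the kinship-adjusted scan; the type-I estimate is the fraction of
#' replicates with any autosomal LOD above the threshold.
#'
#' @inheritParams power_cell
#' @param threshold LOD threshold (scalar) for the chosen model.
#' @param model Scan model (default additive haplotype).
#' @param pheno \code{"gaussian"} (iid N(0,1), the type-I design) or
#'   \code{"polygenic"} (MVN kinship + error).
#' @return List of class \code{type1_result}: \code{type1}, \code{detect},
#'   \code{n}, \code{n_reps}, \code{threshold}.
#' @export
type1_cell <- function(pool, n, threshold, n_reps = 200,
                       model = "haplotype", pheno = c("gaussian", "polygenic"),
                       seed = NULL) {
  pheno <- match.arg(pheno)
  if (!is.null(seed)) set.seed(seed)
  npool <- nrow(pool$state)
  m <- nrow(pool$map)
  f <- length(pool$states$founders)
  Dflat_all <- matrix(pool$dosage, npool, m * f)
  det <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(npool, n)
    Ksub <- pool$K[idx, idx]
    ed <- eigen(Ksub, symmetric = TRUE)
    y <- if (pheno == "gaussian") stats::rnorm(n)
         else as.vector(ed$vectors %*% (sqrt(pmax(ed$values, 0)) *
                                          stats::rnorm(n))) + stats::rnorm(n)
    fit <- fit_polygenic(y, Ksub, eigen_K = ed)
    lods <- switch(model,
      haplotype = mixed_scan_haplo_lod(fit, Dflat_all[idx, , drop = FALSE], m, f),
      full = mixed_scan_full_lod(fit, pool$state[idx, , drop = FALSE],
                                 nrow(pool$states$N)),
      snp = mixed_scan_snp_lod(fit, pool$snp_dos$g[idx, , drop = FALSE]))
    det[r] <- max(lods) > threshold
  }
  structure(list(type1 = mean(det), detect = det, n = n, n_reps = n_reps,
                 threshold = threshold, model = model, pheno = pheno),
            class = "type1_result")
}

#' @export
print.type1_result <- function(x, ...) {
  cat("Type I error cell: n = ", x$n, ", ", x$n_reps,
      " null replicates (", x$pheno, " phenotype): ",
      sprintf("%.3f", x$type1), "\n", sep = "")
  invisible(x)
}

#' Logistic power curve over variance explained
#'
#' Fits, per sample size, a logistic regression of detection on the percent
#' phenotypic variance explained by the QTL, summarizing a grid of power
#' cells.
#'
#' @param grid data.frame with columns \code{n}, \code{pve} (percent),
#'   \code{power}, \code{reps}.
#' @return List of class \code{power_curve}: per sample size the fitted
#'   \code{glm} (NULL and flagged when power is degenerate all-0/all-1) and
#'   \code{pve_at} function(power) returning the percent variance explained
#'   at which that power is attained.
#' @export
power_curve <- function(grid) {
  stopifnot(all(c("n", "pve", "power", "reps") %in% names(grid)),
            nrow(grid) >= 3)
  out <- lapply(split(grid, grid$n), function(gg) {
    succ <- round(gg$power * gg$reps)
    if (all(succ == 0) || all(succ == gg$reps))
      return(list(fit = NULL, degenerate = TRUE, data = gg))
    fit <- stats::glm(cbind(succ, gg$reps - succ) ~ pve, data = gg,
                      family = stats::binomial())
    pve_at <- function(p) {
      b <- stats::coef(fit)
      (stats::qlogis(p) - b[1]) / b[2]
    }
    list(fit = fit, degenerate = FALSE, pve_at = pve_at, data = gg)
  })
  structure(out, class = "power_curve")
}
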