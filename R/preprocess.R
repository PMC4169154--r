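# Intensity preprocessing: cross-cohort quantile normalization, the polar
# coordinate transform, and per-marker Gaussian-mixture cluster
# initialization (diagonal bivariate GMM, number of clusters chosen by BIC;
# hand-rolled since no mixture-model package is available).

#' Quantile-normalize reference intensities onto a target cohort
#'
#' Maps each marker's reference-sample intensities onto the empirical
#' quantiles of the target cohort at that marker (the founder/F1 reference
#' panels are normalized to match the study cohort). Any monotone
#' distributional shift between the cohorts is removed exactly at matching
#' ranks.
#'
#' @param x Reference intensities: an \code{intensity_data} list (X, Y) or a
#'   samples x markers matrix.
#' @param target Target cohort intensities, same type and marker set as
#'   \code{x}.
#' @return \code{x} with each marker column replaced by target-cohort
#'   quantiles at the reference ranks.
#' @export
quantile_normalize <- function(x, target) {
  if (inherits(x, "intensity_data") || (is.list(x) && !is.matrix(x))) {
    stopifnot(is.list(target))
    return(structure(list(X = quantile_normalize(x$X, target$X),
                          Y = quantile_normalize(x$Y, target$Y)),
                     class = "intensity_data"))
  }
  stopifnot(is.matrix(x), is.matrix(target), ncol(x) == ncol(target))
  if (nrow(x) < 2 || nrow(target) < 2)
    stop("quantile normalization needs at least 2 samples per cohort")
  out <- x
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    p <- (rank(x[, j], ties.method = "average") - 1) / (n - 1)
    out[, j] <- stats::quantile(target[, j], probs = p, names = FALSE, type = 7)
  }
  out
}

#' Polar coordinate transform of two-channel intensities
#'
#' theta = (2/pi) * atan2(y, x), scaled to [0, 1] over the first quadrant;
#' rho = sqrt(x^2 + y^2). The degenerate point (0, 0) gets theta = 0.5 and is
#' flagged in the \code{undefined} attribute.
#'
#' @param x,y Non-negative intensity vectors/matrices of equal shape, or
#'   \code{x} an \code{intensity_data} list with \code{y} missing.
#' @return List with \code{theta} and \code{rho} (same shape as input);
#'   attribute \code{undefined} marks (0,0) inputs.
#' @export
polar_transform <- function(x, y = NULL) {
  if (is.null(y)) { y <- x$Y; x <- x$X }
  stopifnot(length(x) == length(y))
  rho <- sqrt(x^2 + y^2)
  theta <- (2 / pi) * atan2(as.vector(y), as.vector(x))
  undef <- x == 0 & y == 0
  theta[undef] <- 0.5
  if (is.matrix(x)) { dim(theta) <- dim(x); dimnames(theta) <- dimnames(x) }
  structure(list(theta = theta, rho = rho), undefined = undef)
}

# ---- diagonal bivariate Gaussian mixture, BIC model selection --------------

# EM fit of a k-component diagonal GMM on an n x d matrix; kmeans init.
fit_gmm <- function(x, k, max_iter = 100, tol = 1e-6, var_floor = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (k == 1) {
    mu <- matrix(colMeans(x), 1)
    v <- matrix(pmax(apply(x, 2, stats::var) * (n - 1) / n, var_floor), 1)
    ll <- sum(stats::dnorm(x, rep(mu, each = n), rep(sqrt(v), each = n), log = TRUE))
    return(list(k = 1, prop = 1, mean = mu, var = v, loglik = ll,
                z = matrix(1, n, 1)))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = min(k, n - 1), nstart = 5,
                                       iter.max = 30))
  mu <- km$centers
  k <- nrow(mu)
  v <- matrix(pmax(apply(x, 2, stats::var) / k, var_floor), k, d, byrow = TRUE)
  prop <- pmax(tabulate(km$cluster, k) / n, 1e-6); prop <- prop / sum(prop)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- matrix(0, n, k)
    for (c in seq_len(k))
      lw[, c] <- log(prop[c]) +
        rowSums(stats::dnorm(x, rep(mu[c, ], each = n),
                             rep(sqrt(v[c, ]), each = n), log = TRUE))
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx)
    sw <- rowSums(w)
    ll <- sum(log(sw) + mx)
    z <- w / sw
    nk <- colSums(z)
    prop <- nk / n
    for (c in seq_len(k)) {
      if (nk[c] < 1e-8) next
      mu[c, ] <- colSums(z[, c] * x) / nk[c]
      v[c, ] <- pmax(colSums(z[, c] * sweep(x, 2, mu[c, ])^2) / nk[c], var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(k = k, prop = prop, mean = mu, var = v, loglik = ll, z = z)
}

# BIC (mclust convention, 2*ll - npar*log(n)); larger is better
gmm_bic <- function(fit, n) {
  npar <- (fit$k - 1) + fit$k * 2 * ncol(fit$mean)
  2 * fit$loglik - npar * log(n)
}

#' Fit a Gaussian mixture with BIC-selected cluster count
#'
#' Fits diagonal bivariate Gaussian mixtures for k in \code{1..kmax} and
#' returns the fit maximizing the BIC.
#'
#' @param x n x 2 matrix (theta, rho).
#' @param kmax Largest candidate cluster count (default 9).
#' @return Best fit (list with \code{k}, \code{prop}, \code{mean}, \code{var},
#'   \code{loglik}, \code{z}) plus \code{bic} and the full \code{bic_trace}.
#' @export
select_clusters <- function(x, kmax = 9) {
  x <- as.matrix(x)
  kmax <- min(kmax, max(1, nrow(x) - 1))
  fits <- lapply(seq_len(kmax), function(k) fit_gmm(x, k))
  bics <- vapply(fits, gmm_bic, 0, n = nrow(x))
  best <- fits[[which.max(bics)]]
  best$bic <- max(bics)
  best$bic_trace <- bics
  best
}

#' Initialize intensity-emission parameters from reference samples
#'
#' At one marker: pools reference (founder/F1, known diplotypes) and cohort
#' intensities in polar coordinates, fits a BIC-selected Gaussian mixture,
#' then assigns each diplotype state to the cluster nearest its reference
#' samples' mean location. States without reference samples are placed at the
#' midpoint of their two founders' homozygote locations and flagged. Initial
#' means/variances per state are the assigned cluster's parameters.
#'
#' @param ref_theta,ref_rho Polar coordinates of the reference samples at the
#'   marker.
#' @param ref_state Integer diplotype state index of each reference sample.
#' @param cohort_theta,cohort_rho Polar coordinates of the study cohort.
#' @param states A \code{\link{diplotype_states}}.
#' @param kmax Cluster-count search range upper bound.
#' @return List: \code{cluster} (state -> cluster index), \code{mu_theta},
#'   \code{var_theta}, \code{mu_rho}, \code{var_rho} (length S), \code{k},
#'   \code{flagged} (states lacking reference samples), \code{gmm}.
#' @export
init_clusters <- function(ref_theta, ref_rho, ref_state,
                          cohort_theta, cohort_rho, states, kmax = 9) {
  s <- length(states$labels)
  xy <- rbind(cbind(ref_theta, ref_rho), cbind(cohort_theta, cohort_rho))
  fit <- select_clusters(xy, kmax = kmax)
  # state reference centers
  cen <- matrix(NA_real_, s, 2)
  for (k in unique(ref_state))
    cen[k, ] <- c(mean(ref_theta[ref_state == k]), mean(ref_rho[ref_state == k]))
  flagged <- which(is.na(cen[, 1]))
  if (length(flagged)) {
    hom_idx <- match(seq_along(states$founders),
                     ifelse(states$homozygous, states$pairs[, 1], NA))
    for (k in flagged) {
      a <- hom_idx[states$pairs[k, 1]]; b <- hom_idx[states$pairs[k, 2]]
      if (!is.na(cen[a, 1]) && !is.na(cen[b, 1]))
        cen[k, ] <- (cen[a, ] + cen[b, ]) / 2
      else  # no usable founder reference at all: overall center
        cen[k, ] <- colMeans(xy)
    }
  }
  # nearest mixture component, scale-standardized distance
  sc <- pmax(apply(xy, 2, stats::sd), 1e-6)
  d2 <- outer(cen[, 1] / sc[1], fit$mean[, 1] / sc[1], "-")^2 +
        outer(cen[, 2] / sc[2], fit$mean[, 2] / sc[2], "-")^2
  cl <- max.col(-d2, ties.method = "first")
  list(cluster = cl,
       mu_theta = fit$mean[cl, 1], var_theta = fit$var[cl, 1],
       mu_rho = fit$mean[cl, 2], var_rho = fit$var[cl, 2],
       k = fit$k, flagged = flagged, gmm = fit)
}
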