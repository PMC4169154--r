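# Polygenic linear mixed model: y = X a + g + e with cov(g) = sigma2_g * K,
# cov(e) = sigma2_e * I. Fitted by ML after eigendecomposition of K (the
# "two-stage GLS" approach): with K = U D U', rotate by U' and the model
# becomes a weighted regression with per-sample variance
# sigma2 * (h * d_i + 1 - h), h = sigma2_g / (sigma2_g + sigma2_e).
# Variance components are estimated once per phenotype under the null and
# held fixed across the genome scan.

# weighted RSS of y ~ X with weights w (both already rotated)
wls_rss <- function(X, y, w) {
  sw <- sqrt(w)
  f <- stats::lm.fit(X * sw, y * sw)
  list(rss = sum(f$residuals^2), coef = f$coefficients, rank = f$rank)
}

#' Fit the null polygenic model
#'
#' Estimates the variance components of the kinship-corrected null model (no
#' locus term) by maximum likelihood and reports the narrow-sense
#' heritability h2 = sigma2_g / (sigma2_g + sigma2_e). The eigendecomposition
#' and fitted weights are retained so genome scans and permutations can reuse
#' them with the variance components fixed.
#'
#' @param pheno Numeric phenotype vector (NAs dropped, with a message, along
#'   with the matching rows of \code{covar}/\code{kinship}).
#' @param kinship n x n kinship matrix (\code{\link{calc_kinship}}), or NULL
#'   for an ordinary linear model.
#' @param covar Covariate data.frame/matrix; categorical columns are one-hot
#'   encoded with a reference level. An intercept is always included.
#' @param eigen_K Optional precomputed \code{eigen(kinship, symmetric=TRUE)}
#'   (valid only when no phenotype rows are dropped); avoids refactorizing in
#'   tight simulation loops.
#' @return Object of class \code{polygenic_fit}: \code{h2}, \code{sigma2_g},
#'   \code{sigma2_e}, \code{loglik}, \code{coef}, plus rotation components
#'   (\code{U}, \code{d}, \code{weights}, \code{Xrot}, \code{yrot},
#'   \code{keep}) used by \code{\link{qtl_scan}}.
#' @export
fit_polygenic <- function(pheno, kinship = NULL, covar = NULL, eigen_K = NULL) {
  y <- as.numeric(pheno)
  keep <- which(!is.na(y))
  if (length(keep) < length(y))
    message("dropping ", length(y) - length(keep), " samples with missing phenotype")
  y <- y[keep]
  n <- length(y)
  X <- build_covar(covar, keep)
  # drop aliased covariate columns
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("dropping ", ncol(X) - q$rank, " aliased covariate column(s)")
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  if (n < ncol(X) + 2) stop("too few samples for the fixed-effect model")
  if (is.null(kinship)) {
    f <- wls_rss(X, y, rep(1, n))
    s2 <- f$rss / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    out <- list(h2 = 0, sigma2_g = 0, sigma2_e = s2, loglik = ll,
                coef = f$coef, U = NULL, d = rep(1, n),
                weights = rep(1, n), Xrot = X, yrot = y, keep = keep, n = n)
    class(out) <- "polygenic_fit"
    return(out)
  }
  ed <- if (!is.null(eigen_K) && length(keep) == length(pheno)) eigen_K
        else eigen(as.matrix(kinship)[keep, keep], symmetric = TRUE)
  d <- pmax(ed$values, 1e-6)  # jitter-clamp: K is not guaranteed PSD
  U <- ed$vectors
  ys <- as.vector(crossprod(U, y))
  Xs <- crossprod(U, X)
  negll <- function(h) {
    v <- h * d + (1 - h)
    f <- wls_rss(Xs, ys, 1 / v)
    s2 <- f$rss / n
    0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  }
  opt <- stats::optimize(negll, c(0, 0.9999))
  h <- if (negll(0) <= opt$objective) 0 else opt$minimum
  v <- h * d + (1 - h)
  w <- 1 / v
  f <- wls_rss(Xs, ys, w)
  s2 <- f$rss / n
  out <- list(h2 = h, sigma2_g = h * s2, sigma2_e = (1 - h) * s2,
              loglik = -negll(h), coef = f$coef, U = U, d = d, weights = w,
              Xrot = Xs, yrot = ys, keep = keep, n = n)
  class(out) <- "polygenic_fit"
  out
}

# covariate matrix with intercept; one-hot with reference level for factors
build_covar <- function(covar, keep) {
  if (is.null(covar))
    return(matrix(1, length(keep), 1, dimnames = list(NULL, "(Intercept)")))
  cv <- as.data.frame(covar)[keep, , drop = FALSE]
  stats::model.matrix(~ ., data = cv)
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Polygenic mixed model (ML)\n")
  cat("  n =", x$n, "\n")
  cat("  h2 =", round(x$h2, 4),
      " sigma2_g =", signif(x$sigma2_g, 4),
      " sigma2_e =", signif(x$sigma2_e, 4), "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
coef.polygenic_fit <- function(object, ...) object$coef

#' Narrow-sense heritability
#'
#' Ratio of the additive genetic variance over the total phenotypic variance
#' from a fitted polygenic model.
#'
#' @param fit A \code{\link{fit_polygenic}} result.
#' @return h2 in [0, 1].
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "polygenic_fit"))
  fit$h2
}
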