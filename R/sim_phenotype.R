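#' Simulate a QTL phenotype
#'
#' Phenotype = QTL term + polygenic background + independent error. The QTL
#' effect (in standardized units) is added to one homozygous class and
#' subtracted from the other; heterozygotes get zero. The polygenic term is
#' multivariate normal with covariance \code{polygenic_var * kinship} (iid
#' normal if \code{kinship} is NULL); the error is iid normal. With the unit
#' default variances the two background components contribute equally, giving
#' background variance 2.
#'
#' @param state_at_qtl Integer vector (length n) of true diplotype state
#'   indices at the QTL locus.
#' @param minor_founders Integer indices (or codes) of the founders carrying
#'   the causative minor allele (the paper-style "MAF" of 1..4 founders).
#' @param effect QTL effect size, standardized units (>= 0). The minor-allele
#'   homozygote class gets \code{-effect}, the major class \code{+effect}.
#' @param states A \code{\link{diplotype_states}}.
#' @param kinship Optional n x n kinship matrix for the polygenic covariance.
#' @param polygenic_var,error_var Background variance components (defaults 1).
#' @param seed Optional integer seed.
#' @return List: \code{y} (phenotype vector), \code{qtl_geno} (minor-allele
#'   dose 0/1/2 per individual), \code{qtl_term}, \code{var_explained}
#'   (realized QTL variance share of total phenotype variance).
#' @export
sim_phenotype <- function(state_at_qtl, minor_founders, effect, states,
                          kinship = NULL, polygenic_var = 1, error_var = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(effect >= 0)
  if (is.character(minor_founders))
    minor_founders <- match(minor_founders, states$founders)
  n <- length(state_at_qtl)
  dose <- rowSums(states$N[state_at_qtl, minor_founders, drop = FALSE])
  qtl <- c(effect, 0, -effect)[dose + 1]  # 0 minor alleles -> +a, 2 -> -a
  if (is.null(kinship)) {
    g <- stats::rnorm(n, 0, sqrt(polygenic_var))
  } else {
    stopifnot(nrow(kinship) == n)
    e <- attr(kinship, "eigen")
    if (is.null(e)) e <- eigen(kinship, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    g <- as.vector(e$vectors %*% (sqrt(lam * polygenic_var) * stats::rnorm(n)))
  }
  y <- qtl + g + stats::rnorm(n, 0, sqrt(error_var))
  vexp <- stats::var(qtl) / stats::var(y)
  list(y = y, qtl_geno = dose, qtl_term = qtl, var_explained = vexp)
}
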