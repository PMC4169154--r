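# 36-state hidden Markov model for diplotype reconstruction: emission models
# (multinomial over A/H/B/N calls; product-of-normals over polar-coordinate
# intensities), scaled forward-backward, and EM fitting of emission
# parameters (transition parameters are held fixed throughout).

CALL_SYMBOLS <- c("A", "H", "B", "N")

#' Initial genotype-call emission distributions
#'
#' Per marker and state, a multinomial over A/H/B/N: the genotype expected
#' from the founder sequences gets probability \code{p_expected} (default
#' 0.97) and the remainder is spread evenly over the other three outcomes, to
#' allow for call errors and no-calls. N is a separate, informative outcome.
#'
#' @param founder_geno M x F founder genotype matrix (1 = reference allele).
#' @param states A \code{\link{diplotype_states}}.
#' @param p_expected Probability of the expected call.
#' @return M x S x 4 array of emission probabilities.
#' @export
genotype_emission_init <- function(founder_geno, states, p_expected = 0.97) {
  m <- nrow(founder_geno); s <- length(states$labels)
  emis <- array((1 - p_expected) / 3, c(m, s, 4),
                dimnames = list(rownames(founder_geno), states$labels, CALL_SYMBOLS))
  for (j in seq_len(m)) {
    eg <- match(expected_genotype(founder_geno[j, ], states), CALL_SYMBOLS)
    emis[cbind(j, seq_len(s), eg)] <- p_expected
  }
  emis
}

# encode calls as integers 1..4; anything else is an error
encode_calls <- function(calls) {
  x <- match(calls, CALL_SYMBOLS)
  bad <- is.na(x) & !is.na(calls)
  if (any(bad)) {
    w <- which(bad)[1]
    stop("unknown genotype call '", calls[w], "' at entry ", w)
  }
  dim(x) <- dim(calls)
  x
}

# per-sample emission likelihood matrix (M x S), scaled so each row's max is
# 1; returns the log scaling in attr "logscale". Missing observations give a
# flat row (log-lik contribution 0).
emission_lik_calls <- function(obs_i, emis) {
  m <- dim(emis)[1]; s <- dim(emis)[2]
  idx <- rep(seq_len(m), s) + (rep(seq_len(s), each = m) - 1L) * m +
    (obs_i - 1L) * (m * s)
  E <- matrix(emis[idx], m, s)
  E[is.na(obs_i), ] <- 1
  structure(E, logscale = numeric(m))
}

emission_lik_intensity <- function(theta_i, rho_i, par) {
  lE <- -0.5 * (sweep(-par$mu_theta, 1, theta_i, "+")^2 / par$var_theta +
                  log(2 * pi * par$var_theta) +
                  sweep(-par$mu_rho, 1, rho_i, "+")^2 / par$var_rho +
                  log(2 * pi * par$var_rho))
  lE[is.na(theta_i) | is.na(rho_i), ] <- 0
  mx <- apply(lE, 1, max)
  structure(exp(lE - mx), logscale = mx)
}

#' Forward-backward posterior diplotype probabilities
#'
#' Scaled forward-backward over one sample and one chromosome. Posteriors sum
#' to one at every marker; the log-likelihood includes emission scaling.
#'
#' @param E M x S emission likelihood matrix (optionally with a
#'   \code{logscale} attribute of per-marker log scaling constants).
#' @param trans List of M-1 transition matrices (S x S), as one chromosome of
#'   a \code{\link{build_transitions}} model.
#' @param prior Initial state distribution (default
#'   \code{\link{diplotype_equilibrium}}-style uniform over pairs is supplied
#'   by callers; here a flat prior if missing).
#' @return List: \code{post} (M x S posterior), \code{loglik}.
#' @export
forward_backward <- function(E, trans, prior = NULL) {
  m <- nrow(E); s <- ncol(E)
  if (m < 1) stop("need at least one marker")
  if (is.null(prior)) prior <- rep(1 / s, s)
  ls <- attr(E, "logscale"); if (is.null(ls)) ls <- numeric(m)
  f <- matrix(0, m, s)
  scale <- numeric(m)
  v <- prior * E[1, ]
  if (sum(v) <= 0) { v <- rep(1, s); warning("all-zero emission row; flat fallback") }
  scale[1] <- sum(v); f[1, ] <- v / scale[1]
  if (m > 1) for (j in 2:m) {
    v <- as.vector(f[j - 1, ] %*% trans[[j - 1]]) * E[j, ]
    if (sum(v) <= 0) { v <- rep(1, s); warning("all-zero emission row; flat fallback") }
    scale[j] <- sum(v); f[j, ] <- v / scale[j]
  }
  b <- matrix(0, m, s)
  b[m, ] <- 1
  if (m > 1) for (j in (m - 1):1) {
    v <- as.vector(trans[[j]] %*% (E[j + 1, ] * b[j + 1, ]))
    mx <- max(v)
    b[j, ] <- if (mx > 0) v / mx else rep(1, s)
  }
  post <- f * b
  post <- post / rowSums(post)
  list(post = post, loglik = sum(log(scale)) + sum(ls))
}

#' Fit the diplotype HMM by EM
#'
#' Reconstructs diplotype probabilities for a cohort from genotype calls or
#' two-channel intensities. The E-step runs forward-backward per sample and
#' chromosome; the M-step re-estimates emission parameters per marker by
#' pooling posterior weights across samples (soft assignments). Transition
#' parameters are never updated. Iteration stops when the log-likelihood
#' changes by less than \code{tol} times the absolute initial log-likelihood
#' (default 1/1000), or at \code{max_iter}.
#'
#' @param calls n x M call matrix over A/H/B/N (for the genotype model), or
#'   NULL.
#' @param intensities \code{intensity_data} list (X, Y) for the intensity
#'   model, or NULL. Exactly one of \code{calls}/\code{intensities} must be
#'   given.
#' @param map A \code{\link{marker_map}}.
#' @param gen Outbreeding generation (drives the transition model).
#' @param states A \code{\link{diplotype_states}}.
#' @param founder_geno M x F founder genotypes; required for the genotype
#'   model's emission initialization.
#' @param init For the intensity model: list of M x S matrices
#'   \code{mu_theta}, \code{var_theta} (or scalar \code{sd_theta}),
#'   \code{mu_rho}, \code{var_rho}/\code{sd_rho}, e.g. from
#'   \code{\link{sim_intensity_clusters}} or per-marker
#'   \code{\link{init_clusters}}.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-3 of
#'   the initial log-likelihood).
#' @param max_iter Maximum EM iterations (default 100).
#' @param transitions Optional prebuilt \code{\link{build_transitions}} model.
#' @param events_per_gen Transition calibration constant.
#' @param var_floor Variance floor for intensity emissions (default 1e-4).
#' @param prob_floor Multinomial floor for call emissions (default 1e-4,
#'   renormalized).
#' @return Object of class \code{diplotype_fit}: list with \code{probs}
#'   (n x M x S posterior array), \code{loglik_trace}, \code{iterations},
#'   \code{converged}, \code{emission}, \code{map}, \code{states},
#'   \code{data_type}.
#' @export
fit_diplotypes <- function(calls = NULL, intensities = NULL, map, gen, states,
                           founder_geno = NULL, init = NULL, tol = 1e-3,
                           max_iter = 100, transitions = NULL,
                           events_per_gen = 23.9, var_floor = 1e-4,
                           prob_floor = 1e-4) {
  if (is.null(calls) == is.null(intensities))
    stop("supply exactly one of 'calls' or 'intensities'")
  type <- if (is.null(calls)) "intensity" else "calls"
  if (type == "calls") {
    obs <- encode_calls(calls)
    n <- nrow(obs)
    if (is.null(founder_geno)) stop("genotype model needs 'founder_geno'")
    emis <- genotype_emission_init(founder_geno, states)
  } else {
    pol <- polar_transform(intensities)
    theta <- pol$theta; rho <- pol$rho
    n <- nrow(theta)
    if (is.null(init)) stop("intensity model needs initial cluster parameters")
    m <- nrow(map); s <- length(states$labels)
    as_mat <- function(mu, v, sd_scalar) {
      if (is.null(v)) v <- matrix(sd_scalar^2, m, s)
      if (!is.matrix(v)) v <- matrix(v, m, s)
      pmax(v, var_floor)
    }
    emis <- list(mu_theta = init$mu_theta,
                 var_theta = as_mat(init$mu_theta, init$var_theta, init$sd_theta),
                 mu_rho = init$mu_rho,
                 var_rho = as_mat(init$mu_rho, init$var_rho, init$sd_rho))
  }
  if (n < 2) stop("EM fitting needs at least 2 samples")
  if (n < 100)
    warning("EM emission estimation works best with several hundred samples; n = ", n)
  m <- nrow(map); s <- length(states$labels)
  if (is.null(transitions)) transitions <- build_transitions(map, gen, states, events_per_gen)
  prior <- diplotype_equilibrium(states)
  idx <- map_chr_index(map)

  post <- array(0, c(n, m, s))
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    ll <- 0
    for (i in seq_len(n)) {
      for (cc in names(idx)) {
        j <- idx[[cc]]
        E <- if (type == "calls") {
          emission_lik_calls(obs[i, j], emis[j, , , drop = FALSE])
        } else {
          emission_lik_intensity(theta[i, j], rho[i, j],
                                 lapply(emis, function(p) p[j, , drop = FALSE]))
        }
        fb <- forward_backward(E, transitions[[cc]]$T, prior)
        post[i, j, ] <- fb$post
        ll <- ll + fb$loglik
      }
    }
    if (!is.finite(ll)) stop("non-finite log-likelihood at EM iteration ", it)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol * abs(ll_trace[1])) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    # ---- M-step ----
    if (type == "calls") {
      for (o in 1:4) {
        msk <- as.numeric(!is.na(obs) & obs == o)
        emis[, , o] <- colSums(post * msk) + prob_floor
      }
      tot <- emis[, , 1] + emis[, , 2] + emis[, , 3] + emis[, , 4]
      for (o in 1:4) emis[, , o] <- emis[, , o] / tot
    } else {
      ok <- as.numeric(!(is.na(theta) | is.na(rho)))
      w <- colSums(post * ok)                       # M x S
      w <- pmax(w, 1e-12)
      th0 <- ifelse(is.na(theta), 0, theta); rh0 <- ifelse(is.na(rho), 0, rho)
      mt <- colSums(post * (ok * as.vector(th0))) / w
      mt2 <- colSums(post * (ok * as.vector(th0^2))) / w
      mr <- colSums(post * (ok * as.vector(rh0))) / w
      mr2 <- colSums(post * (ok * as.vector(rh0^2))) / w
      emis$mu_theta <- mt
      emis$var_theta <- pmax(mt2 - mt^2, var_floor)
      emis$mu_rho <- mr
      emis$var_rho <- pmax(mr2 - mr^2, var_floor)
    }
  }
  dimnames(post) <- list(rownames(if (type == "calls") calls else theta),
                         map$marker, states$labels)
  structure(list(probs = post, loglik_trace = ll_trace, iterations = it,
                 converged = converged, emission = emis, map = map,
                 states = states, data_type = type,
                 lambda = attr(transitions, "lambda"), gen = gen),
            class = "diplotype_fit")
}

#' @export
print.diplotype_fit <- function(x, ...) {
  d <- dim(x$probs)
  cat("Diplotype HMM fit (", x$data_type, " emission model)\n", sep = "")
  cat("  samples:", d[1], " markers:", d[2], " states:", d[3], "\n")
  cat("  EM iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max iterations reached)", "\n")
  cat("  log-likelihood:", format(utils::tail(x$loglik_trace, 1)), "\n")
  invisible(x)
}

#' @export
summary.diplotype_fit <- function(object, ...) {
  mx <- apply(object$probs, c(1, 2), max)
  out <- list(mean_max_prob = mean(mx),
              frac_confident = mean(mx > 0.9),
              loglik_trace = object$loglik_trace)
  class(out) <- "summary.diplotype_fit"
  out
}

#' @export
print.summary.diplotype_fit <- function(x, ...) {
  cat("Mean maximal diplotype probability:", round(x$mean_max_prob, 3), "\n")
  cat("Fraction of (sample, marker) cells with max prob > 0.9:",
      round(x$frac_confident, 3), "\n")
  invisible(x)
}

#' Marginal reconstruction: per-marker maximum-probability diplotype
#'
#' Assigns each (sample, marker) cell the diplotype state with maximum
#' posterior probability. Exact ties are broken toward the lowest state index
#' and flagged.
#'
#' @param probs n x M x S posterior array, or a \code{diplotype_fit}.
#' @return n x M integer state matrix with attribute \code{ties} (logical
#'   matrix marking tied argmaxima).
#' @export
marginal_reconstruction <- function(probs) {
  if (inherits(probs, "diplotype_fit")) probs <- probs$probs
  n <- dim(probs)[1]; m <- dim(probs)[2]
  out <- matrix(0L, n, m, dimnames = dimnames(probs)[1:2])
  ties <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    pm <- matrix(probs[i, , ], nrow = m)
    out[i, ] <- max.col(pm, ties.method = "first")
    mx <- pm[cbind(seq_len(m), out[i, ])]
    ties[i, ] <- rowSums(pm == mx) > 1
  }
  attr(out, "ties") <- ties
  out
}
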