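# Synthetic genotyping-array observations: biallelic founder genotypes,
# genotype calls with state-dependent error/no-call rates, and two-channel
# intensities with cluster structure (including "nonconforming" markers whose
# off-target variants split the three canonical A/H/B clusters into up to six,
# so that several diplotype states share one cluster center).

#' Simulate founder genotypes at map markers
#'
#' Draws a biallelic genotype (1 = reference allele, 0 = alternate) for each
#' founder at each marker; monomorphic markers are redrawn so every marker is
#' informative.
#'
#' @param map A \code{\link{marker_map}}.
#' @param panel A \code{\link{founder_panel}}.
#' @param seed Optional integer seed.
#' @return M x F 0/1 matrix, rows named by marker, columns by founder.
#' @export
sim_founder_geno <- function(map, panel = founder_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- length(panel); m <- nrow(map)
  g <- matrix(stats::rbinom(m * f, 1, 0.5), m, f,
              dimnames = list(map$marker, unclass(panel)))
  mono <- rowSums(g) %in% c(0, f)
  while (any(mono)) {
    g[mono, ] <- stats::rbinom(sum(mono) * f, 1, 0.5)
    mono <- rowSums(g) %in% c(0, f)
  }
  g
}

#' Array noise model
#'
#' Parameters of the synthetic array observation process.
#'
#' @param call_error Probability that a non-missing call is wrong (split
#'   evenly over the two wrong calls). Default 0.01.
#' @param nocall Baseline no-call (N) probability. Default 0.01.
#' @param nocall_state Optional named numeric vector of state-specific N
#'   rates overriding the baseline, named by state label (e.g.
#'   \code{c(FF = 0.9)} for a CAST-homozygote-style dropout).
#' @param theta_sd,rho_sd Cluster standard deviations of the polar-coordinate
#'   intensity angle and radius.
#' @param nonconforming Fraction of markers whose probe carries an off-target
#'   variant, yielding more than three intensity clusters. Default 0.15.
#' @return List of class \code{array_noise}.
#' @export
array_noise <- function(call_error = 0.01, nocall = 0.01, nocall_state = NULL,
                        theta_sd = 0.05, rho_sd = 0.1, nonconforming = 0.15) {
  stopifnot(call_error >= 0, call_error <= 1, nocall >= 0, nocall < 1,
            theta_sd >= 0, rho_sd >= 0, nonconforming >= 0, nonconforming <= 1)
  if (!is.null(nocall_state) &&
      (any(nocall_state < 0) || any(nocall_state > 1)))
    stop("state-specific no-call rates must be probabilities")
  structure(list(call_error = call_error, nocall = nocall,
                 nocall_state = nocall_state, theta_sd = theta_sd,
                 rho_sd = rho_sd, nonconforming = nonconforming),
            class = "array_noise")
}

# Multinomial call distribution over (A,H,B,N) per state at one marker.
# Expected call gets (1-nN)*(1-err); each wrong call (1-nN)*err/2; N gets nN.
call_distribution <- function(founder_alleles, states, noise) {
  s <- length(states$labels)
  expg <- expected_genotype(founder_alleles, states)
  nN <- rep(noise$nocall, s)
  if (!is.null(noise$nocall_state)) {
    i <- match(names(noise$nocall_state), states$labels)
    nN[i[!is.na(i)]] <- noise$nocall_state[!is.na(i)]
  }
  p <- matrix(0, s, 4, dimnames = list(states$labels, c("A", "H", "B", "N")))
  ei <- match(expg, c("A", "H", "B"))
  for (k in seq_len(s)) {
    p[k, 1:3] <- (1 - nN[k]) * noise$call_error / 2
    p[k, ei[k]] <- (1 - nN[k]) * (1 - noise$call_error)
    p[k, 4] <- nN[k]
  }
  p
}

#' Simulate genotype calls
#'
#' Draws A/H/B/N calls from each cell's state-specific multinomial: the call
#' expected under the true diplotype occurs with probability
#' \code{(1-nocall)*(1-call_error)}, wrong calls split the error mass, and N
#' occurs at the (possibly state-dependent) no-call rate. N is informative:
#' its rate depends on the true state.
#'
#' @param truth_state n x M integer matrix of true diplotype state indices
#'   (from \code{\link{true_diplotypes}}).
#' @param founder_geno M x F founder genotype matrix
#'   (\code{\link{sim_founder_geno}}).
#' @param states A \code{\link{diplotype_states}}.
#' @param noise An \code{\link{array_noise}} model.
#' @param seed Optional integer seed.
#' @return n x M character matrix over \code{c("A","H","B","N")}.
#' @export
sim_genotype_calls <- function(truth_state, founder_geno, states,
                               noise = array_noise(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth_state); m <- ncol(truth_state)
  stopifnot(nrow(founder_geno) == m)
  out <- matrix("", n, m, dimnames = dimnames(truth_state))
  syms <- c("A", "H", "B", "N")
  for (j in seq_len(m)) {
    p <- call_distribution(founder_geno[j, ], states, noise)
    pj <- p[truth_state[, j], , drop = FALSE]
    u <- stats::runif(n)
    cp <- pj %*% upper.tri(diag(4), diag = TRUE)  # row-wise cumulative
    out[, j] <- syms[1L + rowSums(u > cp + 1e-15)]
  }
  out
}

#' Cluster centers for synthetic intensities
#'
#' Builds per-marker, per-state polar-coordinate cluster parameters. Each
#' founder allele maps to a channel level; a diplotype's angle center is the
#' mean of its two allele levels, so conforming markers give three clusters
#' (A/H/B) and nonconforming markers (a random fraction, emulating off-target
#' probe variants) give up to six, with many states sharing a center.
#'
#' @inheritParams sim_genotype_calls
#' @param founder_geno M x F founder genotype matrix.
#' @return List of class \code{intensity_clusters} with M x S matrices
#'   \code{mu_theta}, \code{mu_rho} and scalars \code{sd_theta},
#'   \code{sd_rho}; attribute \code{nonconforming} flags affected markers.
#' @export
sim_intensity_clusters <- function(founder_geno, states,
                                   noise = array_noise(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(founder_geno); s <- length(states$labels)
  nonconf <- stats::runif(m) < noise$nonconforming
  mu_theta <- matrix(0, m, s, dimnames = list(rownames(founder_geno), states$labels))
  mu_rho <- matrix(0, m, s, dimnames = dimnames(mu_theta))
  a <- states$pairs[, 1]; b <- states$pairs[, 2]
  for (j in seq_len(m)) {
    lev <- as.numeric(founder_geno[j, ])  # allele channel level in [0,1]
    if (nonconf[j]) {
      shift <- sample(seq_along(lev), sample(1:2, 1))
      lev[shift] <- lev[shift] / 2 + 0.25  # off-target variant displaces allele
    }
    th <- 0.08 + 0.84 * (lev[a] + lev[b]) / 2
    mu_theta[j, ] <- th
    # one radius per distinct angle cluster, near 1
    centers <- sort(unique(round(th, 6)))
    rho_c <- stats::rnorm(length(centers), 1, 0.05)
    mu_rho[j, ] <- rho_c[match(round(th, 6), centers)]
  }
  structure(list(mu_theta = mu_theta, mu_rho = mu_rho,
                 sd_theta = noise$theta_sd, sd_rho = noise$rho_sd),
            class = "intensity_clusters", nonconforming = nonconf)
}

#' Simulate two-channel array intensities
#'
#' Samples (theta, rho) from each cell's cluster (product of two univariate
#' normals) and inverts the polar transform to X/Y channel intensities.
#' With zero cluster variance every sample lands exactly on its state's
#' cluster center.
#'
#' @inheritParams sim_genotype_calls
#' @param clusters An \code{\link{sim_intensity_clusters}} result.
#' @return List of class \code{intensity_data} with n x M matrices \code{X}
#'   and \code{Y} (non-negative).
#' @export
sim_intensities <- function(truth_state, clusters, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth_state); m <- ncol(truth_state)
  stopifnot(nrow(clusters$mu_theta) == m)
  theta <- matrix(0, n, m); rho <- matrix(0, n, m)
  for (j in seq_len(m)) {
    st <- truth_state[, j]
    theta[, j] <- stats::rnorm(n, clusters$mu_theta[j, st], clusters$sd_theta)
    rho[, j] <- stats::rnorm(n, clusters$mu_rho[j, st], clusters$sd_rho)
  }
  theta <- pmin(pmax(theta, 0), 1)
  rho <- pmax(rho, 0)
  x <- rho * cospi(theta / 2)
  y <- rho * sinpi(theta / 2)
  dimnames(x) <- dimnames(y) <- dimnames(truth_state)
  structure(list(X = x, Y = y), class = "intensity_data")
}

#' Simulate a founder SNP table
#'
#' Places SNPs between adjacent genotyped markers with random strain
#' distribution patterns (SDPs) drawn over a configurable number of
#' minor-allele founders. Used for genome-wide SNP imputation and the
#' additive SNP scan.
#'
#' @param map A \code{\link{marker_map}}.
#' @param per_interval SNPs per inter-marker interval (default 4).
#' @param minor_range Number of founders carrying the minor allele for each
#'   SNP, sampled uniformly from this set (default 1:4).
#' @param panel A \code{\link{founder_panel}}.
#' @param seed Optional integer seed.
#' @return data.frame of class \code{founder_snps}: \code{snp}, \code{chr},
#'   \code{bp}, then one 0/1 allele column per founder (1 = reference allele;
#'   minor-allele founders carry 0).
#' @export
sim_founder_snps <- function(map, per_interval = 4, minor_range = 1:4,
                             panel = founder_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- length(panel)
  out <- list()
  for (cc in unique(map$chr)) {
    sub <- map[map$chr == cc, ]
    for (k in seq_len(nrow(sub) - 1)) {
      bp <- sort(round(stats::runif(per_interval, sub$bp[k] + 1,
                                    sub$bp[k + 1] - 1)))
      allele <- matrix(1L, per_interval, f)
      for (q in seq_len(per_interval)) {
        nm <- sample(minor_range, 1)
        allele[q, sample.int(f, nm)] <- 0L
      }
      colnames(allele) <- unclass(panel)
      out[[length(out) + 1L]] <- data.frame(
        snp = sprintf("S%s_%d_%d", cc, sub$bp[k], seq_len(per_interval)),
        chr = cc, bp = bp, allele, check.names = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("founder_snps", "data.frame")
  res
}
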