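# Intensity preprocessing: quantile normalization, polar transform, and
# BIC-selected Gaussian-mixture cluster initialization.

test_that("quantile normalization maps reference onto target quantiles", {
  set.seed(61)
  n <- 40
  target <- matrix(rnorm(n * 5, 2, 1), n, 5)
  # reference differs from target by a monotone transform: undone exactly
  ref <- exp(target / 3)
  out <- quantile_normalize(ref, target)
  for (j in 1:5) expect_equal(sort(out[, j]), sort(target[, j]))
  expect_equal(out[order(ref[, 1]), 1], sort(target[, 1]))

  # reference already equal in distribution: output == input
  expect_equal(quantile_normalize(target, target), target)

  # empirical quantiles equal target quantiles at probed points (sort oracle)
  probs <- c(0.1, 0.5, 0.9)
  expect_equal(quantile(out[, 2], probs), quantile(target[, 2], probs))

  expect_error(quantile_normalize(target[1, , drop = FALSE], target),
               "at least 2")
})

test_that("polar transform handles axes, diagonal and the degenerate origin", {
  p <- polar_transform(c(1, 0, 1, 0), c(0, 1, 1, 0))
  expect_equal(p$theta, c(0, 1, 0.5, 0.5))
  expect_equal(p$rho, c(1, 1, sqrt(2), 0))
  expect_equal(attr(p, "undefined"), c(FALSE, FALSE, FALSE, TRUE))
  # inverse of the intensity generator's parameterization
  theta <- runif(50); rho <- runif(50, 0.5, 2)
  p2 <- polar_transform(rho * cospi(theta / 2), rho * sinpi(theta / 2))
  expect_equal(p2$theta, theta, tolerance = 1e-12)
  expect_equal(p2$rho, rho, tolerance = 1e-12)
})

test_that("BIC selects the generating number of clusters on separated mixtures", {
  set.seed(62)
  hits <- 0; trials <- 20
  for (t in seq_len(trials)) {
    k <- sample(1:3, 1)
    cx <- seq(0.15, 0.85, length.out = max(k, 2))[1:k]
    n <- 70 * k
    x <- cbind(rnorm(n, rep(cx, each = 70), 0.03),
               rnorm(n, rep(1 + 0.3 * seq_len(k), each = 70), 0.05))
    fit <- select_clusters(x, kmax = 6)
    hits <- hits + (fit$k == k)
  }
  expect_gte(hits / trials, 0.9)
})

test_that("cluster initialization assigns states to genotype groups", {
  st <- fx_states()
  set.seed(63)
  al <- c(1, 1, 1, 1, 0, 0, 0, 0)  # founders A-D reference, E-H alternate
  eg <- expected_genotype(al, st)
  centers <- c(A = 0.1, H = 0.5, B = 0.9)
  # reference samples: one per state at its genotype center
  ref_state <- rep(seq_len(36), each = 2)
  ref_theta <- rnorm(72, centers[eg[ref_state]], 0.01)
  ref_rho <- rnorm(72, 1, 0.02)
  coh_state <- sample.int(36, 150, TRUE)
  coh_theta <- rnorm(150, centers[eg[coh_state]], 0.01)
  coh_rho <- rnorm(150, 1, 0.02)
  ini <- init_clusters(ref_theta, ref_rho, ref_state, coh_theta, coh_rho, st)
  expect_equal(ini$k, 3)
  # states expected to share a genotype must share a cluster
  for (g in c("A", "H", "B"))
    expect_equal(length(unique(ini$cluster[eg == g])), 1)
  expect_length(ini$flagged, 0)
  # a state without reference samples is placed (via its founders'
  # homozygote centers) in the same cluster as its genotype group, flagged
  drop <- ref_state != 36
  ini2 <- init_clusters(ref_theta[drop], ref_rho[drop], ref_state[drop],
                        coh_theta, coh_rho, st)
  expect_true(36 %in% ini2$flagged)
  other_B <- setdiff(which(eg == "B"), 36)
  expect_equal(unique(ini2$cluster[other_B]), ini2$cluster[36])
})
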