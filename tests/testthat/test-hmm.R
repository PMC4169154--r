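# The diplotype HMM: emissions, forward-backward against exhaustive path
# enumeration, EM behavior, and marginal reconstruction.

test_that("genotype emissions are normalized and hit the 0.97 initialization", {
  w <- fx_world()
  emis <- genotype_emission_init(w$fg, w$states)
  expect_equal(apply(emis, c(1, 2), sum),
               matrix(1, nrow(w$map), 36), ignore_attr = TRUE)
  eg <- expected_genotype(w$fg[1, ], w$states)
  obs <- match(eg[5], c("A", "H", "B", "N"))
  E <- mosaicqtl:::emission_lik_calls(rep(obs, nrow(w$map)), emis)
  expect_equal(log(E[1, 5]), log(0.97))
})

test_that("forward-backward equals exhaustive path enumeration (<= 6 states)", {
  st3 <- diplotype_states(founder_panel(LETTERS[1:3]))
  S <- nrow(st3$pairs)
  prior <- diplotype_equilibrium(st3)
  set.seed(71)
  for (rep in 1:5) {
    m <- sample(2:4, 1)
    E <- matrix(runif(m * S, 0.05, 1), m, S)
    trans <- lapply(seq_len(m - 1),
                    function(j) diplotype_transition(runif(1, 0.01, 0.2), 3, st3))
    fb <- forward_backward(E, trans, prior)
    # enumerate all S^m paths
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
    wts <- apply(paths, 1, function(pp) {
      v <- prior[pp[1]] * E[1, pp[1]]
      if (m > 1) for (j in 2:m)
        v <- v * trans[[j - 1]][pp[j - 1], pp[j]] * E[j, pp[j]]
      v
    })
    post <- matrix(0, m, S)
    for (j in seq_len(m)) for (s in seq_len(S))
      post[j, s] <- sum(wts[paths[, j] == s])
    post <- post / rowSums(post)
    expect_lt(max(abs(fb$post - post)), 1e-10)
    expect_lt(abs(fb$loglik - log(sum(wts))), 1e-10)
    expect_equal(rowSums(fb$post), rep(1, m), tolerance = 1e-12)
  }
})

test_that("forward-backward degenerate chains behave as linked/unlinked limits", {
  st3 <- diplotype_states(founder_panel(LETTERS[1:3]))
  S <- nrow(st3$pairs)
  prior <- rep(1 / S, S)
  set.seed(72)
  E1 <- matrix(runif(S, 0.1, 1), 1, S)
  fb1 <- forward_backward(E1, list(), prior)
  expect_equal(as.vector(fb1$post), as.vector(E1 / sum(E1)), tolerance = 1e-12)
  # identity transitions: posterior at each marker ~ product of all emissions
  E3 <- matrix(runif(3 * S, 0.1, 1), 3, S)
  trans_id <- list(diag(S), diag(S))
  fb3 <- forward_backward(E3, trans_id, prior)
  prod_e <- apply(E3, 2, prod)
  for (j in 1:3)
    expect_equal(fb3$post[j, ], prod_e / sum(prod_e), tolerance = 1e-12)
})

test_that("EM is a fixed point on exact data, monotone, and recovers parameters", {
  st <- fx_states()
  map <- sim_marker_map(40, chromosomes = 1:2)
  pop <- sim_do_population(map, n_ind = 60, gen = 8, seed = 73)
  truth <- true_diplotypes(pop, map, st)
  cl <- separable_clusters(map, st, sd_theta = 0.02, sd_rho = 0.04)
  ints <- sim_intensities(truth$state, cl, seed = 74)

  fit <- suppressWarnings(
    fit_diplotypes(intensities = ints, map = map, gen = 8, states = st,
                   init = cl, max_iter = 12))
  # log-likelihood non-decreasing
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik_trace[1])))
  # posterior normalization
  expect_equal(apply(fit$probs, c(1, 2), sum),
               matrix(1, 60, nrow(map)), tolerance = 1e-8, ignore_attr = TRUE)
  # data generated at the initial parameters: convergence is quick and the
  # fitted means stay near the generating centers for well-populated states
  expect_lte(fit$iterations, 12)
  cnt <- table(factor(truth$state, levels = 1:36))
  for (s in which(cnt >= 20 * 2)) {
    jset <- which(colSums(truth$state == s) >= 3)
    if (!length(jset)) next
    j <- jset[1]
    nmem <- sum(truth$state[, j] == s)
    se <- 0.02 / sqrt(nmem)
    expect_lt(abs(fit$emission$mu_theta[j, s] - cl$mu_theta[j, s]),
              3 * se + 0.01)
  }

  # genotype-model EM on calls is also monotone
  fg <- sim_founder_geno(map, seed = 75)
  calls <- sim_genotype_calls(truth$state, fg, st, seed = 76)
  fitc <- suppressWarnings(
    fit_diplotypes(calls = calls, map = map, gen = 8, states = st,
                   founder_geno = fg, max_iter = 6))
  expect_true(all(diff(fitc$loglik_trace) > -1e-6 * abs(fitc$loglik_trace[1])))
  expect_error(fit_diplotypes(calls = calls, intensities = ints, map = map,
                              gen = 8, states = st), "exactly one")
})

test_that("marginal reconstruction takes the argmax with flagged low-index ties", {
  st <- fx_states()
  p <- array(0, c(2, 3, 36))
  p[1, , 5] <- 1                       # one-hot
  p[2, 1, c(2, 7)] <- 0.5              # exact tie
  p[2, 2, 9] <- 0.6; p[2, 2, 1] <- 0.4
  p[2, 3, 36] <- 1
  mr <- marginal_reconstruction(p)
  expect_equal(mr[1, ], c(5L, 5L, 5L), ignore_attr = TRUE)
  expect_equal(mr[2, ], c(2L, 9L, 36L), ignore_attr = TRUE)
  expect_true(attr(mr, "ties")[2, 1])
  expect_false(any(attr(mr, "ties")[1, ]))
})

test_that("well-separated intensities reconstruct >= 95% of true diplotypes", {
  w <- fx_world()
  cl <- separable_clusters(w$map, w$states)
  ints <- sim_intensities(w$truth$state, cl, seed = 77)
  fit <- suppressWarnings(
    fit_diplotypes(intensities = ints, map = w$map, gen = 8, states = w$states,
                   init = cl, max_iter = 15))
  mr <- marginal_reconstruction(fit)
  expect_gte(mean(mr == w$truth$state), 0.95)
  fx_cache$recon_fit <- fit   # reused by downstream tests
})

test_that("replicate call draws of the same DNA give concordant dosages", {
  w <- fx_world()
  st <- w$states
  calls1 <- sim_genotype_calls(w$truth$state, w$fg, st, seed = 78)
  calls2 <- sim_genotype_calls(w$truth$state, w$fg, st, seed = 79)
  f1 <- suppressWarnings(fit_diplotypes(calls = calls1, map = w$map, gen = 8,
                                        states = st, founder_geno = w$fg,
                                        max_iter = 3))
  f2 <- suppressWarnings(fit_diplotypes(calls = calls2, map = w$map, gen = 8,
                                        states = st, founder_geno = w$fg,
                                        max_iter = 3))
  d1 <- founder_dosage(f1, st); d2 <- founder_dosage(f2, st)
  expect_gt(cor(as.vector(d1), as.vector(d2)), 0.9)
})
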