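# Breeding simulator and array/phenotype generators.

test_that("mosaics tile chromosomes and simulation is seed-reproducible", {
  map <- sim_marker_map(60, chromosomes = 1:3)
  pop <- sim_do_population(map, n_ind = 30, gen = 6, seed = 21)
  for (i in seq_along(pop$individuals)) {
    for (cc in seq_along(pop$chr)) {
      for (h in c("h1", "h2")) {
        hp <- pop$individuals[[i]][[cc]][[h]]
        expect_true(all(diff(c(0, hp$ends)) > 0))
        expect_equal(hp$ends[length(hp$ends)], unname(pop$L[cc]))
        if (length(hp$founder) > 1)
          expect_true(all(diff(hp$founder) != 0))
        expect_true(all(hp$founder %in% 1:8))
      }
    }
  }
  pop2 <- sim_do_population(map, n_ind = 30, gen = 6, seed = 21)
  expect_identical(pop, pop2)
  expect_error(sim_do_population(map[0, ], 10, gen = 2), "empty")
})

test_that("F1-style seeding (G=1, pure haplotypes) is fully heterozygous", {
  map <- sim_marker_map(40, chromosomes = 1:2)
  pop <- sim_do_population(map, n_ind = 20, gen = 1, g1_density = 0, seed = 22)
  tr <- true_diplotypes(pop, map, fx_states())
  expect_true(all(tr$h1 != tr$h2))
  expect_true(all(true_breakpoints(pop) == 0))
})

test_that("founder shares average near 1/8 and breakpoints grow linearly in G", {
  map <- sim_marker_map(60, chromosomes = 1:6)
  pop <- sim_do_population(map, n_ind = 200, gen = 6, seed = 23)
  sh <- founder_shares(pop)
  expect_equal(rowSums(sh), rep(1, 200), tolerance = 1e-12)
  expect_true(max(abs(colMeans(sh) - 0.125)) < 0.02)

  gens <- 4:12
  bl <- vapply(gens, function(g)
    mean(true_breakpoints(sim_do_population(map, n_ind = 40, gen = g,
                                            seed = 100 + g))), 0)
  fitl <- stats::lm(bl ~ gens)
  expect_gt(stats::coef(fitl)[2], 0)
  expect_gt(summary(fitl)$r.squared, 0.99)
})

test_that("diplotype frequencies match a brute-force tabulation oracle", {
  st <- fx_states()
  w <- fx_world()
  fr <- diplotype_freq(w$truth$state, st)
  expect_equal(sum(fr), 1)
  oracle <- table(factor(as.vector(w$truth$state), levels = 1:36))
  expect_equal(unname(fr), as.vector(oracle / sum(oracle)))
  # single individual, constant AA
  fr1 <- diplotype_freq(matrix(1L, 1, 10), st)
  expect_equal(unname(fr1["AA"]), 1)
  expect_true(all(fr1[-1] == 0))
})

test_that("genotype calls follow the state multinomial, N informative", {
  st <- fx_states()
  map1 <- sim_marker_map(30, chromosomes = 1)
  fg <- sim_founder_geno(map1, seed = 31)
  state <- matrix(rep(1:30, each = 10), 10, 30)  # spread over states
  # zero noise: calls equal the expected genotype of the true state
  clean <- sim_genotype_calls(state, fg, st,
                              array_noise(call_error = 0, nocall = 0), seed = 32)
  for (j in c(1, 15, 30)) {
    eg <- expected_genotype(fg[j, ], st)
    expect_equal(unname(clean[, j]), unname(eg[state[, j]]))
  }
  # state-dependent no-call rates (CAST-homozygote-style dropout)
  noise <- array_noise(call_error = 0, nocall = 0.01,
                       nocall_state = c(FF = 0.9))
  stateFF <- matrix(6L, 200, 30)   # FF everywhere
  stateBB <- matrix(2L, 200, 30)   # BB everywhere
  nFF <- mean(sim_genotype_calls(stateFF, fg, st, noise, seed = 33) == "N")
  nBB <- mean(sim_genotype_calls(stateBB, fg, st, noise, seed = 34) == "N")
  expect_lt(abs(nFF - 0.9), 3 * sqrt(0.9 * 0.1 / 6000))
  expect_lt(abs(nBB - 0.01), 3 * sqrt(0.01 * 0.99 / 6000))

  # empirical frequencies match the configured multinomial (chi-square)
  noise2 <- array_noise(call_error = 0.06, nocall = 0.04)
  big <- sim_genotype_calls(matrix(9L, 10000, 1), fg[1, , drop = FALSE], st,
                            noise2, seed = 35)
  p <- mosaicqtl:::call_distribution(fg[1, ], st, noise2)[9, ]
  obs <- table(factor(big, levels = c("A", "H", "B", "N")))
  chi <- sum((obs - 10000 * p)^2 / (10000 * p))
  expect_lt(chi, qchisq(0.999, 3))
})

test_that("intensities reproduce cluster geometry and moments", {
  st <- fx_states()
  map1 <- sim_marker_map(10, chromosomes = 1)
  fg <- sim_founder_geno(map1, seed = 41)
  noise0 <- array_noise(theta_sd = 0, rho_sd = 0, nonconforming = 0)
  cl <- sim_intensity_clusters(fg, st, noise0, seed = 42)
  state <- matrix(sample.int(36, 50 * 10, TRUE), 50, 10)
  ints <- sim_intensities(state, cl, seed = 43)
  pol <- polar_transform(ints)
  for (j in 1:10) {  # zero variance: samples sit exactly on centers
    expect_equal(pol$theta[, j], unname(cl$mu_theta[j, state[, j]]),
                 tolerance = 1e-9)
    expect_equal(pol$rho[, j], unname(cl$mu_rho[j, state[, j]]),
                 tolerance = 1e-9)
  }
  # conforming marker: exactly 3 distinct centers; many states share one
  expect_equal(length(unique(round(cl$mu_theta[1, ], 6))), 3)

  # nonconforming markers collapse the 36 states onto more than 3 centers,
  # still far fewer than 36 (many states share a center)
  noise6 <- array_noise(theta_sd = 0, rho_sd = 0, nonconforming = 1)
  cl6 <- sim_intensity_clusters(fg, st, noise6, seed = 44)
  ncl <- vapply(1:10, function(j) length(unique(round(cl6$mu_theta[j, ], 6))), 0)
  expect_true(all(ncl > 3 & ncl <= 10))

  # moment recovery at n = 1000 within 3 SE
  noise <- array_noise(theta_sd = 0.05, rho_sd = 0.1, nonconforming = 0)
  cl2 <- sim_intensity_clusters(fg, st, noise, seed = 45)
  stt <- matrix(7L, 1000, 10)
  ii <- sim_intensities(stt, cl2, seed = 46)
  pol <- polar_transform(ii)
  for (j in c(2, 8)) {
    expect_lt(abs(mean(pol$theta[, j]) - cl2$mu_theta[j, 7]),
              3 * 0.05 / sqrt(1000) + 1e-6)
    expect_lt(abs(sd(pol$rho[, j]) - 0.1), 3 * 0.1 / sqrt(2 * 999))
  }
})

test_that("simulated phenotypes decompose as QTL + polygenic + error", {
  st <- fx_states()
  # effect 0, kinship identity: iid normal with variance 2
  s0 <- hwe_states(4000, st, seed = 51)
  ph0 <- sim_phenotype(s0, c(1, 2), 0, st, kinship = diag(4000), seed = 52)
  expect_lt(abs(var(ph0$y) - 2), 0.15)
  expect_true(all(ph0$qtl_term == 0))

  # realized QTL variance ~ 2 p (1-p) a^2 at n = 10000 (HWE oracle)
  a <- 0.8; maf <- 2; p <- maf / 8
  s1 <- hwe_states(10000, st, seed = 53)
  ph1 <- sim_phenotype(s1, c(3, 5), a, st, seed = 54)
  expect_lt(abs(var(ph1$qtl_term) - 2 * p * (1 - p) * a^2), 0.02)
  # +a on the major homozygote, -a on the minor, 0 on heterozygotes
  expect_equal(sort(unique(ph1$qtl_term)), c(-a, 0, a))
  expect_error(sim_phenotype(s1, c(3, 5), -1, st), "effect")
})
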