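# Mixed-model machinery and genome scans: OLS equivalence, nesting, affine
# invariance, founder effects, heritability recovery.

test_that("with K proportional to I the mixed model reduces to OLS", {
  sw <- fx_scan_world()
  n <- length(sw$y)
  sc <- qtl_scan(sw$y, sw$d, sw$w$map, kinship = diag(n) * 0.7,
                 model = "haplotype")
  # OLS oracle via lm()
  for (j in c(3, 20, 47)) {
    X <- sw$d[, j, 1:7]
    f1 <- lm(sw$y ~ X)
    f0 <- lm(sw$y ~ 1)
    lod <- n / 2 * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
    expect_equal(sc$lod[j], lod, tolerance = 1e-6)
  }
  # and matches a kinship-free scan
  sc0 <- qtl_scan(sw$y, sw$d, sw$w$map, kinship = NULL, model = "haplotype")
  expect_equal(sc$lod, sc0$lod, tolerance = 1e-6)
})

test_that("LOD is invariant to affine phenotype transforms", {
  sw <- fx_scan_world()
  sc1 <- qtl_scan(sw$y, sw$d, sw$w$map, kinship = sw$K, model = "haplotype")
  sc2 <- qtl_scan(3 * sw$y + 7, sw$d, sw$w$map, kinship = sw$K,
                  model = "haplotype")
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-6)
})

test_that("full-model LOD dominates the nested additive model", {
  sw <- fx_scan_world()
  sch <- qtl_scan(sw$y, sw$d, sw$w$map, kinship = sw$K, model = "haplotype")
  scf <- qtl_scan(sw$y, mosaicqtl:::state_probs(sw$w$truth$state, sw$w$states),
                  sw$w$map, kinship = sw$K, model = "full")
  expect_true(all(scf$lod >= sch$lod - 1e-6))
  expect_equal(attr(sch, "df"), 7)
  expect_equal(attr(scf, "df"), 35)
  # peak is at/near the planted locus for the additive scan
  expect_equal(max_scan(sch)$chr, sw$w$map$chr[sw$jq])
})

test_that("null phenotypes give baseline LOD levels and constant loci give 0", {
  sw <- fx_scan_world()
  set.seed(103)
  n <- length(sw$y)
  y0 <- rnorm(n)
  sc <- qtl_scan(y0, sw$d, sw$w$map, kinship = sw$K, model = "haplotype")
  # exact null: R^2 ~ Beta(7/2, (n-8)/2), LOD = -(n/2) log10(1 - R^2)
  med_exact <- -(n / 2) * log10(1 - qbeta(0.5, 7 / 2, (n - 8) / 2))
  expect_lt(median(sc$lod), 1.35 * med_exact)
  expect_gt(median(sc$lod), 0.65 * med_exact)
  d2 <- sw$d
  d2[, 5, ] <- rep(c(2, rep(0, 7)), each = nrow(d2))  # constant AA locus
  sc2 <- qtl_scan(y0, d2, sw$w$map, kinship = sw$K, model = "haplotype")
  expect_equal(sc2$lod[5], 0)
})

test_that("founder effects are centered, idempotent and split with the truth", {
  sw <- fx_scan_world()
  st <- sw$w$states
  minor <- c(2, 5)
  ph <- sim_phenotype(sw$w$truth$state[, sw$jq], minor, 1.5, st, seed = 104)
  sc <- qtl_scan(ph$y, sw$d, sw$w$map, kinship = sw$K, model = "haplotype")
  eff <- founder_effects(sc, sw$w$map$marker[sw$jq])
  expect_equal(mean(eff), 0, tolerance = 1e-12)
  # minor-allele founders carry -effect: their coefficients sit below the rest
  expect_lt(max(eff[minor]), min(eff[-minor]))
  # centering is idempotent
  expect_equal(eff - mean(eff), eff)
  expect_error(founder_effects(sc, "nope"), "unknown locus")
})

test_that("variance components recover simulated heritability", {
  pool <- fx_pool()
  set.seed(105)
  errs <- replicate(15, {
    idx <- sample.int(nrow(pool$K), 400)
    K <- pool$K[idx, idx]
    ed <- eigen(K, symmetric = TRUE)
    g <- as.vector(ed$vectors %*% (sqrt(pmax(ed$values, 0)) * rnorm(400)))
    y <- g + rnorm(400)           # h2 = 0.5
    fit_polygenic(y, K, eigen_K = ed)$h2 - 0.5
  })
  expect_lt(mean(abs(errs)), 0.1)

  # pure-noise phenotype with K = I structure: h2 ~ 0
  set.seed(106)
  expect_lt(fit_polygenic(rnorm(300), diag(300))$h2, 0.1)
  # pure polygenic signal: h2 -> 1
  idx <- seq_len(500)
  K <- fx_pool()$K[idx, idx]
  ed <- eigen(K, symmetric = TRUE)
  g <- as.vector(ed$vectors %*% (sqrt(pmax(ed$values, 0)) * rnorm(500)))
  fit1 <- fit_polygenic(g + 0.01 * rnorm(500), K, eigen_K = ed)
  expect_gt(fit1$h2, 0.9)
  expect_equal(heritability(fit1), fit1$h2)
})

test_that("covariates: aliasing is dropped and missing phenotypes excluded", {
  sw <- fx_scan_world()
  cv <- data.frame(a = rep(c(0, 1), length.out = length(sw$y)))
  cv$b <- cv$a * 2   # aliased
  expect_warning(fit_polygenic(sw$y, sw$K, covar = cv), "aliased")
  y2 <- sw$y; y2[3] <- NA
  expect_message(f <- fit_polygenic(y2, sw$K), "dropping 1 samples")
  expect_equal(f$n, length(sw$y) - 1)
})
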