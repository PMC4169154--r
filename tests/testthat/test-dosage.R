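# Founder dosages (d = sum_s p N), SNP imputation (g = sum_h d G) and SDP
# collapsing.

test_that("dosages follow the hand-computed weighted founder counts", {
  st <- fx_states()
  p <- array(0, c(1, 3, 36))
  p[1, 1, match("CC", st$labels)] <- 1
  p[1, 2, match("BC", st$labels)] <- 1
  p[1, 3, match("AA", st$labels)] <- 0.5
  p[1, 3, match("AB", st$labels)] <- 0.5
  d <- founder_dosage(p, st)
  expect_equal(d[1, 1, ], c(A = 0, B = 0, C = 2, D = 0, E = 0, F = 0, G = 0, H = 0))
  expect_equal(unname(d[1, 2, c("B", "C")]), c(1, 1))
  expect_equal(unname(d[1, 3, c("A", "B")]), c(1.5, 0.5))
  expect_equal(apply(d, c(1, 2), sum), matrix(2, 1, 3), ignore_attr = TRUE)

  # random posteriors: sum over founders is always 2
  set.seed(91)
  pr <- array(rexp(5 * 4 * 36), c(5, 4, 36))
  pr <- pr / rep(apply(pr, c(1, 2), sum), 36)
  dr <- founder_dosage(pr, st)
  expect_equal(apply(dr, c(1, 2), sum), matrix(2, 5, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("interval averaging takes flanking means with nearest-end fallback", {
  st <- fx_states()
  map <- marker_map(data.frame(marker = c("a", "b"), chr = "1",
                               bp = c(100, 300), cM = c(0.1, 0.3)))
  p <- array(0, c(1, 2, 36))
  p[1, 1, 1:2] <- c(0.2, 0.8)
  p[1, 2, 1:2] <- c(0.6, 0.4)
  expect_equal(interval_average(p, map, "1", 200)[1, 1:2], c(0.4, 0.6))
  expect_equal(interval_average(p, map, "1", 100)[1, ], p[1, 1, ])  # at marker
  expect_equal(interval_average(p, map, "1", 50)[1, ], p[1, 1, ])   # before 1st
  expect_equal(interval_average(p, map, "1", 999)[1, ], p[1, 2, ])  # after last
  expect_error(interval_average(p, map, "7", 200), "not in the marker map")
})

test_that("SNP dosages implement g = sum_h d(h) G(h) with SDP collapsing", {
  st <- fx_states()
  map <- marker_map(data.frame(marker = c("a", "b"), chr = "1",
                               bp = c(100, 1000), cM = c(0.1, 1)))
  # deterministic dosages: sample1 = AA, sample2 = AB at both markers
  state <- rbind(rep(match("AA", st$labels), 2), rep(match("AB", st$labels), 2))
  d <- dosage_from_states(state, st)
  snps <- data.frame(snp = c("s1", "s2", "s3"), chr = "1",
                     bp = c(200, 400, 600))
  alleles <- rbind(rep(1, 8),                    # all founders reference
                   c(1, 0, 0, 0, 0, 0, 0, 0),   # only A reference
                   c(1, 0, 0, 0, 0, 0, 0, 0))   # identical SDP -> same group
  colnames(alleles) <- LETTERS[1:8]
  snps <- cbind(snps, alleles)
  sd_ <- impute_snp_dosage(d, snps, map)
  g <- sd_$g[, sd_$snps$group]
  expect_equal(unname(g[, 1]), c(2, 2))          # monomorphic reference
  expect_true(sd_$monomorphic[sd_$snps$group[1]])
  expect_equal(unname(g[, 2]), c(2, 1))          # d_A = 2 vs 1
  expect_equal(unname(g[, 2]), unname(g[, 3]))   # same SDP group
  expect_equal(max(sd_$snps$group), 2)
})

test_that("SDP group counts equal the brute-force distinct-pattern oracle", {
  w <- fx_world()
  set.seed(92)
  snps <- sim_founder_snps(w$map, per_interval = 3, seed = 93)
  grp <- collapse_sdp(snps, w$map)
  sdp <- snp_sdp(snps)
  iv <- integer(nrow(snps))
  for (cc in unique(snps$chr)) {
    j <- which(w$map$chr == cc); ww <- which(snps$chr == cc)
    iv[ww] <- findInterval(snps$bp[ww], w$map$bp[j])
  }
  oracle <- length(unique(paste(snps$chr, iv, sdp)))
  expect_equal(max(grp), oracle)
  # all-identical patterns in one interval collapse to one group
  one <- snps[1:3, ]
  one[, LETTERS[1:8]] <- matrix(rep(c(1, 0, 1, 0, 1, 0, 1, 0), each = 3), 3)
  one$bp <- w$map$bp[1] + c(1, 2, 3)
  expect_equal(max(collapse_sdp(one, w$map)), 1)
})

test_that("marginal-genome imputation agrees with rounded probabilistic imputation", {
  w <- fx_world()
  sub <- w$truth$state[1:20, ]
  ph <- phase_reconstruction(sub, w$map, w$states)
  snps <- sim_founder_snps(w$map, per_interval = 1, seed = 94)
  img <- impute_marginal_genome(ph, snps)
  expect_true(all(img$g %in% 0:2))
  d <- dosage_from_states(sub, w$states)
  sd_ <- impute_snp_dosage(d, snps, w$map)
  gprob <- sd_$g[, sd_$snps$group]
  # where the flanking markers carry the same state the posterior at the SNP
  # is exactly one-hot, and rounded probabilistic imputation must equal the
  # marginal-genome route; junction-straddling SNPs are legitimately ambiguous
  flank_same <- matrix(TRUE, nrow(sub), nrow(snps))
  for (s in seq_len(nrow(snps))) {
    j <- which(w$map$chr == snps$chr[s])
    iv <- findInterval(snps$bp[s], w$map$bp[j])
    if (iv >= 1 && iv < length(j))
      flank_same[, s] <- sub[, j[iv]] == sub[, j[iv + 1]]
  }
  expect_true(all((round(gprob) == img$g)[flank_same]))
  expect_gt(mean(round(gprob) == img$g), 0.8)
  # homozygous region doubles the founder allele; heterozygous gives one each
  al <- as.matrix(snps[, LETTERS[1:8]])
  i_hom <- which(ph$h1[, 1] == ph$h2[, 1])[1]
  s1 <- which(snps$chr == w$map$chr[1] & snps$bp > w$map$bp[1] &
                snps$bp < w$map$bp[2])[1]
  if (!is.na(i_hom) && !is.na(s1))
    expect_equal(img$g[i_hom, s1], unname(2L * al[s1, ph$h1[i_hom, 1]]))
})

test_that("SDP collapsing leaves scan statistics unchanged", {
  w <- fx_world()
  set.seed(95)
  sub <- w$truth$state[1:80, ]
  d <- dosage_from_states(sub, w$states)
  snps <- sim_founder_snps(w$map, per_interval = 2, seed = 96)
  y <- rnorm(80) + d[, 10, 2]
  sd_c <- impute_snp_dosage(d, snps, w$map, collapse = TRUE)
  sd_u <- impute_snp_dosage(d, snps, w$map, collapse = FALSE)
  sc_c <- qtl_scan(y, sd_c, model = "snp")
  sc_u <- qtl_scan(y, sd_u, model = "snp")
  expect_equal(sc_c$lod, sc_u$lod, tolerance = 1e-9)
})
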