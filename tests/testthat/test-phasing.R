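# Phasing by minimum strand switches and recombination counting.

test_that("constant and single-junction sequences phase trivially", {
  st <- fx_states()
  iAB <- match("AB", st$labels); iAC <- match("AC", st$labels)
  ph <- mosaicqtl:::phase_chromosome(rep(iAB, 6), st$pairs)
  expect_equal(ph$h1, rep(1L, 6))
  expect_equal(ph$h2, rep(2L, 6))
  # AB -> AC: single event on the B/C strand, A strand intact
  ph2 <- mosaicqtl:::phase_chromosome(c(iAB, iAB, iAC, iAC), st$pairs)
  expect_equal(ph2$h1, rep(1L, 4))
  expect_equal(ph2$h2, c(2L, 2L, 3L, 3L))
})

test_that("phasing attains the exhaustive minimum switch count", {
  st <- fx_states()
  set.seed(81)
  for (rep in 1:15) {
    stseq <- sample.int(36, 10, replace = TRUE)
    ph <- mosaicqtl:::phase_chromosome(stseq, st$pairs)
    got <- sum(diff(ph$h1) != 0) + sum(diff(ph$h2) != 0)
    # brute force over all 2^10 orientation choices
    a <- st$pairs[stseq, 1]; b <- st$pairs[stseq, 2]
    best <- Inf
    for (mask in 0:(2^10 - 1)) {
      o <- bitwAnd(bitwShiftR(mask, 0:9), 1L) == 1L
      h1 <- ifelse(o, b, a); h2 <- ifelse(o, a, b)
      best <- min(best, sum(diff(h1) != 0) + sum(diff(h2) != 0))
    }
    expect_equal(got, best)
  }
})

test_that("phased reconstructions preserve states and place bp midpoints", {
  w <- fx_world()
  sub <- w$truth$state[1:25, ]
  ph <- phase_reconstruction(sub, w$map, w$states)
  # unordered pair at each marker equals the input state
  smat <- matrix(0L, 8, 8)
  smat[w$states$pairs] <- seq_len(36)
  smat[w$states$pairs[, c(2, 1)]] <- seq_len(36)
  re <- matrix(smat[cbind(as.vector(ph$h1), as.vector(ph$h2))], 25)
  expect_equal(re, unname(sub))
  # breakpoints strictly inside the chromosome span, at marker midpoints
  if (nrow(ph$breakpoints)) {
    for (cc in unique(ph$breakpoints$chr)) {
      bpj <- ph$breakpoints$bp[ph$breakpoints$chr == cc]
      rng <- range(w$map$bp[w$map$chr == cc])
      expect_true(all(bpj > rng[1] & bpj < rng[2]))
      mids <- (w$map$bp[w$map$chr == cc][-1] +
                 head(w$map$bp[w$map$chr == cc], -1)) / 2
      expect_true(all(bpj %in% mids))
    }
  }
  expect_true(all(count_recombinations(ph, c("1", "2")) >= 0))
  # no switches -> 0
  const <- matrix(match("AB", w$states$labels), 2, ncol(sub))
  ph0 <- phase_reconstruction(const, w$map, w$states)
  expect_equal(count_recombinations(ph0, c("1", "2")), c(0L, 0L))
})

test_that("event counts undercount truth and increase with marker density", {
  w <- fx_world()
  # visible-truth oracle: strand switches of the true phase at marker scale
  truth_visible <- function(j) {
    rowSums(w$truth$h1[, j[-1], drop = FALSE] !=
              w$truth$h1[, j[-length(j)], drop = FALSE]) +
      rowSums(w$truth$h2[, j[-1], drop = FALSE] !=
                w$truth$h2[, j[-length(j)], drop = FALSE])
  }
  dens <- list(seq(1, ncol(w$truth$state), by = 4),
               seq(1, ncol(w$truth$state), by = 2),
               seq_len(ncol(w$truth$state)))
  counts <- lapply(dens, function(j) {
    ph <- phase_reconstruction(w$truth$state[, j, drop = FALSE],
                               w$map[j, ], w$states)
    count_recombinations(ph, c("1", "2"))
  })
  # parsimony never exceeds the visible truth, which never exceeds the truth
  full_truth <- true_breakpoints(w$pop)
  expect_true(all(counts[[3]] <= truth_visible(dens[[3]])))
  expect_true(all(truth_visible(dens[[3]]) <= full_truth))
  # nested marker sets: minimum switch count is monotone in density
  expect_true(all(counts[[1]] <= counts[[2]]))
  expect_true(all(counts[[2]] <= counts[[3]]))
})
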