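# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code under fixed seeds; nothing is read from disk.

fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fx_cache[[name]])) fx_cache[[name]] <- builder()
  fx_cache[[name]]
}

fx_states <- function() fx("states", function() diplotype_states())

# small dense two-chromosome world for HMM-level tests
fx_world <- function() fx("world", function() {
  map <- sim_marker_map(80, chromosomes = 1:2)
  states <- fx_states()
  pop <- sim_do_population(map, n_ind = 150, gen = 8, seed = 11)
  truth <- true_diplotypes(pop, map, states)
  fg <- sim_founder_geno(map, seed = 12)
  list(map = map, states = states, pop = pop, truth = truth, fg = fg)
})

# cluster layout in which all 36 diplotype states are separable:
# theta encodes the founder-pair mean level, rho the within-pair contrast
separable_clusters <- function(map, states, sd_theta = 0.01, sd_rho = 0.02) {
  lev <- seq(0.05, 0.95, length.out = length(states$founders))
  a <- states$pairs[, 1]; b <- states$pairs[, 2]
  m <- nrow(map); s <- nrow(states$pairs)
  list(mu_theta = matrix(rep((lev[a] + lev[b]) / 2, each = m), m, s),
       mu_rho = matrix(rep(1 + 0.5 * abs(lev[a] - lev[b]), each = m), m, s),
       sd_theta = sd_theta, sd_rho = sd_rho)
}

# the acceptance-scale genome pool (shared by acceptance and a few unit
# tests); seed fixed once for the whole stated world
fx_pool <- function() fx("pool", function() power_pool(n_pool = 1129, seed = 1))

# dense-world dosage/kinship/phenotype bundle for scan-level tests
fx_scan_world <- function() fx("scan_world", function() {
  w <- fx_world()
  set.seed(101)
  st <- w$states
  d <- dosage_from_states(w$truth$state, st)
  K <- calc_kinship(d)
  jq <- 20
  ph <- sim_phenotype(w$truth$state[, jq], c(2, 5), 0.8, st, kinship = K,
                      seed = 102)
  list(w = w, d = d, K = K, jq = jq, y = ph$y)
})

# HWE draw of diplotype states given per-founder haplotype frequency 1/F
hwe_states <- function(n, states, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- length(states$founders)
  smat <- matrix(0L, f, f)
  smat[states$pairs] <- seq_along(states$labels)
  smat[states$pairs[, c(2, 1)]] <- seq_along(states$labels)
  h1 <- sample.int(f, n, replace = TRUE)
  h2 <- sample.int(f, n, replace = TRUE)
  smat[cbind(h1, h2)]
}
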