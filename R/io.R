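# CSV readers/writers for the package's tabular interfaces (locale-fixed:
# period decimals, UTF-8, LF) and the end-to-end demonstration pipeline.

#' Read / write genotype call matrices
#'
#' CSV schema: first column \code{sample}, then one column per marker with
#' values in A/H/B/N. Unknown symbols are rejected with the offending
#' row/column named.
#'
#' @param path File path.
#' @param calls n x M character matrix (markers as column names).
#' @return \code{read_calls}: the character matrix with sample rownames.
#' @export
read_calls <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "sample") stop("first column must be 'sample'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  bad <- which(matrix(!(m %in% CALL_SYMBOLS), nrow(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid call symbol '", m[bad[1, 1], bad[1, 2]], "' at row ",
         bad[1, 1], " (sample ", df$sample[bad[1, 1]], "), column '",
         colnames(m)[bad[1, 2]], "'")
  }
  m
}

#' @rdname read_calls
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(sample = rownames(calls) %||% seq_len(nrow(calls)),
                   calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write two-channel intensities
#'
#' Two CSVs (X and Y channels), same schema as \code{\link{read_calls}} with
#' numeric entries.
#'
#' @param x_path,y_path Channel file paths.
#' @param intensities An \code{intensity_data} list (X, Y).
#' @return \code{read_intensities}: \code{intensity_data} list.
#' @export
read_intensities <- function(x_path, y_path) {
  rd <- function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(!is.finite(m)) || any(m < 0))
      stop("intensities must be finite and non-negative: ", p)
    m
  }
  x <- rd(x_path); y <- rd(y_path)
  if (!identical(dim(x), dim(y))) stop("X and Y intensity shapes differ")
  structure(list(X = x, Y = y), class = "intensity_data")
}

#' @rdname read_intensities
#' @export
write_intensities <- function(intensities, x_path, y_path) {
  wr <- function(m, p) {
    df <- data.frame(sample = rownames(m) %||% seq_len(nrow(m)), m,
                     check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  }
  wr(intensities$X, x_path); wr(intensities$Y, y_path)
}

#' Read a phenotype/covariate table
#'
#' CSV with columns \code{sample}, \code{phenotype}, and any number of
#' covariate columns.
#'
#' @param path File path.
#' @return data.frame with \code{sample} as character.
#' @export
read_pheno <- function(path) {
  df <- utils::read.csv(path, colClasses = c(sample = "character"))
  if (!all(c("sample", "phenotype") %in% names(df)))
    stop("phenotype table needs 'sample' and 'phenotype' columns")
  df
}

#' Read / write a founder SNP table
#'
#' CSV schema: \code{snp}, \code{chr}, \code{bp}, then one 0/1 column per
#' founder.
#'
#' @param path File path.
#' @param panel A \code{\link{founder_panel}}.
#' @param snps The table to write.
#' @return \code{read_founder_snps}: \code{founder_snps} data.frame.
#' @export
read_founder_snps <- function(path, panel = founder_panel()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(chr = "character"))
  need <- c("snp", "chr", "bp", unclass(panel))
  if (!all(need %in% names(df)))
    stop("founder SNP table needs columns: ", paste(need, collapse = ", "))
  al <- as.matrix(df[, unclass(panel)])
  if (!all(al %in% c(0, 1))) stop("founder alleles must be 0/1")
  class(df) <- c("founder_snps", "data.frame")
  df
}

#' @rdname read_founder_snps
#' @export
write_founder_snps <- function(snps, path) {
  utils::write.csv(as.data.frame(snps), path, row.names = FALSE, quote = FALSE)
}

#' Write a genome scan result
#'
#' @param scan A \code{\link{qtl_scan}}.
#' @param path Output CSV path.
#' @export
write_scan <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE, quote = FALSE)
}

#' End-to-end demonstration pipeline on synthetic data
#'
#' Emulates the full mapping workflow on a simulated cohort: breed a DO-style
#' population, generate genotype calls, reconstruct diplotypes with the HMM,
#' compute dosages and LOCO kinship, simulate a phenotype with sex/batch
#' covariates and one planted additive QTL, scan under all three regression
#' models, compute a permutation threshold (haplotype model), centered
#' founder effects at the peak, and the 95\% credible support interval.
#'
#' @param seed Integer seed (echoed in the output; drives every stage).
#' @param n Cohort size (default 250).
#' @param n_markers Markers genome-wide (default 250).
#' @param maf,effect Planted QTL: minor-allele founder count and effect (SD
#'   units).
#' @param n_perm Permutations for the threshold (default 200).
#' @param em_max_iter EM iteration cap for the reconstruction (default 10).
#' @param out_dir Optional directory: writes map, calls, scans and a summary
#'   as CSVs.
#' @param quiet Suppress progress messages.
#' @return Object of class \code{do_demo} with all stage outputs (see
#'   \code{print} method for the headline numbers).
#' @export
run_demo <- function(seed = 1, n = 300, n_markers = 250, maf = 2, effect = 1.5,
                     n_perm = 200, em_max_iter = 10, out_dir = NULL,
                     quiet = FALSE) {
  say <- function(...) if (!quiet) message("[demo] ", ...)
  set.seed(seed)
  say("seed = ", seed, "; simulating population (n = ", n, ", markers = ",
      n_markers, ")")
  map <- sim_marker_map(n_markers)
  states <- diplotype_states()
  pop <- sim_do_population(map, n_ind = n, gen = 8)
  truth <- true_diplotypes(pop, map, states)
  fg <- sim_founder_geno(map)
  calls <- sim_genotype_calls(truth$state, fg, states)

  say("reconstructing diplotypes (genotype-call HMM, EM)")
  fit <- suppressWarnings(fit_diplotypes(calls = calls, map = map, gen = 8,
                                         states = states, founder_geno = fg,
                                         max_iter = em_max_iter))
  say("EM iterations: ", fit$iterations, "; log-likelihood ",
      format(utils::tail(fit$loglik_trace, 1)))
  D <- founder_dosage(fit, states)
  K <- loco_kinship(D, map)
  Kall <- calc_kinship(D)

  say("simulating phenotype (MAF ", maf, ", effect ", effect, " SD)")
  snps <- sim_founder_snps(map, per_interval = 2)
  al <- as.matrix(snps[, unclass(states$founders)])
  cand <- which(rowSums(al == 0) == maf)
  cs <- sample(cand, 1)   # causal SNP: its SDP defines the minor founders
  minor <- which(al[cs, ] == 0)
  jchr <- which(map$chr == snps$chr[cs])
  jq <- jchr[which.min(abs(map$bp[jchr] - snps$bp[cs]))]
  ph <- sim_phenotype(truth$state[, jq], minor, effect, states, kinship = Kall)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- factor(sample(1:3, n, replace = TRUE))
  covar <- data.frame(sex = sex, batch = batch)
  y <- ph$y + 0.5 * (sex == "M") + 0.2 * as.integer(batch)

  say("null mixed model / heritability")
  null_fit <- fit_polygenic(y, Kall, covar)

  say("genome scans: full, additive haplotype, additive SNP")
  snp_dos <- impute_snp_dosage(D, snps, map)
  scan_h <- qtl_scan(y, D, map, kinship = K, covar = covar, model = "haplotype")
  scan_f <- qtl_scan(y, fit$probs, map, kinship = K, covar = covar, model = "full")
  scan_s <- qtl_scan(y, snp_dos, map, kinship = K, covar = covar, model = "snp")

  say("permutation threshold (", n_perm, " permutations, no kinship term)")
  perm <- perm_threshold(y, D, map, covar = covar, model = "haplotype",
                         n_perm = n_perm)
  pk <- max_scan(scan_h)
  eff <- founder_effects(scan_h, pk$locus)
  ci <- credible_interval(scan_h, chr = pk$chr)

  out <- structure(list(seed = seed, map = map, calls = calls, fit = fit,
                        dosage = D, kinship = K, null_fit = null_fit,
                        h2 = heritability(null_fit),
                        qtl = list(marker = map$marker[jq], chr = map$chr[jq],
                                   bp = map$bp[jq], minor = minor,
                                   effect = effect),
                        scans = list(haplotype = scan_h, full = scan_f,
                                     snp = scan_s),
                        perm = perm, peak = pk, founder_effects = eff,
                        interval = ci),
                   class = "do_demo")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_marker_map(map, file.path(out_dir, "map.csv"))
    write_calls(calls, file.path(out_dir, "calls.csv"))
    write_scan(scan_h, file.path(out_dir, "scan_haplotype.csv"))
    write_scan(scan_f, file.path(out_dir, "scan_full.csv"))
    write_scan(scan_s, file.path(out_dir, "scan_snp.csv"))
    writeLines(utils::capture.output(print(out)),
               file.path(out_dir, "summary.txt"))
  }
  out
}

#' @export
print.do_demo <- function(x, ...) {
  cat("Synthetic DO mapping demo (seed ", x$seed, ")\n", sep = "")
  cat("  true QTL: ", x$qtl$marker, " (chr ", x$qtl$chr, ", ",
      round(x$qtl$bp / 1e6, 2), " Mb), minor founders ",
      paste(LETTERS[sort(x$qtl$minor)], collapse = ""), ", effect ",
      x$qtl$effect, " SD\n", sep = "")
  cat("  heritability (null model): h2 = ", round(x$h2, 3), "\n", sep = "")
  thr <- x$perm$threshold[1]
  for (mod in names(x$scans)) {
    pk <- max_scan(x$scans[[mod]])
    cat("  ", format(mod, width = 10), " peak LOD ",
        sprintf("%6.2f", pk$lod), " at chr ", pk$chr, " ",
        round(pk$bp / 1e6, 1), " Mb\n", sep = "")
  }
  cat("  permutation LOD threshold (alpha 0.05, haplotype): ",
      round(thr, 2), "\n", sep = "")
  cat("  support interval: chr ", x$interval$chr, " ",
      round(x$interval$lo_bp / 1e6, 2), "-",
      round(x$interval$hi_bp / 1e6, 2), " Mb\n", sep = "")
  cat("  centered founder effects at peak:\n")
  print(round(x$founder_effects, 3))
  invisible(x)
}
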