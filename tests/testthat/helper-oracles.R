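# Shared fixtures and independent oracles for the test suite.

dna_alphabet <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(dna_alphabet, n, replace = TRUE), collapse = "")

make_track <- function(values, strand = "+", semantics = "coverage",
                       strain = "s", seq_id = "chr") {
  dtx_track(strain, seq_id, strand, values, semantics)
}

# a minimal library with given plus-strand tracks and flat minus strand
make_library <- function(starts_plus, cov_plus, raw_total = 1e8,
                         condition = "exp", treated = TRUE,
                         starts_minus = numeric(length(starts_plus)),
                         cov_minus = numeric(length(starts_plus)),
                         id = paste0("lib_", condition)) {
  dtx_library(id, condition, treated,
              list(read_starts = list("+" = make_track(starts_plus, "+", "read_starts"),
                                      "-" = make_track(starts_minus, "-", "read_starts")),
                   coverage = list("+" = make_track(cov_plus, "+", "coverage"),
                                   "-" = make_track(cov_minus, "-", "coverage"))),
              raw_total)
}

# independent cubic-DP local alignment oracle (affine gap: open + k*ext)
sw_oracle <- function(q, s, match = 2, mism = -3, open = 5, ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1); best <- 0
  for (i in 1:m) for (j in 1:n) {
    sub <- if (qc[i] == sc[j] && qc[i] != "N") match else mism
    v <- H[i, j] + sub
    for (k in 1:i) v <- max(v, H[i - k + 1, j + 1] - open - ext * k)
    for (k in 1:j) v <- max(v, H[i + 1, j - k + 1] - open - ext * k)
    H[i + 1, j + 1] <- max(0, v)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# independent global (Needleman-Wunsch) score oracle with affine gaps
# (open + k*ext, end gaps penalized), BLOSUM62
nw_score_oracle <- function(a, b, open = 11, ext = 1) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  m <- length(ac); n <- length(bc)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); X <- matrix(NEG, m + 1, n + 1); Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in 2:(m + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(n + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 1:m) for (j in 1:n) {
    s <- sm[ac[i], bc[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Monte Carlo oracle for the Gamma-Poisson two-fold posterior
mc_posterior_oracle <- function(a, b, La = 1, Lb = 1, n = 1e6) {
  ra <- stats::rgamma(n, a + 0.5, La)
  rb <- stats::rgamma(n, b + 0.5, Lb)
  r <- ra / rb
  mean(r >= 2 | r <= 0.5)
}

# small shared two-strain fixture, generated once per test run
.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 7) {
  sim_config(seed = seed, genome_length = 80000, n_ortholog_genes = 30,
             n_strain_specific_genes = 9, n_gtss = 24, n_atss = 8, n_itss = 6,
             n_ntss = 8, n_conserved = c(g = 16, a = 4, i = 3, n = 4),
             n_promoter_snp_cases = 2, n_actuatons = 3, n_actuaton_decoys = 4,
             n_leaderless = 4)
}

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_genome_pair(small_sim_config())
    .fixture_cache$libs <- simulate_read_starts(.fixture_cache$sim)
  }
  list(sim = .fixture_cache$sim, libs = .fixture_cache$libs)
}

# noise-free variant of the small fixture (dispersion 0)
small_run_noise_free <- function(strain = "a") {
  key <- paste0("run0_", strain)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- small_sim_config()
    cfg$dispersion <- 0
    sim <- generate_genome_pair(cfg)
    libs <- simulate_read_starts(sim)
    th <- dtx_thresholds()
    treated <- Filter(function(l) l$treated, libs[[strain]])
    nl <- normalize_libraries(treated, th)
    tss <- build_tss_set(nl, raw_libs = treated, strain = strain)
    unt <- scale_library(libs[[strain]]$untreated, th)
    bt <- build_tus(tss, unt$tracks$coverage, sim$genes[[strain]],
                    dtx_segmentation_params(), th)
    .fixture_cache[[key]] <- list(tss = bt$tss, tus = bt$tus, untreated = unt,
                                  genes = sim$genes[[strain]],
                                  genome = sim$genomes[[strain]],
                                  truth = sim$truth)
  }
  .fixture_cache[[key]]
}

# run the single-strain stages in memory on the small fixture
small_run <- function(strain = "a") {
  key <- paste0("run_", strain)
  if (is.null(.fixture_cache[[key]])) {
    fx <- small_sim()
    th <- dtx_thresholds()
    treated <- Filter(function(l) l$treated, fx$libs[[strain]])
    nl <- normalize_libraries(treated, th)
    tss <- build_tss_set(nl, raw_libs = treated, strain = strain)
    unt <- scale_library(fx$libs[[strain]]$untreated, th)
    bt <- build_tus(tss, unt$tracks$coverage, fx$sim$genes[[strain]],
                    dtx_segmentation_params(), th)
    .fixture_cache[[key]] <- list(tss = bt$tss, tus = bt$tus, untreated = unt,
                                  genes = fx$sim$genes[[strain]],
                                  genome = fx$sim$genomes[[strain]],
                                  truth = fx$sim$truth)
  }
  .fixture_cache[[key]]
}
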