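test_that("the generator honors the configured feature census", {
  fx <- small_sim()
  cfg <- small_sim_config()
  sim <- fx$sim
  expect_equal(nrow(sim$orthologs), cfg$n_ortholog_genes)
  for (strain in c("a", "b")) {
    tt <- sim$truth$tss[sim$truth$tss$strain == strain, ]
    expect_equal(sum(tt$class == "g"), cfg$n_gtss)
    expect_equal(sum(tt$class == "a"), cfg$n_atss)
    expect_equal(sum(tt$class == "i"), cfg$n_itss)
    expect_equal(sum(tt$class == "n"), cfg$n_ntss)
    gn <- sim$genes[[strain]]
    expect_equal(sum(gn$kind == "protein_coding"),
                 cfg$n_ortholog_genes + cfg$n_strain_specific_genes)
  }
  expect_equal(sum(sim$truth$actuatons$kind == "actuaton") / 2, cfg$n_actuatons)
  expect_equal(nrow(sim$truth$promoter_snps), cfg$n_promoter_snp_cases)
  expect_equal(nrow(sim$truth$leaderless), cfg$n_leaderless)
})

test_that("zero strain-specific genes give equal gene counts in both strains", {
  cfg <- small_sim_config()
  cfg$n_strain_specific_genes <- 0L
  cfg$n_actuatons <- 0L
  cfg$n_actuaton_decoys <- 0L
  sim <- generate_genome_pair(cfg)
  expect_equal(nrow(sim$genes$a), nrow(sim$genes$b))
})

test_that("the same seed reproduces the fixture exactly", {
  cfg <- small_sim_config(seed = 12)
  s1 <- generate_genome_pair(cfg)
  s2 <- generate_genome_pair(cfg)
  expect_identical(s1$genomes$a$seq, s2$genomes$a$seq)
  expect_identical(s1$genomes$b$seq, s2$genomes$b$seq)
  expect_identical(s1$truth$tss, s2$truth$tss)
  l1 <- simulate_read_starts(s1); l2 <- simulate_read_starts(s2)
  expect_identical(l1$a[[1]]$tracks$read_starts[["+"]]$values,
                   l2$a[[1]]$tracks$read_starts[["+"]]$values)
  s3 <- generate_genome_pair(small_sim_config(seed = 13))
  expect_false(identical(s1$genomes$a$seq, s3$genomes$a$seq))
})

test_that("infeasible packing errors before emission", {
  cfg <- small_sim_config()
  cfg$genome_length <- 20000L
  expect_error(generate_genome_pair(cfg), "infeasible")
})

test_that("zero dispersion makes read starts equal their planted rates exactly", {
  cfg <- small_sim_config()
  cfg$dispersion <- 0
  cfg$background_start_rate <- 0
  sim <- generate_genome_pair(cfg)
  libs <- simulate_read_starts(sim)
  tt <- sim$truth$tss[sim$truth$tss$strain == "a", ]
  lib1 <- libs$a[[1]]   # first condition
  rate1 <- tt[[paste0("rate_", lib1$condition)]]
  got <- vapply(seq_len(nrow(tt)), function(k)
    lib1$tracks$read_starts[[tt$strand[k]]]$values[tt$position[k]], numeric(1))
  expect_equal(got, round(rate1))
})

test_that("planted read-through reproduces the configured coverage ratio on average", {
  cfg <- small_sim_config()
  cfg$dispersion <- 0
  sim <- generate_genome_pair(cfg)
  libs <- simulate_read_starts(sim)
  acts <- sim$truth$actuatons
  acts <- acts[acts$strain == "a" & acts$kind == "actuaton", ]
  tt <- sim$truth$tss[sim$truth$tss$strain == "a", ]
  cov <- libs$a$untreated$tracks$coverage
  for (k in seq_len(nrow(acts))) {
    row <- tt[tt$role == "actuaton" & tt$position == acts$tss[k], ]
    s <- acts$strand[k]
    srna_mean <- mean(cov[[s]]$values[acts$srna_start[k]:acts$srna_end[k]])
    gene <- sim$genes$a[sim$genes$a$gene_id == acts$gene_id[k], ]
    gene_mean <- mean(cov[[s]]$values[gene$start:gene$end])
    expect_equal(gene_mean / srna_mean, acts$readthrough[k], tolerance = 0.05)
  }
})

test_that("conserved partners obey the per-class conservation bookkeeping", {
  fx <- small_sim()
  tt <- fx$sim$truth$tss
  cons <- tt[tt$conserved & tt$strain == "a", ]
  partners <- tt[match(cons$partner_id, tt$id), ]
  expect_true(all(partners$strain == "b"))
  # gTSS: both cover orthologous genes
  ga <- cons[cons$class == "g", ]; gb <- partners[cons$class == "g", ]
  orth <- fx$sim$orthologs
  expect_true(all(orth$gene_b[match(ga$gene_id, orth$gene_a)] == gb$gene_id))
  # a/iTSS: aligned offset at most 10 nt (genes are codon-aligned copies)
  ai <- cons$class %in% c("a", "i")
  ga_genes <- fx$sim$genes$a[match(cons$gene_id[ai], fx$sim$genes$a$gene_id), ]
  gb_genes <- fx$sim$genes$b[match(partners$gene_id[ai], fx$sim$genes$b$gene_id), ]
  off_a <- ifelse(ga_genes$strand == "+", cons$position[ai] - ga_genes$start,
                  ga_genes$end - cons$position[ai])
  off_b <- ifelse(gb_genes$strand == "+", partners$position[ai] - gb_genes$start,
                  gb_genes$end - partners$position[ai])
  expect_true(all(abs(off_a - off_b) <= 10))
  # nTSS: at least half the transcript span is alignable (substitution rate 0.1)
  nn <- cons$class == "n"
  expect_true(all(tt$tu_end[match(cons$id[nn], tt$id)] - tt$tu_start[match(cons$id[nn], tt$id)] ==
                  partners$tu_end[nn] - partners$tu_start[nn]))
})

test_that("promoter-SNP cases are silent in strain B and differ by one -10 base", {
  fx <- small_sim()
  snps <- fx$sim$truth$promoter_snps
  tt <- fx$sim$truth$tss
  for (k in seq_len(nrow(snps))) {
    expect_equal(adist(snps$hexamer_a[k], snps$hexamer_b[k])[1, 1], 1)
    # no planted TSS anywhere near the expected strain-B position
    near <- tt$strain == "b" & abs(tt$position - snps$tss_b_expected[k]) < 20
    expect_false(any(near))
  }
  # silenced loci produce zero planted reads in strain B
  lib <- small_sim()$libs$b[[1]]
  for (k in seq_len(nrow(snps))) {
    s <- snps$strand[k]; p <- snps$tss_b_expected[k]
    expect_equal(lib$tracks$read_starts[[s]]$values[p], 0)
  }
})

test_that("fixture files are emitted with the expected census and reread losslessly", {
  cfg <- sim_config(seed = 3, genome_length = 42000, n_ortholog_genes = 12,
                    n_strain_specific_genes = 4, n_gtss = 9, n_atss = 3,
                    n_itss = 2, n_ntss = 3, n_conserved = c(g = 6, a = 1, i = 1, n = 1),
                    n_promoter_snp_cases = 1, n_actuatons = 2, n_actuaton_decoys = 3,
                    n_leaderless = 2)
  dir <- withr::local_tempdir()
  sim <- simulate_fixture(cfg, dir)
  tracks <- list.files(file.path(dir, "tracks"))
  expect_length(tracks, 88L)   # 2 strains x 11 libraries x 2 strands x 2 semantics
  expect_true(all(file.exists(file.path(dir, c("strainA.fasta", "strainB.gff3",
                                               "orthologs.tsv", "config.yaml")))))
  libs <- read_fixture_libraries(dir, "a", cfg$genome_length)
  expect_length(libs, 11L)
  mem <- simulate_read_starts(sim)
  expect_equal(libs[[1]]$tracks$read_starts[["+"]]$values,
               mem$a[[1]]$tracks$read_starts[["+"]]$values)
  genes <- read_annotation(file.path(dir, "strainA.gff3"))
  expect_equal(nrow(genes), nrow(sim$genes$a))
})
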