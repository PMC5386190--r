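toy_pair <- function(seq_a, seq_b, strand_a = "+", strand_b = "+") {
  ga <- data.frame(gene_id = "ga", seq_id = "A", start = 101L,
                   end = 100L + nchar(seq_a), strand = strand_a,
                   kind = "protein_coding", product = "", stringsAsFactors = FALSE)
  gb <- data.frame(gene_id = "gb", seq_id = "B", start = 201L,
                   end = 200L + nchar(seq_b), strand = strand_b,
                   kind = "protein_coding", product = "", stringsAsFactors = FALSE)
  aa <- function(nt) sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(nt))))
  aln <- align_proteins(aa(seq_a), aa(seq_b))
  aln$gene_a <- ga; aln$gene_b <- gb
  aln
}

test_that("positions map through the protein alignment, codon-exact", {
  s <- "ATGAAACCCGGGTTTACCTAA"
  aln <- toy_pair(s, s)
  expect_equal(map_position_via_protein(aln, 101L + 9L)$position, 201L + 9L)
  expect_equal(map_position_via_protein(aln, 101L + 11L)$position, 201L + 11L)
  expect_error(map_position_via_protein(aln, 50L), "outside")
  # a one-codon insertion in gene_b shifts downstream positions by +3
  s_ins <- paste0(substr(s, 1, 6), "GCA", substr(s, 7, nchar(s)))
  aln2 <- toy_pair(s, s_ins)
  expect_equal(map_position_via_protein(aln2, 101L + 9L)$position, 201L + 12L)
  # round trip a -> b -> a is the identity on gap-free columns
  aln_rev <- toy_pair(s_ins, s)
  p_b <- map_position_via_protein(aln2, 101L + 15L)$position
  back <- map_position_via_protein(aln_rev, p_b - 100L)$position
  expect_equal(back, 201L + 15L)
})

test_that("minus-strand genes map strand-aware", {
  s <- "ATGAAACCCGGGTTTACCTAA"
  aln <- toy_pair(s, s, strand_a = "-", strand_b = "-")
  # offset 9 from the 5' end = end - 9 on the minus strand
  expect_equal(map_position_via_protein(aln, aln$gene_a$end - 9L)$position,
               aln$gene_b$end - 9L)
})

test_that("gTSS conservation requires a gTSS in both orthologs", {
  tus_a <- data.frame(tu_id = "TU1", label = "g", member_genes = "ga1",
                      stringsAsFactors = FALSE)
  tus_b <- data.frame(tu_id = "TU1", label = "g", member_genes = "gb2",
                      stringsAsFactors = FALSE)
  orth <- data.frame(gene_a = c("ga1", "ga2", "ga3"),
                     gene_b = c("gb1", "gb2", "gb3"), stringsAsFactors = FALSE)
  rec <- conserved_gtss(tus_a, tus_b, orth)
  expect_equal(rec$verdict, c("strain_specific_a", "strain_specific_b", "absent"))
  tus_b2 <- data.frame(tu_id = "TU1", label = "ga", member_genes = "gb1",
                       stringsAsFactors = FALSE)
  expect_equal(conserved_gtss(tus_a, tus_b2, orth)$verdict[1], "conserved")
})

test_that("internal TSS conservation obeys the 10-nt offset boundary", {
  s <- paste0("ATG", paste(rep("AAA", 40), collapse = ""), "TAA")  # 126 nt
  mk <- function(offset_b) {
    aln <- toy_pair(s, s)
    alns <- list(ga = aln)
    tss_a <- data.frame(position = 101L + 60L, strand = "+", class = "i",
                        stringsAsFactors = FALSE)
    tss_b <- data.frame(position = 201L + 60L + offset_b, strand = "+", class = "i",
                        stringsAsFactors = FALSE)
    conserved_internal_antisense_tss(tss_a, tss_b,
                                     aln$gene_a, aln$gene_b, alns, "i")
  }
  r10 <- mk(10L)
  expect_equal(r10$verdict[r10$class == "i" & !is.na(r10$tss_a) & !is.na(r10$tss_b)],
               "conserved")
  expect_equal(r10$offset[r10$verdict == "conserved"], 10)
  r11 <- mk(11L)
  expect_false(any(r11$verdict == "conserved"))
  expect_setequal(r11$verdict, c("strain_specific_a", "strain_specific_b"))
})

test_that("aTSS conservation maps through the sense gene on the opposite strand", {
  s <- paste0("ATG", paste(rep("GCA", 50), collapse = ""), "TAA")
  aln <- toy_pair(s, s)
  alns <- list(ga = aln)
  tss_a <- data.frame(position = 101L + 80L, strand = "-", class = "a",
                      stringsAsFactors = FALSE)
  tss_b <- data.frame(position = 201L + 83L, strand = "-", class = "a",
                      stringsAsFactors = FALSE)
  rec <- conserved_internal_antisense_tss(tss_a, tss_b, aln$gene_a, aln$gene_b,
                                          alns, "a")
  expect_equal(rec$verdict[1], "conserved")
  expect_equal(rec$offset[1], 3)
})

test_that("nTU conservation separates conserved-as-nTU from other classes", {
  set.seed(51)
  gseq_a <- random_dna(6000)
  elem <- substr(gseq_a, 2001, 2200)
  gseq_b <- paste0(random_dna(3000), elem, random_dna(2800))
  genome_a <- dtx_genome("A", "chrA", gseq_a)
  tus_a <- data.frame(tu_id = "TUa", label = "n", start = 2001L, end = 2200L,
                      strand = "+", stringsAsFactors = FALSE)
  tus_b_ntu <- data.frame(tu_id = "TUb", label = "n", start = 3001L, end = 3200L,
                          strand = "+", stringsAsFactors = FALSE)
  rec <- conserved_ntss(tus_a, genome_a, gseq_b, tus_b_ntu)
  expect_equal(rec$verdict, "conserved_as_ntu")
  # the same hit overlapping a gene-covering TU instead: classified differently
  tus_b_gtu <- data.frame(tu_id = "TUb", label = "g", start = 3001L, end = 3200L,
                          strand = "+", stringsAsFactors = FALSE)
  rec2 <- conserved_ntss(tus_a, genome_a, gseq_b, tus_b_gtu)
  expect_equal(rec2$verdict, "conserved_other_class")
  # no homologous sequence: strain-specific
  rec3 <- conserved_ntss(tus_a, genome_a, random_dna(6000), tus_b_ntu)
  expect_equal(rec3$verdict, "strain_specific_a")
})

test_that("promoter divergence flags single -10 element transitions", {
  set.seed(61)
  up <- random_dna(38)
  minus10 <- "TATAAT"
  tail6 <- random_dna(6)
  wa <- paste0(up, minus10, tail6)           # 50-nt upstream window
  mk_genomes <- function(hex_b) {
    wb <- paste0(up, hex_b, tail6)
    ga <- dtx_genome("A", "cA", paste0(wa, "GTTT", random_dna(46)))
    gb <- dtx_genome("B", "cB", paste0(wb, "GTTT", random_dna(46)))
    list(a = ga, b = gb)
  }
  g <- mk_genomes("TATGAT")
  rep <- promoter_divergence(g$a, 51L, "+", g$b, 51L, "+")
  expect_true(rep$minus10_mismatch)
  expect_length(rep$mismatch_offsets, 1L)
  expect_equal(rep$minus10_a, "TATAAT")
  expect_equal(rep$minus10_b, "TATGAT")
  g2 <- mk_genomes("TGTAAT")
  rep2 <- promoter_divergence(g2$a, 51L, "+", g2$b, 51L, "+")
  expect_true(rep2$minus10_mismatch)
  expect_length(rep2$mismatch_offsets, 1L)
  g3 <- mk_genomes("TATAAT")
  rep3 <- promoter_divergence(g3$a, 51L, "+", g3$b, 51L, "+")
  expect_length(rep3$mismatch_offsets, 0L)
  expect_false(rep3$minus10_mismatch)
  # mismatch outside the hexamer does not set the flag
  g4 <- mk_genomes("TATAAT")
  gb4 <- dtx_genome("B", "cB", paste0("A", substr(g4$b$seq, 2, g4$b$length)))
  rep4 <- promoter_divergence(g4$a, 51L, "+", gb4, 51L, "+")
  expect_false(rep4$minus10_mismatch)
  expect_equal(rep4$mismatch_offsets, -50L)
  # window out of range: unalignable
  rep5 <- promoter_divergence(g4$a, 20L, "+", g4$b, 51L, "+")
  expect_equal(rep5$verdict, "unalignable")
})

test_that("planted conservation is recovered with high precision per class", {
  fx <- small_sim()
  ra <- small_run("a"); rb <- small_run("b")
  orth <- fx$sim$orthologs
  truth <- fx$sim$truth$tss
  alns <- ortholog_alignments(orth, ra$genes, rb$genes, ra$genome, rb$genome)
  # gTSS: predicted conserved pairs should be planted-conserved pairs
  cg <- conserved_gtss(ra$tus, rb$tus, orth)
  planted_g <- truth$gene_id[truth$strain == "a" & truth$class == "g" & truth$conserved]
  pred_g <- cg$gene_a[cg$verdict == "conserved"]
  expect_gte(mean(pred_g %in% planted_g), 0.9)
  expect_gte(mean(planted_g %in% pred_g), 0.9)
  for (cls in c("a", "i")) {
    rec <- conserved_internal_antisense_tss(ra$tss, rb$tss, ra$genes, rb$genes,
                                            alns, cls)
    planted <- truth[truth$strain == "a" & truth$class == cls & truth$conserved, ]
    pred <- rec[rec$verdict == "conserved", ]
    expect_gte(mean(pred$tss_a %in% planted$position), 0.9)
    expect_gte(mean(planted$position %in% pred$tss_a), 0.9)
  }
  idx_b <- build_subject_index(rb$genome$seq)
  rec_n <- conserved_ntss(ra$tus, ra$genome, idx_b, rb$tus)
  planted_n <- truth[truth$strain == "a" & truth$class == "n" & truth$conserved, ]
  pred_pos <- ra$tus$tss_position[match(rec_n$tu_id[rec_n$verdict == "conserved_as_ntu"],
                                        ra$tus$tu_id)]
  expect_gte(mean(pred_pos %in% planted_n$position), 0.9)
  expect_gte(mean(planted_n$position %in% pred_pos), 0.9)
})

test_that("conservation verdicts are symmetric under swapping the strains", {
  fx <- small_sim()
  ra <- small_run("a"); rb <- small_run("b")
  orth <- fx$sim$orthologs
  cg_ab <- conserved_gtss(ra$tus, rb$tus, orth)
  orth_swapped <- data.frame(gene_a = orth$gene_b, gene_b = orth$gene_a,
                             stringsAsFactors = FALSE)
  cg_ba <- conserved_gtss(rb$tus, ra$tus, orth_swapped)
  expect_equal(sum(cg_ab$verdict == "conserved"), sum(cg_ba$verdict == "conserved"))
  expect_equal(sum(cg_ab$verdict == "strain_specific_a"),
               sum(cg_ba$verdict == "strain_specific_b"))
  expect_equal(sum(cg_ab$verdict == "strain_specific_b"),
               sum(cg_ba$verdict == "strain_specific_a"))
})
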