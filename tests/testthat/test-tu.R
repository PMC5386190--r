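test_that("segmentation follows coverage plateaus and fractional drops", {
  cov <- make_track(c(rep(100, 500), rep(0, 200)))
  seg <- segment_tu(1, "+", cov)
  expect_equal(seg$length, 500L)
  # a sustained drop to 5% of the running max ends the TU at the drop
  cov2 <- make_track(c(rep(100, 300), rep(5, 300)))
  seg2 <- segment_tu(1, "+", cov2)
  expect_equal(seg2$end, 300)
  # a drop to 20% is retained
  cov3 <- make_track(c(rep(100, 300), rep(20, 300)))
  expect_equal(segment_tu(1, "+", cov3)$end, 600)
  # minus strand walks leftward
  seg4 <- segment_tu(500, "-", cov)
  expect_equal(c(seg4$start, seg4$end), c(1, 500))
  # zero coverage at the TSS: 1-nt TU, flagged
  seg5 <- segment_tu(600, "+", cov)
  expect_equal(seg5$flag, "zero_coverage")
  expect_equal(seg5$length, 1L)
  # max_tu_length caps extension
  long <- make_track(rep(50, 3000))
  expect_equal(segment_tu(1, "+", long, dtx_segmentation_params(max_tu_length = 1000))$length,
               1000L)
})

test_that("gaps shorter than max_gap are bridged, longer ones terminate", {
  cov <- c(rep(100, 200), rep(0, 40), rep(100, 200), rep(0, 60), rep(100, 200))
  seg <- segment_tu(1, "+", make_track(cov))
  expect_equal(seg$end, 440)   # 40-nt gap bridged, 60-nt gap terminates
})

grid_genes <- function() {
  data.frame(gene_id = c("sense1", "sense2", "anti1"),
             seq_id = "chr",
             start = c(1000L, 2500L, 4000L),
             end = c(2000L, 3200L, 5000L),
             strand = c("+", "+", "-"),
             kind = "protein_coding", product = "", stringsAsFactors = FALSE)
}

mk_tus <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(tu_id = paste0("TU", i), seq_id = "chr", strand = r$strand,
               start = r$start, end = r$end, tss_position = r$tss,
               stringsAsFactors = FALSE)
  }))
  df
}

test_that("TU classification matches the rule grid exactly", {
  genes <- grid_genes()
  th <- dtx_thresholds()
  # plain gene-covering TU
  tus <- classify_tus(mk_tus(list(strand = "+", start = 950, end = 2100, tss = 950)), genes, th)
  expect_equal(tus$label, "g")
  expect_equal(tus$member_genes, "sense1")
  # antisense overlap of exactly 20 nt with a gene counts, 19 does not
  tus <- classify_tus(mk_tus(list(strand = "+", start = 4981, end = 5400, tss = 4981)), genes, th)
  expect_equal(tus$label, "a")
  tus <- classify_tus(mk_tus(list(strand = "+", start = 4982, end = 5400, tss = 4982)), genes, th)
  expect_equal(tus$label, "n")
  # TSS strictly inside a sense gene: i; at the gene edge: not i
  tus <- classify_tus(mk_tus(list(strand = "+", start = 1500, end = 1900, tss = 1500)), genes, th)
  expect_equal(tus$label, "i")
  tus <- classify_tus(mk_tus(list(strand = "+", start = 1000, end = 1900, tss = 1000)), genes, th)
  expect_equal(tus$label, "g")   # TSS at the first base is not "within"
  tus <- classify_tus(mk_tus(list(strand = "+", start = 2000, end = 2400, tss = 2000)), genes, th)
  expect_equal(tus$label, "g")   # TSS at the last base
  # free-standing
  tus <- classify_tus(mk_tus(list(strand = "+", start = 3500, end = 3700, tss = 3500)), genes, th)
  expect_equal(tus$label, "n")
  # composite gaiTU: iTSS inside sense1, covers sense2, antisense into anti1
  tus <- classify_tus(mk_tus(list(strand = "+", start = 1500, end = 4100, tss = 1500)), genes, th)
  expect_equal(tus$label, "gai")
  expect_equal(tus$class, "gaiTU")
  expect_equal(tus$member_genes, "sense2")
  expect_equal(tus$i_host, "sense1")
})

test_that("antisense classification against other TUs is symmetric", {
  genes <- grid_genes()[0, ]
  th <- dtx_thresholds()
  tus <- classify_tus(mk_tus(list(strand = "+", start = 100, end = 400, tss = 100),
                             list(strand = "-", start = 381, end = 700, tss = 700)),
                      genes, th)
  expect_equal(tus$label, c("a", "a"))   # 20-nt reciprocal overlap
  tus19 <- classify_tus(mk_tus(list(strand = "+", start = 100, end = 400, tss = 100),
                               list(strand = "-", start = 382, end = 700, tss = 700)),
                        genes, th)
  expect_equal(tus19$label, c("n", "n"))
})

test_that("every TU carries at least one label and labels are deterministic", {
  run <- small_run("a")
  expect_true(all(nzchar(run$tus$label)))
  again <- classify_tus(run$tus[, c("tu_id", "seq_id", "strand", "start", "end",
                                    "tss_position")],
                        run$genes, dtx_thresholds())
  expect_identical(again$label, run$tus$label)
})

test_that("UTR lengths measure TSS-to-start and stop-to-TU-end distances", {
  genes <- grid_genes()
  mk1 <- function(start, end, tss, strand = "+")
    classify_tus(mk_tus(list(strand = strand, start = start, end = end, tss = tss)),
                 genes, dtx_thresholds())
  # TSS 54 nt upstream of the start codon
  tu <- compute_utrs(mk1(946, 2128, 946), genes)
  expect_equal(tu$utr5, 54)
  expect_equal(tu$utr3, 128)
  # leaderless: TSS at the A of AUG
  tu <- compute_utrs(mk1(1000, 2000, 1000), genes)
  expect_equal(tu$utr5, 0)
  expect_equal(tu$utr3, 0)   # TU ends exactly at the stop codon
  # TSS inside the first member gene: utr5 undefined
  tu <- compute_utrs(mk1(1500, 3300, 1500), genes)
  expect_true(is.na(tu$utr5))
  # non-gene TU: both undefined
  tu <- compute_utrs(mk1(3500, 3700, 3500), genes)
  expect_true(is.na(tu$utr5) && is.na(tu$utr3))
})

test_that("UTRs and gene span add up to the TU length for single-gene gTUs", {
  run <- small_run("a")
  g <- run$tus[run$tus$label == "g" & !is.na(run$tus$utr5) & !is.na(run$tus$utr3), ]
  glen <- vapply(g$member_genes, function(id) {
    r <- run$genes[run$genes$gene_id == id, ]
    r$end - r$start + 1
  }, numeric(1))
  expect_true(all(g$utr5 + glen + g$utr3 == g$end - g$start + 1))
})

test_that("the leaderless window is the start codon plus 10 nt upstream", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD"), seq_id = "chr",
                      start = c(100L, 300L, 500L, 700L), end = c(200L, 400L, 600L, 790L),
                      strand = c("+", "+", "+", "-"), kind = "protein_coding",
                      product = "", stringsAsFactors = FALSE)
  tss <- data.frame(position = c(100L, 290L, 489L, 800L), strand = c("+", "+", "+", "-"),
                    class = "g", stringsAsFactors = FALSE)
  got <- detect_leaderless(tss, genes)
  # at the A: offset 0; 10 upstream: flagged; 11 upstream: not; minus strand 10 upstream
  expect_setequal(got$gene_id, c("gA", "gB", "gD"))
  expect_equal(got$offset[got$gene_id == "gA"], 0)
  expect_equal(got$offset[got$gene_id == "gB"], 10)
  expect_equal(got$offset[got$gene_id == "gD"], 10)
})

test_that("planted TU classes are recovered on the synthetic strain", {
  run <- small_run("a")
  truth <- run$truth$tss[run$truth$tss$strain == "a", ]
  m <- match(paste(truth$position, truth$strand),
             paste(run$tss$position, run$tss$strand))
  ok <- !is.na(m)
  expect_gte(mean(ok), 0.95)
  planted <- truth$class[ok]
  got <- run$tss$class[m[ok]]
  agree <- mapply(function(p, g) if (p == "srna") grepl("[gn]", g) else grepl(p, g, fixed = TRUE),
                  planted, got)
  expect_gte(mean(agree), 0.95)
})

test_that("planted TU 3' ends are recovered within the gap tolerance", {
  run0 <- small_run_noise_free("a")   # noise-free parameter recovery
  truth <- run0$truth$tss[run0$truth$tss$strain == "a" &
                            run0$truth$tss$class %in% c("g", "n"), ]
  m <- match(paste(truth$position, truth$strand),
             paste(run0$tus$tss_position, run0$tus$strand))
  ok <- !is.na(m)
  end3_true <- ifelse(truth$strand == "+", truth$tu_end, truth$tu_start)
  end3_got <- ifelse(truth$strand == "+", run0$tus$end[m], run0$tus$start[m])
  err <- abs(end3_got[ok] - end3_true[ok])
  expect_lte(mean(err), dtx_segmentation_params()$max_gap)
})
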