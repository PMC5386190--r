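# Synthetic two-strain dRNA-seq fixture generator. Emits two genomes with
# orthologous and strain-specific genes, planted TSSs of all four classes
# with condition-specific activities, TU extents with UTRs, promoter
# single-nucleotide differences that silence a TSS in one strain, actuaton
# arrangements, and simulated strand-specific read-start/coverage tracks with
# overdispersed noise -- all fully determined by the seed.

#' Simulation configuration
#'
#' Defines the conditions the fixture emulates: a 200 kb genome per strain,
#' 120 ortholog genes plus 15 strain-specific genes each, planted TSSs of the
#' four classes (100 gTSS / 30 aTSS / 20 iTSS / 25 nTSS per strain) with
#' per-class conserved subsets, four promoter single-nucleotide cases that
#' silence a gTSS in one strain, six actuatons plus six decoys, and eight
#' leaderless genes. Expression follows a per-TSS log-normal baseline with
#' per-condition log2-normal multipliers (shared between conserved partners
#' at correlation `inter_strain_cor`) and negative-binomial read-start noise.
#'
#' @param seed Integer seed; fully determines the fixture.
#' @param genome_length Genome length per strain (nt).
#' @param n_ortholog_genes,n_strain_specific_genes Gene counts.
#' @param n_gtss,n_atss,n_itss,n_ntss Planted TSSs per class per strain.
#' @param n_conserved Named vector (g/a/i/n): conserved TSS pairs per class.
#' @param n_promoter_snp_cases Promoter single-nucleotide silencing cases.
#' @param n_actuatons,n_actuaton_decoys Planted actuatons and decoys per
#'   strain (decoys split between a downstream gene with its own gTSS and a
#'   free-standing sRNA without read-through).
#' @param n_leaderless Genes whose gTSS lies within 10 nt of the start codon.
#' @param baseline_meanlog,baseline_sdlog Log-normal raw read-start baseline.
#' @param condition_effect_sd SD of per-condition log2 multipliers.
#' @param inter_strain_cor Correlation of condition effects between conserved
#'   partners.
#' @param dispersion Negative-binomial dispersion (1/size); 0 = noise-free
#'   (counts equal their means exactly).
#' @param background_start_rate Spurious (non-primary) read starts per
#'   transcript read, distributed over the TU body.
#' @param body_coverage_fraction Residual body coverage in treated libraries
#'   as a fraction of the TSS read count.
#' @param read_length Read length used to spread coverage downstream (nt).
#' @param bulk_reads Condition-stable mapped reads per treated library that do
#'   not appear in the start tracks (rRNA and bulk mRNA fragments), included
#'   in the library size used for scaling, as in real mapping statistics.
#' @param substitution_rate Per-site substitution rate applied to ortholog
#'   gene bodies and conserved intergenic elements in strain B.
#' @param readthrough_range Range of planted actuaton read-through fractions.
#'   The lower bound sits above the TU segmentation floor
#'   (`min_coverage_fraction`) so that a planted read-through is
#'   distinguishable from ordinary TU termination.
#' @param srna_len_range,ntu_len_range Feature length ranges (nt).
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog Log-normal UTR
#'   length models (medians 54 and 128 nt).
#' @param decay_len Geometric coverage decay length past the TU 3' end (nt).
#' @param special_uef Multiplier of the planted iron-depletion sRNA in the
#'   -Fe condition (flat elsewhere), emulating a strongly condition-specific
#'   regulator.
#' @param enrichment_efficiency Optional named per-condition 5'-PPP
#'   enrichment efficiencies (default 1 for all).
#' @return List of class `dtx_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_ortholog_genes = 120L,
                       n_strain_specific_genes = 15L,
                       n_gtss = 100L, n_atss = 30L, n_itss = 20L, n_ntss = 25L,
                       n_conserved = c(g = 78L, a = 12L, i = 10L, n = 10L),
                       n_promoter_snp_cases = 4L,
                       n_actuatons = 6L,
                       n_actuaton_decoys = 6L,
                       n_leaderless = 8L,
                       baseline_meanlog = log(3000), baseline_sdlog = 0.8,
                       condition_effect_sd = 1.5,
                       inter_strain_cor = 0.97,
                       dispersion = 0.2,
                       background_start_rate = 0.02,
                       body_coverage_fraction = 0.25,
                       read_length = 100L,
                       bulk_reads = 2e6,
                       substitution_rate = 0.1,
                       readthrough_range = c(0.12, 0.4),
                       srna_len_range = c(80L, 250L),
                       ntu_len_range = c(150L, 300L),
                       utr5_meanlog = log(54), utr5_sdlog = 0.55,
                       utr3_meanlog = log(128), utr3_sdlog = 0.5,
                       decay_len = 15,
                       special_uef = 130.9,
                       enrichment_efficiency = NULL) {
  cfg <- as.list(environment())
  conds <- dtx_conditions()
  if (is.null(cfg$enrichment_efficiency))
    cfg$enrichment_efficiency <- stats::setNames(rep(1, length(conds)), conds)
  nda <- ceiling(n_actuaton_decoys / 2)
  if (n_strain_specific_genes < n_actuatons + nda)
    stopf("need at least %d strain-specific genes for actuatons and decoys",
          n_actuatons + nda)
  need_a_only <- n_gtss - n_conserved[["g"]] - n_promoter_snp_cases - nda
  need_b_only <- n_gtss - n_conserved[["g"]] - nda
  if (need_a_only < 0 || need_b_only < 0)
    stopf("n_gtss too small for the requested conserved/promoter-SNP/decoy counts")
  if (n_conserved[["g"]] + n_promoter_snp_cases + need_a_only + need_b_only > n_ortholog_genes)
    stopf("not enough ortholog genes for the requested gTSS roles")
  if (n_conserved[["a"]] > n_atss || n_conserved[["i"]] > n_itss || n_conserved[["n"]] > n_ntss)
    stopf("conserved counts exceed per-class totals")
  class(cfg) <- "dtx_sim_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

all_sense_codons <- function() {
  cods <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
  setdiff(cods, STOP_CODONS)
}

random_gene_seq <- function(n_codons) {
  paste0("ATG", paste(sample(all_sense_codons(), n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# substitute nucleotides at `rate`, codon-wise, reverting codons that would
# become stops; start/stop codons untouched
mutate_gene_seq <- function(seq, rate) {
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  for (i in seq(2, length(cods) - 1L)) {
    ch <- strsplit(cods[i], "")[[1]]
    hit <- stats::runif(3) < rate
    if (!any(hit)) next
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
    cand <- paste(ch, collapse = "")
    if (!cand %in% STOP_CODONS) cods[i] <- cand
  }
  paste(cods, collapse = "")
}

mutate_plain_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
  paste(ch, collapse = "")
}

# negative-binomial draw; dispersion 0 = deterministic mean
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(round(mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

rlen <- function(n, meanlog, sdlog, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rlnorm(n, meanlog, sdlog))))
}

place_seq <- function(chars, start, end, strand, seq) {
  g <- if (strand == "-") revcomp(seq) else seq
  chars[start:end] <- strsplit(g, "")[[1]]
  chars
}

# genomic interval of the -10 hexamer (offsets -12..-7 relative to TSS)
minus10_interval <- function(tss, strand) {
  if (strand == "+") c(tss - 12L, tss - 7L) else c(tss + 7L, tss + 12L)
}

place_minus10 <- function(chars, tss, strand) {
  iv <- minus10_interval(tss, strand)
  place_seq(chars, iv[1], iv[2], strand, "TATAAT")
}

#' Generate the two-strain genome pair with planted ground truth
#'
#' Lays out gene, sRNA and free-standing transcript loci on a shared
#' coordinate frame, writes the two genome sequences (ortholog gene bodies
#' are copies at the configured per-site substitution rate; conserved
#' intergenic elements and promoter windows are copied; everything else is
#' independent random background), and plants every TSS with its class,
#' extent, UTRs, expression parameters and conservation partner.
#'
#' @param config A [sim_config()].
#' @return List of class `dtx_sim`: `genomes` (a/b [dtx_genome()]s), `genes`
#'   (a/b annotation data.frames), `orthologs`, `truth` (list of tss /
#'   actuatons / promoter_snps / leaderless data.frames) and `config`.
#' @export
generate_genome_pair <- function(config = sim_config()) {
  set.seed(config$seed)
  conds <- dtx_conditions()
  ncond <- length(conds)
  nda <- ceiling(config$n_actuaton_decoys / 2)     # decoy: gene with own gTSS
  ndb <- config$n_actuaton_decoys - nda            # decoy: free sRNA, no read-through

  # ---- slot bookkeeping -------------------------------------------------
  slots <- list()
  add_slot <- function(type, ...) slots[[length(slots) + 1L]] <<- list(type = type, ...)
  for (i in seq_len(config$n_ortholog_genes)) add_slot("ortho_gene", idx = i)
  for (i in seq_len(config$n_strain_specific_genes)) {
    kind <- if (i <= config$n_actuatons) "actuaton"
            else if (i <= config$n_actuatons + nda) "decoy_a"
            else "plain"
    add_slot("spec_gene_a", idx = i, arrangement = kind)
    add_slot("spec_gene_b", idx = i, arrangement = kind)
  }
  for (i in seq_len(ndb)) { add_slot("decoy_srna_a", idx = i); add_slot("decoy_srna_b", idx = i) }
  for (i in seq_len(config$n_ntss)) {
    shared <- i <= config$n_conserved[["n"]]
    add_slot("ntu", idx = i, shared = shared, strain = "a")
    if (!shared) add_slot("ntu", idx = i, strain = "b")
  }
  slots <- slots[sample(length(slots))]

  # ---- per-slot geometry -------------------------------------------------
  cursor <- 200L
  for (k in seq_along(slots)) {
    sl <- slots[[k]]
    sl$strand <- sample(c("+", "-"), 1L)
    if (sl$type %in% c("ortho_gene", "spec_gene_a", "spec_gene_b")) {
      sl$n_codons <- if (sl$type == "ortho_gene") sample(180L:260L, 1L)
                     else sample(80L:200L, 1L)
      sl$gene_len <- 3L * sl$n_codons
      sl$utr5 <- rlen(1, config$utr5_meanlog, config$utr5_sdlog, 15, 120)
      sl$utr3 <- rlen(1, config$utr3_meanlog, config$utr3_sdlog, 20, 250)
      arr <- sl$arrangement %||% "plain"
      if (arr %in% c("actuaton", "decoy_a")) {
        sl$srna_len <- sample(config$srna_len_range[1]:config$srna_len_range[2], 1L)
        sl$gene_gap <- sample(60:200, 1L)
        span <- sl$srna_len + sl$gene_gap + sl$gene_len + sl$utr3
      } else {
        span <- sl$utr5 + sl$gene_len + sl$utr3
      }
      sl$span <- span + 90L      # decay tail (<= 5*decay_len) + separation
    } else if (sl$type %in% c("decoy_srna_a", "decoy_srna_b")) {
      sl$srna_len <- sample(config$srna_len_range[1]:config$srna_len_range[2], 1L)
      sl$span <- sl$srna_len + 90L
    } else {
      sl$len <- sample(config$ntu_len_range[1]:config$ntu_len_range[2], 1L)
      sl$span <- sl$len + 90L
    }
    gap <- 100L + sample(0:100, 1L)   # zero-coverage gap always > max_gap
    sl$start <- cursor + 60L   # promoter margin
    sl$end <- sl$start + sl$span - 1L
    cursor <- sl$end + gap
    slots[[k]] <- sl
  }
  if (cursor + 200L > config$genome_length)
    stopf("infeasible packing: features need %d nt but genome_length is %d",
          cursor + 200L, config$genome_length)

  # ---- gene tables -------------------------------------------------------
  genes_a <- list(); genes_b <- list(); orthologs <- list()
  srnas_a <- list(); srnas_b <- list()
  ortho_slots <- which(vapply(slots, function(s) s$type == "ortho_gene", logical(1)))
  gene_row <- function(id, sl, s0) {
    # gene body placed after utr5 (plain) or after sRNA+gap (compound), in
    # transcription direction from the slot's 5' edge
    arr <- sl$arrangement %||% "plain"
    lead <- if (arr %in% c("actuaton", "decoy_a")) sl$srna_len + sl$gene_gap else sl$utr5
    if (sl$strand == "+") {
      gs <- sl$start + lead; ge <- gs + sl$gene_len - 1L
    } else {
      ge <- sl$end - lead; gs <- ge - sl$gene_len + 1L
    }
    data.frame(gene_id = id, seq_id = s0, start = gs, end = ge,
               strand = sl$strand, kind = "protein_coding", product = "hypothetical protein",
               stringsAsFactors = FALSE)
  }
  for (j in seq_along(ortho_slots)) {
    sl <- slots[[ortho_slots[j]]]
    ida <- sprintf("SYNA_%04d", j); idb <- sprintf("SYNB_%04d", j)
    genes_a[[length(genes_a) + 1L]] <- gene_row(ida, sl, "chrA")
    genes_b[[length(genes_b) + 1L]] <- gene_row(idb, sl, "chrB")
    orthologs[[length(orthologs) + 1L]] <- data.frame(gene_a = ida, gene_b = idb,
                                                      slot = ortho_slots[j],
                                                      stringsAsFactors = FALSE)
  }
  spec_a <- which(vapply(slots, function(s) s$type == "spec_gene_a", logical(1)))
  spec_b <- which(vapply(slots, function(s) s$type == "spec_gene_b", logical(1)))
  for (j in seq_along(spec_a))
    genes_a[[length(genes_a) + 1L]] <- gene_row(sprintf("SYNA_S%03d", j), slots[[spec_a[j]]], "chrA")
  for (j in seq_along(spec_b))
    genes_b[[length(genes_b) + 1L]] <- gene_row(sprintf("SYNB_S%03d", j), slots[[spec_b[j]]], "chrB")
  genes_a <- do.call(rbind, genes_a); genes_b <- do.call(rbind, genes_b)
  orthologs <- do.call(rbind, orthologs)

  # ---- TSS planting ------------------------------------------------------
  z_draw <- function() stats::rnorm(ncond, 0, config$condition_effect_sd)
  z_partner <- function(z) {
    r <- config$inter_strain_cor
    r * z + sqrt(1 - r^2) * stats::rnorm(ncond, 0, config$condition_effect_sd)
  }
  tss <- list()
  add_tss <- function(strain, id, pos, strand, class, gene_id, baseline, z,
                      tu_start, tu_end, role = "regular", conserved = FALSE,
                      partner_id = NA_character_, utr5 = NA_real_, utr3 = NA_real_,
                      drop_pos = NA_integer_, readthrough = NA_real_) {
    row <- data.frame(strain = strain, id = id, position = as.integer(pos),
                      strand = strand, class = class, gene_id = gene_id,
                      baseline = baseline, tu_start = as.integer(tu_start),
                      tu_end = as.integer(tu_end), role = role,
                      conserved = conserved, partner_id = partner_id,
                      utr5 = utr5, utr3 = utr3, drop_pos = drop_pos,
                      readthrough = readthrough, stringsAsFactors = FALSE)
    for (ci in seq_len(ncond)) row[[paste0("rate_", conds[ci])]] <- baseline * 2^z[ci]
    tss[[length(tss) + 1L]] <<- row
  }
  new_baseline <- function(boost = 0, sdlog = config$baseline_sdlog)
    stats::rlnorm(1, config$baseline_meanlog + boost, sdlog)

  # gTSS roles over ortholog slots
  n_cons_g <- config$n_conserved[["g"]]
  need_a_only <- config$n_gtss - n_cons_g - config$n_promoter_snp_cases - nda
  need_b_only <- config$n_gtss - n_cons_g - nda
  perm <- sample(nrow(orthologs))
  role_g <- rep("none", nrow(orthologs))
  role_g[perm[seq_len(n_cons_g)]] <- "conserved"
  off <- n_cons_g
  role_g[perm[off + seq_len(config$n_promoter_snp_cases)]] <- "snp"
  off <- off + config$n_promoter_snp_cases
  role_g[perm[off + seq_len(need_a_only)]] <- "a_only"
  off <- off + need_a_only
  role_g[perm[off + seq_len(need_b_only)]] <- "b_only"

  leaderless_pool <- which(role_g == "conserved")[seq_len(config$n_leaderless)]
  leaderless <- list(); promoter_snps <- list()

  gtss_of <- function(gene, sl, utr5) {
    feat5 <- feat_5p(gene$start, gene$end, gene$strand)
    shift_up(feat5, utr5, gene$strand)
  }
  tu_extent <- function(gene, tsspos, utr3) {
    if (gene$strand == "+") c(tsspos, gene$end + utr3) else c(gene$start - utr3, tsspos)
  }

  gid <- 0L
  for (j in seq_len(nrow(orthologs))) {
    if (role_g[j] == "none") next
    sl <- slots[[orthologs$slot[j]]]
    ga <- genes_a[genes_a$gene_id == orthologs$gene_a[j], ]
    gb <- genes_b[genes_b$gene_id == orthologs$gene_b[j], ]
    is_ll <- j %in% leaderless_pool
    utr5 <- if (is_ll) sample(0:10, 1L) else sl$utr5
    pos_a <- gtss_of(ga, sl, utr5); pos_b <- gtss_of(gb, sl, utr5)
    ext_a <- tu_extent(ga, pos_a, sl$utr3); ext_b <- tu_extent(gb, pos_b, sl$utr3)
    base <- new_baseline(); za <- z_draw()
    gid <- gid + 1L
    if (role_g[j] == "conserved") {
      sf <- stats::rlnorm(1, 0, 0.3)
      add_tss("a", sprintf("gT%03da", gid), pos_a, sl$strand, "g", ga$gene_id,
              base, za, ext_a[1], ext_a[2], conserved = TRUE,
              partner_id = sprintf("gT%03db", gid), utr5 = utr5, utr3 = sl$utr3)
      add_tss("b", sprintf("gT%03db", gid), pos_b, sl$strand, "g", gb$gene_id,
              base * sf, z_partner(za), ext_b[1], ext_b[2], conserved = TRUE,
              partner_id = sprintf("gT%03da", gid), utr5 = utr5, utr3 = sl$utr3)
      if (is_ll) {
        leaderless[[length(leaderless) + 1L]] <-
          data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id, offset = utr5,
                     stringsAsFactors = FALSE)
      }
    } else if (role_g[j] == "snp") {
      add_tss("a", sprintf("gT%03da", gid), pos_a, sl$strand, "g", ga$gene_id,
              base, za, ext_a[1], ext_a[2], role = "snp_active",
              utr5 = utr5, utr3 = sl$utr3)
      promoter_snps[[length(promoter_snps) + 1L]] <-
        data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id,
                   tss_a = pos_a, tss_b_expected = pos_b, strand = sl$strand,
                   stringsAsFactors = FALSE)
    } else if (role_g[j] == "a_only") {
      add_tss("a", sprintf("gT%03da", gid), pos_a, sl$strand, "g", ga$gene_id,
              base, za, ext_a[1], ext_a[2], utr5 = utr5, utr3 = sl$utr3)
    } else {
      add_tss("b", sprintf("gT%03db", gid), pos_b, sl$strand, "g", gb$gene_id,
              base, za, ext_b[1], ext_b[2], utr5 = utr5, utr3 = sl$utr3)
    }
  }

  # aTSS / iTSS over ortholog gene bodies -------------------------------
  body_pos <- function(gene, cls) {
    # sense-direction offset range within the gene body
    lo <- if (cls == "a") 120L else 150L
    off <- sample(lo:(gene$end - gene$start - 20L), 1L)
    if (gene$strand == "+") gene$start + off else gene$end - off
  }
  long_enough <- (genes_a$end - genes_a$start + 1L)[match(orthologs$gene_a, genes_a$gene_id)] >= 520L
  pool <- sample(which(long_enough))
  need_hosts <- config$n_conserved[["a"]] + 2L * (config$n_atss - config$n_conserved[["a"]]) +
    config$n_conserved[["i"]] + 2L * (config$n_itss - config$n_conserved[["i"]])
  if (length(pool) < need_hosts)
    stopf("not enough long ortholog genes (%d) to host %d internal/antisense TSSs",
          length(pool), need_hosts)
  plant_ai <- function(cls, n_total, n_cons, pool, gid0) {
    used <- 0L
    ext_len <- function() sample(100:220, 1L)
    for (i in seq_len(n_cons)) {
      used <- used + 1L; j <- pool[used]
      ga <- genes_a[genes_a$gene_id == orthologs$gene_a[j], ]
      gb <- genes_b[genes_b$gene_id == orthologs$gene_b[j], ]
      pos_a <- body_pos(ga, cls)
      off_sense <- if (ga$strand == "+") pos_a - ga$start else ga$end - pos_a
      delta <- sample(-6:6, 1L)
      pos_b <- (if (gb$strand == "+") gb$start + off_sense else gb$end - off_sense) + delta
      s_a <- if (cls == "a") other_strand(ga$strand) else ga$strand
      L1 <- ext_len(); L2 <- ext_len()
      base <- new_baseline(if (cls == "i") 1.0 else 0.3); za <- z_draw()
      e_a <- if (s_a == "+") c(pos_a, pos_a + L1) else c(pos_a - L1, pos_a)
      e_b <- if (s_a == "+") c(pos_b, pos_b + L2) else c(pos_b - L2, pos_b)
      add_tss("a", sprintf("%sT%03da", cls, gid0 + i), pos_a, s_a, cls, ga$gene_id,
              base, za, e_a[1], e_a[2], conserved = TRUE,
              partner_id = sprintf("%sT%03db", cls, gid0 + i))
      add_tss("b", sprintf("%sT%03db", cls, gid0 + i), pos_b, s_a, cls, gb$gene_id,
              base * stats::rlnorm(1, 0, 0.3), z_partner(za), e_b[1], e_b[2],
              conserved = TRUE, partner_id = sprintf("%sT%03da", cls, gid0 + i))
    }
    for (strain in c("a", "b")) {
      for (i in seq_len(n_total - n_cons)) {
        used <- used + 1L; j <- pool[used]
        gg <- if (strain == "a") genes_a[genes_a$gene_id == orthologs$gene_a[j], ]
              else genes_b[genes_b$gene_id == orthologs$gene_b[j], ]
        pos <- body_pos(gg, cls)
        s <- if (cls == "a") other_strand(gg$strand) else gg$strand
        L1 <- ext_len()
        e <- if (s == "+") c(pos, pos + L1) else c(pos - L1, pos)
        add_tss(strain, sprintf("%sT%03d%s", cls, gid0 + n_cons + i, strain), pos, s,
                cls, gg$gene_id, new_baseline(if (cls == "i") 1.0 else 0.3),
                z_draw(), e[1], e[2])
      }
    }
    used
  }
  used <- plant_ai("a", config$n_atss, config$n_conserved[["a"]], pool, 0L)
  pool2 <- pool[-seq_len(used)]
  plant_ai("i", config$n_itss, config$n_conserved[["i"]], pool2, 1000L)

  # nTSS over free-standing loci ----------------------------------------
  ntu_slots <- which(vapply(slots, function(s) s$type == "ntu", logical(1)))
  special_done <- FALSE
  for (k in ntu_slots) {
    sl <- slots[[k]]
    pos5 <- if (sl$strand == "+") sl$start else sl$start + sl$len - 1L
    ext <- if (sl$strand == "+") c(pos5, pos5 + sl$len - 1L) else c(sl$start, pos5)
    if (isTRUE(sl$shared)) {
      if (!special_done) {   # iron-depletion regulator: -Fe times special_uef
        # moderate baseline so the induced library stays composition-stable
        z <- rep(0, ncond); z[match("-Fe", conds)] <- log2(config$special_uef)
        base <- exp(config$baseline_meanlog) / 10
        add_tss("a", sprintf("nT%03da", sl$idx), pos5, sl$strand, "n", NA_character_,
                base, z, ext[1], ext[2], role = "fe_special", conserved = TRUE,
                partner_id = sprintf("nT%03db", sl$idx))
        add_tss("b", sprintf("nT%03db", sl$idx), pos5, sl$strand, "n", NA_character_,
                base, z, ext[1], ext[2], role = "fe_special", conserved = TRUE,
                partner_id = sprintf("nT%03da", sl$idx))
        special_done <- TRUE
      } else {
        base <- new_baseline(); za <- z_draw()
        add_tss("a", sprintf("nT%03da", sl$idx), pos5, sl$strand, "n", NA_character_,
                base, za, ext[1], ext[2], conserved = TRUE,
                partner_id = sprintf("nT%03db", sl$idx))
        add_tss("b", sprintf("nT%03db", sl$idx), pos5, sl$strand, "n", NA_character_,
                base * stats::rlnorm(1, 0, 0.3), z_partner(za), ext[1], ext[2],
                conserved = TRUE, partner_id = sprintf("nT%03da", sl$idx))
      }
    } else {
      add_tss(sl$strain, sprintf("nT%03d%s", sl$idx, sl$strain), pos5, sl$strand,
              "n", NA_character_, new_baseline(), z_draw(), ext[1], ext[2])
    }
  }

  # actuatons and decoys -------------------------------------------------
  actuatons <- list()
  for (strain in c("a", "b")) {
    spec_idx <- if (strain == "a") spec_a else spec_b
    gtab <- if (strain == "a") genes_a else genes_b
    for (j in seq_along(spec_idx)) {
      sl <- slots[[spec_idx[j]]]
      arr <- sl$arrangement
      gene_id <- sprintf("SYN%s_S%03d", toupper(strain), j)
      gg <- gtab[gtab$gene_id == gene_id, ]
      if (arr %in% c("actuaton", "decoy_a")) {
        # sRNA at the slot's 5' edge, gene downstream of the drop
        if (sl$strand == "+") {
          tsspos <- sl$start; drop <- sl$start + sl$srna_len - 1L
          tu_end <- gg$end + sl$utr3; ext <- c(tsspos, tu_end)
          srna_iv <- c(tsspos, drop)
        } else {
          tsspos <- sl$end; drop <- sl$end - sl$srna_len + 1L
          tu_end <- gg$start - sl$utr3; ext <- c(tu_end, tsspos)
          srna_iv <- c(drop, tsspos)
        }
        f <- stats::runif(1, config$readthrough_range[1], config$readthrough_range[2])
        add_tss(strain, sprintf("act%02d%s", j, strain), tsspos, sl$strand,
                "srna", gene_id, new_baseline(2.5, 0.25), z_draw(), ext[1], ext[2],
                role = if (arr == "actuaton") "actuaton" else "decoy_a",
                drop_pos = drop, readthrough = f)
        srna_id <- sprintf("sR%s%02d", strain, j)
        srow <- data.frame(gene_id = srna_id, seq_id = gg$seq_id,
                           start = srna_iv[1], end = srna_iv[2], strand = sl$strand,
                           kind = "known_sRNA", product = "small regulatory RNA",
                           stringsAsFactors = FALSE)
        if (strain == "a") srnas_a[[length(srnas_a) + 1L]] <- srow
        else srnas_b[[length(srnas_b) + 1L]] <- srow
        if (arr == "decoy_a") {
          # downstream gene gets its own gTSS between drop and gene start
          u5 <- min(sl$utr5, sl$gene_gap - 20L)
          own <- gtss_of(gg, sl, u5)
          oe <- tu_extent(gg, own, sl$utr3)
          # the decoy promoter is as strong as the sRNA's, so it reliably
          # passes the start/coverage ratio despite the sRNA read-through
          add_tss(strain, sprintf("dgT%02d%s", j, strain), own, sl$strand, "g",
                  gene_id, new_baseline(2.5, 0.25), z_draw(), oe[1], oe[2],
                  role = "decoy_target_gtss", utr5 = u5, utr3 = sl$utr3)
        }
        actuatons[[length(actuatons) + 1L]] <-
          data.frame(strain = strain, tss = tsspos, strand = sl$strand,
                     srna_start = srna_iv[1], srna_end = srna_iv[2],
                     gene_id = gene_id, readthrough = f,
                     kind = if (arr == "actuaton") "actuaton" else "decoy_own_gtss",
                     stringsAsFactors = FALSE)
      }
    }
    # free-standing sRNA decoys
    dec_idx <- which(vapply(slots, function(s)
      s$type == paste0("decoy_srna_", strain), logical(1)))
    for (j in seq_along(dec_idx)) {
      sl <- slots[[dec_idx[j]]]
      if (sl$strand == "+") { tsspos <- sl$start; ext <- c(sl$start, sl$start + sl$srna_len - 1L) }
      else { tsspos <- sl$end; ext <- c(sl$end - sl$srna_len + 1L, sl$end) }
      add_tss(strain, sprintf("dsr%02d%s", j, strain), tsspos, sl$strand, "srna",
              NA_character_, new_baseline(2.5, 0.25), z_draw(), ext[1], ext[2],
              role = "decoy_free_srna")
      srna_id <- sprintf("sRd%s%02d", strain, j)
      srow <- data.frame(gene_id = srna_id, seq_id = if (strain == "a") "chrA" else "chrB",
                         start = ext[1], end = ext[2], strand = sl$strand,
                         kind = "known_sRNA", product = "small regulatory RNA",
                         stringsAsFactors = FALSE)
      if (strain == "a") srnas_a[[length(srnas_a) + 1L]] <- srow
      else srnas_b[[length(srnas_b) + 1L]] <- srow
      actuatons[[length(actuatons) + 1L]] <-
        data.frame(strain = strain, tss = tsspos, strand = sl$strand,
                   srna_start = ext[1], srna_end = ext[2], gene_id = NA_character_,
                   readthrough = 0, kind = "decoy_free_srna", stringsAsFactors = FALSE)
    }
  }
  tss <- do.call(rbind, tss)
  rownames(tss) <- NULL

  # ---- genome sequences --------------------------------------------------
  L <- config$genome_length
  chA <- sample(BASES, L, replace = TRUE)
  chB <- sample(BASES, L, replace = TRUE)
  gene_seqs <- list()
  for (j in seq_len(nrow(genes_a))) {
    g <- genes_a[j, ]
    sq <- random_gene_seq((g$end - g$start + 1L) / 3L)
    gene_seqs[[g$gene_id]] <- sq
    chA <- place_seq(chA, g$start, g$end, g$strand, sq)
  }
  for (j in seq_len(nrow(genes_b))) {
    g <- genes_b[j, ]
    oa <- orthologs$gene_a[match(g$gene_id, orthologs$gene_b)]
    sq <- if (!is.na(oa)) mutate_gene_seq(gene_seqs[[oa]], config$substitution_rate)
          else random_gene_seq((g$end - g$start + 1L) / 3L)
    chB <- place_seq(chB, g$start, g$end, g$strand, sq)
  }
  # conserved free-standing loci: copy with substitutions (no indels)
  for (k in ntu_slots) {
    sl <- slots[[k]]
    if (!isTRUE(sl$shared)) next
    lo <- max(1L, sl$start - 60L); hi <- min(L, sl$start + sl$len + 40L)
    seg <- paste(chA[lo:hi], collapse = "")
    chB <- place_seq(chB, lo, hi, "+", mutate_plain_seq(seg, config$substitution_rate))
  }
  # promoter hexamers for intergenic TSSs; copied windows for conserved ones
  inter <- tss$class %in% c("g", "n", "srna")
  for (j in which(inter & tss$strain == "a")) chA <- place_minus10(chA, tss$position[j], tss$strand[j])
  for (j in which(inter & tss$strain == "b")) chB <- place_minus10(chB, tss$position[j], tss$strand[j])
  for (j in which(inter & tss$strain == "a" & tss$conserved & tss$class == "g")) {
    p <- tss$position[j]
    win <- if (tss$strand[j] == "+") c(p - 50L, p - 1L) else c(p + 1L, p + 50L)
    chB[win[1]:win[2]] <- chA[win[1]:win[2]]
  }
  # promoter-SNP cases: copy the window, then one substitution in the -10 box
  if (length(promoter_snps)) {
    promoter_snps <- do.call(rbind, promoter_snps)
    promoter_snps$snp_offset <- NA_integer_
    promoter_snps$hexamer_a <- NA_character_; promoter_snps$hexamer_b <- NA_character_
    for (j in seq_len(nrow(promoter_snps))) {
      p <- promoter_snps$tss_a[j]; s <- promoter_snps$strand[j]
      win <- if (s == "+") c(p - 50L, p - 1L) else c(p + 1L, p + 50L)
      chB[win[1]:win[2]] <- chA[win[1]:win[2]]
      iv <- minus10_interval(p, s)
      mutpos <- sample(iv[1]:iv[2], 1L)
      chB[mutpos] <- sample(setdiff(BASES, chB[mutpos]), 1L)
      promoter_snps$snp_offset[j] <- if (s == "+") mutpos - p else p - mutpos
      hex <- function(ch) {
        h <- paste(ch[iv[1]:iv[2]], collapse = "")
        if (s == "-") revcomp(h) else h
      }
      promoter_snps$hexamer_a[j] <- hex(chA); promoter_snps$hexamer_b[j] <- hex(chB)
    }
  } else promoter_snps <- data.frame()

  genes_a <- rbind(genes_a, do.call(rbind, srnas_a))
  genes_b <- rbind(genes_b, do.call(rbind, srnas_b))
  truth <- list(tss = tss,
                actuatons = if (length(actuatons)) do.call(rbind, actuatons) else data.frame(),
                promoter_snps = promoter_snps,
                leaderless = if (length(leaderless)) do.call(rbind, leaderless) else data.frame())
  structure(list(config = config,
                 genomes = list(a = dtx_genome("strainA", "chrA", paste(chA, collapse = "")),
                                b = dtx_genome("strainB", "chrB", paste(chB, collapse = ""))),
                 genes = list(a = genes_a, b = genes_b),
                 orthologs = orthologs[, c("gene_a", "gene_b")],
                 truth = truth),
            class = "dtx_sim")
}
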