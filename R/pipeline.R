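# End-to-end orchestration: per-strain analysis (scale -> call primary ->
# correct -> TSS set -> segment -> classify -> UTRs/leaderless -> UEF) and
# the comparative stage (conservation per class, promoter divergence,
# ortholog expression clustering and fold-change correlation, actuatons).

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the single-strain analysis stage
#'
#' Reads one strain's fixture inputs (FASTA genome, GFF3 annotation, library
#' manifest with bedGraph tracks), normalizes the ten treated libraries,
#' calls TSSs, segments and classifies TUs, computes UTRs, leaderless genes,
#' UEF statistics and actuaton calls, and writes all result tables plus a
#' run log.
#'
#' @param fixture_dir Directory holding the strain inputs
#'   ([simulate_fixture()] layout).
#' @param strain `"a"` or `"b"`.
#' @param out_dir Output directory for tables and the log.
#' @param th,seg_params,act_params Parameter objects.
#' @return List (class `dtx_strain_result`): genome, genes, tss, tus, uef,
#'   leaderless, actuatons, untreated (scaled library), lib_sizes.
#' @export
run_single <- function(fixture_dir, strain, out_dir,
                       th = dtx_thresholds(),
                       seg_params = dtx_segmentation_params(),
                       act_params = dtx_actuaton_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sid <- if (strain == "a") "strainA" else "strainB"
  logf <- file(file.path(out_dir, paste0("run_", sid, ".log")), open = "wt")
  on.exit(close(logf))
  stage <- "read inputs"
  res <- tryCatch({
    genome <- read_genome(file.path(fixture_dir, paste0(sid, ".fasta")), sid)
    genes <- read_annotation(file.path(fixture_dir, paste0(sid, ".gff3")))
    libs <- read_fixture_libraries(fixture_dir, strain, genome$length)
    treated <- Filter(function(l) l$treated, libs)
    untreated <- Filter(function(l) !l$treated, libs)
    if (!length(untreated))
      stopf("no untreated library in manifest %s",
            file.path(fixture_dir, paste0("libraries_", sid, ".tsv")))
    untreated <- untreated[[1]]
    log_line(logf, "[%s] genome %d nt, %d genes, %d treated + 1 untreated libraries",
             sid, genome$length, nrow(genes), length(treated))
    log_line(logf, "[%s] thresholds: scale=%g min_starts=%g ratio>%g overlap>=%d offset<=%d",
             sid, th$scale_target, th$min_read_starts, th$min_start_coverage_ratio,
             th$antisense_overlap_min, th$ortholog_tss_offset_max)

    stage <- "normalize"
    nlibs <- normalize_libraries(treated, th)
    log_line(logf, "[%s] correction factors: %s", sid,
             paste(sprintf("%s=%.3f", vapply(nlibs, `[[`, character(1), "condition"),
                           vapply(nlibs, `[[`, numeric(1), "correction_factor")),
                   collapse = " "))
    stage <- "TSS set"
    tss <- build_tss_set(nlibs, raw_libs = treated, strain = sid)
    log_line(logf, "[%s] %d TSSs called", sid, nrow(tss))

    stage <- "TU segmentation/classification"
    unt_scaled <- scale_library(untreated, th)
    bt <- build_tus(tss, unt_scaled$tracks$coverage, genes, seg_params, th)
    log_line(logf, "[%s] TU classes: %s", sid,
             paste(sprintf("%s=%d", names(table(bt$tus$class)), table(bt$tus$class)),
                   collapse = " "))
    stage <- "leaderless"
    ll <- detect_leaderless(bt$tss, genes, th)
    log_line(logf, "[%s] %d leaderless genes", sid, nrow(ll))
    stage <- "UEF"
    lib_sizes <- stats::setNames(vapply(treated, `[[`, numeric(1), "raw_total"),
                                 vapply(treated, `[[`, character(1), "condition"))
    ueft <- uef_table(bt$tus, lib_sizes = lib_sizes[dtx_conditions()], th = th)
    stage <- "actuatons"
    acts <- detect_actuatons(bt$tus, bt$tss, genes, unt_scaled$tracks$coverage, act_params)
    log_line(logf, "[%s] %d actuaton calls", sid, nrow(acts))

    stage <- "write tables"
    write_table(bt$tss, file.path(out_dir, paste0("tss_", sid, ".tsv")))
    write_table(bt$tus, file.path(out_dir, paste0("tu_", sid, ".tsv")))
    write_table(ueft, file.path(out_dir, paste0("uef_", sid, ".tsv")))
    write_table(ll, file.path(out_dir, paste0("leaderless_", sid, ".tsv")))
    write_table(acts, file.path(out_dir, paste0("actuatons_", sid, ".tsv")))
    list(strain = strain, sid = sid, genome = genome, genes = genes,
         tss = bt$tss, tus = bt$tus, uef = ueft, leaderless = ll,
         actuatons = acts, untreated = unt_scaled, lib_sizes = lib_sizes)
  }, error = function(e) stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  class(res) <- "dtx_strain_result"
  res
}

# TU representing a gene's transcription: the gene-covering TU with this gene
# as first member (preferred) or any covering TU
tu_of_gene <- function(tus, gene_id) {
  g <- tus[grepl("g", tus$label, fixed = TRUE) & tus$member_genes != "", , drop = FALSE]
  first <- vapply(strsplit(g$member_genes, ",", fixed = TRUE), `[`, character(1), 1L)
  k <- which(first == gene_id)
  if (length(k)) return(g[k[1], , drop = FALSE])
  k <- which(vapply(strsplit(g$member_genes, ",", fixed = TRUE),
                    function(m) gene_id %in% m, logical(1)))
  if (length(k)) g[k[1], , drop = FALSE] else NULL
}

promoter_scan_one_side <- function(res_with, res_without, gene_with, gene_without,
                                   window = 50L) {
  tu <- tu_of_gene(res_with$tus, gene_with)
  if (is.null(tu)) return(NULL)
  gw <- res_with$genes[res_with$genes$gene_id == gene_with, ]
  go <- res_without$genes[res_without$genes$gene_id == gene_without, ]
  d <- abs(feat_5p(gw$start, gw$end, gw$strand) - tu$tss_position)
  expected <- shift_up(feat_5p(go$start, go$end, go$strand), d, go$strand)
  rep <- promoter_divergence(res_with$genome, tu$tss_position, tu$strand,
                             res_without$genome, expected, go$strand, window)
  data.frame(gene_with = gene_with, gene_without = gene_without,
             tss = tu$tss_position, expected_partner_pos = expected,
             verdict = rep$verdict,
             n_mismatches = length(rep$mismatch_offsets),
             minus10_a = rep$minus10_a %||% NA_character_,
             minus10_b = rep$minus10_b %||% NA_character_,
             minus10_mismatch = rep$minus10_mismatch,
             window_a = rep$window_a %||% NA_character_,
             window_b = rep$window_b %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Run the comparative stage on two strain results
#'
#' Computes cross-strain conservation for every TSS class, promoter
#' -10-element divergence of strain-specific gTSSs, the combined k-means
#' clustering of ortholog expression profiles, the cross-strain fold-change
#' correlation, and joins the per-strain actuaton calls; writes all
#' comparative tables plus a plain-text summary.
#'
#' @param res_a,res_b [run_single()] results.
#' @param orthologs Ortholog table (gene_a / gene_b).
#' @param out_dir Output directory.
#' @param th Thresholds.
#' @param align_params [dtx_align_params()] for nTU conservation.
#' @param seed Seed for the k-means clustering.
#' @return List (class `dtx_compare_result`): conservation_g/a/i/n tables,
#'   promoter_reports, clustering, fc (scatter + r2), summary.
#' @export
run_compare <- function(res_a, res_b, orthologs, out_dir,
                        th = dtx_thresholds(),
                        align_params = dtx_align_params(),
                        seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  missing_a <- setdiff(orthologs$gene_a, res_a$genes$gene_id)
  missing_b <- setdiff(orthologs$gene_b, res_b$genes$gene_id)
  if (length(missing_a) || length(missing_b))
    stopf("ortholog table references unknown genes: %s",
          paste(c(missing_a, missing_b), collapse = ","))

  alns <- ortholog_alignments(orthologs, res_a$genes, res_b$genes,
                              res_a$genome, res_b$genome)
  cons_g <- conserved_gtss(res_a$tus, res_b$tus, orthologs)
  cons_a <- conserved_internal_antisense_tss(res_a$tss, res_b$tss, res_a$genes,
                                             res_b$genes, alns, "a", th)
  cons_i <- conserved_internal_antisense_tss(res_a$tss, res_b$tss, res_a$genes,
                                             res_b$genes, alns, "i", th)
  idx_b <- build_subject_index(res_b$genome$seq, align_params$word)
  cons_n <- conserved_ntss(res_a$tus, res_a$genome, idx_b, res_b$tus, th, align_params)

  # promoter scans for strain-specific gTSSs
  reports <- list()
  for (k in which(cons_g$verdict == "strain_specific_a")) {
    r <- promoter_scan_one_side(res_a, res_b, cons_g$gene_a[k], cons_g$gene_b[k])
    if (!is.null(r)) { r$strain_with_tss <- "a"; reports[[length(reports) + 1L]] <- r }
  }
  for (k in which(cons_g$verdict == "strain_specific_b")) {
    r <- promoter_scan_one_side(res_b, res_a, cons_g$gene_b[k], cons_g$gene_a[k])
    if (!is.null(r)) { r$strain_with_tss <- "b"; reports[[length(reports) + 1L]] <- r }
  }
  reports <- if (length(reports)) do.call(rbind, reports) else data.frame()

  # ortholog gTU expression pairs
  conds <- dtx_conditions()
  pa <- list(); pb <- list(); pair_genes <- character()
  for (k in which(cons_g$verdict == "conserved")) {
    ta <- tu_of_gene(res_a$tus, cons_g$gene_a[k])
    tb <- tu_of_gene(res_b$tus, cons_g$gene_b[k])
    if (is.null(ta) || is.null(tb)) next
    pa[[length(pa) + 1L]] <- as.numeric(ta[1, conds])
    pb[[length(pb) + 1L]] <- as.numeric(tb[1, conds])
    pair_genes <- c(pair_genes, cons_g$gene_a[k])
  }
  profiles_a <- do.call(rbind, pa); profiles_b <- do.call(rbind, pb)
  colnames(profiles_a) <- conds; colnames(profiles_b) <- conds
  clus <- cluster_ortholog_profiles(profiles_a, profiles_b, k = th$kmeans_k, seed = seed)
  fc <- pairwise_fc_correlation(profiles_a, profiles_b)

  summary <- list(
    n_ortholog_pairs = nrow(orthologs),
    n_conserved_gtss = sum(cons_g$verdict == "conserved"),
    n_strain_specific_gtss_a = sum(cons_g$verdict == "strain_specific_a"),
    n_strain_specific_gtss_b = sum(cons_g$verdict == "strain_specific_b"),
    n_conserved_atss = sum(cons_a$verdict == "conserved"),
    n_conserved_itss = sum(cons_i$verdict == "conserved"),
    n_conserved_ntu = sum(cons_n$verdict == "conserved_as_ntu"),
    n_ntu_other_class = sum(cons_n$verdict == "conserved_other_class"),
    same_cluster_fraction = clus$same_cluster_fraction,
    fc_r2 = fc$r2,
    n_actuatons_a = nrow(res_a$actuatons),
    n_actuatons_b = nrow(res_b$actuatons),
    n_minus10_divergent = if (nrow(reports)) sum(reports$minus10_mismatch, na.rm = TRUE) else 0L)

  write_table(cons_g, file.path(out_dir, "conservation_gtss.tsv"))
  write_table(cons_a, file.path(out_dir, "conservation_atss.tsv"))
  write_table(cons_i, file.path(out_dir, "conservation_itss.tsv"))
  write_table(cons_n, file.path(out_dir, "conservation_ntu.tsv"))
  if (nrow(reports)) write_table(reports, file.path(out_dir, "promoter_reports.tsv"))
  write_table(fc$scatter, file.path(out_dir, "fc_scatter.tsv"))
  writeLines(sprintf("%s\t%s", names(summary),
                     vapply(summary, function(x) format(x, digits = 6), character(1))),
             file.path(out_dir, "summary.txt"))
  structure(list(conservation_g = cons_g, conservation_a = cons_a,
                 conservation_i = cons_i, conservation_n = cons_n,
                 promoter_reports = reports, clustering = clus, fc = fc,
                 profiles = list(a = profiles_a, b = profiles_b, genes = pair_genes),
                 summary = summary),
            class = "dtx_compare_result")
}

#' Printed-count accounting of a double-comparative study
#'
#' Arithmetic identities over headline counts of a two-strain comparison:
#' the percentage of shared orthologs transcribed from a gTSS in both
#' strains, the percentage of gTUs whose complete arrangement is conserved,
#' and the per-strain unique (non-shared) gene counts.
#'
#' @param n_shared_orthologs Shared protein-coding genes.
#' @param n_expressed_both Orthologs with a gTSS in both strains.
#' @param n_gtu gTUs in the reference strain.
#' @param n_conserved_gtu Fully conserved gTUs.
#' @param n_protein_a,n_protein_b Protein-coding genes per strain.
#' @return List: pct_expressed_orthologs, pct_conserved_gtu,
#'   unique_genes_a, unique_genes_b.
#' @export
ortholog_accounting <- function(n_shared_orthologs, n_expressed_both,
                                n_gtu, n_conserved_gtu,
                                n_protein_a, n_protein_b) {
  list(pct_expressed_orthologs = 100 * n_expressed_both / n_shared_orthologs,
       pct_conserved_gtu = 100 * n_conserved_gtu / n_gtu,
       unique_genes_a = n_protein_a - n_shared_orthologs,
       unique_genes_b = n_protein_b - n_shared_orthologs)
}
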