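# Actuaton detection: TUs in which an abundant, discrete sRNA ends at a sharp
# coverage drop and reads through, at a substoichiometric level, into a
# downstream sense gene that has no gTSS of its own.

# coverage values along a TU in transcription order
tu_profile <- function(tu_start, tu_end, strand, coverage) {
  v <- coverage$values[tu_start:tu_end]
  if (strand == "-") rev(v) else v
}

#' Find the sRNA 3'-boundary coverage drop within a TU
#'
#' Scans downstream of the TSS for the most 5' position where the mean
#' coverage over the following `flank` nt is at most `max_drop_ratio` times
#' the mean over the preceding `flank` nt, within `max_srna_len` of the TSS.
#'
#' @param tu_start,tu_end,strand TU interval (1-based inclusive) and strand.
#' @param coverage Untreated-coverage [dtx_track()] on the TU strand.
#' @param params A [dtx_actuaton_params()].
#' @param flank Averaging window on each side of the candidate boundary (nt).
#' @return NULL if no drop; else list `offset` (sRNA length in nt),
#'   `position` (genomic position of the last sRNA nucleotide) and `ratio`.
#' @export
find_coverage_drop <- function(tu_start, tu_end, strand, coverage,
                               params = dtx_actuaton_params(), flank = 20L) {
  w <- tu_profile(tu_start, tu_end, strand, coverage)
  L <- length(w)
  if (L <= 2L * flank) return(NULL)
  cs <- cumsum(w)
  d_max <- min(params$max_srna_len, L - flank)
  ds <- flank:d_max
  before <- (cs[ds] - c(0, cs)[ds - flank + 1L]) / flank
  after <- (cs[ds + flank] - cs[ds]) / flank
  ratio <- ifelse(before > 0, after / before, Inf)
  hit <- which(ratio <= params$max_drop_ratio)
  if (!length(hit)) return(NULL)
  # refine the first qualifying region to its sharpest point (the boundary):
  # within one flank of the first hit, take the minimal ratio (earliest tie)
  win <- hit[1L]:min(hit[1L] + 2L * flank, length(ratio))
  best <- win[which.min(ratio[win])]
  d <- ds[best]
  pos <- if (strand == "+") tu_start + d - 1L else tu_end - d + 1L
  list(offset = d, position = pos, ratio = ratio[best])
}

# first-member genes of gene-covering TUs, per TU id
first_gtu_gene <- function(tus) {
  g <- tus[grepl("g", tus$label, fixed = TRUE) & tus$member_genes != "", , drop = FALSE]
  data.frame(tu_id = g$tu_id,
             gene = vapply(strsplit(g$member_genes, ",", fixed = TRUE), `[`, character(1), 1L),
             stringsAsFactors = FALSE)
}

#' Detect actuatons
#'
#' A call requires that (1) the segment between the TSS and the coverage drop
#' is sRNA-like — it overlaps an annotated known sRNA or no sense
#' protein-coding gene, (2) a sharp coverage drop exists within
#' `max_srna_len` of the TSS ([find_coverage_drop()]), (3) a sense
#' protein-coding gene starts downstream of the drop within
#' `gene_search_window` and inside the TU, (4) that gene has no gTSS of its
#' own (it is the first member gene of no other gene-covering TU), (5) the
#' TSS abundance is at or above the `min_abundance_percentile` percentile of
#' all TSSs, and (6) the read-through fraction (mean gene-body over mean
#' sRNA-body coverage) lies in `[min_readthrough, max_drop_ratio)`. A call
#' whose 5' segment is a plain 5' UTR (no sRNA annotation, TU covers the
#' gene from a gTSS) is flagged `utr_derived`.
#'
#' @param tus Classified TU table ([build_tus()]).
#' @param tss The matching classified TSS table (for abundance ranks).
#' @param genes Annotation data.frame (kinds `protein_coding` /
#'   `known_sRNA`).
#' @param coverage List of `"+"`/`"-"` untreated coverage [dtx_track()]s.
#' @param params A [dtx_actuaton_params()].
#' @return data.frame of calls: tu_id, tss_position, strand, srna_start,
#'   srna_end, drop_ratio, downstream_gene, readthrough_fraction,
#'   srna_abundance_rank, utr_derived.
#' @export
detect_actuatons <- function(tus, tss, genes, coverage,
                             params = dtx_actuaton_params()) {
  coding <- genes[genes$kind == "protein_coding", , drop = FALSE]
  srnas <- genes[genes$kind == "known_sRNA", , drop = FALSE]
  own_gtss_genes <- first_gtu_gene(tus)
  all_max <- tus$max_count
  out <- list()
  for (k in seq_len(nrow(tus))) {
    if (tus$end[k] - tus$start[k] + 1L <= 50L) next
    s <- tus$strand[k]
    drop <- find_coverage_drop(tus$start[k], tus$end[k], s, coverage[[s]], params)
    if (is.null(drop)) next
    srna_start <- if (s == "+") tus$start[k] else drop$position
    srna_end <- if (s == "+") drop$position else tus$end[k]
    # (1) the 5' segment must be sRNA-like
    has_srna_annot <- any(srnas$strand == s &
                            overlap_width(srna_start, srna_end, srnas$start, srnas$end) > 0L)
    overlaps_coding <- any(coding$strand == s &
                             overlap_width(srna_start, srna_end, coding$start, coding$end) > 0L)
    if (!has_srna_annot && overlaps_coding) next
    # (3) first sense gene starting downstream of the drop, inside the TU
    g5 <- feat_5p(coding$start, coding$end, coding$strand)
    dist <- (g5 - drop$position) * (if (s == "+") 1 else -1)
    inside <- coding$strand == s & g5 >= tus$start[k] & g5 <= tus$end[k] &
      dist > 0 & dist <= params$gene_search_window
    if (!any(inside)) next
    gi <- which(inside)[which.min(dist[inside])]
    gene <- coding[gi, ]
    # (4) the gene must lack its own gTSS
    other <- own_gtss_genes[own_gtss_genes$gene == gene$gene_id &
                              own_gtss_genes$tu_id != tus$tu_id[k], ]
    if (nrow(other)) next
    # (5) abundance percentile of the TSS
    pct <- 100 * mean(all_max <= tus$max_count[k])
    if (pct < params$min_abundance_percentile) next
    # (6) read-through fraction
    gene_lo <- max(gene$start, tus$start[k]); gene_hi <- min(gene$end, tus$end[k])
    if (gene_lo > gene_hi) next
    cov_gene <- mean(coverage[[s]]$values[gene_lo:gene_hi])
    cov_srna <- mean(coverage[[s]]$values[srna_start:srna_end])
    if (cov_srna <= 0) next
    rt <- cov_gene / cov_srna
    if (rt < params$min_readthrough || rt >= params$max_drop_ratio) next
    out[[length(out) + 1L]] <- data.frame(
      tu_id = tus$tu_id[k], tss_position = tus$tss_position[k], strand = s,
      srna_start = srna_start, srna_end = srna_end, drop_ratio = drop$ratio,
      downstream_gene = gene$gene_id, readthrough_fraction = rt,
      srna_abundance_rank = pct,
      utr_derived = !has_srna_annot && grepl("g", tus$label[k], fixed = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tu_id = character(), tss_position = integer(),
                      strand = character(), srna_start = integer(),
                      srna_end = integer(), drop_ratio = numeric(),
                      downstream_gene = character(), readthrough_fraction = numeric(),
                      srna_abundance_rank = numeric(), utr_derived = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
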