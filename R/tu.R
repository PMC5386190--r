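# Transcriptional-unit inference: coverage-based segmentation downstream of
# each TSS, class labels (g/a/i/n with composites such as gaiTU), UTR lengths
# and leaderless-mRNA detection.

#' Segment a transcriptional unit downstream of a TSS
#'
#' Running-maximum fractional-coverage segmentation: starting at the TSS the
#' TU is extended in transcription direction while coverage is at least
#' `min_coverage_fraction` times the running maximum observed since the TSS;
#' it terminates after more than `max_gap` consecutive sub-threshold
#' positions, ends at the last supra-threshold position, and never exceeds
#' `max_tu_length`. A TSS with zero coverage at its own position yields a
#' 1-nt TU flagged `zero_coverage`.
#'
#' @param tss_position 1-based genomic position of the TSS.
#' @param strand `"+"` or `"-"`.
#' @param coverage A [dtx_track()] on the TSS strand (untreated library).
#' @param params A [dtx_segmentation_params()].
#' @return List with `start`, `end` (1-based inclusive, start <= end),
#'   `length` and `flag` (`""` or `"zero_coverage"`).
#' @export
segment_tu <- function(tss_position, strand, coverage, params = dtx_segmentation_params()) {
  v <- coverage$values
  L <- length(v)
  p <- as.integer(tss_position)
  if (p < 1L || p > L) stopf("TSS position %d outside genome (length %d)", p, L)
  if (v[p] <= 0) {
    return(list(start = p, end = p, length = 1L, flag = "zero_coverage"))
  }
  if (strand == "+") {
    w <- v[p:min(L, p + params$max_tu_length - 1L)]
  } else {
    w <- rev(v[max(1L, p - params$max_tu_length + 1L):p])
  }
  # running maximum of a trailing mean: robust to isolated noise spikes,
  # identical to the raw running maximum on noise-free profiles
  k <- max(1L, params$runmax_window)
  cs <- cumsum(w)
  denom <- pmin(seq_along(w), k)
  tm <- (cs - c(rep(0, k), utils::head(cs, -k))[seq_along(w)]) / denom
  runmax <- cummax(tm)
  below <- w < params$min_coverage_fraction * runmax
  # last supra-threshold position before the first gap longer than max_gap
  r <- rle(below)
  endpos <- cumsum(r$lengths)
  last_above <- 0L
  stop_at <- length(w)
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      if (r$lengths[i] > params$max_gap) { stop_at <- last_above; break }
    } else {
      last_above <- endpos[i]
    }
  }
  ext <- if (stop_at == length(w)) last_above else stop_at
  ext <- max(ext, 1L)   # TSS itself is covered
  if (strand == "+") {
    list(start = p, end = p + ext - 1L, length = ext, flag = "")
  } else {
    list(start = p - ext + 1L, end = p, length = ext, flag = "")
  }
}

# sense genes whose body strictly contains pos (start < pos < end)
i_host_genes <- function(genes, pos, strand) {
  genes$gene_id[genes$strand == strand & genes$start < pos & genes$end > pos]
}

#' Classify transcriptional units
#'
#' Applies the class rules to every TU given the full TU set of both strands:
#' `g` if at least one annotated gene is covered in sense orientation (any
#' overlap of the gene body; a gene that merely hosts the TSS in its interior
#' does not count), `a` if the TU overlaps a gene or another TU in antisense
#' orientation by at least `antisense_overlap_min` nt, `i` if the TSS lies
#' strictly inside a sense gene body, and `n` if none of these apply. Labels
#' are emitted in the canonical order g, a, i (composites such as `gaiTU`).
#'
#' @param tus data.frame with columns tu_id, seq_id, strand, start, end,
#'   tss_position (one row per TU; both strands).
#' @param genes Annotation data.frame ([read_annotation()]).
#' @param th A [dtx_thresholds()].
#' @return `tus` with added columns `label` (e.g. `"ga"`), `class`
#'   (`"gaTU"`), `member_genes` (comma-separated sense gene ids in
#'   transcription order), `i_host` (gene hosting the TSS, or `""`).
#' @export
classify_tus <- function(tus, genes, th = dtx_thresholds()) {
  n <- nrow(tus)
  label <- character(n); members <- character(n); ihost <- character(n)
  # class rules operate on protein-coding annotation; known-sRNA features are
  # transcripts, not genes to be "covered"
  coding <- if ("kind" %in% names(genes)) genes[genes$kind == "protein_coding", , drop = FALSE] else genes
  for (k in seq_len(n)) {
    s <- tus$strand[k]; a1 <- tus$start[k]; a2 <- tus$end[k]; tsspos <- tus$tss_position[k]
    hosts <- i_host_genes(coding, tsspos, s)
    has_i <- length(hosts) > 0L
    ov <- overlap_width(a1, a2, coding$start, coding$end)
    sense <- which(coding$strand == s & ov > 0L & !(coding$gene_id %in% hosts))
    has_g <- length(sense) > 0L
    anti_gene <- any(coding$strand == other_strand(s) & ov >= th$antisense_overlap_min)
    ov_tu <- overlap_width(a1, a2, tus$start, tus$end)
    anti_tu <- any(tus$strand == other_strand(s) & ov_tu >= th$antisense_overlap_min &
                     seq_len(n) != k)
    has_a <- anti_gene || anti_tu
    lab <- paste0(if (has_g) "g" else "", if (has_a) "a" else "", if (has_i) "i" else "")
    if (lab == "") lab <- "n"
    label[k] <- lab
    if (has_g) {
      ord <- if (s == "+") order(coding$start[sense]) else order(-coding$end[sense])
      members[k] <- paste(coding$gene_id[sense][ord], collapse = ",")
    }
    ihost[k] <- if (has_i) hosts[1] else ""
  }
  tus$label <- label
  tus$class <- paste0(label, "TU")
  tus$member_genes <- members
  tus$i_host <- ihost
  tus
}

#' Compute 5' and 3' UTR lengths of a gene-covering TU
#'
#' For gTUs only: the 5' UTR is the distance from the TSS to the start codon
#' of the first member gene (0 allowed); the 3' UTR is the distance from the
#' stop codon of the last member gene to the TU end. Undefined (NA) for TUs
#' without the `g` label, when the TSS lies inside the first member gene, or
#' when the TU ends before the last member gene does.
#'
#' @param tus Classified TU data.frame ([classify_tus()]).
#' @param genes Annotation data.frame.
#' @return `tus` with numeric columns `utr5` and `utr3` added.
#' @export
compute_utrs <- function(tus, genes) {
  g5 <- stats::setNames(feat_5p(genes$start, genes$end, genes$strand), genes$gene_id)
  g3 <- stats::setNames(feat_3p(genes$start, genes$end, genes$strand), genes$gene_id)
  utr5 <- rep(NA_real_, nrow(tus)); utr3 <- rep(NA_real_, nrow(tus))
  for (k in seq_len(nrow(tus))) {
    if (!grepl("g", tus$label[k], fixed = TRUE) || tus$member_genes[k] == "") next
    mem <- strsplit(tus$member_genes[k], ",", fixed = TRUE)[[1]]
    s <- tus$strand[k]
    dir <- if (s == "+") 1 else -1
    u5 <- (g5[mem[1]] - tus$tss_position[k]) * dir
    # a TSS inside a gene body (i label) has no real 5' UTR
    if (u5 >= 0 && !grepl("i", tus$label[k], fixed = TRUE)) utr5[k] <- u5
    tu3 <- if (s == "+") tus$end[k] else tus$start[k]
    u3 <- (tu3 - g3[mem[length(mem)]]) * dir
    if (u3 >= 0) utr3[k] <- u3
  }
  tus$utr5 <- utr5
  tus$utr3 <- utr3
  tus
}

#' Detect leaderless mRNAs
#'
#' A gene is flagged leaderless iff a gene-covering TSS (class contains `g`)
#' on the gene's strand lies at the A of its start codon or within the
#' `leaderless_window` nucleotides immediately upstream (a strand-aware
#' closed window of `leaderless_window + 1` positions).
#'
#' @param tss Classified TSS table (column `class` containing `g` for gTSSs).
#' @param genes Annotation data.frame.
#' @param th A [dtx_thresholds()].
#' @return data.frame of flagged genes: gene_id, tss_position, offset
#'   (0 = at the start codon).
#' @export
detect_leaderless <- function(tss, genes, th = dtx_thresholds()) {
  gt <- tss[grepl("g", tss$class, fixed = TRUE), , drop = FALSE]
  if ("kind" %in% names(genes)) genes <- genes[genes$kind == "protein_coding", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(genes))) {
    s <- genes$strand[k]
    start5 <- feat_5p(genes$start[k], genes$end[k], s)
    cand <- gt[gt$strand == s, , drop = FALSE]
    off <- (start5 - cand$position) * (if (s == "+") 1 else -1)
    hit <- which(off >= 0 & off <= th$leaderless_window)
    if (length(hit)) {
      hit <- hit[which.min(off[hit])]
      out[[length(out) + 1L]] <- data.frame(gene_id = genes$gene_id[k],
                                            tss_position = cand$position[hit],
                                            offset = off[hit],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), tss_position = integer(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build and classify the TU table for one strain
#'
#' Segments a TU downstream of every TSS on the untreated coverage, applies
#' the class rules, computes UTRs and copies the TSS expression vector onto
#' the TU. TSS class labels (gTSS/aTSS/iTSS/nTSS) are derived from the TU
#' labels and written back onto the returned TSS table.
#'
#' @param tss A TSS table ([build_tss_set()]).
#' @param untreated_cov List with `"+"`/`"-"` untreated coverage
#'   [dtx_track()]s.
#' @param genes Annotation data.frame.
#' @param params A [dtx_segmentation_params()].
#' @param th A [dtx_thresholds()].
#' @return List with elements `tus` (TU table) and `tss` (TSS table with a
#'   `class` column, e.g. `"gai"`).
#' @export
build_tus <- function(tss, untreated_cov, genes,
                      params = dtx_segmentation_params(), th = dtx_thresholds()) {
  n <- nrow(tss)
  segs <- vector("list", n)
  for (k in seq_len(n)) {
    segs[[k]] <- segment_tu(tss$position[k], tss$strand[k],
                            untreated_cov[[tss$strand[k]]], params)
  }
  tus <- data.frame(tu_id = sprintf("TU%04d", seq_len(n)),
                    strain = tss$strain, seq_id = tss$seq_id,
                    strand = tss$strand,
                    start = vapply(segs, `[[`, numeric(1), "start"),
                    end = vapply(segs, `[[`, numeric(1), "end"),
                    tss_position = tss$position,
                    seg_flag = vapply(segs, `[[`, character(1), "flag"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  tus <- classify_tus(tus, genes, th)
  tus <- compute_utrs(tus, genes)
  keep <- c(dtx_conditions(), paste0("raw_", dtx_conditions()), "max_condition", "max_count")
  for (cn in intersect(keep, names(tss)))
    tus[[cn]] <- tss[[cn]]
  tss$class <- tus$label
  tss$tu_id <- tus$tu_id
  list(tus = tus, tss = tss)
}
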