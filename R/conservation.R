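# Cross-strain conservation: gTSS co-occurrence on ortholog pairs,
# protein-alignment position mapping for internal/antisense TSSs,
# alignment-based conservation of free-standing transcripts, and the
# promoter -10-element divergence scan.

#' Extract a transcript-orientation subsequence from a genome
#'
#' @param genome A [dtx_genome()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"` (minus returns the reverse complement).
#' @return Nucleotide string.
#' @export
subseq_strand <- function(genome, start, end, strand) {
  if (start < 1L || end > genome$length || start > end)
    stopf("subsequence %d..%d outside genome %s", start, end, genome$seq_id)
  s <- substr(genome$seq, start, end)
  if (strand == "-") revcomp(s) else s
}

translate_gene <- function(genome, gene) {
  nt <- subseq_strand(genome, gene$start, gene$end, gene$strand)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt), if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Global protein alignment of an ortholog pair
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scores, gap open 11 /
#' extend 1, as used to express TSS positions in the coordinate frame of the
#' encoded amino-acid sequence.
#'
#' @param aa_a,aa_b Amino-acid strings.
#' @return List: `score`, `pid` (percent identity), `aligned_a`, `aligned_b`
#'   (gapped strings) and `map_a2b` (per residue of `aa_a`, the aligned
#'   residue index in `aa_b`, NA at gap columns).
#' @export
align_proteins <- function(aa_a, aa_b) {
  if (!nchar(aa_a) || !nchar(aa_b)) stopf("align_proteins: empty sequence")
  aln <- Biostrings::pairwiseAlignment(aa_a, aa_b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(aa_a))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ga)) {
    if (ga[k] != "-") ia <- ia + 1L
    if (gb[k] != "-") ib <- ib + 1L
    if (ga[k] != "-" && gb[k] != "-") map[ia] <- ib
  }
  list(score = Biostrings::score(aln), pid = Biostrings::pid(aln),
       aligned_a = paste(ga, collapse = ""), aligned_b = paste(gb, collapse = ""),
       map_a2b = map)
}

#' Protein alignments for an ortholog table
#'
#' @param orthologs data.frame with gene_a, gene_b.
#' @param genes_a,genes_b Annotation data.frames.
#' @param genome_a,genome_b [dtx_genome()]s.
#' @return Named list (key `gene_a`) of [align_proteins()] results plus the
#'   two annotation rows.
#' @export
ortholog_alignments <- function(orthologs, genes_a, genes_b, genome_a, genome_b) {
  out <- list()
  for (k in seq_len(nrow(orthologs))) {
    ga <- genes_a[genes_a$gene_id == orthologs$gene_a[k], ]
    gb <- genes_b[genes_b$gene_id == orthologs$gene_b[k], ]
    if (nrow(ga) != 1L || nrow(gb) != 1L)
      stopf("ortholog table references unknown gene: %s / %s",
            orthologs$gene_a[k], orthologs$gene_b[k])
    aln <- align_proteins(translate_gene(genome_a, ga), translate_gene(genome_b, gb))
    aln$gene_a <- ga; aln$gene_b <- gb
    out[[orthologs$gene_a[k]]] <- aln
  }
  out
}

#' Map a genomic position between orthologs via the protein alignment
#'
#' Position -> codon index -> aligned residue in the partner (a gap column
#' maps to the nearest aligned residue and is flagged) -> same within-codon
#' offset -> genomic coordinate, strand-aware.
#'
#' @param aln An element of [ortholog_alignments()].
#' @param position 1-based genomic position inside `gene_a`'s body.
#' @return List: `position` (in strain B), `flagged` (TRUE when the residue
#'   fell in a gap column).
#' @export
map_position_via_protein <- function(aln, position) {
  ga <- aln$gene_a; gb <- aln$gene_b
  if (position < ga$start || position > ga$end)
    stopf("position %d outside gene %s (%d..%d)", position, ga$gene_id, ga$start, ga$end)
  off <- if (ga$strand == "+") position - ga$start else ga$end - position
  codon <- off %/% 3L + 1L
  within <- off %% 3L
  map <- aln$map_a2b
  codon <- min(codon, length(map))
  flagged <- FALSE
  res_b <- map[codon]
  if (is.na(res_b)) {
    flagged <- TRUE
    ok <- which(!is.na(map))
    if (!length(ok)) stopf("no aligned residues between %s and %s", ga$gene_id, gb$gene_id)
    res_b <- map[ok[which.min(abs(ok - codon))]]
  }
  off_b <- (res_b - 1L) * 3L + within
  pos_b <- if (gb$strand == "+") gb$start + off_b else gb$end - off_b
  list(position = pos_b, flagged = flagged)
}

# genes covered by at least one gene-covering TU
gtss_gene_set <- function(tus) {
  g <- tus[grepl("g", tus$label, fixed = TRUE) & tus$member_genes != "", "member_genes"]
  unique(unlist(strsplit(g, ",", fixed = TRUE)))
}

#' Conserved gTSSs across ortholog pairs
#'
#' A gTSS is conserved for an ortholog pair iff each ortholog is covered by a
#' gene-covering TU (i.e. transcribed from a gTSS, any position) in at least
#' one condition; pairs with a gTSS in exactly one strain yield
#' strain-specific records.
#'
#' @param tus_a,tus_b Classified TU tables of the two strains.
#' @param orthologs data.frame gene_a/gene_b.
#' @return data.frame: gene_a, gene_b, class, verdict
#'   (conserved / strain_specific_a / strain_specific_b / absent), evidence.
#' @export
conserved_gtss <- function(tus_a, tus_b, orthologs) {
  in_a <- orthologs$gene_a %in% gtss_gene_set(tus_a)
  in_b <- orthologs$gene_b %in% gtss_gene_set(tus_b)
  verdict <- ifelse(in_a & in_b, "conserved",
                    ifelse(in_a, "strain_specific_a",
                           ifelse(in_b, "strain_specific_b", "absent")))
  data.frame(gene_a = orthologs$gene_a, gene_b = orthologs$gene_b,
             class = "g", verdict = verdict,
             evidence = ifelse(verdict == "conserved", "gTSS in both orthologs",
                               ifelse(verdict == "absent", "", "gTSS in one ortholog")),
             stringsAsFactors = FALSE)
}

# host gene of an internal (sense) or antisense TSS, or NA
host_gene_of <- function(genes, pos, strand, cls) {
  hit <- if (cls == "i") {
    which(genes$strand == strand & genes$start < pos & genes$end > pos)
  } else {
    which(genes$strand == other_strand(strand) & genes$start <= pos & genes$end >= pos)
  }
  if (length(hit)) genes$gene_id[hit[1]] else NA_character_
}

#' Conserved internal/antisense TSSs
#'
#' For iTSSs and aTSSs located within orthologous gene bodies, the position
#' is mapped into the partner gene via the protein alignment; a pair is
#' conserved iff the observed and expected positions differ by at most
#' `ortholog_tss_offset_max` nt. Each TSS is matched to at most one partner
#' (nearest offset, ties to the lower coordinate).
#'
#' @param tss_a,tss_b Classified TSS tables.
#' @param genes_a,genes_b Annotation data.frames.
#' @param alns [ortholog_alignments()] result.
#' @param cls `"i"` or `"a"`.
#' @param th A [dtx_thresholds()].
#' @return data.frame: class, tss_a, tss_b, gene_a, gene_b, offset, verdict.
#' @export
conserved_internal_antisense_tss <- function(tss_a, tss_b, genes_a, genes_b,
                                             alns, cls = c("i", "a"),
                                             th = dtx_thresholds()) {
  cls <- match.arg(cls)
  sub_a <- tss_a[grepl(cls, tss_a$class, fixed = TRUE), , drop = FALSE]
  sub_b <- tss_b[grepl(cls, tss_b$class, fixed = TRUE), , drop = FALSE]
  sub_a$host <- mapply(function(p, s) host_gene_of(genes_a, p, s, cls),
                       sub_a$position, sub_a$strand)
  sub_b$host <- mapply(function(p, s) host_gene_of(genes_b, p, s, cls),
                       sub_b$position, sub_b$strand)
  gene_b_of <- vapply(alns, function(a) a$gene_b$gene_id, character(1))
  cand <- list()
  for (i in seq_len(nrow(sub_a))) {
    h <- sub_a$host[i]
    if (is.na(h) || is.null(alns[[h]])) next
    mp <- map_position_via_protein(alns[[h]], sub_a$position[i])
    partner <- alns[[h]]$gene_b$gene_id
    js <- which(sub_b$host == partner)
    for (j in js) {
      off <- abs(sub_b$position[j] - mp$position)
      if (off <= th$ortholog_tss_offset_max)
        cand[[length(cand) + 1L]] <- data.frame(i = i, j = j, offset = off,
                                                pos_b = sub_b$position[j])
    }
  }
  used_a <- logical(nrow(sub_a)); used_b <- logical(nrow(sub_b))
  recs <- list()
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd$offset, cd$pos_b), , drop = FALSE]
    for (r in seq_len(nrow(cd))) {
      i <- cd$i[r]; j <- cd$j[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recs[[length(recs) + 1L]] <- data.frame(
        class = cls, tss_a = sub_a$position[i], tss_b = sub_b$position[j],
        gene_a = sub_a$host[i], gene_b = sub_b$host[j], offset = cd$offset[r],
        verdict = "conserved", stringsAsFactors = FALSE)
    }
  }
  for (i in which(!used_a & !is.na(sub_a$host) & sub_a$host %in% names(alns)))
    recs[[length(recs) + 1L]] <- data.frame(
      class = cls, tss_a = sub_a$position[i], tss_b = NA_integer_,
      gene_a = sub_a$host[i], gene_b = NA_character_, offset = NA_integer_,
      verdict = "strain_specific_a", stringsAsFactors = FALSE)
  for (j in which(!used_b & !is.na(sub_b$host) & sub_b$host %in% gene_b_of))
    recs[[length(recs) + 1L]] <- data.frame(
      class = cls, tss_a = NA_integer_, tss_b = sub_b$position[j],
      gene_a = NA_character_, gene_b = sub_b$host[j], offset = NA_integer_,
      verdict = "strain_specific_b", stringsAsFactors = FALSE)
  if (!length(recs)) {
    return(data.frame(class = character(), tss_a = integer(), tss_b = integer(),
                      gene_a = character(), gene_b = character(),
                      offset = integer(), verdict = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Conservation of free-standing (nTU) transcripts by sequence search
#'
#' Each nTU transcript sequence of strain A is searched against the strain B
#' genome with [local_align_search()]; it is conserved iff the best hit has
#' E-value at most `ntss_evalue_max` and query coverage at least
#' `ntss_qcov_min`. Hit coordinates are cross-checked against the partner
#' strain's nTU catalog: an overlapping partner nTU gives
#' `conserved_as_ntu`, otherwise `conserved_other_class`.
#'
#' @param tus_a Classified TU table of strain A (rows with label `n` are
#'   used).
#' @param genome_a Strain A [dtx_genome()].
#' @param subject_b Strain B genome string or [build_subject_index()].
#' @param tus_b Classified TU table of strain B.
#' @param th A [dtx_thresholds()].
#' @param params A [dtx_align_params()].
#' @return data.frame: tu_id, class, verdict, evalue, qcov, hit_start,
#'   hit_end, hit_strand.
#' @export
conserved_ntss <- function(tus_a, genome_a, subject_b, tus_b,
                           th = dtx_thresholds(), params = dtx_align_params()) {
  ntu_a <- tus_a[tus_a$label == "n", , drop = FALSE]
  ntu_b <- tus_b[tus_b$label == "n", , drop = FALSE]
  out <- data.frame(tu_id = ntu_a$tu_id, class = "n",
                    verdict = "strain_specific_a", evalue = NA_real_,
                    qcov = NA_real_, hit_start = NA_integer_,
                    hit_end = NA_integer_, hit_strand = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ntu_a))) {
    qseq <- subseq_strand(genome_a, ntu_a$start[k], ntu_a$end[k], ntu_a$strand[k])
    hits <- local_align_search(qseq, subject_b, params)
    if (!nrow(hits)) next
    best <- hits[1L, ]
    out$evalue[k] <- best$evalue; out$qcov[k] <- best$qcov
    out$hit_start[k] <- best$s_start; out$hit_end[k] <- best$s_end
    out$hit_strand[k] <- best$strand
    if (best$evalue <= th$ntss_evalue_max && best$qcov >= th$ntss_qcov_min) {
      ovl <- any(overlap_width(best$s_start, best$s_end, ntu_b$start, ntu_b$end) > 0L)
      out$verdict[k] <- if (ovl) "conserved_as_ntu" else "conserved_other_class"
    }
  }
  out
}

#' Promoter divergence scan for a strain-specific TSS
#'
#' Compares the upstream promoter windows of a TSS and its homologous locus
#' in the partner strain. The -10 element is taken as positions -12..-7
#' relative to the TSS (+1 = TSS, canonical bacterial promoter spacing). All
#' mismatching window positions are reported and any mismatch inside the
#' hexamer is flagged (N mismatches everything).
#'
#' @param genome_a,genome_b [dtx_genome()]s.
#' @param tss_a TSS position in strain A.
#' @param strand_a Strand in strain A.
#' @param tss_b_expected Homologous (expected) TSS position in strain B, e.g.
#'   anchored via the ortholog of the downstream gene.
#' @param strand_b Strand in strain B.
#' @param window Upstream window length (nt).
#' @return List of class `dtx_promoter_report`: `window_a`, `window_b`,
#'   `mismatch_offsets` (relative to TSS, e.g. -10), `minus10_a`,
#'   `minus10_b`, `minus10_mismatch`, `verdict`.
#' @export
promoter_divergence <- function(genome_a, tss_a, strand_a,
                                genome_b, tss_b_expected, strand_b,
                                window = 50L) {
  up <- function(gn, tss, s) {
    if (s == "+") {
      if (tss - window < 1L) return(NULL)
      subseq_strand(gn, tss - window, tss - 1L, "+")
    } else {
      if (tss + window > gn$length) return(NULL)
      subseq_strand(gn, tss + 1L, tss + window, "-")
    }
  }
  wa <- up(genome_a, tss_a, strand_a)
  wb <- up(genome_b, tss_b_expected, strand_b)
  if (is.null(wa) || is.null(wb)) {
    return(structure(list(window_a = wa, window_b = wb,
                          mismatch_offsets = integer(), minus10_a = NA_character_,
                          minus10_b = NA_character_, minus10_mismatch = NA,
                          verdict = "unalignable"),
                     class = "dtx_promoter_report"))
  }
  ca <- strsplit(wa, "")[[1]]; cb <- strsplit(wb, "")[[1]]
  mis <- which(ca != cb | ca == "N" | cb == "N")
  offsets <- mis - window - 1L          # window index i corresponds to TSS offset i-window-1
  hex_idx <- (window - 11L):(window - 6L)   # offsets -12..-7
  structure(list(window_a = wa, window_b = wb,
                 mismatch_offsets = offsets,
                 minus10_a = substr(wa, hex_idx[1], hex_idx[6]),
                 minus10_b = substr(wb, hex_idx[1], hex_idx[6]),
                 minus10_mismatch = any(mis %in% hex_idx),
                 verdict = "aligned"),
            class = "dtx_promoter_report")
}
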