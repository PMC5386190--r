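#' Analysis thresholds
#'
#' Container for every numeric threshold used by the pipeline, defaulted to the
#' values of the original study design: treated libraries are scaled to 1e8
#' reads; a position is a true primary position (TSS) if it carries >= 500
#' scaled read starts and a read-start/coverage ratio > 0.5; antisense calls
#' require >= 20 nt overlap; orthologous internal/antisense TSSs may differ by
#' at most 10 nt in protein-aligned position; free-standing transcript
#' conservation requires an alignment hit with E-value <= 1e-5 and query
#' coverage >= 0.5; a fold change is called significant at |FC| >= 2 with
#' posterior probability >= 0.95; a unique expression factor > 5 marks strong
#' single-condition induction; a leaderless mRNA has its TSS at the start
#' codon A or within the 10 nt upstream; ortholog expression profiles are
#' clustered with k-means at k = 10.
#'
#' @param scale_target Library size after scaling (reads).
#' @param min_read_starts Minimum scaled read starts at a primary position.
#' @param min_start_coverage_ratio Read-start/coverage ratio that must be
#'   exceeded (strictly) at a primary position.
#' @param antisense_overlap_min Minimum antisense overlap (nt) for an `a` label.
#' @param ortholog_tss_offset_max Maximum protein-aligned positional offset (nt)
#'   for conserved internal/antisense TSSs.
#' @param ntss_evalue_max,ntss_qcov_min E-value and query-coverage cut-offs for
#'   free-standing (nTU) conservation.
#' @param fc_min Minimum fold change for significance.
#' @param posterior_min Minimum posterior probability for significance.
#' @param uef_high UEF above which a TSS counts as condition-specific.
#' @param leaderless_window Upstream window (nt) for leaderless detection.
#' @param kmeans_k Number of k-means clusters for ortholog profiles.
#' @return A named list of class `dtx_thresholds`.
#' @export
dtx_thresholds <- function(scale_target = 1e8,
                           min_read_starts = 500,
                           min_start_coverage_ratio = 0.5,
                           antisense_overlap_min = 20L,
                           ortholog_tss_offset_max = 10L,
                           ntss_evalue_max = 1e-5,
                           ntss_qcov_min = 0.5,
                           fc_min = 2.0,
                           posterior_min = 0.95,
                           uef_high = 5.0,
                           leaderless_window = 10L,
                           kmeans_k = 10L) {
  th <- list(scale_target = scale_target,
             min_read_starts = min_read_starts,
             min_start_coverage_ratio = min_start_coverage_ratio,
             antisense_overlap_min = as.integer(antisense_overlap_min),
             ortholog_tss_offset_max = as.integer(ortholog_tss_offset_max),
             ntss_evalue_max = ntss_evalue_max,
             ntss_qcov_min = ntss_qcov_min,
             fc_min = fc_min,
             posterior_min = posterior_min,
             uef_high = uef_high,
             leaderless_window = as.integer(leaderless_window),
             kmeans_k = as.integer(kmeans_k))
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && length(x) == 1L && x > 0, logical(1))]
  if (length(bad)) stopf("thresholds must be positive scalars; offending: %s", paste(bad, collapse = ", "))
  class(th) <- "dtx_thresholds"
  th
}

#' TU segmentation parameters
#'
#' Parameters of the running-maximum fractional-coverage segmentation that
#' replaces a dedicated segmentation tool: starting at the TSS, the TU is
#' extended downstream while coverage stays at or above `min_coverage_fraction`
#' of the running maximum seen since the TSS; it terminates after `max_gap`
#' consecutive sub-threshold positions and never exceeds `max_tu_length`.
#'
#' @param min_coverage_fraction Fraction of the running maximum (0 < f < 1).
#' @param max_gap Consecutive sub-threshold positions tolerated (nt).
#' @param max_tu_length Hard cap on TU length (nt).
#' @param runmax_window Trailing-mean window (nt) over which the running
#'   maximum is computed, so that isolated noise spikes do not inflate the
#'   termination threshold; 1 = raw running maximum.
#' @return Named list of class `dtx_segmentation_params`.
#' @export
dtx_segmentation_params <- function(min_coverage_fraction = 0.1,
                                    max_gap = 50L,
                                    max_tu_length = 20000L,
                                    runmax_window = 20L) {
  if (!(min_coverage_fraction > 0 && min_coverage_fraction < 1))
    stopf("min_coverage_fraction must be in (0,1)")
  structure(list(min_coverage_fraction = min_coverage_fraction,
                 max_gap = as.integer(max_gap),
                 max_tu_length = as.integer(max_tu_length),
                 runmax_window = as.integer(runmax_window)),
            class = "dtx_segmentation_params")
}

#' Actuaton detection parameters
#'
#' An actuaton is called for a TU in which an abundant, discrete sRNA reads
#' through into a downstream sense gene lacking its own gTSS. The qualitative
#' definition is operationalised with these thresholds: the sRNA TSS must rank
#' at or above `min_abundance_percentile` among all TSSs; the sRNA 3' boundary
#' is the most 5' position where coverage drops to `max_drop_ratio` or less of
#' the preceding level, within `max_srna_len` of the TSS; the downstream gene
#' must start within `gene_search_window` of the drop; and the read-through
#' fraction (gene-body over sRNA-body coverage) must lie in
#' `[min_readthrough, max_drop_ratio)`.
#'
#' @param min_abundance_percentile Abundance percentile cut-off (0-100).
#' @param max_drop_ratio Coverage ratio at/below which a drop is called.
#' @param min_readthrough Minimum read-through fraction.
#' @param max_srna_len Maximum sRNA length searched for a drop (nt).
#' @param gene_search_window Maximum distance drop -> gene start (nt).
#' @return Named list of class `dtx_actuaton_params`.
#' @export
dtx_actuaton_params <- function(min_abundance_percentile = 75,
                                max_drop_ratio = 0.5,
                                min_readthrough = 0.02,
                                max_srna_len = 400L,
                                gene_search_window = 500L) {
  if (!(max_drop_ratio > 0 && max_drop_ratio < 1))
    stopf("max_drop_ratio must be in (0,1)")
  structure(list(min_abundance_percentile = min_abundance_percentile,
                 max_drop_ratio = max_drop_ratio,
                 min_readthrough = min_readthrough,
                 max_srna_len = as.integer(max_srna_len),
                 gene_search_window = as.integer(gene_search_window)),
            class = "dtx_actuaton_params")
}
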