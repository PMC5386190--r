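# TSS calling: the two-step normalisation scheme and the assembly of the TSS
# table. Step one scales every treated library to a common size and calls
# true primary positions; step two applies library-specific correction factors
# derived from the fraction of read-start counts falling on primary positions.

#' Scale a library to the target size
#'
#' Multiplies every track value by `scale_target / raw_total`, i.e. expresses
#' all tracks as counts per 1e8 mapped reads (applied identically to treated
#' and untreated libraries).
#'
#' @param lib A [dtx_library()].
#' @param th A [dtx_thresholds()].
#' @return The scaled library.
#' @export
scale_library <- function(lib, th = dtx_thresholds()) {
  if (!is.numeric(lib$raw_total) || lib$raw_total <= 0)
    stopf("library %s: raw_total must be > 0", lib$library_id)
  f <- th$scale_target / lib$raw_total
  for (sem in c("read_starts", "coverage"))
    for (s in c("+", "-"))
      lib$tracks[[sem]][[s]]$values <- lib$tracks[[sem]][[s]]$values * f
  lib$scaled <- TRUE
  lib
}

#' Call true primary positions on one strand
#'
#' A position is a true primary position (candidate TSS) iff its scaled read
#' starts are at least `min_read_starts` and the read-start/coverage ratio
#' strictly exceeds `min_start_coverage_ratio`. A position with zero coverage
#' but nonzero read starts counts as ratio 1 (read starts imply at least that
#' much coverage in real data).
#'
#' @param read_starts,coverage [dtx_track()]s on the same strand.
#' @param th A [dtx_thresholds()].
#' @return Sorted integer vector of 1-based positions.
#' @export
call_true_primary_positions <- function(read_starts, coverage, th = dtx_thresholds()) {
  rs <- read_starts$values
  cv <- coverage$values
  if (length(rs) != length(cv)) stopf("read_starts and coverage tracks differ in length")
  ratio <- ifelse(cv > 0, rs / cv, ifelse(rs > 0, 1, 0))
  which(rs >= th$min_read_starts & ratio > th$min_start_coverage_ratio)
}

call_primary_both_strands <- function(lib, th) {
  lapply(stats::setNames(c("+", "-"), c("+", "-")), function(s)
    call_true_primary_positions(lib$tracks$read_starts[[s]], lib$tracks$coverage[[s]], th))
}

primary_fraction <- function(lib, primary) {
  tot <- sum(lib$tracks$read_starts[["+"]]$values) + sum(lib$tracks$read_starts[["-"]]$values)
  at_primary <- sum(lib$tracks$read_starts[["+"]]$values[primary[["+"]]]) +
    sum(lib$tracks$read_starts[["-"]]$values[primary[["-"]]])
  if (tot == 0) stopf("library %s has no read starts", lib$library_id)
  at_primary / tot
}

#' Normalize a strain's treated libraries
#'
#' Scales every treated library, calls true primary positions on the scaled
#' tracks, then computes the library-specific correction factor as
#' (mean primary fraction across the strain's treated libraries) / (this
#' library's primary fraction) and multiplies the read-start tracks by it.
#' The factor equalises the share of counts that fall on true primary
#' positions across libraries, compensating library-dependent efficiency of
#' the 5'-PPP enrichment; it is invariant under rescaling of a library's
#' tracks. Positions are called on scaled-but-uncorrected tracks; counts are
#' corrected afterwards.
#'
#' @param libs List of treated [dtx_library()]s (one per condition).
#' @param th A [dtx_thresholds()].
#' @return List of normalized libraries, each with elements
#'   `correction_factor` and `primary_positions` (per-strand position lists)
#'   added, read-start tracks scaled and corrected.
#' @export
normalize_libraries <- function(libs, th = dtx_thresholds()) {
  if (!length(libs)) return(list())
  scaled <- lapply(libs, scale_library, th = th)
  primary <- lapply(scaled, call_primary_both_strands, th = th)
  fracs <- mapply(primary_fraction, scaled, primary)
  zero <- which(fracs == 0)
  if (length(zero))
    stopf("correction factor undefined: library %s has zero primary counts",
          scaled[[zero[1]]]$library_id)
  target <- mean(fracs)
  out <- vector("list", length(scaled))
  for (i in seq_along(scaled)) {
    lib <- scaled[[i]]
    fct <- target / fracs[i]
    for (s in c("+", "-"))
      lib$tracks$read_starts[[s]]$values <- lib$tracks$read_starts[[s]]$values * fct
    lib$correction_factor <- fct
    lib$primary_positions <- primary[[i]]
    out[[i]] <- lib
  }
  names(out) <- names(libs)
  out
}

#' Assemble the TSS table from normalized libraries
#'
#' One record per (seq_id, strand, position) that is a true primary position
#' in at least one condition. The per-condition expression vector holds the
#' corrected, scaled read-start value of every condition (values at
#' conditions where the position was not itself called primary are reported
#' as-is, not zeroed). `max_condition` is the argmax of the vector, ties
#' broken by the fixed condition order. When the matching raw (unscaled)
#' libraries are supplied, raw per-condition read-start counts are attached
#' for use by the count-based significance test.
#'
#' @param nlibs List of normalized treated libraries as returned by
#'   [normalize_libraries()], named or ordered by condition.
#' @param raw_libs Optional list of the corresponding unscaled libraries.
#' @param strain Strain identifier stored in the table.
#' @return A data.frame (class `dtx_tss_table`): strain, seq_id, position,
#'   strand, one numeric column per condition, `raw_*` columns when raw
#'   libraries were given, max_condition, max_count.
#' @export
build_tss_set <- function(nlibs, raw_libs = NULL, strain = "") {
  conds <- dtx_conditions()
  empty <- data.frame(strain = character(), seq_id = character(),
                      position = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  for (cn in conds) empty[[cn]] <- numeric()
  empty$max_condition <- character(); empty$max_count <- numeric()
  if (!length(nlibs)) return(structure(empty, class = c("dtx_tss_table", "data.frame")))

  libconds <- vapply(nlibs, function(l) l$condition, character(1))
  if (!setequal(libconds, conds))
    stopf("normalize/build: expected one library per condition; got: %s",
          paste(libconds, collapse = ","))
  nlibs <- nlibs[match(conds, libconds)]
  if (!is.null(raw_libs)) {
    rawconds <- vapply(raw_libs, function(l) l$condition, character(1))
    raw_libs <- raw_libs[match(conds, rawconds)]
  }
  seq_id <- nlibs[[1]]$tracks$read_starts[["+"]]$seq_id

  rows <- list()
  for (s in c("+", "-")) {
    pos <- sort(unique(unlist(lapply(nlibs, function(l) l$primary_positions[[s]]))))
    if (!length(pos)) next
    counts <- vapply(nlibs, function(l) l$tracks$read_starts[[s]]$values[pos],
                     numeric(length(pos)))
    counts <- matrix(counts, nrow = length(pos), dimnames = list(NULL, conds))
    df <- data.frame(strain = strain, seq_id = seq_id, position = pos,
                     strand = s, stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(conds)) df[[conds[j]]] <- counts[, j]
    if (!is.null(raw_libs)) {
      raw <- vapply(raw_libs, function(l) l$tracks$read_starts[[s]]$values[pos],
                    numeric(length(pos)))
      raw <- matrix(raw, nrow = length(pos))
      for (j in seq_along(conds)) df[[paste0("raw_", conds[j])]] <- raw[, j]
    }
    imax <- apply(counts, 1L, first_max)
    df$max_condition <- conds[imax]
    df$max_count <- counts[cbind(seq_len(nrow(counts)), imax)]
    rows[[s]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(out)) out <- empty
  structure(out, class = c("dtx_tss_table", "data.frame"))
}

tss_raw_matrix <- function(tss) {
  cols <- paste0("raw_", dtx_conditions())
  if (!all(cols %in% names(tss))) return(NULL)
  as.matrix(tss[, cols, drop = FALSE])
}

tss_count_matrix <- function(tss) {
  as.matrix(tss[, dtx_conditions(), drop = FALSE])
}
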