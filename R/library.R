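#' dRNA-seq sequencing library container
#'
#' One library = one condition (or the pooled untreated library) with
#' strand-specific read-start and coverage tracks plus the raw mapped read
#' total used for scaling.
#'
#' @param library_id Identifier.
#' @param condition One of [dtx_conditions()] or `"untreated"`.
#' @param treated Logical; `TRUE` for exonuclease-treated (5'-PPP enriched)
#'   libraries.
#' @param tracks List with elements `read_starts` and `coverage`, each a list
#'   with elements `"+"` and `"-"` holding [dtx_track()] objects.
#' @param raw_total Total mapped read count (> 0).
#' @return List of class `dtx_library`.
#' @export
dtx_library <- function(library_id, condition, treated, tracks, raw_total) {
  for (sem in c("read_starts", "coverage")) {
    if (is.null(tracks[[sem]])) stopf("library %s lacks %s tracks", library_id, sem)
    for (s in c("+", "-")) {
      tr <- tracks[[sem]][[s]]
      if (is.null(tr)) stopf("library %s lacks a %s track on strand %s", library_id, sem, s)
      if (!identical(tr$semantics, sem))
        stopf("library %s: track on strand %s has semantics '%s', expected '%s'",
              library_id, s, tr$semantics, sem)
    }
    extra <- setdiff(names(tracks[[sem]]), c("+", "-"))
    if (length(extra)) stopf("library %s: unexpected %s track(s): %s", library_id, sem,
                             paste(extra, collapse = ","))
  }
  if (length(tracks$read_starts[["+"]]$values) != length(tracks$coverage[["+"]]$values))
    stopf("library %s: read_starts and coverage tracks differ in length", library_id)
  structure(list(library_id = library_id, condition = condition,
                 treated = isTRUE(treated), tracks = tracks,
                 raw_total = raw_total),
            class = "dtx_library")
}

lib_genome_length <- function(lib) length(lib$tracks$read_starts[["+"]]$values)
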