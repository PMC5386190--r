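# Internal helpers shared across modules.

#' Fixed condition order used in all tables
#'
#' The ten growth/stress conditions, in the fixed column order used for every
#' expression vector and output table: cold (15C), heat (42C), inorganic-carbon
#' depletion (-C), darkness, iron depletion (-Fe), high light (HL), nitrogen
#' depletion (-N), phosphate depletion (-P), stationary and exponential phase.
#'
#' @return Character vector of length 10.
#' @export
dtx_conditions <- function() {
  c("15C", "42C", "-C", "dark", "-Fe", "HL", "-N", "-P", "stat", "exp")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# 5' end of a feature given its strand
feat_5p <- function(start, end, strand) ifelse(strand == "+", start, end)
feat_3p <- function(start, end, strand) ifelse(strand == "+", end, start)

# walk k nt downstream (in transcription direction) from pos
shift_down <- function(pos, k, strand) ifelse(strand == "+", pos + k, pos - k)
# walk k nt upstream
shift_up <- function(pos, k, strand) ifelse(strand == "+", pos - k, pos + k)

other_strand <- function(strand) ifelse(strand == "+", "-", "+")

# overlap width of [s1,e1] and [s2,e2] (1-based inclusive); 0 if disjoint
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# deterministic which.max: first index of the maximum
first_max <- function(x) which(x == max(x))[1L]
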