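# Built-in nucleotide local alignment: exact affine-gap Smith-Waterman for
# small problems and word-seeded ungapped X-drop extension at genome scale,
# with ungapped Karlin-Altschul E-values. Used for free-standing transcript
# conservation; an external search tool can be plugged in through the same
# hit-table shape but is never required.

#' Local alignment scoring parameters
#'
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_ext Affine gap penalties (a gap of length k costs
#'   `gap_open + k * gap_ext`).
#' @param word Seed word size for genome-scale search.
#' @param xdrop X-drop cut-off for ungapped extension.
#' @param dp_limit Maximum `query x subject` cell count for which the exact
#'   Smith-Waterman DP is used instead of seeding.
#' @return Named list of class `dtx_align_params`.
#' @export
dtx_align_params <- function(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2,
                             word = 11L, xdrop = 20, dp_limit = 250000) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, word = as.integer(word), xdrop = xdrop,
                 dp_limit = dp_limit),
            class = "dtx_align_params")
}

#' Ungapped Karlin-Altschul parameters for a match/mismatch scheme
#'
#' `lambda` solves `sum p_i p_j exp(lambda * s_ij) = 1` under uniform base
#' composition and `H` is the relative entropy of the induced target
#' distribution. `K` is the standard tabulated value 0.41 for the default
#' +2/-3 scheme; other schemes fall back to a conservative 0.3.
#'
#' @param match,mismatch Scores.
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_ungapped <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  qm <- 0.25 * exp(lambda * match)
  qx <- 0.75 * exp(lambda * mismatch)
  H <- lambda * (qm * match + qx * mismatch)
  K <- if (match == 2 && mismatch == -3) 0.41 else 0.3
  list(lambda = lambda, K = K, H = H)
}

align_evalue <- function(score, qlen, slen, ka) {
  # both strands searched: effective space 2 * m * n
  ka$K * qlen * (2 * slen) * exp(-ka$lambda * score)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Exact affine-gap Smith-Waterman local alignment
#'
#' Full dynamic program with affine gaps; deterministic tie-breaking (the
#' highest-scoring cell with the smallest subject, then query, end
#' coordinate).
#'
#' @param query,subject Nucleotide strings (N mismatches everything,
#'   including itself).
#' @param params A [dtx_align_params()].
#' @return List: `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based; all 0 when the best score is 0).
#' @export
smith_waterman <- function(query, subject, params = dtx_align_params()) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(q); n <- length(s)
  go <- params$gap_open + params$gap_ext   # cost of opening (first gap position)
  ge <- params$gap_ext
  H <- matrix(0, m + 1L, n + 1L)   # best score ending at (i,j)
  E <- matrix(-Inf, m + 1L, n + 1L) # gap in query (consumes subject)
  Fm <- matrix(-Inf, m + 1L, n + 1L) # gap in subject (consumes query)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(m)) {
    sub <- ifelse(s == q[i] & q[i] != "N", params$match, params$mismatch)
    for (j in seq_len(n)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go, E[i + 1L, j] - ge)
      Fm[i + 1L, j + 1L] <- max(H[i, j + 1L] - go, Fm[i, j + 1L] - ge)
      h <- max(0, H[i, j] + sub[j], E[i + 1L, j + 1L], Fm[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L))
  # traceback for the start coordinates
  i <- bi; j <- bj; state <- "H"
  qs <- bi; ss <- bj
  repeat {
    h <- H[i + 1L, j + 1L]
    if (state == "H") {
      if (h == 0) break
      sub <- if (s[j] == q[i] && q[i] != "N") params$match else params$mismatch
      if (h == H[i, j] + sub) { qs <- i; ss <- j; i <- i - 1L; j <- j - 1L }
      else if (h == E[i + 1L, j + 1L]) state <- "E"
      else state <- "F"
      if (i == 0L || j == 0L) break
    } else if (state == "E") {
      if (E[i + 1L, j + 1L] == H[i + 1L, j] - go) state <- "H"
      j <- j - 1L
      if (j == 0L) break
    } else {
      if (Fm[i + 1L, j + 1L] == H[i, j + 1L] - go) state <- "H"
      i <- i - 1L
      if (i == 0L) break
    }
  }
  list(score = best, q_start = qs, q_end = bi, s_start = ss, s_end = bj)
}

#' Pre-computed word index of a subject sequence
#'
#' @param subject Nucleotide string.
#' @param word Word size.
#' @return List of class `dtx_subject_index`.
#' @export
build_subject_index <- function(subject, word = 11L) {
  subject <- toupper(subject)
  n <- nchar(subject)
  if (n < word) {
    idx <- list()
  } else {
    words <- substring(subject, 1:(n - word + 1L), word:n)
    keep <- !grepl("N", words, fixed = TRUE)
    idx <- split(which(keep), words[keep])
  }
  structure(list(seq = subject, chars = strsplit(subject, "")[[1]],
                 word = as.integer(word), index = idx, length = n),
            class = "dtx_subject_index")
}

# ungapped X-drop extension of a seed on one diagonal; returns best segment
extend_seed <- function(qc, sc, d, anchor, params) {
  m <- length(qc); n <- length(sc)
  lo <- max(1L, 1L - d); hi <- min(m, n - d)
  qr <- lo:hi
  comp <- qc[qr] == sc[qr + d] & qc[qr] != "N" & sc[qr + d] != "N"
  sco <- ifelse(comp, params$match, params$mismatch)
  a <- anchor - lo + 1L   # index of seed start within sco
  # rightwards from a
  cr <- cumsum(sco[a:length(sco)])
  rmax <- cummax(cr)
  cut <- which(cr < rmax - params$xdrop)
  stop_r <- if (length(cut)) cut[1] - 1L else length(cr)
  right_best <- which.max(cr[seq_len(stop_r)])
  right_score <- cr[right_best]
  # leftwards from a-1
  if (a > 1L) {
    cl <- cumsum(rev(sco[seq_len(a - 1L)]))
    lmax <- cummax(cl)
    cutl <- which(cl < lmax - params$xdrop)
    stop_l <- if (length(cutl)) cutl[1] - 1L else length(cl)
    if (stop_l > 0L && max(cl[seq_len(stop_l)]) > 0) {
      left_best <- which.max(cl[seq_len(stop_l)])
      left_score <- cl[left_best]
    } else { left_best <- 0L; left_score <- 0 }
  } else { left_best <- 0L; left_score <- 0 }
  q_start <- qr[a - left_best]
  q_end <- qr[a + right_best - 1L]
  list(score = right_score + left_score,
       q_start = q_start, q_end = q_end,
       s_start = q_start + d, s_end = q_end + d)
}

search_one_strand <- function(qchars, sidx, params) {
  w <- params$word
  m <- length(qchars)
  if (m < w) return(NULL)
  qstr <- paste(qchars, collapse = "")
  qwords <- substring(qstr, 1:(m - w + 1L), w:m)
  hits <- list()
  seen_diag <- integer(0)
  for (qp in seq_along(qwords)) {
    spos <- sidx$index[[qwords[qp]]]
    if (is.null(spos)) next
    for (sp in spos) {
      d <- sp - qp
      if (d %in% seen_diag) next
      seen_diag <- c(seen_diag, d)
      hits[[length(hits) + 1L]] <- extend_seed(qchars, sidx$chars, d, qp, params)
    }
  }
  hits
}

#' Seed-and-extend local alignment search of a query against a genome
#'
#' Finds local alignments of `query` on both strands of the subject. Small
#' problems (up to `dp_limit` cells) are solved by the exact affine
#' Smith-Waterman DP; larger subjects are searched by word seeding (word size
#' 11) followed by ungapped X-drop extension, one extension per diagonal.
#' E-values use the ungapped Karlin-Altschul formula over a two-strand
#' search space; query coverage is the aligned query span over the query
#' length (gaps in the query excluded).
#'
#' @param query Nucleotide string (length >= the seed word size for
#'   genome-scale search).
#' @param subject A nucleotide string or a [build_subject_index()].
#' @param params A [dtx_align_params()].
#' @param min_score Hits below this raw score are dropped (default 0 keeps
#'   all positive-score hits).
#' @return data.frame sorted by E-value: strand, score, evalue, qcov,
#'   q_start, q_end (original query coordinates), s_start, s_end.
#' @export
local_align_search <- function(query, subject, params = dtx_align_params(),
                               min_score = 0) {
  query <- toupper(query)
  empty <- data.frame(strand = character(), score = numeric(), evalue = numeric(),
                      qcov = numeric(), q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(), stringsAsFactors = FALSE)
  if (gsub("N", "", query, fixed = TRUE) == "") return(empty)
  is_idx <- inherits(subject, "dtx_subject_index")
  slen <- if (is_idx) subject$length else nchar(subject)
  m <- nchar(query)
  ka <- karlin_ungapped(params$match, params$mismatch)
  rows <- list()
  add_hit <- function(h, strand) {
    if (h$score <= min_score || h$score <= 0) return()
    qs <- h$q_start; qe <- h$q_end
    if (strand == "-") { qs <- m - h$q_end + 1L; qe <- m - h$q_start + 1L }
    rows[[length(rows) + 1L]] <<- data.frame(
      strand = strand, score = h$score,
      evalue = align_evalue(h$score, m, slen, ka),
      qcov = (h$q_end - h$q_start + 1L) / m,
      q_start = qs, q_end = qe, s_start = h$s_start, s_end = h$s_end,
      stringsAsFactors = FALSE)
  }
  if (!is_idx && as.double(m) * slen <= params$dp_limit) {
    add_hit(smith_waterman(query, subject, params), "+")
    add_hit(smith_waterman(revcomp(query), subject, params), "-")
  } else {
    sidx <- if (is_idx) subject else build_subject_index(subject, params$word)
    qc <- strsplit(query, "")[[1]]
    for (h in search_one_strand(qc, sidx, params)) add_hit(h, "+")
    qrc <- strsplit(revcomp(query), "")[[1]]
    for (h in search_one_strand(qrc, sidx, params)) add_hit(h, "-")
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$evalue, -out$score), , drop = FALSE]
}
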