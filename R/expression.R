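# Expression statistics: fold changes, the unique expression factor (UEF)
# with a count-based significance test, ortholog profile clustering and the
# cross-strain fold-change correlation.

#' Fold change between two normalized counts
#'
#' `(a + pc) / (b + pc)` with a pseudocount on the normalized scale. The
#' default pseudocount 1 keeps all-or-nothing expression patterns finite.
#'
#' @param a,b Non-negative normalized counts (vectorised).
#' @param pc Pseudocount (>= 0).
#' @return Numeric fold change(s).
#' @export
fold_change <- function(a, b, pc = 1.0) {
  if (any(a < 0) || any(b < 0)) stopf("fold_change: negative input")
  (a + pc) / (b + pc)
}

#' Unique expression factor of an expression vector
#'
#' The UEF is the ratio of the count in the condition with the maximum number
#' of reads to the count in the condition with the second-highest number of
#' reads, after pseudocounting. A UEF above `uef_high` (default 5) marks
#' strong induction under one particular condition. If the two top counts tie,
#' the UEF is 1. An all-zero vector is flagged undefined.
#'
#' @param counts Numeric vector (>= 2 conditions), named or in the fixed
#'   condition order.
#' @param pc Pseudocount.
#' @param th A [dtx_thresholds()].
#' @return List: `uef`, `top_condition`, `second_condition`, `high`,
#'   `defined`.
#' @export
uef <- function(counts, pc = 1.0, th = dtx_thresholds()) {
  if (length(counts) < 2L) stopf("uef: need at least two conditions")
  conds <- names(counts) %||% dtx_conditions()[seq_along(counts)]
  if (all(counts == 0)) {
    return(list(uef = NA_real_, top_condition = NA_character_,
                second_condition = NA_character_, high = FALSE, defined = FALSE))
  }
  i1 <- first_max(counts)
  rest <- counts[-i1]
  i2r <- first_max(rest)
  i2 <- seq_along(counts)[-i1][i2r]
  val <- if (counts[i1] == counts[i2]) 1.0 else (counts[i1] + pc) / (counts[i2] + pc)
  list(uef = unname(val), top_condition = conds[i1], second_condition = conds[i2],
       high = val > th$uef_high, defined = TRUE)
}

#' Posterior probability of a two-fold rate difference from raw counts
#'
#' Models each raw count as Poisson with exposure equal to its library size
#' and a Jeffreys Gamma(1/2, eps -> 0) prior on the rate, so the posterior
#' rate is Gamma(count + 1/2, library size). The posterior probability that
#' the rate ratio is >= 2 or <= 1/2 has a closed form through the Beta
#' distribution of `La*ra / (La*ra + Lb*rb)` and is returned exactly.
#'
#' @param raw_a,raw_b Raw (unscaled) integer read counts.
#' @param lib_a,lib_b Library sizes (exposures) of the two counts.
#' @param fc_min The fold-change magnitude of interest (default 2).
#' @return Posterior probability P(ratio >= fc_min or <= 1/fc_min).
#' @export
uef_significance <- function(raw_a, raw_b, lib_a = 1, lib_b = 1, fc_min = 2) {
  if (!is_count1(raw_a) || !is_count1(raw_b))
    stopf("uef_significance: raw counts must be non-negative integers")
  a <- raw_a + 0.5
  b <- raw_b + 0.5
  # ratio rho = (lambda_a/lambda_b); B = La*la/(La*la + Lb*lb) ~ Beta(a, b)
  # rho >= c  <=>  B >= c*La/(c*La + Lb)
  p_hi <- stats::pbeta(fc_min * lib_a / (fc_min * lib_a + lib_b), a, b, lower.tail = FALSE)
  p_lo <- stats::pbeta(lib_a / (lib_a + fc_min * lib_b), a, b)
  p_hi + p_lo
}

#' UEF results with significance for a TSS/TU table
#'
#' Computes the UEF of every row's expression vector and, where raw counts
#' are available, the posterior support for a two-fold difference between the
#' top and second condition. A UEF is significant iff the fold change is at
#' least `fc_min` and the posterior is at least `posterior_min`.
#'
#' @param tab A TSS or TU table carrying the condition columns (and
#'   optionally `raw_*` columns) plus an id column.
#' @param id_col Name of the identifier column.
#' @param lib_sizes Named vector of raw library sizes per condition (used as
#'   exposures; defaults to equal sizes).
#' @param pc Pseudocount for the UEF.
#' @param th A [dtx_thresholds()].
#' @return data.frame: id, uef, top_condition, second_condition, posterior,
#'   high, significant.
#' @export
uef_table <- function(tab, id_col = "tu_id", lib_sizes = NULL, pc = 1.0,
                      th = dtx_thresholds()) {
  conds <- dtx_conditions()
  cm <- as.matrix(tab[, conds, drop = FALSE])
  rawm <- tss_raw_matrix(tab)
  if (is.null(lib_sizes)) lib_sizes <- stats::setNames(rep(1, length(conds)), conds)
  out <- data.frame(id = tab[[id_col]], uef = NA_real_,
                    top_condition = NA_character_, second_condition = NA_character_,
                    posterior = NA_real_, high = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tab))) {
    u <- uef(stats::setNames(cm[k, ], conds), pc = pc, th = th)
    out$uef[k] <- u$uef
    out$top_condition[k] <- u$top_condition
    out$second_condition[k] <- u$second_condition
    out$high[k] <- u$high
    if (u$defined && !is.null(rawm)) {
      i1 <- match(u$top_condition, conds); i2 <- match(u$second_condition, conds)
      post <- uef_significance(round(rawm[k, i1]), round(rawm[k, i2]),
                               lib_a = lib_sizes[i1], lib_b = lib_sizes[i2],
                               fc_min = th$fc_min)
      out$posterior[k] <- post
      out$significant[k] <- (u$uef >= th$fc_min) && (post >= th$posterior_min)
    }
  }
  out[order(-ifelse(is.na(out$uef), -Inf, out$uef)), , drop = FALSE]
}

profile_transform <- function(m) {
  z <- log2(m + 1)
  mu <- rowMeans(z)
  sdv <- apply(z, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  (z - mu) / sdv
}

#' Cluster ortholog expression profiles across both strains
#'
#' log2(x+1)-transforms and z-scores every profile, pools the profiles of
#' both strains and runs a single k-means (fixed seed, `nstart` restarts,
#' best inertia). Reports the fraction of ortholog pairs whose two members
#' land in the same cluster.
#'
#' @param profiles_a,profiles_b Numeric matrices (pairs x conditions), row i
#'   of `profiles_a` orthologous to row i of `profiles_b`.
#' @param k Number of clusters.
#' @param seed Random seed.
#' @param nstart k-means restarts.
#' @return List: `assignments_a`, `assignments_b`, `same_cluster_fraction`.
#' @export
cluster_ortholog_profiles <- function(profiles_a, profiles_b, k = 10L, seed = 1L,
                                      nstart = 10L) {
  stopifnot(nrow(profiles_a) == nrow(profiles_b))
  n <- nrow(profiles_a)
  pooled <- rbind(profile_transform(profiles_a), profile_transform(profiles_b))
  if (k > nrow(pooled)) stopf("k = %d exceeds the number of profiles (%d)", k, nrow(pooled))
  set.seed(seed)
  km <- stats::kmeans(pooled, centers = k, nstart = nstart, iter.max = 50L)
  ca <- km$cluster[seq_len(n)]
  cb <- km$cluster[n + seq_len(n)]
  list(assignments_a = ca, assignments_b = cb,
       same_cluster_fraction = mean(ca == cb))
}

#' Cross-strain correlation of pairwise fold changes
#'
#' For every ortholog pair and every unordered pair of conditions (45 for 10
#' conditions) the log2 fold change is computed in each strain; returned is
#' the squared Pearson correlation over all points plus the scatter table.
#'
#' @param profiles_a,profiles_b Numeric matrices (pairs x conditions).
#' @param pc Pseudocount.
#' @return List: `r2`, `scatter` (data.frame pair, cond_i, cond_j, lfc_a,
#'   lfc_b), `defined`.
#' @export
pairwise_fc_correlation <- function(profiles_a, profiles_b, pc = 1.0) {
  stopifnot(nrow(profiles_a) == nrow(profiles_b),
            ncol(profiles_a) == ncol(profiles_b))
  if (nrow(profiles_a) < 2L) stopf("need at least two ortholog pairs")
  conds <- colnames(profiles_a) %||% dtx_conditions()[seq_len(ncol(profiles_a))]
  cp <- utils::combn(ncol(profiles_a), 2L)
  la <- log2(profiles_a + pc)
  lb <- log2(profiles_b + pc)
  fa <- la[, cp[1, ], drop = FALSE] - la[, cp[2, ], drop = FALSE]
  fb <- lb[, cp[1, ], drop = FALSE] - lb[, cp[2, ], drop = FALSE]
  x <- as.vector(fa); y <- as.vector(fb)
  scatter <- data.frame(pair = rep(seq_len(nrow(profiles_a)), ncol(cp)),
                        cond_i = rep(conds[cp[1, ]], each = nrow(profiles_a)),
                        cond_j = rep(conds[cp[2, ]], each = nrow(profiles_a)),
                        lfc_a = x, lfc_b = y, stringsAsFactors = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r2 = NA_real_, scatter = scatter, defined = FALSE))
  }
  list(r2 = stats::cor(x, y)^2, scatter = scatter, defined = TRUE)
}
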