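# Simulation of the dRNA-seq signal: treated libraries concentrate read
# starts at planted TSSs (negative-binomial counts around the per-condition
# rate) with residual body coverage and low-rate spurious internal starts
# that fail the start/coverage ratio rule in expectation; the untreated
# library is the condition-pooled coverage without 5' enrichment.

add_range <- function(vec, lo, hi, val) {
  lo <- max(1L, lo); hi <- min(length(vec), hi)
  if (lo > hi) return(vec)
  vec[lo:hi] <- vec[lo:hi] + val
  vec
}

# deposit one transcript's treated-library signal
deposit_treated <- function(starts, cov, row, count, cfg) {
  if (count <= 0) return(list(starts = starts, cov = cov))
  p <- row$position; s <- row$strand
  t1 <- row$tu_start; t2 <- row$tu_end
  starts[p] <- starts[p] + count
  rl <- cfg$read_length
  bodyf <- cfg$body_coverage_fraction
  if (!is.na(row$drop_pos)) {
    d <- row$drop_pos; f <- row$readthrough
    if (s == "+") {
      cov <- add_range(cov, p, min(p + rl - 1L, d), count)
      cov <- add_range(cov, p, d, bodyf * count)
      if (f > 0 && d < t2) {
        cov <- add_range(cov, d + 1L, min(d + rl, t2), f * count)
        cov <- add_range(cov, d + 1L, t2, f * bodyf * count)
      }
    } else {
      cov <- add_range(cov, max(p - rl + 1L, d), p, count)
      cov <- add_range(cov, d, p, bodyf * count)
      if (f > 0 && d > t1) {
        cov <- add_range(cov, max(d - rl, t1), d - 1L, f * count)
        cov <- add_range(cov, t1, d - 1L, f * bodyf * count)
      }
    }
  } else {
    if (s == "+") cov <- add_range(cov, p, min(p + rl - 1L, t2), count)
    else cov <- add_range(cov, max(p - rl + 1L, t1), p, count)
    cov <- add_range(cov, t1, t2, bodyf * count)
  }
  # spurious internal starts, uniform over the body (ratio stays low there)
  nbg <- stats::rpois(1, cfg$background_start_rate * count)
  if (nbg > 0) {
    offs <- t1 + sample.int(t2 - t1 + 1L, nbg, replace = TRUE) - 1L
    tb <- table(offs)
    idx <- as.integer(names(tb))
    starts[idx] <- starts[idx] + as.integer(tb)
    cov[idx] <- cov[idx] + as.integer(tb)
  }
  list(starts = starts, cov = cov)
}

sim_rate_matrix <- function(ttss) {
  as.matrix(ttss[, paste0("rate_", dtx_conditions()), drop = FALSE])
}

#' Simulate the library set of one fixture
#'
#' Generates, per strain, ten treated libraries (one per condition) and one
#' pooled untreated library, as [dtx_library()] objects. Treated read starts
#' at a planted TSS are negative-binomial around baseline x condition
#' multiplier (x per-library enrichment efficiency); the untreated coverage
#' is the condition-pooled transcript abundance shaped by TU extents,
#' actuaton read-through drops, and a geometric 3'-end decay.
#'
#' @param sim A [generate_genome_pair()] result.
#' @return List with elements `a` and `b`, each a list of 11 libraries
#'   (conditions in the fixed order, then `untreated`).
#' @export
simulate_read_starts <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  conds <- dtx_conditions()
  L <- cfg$genome_length
  out <- list()
  for (strain in c("a", "b")) {
    ttss <- sim$truth$tss[sim$truth$tss$strain == strain, , drop = FALSE]
    rates <- sim_rate_matrix(ttss)
    seq_id <- if (strain == "a") "chrA" else "chrB"
    strain_id <- if (strain == "a") "strainA" else "strainB"
    libs <- list()
    for (ci in seq_along(conds)) {
      eff <- cfg$enrichment_efficiency[[conds[ci]]]
      tr <- list(read_starts = list(), coverage = list())
      for (s in c("+", "-")) {
        starts <- numeric(L); cov <- numeric(L)
        rows <- which(ttss$strand == s)
        if (length(rows)) {
          counts <- rnb(length(rows), rates[rows, ci] * eff, cfg$dispersion)
          for (ri in seq_along(rows)) {
            dep <- deposit_treated(starts, cov, ttss[rows[ri], ], counts[ri], cfg)
            starts <- dep$starts; cov <- dep$cov
          }
        }
        tr$read_starts[[s]] <- dtx_track(strain_id, seq_id, s, starts, "read_starts")
        tr$coverage[[s]] <- dtx_track(strain_id, seq_id, s, cov, "coverage")
      }
      raw_total <- sum(tr$read_starts[["+"]]$values) + sum(tr$read_starts[["-"]]$values) +
        cfg$bulk_reads
      libs[[conds[ci]]] <- dtx_library(paste0("treated_", gsub("[^A-Za-z0-9]", "", conds[ci])),
                                       conds[ci], TRUE, tr, max(raw_total, 1))
    }
    # untreated: pooled coverage without 5' enrichment
    tr <- list(read_starts = list(), coverage = list())
    for (s in c("+", "-")) {
      shape <- numeric(L)
      rows <- which(ttss$strand == s)
      for (ri in rows) {
        row <- ttss[ri, ]
        mu <- mean(rates[ri, ])
        t1 <- row$tu_start; t2 <- row$tu_end
        if (!is.na(row$drop_pos)) {
          d <- row$drop_pos; f <- row$readthrough
          if (s == "+") {
            shape <- add_range(shape, t1, d, mu)
            if (d < t2) shape <- add_range(shape, d + 1L, t2, f * mu)
          } else {
            shape <- add_range(shape, d, t2, mu)
            if (d > t1) shape <- add_range(shape, t1, d - 1L, f * mu)
          }
          tail_mu <- if (f > 0) f * mu else mu
        } else {
          shape <- add_range(shape, t1, t2, mu)
          tail_mu <- mu
        }
        dd <- ceiling(5 * cfg$decay_len)
        decay <- tail_mu * exp(-(1:dd) / cfg$decay_len)
        if (s == "+") {
          hi <- min(L, t2 + dd)
          if (hi > t2) shape[(t2 + 1L):hi] <- shape[(t2 + 1L):hi] + decay[seq_len(hi - t2)]
        } else {
          lo <- max(1L, t1 - dd)
          if (lo < t1) shape[(t1 - 1L):lo] <- shape[(t1 - 1L):lo] + decay[seq_len(t1 - lo)]
        }
      }
      cov <- numeric(L)
      nz <- which(shape > 0)
      if (length(nz)) cov[nz] <- rnb(length(nz), shape[nz], cfg$dispersion)
      starts <- numeric(L)
      if (length(nz)) starts[nz] <- stats::rpois(length(nz), 0.005 * shape[nz])
      tr$coverage[[s]] <- dtx_track(strain_id, seq_id, s, cov, "coverage")
      tr$read_starts[[s]] <- dtx_track(strain_id, seq_id, s, starts, "read_starts")
    }
    raw_total <- round((sum(tr$coverage[["+"]]$values) + sum(tr$coverage[["-"]]$values)) /
                         cfg$read_length) + 1
    libs[["untreated"]] <- dtx_library("untreated", "untreated", FALSE, tr, raw_total)
    out[[strain]] <- libs
  }
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the exact formats the pipeline reads: one FASTA and GFF3 per strain,
#' the ortholog TSV, one bedGraph per strain x library x strand x
#' {read_starts, coverage} (2 x 11 x 2 x 2 = 88 files), a per-strain library
#' manifest, the ground-truth tables and the configuration as a YAML file.
#' Deterministic: rerunning with the same seed yields byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the simulation object with an added `files` element.
#' @export
simulate_fixture <- function(config, dir) {
  sim <- generate_genome_pair(config)
  libs <- simulate_read_starts(sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  files <- character()
  wf <- function(p) { files <<- c(files, p); p }
  for (strain in c("a", "b")) {
    sid <- if (strain == "a") "strainA" else "strainB"
    write_genome(sim$genomes[[strain]], wf(file.path(dir, paste0(sid, ".fasta"))))
    write_annotation(sim$genes[[strain]], wf(file.path(dir, paste0(sid, ".gff3"))))
    manifest <- list()
    for (lib in libs[[strain]]) {
      paths <- list()
      for (sem in c("read_starts", "coverage")) {
        for (s in c("+", "-")) {
          fn <- sprintf("%s_%s_%s_%s.bedGraph", sid, lib$library_id,
                        if (s == "+") "p" else "m",
                        if (sem == "read_starts") "starts" else "cov")
          write_track(lib$tracks[[sem]][[s]], wf(file.path(dir, "tracks", fn)))
          paths[[paste(sem, s)]] <- file.path("tracks", fn)
        }
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        library_id = lib$library_id, condition = lib$condition,
        treated = lib$treated, raw_total = lib$raw_total,
        starts_plus = paths[["read_starts +"]], starts_minus = paths[["read_starts -"]],
        cov_plus = paths[["coverage +"]], cov_minus = paths[["coverage -"]],
        stringsAsFactors = FALSE)
    }
    write_table(do.call(rbind, manifest),
                wf(file.path(dir, paste0("libraries_", sid, ".tsv"))))
  }
  ortho <- sim$orthologs
  write_table(ortho, wf(file.path(dir, "orthologs.tsv")))
  for (nm in names(sim$truth)) {
    if (nrow(sim$truth[[nm]]) > 0)
      write_table(sim$truth[[nm]], wf(file.path(dir, paste0("ground_truth_", nm, ".tsv"))))
  }
  cfg <- unclass(config)
  cfg$n_conserved <- as.list(cfg$n_conserved)
  cfg$enrichment_efficiency <- as.list(cfg$enrichment_efficiency)
  yaml::write_yaml(cfg, wf(file.path(dir, "config.yaml")))
  sim$files <- files
  invisible(sim)
}

#' Load the libraries of a fixture strain from disk
#'
#' @param dir Fixture directory ([simulate_fixture()]).
#' @param strain `"a"` or `"b"`.
#' @param genome_length Genome length (densifies the bedGraphs).
#' @return Named list of [dtx_library()] objects.
#' @export
read_fixture_libraries <- function(dir, strain, genome_length) {
  sid <- if (strain == "a") "strainA" else "strainB"
  man <- utils::read.delim(file.path(dir, paste0("libraries_", sid, ".tsv")),
                           stringsAsFactors = FALSE)
  libs <- list()
  for (k in seq_len(nrow(man))) {
    paths <- c(man$starts_plus[k], man$starts_minus[k], man$cov_plus[k], man$cov_minus[k])
    for (p in paths) {
      if (!file.exists(file.path(dir, p)))
        stopf("missing track file: %s", file.path(dir, p))
    }
    tr <- list(
      read_starts = list(
        "+" = read_track(file.path(dir, man$starts_plus[k]), genome_length, sid, "", "+", "read_starts"),
        "-" = read_track(file.path(dir, man$starts_minus[k]), genome_length, sid, "", "-", "read_starts")),
      coverage = list(
        "+" = read_track(file.path(dir, man$cov_plus[k]), genome_length, sid, "", "+", "coverage"),
        "-" = read_track(file.path(dir, man$cov_minus[k]), genome_length, sid, "", "-", "coverage")))
    libs[[man$library_id[k]]] <- dtx_library(man$library_id[k], man$condition[k],
                                             man$treated[k], tr, man$raw_total[k])
  }
  libs
}
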