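# Readers/writers for the standard formats the pipeline touches (FASTA, GFF3,
# bedGraph, TSV) and the coordinate convention at the format boundary.
#
# Genomic coordinates are 1-based inclusive throughout the package (the GFF3
# and R-native convention); bedGraph's 0-based half-open intervals are
# converted exactly at the read/write boundary.

#' Convert 1-based inclusive intervals to 0-based half-open (and back)
#'
#' Used at the bedGraph boundary only. The pair of conversions is a bijection
#' on valid intervals.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param start0,end0 0-based half-open coordinates.
#' @return A list with the converted `start`/`end` components.
#' @export
to_zero_based <- function(start, end) list(start0 = start - 1L, end0 = end)

#' @rdname to_zero_based
#' @export
to_one_based <- function(start0, end0) list(start = start0 + 1L, end = end0)

#' Genome sequence container
#'
#' @param strain_id,seq_id Identifiers.
#' @param seq Nucleotide string over A/C/G/T/N (uppercased).
#' @return List of class `dtx_genome`.
#' @export
dtx_genome <- function(strain_id, seq_id, seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stopf("genome '%s' has zero length", seq_id)
  if (grepl("[^ACGTN]", seq)) stopf("genome '%s' contains non-ACGTN residues", seq_id)
  structure(list(strain_id = strain_id, seq_id = seq_id, seq = seq,
                 length = nchar(seq)),
            class = "dtx_genome")
}

#' Read a genome FASTA
#'
#' @param path FASTA file with a single sequence.
#' @param strain_id Strain identifier to attach.
#' @return A `dtx_genome`.
#' @export
read_genome <- function(path, strain_id) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stopf("expected exactly one sequence in %s, found %d", path, length(ss))
  dtx_genome(strain_id, sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' Write a genome FASTA
#' @param genome A `dtx_genome`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$seq_id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Keeps gene-level features (GFF3 type `gene`). The attributes `kind`
#' (protein_coding / known_sRNA / other) and `product` are carried through
#' when present.
#'
#' @param path GFF3 file, 1-based inclusive coordinates.
#' @return A data.frame with columns gene_id, seq_id, start, end, strand,
#'   kind, product.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stopf("GFF3 parse error at line %d of %s: expected 9 tab-separated fields, found %d",
          body[which(nf != 9L)[1]], path, nf[nf != 9L][1])
  if (!length(body)) {
    return(data.frame(gene_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      kind = character(), product = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) stopf("gene feature without ID attribute in %s", path)
  if (anyDuplicated(ids)) stopf("duplicate gene_id '%s' in %s", ids[duplicated(ids)][1], path)
  kind <- if (!is.null(gr$kind)) as.character(gr$kind) else rep("protein_coding", length(gr))
  kind[is.na(kind)] <- "protein_coding"
  product <- if (!is.null(gr$product)) as.character(gr$product) else rep("", length(gr))
  product[is.na(product)] <- ""
  data.frame(gene_id = ids,
             seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             kind = kind, product = product, stringsAsFactors = FALSE)
}

#' Write gene annotation as GFF3
#' @param genes Annotation data.frame (see [read_annotation()]).
#' @param path Output path.
#' @export
write_annotation <- function(genes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    attrs <- sprintf("ID=%s;kind=%s;product=%s", genes$gene_id, genes$kind, genes$product)
    writeLines(sprintf("%s\tdualtx\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$seq_id, genes$start, genes$end, genes$strand, attrs), con)
  }
  invisible(path)
}

#' Strand-specific per-position track
#'
#' @param strain_id,seq_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param values One non-negative value per genomic position.
#' @param semantics `"read_starts"` or `"coverage"`.
#' @return List of class `dtx_track`.
#' @export
dtx_track <- function(strain_id, seq_id, strand, values, semantics) {
  if (!strand %in% c("+", "-")) stopf("track strand must be '+' or '-' (unstranded tracks are rejected)")
  if (!semantics %in% c("read_starts", "coverage")) stopf("unknown track semantics '%s'", semantics)
  if (any(values < 0)) stopf("track contains negative values")
  structure(list(strain_id = strain_id, seq_id = seq_id, strand = strand,
                 values = as.numeric(values), semantics = semantics),
            class = "dtx_track")
}

#' Read a bedGraph into a dense per-position track
#'
#' bedGraph intervals are 0-based half-open (the standard dialect); positions
#' not covered by any interval are 0.
#'
#' @param path bedGraph file.
#' @param genome_length Length of the genome (defines the dense vector).
#' @param strain_id,seq_id,strand,semantics Track metadata.
#' @return A `dtx_track`.
#' @export
read_track <- function(path, genome_length, strain_id = "", seq_id = "",
                       strand = "+", semantics = "coverage") {
  vec <- numeric(genome_length)
  info <- file.info(path)
  has_data <- !is.na(info$size) && info$size > 0 &&
    length(readLines(path, n = 1L, warn = FALSE)) > 0
  if (has_data) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
      st <- GenomicRanges::start(gr)   # rtracklayer converts to 1-based inclusive
      en <- GenomicRanges::end(gr)
      sc <- as.numeric(gr$score)
      if (any(en > genome_length)) stopf("bedGraph interval exceeds genome length in %s", path)
      if (any(sc < 0)) stopf("negative value in bedGraph %s", path)
      idx <- sequence(en - st + 1L, from = st)
      vec[idx] <- rep(sc, en - st + 1L)
    }
  }
  dtx_track(strain_id, seq_id, strand, vec, semantics)
}

#' Write a dense track as bedGraph
#'
#' Runs of equal values are collapsed into 0-based half-open intervals;
#' zero runs are omitted.
#'
#' @param track A `dtx_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  r <- rle(track$values)
  en <- cumsum(r$lengths)          # 1-based inclusive ends
  st <- en - r$lengths + 1L
  keep <- r$values != 0
  z <- to_zero_based(st[keep], en[keep])
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", track$seq_id, z$start0, z$end0,
                       format(r$values[keep], trim = TRUE, scientific = FALSE, digits = 15)),
               con)
  }
  invisible(path)
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), header row, UTF-8, byte-for-byte
#' reproducible for identical input.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot write table to '%s'", path)
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an ortholog table (TSV of gene-ID pairs)
#'
#' @param path TSV with columns `gene_a` and `gene_b`.
#' @return data.frame with character columns gene_a, gene_b.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stopf("ortholog table %s must have columns gene_a and gene_b", path)
  df[, c("gene_a", "gene_b")]
}
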