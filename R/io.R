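# Readers and writers for the pipeline's interchange formats: FASTA,
# GFF3, FASTQ (see utils.R), and the TSV tables tying stages together.

#' Write the genome to FASTA
#'
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, format = "fasta")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write the gene annotation to GFF3
#'
#' Coordinates are 1-based inclusive; features carry `gene_id` and
#' `allele_species` attributes.
#'
#' @param annotation `GRanges` of gene features.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  gr <- annotation
  if (is.null(gr$type)) gr$type <- "gene"
  gr$ID <- gr$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' @param path GFF3 path.
#' @param genome Optional genome `DNAStringSet`; when given, contig
#'   lengths are attached so downstream bounds checks work.
#' @return `GRanges` of gene features with mcols `gene_id`,
#'   `allele_species`.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  stopifnot(!is.null(gr$gene_id), !is.null(gr$allele_species))
  if (!is.null(genome)) {
    S4Vectors::metadata(gr)$contig_lengths <-
      stats::setNames(Biostrings::width(genome), names(genome))
  }
  gr
}

#' Write an insertion catalog
#'
#' TSV records plus, optionally, a JSON QC summary alongside.
#'
#' @param catalog An `insertion_catalog`.
#' @param path Output TSV path.
#' @param qc_path Optional JSON path for the QC tallies.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path, qc_path = NULL) {
  write_tsv(catalog$records, path)
  if (!is.null(qc_path)) {
    jsonlite::write_json(catalog$qc, qc_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read an insertion catalog TSV
#'
#' @param path Catalog TSV path.
#' @return An `insertion_catalog` (with empty QC).
#' @export
read_catalog <- function(path) {
  structure(list(records = read_tsv(path), qc = list()),
            class = "insertion_catalog")
}

#' Write a count matrix (wide TSV: barcode, then one column per sample)
#'
#' @param counts Barcode x sample matrix.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix TSV
#'
#' @param path Counts TSV path.
#' @return Barcode x sample numeric matrix.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  storage.mode(m) <- "numeric"
  m
}

#' Write / read a sample sheet (sample_id, temperature, replicate)
#'
#' @param samples data.frame sample sheet.
#' @param path TSV path.
#' @return The path (write) or the data.frame (read).
#' @export
write_sample_sheet <- function(samples, path) write_tsv(samples, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("sample_id", "temperature", "replicate") %in% names(df)))
  if (!all(df$temperature %in% c("experimental", "control"))) {
    stop("temperature must be 'experimental' or 'control'")
  }
  df
}

#' Write the ground-truth table of a simulated pool
#'
#' @param truth A `sim_truth` data.frame.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) write_tsv(as.data.frame(truth), path)

#' @rdname write_truth
#' @param ... ignored.
#' @export
read_truth <- function(path, ...) {
  df <- read_tsv(path)
  class(df) <- c("sim_truth", "data.frame")
  df
}
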