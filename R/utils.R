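# Internal helpers shared across the pipeline stages.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between equal-length strings
#'
#' @param a,b Character scalars of equal nchar.
#' @return Integer number of mismatching positions.
#' @keywords internal
#' @noRd
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming() requires equal-length strings")
  sum(ra != rb)
}

# Random DNA strings, one per element of `width`.
random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute each base with probability `rate`, drawing a different base.
# Vectorised over a character vector of sequences.
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  widths <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), widths, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(widths[i], n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a child seed for a pipeline stage
#'
#' A single run-level seed is fanned out to per-stage seeds through a
#' counter scheme, so each stage is reproducible when run standalone.
#'
#' @param seed Integer run seed.
#' @param stage Integer stage counter (>= 0).
#' @return Integer child seed in \[0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  (abs(as.double(seed)) + 1000003 * as.double(stage)) %% 2147483647
}

# Maximum count among Hamming-neighbours within `distance` (1 or 2) for each
# barcode, computed by position-masking so no all-pairs scan is needed.
# Returns a numeric vector aligned with `barcodes`.
neighbor_max_count <- function(barcodes, counts, distance) {
  n <- length(barcodes)
  best <- numeric(n)
  if (n < 2L) return(best)
  L <- nchar(barcodes[1L])
  if (any(nchar(barcodes) != L)) stop("barcodes must share one length")
  masks <- if (distance == 1L) {
    as.list(seq_len(L))
  } else {
    utils::combn(L, 2L, simplify = FALSE)
  }
  for (m in masks) {
    key <- barcodes
    for (p in m) substr(key, p, p) <- "."
    grp <- split(seq_len(n), key)
    grp <- grp[lengths(grp) > 1L]
    for (g in grp) {
      cg <- counts[g]
      mx <- max(cg)
      second <- if (sum(cg == mx) > 1L) mx else max(cg[cg < mx])
      nb <- ifelse(cg == mx, second, mx)
      best[g] <- pmax(best[g], nb)
    }
  }
  best
}

# write/read helpers for the package's TSV interchange formats ---------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write reads to FASTQ with placeholder qualities
#'
#' @param seqs Named character vector or `DNAStringSet` of read sequences.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  x <- if (methods::is(seqs, "DNAStringSet")) seqs else Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ path.
#' @return A `DNAStringSet` (qualities are discarded; the pipeline is
#'   quality-agnostic).
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
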