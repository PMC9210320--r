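# Bar-seq: barcode extraction from amplicon reads and catalog-restricted
# counting across competition samples.

#' Extract barcodes from Bar-seq amplicon reads
#'
#' Locates the upstream priming flank (leftmost hit, Hamming distance <=
#' `max_flank_mismatches`), takes the following `barcode_length` bases as
#' the barcode, and verifies the downstream flank immediately after it at
#' the same mismatch allowance. Reads failing any step are rejected with
#' a reason code.
#'
#' @param reads `DNAStringSet` or character vector of amplicon reads.
#' @param upstream_flank,downstream_flank Constant priming sequences
#'   flanking the barcode.
#' @param barcode_length Barcode length.
#' @param max_flank_mismatches Mismatch allowance for each flank.
#' @return List with `barcodes` (character, one per accepted read) and
#'   `rejected` (named tallies: `no_upstream`, `truncated`,
#'   `bad_downstream`).
#' @export
extract_barcodes <- function(reads, upstream_flank, downstream_flank,
                             barcode_length = 20, max_flank_mismatches = 2) {
  x <- if (methods::is(reads, "DNAStringSet")) reads else Biostrings::DNAStringSet(reads)
  widths <- Biostrings::width(x)
  up_len <- nchar(upstream_flank)
  dn_len <- nchar(downstream_flank)
  if (length(x) == 0L) {
    return(list(barcodes = character(0),
                rejected = c(no_upstream = 0L, truncated = 0L, bad_downstream = 0L)))
  }

  hits <- Biostrings::vmatchPattern(upstream_flank, x, max.mismatch = max_flank_mismatches)
  starts <- Biostrings::startIndex(hits)
  first <- vapply(starts, function(s) if (is.null(s) || !length(s)) NA_integer_ else s[1L], integer(1))

  ok_up <- !is.na(first)
  bc_start <- first + up_len
  dn_start <- bc_start + barcode_length
  ok_len <- ok_up & (dn_start + dn_len - 1L) <= widths

  seq_chr <- as.character(x)
  dn_obs <- substr(seq_chr, dn_start, dn_start + dn_len - 1L)
  dn_ok <- rep(FALSE, length(x))
  check <- which(ok_len)
  if (length(check)) {
    dn_raw <- charToRaw(downstream_flank)
    dn_ok[check] <- vapply(check, function(i) {
      sum(charToRaw(dn_obs[i]) != dn_raw) <= max_flank_mismatches
    }, logical(1))
  }

  accepted <- ok_len & dn_ok
  list(
    barcodes = unname(substr(seq_chr[accepted], bc_start[accepted],
                             bc_start[accepted] + barcode_length - 1L)),
    rejected = c(no_upstream = sum(!ok_up),
                 truncated = sum(ok_up & !ok_len),
                 bad_downstream = sum(ok_len & !dn_ok))
  )
}

#' Count catalog barcodes across competition samples
#'
#' Tallies extracted barcodes that match the Tn-seq-validated catalog
#' exactly; barcodes absent from the catalog are counted into a
#' per-sample orphan tally and discarded (no error-tolerant rescue at
#' this stage: a Bar-seq-only barcode is never used).
#'
#' @param sample_reads Named list: sample_id -> reads (`DNAStringSet` or
#'   character vector of amplicons).
#' @param catalog An `insertion_catalog` (or its `records` data.frame).
#' @param sample_sheet data.frame with columns `sample_id`, `temperature`,
#'   `replicate`; every sample in `sample_reads` must appear.
#' @param upstream_flank,downstream_flank,barcode_length,max_flank_mismatches
#'   Passed to [extract_barcodes()].
#' @return List with `counts` (catalog-barcode x sample integer matrix)
#'   and `qc` (per-sample accepted/rejected/orphan tallies).
#' @export
count_barcodes <- function(sample_reads, catalog, sample_sheet,
                           upstream_flank, downstream_flank,
                           barcode_length = 20, max_flank_mismatches = 2) {
  records <- if (inherits(catalog, "insertion_catalog")) catalog$records else catalog
  cat_bcs <- records$barcode
  missing <- setdiff(names(sample_reads), sample_sheet$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) absent from sample sheet: %s",
                 paste(missing, collapse = ", ")))
  }
  counts <- matrix(0L, nrow = length(cat_bcs), ncol = length(sample_reads),
                   dimnames = list(cat_bcs, names(sample_reads)))
  qc <- list()
  for (s in names(sample_reads)) {
    ex <- extract_barcodes(sample_reads[[s]], upstream_flank, downstream_flank,
                           barcode_length = barcode_length,
                           max_flank_mismatches = max_flank_mismatches)
    in_cat <- ex$barcodes %in% cat_bcs
    tab <- table(ex$barcodes[in_cat])
    counts[names(tab), s] <- as.integer(tab)
    if (sum(counts[, s]) == 0L) {
      warning(sprintf("sample '%s' has no catalog barcode reads", s))
    }
    qc[[s]] <- list(
      total_reads = length(sample_reads[[s]]),
      accepted = sum(in_cat),
      orphan = sum(!in_cat),
      rejected = as.list(ex$rejected)
    )
  }
  list(counts = counts, qc = qc)
}

#' Restrict a count matrix to catalog barcodes
#'
#' The matrix analogue of the catalog-restriction rule: rows whose
#' barcode is not in the insertion catalog are dropped (tallied as
#' orphans); catalog barcodes never observed get zero rows.
#'
#' @param counts Barcode x sample matrix.
#' @param catalog An `insertion_catalog` or its `records` data.frame.
#' @return List with `counts` (restricted matrix, rows ordered as the
#'   catalog) and `orphan_barcodes` (count of dropped rows).
#' @export
restrict_counts <- function(counts, catalog) {
  records <- if (inherits(catalog, "insertion_catalog")) catalog$records else catalog
  keep <- intersect(records$barcode, rownames(counts))
  out <- matrix(0L, nrow = nrow(records), ncol = ncol(counts),
                dimnames = list(records$barcode, colnames(counts)))
  out[keep, ] <- counts[keep, , drop = FALSE]
  list(counts = out, orphan_barcodes = nrow(counts) - length(keep))
}
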