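# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Sliding-window Hamming search: leftmost position of `pat` in `read`
# with at most max_mm mismatches, or NA.
oracle_find_pattern <- function(read, pat, max_mm) {
  L <- nchar(pat)
  n <- nchar(read)
  if (n < L) return(NA_integer_)
  for (s in seq_len(n - L + 1L)) {
    if (hamming_str(substr(read, s, s + L - 1L), pat) <= max_mm) return(s)
  }
  NA_integer_
}

# All-pairs Hamming elimination oracle for barcode collapsing.
oracle_collapse <- function(counts, distance, ratio) {
  bcs <- names(counts)
  n <- length(bcs)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (hamming_str(bcs[i], bcs[j]) <= distance &&
          counts[j] >= ratio * counts[i]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  list(retained = counts[!drop], eliminated = bcs[drop])
}

# Exact two-sided Mann-Whitney p by enumeration of all labelings.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n1 + n2, n1, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Step-up BH by the textbook formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Mismatch-tolerant "regex" oracle for Bar-seq extraction: first position
# where the upstream flank matches with <= max_mm, then fixed-width
# barcode, then downstream flank check.
oracle_extract <- function(read, up, dn, bc_len, max_mm) {
  s <- oracle_find_pattern(read, up, max_mm)
  if (is.na(s)) return(NA_character_)
  bc_start <- s + nchar(up)
  dn_start <- bc_start + bc_len
  if (dn_start + nchar(dn) - 1L > nchar(read)) return(NA_character_)
  if (hamming_str(substr(read, dn_start, dn_start + nchar(dn) - 1L), dn) > max_mm) {
    return(NA_character_)
  }
  substr(read, bc_start, bc_start + bc_len - 1L)
}

# A truth table recast as a perfect insertion catalog (bypasses read-level
# processing where a test targets the statistics downstream).
catalog_from_truth <- function(truth) {
  data.frame(barcode = truth$barcode, chrom = truth$chrom,
             position = truth$position, strand = truth$strand,
             n_reads = 1L, mapping_class = "unique",
             gene_id = truth$gene_id, allele_species = truth$allele_species,
             stringsAsFactors = FALSE)
}

# Random barcode set with guaranteed pairwise distance >= 3 (rejection).
distinct_barcodes <- function(n, len, seed) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (all(vapply(out, function(b) hamming_str(b, cand) >= 3, logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}

# Mutate `k` distinct positions of a barcode.
mutate_barcode <- function(bc, k) {
  chars <- strsplit(bc, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
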