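# Tn-seq read processing: junction detection, fragment mapping, barcode
# error collapsing, mapping-class filters, and genic annotation, producing
# a quality-controlled insertion catalog.

#' Detect barcoded transposon-genome junctions in Tn-seq reads
#'
#' Scans each read for the final 22 bp of the transposon right arm,
#' allowing up to `max_mismatches` substitutions (no indels). The
#' leftmost hit is taken. The barcode is read `barcode_gap` bases
#' upstream of the hit (spanning `barcode_length` bases) and the genomic
#' fragment is everything downstream of the hit; reads where either span
#' runs off the read, or where the fragment is shorter than
#' `min_fragment`, are rejected with a reason code.
#'
#' @param reads `DNAStringSet` (or named character vector) of Tn-seq reads.
#' @param arm Transposon right-arm sequence (>= 22 bp; the final 22 bp are
#'   searched).
#' @param max_mismatches Maximum Hamming distance for the arm hit.
#' @param barcode_length Barcode length.
#' @param barcode_gap Bases between the end of the barcode and the start of
#'   the searched 22-mer (spacer length plus any arm prefix upstream of the
#'   final 22 bp).
#' @param min_fragment Minimum genomic fragment length.
#' @return List with `observations` (data.frame: `read_id`, `barcode`,
#'   `fragment`) and `rejected` (named integer tallies: `no_arm`,
#'   `truncated`).
#' @export
detect_junctions <- function(reads, arm, max_mismatches = 2,
                             barcode_length = 20, barcode_gap = 0,
                             min_fragment = 30) {
  if (nchar(as.character(arm)[1]) < 22) stop("arm must be >= 22 bp")
  arm22 <- substr(as.character(arm), nchar(as.character(arm)) - 21L, nchar(as.character(arm)))
  x <- if (methods::is(reads, "DNAStringSet")) reads else Biostrings::DNAStringSet(reads)
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))

  hits <- Biostrings::vmatchPattern(arm22, x, max.mismatch = max_mismatches)
  starts <- Biostrings::startIndex(hits)
  first <- vapply(starts, function(s) if (is.null(s) || !length(s)) NA_integer_ else s[1L], integer(1))

  widths <- Biostrings::width(x)
  bc_start <- first - barcode_gap - barcode_length
  frag_start <- first + 22L
  ok_arm <- !is.na(first)
  ok_span <- ok_arm & bc_start >= 1L & (widths - frag_start + 1L) >= min_fragment

  seq_chr <- as.character(x)
  obs <- data.frame(
    read_id = names(x)[ok_span],
    barcode = unname(substr(seq_chr[ok_span], bc_start[ok_span],
                            bc_start[ok_span] + barcode_length - 1L)),
    fragment = unname(substr(seq_chr[ok_span], frag_start[ok_span], widths[ok_span])),
    stringsAsFactors = FALSE
  )
  list(
    observations = obs,
    rejected = c(no_arm = sum(!ok_arm), truncated = sum(ok_arm & !ok_span))
  )
}

#' Build an exact k-mer index of a genome
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param k Seed length.
#' @return An object of class `genome_index` for [map_fragment()].
#' @export
build_genome_index <- function(genome, k = 15) {
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome) else genome
  if (is.null(names(seqs))) stop("genome must be named")
  kmers <- character(0); chroms <- character(0); pos <- integer(0)
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    n <- nchar(s)
    if (n < k) next
    p <- seq_len(n - k + 1L)
    kmers <- c(kmers, substring(s, p, p + k - 1L))
    chroms <- c(chroms, rep(chrom, length(p)))
    pos <- c(pos, p)
  }
  loc <- paste0(chroms, ":", pos)
  idx <- list2env(split(loc, kmers), hash = TRUE)
  structure(list(index = idx, k = k, seqs = seqs,
                 lens = stats::setNames(nchar(seqs), names(seqs))),
            class = "genome_index")
}

#' Map a genomic fragment by k-mer seeding and Hamming verification
#'
#' Every k-mer of the fragment (and of its reverse complement) is looked
#' up in the exact k-mer index; each seed hit proposes a full-length
#' placement, which is verified by Hamming comparison against the genome
#' with at most `max_map_mismatches` substitutions. The reported position
#' follows the junction convention: the first genomic base 3' of the
#' transposon arm on the reference strand, i.e. the placement start for
#' `+`-strand hits and the placement end for `-`-strand hits.
#'
#' @param fragment Character scalar (>= k bases).
#' @param index A `genome_index` from [build_genome_index()].
#' @param max_map_mismatches Maximum substitutions over the full fragment.
#' @return data.frame with columns `chrom`, `position`, `strand`,
#'   `mismatches`, `score` (matched bases minus mismatches); zero rows if
#'   no placement qualifies.
#' @export
map_fragment <- function(fragment, index, max_map_mismatches = 2) {
  k <- index$k
  L <- nchar(fragment)
  if (L < k) stop("fragment shorter than index k")
  out <- list()
  for (strand in c("+", "-")) {
    f <- if (strand == "+") fragment else revcomp(fragment)
    fr <- charToRaw(f)
    offs <- seq_len(L - k + 1L) - 1L
    cand <- character(0)
    for (o in offs) {
      hit <- index$index[[substr(f, o + 1L, o + k)]]
      if (!is.null(hit)) {
        sp <- strsplit(hit, ":", fixed = TRUE)
        cand <- c(cand, vapply(sp, function(z) {
          paste0(z[1L], ":", as.integer(z[2L]) - o)
        }, character(1)))
      }
    }
    for (cd in unique(cand)) {
      z <- strsplit(cd, ":", fixed = TRUE)[[1L]]
      chrom <- z[1L]; start <- as.integer(z[2L])
      if (start < 1L || start + L - 1L > index$lens[[chrom]]) next
      mm <- sum(charToRaw(substr(index$seqs[[chrom]], start, start + L - 1L)) != fr)
      if (mm <= max_map_mismatches) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          position = if (strand == "+") start else start + L - 1L,
          strand = strand, mismatches = mm, score = L - 2L * mm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      score = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Eliminate likely sequencing-error barcode satellites
#'
#' A barcode is eliminated iff some other barcode within the given
#' Hamming distance has a read count at least `dominance_ratio` times its
#' own. Elimination is removal, not merging, and all comparisons use the
#' input counts (dominating barcodes need not themselves survive). The
#' pipeline applies this first at distance 1, then at distance 2 on the
#' survivors.
#'
#' @param barcode_counts Named numeric vector: barcode -> read count (>= 1).
#' @param distance Hamming radius, 1 or 2.
#' @param dominance_ratio Dominance factor ("much more abundant").
#' @return List with `retained` (named counts) and `eliminated` (character
#'   vector of dropped barcodes).
#' @export
collapse_error_barcodes <- function(barcode_counts, distance = 1,
                                    dominance_ratio = 10) {
  if (!length(barcode_counts)) {
    return(list(retained = barcode_counts, eliminated = character(0)))
  }
  stopifnot(distance %in% c(1, 2), all(barcode_counts >= 1))
  nb <- neighbor_max_count(names(barcode_counts), unname(barcode_counts),
                           distance = as.integer(distance))
  drop <- nb >= dominance_ratio * barcode_counts
  list(retained = barcode_counts[!drop], eliminated = names(barcode_counts)[drop])
}

#' Classify a barcode's mapping evidence
#'
#' A location is *strong* when its best placement is within
#' `strong_margin` score units of a perfect full-length match (margin 2
#' admits one substitution). A barcode is `unique` with one strong
#' location and reads at weaker locations not outnumbering it;
#' `multilocus` with two or more strong locations; `ambiguous` with one
#' strong location whose reads are outnumbered by reads at weaker
#' locations; and `unmapped` with no strong location. Only `unique`
#' barcodes are retained downstream.
#'
#' @param observations data.frame with one row per candidate location:
#'   columns `chrom`, `position`, `strand`, `n_reads`, `margin` (best
#'   full-length score deficit, i.e. `2 * mismatches`).
#' @param strong_margin Maximum score deficit for a strong location.
#' @return Character scalar: `"unique"`, `"multilocus"`, `"ambiguous"`, or
#'   `"unmapped"`.
#' @export
classify_mapping <- function(observations, strong_margin = 2) {
  if (is.null(observations) || nrow(observations) == 0L) return("unmapped")
  strong <- observations$margin <= strong_margin
  n_strong <- sum(strong)
  if (n_strong == 0L) return("unmapped")
  if (n_strong >= 2L) return("multilocus")
  strong_reads <- observations$n_reads[strong]
  weak_reads <- sum(observations$n_reads[!strong])
  if (weak_reads > strong_reads) "ambiguous" else "unique"
}

#' Annotate insertion records against a gene annotation
#'
#' Assigns `gene_id` and `allele_species` when a record's position falls
#' within a gene feature on the matching chromosome; positions between
#' genes are `"intergenic"`, and records on a plasmid contig are labeled
#' `"plasmid"` (excluded from hemizygosity testing downstream).
#'
#' @param records data.frame with columns `barcode`, `chrom`, `position`,
#'   `strand`, `n_reads`, `mapping_class`.
#' @param annotation `GRanges` of gene features with mcols `gene_id` and
#'   `allele_species`.
#' @param plasmid_contigs Contig names to label `"plasmid"`.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   given, positions outside their contig raise an error (corrupt input).
#' @return The records with `gene_id` and `allele_species` columns added.
#' @export
annotate_catalog <- function(records, annotation, plasmid_contigs = "plasmid",
                             contig_lengths = NULL) {
  if (is.null(contig_lengths)) {
    contig_lengths <- S4Vectors::metadata(annotation)$contig_lengths
  }
  if (!is.null(contig_lengths)) {
    known <- records$chrom %in% c(names(contig_lengths))
    bad <- !known | records$position < 1L |
      records$position > unname(contig_lengths[records$chrom])
    if (any(bad)) {
      stop(sprintf("record position outside contig bounds (e.g. %s:%d)",
                   records$chrom[bad][1L], records$position[bad][1L]))
    }
  }
  records$gene_id <- ifelse(records$chrom %in% plasmid_contigs, "plasmid", "intergenic")
  records$allele_species <- "na"
  if (nrow(records)) {
    q <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$position, width = 1L))
    # suppress the seqlevel-mismatch warning: plasmid contigs legitimately
    # carry no features
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(q, annotation, ignore.strand = TRUE)
    )
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    records$gene_id[qi] <- annotation$gene_id[si]
    records$allele_species[qi] <- annotation$allele_species[si]
  }
  records
}

#' Run the full Tn-seq mapping stage
#'
#' Junction detection, off-by-one then off-by-two barcode collapsing,
#' fragment mapping of the retained barcodes' reads, mapping
#' classification, and genic annotation. Every input read is accounted
#' for exactly once in the QC tallies.
#'
#' @param reads Tn-seq reads (`DNAStringSet` or named character vector).
#' @param genome Genome (`DNAStringSet`).
#' @param annotation Gene `GRanges` (as from [generate_hybrid_genome()] or
#'   [read_annotation()]).
#' @param arm Transposon right-arm sequence.
#' @param barcode_length,barcode_gap,min_fragment See [detect_junctions()].
#' @param max_mismatches Arm-search mismatch allowance.
#' @param dominance_ratio Barcode-collapsing dominance factor.
#' @param k Index seed length.
#' @param max_map_mismatches Full-length mapping mismatch allowance.
#' @param strong_margin See [classify_mapping()].
#' @param plasmid_contigs Contig names labeled `"plasmid"`.
#' @return List of class `insertion_catalog`: `records` (one row per
#'   retained unique barcode: `barcode`, `chrom`, `position`, `strand`,
#'   `n_reads`, `mapping_class`, `gene_id`, `allele_species`) and `qc`
#'   (per-stage elimination tallies).
#' @export
tnseq_map <- function(reads, genome, annotation, arm,
                      barcode_length = 20, barcode_gap = 0, min_fragment = 30,
                      max_mismatches = 2, dominance_ratio = 10,
                      k = 15, max_map_mismatches = 2, strong_margin = 2,
                      plasmid_contigs = "plasmid") {
  det <- detect_junctions(reads, arm, max_mismatches = max_mismatches,
                          barcode_length = barcode_length,
                          barcode_gap = barcode_gap, min_fragment = min_fragment)
  obs <- det$observations

  bc_counts <- table(obs$barcode)
  bc_counts <- stats::setNames(as.numeric(bc_counts), names(bc_counts))
  st1 <- collapse_error_barcodes(bc_counts, distance = 1, dominance_ratio = dominance_ratio)
  st2 <- collapse_error_barcodes(st1$retained, distance = 2, dominance_ratio = dominance_ratio)
  obs_kept <- obs[obs$barcode %in% names(st2$retained), , drop = FALSE]

  idx <- build_genome_index(genome, k = k)
  contig_lengths <- idx$lens

  # map each distinct fragment once (identical fragments are common at
  # realistic depths), keeping only each read's best-scoring placements
  frag_unique <- unique(obs_kept$fragment)
  frag_hits <- lapply(frag_unique, function(f) {
    if (nchar(f) < k) return(NULL)
    m <- map_fragment(f, idx, max_map_mismatches)
    if (nrow(m) == 0L) return(NULL)
    m[m$mismatches == min(m$mismatches), , drop = FALSE]
  })
  names(frag_hits) <- frag_unique

  # aggregate per barcode x location, then classify
  recs <- list(); class_tally <- c(unique = 0L, multilocus = 0L,
                                   ambiguous = 0L, unmapped = 0L)
  by_bc <- split(obs_kept$fragment, obs_kept$barcode)
  for (bc in names(by_bc)) {
    frags <- by_bc[[bc]]
    hit_list <- frag_hits[frags]
    keep <- !vapply(hit_list, is.null, logical(1))
    obs_df <- NULL
    if (any(keep)) {
      m <- do.call(rbind, hit_list[keep])
      key <- paste(m$chrom, m$position, m$strand, sep = "\r")
      n_reads <- tapply(rep(1L, length(key)), key, sum)
      margin <- tapply(2L * m$mismatches, key, min)
      parts <- do.call(rbind, strsplit(names(n_reads), "\r", fixed = TRUE))
      obs_df <- data.frame(
        chrom = parts[, 1L], position = as.integer(parts[, 2L]),
        strand = parts[, 3L],
        n_reads = as.integer(n_reads), margin = as.numeric(margin),
        stringsAsFactors = FALSE
      )
    }
    cls <- classify_mapping(obs_df, strong_margin = strong_margin)
    class_tally[cls] <- class_tally[cls] + 1L
    if (cls == "unique") {
      i <- which(obs_df$margin <= strong_margin)
      recs[[bc]] <- data.frame(
        barcode = bc, chrom = obs_df$chrom[i], position = obs_df$position[i],
        strand = obs_df$strand[i],
        n_reads = length(frags), mapping_class = "unique",
        stringsAsFactors = FALSE
      )
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(barcode = character(0), chrom = character(0),
               position = integer(0), strand = character(0),
               n_reads = integer(0), mapping_class = character(0),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  records <- annotate_catalog(records, annotation,
                              plasmid_contigs = plasmid_contigs,
                              contig_lengths = contig_lengths)

  qc <- list(
    input_reads = length(reads),
    rejected_reads = as.list(det$rejected),
    junction_reads = nrow(obs),
    barcodes_observed = length(bc_counts),
    off_by_one_eliminated = length(st1$eliminated),
    off_by_two_eliminated = length(st2$eliminated),
    barcodes_after_collapse = length(st2$retained),
    mapping_class = as.list(class_tally),
    catalog_size = nrow(records)
  )
  structure(list(records = records, qc = qc), class = "insertion_catalog")
}
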