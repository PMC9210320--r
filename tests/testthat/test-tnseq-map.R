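# Tn-seq mapping stage: junction detection, fragment mapping, barcode
# collapsing, mapping classification, annotation, and the stage pipeline.

ARM <- "TTGACTGTACGGATTAACCCTAGAAAGATA"  # final 22 bp searched
ARM22 <- substr(ARM, nchar(ARM) - 21, nchar(ARM))

test_that("junction detection splits reads at the arm hit", {
  bc <- strrep("ACGT", 5)
  frag <- strrep("GATTACA", 6)  # 42 bp
  read <- paste0("ACCTGT", bc, ARM22, frag)
  det <- detect_junctions(read, ARM22, barcode_length = 20, barcode_gap = 0)
  expect_equal(det$observations$barcode, bc)
  expect_equal(det$observations$fragment, frag)

  # arm carrying 3 substitutions exceeds the 2-mismatch allowance
  set.seed(1)
  arm_bad <- mutate_barcode(ARM22, 3)
  det2 <- detect_junctions(paste0("ACCTGT", bc, arm_bad, frag), ARM22,
                           barcode_length = 20, barcode_gap = 0)
  expect_equal(nrow(det2$observations), 0L)
  expect_equal(unname(det2$rejected["no_arm"]), 1L)

  # barcode would run off the read start -> truncated
  det3 <- detect_junctions(paste0("AC", ARM22, frag), ARM22,
                           barcode_length = 20, barcode_gap = 0)
  expect_equal(unname(det3$rejected["truncated"]), 1L)
})

test_that("junction detection agrees with a sliding-window Hamming oracle", {
  set.seed(42)
  n <- 400
  reads <- character(n)
  for (i in seq_len(n)) {
    # a mix: true junctions with 0-3 arm errors, and pure random reads
    if (i %% 4 == 0) {
      reads[i] <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    } else {
      arm <- ARM22
      k <- sample(0:3, 1)
      if (k > 0) arm <- mutate_barcode(arm, k)
      bc <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
      frag <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
      reads[i] <- paste0("ACCTGT", bc, arm, frag)
    }
  }
  det <- detect_junctions(reads, ARM22, max_mismatches = 2,
                          barcode_length = 20, barcode_gap = 0, min_fragment = 30)
  got <- logical(n)
  names(reads) <- paste0("read", seq_len(n))
  got[match(det$observations$read_id, names(reads))] <- TRUE
  for (i in seq_len(n)) {
    s <- oracle_find_pattern(reads[i], ARM22, 2)
    want <- !is.na(s) && (s - 20 - 1) >= 0 && (nchar(reads[i]) - (s + 22) + 1) >= 30
    expect_equal(got[i], want, info = paste("read", i))
    if (want) {
      row <- det$observations[det$observations$read_id == names(reads)[i], ]
      expect_equal(row$barcode, unname(substr(reads[i], s - 20, s - 1)))
      expect_equal(row$fragment, unname(substr(reads[i], s + 22, nchar(reads[i]))))
    }
  }
  expect_equal(nrow(det$observations) + sum(det$rejected), n)  # accounting
})

test_that("fragment mapping finds unique, duplicated, and absent spans", {
  set.seed(7)
  chrA <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  dup <- substr(chrA, 101, 140)
  chrB <- paste0(
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
    dup,
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  )
  idx <- build_genome_index(c(A = chrA, B = chrB), k = 15)

  m1 <- map_fragment(substr(chrA, 301, 340), idx)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$chrom, "A"); expect_equal(m1$position, 301L)
  expect_equal(m1$strand, "+"); expect_equal(m1$mismatches, 0L)

  m2 <- map_fragment(dup, idx)
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$chrom, c("A", "B"))
  expect_true(all(m2$score == max(m2$score)))

  m3 <- map_fragment(paste(rep("ACGT", 10), collapse = ""), idx)
  expect_equal(nrow(m3), 0L)

  # reverse strand: position reports the reference end of the placement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(substr(chrA, 301, 340))))
  m4 <- map_fragment(rc, idx)
  expect_equal(m4$strand, "-")
  expect_equal(m4$position, 340L)

  expect_error(map_fragment("ACGTACGT", idx), "shorter")
})

test_that("barcode collapsing follows the dominance rule", {
  a <- strrep("A", 20)
  b <- a; substr(b, 3, 3) <- "C"   # distance 1 from a
  r1 <- collapse_error_barcodes(c(setNames(1000, a), setNames(5, b)),
                                distance = 1, dominance_ratio = 10)
  expect_setequal(names(r1$retained), a)
  expect_equal(r1$eliminated, b)

  # near-equal abundances: genuine distinct clones, both kept
  r2 <- collapse_error_barcodes(c(setNames(1000, a), setNames(800, b)),
                                distance = 1, dominance_ratio = 10)
  expect_equal(length(r2$eliminated), 0L)

  expect_equal(collapse_error_barcodes(setNames(numeric(0), character(0)))$eliminated,
               character(0))
})

test_that("collapsing matches the all-pairs oracle on satellite-laden sets", {
  parents <- distinct_barcodes(60, 12, seed = 13)
  set.seed(14)
  counts <- setNames(sample(200:2000, 60, replace = TRUE), parents)
  for (p in sample(parents, 30)) {                      # distance-1 satellites
    sat <- mutate_barcode(p, 1)
    counts[sat] <- sample(1:10, 1)
  }
  for (p in sample(parents, 15)) {                      # distance-2 satellites
    sat <- mutate_barcode(p, 2)
    counts[sat] <- sample(1:10, 1)
  }
  counts <- counts[!duplicated(names(counts))]

  got1 <- collapse_error_barcodes(counts, distance = 1, dominance_ratio = 10)
  want1 <- oracle_collapse(counts, 1, 10)
  expect_setequal(names(got1$retained), names(want1$retained))

  got2 <- collapse_error_barcodes(got1$retained, distance = 2, dominance_ratio = 10)
  want2 <- oracle_collapse(want1$retained, 2, 10)
  expect_setequal(names(got2$retained), names(want2$retained))
})

test_that("mapping classes follow the strong/weak evidence rules", {
  one <- data.frame(chrom = "A", position = 10L, strand = "+",
                    n_reads = 40L, margin = 0)
  expect_equal(classify_mapping(one), "unique")

  two <- rbind(one, data.frame(chrom = "B", position = 99L, strand = "+",
                               n_reads = 3L, margin = 2))
  expect_equal(classify_mapping(two), "multilocus")

  amb <- rbind(one, data.frame(chrom = "B", position = 99L, strand = "+",
                               n_reads = 25L, margin = 6))
  amb$n_reads[1] <- 10L
  expect_equal(classify_mapping(amb), "ambiguous")

  expect_equal(classify_mapping(NULL), "unmapped")
})

test_that("annotation assigns genes, intergenic spans, and plasmid records", {
  cfg <- sim_config(n_genes = 3, seed = 21)
  ga <- generate_hybrid_genome(cfg)
  g1 <- ga$annotation[ga$annotation$gene_id == "g0001" &
                      ga$annotation$allele_species == "cer"]
  recs <- data.frame(
    barcode = c("b1", "b2", "b3"),
    chrom = c("cer_chrI", "cer_chrI", "plasmid"),
    position = c(GenomicRanges::start(g1) + 5L, 10L, 100L),
    strand = "+", n_reads = 5L, mapping_class = "unique",
    stringsAsFactors = FALSE
  )
  ann <- annotate_catalog(recs, ga$annotation)
  expect_equal(ann$gene_id, c("g0001", "intergenic", "plasmid"))
  expect_equal(ann$allele_species, c("cer", "na", "na"))

  recs$position[1] <- 10^7
  expect_error(annotate_catalog(recs, ga$annotation), "bounds")
})

test_that("error-free reads reconstruct the truth catalog exactly", {
  cfg <- sim_config(n_genes = 12, inserts_per_allele_mean = 4, base_error_rate = 0,
                    frac_multilocus = 0, tnseq_depth_mean = 20, seed = 31)
  sim <- simulate_experiment(cfg)
  gap <- nchar(cfg$sequences$u1_spacer) + nchar(cfg$sequences$tn_arm) - 22L
  cat <- tnseq_map(sim$tnseq_reads, sim$genome, sim$annotation,
                   cfg$sequences$tn_arm, barcode_gap = gap)
  seen <- unique(substr(as.character(sim$tnseq_reads), 7L, 26L))  # depth>0 clones
  truth <- sim$truth[sim$truth$barcode %in% seen, ]
  expect_equal(nrow(cat$records), nrow(truth))
  m <- merge(cat$records, truth, by = "barcode")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$chrom.x == m$chrom.y))
  expect_true(all(m$position.x == m$position.y))
  expect_true(all(m$strand.x == m$strand.y))
  expect_true(all(m$gene_id.x == m$gene_id.y))
  expect_true(all(m$allele_species.x == m$allele_species.y))
  # accounting: reads in = junction reads + rejected
  expect_equal(cat$qc$junction_reads + sum(unlist(cat$qc$rejected_reads)),
               cat$qc$input_reads)
})

test_that("relabeling the allele chromosomes only relabels allele_species", {
  cfg <- sim_config(n_genes = 8, inserts_per_allele_mean = 4, base_error_rate = 0,
                    frac_multilocus = 0, tnseq_depth_mean = 15, seed = 33)
  sim <- simulate_experiment(cfg)
  gap <- nchar(cfg$sequences$u1_spacer) + nchar(cfg$sequences$tn_arm) - 22L

  swap <- function(x) ifelse(x == "cer_chrI", "par_chrI",
                             ifelse(x == "par_chrI", "cer_chrI", x))
  genome2 <- sim$genome
  names(genome2) <- swap(names(genome2))
  ann2 <- GenomicRanges::GRanges(swap(as.character(GenomicRanges::seqnames(sim$annotation))),
                                 IRanges::IRanges(GenomicRanges::start(sim$annotation),
                                                  GenomicRanges::end(sim$annotation)),
                                 gene_id = sim$annotation$gene_id,
                                 allele_species = ifelse(sim$annotation$allele_species == "cer",
                                                         "par", "cer"))
  S4Vectors::metadata(ann2)$contig_lengths <-
    setNames(Biostrings::width(genome2), names(genome2))

  c1 <- tnseq_map(sim$tnseq_reads, sim$genome, sim$annotation,
                  cfg$sequences$tn_arm, barcode_gap = gap)
  c2 <- tnseq_map(sim$tnseq_reads, genome2, ann2,
                  cfg$sequences$tn_arm, barcode_gap = gap)
  r1 <- c1$records[order(c1$records$barcode), ]
  r2 <- c2$records[order(c2$records$barcode), ]
  expect_equal(r2$chrom, swap(r1$chrom))
  expect_equal(r1$position, r2$position)
  expect_equal(r1$gene_id, r2$gene_id)
  flip <- c(cer = "par", par = "cer", na = "na")
  expect_equal(r2$allele_species, unname(flip[r1$allele_species]))
})
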