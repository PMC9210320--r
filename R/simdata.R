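# Synthetic hemizygote-pool experiment: hybrid genome, barcoded insertion
# pool, Tn-seq junction reads, and Bar-seq competition count matrices with
# known ground-truth allelic fitness effects.

#' Configuration for the synthetic hemizygote-pool experiment
#'
#' Bundles every knob of the simulator. Defaults describe the emulated
#' experiment: random 20-bp barcodes flanked by constant priming regions,
#' a per-base sequencing error rate of 1.38% (so off-by-one barcode
#' satellites arise naturally), Tn-seq read depth with median ~47 reads
#' per insertion, 12 experimental and 12 control replicate competition
#' cultures, and 12 doublings of logarithmic growth (the emulated
#' competitions ran 10--15 generations).
#'
#' @param n_genes Number of genes per allele set (each gene exists once on
#'   the cer chromosome and once on the par chromosome).
#' @param gene_length_bp Gene length in bp.
#' @param intergenic_bp Intergenic spacer length in bp (also flanks ends).
#' @param barcode_length Barcode length in bp (>= 8).
#' @param inserts_per_allele_mean Poisson mean of insertions per gene per
#'   allele.
#' @param tnseq_depth_mean Poisson mean of Tn-seq reads per insertion.
#' @param barseq_depth_mean Mean Bar-seq reads per clone per sample.
#' @param base_error_rate Per-base substitution error probability applied to
#'   simulated reads.
#' @param frac_multilocus Probability that a barcode is assigned a second
#'   insertion location (exercises the multi-locus filter).
#' @param n_replicates_exp,n_replicates_ctrl Replicate competition cultures
#'   at the experimental and control temperature.
#' @param doublings Number of population doublings during the competition;
#'   must lie in \[10, 15\].
#' @param effect_table `NULL` (all fitness 1) or a data.frame with columns
#'   `gene_id`, `w_cer_uncovered`, `w_par_uncovered`: per-doubling relative
#'   fitness at the experimental temperature of a clone whose *intact*
#'   allele is the named species. Control-temperature fitness is 1 for all
#'   clones.
#' @param tnseq_context_bp Genomic context length carried by each Tn-seq
#'   junction read.
#' @param freq_sdlog Log-sd of clone starting frequencies (lognormal).
#' @param plasmid_bp Length of the plasmid contig.
#' @param seed Default seed used when an operation is called without one.
#' @param sequences List of the fixed construct sequences: `tn_flank`
#'   (read prefix upstream of the barcode), `u1_spacer` (between barcode
#'   and transposon arm in Tn-seq reads), `tn_arm` (transposon right-arm
#'   terminus; detection uses its final 22 bp), `bar_up`/`bar_dn` (priming
#'   regions flanking the barcode in Bar-seq amplicons). These are
#'   parameters of the detection operations, not hard-coded constants.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       gene_length_bp = 300,
                       intergenic_bp = 150,
                       barcode_length = 20,
                       inserts_per_allele_mean = 5,
                       tnseq_depth_mean = 47,
                       barseq_depth_mean = 50,
                       base_error_rate = 0.0138,
                       frac_multilocus = 0.05,
                       n_replicates_exp = 12,
                       n_replicates_ctrl = 12,
                       doublings = 12,
                       effect_table = NULL,
                       tnseq_context_bp = 40,
                       freq_sdlog = 0.5,
                       plasmid_bp = 3000,
                       seed = 1,
                       sequences = list(
                         tn_flank  = "ACCTGT",
                         u1_spacer = "CGTACGCTGCAG",
                         tn_arm    = "TTGACTGTACGGATTAACCCTAGAAAGATA",
                         bar_up    = "GTCGACCTGCAGCGTACG",
                         bar_dn    = "AGAGACCTCGTGGACATC"
                       )) {
  cfg <- list(
    n_genes = n_genes, gene_length_bp = gene_length_bp,
    intergenic_bp = intergenic_bp, barcode_length = barcode_length,
    inserts_per_allele_mean = inserts_per_allele_mean,
    tnseq_depth_mean = tnseq_depth_mean,
    barseq_depth_mean = barseq_depth_mean,
    base_error_rate = base_error_rate,
    frac_multilocus = frac_multilocus,
    n_replicates_exp = n_replicates_exp,
    n_replicates_ctrl = n_replicates_ctrl,
    doublings = doublings, effect_table = effect_table,
    tnseq_context_bp = tnseq_context_bp, freq_sdlog = freq_sdlog,
    plasmid_bp = plasmid_bp, seed = seed, sequences = sequences
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' @param config A `sim_config` list.
#' @return The config, invisibly; stops with a message naming the first
#'   offending field otherwise.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  pos_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
  prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
  chk(pos_count(config$n_genes), "n_genes", "must be a positive count")
  chk(pos_count(config$gene_length_bp), "gene_length_bp", "must be a positive count")
  chk(pos_count(config$intergenic_bp), "intergenic_bp", "must be a positive count")
  chk(pos_count(config$barcode_length) && config$barcode_length >= 8,
      "barcode_length", "must be a count >= 8")
  chk(is.numeric(config$inserts_per_allele_mean) && config$inserts_per_allele_mean > 0,
      "inserts_per_allele_mean", "must be positive")
  chk(is.numeric(config$tnseq_depth_mean) && config$tnseq_depth_mean > 0,
      "tnseq_depth_mean", "must be positive")
  chk(is.numeric(config$barseq_depth_mean) && config$barseq_depth_mean > 0,
      "barseq_depth_mean", "must be positive")
  chk(prob(config$base_error_rate), "base_error_rate", "must be a probability")
  chk(prob(config$frac_multilocus), "frac_multilocus", "must be a probability")
  chk(pos_count(config$n_replicates_exp), "n_replicates_exp", "must be a positive count")
  chk(pos_count(config$n_replicates_ctrl), "n_replicates_ctrl", "must be a positive count")
  chk(is.numeric(config$doublings) && config$doublings >= 10 && config$doublings <= 15,
      "doublings", "must lie in [10, 15]")
  chk(config$intergenic_bp >= config$tnseq_context_bp,
      "intergenic_bp", "must be >= tnseq_context_bp so junction context never runs off a contig")
  chk(nchar(config$sequences$tn_arm) >= 22, "sequences$tn_arm", "must be >= 22 bp")
  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    chk(is.data.frame(et) && all(c("gene_id", "w_cer_uncovered", "w_par_uncovered") %in% names(et)),
        "effect_table", "needs columns gene_id, w_cer_uncovered, w_par_uncovered")
    chk(all(et$w_cer_uncovered >= 0) && all(et$w_par_uncovered >= 0),
        "effect_table", "fitness values must be >= 0")
  }
  invisible(config)
}

#' Generate a synthetic hybrid genome and annotation
#'
#' Builds one chromosome per parental allele set (`cer_chrI`, `par_chrI`)
#' with `n_genes` non-overlapping genes each, separated by intergenic
#' spacers, plus a `plasmid` contig carrying no gene features. The two
#' allele chromosomes carry independent random sequence, emulating the
#' interspecies divergence that lets junction fragments map uniquely to
#' one allele. Gene features carry `gene_id` and `allele_species`
#' attributes; the same `gene_id` appears once per species.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `genome` (a named `DNAStringSet`) and `annotation`
#'   (a `GRanges` of gene features with mcols `gene_id`, `allele_species`).
#' @export
generate_hybrid_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, 1L))
  ng <- config$n_genes
  gl <- config$gene_length_bp
  ig <- config$intergenic_bp
  chrom_len <- ng * gl + (ng + 1L) * ig
  gene_ids <- sprintf("g%04d", seq_len(ng))
  starts <- ig + (seq_len(ng) - 1L) * (gl + ig) + 1L

  seqs <- c(
    cer_chrI = random_dna(1L, chrom_len),
    par_chrI = random_dna(1L, chrom_len),
    plasmid  = random_dna(1L, config$plasmid_bp)
  )
  genome <- Biostrings::DNAStringSet(seqs)

  ann <- GenomicRanges::GRanges(
    seqnames = rep(c("cer_chrI", "par_chrI"), each = ng),
    ranges = IRanges::IRanges(start = rep(starts, 2L), width = gl),
    strand = "+",
    type = "gene",
    gene_id = rep(gene_ids, 2L),
    allele_species = rep(c("cer", "par"), each = ng)
  )
  # consumers take contig lengths from metadata; GFF3 round-trips re-derive
  # them from the genome FASTA instead
  S4Vectors::metadata(ann)$contig_lengths <- stats::setNames(nchar(seqs), names(seqs))
  list(genome = genome, annotation = ann)
}

#' Generate a barcoded insertion pool with ground truth
#'
#' Draws transposon insertion sites uniformly within genes and intergenic
#' spans on both allele chromosomes (and on the plasmid contig), assigns
#' each clone a random barcode, marks a fraction of barcodes as
#' multi-locus (two insertion locations), and draws lognormal clone
#' starting frequencies. True (single-locus) barcodes are regenerated
#' until all pairwise Hamming distances are >= 3, so that injected
#' sequencing errors create unambiguous off-by-one satellites.
#'
#' @param genome,annotation Output of [generate_hybrid_genome()].
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A data.frame of class `sim_truth`, one row per insertion
#'   location, with columns `barcode`, `chrom`, `position` (1-based, first
#'   genomic base 3' of the transposon arm on the reference strand),
#'   `strand`, `gene_id` (`"intergenic"`/`"plasmid"` for non-genic),
#'   `allele_species` (`"na"` for non-genic), `multilocus`,
#'   `initial_frequency` (per clone; rows of a multi-locus barcode share
#'   it; sums to 1 over clones).
#' @export
generate_pool <- function(genome, annotation, config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, 2L))
  ctx <- config$tnseq_context_bp
  lens <- S4Vectors::metadata(annotation)$contig_lengths
  if (is.null(lens)) lens <- stats::setNames(Biostrings::width(genome), names(genome))

  ann_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    gene_id = annotation$gene_id,
    allele_species = annotation$allele_species,
    stringsAsFactors = FALSE
  )

  # genic insertions: Poisson per gene per allele, uniform within the gene
  n_per_gene <- stats::rpois(nrow(ann_df), config$inserts_per_allele_mean)
  gidx <- rep(seq_len(nrow(ann_df)), n_per_gene)
  genic <- data.frame(
    chrom = ann_df$chrom[gidx],
    position = ann_df$start[gidx] +
      floor(stats::runif(length(gidx)) * (ann_df$end[gidx] - ann_df$start[gidx] + 1L)),
    gene_id = ann_df$gene_id[gidx],
    allele_species = ann_df$allele_species[gidx],
    stringsAsFactors = FALSE
  )

  # intergenic + plasmid insertions at the same per-bp density
  per_bp <- config$inserts_per_allele_mean / config$gene_length_bp
  nongenic <- list()
  for (chrom in names(lens)) {
    len <- lens[[chrom]]
    genes_here <- ann_df[ann_df$chrom == chrom, , drop = FALSE]
    # positions must leave room for a full downstream context on + strand
    # and upstream on -; restrict draw range accordingly
    lo <- ctx
    hi <- len - ctx + 1L
    if (hi <= lo) next
    span_bp <- if (nrow(genes_here)) len - sum(genes_here$end - genes_here$start + 1L) else len
    n <- stats::rpois(1L, per_bp * span_bp)
    if (n == 0L) next
    pos <- integer(0)
    while (length(pos) < n) {
      cand <- sample(seq.int(lo, hi), n - length(pos), replace = TRUE)
      if (nrow(genes_here)) {
        in_gene <- vapply(cand, function(p) any(p >= genes_here$start & p <= genes_here$end), logical(1))
        cand <- cand[!in_gene]
      }
      pos <- c(pos, cand)
    }
    nongenic[[chrom]] <- data.frame(
      chrom = chrom, position = pos,
      gene_id = if (chrom == "plasmid") "plasmid" else "intergenic",
      allele_species = "na", stringsAsFactors = FALSE
    )
  }
  sites <- rbind(genic, do.call(rbind, nongenic))
  # clamp genic positions for context room as well (gene bodies always have
  # an intergenic spacer >= ctx downstream, but keep the guard explicit)
  sites$position <- pmin(pmax(sites$position, ctx), lens[sites$chrom] - ctx + 1L)
  sites$strand <- sample(c("+", "-"), nrow(sites), replace = TRUE)
  sites <- sites[sample.int(nrow(sites)), , drop = FALSE]  # shuffle before barcode assignment
  rownames(sites) <- NULL

  n_sites <- nrow(sites)
  if (n_sites == 0L) stop("configuration produced an empty pool")
  if (4^config$barcode_length < 100 * n_sites) {
    stop("requested pool size exceeds distinct-barcode capacity at this barcode_length")
  }

  # assign sites to barcodes; a multilocus barcode consumes two sites
  ml_flag <- stats::runif(n_sites) < config$frac_multilocus
  consumed <- cumsum(1L + as.integer(ml_flag))
  n_clones <- which(consumed >= n_sites)[1L]
  if (is.na(n_clones)) n_clones <- n_sites
  ml_flag <- ml_flag[seq_len(n_clones)]
  if (consumed[n_clones] > n_sites) ml_flag[n_clones] <- FALSE  # last clone takes one site

  barcodes <- random_dna(n_clones, config$barcode_length)
  repeat {
    nb <- neighbor_max_count(barcodes, rep(1, n_clones), distance = 2L)
    clash <- which(nb > 0)
    if (!length(clash)) break
    barcodes[clash] <- random_dna(length(clash), config$barcode_length)
  }

  clone_of_site <- rep(seq_len(n_clones), times = 1L + as.integer(ml_flag))[seq_len(n_sites)]
  freq <- stats::rlnorm(n_clones, 0, config$freq_sdlog)
  freq <- freq / sum(freq)

  truth <- sites
  truth$barcode <- barcodes[clone_of_site]
  truth$multilocus <- ml_flag[clone_of_site]
  truth$initial_frequency <- freq[clone_of_site]
  truth <- truth[, c("barcode", "chrom", "position", "strand", "gene_id",
                     "allele_species", "multilocus", "initial_frequency")]
  class(truth) <- c("sim_truth", "data.frame")
  attr(truth, "effect_table") <- config$effect_table
  truth
}

#' Ground-truth allelic effects on the temperature statistic
#'
#' The simulated true difference in the temperature effect t between
#' clones disrupted in the cer allele and clones disrupted in the par
#' allele of each gene: `doublings * log2(w_par_uncovered / w_cer_uncovered)`.
#'
#' @param config A `sim_config`.
#' @return Named numeric vector over genes in the effect table (empty if
#'   none); genes absent from the table have true effect 0.
#' @export
true_effects <- function(config) {
  et <- config$effect_table
  if (is.null(et)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(
    config$doublings * log2(et$w_par_uncovered / et$w_cer_uncovered),
    et$gene_id
  )
}

#' Simulate Tn-seq junction reads
#'
#' Each read is `[flank][barcode][spacer][transposon arm][genomic context]`,
#' with per-base substitution errors applied to the whole read at
#' `base_error_rate` (so distance-1 barcode satellites arise naturally).
#' Read count per insertion location is Poisson(`tnseq_depth_mean`);
#' locations drawn at depth 0 are absent from the output.
#'
#' @param truth A `sim_truth` from [generate_pool()].
#' @param genome The genome `DNAStringSet`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A named `DNAStringSet` of reads (names carry the truth row and
#'   read index).
#' @export
simulate_tnseq_reads <- function(truth, genome, config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, 3L))
  ctx <- config$tnseq_context_bp
  sq <- config$sequences
  depth <- stats::rpois(nrow(truth), config$tnseq_depth_mean)
  keep <- which(depth > 0L)
  if (!length(keep)) return(Biostrings::DNAStringSet())

  genome_chr <- as.character(genome)
  context <- vapply(keep, function(i) {
    chrom <- truth$chrom[i]; p <- truth$position[i]
    if (truth$strand[i] == "+") {
      substr(genome_chr[[chrom]], p, p + ctx - 1L)
    } else {
      revcomp(substr(genome_chr[[chrom]], p - ctx + 1L, p))
    }
  }, character(1))

  templates <- paste0(sq$tn_flank, truth$barcode[keep], sq$u1_spacer, sq$tn_arm, context)
  reads <- rep(templates, depth[keep])
  ids <- paste0("tn_", rep(keep, depth[keep]), "_",
                unlist(lapply(depth[keep], seq_len)))
  reads <- inject_substitutions(reads, config$base_error_rate)
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  out
}

#' Simulate Bar-seq amplicon reads for one sample
#'
#' Produces `counts[b]` amplicons `[bar_up][barcode][bar_dn]` per barcode,
#' with per-base substitution errors at `base_error_rate`.
#'
#' @param counts Named integer vector (barcode -> read count).
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return A named `DNAStringSet` of amplicon reads.
#' @export
simulate_barseq_reads <- function(counts, config, seed = config$seed) {
  set.seed(stage_seed(seed, 4L))
  counts <- counts[counts > 0]
  sq <- config$sequences
  reads <- rep(paste0(sq$bar_up, names(counts), sq$bar_dn), counts)
  if (!length(reads)) return(Biostrings::DNAStringSet())
  reads <- inject_substitutions(reads, config$base_error_rate)
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- paste0("bar_", seq_along(reads))
  out
}

#' Simulate the pooled competition and Bar-seq counting
#'
#' Deterministic exponential growth per doubling with multinomial
#' sequencing noise only: a clone inserted in the cer allele of gene g
#' (par allele uncovered, i.e. intact) has expected frequency
#' proportional to `initial_frequency * w_par_uncovered(g)^doublings` in
#' experimental samples; all clones have fitness 1 at the control
#' temperature. A multi-locus clone multiplies the fitness factors of its
#' disrupted loci. Per sample, a library of
#' `round(barseq_depth_mean * n_clones)` reads is drawn multinomially.
#'
#' @param truth A `sim_truth`.
#' @param config A `sim_config` (its `effect_table` supplies fitness pairs).
#' @param seed Integer seed.
#' @return List with `counts` (barcode x sample integer matrix) and
#'   `samples` (data.frame: `sample_id`, `temperature` in
#'   `{experimental, control}`, `replicate`).
#' @export
simulate_competition <- function(truth, config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, 5L))
  et <- config$effect_table

  clones <- unique(truth$barcode)
  f0 <- truth$initial_frequency[match(clones, truth$barcode)]

  w <- rep(1, length(clones))
  if (!is.null(et)) {
    if (any(et$w_cer_uncovered < 0) || any(et$w_par_uncovered < 0)) {
      stop("fitness values must be >= 0")
    }
    for (j in seq_len(nrow(truth))) {
      g <- truth$gene_id[j]
      row <- match(g, et$gene_id)
      if (is.na(row)) next
      k <- match(truth$barcode[j], clones)
      # insertion in the cer allele leaves the par allele uncovered (intact)
      w[k] <- w[k] * if (truth$allele_species[j] == "cer") {
        et$w_par_uncovered[row]
      } else {
        et$w_cer_uncovered[row]
      }
    }
  }

  freq_ctrl <- f0 / sum(f0)
  freq_exp <- f0 * w^config$doublings
  freq_exp <- freq_exp / sum(freq_exp)

  n_exp <- config$n_replicates_exp
  n_ctrl <- config$n_replicates_ctrl
  sample_ids <- c(sprintf("exp_%02d", seq_len(n_exp)),
                  sprintf("ctrl_%02d", seq_len(n_ctrl)))
  sheet <- data.frame(
    sample_id = sample_ids,
    temperature = rep(c("experimental", "control"), c(n_exp, n_ctrl)),
    replicate = c(seq_len(n_exp), seq_len(n_ctrl)),
    stringsAsFactors = FALSE
  )

  lib_size <- round(config$barseq_depth_mean * length(clones))
  counts <- matrix(0L, nrow = length(clones), ncol = length(sample_ids),
                   dimnames = list(clones, sample_ids))
  for (s in seq_along(sample_ids)) {
    p <- if (sheet$temperature[s] == "experimental") freq_exp else freq_ctrl
    counts[, s] <- stats::rmultinom(1L, lib_size, p)[, 1L]
  }
  list(counts = counts, samples = sheet)
}

#' Run the whole simulator in one call
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List: `genome`, `annotation`, `truth`, `tnseq_reads`, `counts`,
#'   `samples`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  ga <- generate_hybrid_genome(config, seed)
  truth <- generate_pool(ga$genome, ga$annotation, config, seed)
  reads <- simulate_tnseq_reads(truth, ga$genome, config, seed)
  comp <- simulate_competition(truth, config, seed)
  list(genome = ga$genome, annotation = ga$annotation, truth = truth,
       tnseq_reads = reads, counts = comp$counts, samples = comp$samples)
}
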