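# Reciprocal hemizygosity testing: normalization, per-clone temperature
# effects, genotype and gene quality gates, Mann-Whitney tests with BH
# correction, allelic effect sizes and hit calling.

#' Parameters of the reciprocal hemizygosity test
#'
#' Defaults are the screen's standard thresholds: a genotype is dropped
#' when the coefficient of variation of its t vector exceeds 2.0 or its
#' mean control abundance is below 1.1 normalized reads; a gene needs at
#' least three genotypes per allele and per-allele pooled-t CV at most
#' 10; hits require adjusted P < 0.05 and effect size < -0.5.
#'
#' @param cv_max Per-genotype CV ceiling on the t vector.
#' @param min_norm_reads Floor on mean control-replicate normalized
#'   abundance.
#' @param min_genotypes Minimum retained genotypes per allele per gene.
#' @param cv_t_max Ceiling on the CV of the pooled per-allele t values.
#' @param p_max Hit threshold on BH-adjusted P.
#' @param effect_max Hit threshold on effect size (strictly below).
#' @param zero_pseudo Pseudoreads substituted for a zero experimental
#'   abundance: t_i becomes `log2(zero_pseudo / a_control_mean)`, keeping
#'   fully-dropped-out clones (the strongest phenotypes) in the test.
#' @param cv_on Basis of the genotype CV filter; see [filter_genotypes()].
#' @return A list of class `rh_params`.
#' @export
rh_params <- function(cv_max = 2.0, min_norm_reads = 1.1, min_genotypes = 3,
                      cv_t_max = 10, p_max = 0.05, effect_max = -0.5,
                      zero_pseudo = 0.5, cv_on = "abundance") {
  structure(list(cv_max = cv_max, min_norm_reads = min_norm_reads,
                 min_genotypes = min_genotypes, cv_t_max = cv_t_max,
                 p_max = p_max, effect_max = effect_max,
                 zero_pseudo = zero_pseudo, cv_on = cv_on),
            class = "rh_params")
}

#' Normalize per-sample counts to a common sequencing depth
#'
#' Each sample's counts are scaled so its total equals the median raw
#' column total across samples. Using the median (rather than, say, 1)
#' keeps normalized abundances on a raw-read scale, so the
#' 1.1-normalized-reads genotype floor retains its meaning.
#'
#' @param counts Barcode x sample numeric matrix.
#' @return Normalized matrix of the same shape; all column totals equal
#'   the median raw total.
#' @export
normalize_counts <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("sample '%s' has zero total reads",
                 colnames(counts)[which(totals == 0)[1L]]))
  }
  target <- stats::median(totals)
  sweep(counts, 2L, target / totals, `*`)
}

#' Per-genotype temperature effects
#'
#' For each genotype (barcode), the mean normalized control abundance
#' `a_control_mean` is taken over all control replicates, and the
#' temperature effect in experimental replicate i is
#' `t_i = log2(a_experimental_i / a_control_mean)`. Genotypes absent from
#' every control replicate are excluded (reason-coded). A zero
#' experimental abundance with positive control mean yields a -Inf
#' sentinel, immediately replaced by `log2(zero_pseudo / a_control_mean)`.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param sample_sheet data.frame: `sample_id`, `temperature`
#'   (`"experimental"`/`"control"`), `replicate`.
#' @param zero_pseudo Pseudoread level replacing zero experimental
#'   abundances (set `NA` to keep -Inf sentinels).
#' @return List of class `temperature_effect`: `t` (genotype x
#'   experimental-replicate matrix), `a_ctrl_mean` (named vector), and
#'   `excluded` (data.frame `barcode`, `reason`).
#' @export
temperature_effect <- function(norm, sample_sheet, zero_pseudo = 0.5) {
  stopifnot(all(c("sample_id", "temperature") %in% names(sample_sheet)))
  exp_ids <- sample_sheet$sample_id[sample_sheet$temperature == "experimental"]
  ctrl_ids <- sample_sheet$sample_id[sample_sheet$temperature == "control"]
  stopifnot(all(c(exp_ids, ctrl_ids) %in% colnames(norm)))

  a_ctrl <- norm[, ctrl_ids, drop = FALSE]
  a_ctrl_mean <- rowMeans(a_ctrl)
  ok <- a_ctrl_mean > 0
  excluded <- data.frame(barcode = rownames(norm)[!ok],
                         reason = rep("zero_control_mean", sum(!ok)),
                         stringsAsFactors = FALSE)
  a_exp <- norm[ok, exp_ids, drop = FALSE]
  t_mat <- log2(sweep(a_exp, 1L, a_ctrl_mean[ok], `/`))
  if (!is.na(zero_pseudo)) {
    zero <- a_exp == 0
    if (any(zero)) {
      repl <- log2(zero_pseudo / a_ctrl_mean[ok])
      t_mat[zero] <- matrix(repl, nrow = nrow(t_mat),
                            ncol = ncol(t_mat))[zero]
    }
  }
  cv_ctrl <- apply(a_ctrl[ok, , drop = FALSE], 1L, function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / mean(x)
  })
  structure(list(t = t_mat, a_ctrl_mean = a_ctrl_mean[ok],
                 cv_ctrl = cv_ctrl, excluded = excluded),
            class = "temperature_effect")
}

# CV with sd (n-1 denominator) over |mean|; NA when fewer than 2 values.
cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / abs(mean(x))
}

#' Filter noisy or low-abundance genotypes
#'
#' Drops a genotype when its replicate-to-replicate coefficient of
#' variation exceeds `cv_max`, when its mean control-replicate normalized
#' abundance is below `min_norm_reads`, or when too few replicates leave
#' the CV undefined. All drops are reason-coded.
#'
#' The CV is computed, by default, on the genotype's normalized
#' abundances across control replicates (the denominator of t, whose
#' noise the filter guards); setting `cv_on = "t"` instead takes
#' `sd(t)/|mean(t)|` over the t vector. The abundance basis is the
#' default because under a true null the mean of t is near zero, so a CV
#' on t diverges and would discard well-measured genotypes wholesale.
#'
#' @param effects A `temperature_effect`.
#' @param cv_max,min_norm_reads See [rh_params()].
#' @param cv_on Quantity the CV filter operates on: `"abundance"`
#'   (control-replicate normalized abundances, default) or `"t"`.
#' @return A `temperature_effect` restricted to retained genotypes, with
#'   the new exclusions appended to `excluded`.
#' @export
filter_genotypes <- function(effects, cv_max = 2.0, min_norm_reads = 1.1,
                             cv_on = c("abundance", "t")) {
  cv_on <- match.arg(cv_on)
  t_mat <- effects$t
  cvs <- if (cv_on == "t") apply(t_mat, 1L, cv) else effects$cv_ctrl
  low <- effects$a_ctrl_mean < min_norm_reads
  undef <- is.na(cvs)
  noisy <- !undef & cvs > cv_max
  drop <- low | undef | noisy
  reason <- ifelse(low, "low_control_abundance",
                   ifelse(undef, "cv_undefined", "cv_exceeds_max"))
  excluded <- rbind(
    effects$excluded,
    data.frame(barcode = rownames(t_mat)[drop], reason = reason[drop],
               stringsAsFactors = FALSE)
  )
  structure(list(t = t_mat[!drop, , drop = FALSE],
                 a_ctrl_mean = effects$a_ctrl_mean[!drop],
                 cv_ctrl = effects$cv_ctrl[!drop],
                 excluded = excluded),
            class = "temperature_effect")
}

#' Gate genes for testing
#'
#' A gene is eligible when both alleles have at least `min_genotypes`
#' retained genotypes and the CV of each allele's pooled t values (all
#' replicates x all genotypes) is at most `cv_t_max`.
#'
#' @param effects A filtered `temperature_effect`.
#' @param catalog An `insertion_catalog` (or records data.frame) mapping
#'   barcodes to `gene_id` / `allele_species`.
#' @param min_genotypes,cv_t_max See [rh_params()].
#' @return List: `eligible` (character vector of gene ids) and
#'   `excluded_genes` (data.frame `gene_id`, `reason`).
#' @export
gene_gate <- function(effects, catalog, min_genotypes = 3, cv_t_max = 10) {
  records <- if (inherits(catalog, "insertion_catalog")) catalog$records else catalog
  genic <- records[!(records$gene_id %in% c("intergenic", "plasmid")), , drop = FALSE]
  genic <- genic[genic$barcode %in% rownames(effects$t), , drop = FALSE]

  eligible <- character(0)
  exc <- list()
  for (g in unique(genic$gene_id)) {
    sub <- genic[genic$gene_id == g, , drop = FALSE]
    n_cer <- sum(sub$allele_species == "cer")
    n_par <- sum(sub$allele_species == "par")
    if (n_cer < min_genotypes || n_par < min_genotypes) {
      exc[[g]] <- "too_few_genotypes"
      next
    }
    t_cer <- as.vector(effects$t[sub$barcode[sub$allele_species == "cer"], , drop = FALSE])
    t_par <- as.vector(effects$t[sub$barcode[sub$allele_species == "par"], , drop = FALSE])
    cvs <- c(cv(t_cer), cv(t_par))
    if (any(is.na(cvs)) || any(cvs > cv_t_max)) {
      exc[[g]] <- "pooled_t_cv_exceeds_max"
      next
    }
    eligible <- c(eligible, g)
  }
  list(
    eligible = eligible,
    excluded_genes = data.frame(gene_id = names(exc),
                                reason = unlist(exc, use.names = FALSE),
                                stringsAsFactors = FALSE)
  )
}

#' Mann-Whitney comparison of the two allelic t vectors
#'
#' Two-sided Mann-Whitney U with midranks for ties; the exact null
#' distribution is used when both vectors have at most 8 values and no
#' ties are present, and the normal approximation with tie correction
#' (and continuity correction) otherwise.
#'
#' @param t_cer,t_par Pooled t values (all replicates x all genotypes)
#'   for insertions in the cer and par allele respectively.
#' @return List with `U` (statistic for the cer sample) and `p_raw`.
#' @export
test_gene <- function(t_cer, t_par) {
  if (!length(t_cer) || !length(t_par)) stop("both t vectors must be non-empty")
  ties <- anyDuplicated(c(t_cer, t_par)) > 0L
  exact <- !ties && length(t_cer) <= 8L && length(t_par) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(t_cer, t_par, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p_raw = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment across all tested genes (applied once
#' per screen); monotone and clipped at 1.
#'
#' @param p_raw Numeric vector of raw P-values (optionally named).
#' @return Adjusted P-values, same order and names.
#' @export
adjust_bh <- function(p_raw) {
  stats::p.adjust(p_raw, method = "BH")
}

#' Allelic effect sizes and hit calls
#'
#' Per genotype, t is averaged over experimental replicates; the gene's
#' effect size is the mean over cer-insertion genotypes minus the mean
#' over par-insertion genotypes (genotypes equally weighted). A gene is a
#' hit when `p_adj < p_max` and `effect_size < effect_max` (negative
#' effects mean the cer allele carries the advantage at the experimental
#' temperature).
#'
#' @param effects A filtered `temperature_effect`.
#' @param catalog Catalog mapping barcodes to gene/allele.
#' @param genes Character vector of tested genes.
#' @param p_adj Named (by gene) adjusted P-values.
#' @param p_max,effect_max Hit thresholds.
#' @return data.frame: `gene_id`, `n_genotypes_cer`, `n_genotypes_par`,
#'   `effect_size`, `p_adj`, `is_hit`.
#' @export
effect_and_call <- function(effects, catalog, genes, p_adj,
                            p_max = 0.05, effect_max = -0.5) {
  records <- if (inherits(catalog, "insertion_catalog")) catalog$records else catalog
  geno_mean <- rowMeans(effects$t)
  out <- lapply(genes, function(g) {
    sub <- records[records$gene_id == g & records$barcode %in% names(geno_mean), , drop = FALSE]
    m_cer <- geno_mean[sub$barcode[sub$allele_species == "cer"]]
    m_par <- geno_mean[sub$barcode[sub$allele_species == "par"]]
    data.frame(gene_id = g,
               n_genotypes_cer = length(m_cer), n_genotypes_par = length(m_par),
               effect_size = mean(m_cer) - mean(m_par),
               p_adj = unname(p_adj[g]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$is_hit <- res$p_adj < p_max & res$effect_size < effect_max
  res
}

#' Run the full reciprocal hemizygosity test
#'
#' Drops intergenic and plasmid insertions, normalizes counts, computes
#' temperature effects, applies the genotype and gene gates, tests each
#' eligible gene with the Mann-Whitney test, adjusts P across genes with
#' Benjamini-Hochberg, and calls hits.
#'
#' @param counts Barcode x sample count matrix (catalog-restricted).
#' @param catalog An `insertion_catalog` or records data.frame.
#' @param sample_sheet data.frame: `sample_id`, `temperature`, `replicate`.
#' @param params An [rh_params()] list.
#' @return List of class `rh_result`: `genes` (data.frame `gene_id`,
#'   `n_genotypes_cer`, `n_genotypes_par`, `U`, `p_raw`, `p_adj`,
#'   `effect_size`, `is_hit`), `genotypes` (per-genotype t table),
#'   `qc` (exclusion tallies at every stage).
#' @export
rh_test <- function(counts, catalog, sample_sheet, params = rh_params()) {
  records <- if (inherits(catalog, "insertion_catalog")) catalog$records else catalog
  genic <- records[!(records$gene_id %in% c("intergenic", "plasmid")), , drop = FALSE]
  n_nongenic <- nrow(records) - nrow(genic)
  counts <- counts[intersect(rownames(counts), genic$barcode), , drop = FALSE]

  norm <- normalize_counts(counts)
  eff <- temperature_effect(norm, sample_sheet, zero_pseudo = params$zero_pseudo)
  eff <- filter_genotypes(eff, cv_max = params$cv_max,
                          min_norm_reads = params$min_norm_reads,
                          cv_on = params$cv_on)
  gate <- gene_gate(eff, genic, min_genotypes = params$min_genotypes,
                    cv_t_max = params$cv_t_max)

  genes <- gate$eligible
  if (!length(genes)) {
    res <- data.frame(gene_id = character(0), n_genotypes_cer = integer(0),
                      n_genotypes_par = integer(0), U = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      effect_size = numeric(0), is_hit = logical(0))
  } else {
    tests <- lapply(genes, function(g) {
      sub <- genic[genic$gene_id == g & genic$barcode %in% rownames(eff$t), , drop = FALSE]
      t_cer <- as.vector(eff$t[sub$barcode[sub$allele_species == "cer"], , drop = FALSE])
      t_par <- as.vector(eff$t[sub$barcode[sub$allele_species == "par"], , drop = FALSE])
      test_gene(t_cer, t_par)
    })
    p_raw <- vapply(tests, `[[`, numeric(1), "p_raw")
    p_adj <- stats::setNames(adjust_bh(p_raw), genes)
    res <- effect_and_call(eff, genic, genes, p_adj,
                           p_max = params$p_max, effect_max = params$effect_max)
    res$U <- vapply(tests, `[[`, numeric(1), "U")
    res$p_raw <- p_raw
    res <- res[, c("gene_id", "n_genotypes_cer", "n_genotypes_par", "U",
                   "p_raw", "p_adj", "effect_size", "is_hit")]
  }

  geno_tab <- data.frame(
    barcode = rownames(eff$t),
    gene_id = genic$gene_id[match(rownames(eff$t), genic$barcode)],
    allele_species = genic$allele_species[match(rownames(eff$t), genic$barcode)],
    a_ctrl_mean = unname(eff$a_ctrl_mean),
    t_mean = rowMeans(eff$t),
    stringsAsFactors = FALSE
  )

  qc <- list(
    nongenic_removed = n_nongenic,
    genotype_exclusions = as.list(table(eff$excluded$reason)),
    genotypes_retained = nrow(eff$t),
    gene_exclusions = as.list(table(gate$excluded_genes$reason)),
    genes_tested = length(genes),
    hits = sum(res$is_hit)
  )
  structure(list(genes = res, genotypes = geno_tab, qc = qc),
            class = "rh_result")
}
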