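# Reciprocal hemizygosity test: normalization, temperature effects,
# quality gates, Mann-Whitney/BH, effect sizes, and invariances.

toy_sheet <- function(n_exp, n_ctrl) {
  data.frame(sample_id = c(sprintf("exp_%02d", seq_len(n_exp)),
                           sprintf("ctrl_%02d", seq_len(n_ctrl))),
             temperature = rep(c("experimental", "control"), c(n_exp, n_ctrl)),
             replicate = c(seq_len(n_exp), seq_len(n_ctrl)),
             stringsAsFactors = FALSE)
}

test_that("normalization equalizes column totals at the median raw total", {
  m <- matrix(c(10, 990, 40, 1960), nrow = 2,
              dimnames = list(c("b1", "b2"), c("s1", "s2")))
  nm <- normalize_counts(m)  # totals 1000, 2000; median 1500
  expect_equal(unname(colSums(nm)), c(1500, 1500))
  expect_equal(nm["b1", "s1"], 15)
  expect_equal(nm["b1", "s2"], 30)

  same <- matrix(c(5, 5, 6, 4), nrow = 2,
                 dimnames = list(c("b1", "b2"), c("s1", "s2")))
  expect_equal(normalize_counts(same), same)

  zero <- matrix(c(1, 1, 0, 0), nrow = 2,
                 dimnames = list(c("b1", "b2"), c("s1", "bad")))
  expect_error(normalize_counts(zero), "bad")

  set.seed(1)
  r <- matrix(rpois(60, 40), nrow = 6,
              dimnames = list(paste0("b", 1:6), paste0("s", 1:10)))
  expect_true(all(abs(colSums(normalize_counts(r)) - median(colSums(r))) < 1e-9))
})

test_that("temperature effects implement t_i = log2(a_exp_i / a_ctrl_mean)", {
  sheet <- toy_sheet(2, 2)
  m <- matrix(c(8, 2,    4, 2,   # exp_01, exp_02
                2, 2,    2, 2),  # ctrl_01, ctrl_02
              nrow = 2, byrow = FALSE,
              dimnames = list(c("b1", "b2"),
                              c("exp_01", "exp_02", "ctrl_01", "ctrl_02")))
  eff <- temperature_effect(m, sheet)   # taken as already-normalized abundances
  expect_equal(eff$t["b1", "exp_01"], 2)        # log2(8/2)
  expect_equal(eff$t["b1", "exp_02"], 1)        # log2(4/2)
  expect_equal(eff$t["b2", "exp_01"], 0)        # a_exp = a_ctrl_mean

  # genotype absent from all controls is excluded
  m2 <- rbind(m, b3 = c(5, 5, 0, 0))
  eff2 <- temperature_effect(m2, sheet)
  expect_false("b3" %in% rownames(eff2$t))
  expect_equal(eff2$excluded$reason, "zero_control_mean")

  # zero experimental abundance takes the half-pseudoread value
  m3 <- rbind(m, b4 = c(0, 4, 4, 4))
  eff3 <- temperature_effect(m3, sheet, zero_pseudo = 0.5)
  expect_equal(eff3$t["b4", "exp_01"], log2(0.5 / 4))
})

test_that("genotype filters drop on CV and on the 1.1-read floor", {
  sheet <- toy_sheet(3, 3)
  # stable genotype, noisy genotype, low-abundance genotype
  m <- matrix(c(40, 41, 39,  40, 40, 40,
                90,  2, 30,  40, 40, 40,
                 1,  1,  1,   1,  1,  1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("ok", "noisy_t", "low"),
                              c("exp_01", "exp_02", "exp_03",
                                "ctrl_01", "ctrl_02", "ctrl_03")))
  eff <- temperature_effect(m, sheet)

  f_ab <- filter_genotypes(eff, cv_max = 2, min_norm_reads = 1.1, cv_on = "abundance")
  expect_true("ok" %in% rownames(f_ab$t))
  expect_true("noisy_t" %in% rownames(f_ab$t))  # control side is clean
  expect_false("low" %in% rownames(f_ab$t))     # mean control abundance 1 < 1.1
  expect_true("low_control_abundance" %in% f_ab$excluded$reason)

  # on the t basis, a near-zero-mean wild t vector is dropped:
  # t = [2, -2, 0.1] has CV >> 2
  a_ctrl <- 4
  m2 <- matrix(c(a_ctrl * 2^2, a_ctrl * 2^-2, a_ctrl * 2^0.1,
                 a_ctrl, a_ctrl, a_ctrl),
               nrow = 1, byrow = TRUE,
               dimnames = list("wild", colnames(m)))
  f_t <- filter_genotypes(temperature_effect(m2, sheet), cv_on = "t")
  expect_false("wild" %in% rownames(f_t$t))
  # while t = [1, 1, 1] has CV 0 and is retained
  m3 <- matrix(c(rep(a_ctrl * 2, 3), rep(a_ctrl, 3)), nrow = 1, byrow = TRUE,
               dimnames = list("flat", colnames(m)))
  expect_true("flat" %in% rownames(filter_genotypes(temperature_effect(m3, sheet),
                                                    cv_on = "t")$t))
})

test_that("gene gate enforces three genotypes per allele and the pooled-t CV cap", {
  sheet <- toy_sheet(2, 2)
  mk_eff <- function(barcodes, t1, t2) {
    m <- cbind(matrix(rep(4 * 2^cbind(t1, t2), 1), ncol = 2,
                      dimnames = list(barcodes, c("exp_01", "exp_02"))),
               matrix(4, length(barcodes), 2,
                      dimnames = list(barcodes, c("ctrl_01", "ctrl_02"))))
    temperature_effect(m, sheet)
  }
  cat_df <- data.frame(
    barcode = c(paste0("c", 1:3), paste0("p", 1:3), paste0("x", 1:2), paste0("y", 1:3)),
    gene_id = c(rep("gA", 6), rep("gB", 5)),
    allele_species = c(rep("cer", 3), rep("par", 3), rep("cer", 2), rep("par", 3)),
    stringsAsFactors = FALSE
  )
  eff <- mk_eff(cat_df$barcode, t1 = seq(0.5, 1.5, length.out = 11),
                t2 = seq(0.6, 1.6, length.out = 11))
  gate <- gene_gate(eff, cat_df, min_genotypes = 3, cv_t_max = 10)
  expect_equal(gate$eligible, "gA")
  expect_equal(gate$excluded_genes$reason[gate$excluded_genes$gene_id == "gB"],
               "too_few_genotypes")  # 2 cer-insert genotypes only

  # pooled-t CV above 10 excludes the gene
  eff2 <- mk_eff(cat_df$barcode,
                 t1 = c(2, -2, 0.1, 0.5, 0.6, 0.7, rep(0.5, 5)),
                 t2 = c(-1.9, 2.1, 0.2, 0.5, 0.6, 0.7, rep(0.5, 5)))
  gate2 <- gene_gate(eff2, cat_df, min_genotypes = 3, cv_t_max = 10)
  expect_false("gA" %in% gate2$eligible)
})

test_that("Mann-Whitney matches the textbook example and the enumeration oracle", {
  r <- test_gene(c(-3, -2.5, -2), c(0, 0.5, 1))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_raw, 0.1)  # exact two-sided, complete separation at n=3+3

  same <- test_gene(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_raw, 0.6)  # no separation

  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, sample(c(0, 1), 1)), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(test_gene(x, y)$p_raw, oracle_mw_p(x, y),
                 tolerance = 1e-12, info = sprintf("case %d", i))
  }
})

test_that("BH adjustment matches the hand formula", {
  expect_equal(adjust_bh(c(0.001, 0.02, 0.03, 0.5)), c(0.004, 0.04, 0.04, 0.5))
  expect_equal(adjust_bh(0.123), 0.123)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("effect sizes average genotypes equally and hits are one-directional", {
  sheet <- toy_sheet(3, 3)
  bcs <- c("c1", "c2", "c3", "p1", "p2", "p3")
  t_means <- c(-1.0, -1.2, -0.8, 0.1, -0.1, 0.0)
  m <- cbind(matrix(4 * 2^rep(t_means, 3), ncol = 3,
                    dimnames = list(bcs, sprintf("exp_%02d", 1:3))),
             matrix(4, 6, 3, dimnames = list(bcs, sprintf("ctrl_%02d", 1:3))))
  eff <- temperature_effect(m, sheet)
  cat_df <- data.frame(barcode = bcs, gene_id = "gA",
                       allele_species = rep(c("cer", "par"), each = 3),
                       stringsAsFactors = FALSE)
  res <- effect_and_call(eff, cat_df, "gA", c(gA = 0.01))
  expect_equal(res$effect_size, -1.0)
  expect_true(res$is_hit)

  # significant but positive effect is not a hit
  cat_flip <- cat_df
  cat_flip$allele_species <- rev(cat_flip$allele_species)
  res3 <- effect_and_call(eff, cat_flip, "gA", c(gA = 0.01))
  expect_equal(res3$effect_size, 1.0)
  expect_false(res3$is_hit)
})

test_that("species-label swap negates effects and preserves p; rescaling a sample is absorbed", {
  cfg <- sim_config(n_genes = 30, inserts_per_allele_mean = 6, frac_multilocus = 0,
                    barseq_depth_mean = 60, seed = 41,
                    effect_table = data.frame(gene_id = c("g0001", "g0002"),
                                              w_cer_uncovered = c(1, 0.95),
                                              w_par_uncovered = c(0.93, 1)))
  ga <- generate_hybrid_genome(cfg)
  truth <- generate_pool(ga$genome, ga$annotation, cfg)
  comp <- simulate_competition(truth, cfg)
  cat_df <- catalog_from_truth(truth)

  res <- rh_test(comp$counts, cat_df, comp$samples)

  cat_sw <- cat_df
  cat_sw$allele_species <- c(cer = "par", par = "cer", na = "na")[cat_df$allele_species]
  res_sw <- rh_test(comp$counts, cat_sw, comp$samples)
  o1 <- res$genes[order(res$genes$gene_id), ]
  o2 <- res_sw$genes[order(res_sw$genes$gene_id), ]
  expect_equal(o1$gene_id, o2$gene_id)
  expect_equal(o2$effect_size, -o1$effect_size)
  expect_equal(o2$p_raw, o1$p_raw)

  # multiplying one sample's raw counts by a constant changes no t value
  counts2 <- comp$counts
  counts2[, "exp_03"] <- counts2[, "exp_03"] * 7L
  norm1 <- normalize_counts(comp$counts)
  norm2 <- normalize_counts(counts2)
  e1 <- temperature_effect(norm1, comp$samples)
  e2 <- temperature_effect(norm2, comp$samples)
  expect_equal(e2$t, e1$t, tolerance = 1e-12)
})

test_that("rh_test excludes intergenic and plasmid insertions and reconciles QC", {
  cfg <- sim_config(n_genes = 15, inserts_per_allele_mean = 6, frac_multilocus = 0,
                    barseq_depth_mean = 60, seed = 43)
  ga <- generate_hybrid_genome(cfg)
  truth <- generate_pool(ga$genome, ga$annotation, cfg)
  comp <- simulate_competition(truth, cfg)
  cat_df <- catalog_from_truth(truth)
  res <- rh_test(comp$counts, cat_df, comp$samples)
  expect_equal(res$qc$nongenic_removed,
               sum(cat_df$gene_id %in% c("intergenic", "plasmid")))
  expect_false(any(res$genotypes$gene_id %in% c("intergenic", "plasmid")))
  n_genic <- sum(!(cat_df$gene_id %in% c("intergenic", "plasmid")))
  expect_equal(res$qc$genotypes_retained +
                 sum(unlist(res$qc$genotype_exclusions)), n_genic)
  expect_true(all(res$genes$p_adj >= res$genes$p_raw))
})
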