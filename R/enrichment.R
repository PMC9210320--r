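# Downstream resampling analyses on the hit list: gene-set
# overrepresentation and effect-size enrichment with essentiality-matched
# null sets, protein interaction enrichment, and McDonald-Kreitman tests.

#' Filter a gene-set annotation
#'
#' Removes terms with fewer than `min_size` or more than `max_size`
#' members (membership counted among `genome_genes`); among groups of
#' terms with identical membership, the lexicographically smallest
#' term_id is retained and the others recorded as aliases.
#'
#' @param annotation data.frame with columns `term_id`, `gene_id` and
#'   optionally `term_name`, or a named list term_id -> gene vector.
#' @param genome_genes Character vector of genes defining the universe.
#' @param min_size,max_size Size bounds (inclusive).
#' @return List of class `gene_sets`: `terms` (named list term_id ->
#'   member genes), `term_name` (named character), `aliases` (data.frame
#'   `alias`, `retained`).
#' @export
filter_terms <- function(annotation, genome_genes, min_size = 5, max_size = 200) {
  if (is.data.frame(annotation)) {
    terms <- split(annotation$gene_id, annotation$term_id)
    term_name <- if ("term_name" %in% names(annotation)) {
      nm <- annotation$term_name[!duplicated(annotation$term_id)]
      stats::setNames(nm, annotation$term_id[!duplicated(annotation$term_id)])
    } else {
      stats::setNames(names(terms), names(terms))
    }
  } else {
    terms <- annotation
    term_name <- stats::setNames(names(terms), names(terms))
  }
  terms <- lapply(terms, function(g) sort(unique(intersect(g, genome_genes))))
  sizes <- lengths(terms)
  terms <- terms[sizes >= min_size & sizes <= max_size]

  # deduplicate identical memberships, keeping the smallest term_id
  keys <- vapply(terms, paste, character(1), collapse = "\r")
  ord <- order(names(terms))
  terms <- terms[ord]; keys <- keys[ord]
  dup <- duplicated(keys)
  aliases <- data.frame(
    alias = names(terms)[dup],
    retained = names(terms)[match(keys[dup], keys)],
    stringsAsFactors = FALSE
  )
  terms <- terms[!dup]
  structure(list(terms = terms, term_name = term_name[names(terms)],
                 aliases = aliases),
            class = "gene_sets")
}

#' Essentiality-matched random gene set
#'
#' Draws `round(k * p_ess)` genes without replacement from the essential
#' stratum of the genome and the remainder from the non-essential
#' stratum, so null sets preserve the focal set's essential fraction.
#'
#' @param k Set size.
#' @param genome_genes Character vector of genes to draw from.
#' @param essential Character vector of essential genes (or named logical
#'   over genes).
#' @param p_ess Essential fraction of the focal set.
#' @return Character vector of `k` distinct genes.
#' @export
matched_resample <- function(k, genome_genes, essential, p_ess) {
  if (is.logical(essential)) essential <- names(essential)[essential]
  ess <- intersect(genome_genes, essential)
  non <- setdiff(genome_genes, essential)
  n_ess <- round(k * p_ess)
  n_non <- k - n_ess
  if (n_ess > length(ess) || n_non > length(non)) {
    stop("essentiality stratum smaller than requested draw")
  }
  c(if (n_ess > 0) sample(ess, n_ess) else character(0),
    if (n_non > 0) sample(non, n_non) else character(0))
}

#' Gene-set overrepresentation by essentiality-matched resampling
#'
#' For each term with at least one hit member, draws `n_resamples`
#' essentiality-matched gene sets of the hit-list size and counts how
#' many carry *more* members of the term than the hit list does
#' (strictly more by default; set `strict = FALSE` for a >= convention).
#' The proportion is the term's P-value; BH correction is applied across
#' terms.
#'
#' @param hits Character vector of hit genes.
#' @param gene_sets A `gene_sets` object from [filter_terms()].
#' @param genome_genes Gene universe to resample from.
#' @param essential Essential genes (character vector or named logical).
#' @param n_resamples Number of resamples.
#' @param seed Integer seed.
#' @param strict Use strictly-greater exceedance (default) or >=.
#' @return data.frame per term: `term_id`, `term_name`, `n_members`,
#'   `n_in_hits`, `k` (null exceedances), `n_resamples`, `p`, `p_adj`.
#' @export
go_overrep <- function(hits, gene_sets, genome_genes, essential,
                       n_resamples = 10000, seed = 1, strict = TRUE) {
  if (!length(hits)) stop("hit set is empty")
  if (is.logical(essential)) essential <- names(essential)[essential]
  set.seed(stage_seed(seed, 10L))
  terms <- gene_sets$terms
  obs <- vapply(terms, function(g) length(intersect(g, hits)), integer(1))
  terms <- terms[obs >= 1L]
  obs <- obs[obs >= 1L]
  if (!length(terms)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      n_members = integer(0), n_in_hits = integer(0),
                      k = integer(0), n_resamples = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  p_ess <- length(intersect(hits, essential)) / length(hits)
  k_size <- length(hits)

  exceed <- stats::setNames(integer(length(terms)), names(terms))
  for (r in seq_len(n_resamples)) {
    rs <- matched_resample(k_size, genome_genes, essential, p_ess)
    cnt <- vapply(terms, function(g) length(intersect(g, rs)), integer(1))
    exceed <- exceed + if (strict) as.integer(cnt > obs) else as.integer(cnt >= obs)
  }
  p <- exceed / n_resamples
  data.frame(
    term_id = names(terms),
    term_name = unname(gene_sets$term_name[names(terms)]),
    n_members = lengths(terms),
    n_in_hits = unname(obs),
    k = unname(exceed), n_resamples = n_resamples,
    p = unname(p), p_adj = unname(adjust_bh(p)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Effect-size gene-set enrichment with two-stage resampling
#'
#' Restricted to genes with effect-size data: for each term, the observed
#' statistic `e_true` is the median absolute effect size of its members
#' with data; `n1` essentiality-matched resamples of the same size give
#' an initial P (proportion with `e_resample >= e_true`); terms with
#' initial P below `promote_below` are rerun at `n2` resamples. BH is
#' applied to the final P-values.
#'
#' @param effects Named numeric vector: gene -> effect size (the gene
#'   universe is `names(effects)`).
#' @param gene_sets A `gene_sets` object.
#' @param essential Essential genes.
#' @param n1,n2 First- and second-stage resample counts.
#' @param promote_below Promotion threshold on the initial P.
#' @param seed Integer seed.
#' @return data.frame per term: `term_id`, `n_members_with_data`,
#'   `e_true`, `k`, `n_resamples`, `p`, `p_adj`, `promoted`.
#' @export
go_effectsize <- function(effects, gene_sets, essential,
                          n1 = 100, n2 = 10000, promote_below = 0.1, seed = 1) {
  if (is.logical(essential)) essential <- names(essential)[essential]
  set.seed(stage_seed(seed, 11L))
  genome <- names(effects)
  members <- lapply(gene_sets$terms, intersect, y = genome)
  keep <- lengths(members) >= 1L
  members <- members[keep]
  if (!length(members)) {
    return(data.frame(term_id = character(0), n_members_with_data = integer(0),
                      e_true = numeric(0), k = integer(0),
                      n_resamples = integer(0), p = numeric(0),
                      p_adj = numeric(0), promoted = logical(0)))
  }
  abs_eff <- abs(effects)

  run_stage <- function(m, e_true, n) {
    p_ess <- length(intersect(m, essential)) / length(m)
    k <- 0L
    for (r in seq_len(n)) {
      rs <- matched_resample(length(m), genome, essential, p_ess)
      if (stats::median(abs_eff[rs]) >= e_true) k <- k + 1L
    }
    k
  }

  e_true <- vapply(members, function(m) stats::median(abs_eff[m]), numeric(1))
  k1 <- mapply(run_stage, members, e_true, MoreArgs = list(n = n1))
  p1 <- k1 / n1
  promoted <- p1 < promote_below
  k_final <- k1; n_final <- rep(n1, length(members))
  for (i in which(promoted)) {
    k_final[i] <- run_stage(members[[i]], e_true[i], n2)
    n_final[i] <- n2
  }
  p <- k_final / n_final
  data.frame(
    term_id = names(members),
    n_members_with_data = lengths(members),
    e_true = unname(e_true),
    k = unname(k_final), n_resamples = unname(n_final),
    p = unname(p), p_adj = unname(adjust_bh(p)),
    promoted = unname(promoted),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Undirected edge list: dedupe, drop self loops, restrict to the genome.
clean_edges <- function(edges, genome_genes) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b & a %in% genome_genes & b %in% genome_genes
  e <- unique(data.frame(gene_a = a[keep], gene_b = b[keep],
                         stringsAsFactors = FALSE))
  rownames(e) <- NULL
  e
}

# r statistic: internal edges / edges touching the set (0 if none touch
# and zero_as = 0; NA if zero_as = NA).
edge_ratio <- function(edges, genes, zero_as = 0) {
  in_a <- edges$gene_a %in% genes
  in_b <- edges$gene_b %in% genes
  touching <- sum(in_a | in_b)
  if (touching == 0L) return(zero_as)
  sum(in_a & in_b) / touching
}

#' Interaction enrichment among hit genes
#'
#' `r_true` is the number of interaction edges with both endpoints in the
#' hit list divided by the number of edges with at least one endpoint in
#' it. The same ratio is computed on `n_resamples` essentiality-matched
#' random sets of the hit-list size; the one-sided P is the proportion of
#' resamples with `r_resample >= r_true`. Edges are undirected,
#' deduplicated, self-loop-free; resamples touching no edge contribute
#' r = 0. If the hits touch no edge, `r_true` and `p` are NA.
#'
#' @param hits Character vector of hit genes.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param genome_genes Gene universe.
#' @param essential Essential genes.
#' @param n_resamples Number of resamples.
#' @param seed Integer seed.
#' @return One-row data.frame: `r_true`, `k`, `n_resamples`, `p`.
#' @export
interaction_enrich <- function(hits, edges, genome_genes, essential,
                               n_resamples = 10000, seed = 1) {
  if (is.logical(essential)) essential <- names(essential)[essential]
  set.seed(stage_seed(seed, 12L))
  e <- clean_edges(edges, genome_genes)
  r_true <- edge_ratio(e, hits, zero_as = NA_real_)
  if (is.na(r_true)) {
    return(data.frame(r_true = NA_real_, k = NA_integer_,
                      n_resamples = n_resamples, p = NA_real_))
  }
  p_ess <- length(intersect(hits, essential)) / length(hits)
  k <- 0L
  for (r in seq_len(n_resamples)) {
    rs <- matched_resample(length(hits), genome_genes, essential, p_ess)
    if (edge_ratio(e, rs, zero_as = 0) >= r_true) k <- k + 1L
  }
  data.frame(r_true = r_true, k = k, n_resamples = n_resamples,
             p = k / n_resamples)
}

#' McDonald-Kreitman tests per gene
#'
#' Two-sided Fisher's exact test on the 2x2 table of nonsynonymous and
#' synonymous divergences (Dn, Ds) versus polymorphisms (Pn, Ps), with
#' BH correction across genes. The neutrality index
#' `NI = (Pn/Ps) / (Dn/Ds)` is reported where defined (NA when any ratio
#' is undefined).
#'
#' @param mk_counts data.frame with columns `gene_id`, `dn`, `ds`, `pn`,
#'   `ps` (non-negative integer counts).
#' @return data.frame: `gene_id`, `dn`, `ds`, `pn`, `ps`, `ni`, `p_raw`,
#'   `p_adj`.
#' @export
mk_test <- function(mk_counts) {
  stopifnot(all(c("gene_id", "dn", "ds", "pn", "ps") %in% names(mk_counts)))
  cnt <- mk_counts[, c("dn", "ds", "pn", "ps")]
  if (any(cnt < 0)) stop("MK counts must be non-negative")
  p_raw <- vapply(seq_len(nrow(mk_counts)), function(i) {
    tab <- matrix(as.numeric(cnt[i, ]), nrow = 2L, byrow = TRUE)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  ni <- with(mk_counts, ifelse(ds > 0 & ps > 0 & dn > 0,
                               (pn / ps) / (dn / ds), NA_real_))
  data.frame(gene_id = mk_counts$gene_id,
             dn = mk_counts$dn, ds = mk_counts$ds,
             pn = mk_counts$pn, ps = mk_counts$ps,
             ni = ni, p_raw = p_raw, p_adj = adjust_bh(p_raw),
             stringsAsFactors = FALSE)
}
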