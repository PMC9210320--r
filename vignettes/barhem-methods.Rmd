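---
title: "Methods: barcoded reciprocal hemizygosity screening with barhem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded reciprocal hemizygosity screening with barhem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barhem)
```

## The screen

Reciprocal hemizygosity analysis maps the genetic basis of a trait
difference between two species onto individual genes. In an F1
interspecies hybrid (here, *S. cerevisiae* × *S. paradoxus*), a
transposon insertion in one species' allele of a gene leaves the other
species' allele as the only functional copy — a hemizygote. Comparing
the pooled fitness of clones disrupted in the *cerevisiae* allele of a
gene against clones disrupted in its *paradoxus* allele isolates the
contribution of allelic variation at that gene, on an otherwise
identical hybrid background. Random DNA barcodes cloned into the
transposon make the readout cheap: one sequencing pass across
transposon–genome junctions (Tn-seq) associates each barcode with its
insertion site once, after which clone abundances in any number of
competition samples are quantified by amplicon sequencing of the
barcode alone (Bar-seq).

`barhem` implements the full desk-side analysis: Tn-seq read processing
into a quality-controlled insertion catalog, catalog-restricted Bar-seq
counting, the reciprocal hemizygosity test proper, and downstream
resampling analyses of the hit list. A synthetic-data generator
emulates the wet experiment end to end with known ground truth, so
every stage is testable without any external data.

## Tn-seq read processing

A junction read carries, in order, a constant flank, the 20-bp clone
barcode, a constant spacer, the transposon right-arm terminus, and
genomic context. Detection searches each read for the final 22 bp of
the right arm, allowing two substitutions; the leftmost qualifying hit
is taken (a deterministic tie-break). The barcode is read at a fixed
offset upstream and the genomic fragment is everything downstream;
reads with no arm hit, or whose barcode or fragment would run off the
read, are rejected with reason codes. Every input read is accounted for
exactly once.

**Barcode error collapsing.** Sequencing errors create artifactual
"satellite" barcodes differing from an abundant true barcode at one or
two positions. A barcode is eliminated when another barcode within
Hamming distance 1 carries at least `dominance_ratio` (default 10)
times its reads; the same rule is then applied at distance 2 to the
survivors. Elimination is removal, not merging. The default ratio is a
package choice: at a ~1.4% per-base error rate, satellites are ≳50-fold
rarer than their parents, so a factor of 10 separates satellites from
genuinely distinct co-abundant clones. Errors at three or more barcode
positions fall outside any distance-2 neighbourhood; such residuals are
rare (binomial tail at 1.38% over 20 bp), carry 1–3 reads, and are
removed downstream by the abundance floor because they draw no Bar-seq
counts.

**Fragment mapping.** Desk-scale genomes allow a transparent,
deterministic mapper in place of a production aligner: an exact k-mer
index (default k = 15) proposes candidate placements from every k-mer
of the fragment and of its reverse complement, and each candidate is
verified by full-length Hamming comparison with at most 2
substitutions. A placement is reported as the first genomic base 3′ of
the transposon arm on the reference strand. As with any seed-and-verify
mapper, a true placement whose mismatches disrupt every seed k-mer can
be missed; with ≥40-bp fragments and ≤2 substitutions this requires the
two errors to straddle every window and is negligible at the simulated
error rate (and absent for exact matches, where the mapper is
provably complete).

**Mapping classes.** A location is *strong* when its best placement is
within one substitution of perfect. Barcodes with two or more strong
locations are `multilocus` (the transposon inserted at several sites in
one or many clones); barcodes with one strong location whose reads are
outnumbered by reads at weaker locations are `ambiguous`; barcodes with
no strong location are `unmapped`. Only `unique` barcodes enter the
catalog. Positions are then annotated against the GFF3 gene features
(`gene_id`, `allele_species`), with non-genic positions labeled
`intergenic` and anything on the plasmid contig labeled `plasmid`.

## Bar-seq counting

Amplicon reads are `[priming flank][barcode][priming flank]`. The
upstream flank is located with at most two mismatches, the next 20
bases are the barcode, and the downstream flank is verified at the same
allowance. Extracted barcodes are tallied only when they match the
Tn-seq-validated catalog **exactly**; everything else is an orphan,
counted and discarded. There is deliberately no error-tolerant rescue
at this stage: a barcode seen only in Bar-seq is never trusted, so
Bar-seq sequencing errors cost a small, quantified fraction of reads
rather than risking misassignment.

## The reciprocal hemizygosity test

Counts are normalized per sample to a common total — the median raw
column total, a package choice that keeps normalized abundances on a
raw-read scale so the abundance floor below retains its meaning.
Intergenic and plasmid insertions are removed. For each genotype
(barcode), with `a` the normalized abundance,

> t_i = log2(a_experimental,i / a_control,mean),   i = 1…12,

where `a_control,mean` averages the genotype over all control-
temperature replicates. A genotype absent from every control replicate
is excluded. A zero experimental abundance would give t = −∞; it is
replaced by `log2(0.5 / a_control,mean)` (half a pseudoread,
configurable), keeping complete dropouts — the strongest phenotypes —
in the test instead of discarding them.

**Genotype filters.** A genotype is dropped when its mean control
abundance is below 1.1 normalized reads, or when its
replicate-to-replicate coefficient of variation exceeds 2.0. The CV is
computed on the control-replicate abundances by default. The
alternative basis — CV of the t vector itself, `sd(t)/|mean(t)|` — is
available (`cv_on = "t"`) but is not the default for a structural
reason: when a genotype's true temperature effect is zero, `mean(t)`
approaches 0 and the ratio diverges, so the filter would discard
roughly nine in ten perfectly well-measured null genotypes (the
rejection probability under a pure null is P(|Z| < √12/2) ≈ 0.92,
independent of depth). The control-abundance basis guards exactly the
quantity whose noise propagates into every t_i — the denominator — in
the same spirit as the 1.1-read floor.

**Gene gates.** A gene is tested only when each allele retains at least
three genotypes, and the pooled per-allele t values (all replicates ×
all genotypes) have CV at most 10 for both alleles.

**Test, correction, and calls.** The two pooled per-allele t vectors
are compared with a two-sided Mann–Whitney test (exact null when both
sizes are ≤8 with no ties; normal approximation with tie and continuity
correction otherwise), and Benjamini–Hochberg correction is applied
once across all tested genes. The effect size is the mean over
cer-insertion genotypes of the genotype-average t, minus the same mean
over par-insertion genotypes (genotypes weighted equally). A gene is a
hit when adjusted P < 0.05 **and** effect size < −0.5 — one-directional
by design: negative effects mean disrupting the *cerevisiae* allele
hurts growth at the experimental temperature, i.e. the *cerevisiae*
allele carries the advantage.

### Calibration of the pooled test: a known limitation

The pooled vectors treat the 12 replicate t values of each genotype as
independent observations, but they share one realization of
`a_control,mean` in their denominator. This induces an intraclass
correlation of about 1/13 at cluster size 12 — a design effect near
1.85 — so the Mann–Whitney null is anti-conservative: on simulated
all-fitness-equal pools the fraction of tested genes with raw P < 0.05
is about 0.25 rather than 0.05 (the gene gate's pooled-CV cap, which
preferentially excludes genes whose allele means sit near zero,
contributes part of this; the clustering alone gives ≈0.15). A variant
test on genotype-mean t values is calibrated (≈0.05) in the same
simulations. The package implements the pooled form because it is the
screen's published procedure; the raw P-values should be read as a
ranking rather than as calibrated tail probabilities. The hit rule is
nonetheless robust under the null: the effect-size threshold of −0.5 is
many standard errors away from null effect sizes at realistic depths,
and across ten simulated null screens no gene is ever called a hit.

## Downstream resampling analyses

All null sets are *essentiality-matched*: a random gene set of size k
preserves the focal set's fraction of essential genes by stratified
sampling without replacement, since essentiality is a strong confounder
of both interaction density and annotation membership.

- **Gene-set overrepresentation.** Terms are filtered to 5–200 members
  with identical-membership duplicates collapsed (smallest term id
  kept, aliases recorded); terms with no hit member are not tested.
  For each term, 10,000 matched resamples of the hit-list size are
  drawn and the P-value is the proportion carrying strictly more term
  members than the hit list (a ≥ convention is available as a flag;
  the strict form is the default and the two differ only through
  discrete ties). BH correction is applied across terms. A reported
  p of 0 should be read as "< 1/N"; no pseudocount is added.
- **Effect-size enrichment.** Restricted to genes with effect-size
  data, a term's statistic is the median |effect| of its members;
  100 matched resamples give an initial P (proportion with resampled
  median ≥ observed), terms below 0.1 are re-run at 10,000 resamples,
  and BH is applied to the final values.
- **Interaction enrichment.** With an undirected, deduplicated,
  self-loop-free edge list, r = (edges internal to the set)/(edges
  touching the set); the one-sided P is the proportion of 10,000
  matched resamples with r at least the observed value. Resamples
  touching no edge contribute r = 0; a hit set touching no edge yields
  NA.
- **McDonald–Kreitman.** Per gene, a two-sided Fisher exact test on
  [[Dn, Ds], [Pn, Ps]] with BH across genes, plus the neutrality index
  NI = (Pn/Ps)/(Dn/Ds) where defined.

## The synthetic experiment

The generator emulates the experiment's design parameters: random
20-bp barcodes flanked by constant priming regions; per-base
substitution errors at 1.38% (the empirically estimated rate), which
produces off-by-one satellites naturally; Tn-seq depth Poisson with
mean 47 reads per insertion (the observed median); 12 experimental and
12 control replicate cultures; and 12 population doublings (the
competitions ran 10–15 generations). Two independent random chromosome
sequences stand in for the two parental genomes — divergence is carried
by chromosome identity, not simulated SNPs — plus a geneless plasmid
contig. Insertions land uniformly within genes (Poisson mean 5 per gene
per allele by default) and at matched per-bp density in intergenic and
plasmid sequence; a configurable fraction of barcodes (default 5%)
receives a second location to exercise the multilocus filter; true
barcodes are kept at pairwise Hamming distance ≥3 so injected errors are
unambiguous satellites. Clone starting frequencies are lognormal
(sdlog 0.5).

Growth is deterministic exponential: a clone whose intact allele of
gene g is species s multiplies its frequency by `w_s_uncovered(g)` per
doubling at the experimental temperature and by 1 at the control
temperature, so the true allelic effect on t is
`doublings × log2(w_par_uncovered / w_cer_uncovered)`. Sequencing is
the only noise: each sample draws a multinomial library of
`barseq_depth_mean × n_clones` reads (default mean depth 50 per clone,
between the real screen's median and mean Bar-seq depths). Drift
between back-dilutions is deliberately omitted — the emulated
experiment kept bottlenecking modest — so passing recovery tests
demonstrate correctness of the inference chain, not robustness to
demographic noise, batch effects, PCR jackpotting, or quality-score
pathologies, none of which are modeled.

## Numerical and design choices

- Detection ties (two equal arm hits) resolve to the leftmost hit;
  "strong" mapping means within one substitution of perfect
  (strong_margin 2 on the score deficit); both are deterministic.
- The off-by-two barcode filter uses the same dominance criterion as
  the off-by-one filter (configurable), rather than removing all
  distance-2 neighbours unconditionally.
- BH is applied once per screen across all tested genes, not per
  allele; effect sizes weight genotypes equally rather than by reads.
- The run-level seed is fanned out to per-stage child seeds by a
  counter scheme, so stages rerun standalone reproduce their in-
  pipeline output exactly; all outputs are byte-identical for a fixed
  (config, seed).
- Degenerate inputs fail loudly with the offending field or sample
  named: zero-total samples, positions outside contig bounds, fitness
  below zero, pool sizes exceeding barcode capacity.

## Problem sizes used in the checks

The automated checks run the read-level pipeline at ~10,000 junction
reads over 25-gene genomes, statistical calibration and recovery at 200
genes × 24 samples (ten independent null screens; one screen with 20
genes planted at a true allelic effect of −1.5), and resampling tests
at 10,000 iterations on toy genomes small enough for exhaustive
enumeration. These sizes give the oracle comparisons and binomial
tolerance bands quoted in the tests while keeping a full run in the
low minutes on one core.
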