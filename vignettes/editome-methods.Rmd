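---
title: "Methods: A-to-I editome discovery, quantification and differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-to-I editome discovery, quantification and differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the detection model
and its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical and design choices made
where the design was genuinely open, and the package's limitations.

## The detection problem

An A-to-I editing event appears in RNA-seq as an A>G mismatch on the
transcribed strand. The same signal is produced by germline variation,
sequencing error, and several classes of alignment artifact, so detection
is a filtering problem: call every plausible single-nucleotide variant,
then remove everything whose evidence pattern is better explained by a
non-editing mechanism.

### Candidate calling

From per-sample pileups (only bases with Phred quality ≥ 25 count, and
deletions/reference-skips never count), a position becomes a candidate if
in at least one sample:

* total qualifying depth ≥ 10,
* some single alternate base has ≥ 2 supporting reads, and
* the alternative allele frequency (AAF) is ≥ 1%.

Multi-allelic columns keep the majority alternate only (ties broken
alphabetically for determinism), mirroring the behaviour of single-alt SNV
callers. Thresholds are evaluated **per sample**; a pooled-counts variant
is available (`mode = "pooled"` in `call_candidate_snvs()`) because the
choice between the two is a genuine ambiguity — per-sample evaluation is
the default since it does not let one deep sample dominate.

### Orientation

Editing is strand-specific: genomic A>G inside a plus-strand gene, or
genomic T>C inside a minus-strand gene, is class `A_to_I`. Positions under
genes on both strands where the two orientations disagree are `ambiguous`
and are dropped (and counted in the attrition table); unstranded short-read
data cannot resolve them. Everything else is `other` and excluded — only
`A_to_I` sites can reach the final set.

### The exclusion cascade

Rules apply in a fixed order and the first failing rule is recorded, so
attrition accounting is deterministic and reproducible:

1. **homopolymer** — the site lies inside, *or immediately adjacent to*, a
   reference run of ≥ 5 identical bases. The adjacency extension is this
   package's choice: polymerase-slippage artifacts concentrate at run
   boundaries, and the boundary base is not inside the run under a strict
   reading.
2. **simple_repeat** — the site falls in a user-supplied repeat mask.
3. **mitochondrial** — the site is on the named mitochondrial chromosome.
4. **splice_junction** — within 6 nt of an annotated splice junction.
   Distance is measured on the genome to the nearest annotated exon
   boundary base (donor or acceptor side) of any transcript; transcript
   termini are not junctions. An annotation-derived junction set was chosen
   over a read-derived one for determinism.
5. **indel_proximity** — within 1 nt of an indel observed in the pileup on
   ≥ 2 reads. The observed-indel source is this package's choice; with no
   indels in the alignments the rule is inert.
6. **read_end** — alternate-supporting reads whose mismatch lies within
   `floor(0.04 × aligned_length)` bases of either read end are discarded
   and the call re-evaluated; the site fails if no sample retains ≥ 2
   surviving alternate reads. Read-level discard (rather than discarding
   the whole site whenever any support is end-proximal) was chosen because
   genuinely edited sites also receive some end-proximal reads; the
   retained counts for level quantification are the *unfiltered* counts,
   since interior/terminal read position is independent of editing status
   and discarding would bias levels downward by excluding ~8% of reads.
7. **dbsnp** — membership in a known-variant list.
8. **germline_pattern** — among samples covered at depth ≥ 10, AAF = 100%
   (every qualifying read alternate, compared on integer counts, not
   floating point) or 0.40 ≤ AAF ≤ 0.60 in **more than** 90% of the
   covered samples. "Over 90%" is read strictly, and only covered samples
   enter the denominator — an uncovered sample carries no genotype
   evidence. A site covered in no sample is indeterminate and dropped with
   its own attrition line.

A whitelist of known editing positions (REDIportal-style) exempts a site
from **all** rules, including the germline rule — a catalogued editing site
that also matches a genotype pattern is still reported, flagged
`whitelisted`.

Finally, sites are retained when the editing level is ≥ 1% in ≥ 2 covered
samples. Every threshold lives in `discovery_thresholds()` with the
defaults above.

### Editing level and its estimation error

The editing level is the edited-read fraction, per sample, with cells
below 10× coverage masked. Quantification accuracy is characterised on
synthetic data as the mean absolute error of the **pooled** estimate
(Σ edited / Σ total across samples) against the depth-weighted true level:
at 50× mean coverage across 6 samples the pooled denominator is ~300 reads,
giving MAE ≈ 0.016 in the bundled experiments, and the error shrinks
monotonically from 20× to 200×. Per-sample, per-site estimates at 50× are
binomial with sd ≈ 0.06 at mid levels; the pooled quantity is what the
package's accuracy checks track.

## Statistics

**Differential editing.** Per site, a binomial GLM with logit link on the
per-sample (edited, total) counts: full model `~ group` (groups as an
unordered factor — developmental time is not modelled as a trend), null
model intercept-only; the LRT statistic is the deviance difference,
referred to χ² with `n_groups − 1` degrees of freedom. Groups with no
covered sample are dropped and the degrees of freedom adjusted; sites with
fewer than two covered groups are skipped with a recorded reason. The
plain binomial family is the default deliberately: it is exactly testable
against a closed-form pooled-vs-per-group MLE oracle, and at the package's
calibration conditions (two groups of three samples, 30× coverage, level
0.1) its empirical type-I error at α = 0.05 is ≈ 0.058 — slightly
anticonservative, as expected for χ² asymptotics on discrete counts, and
within the package's accepted [0.035, 0.065] band. It does not model
biological overdispersion beyond binomial sampling; with strong
replicate-level extra-variance a beta-binomial would be more conservative,
and the q-values should be read accordingly. Differentially edited sites
(DES) are defined as q < 0.05 after Benjamini–Hochberg adjustment (missing
p-values propagate and are excluded from the adjustment count).

**Correlation.** Spearman's rho is computed as the Pearson correlation of
mid-ranks (average ranks on ties). For n > 9 complete pairs the p-value
uses the t approximation; for n ≤ 9 it is the exact two-sided permutation
probability over all n! rank permutations (enumeration is cheap at 9! and
exactness matters at the tiny n of grouped designs). Editing–expression
correlations pair each site with its host gene's TPM over samples where
the site is covered, requiring ≥ 5 covered samples per pair (configurable;
with fewer pairs the exact p-values are too coarse to flag anything).

**Overall editing level.** Both common definitions are reported, since the
field uses both: the unweighted mean of defined site levels per sample, and
the read-weighted pooled fraction Σedited/Σtotal. On synthetic studies with
a graded per-sample ADAR activity both recover the activity ranking
(Spearman rho > 0.95 in the bundled 12-sample experiment).

**PCA.** The site × sample level matrix is mean-imputed per site at masked
cells (complete-case deletion degenerates on sparse matrices), sites are
centred, and scores/loadings come from SVD (`prcomp`). Variance fractions
are reported per component. Imputation toward the site mean shrinks masked
samples toward the centre, which slightly deflates the variance of
low-coverage samples — acceptable for the visual/QC role PCA plays here.

**TPM.** `rate = count / (exonic_kb)`, normalised to 10⁶ per sample. Gene
length is the union of exonic bases, matching how reads are counted;
isoform-resolved effective lengths are out of scope.

**Overlaps.** Venn-style region counts for up to four site or gene sets,
plus per-set unique lists and shared-by-at-least-k counts, computed by
exact membership-pattern tallying.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth for every planted signal:

* **Genome/annotation** — random chromosomes plus a small mitochondrial
  chromosome; multi-exon genes on alternating strands, most coding (CDS
  length divisible by 3, UTRs derived), one non-coding gene per
  chromosome. Homopolymer runs are written into expressed exons and repeat
  intervals recorded, so every context rule has real targets.
* **Editing** — true sites are placed at transcript-adenosine positions
  that are *discoverable*: outside homopolymers (including adjacency),
  repeats, the mitochondrial chromosome, and > 6 nt from junctions, and at
  least half a read length from transcript ends (closer positions have
  structurally collapsed coverage, which would conflate placement with
  detection). True level of site *i* in sample *s* is
  `activity_s × base_i` capped at 1, `base_i ~ beta(2, 5)` — a modelling
  choice of this package: a right-skewed distribution with mean ≈ 0.29,
  matching the common observation that most editing is partial; the
  parameters are exposed in `simulation_config()`. Per-sample activity defaults to an
  even ramp 0.5–0.95, giving the ADAR-expression-like gradient the
  summary statistics are tested against.
* **Confounders** — heterozygous SNPs alternate alleles per read with
  probability 0.5, homozygous always; contaminants are planted one third
  each inside homopolymer runs, within 6 nt of junctions, and as
  read-end-biased mismatches that only ever occur in the terminal 4% of a
  read (alternate probability 0.9 there, to guarantee they would be called
  without the read-end rule).
* **Reads** — single-end 100 nt reads drawn uniformly along spliced
  transcripts at per-gene depths set by log-normal expression weights
  (sdlog 0.3) around the target mean exonic coverage; gapped `M`/`N`
  CIGARs place them back on the genome, so junction proximity is
  meaningful. Per-base errors are independent at 0.1% with uniform
  substitution; base qualities are constant high.

Not emulated: realistic quality-score profiles, indels, PCR duplicates
(the pipeline contract assumes deduplicated input), stranded protocols,
paired ends, intronic reads, and mapping ambiguity. Consequently, passing
the bundled checks demonstrates the *logic* of the cascade and the
statistics — not robustness to alignment artifacts of real data, which are
upstream of this package's contract. One structural consequence: simulated
reads are exonic, so the synthetic region distribution is CDS/UTR-heavy,
unlike the intron-dominated distributions of real editomes.

In the standard end-to-end study (two 100 kb chromosomes, 6 samples in two
groups, 200 true sites, 100 het + 50 hom SNPs, 30 contaminants, 50×
coverage, 0.1% error) the cascade reaches precision ≈ 1.0 and recall
≈ 0.98, with zero germline or contaminant survivors; the residual misses
are sites whose base level falls in the lowest percentiles of beta(2, 5),
below the reach of the ≥ 2-read calling threshold. In that study the
germline VCF written by the generator is supplied to the pipeline as the
known-SNP exclusion list — the role a dbSNP build plays on real data for an
inbred strain — while the cross-sample germline-pattern rule remains the
backstop for uncatalogued variants and is exercised directly by unit and
oracle-equivalence tests: with six samples at 50×, binomial noise takes a
het site's AAF outside the 40–60% band in some sample often enough that
the pattern rule alone, read strictly ("over 90% of covered samples"),
would leak a fraction of unlisted het SNPs.

## Annotation

Regions are assigned with precedence CDS > 3′UTR > 5′UTR > non-coding exon
> intron > intergenic across all overlapping transcripts, an approximation
of consequence-ranking practice in standard annotators (the exact VEP
ranking is not reproduced). Coding consequences substitute A→G in
transcript orientation — inosine is read as guanosine, a biochemical fact,
so the alternate base is never taken from the genomic call — and translate
ref/alt codons under the standard genetic code; a stop codon gained or
lost is `stop_altering`. CDS lengths not divisible by 3 raise an
annotation error naming the gene.

## Numerical and interface choices

* Coordinates are 1-based inclusive internally; BED output is 0-based
  half-open; GTF/VCF/SAM follow their standards.
* All randomness flows from a single integer seed through fixed per-stage
  derived seeds; a fixed seed makes every emitted file byte-identical.
* All output tables are tab-separated with a header and a `#`-prefixed
  provenance comment (seed and thresholds).
* AAF = 100% is tested as `alt_depth == depth` on integers; band edges
  (0.40, 0.60) are inclusive.
* Exact-tie behaviour is made deterministic everywhere (alphabetical
  alternate-base tie-break, fixed rule order, stable sorts).

## Problem sizes in the bundled experiments

The test-suite and acceptance experiments use: the standard 6-sample study
above; coverage sweeps at 20×/50×/200× on a single 60 kb chromosome with
100 sites; LRT calibration with 2,000 null and 1,000 alternative
count-level replicates; a 12-sample, 4-group study at 30× for the
activity-gradient recovery; 500 randomized single-site contexts for
filter-oracle equivalence; and 200 random CDS positions for the
consequence oracle. These sizes give Monte-Carlo standard errors
comfortably inside the acceptance bands (e.g. ±0.005 on the type-I rate at
2,000 replicates) while keeping the whole suite inside a few minutes on
one CPU.

## Limitations

* The binomial LRT ignores replicate overdispersion (see above).
* Hyper-editing rescue (clusters of mismatches that defeat alignment),
  editing-type spectra beyond A-to-I, realignment and base-quality
  recalibration are out of scope; inputs are assumed deduplicated and
  recalibrated upstream.
* VarScan's additional default filters (strand bias, its p-value) are not
  reproduced; the four explicit thresholds are the contract.
* Ambiguous-strand sites are dropped, not rescued by stranded evidence.
* The simulator's fidelity limits are listed above; conclusions about real
  data should rest on the cascade's logic, not on the synthetic
  benchmarks alone.
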