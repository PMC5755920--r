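---
title: "Methylation domains, sequence classifiers, and ectopic methylation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation domains, sequence classifiers, and ectopic methylation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the pipeline

Vertebrate genomes are globally CpG-methylated, punctuated by
hypomethylated islands at regulatory regions. A natural hypothesis is that
the DNA sequence of those regions determines their methylation state. This
package implements the computational machinery for interrogating that
hypothesis: segmenting a methylome into hypo- and hypermethylated domains,
asking how well sequence alone predicts domain identity, and quantifying
whether sequences reintegrated elsewhere in the genome re-establish their
endogenous state or simply maintain whatever state they arrived with.

All pipeline inputs can be simulated (`generate_genome()`,
`simulate_methylome()`, `msp1_capture()`, `simulate_integration()`,
`simulate_trace()`), so every claim the test suite makes is computed from a
stated generative world rather than from inaccessible sequencing data.

# Domain calling

## Definitions

A CpG dyad is addressed by the 0-based position of its plus-strand C.
After coverage filtering (≥ 5×, `filter_coverage()`), each genomic CG is

* *qualifying* — called, and rate < 40% (hypo) or > 60% (hyper); the
  boundary values 40 and 60 are non-qualifying (strict inequalities);
* *nonqualifying* — called but not qualifying;
* *undetermined* — a genomic CG with no valid call (unsampled, unmappable
  or low coverage), which is why the caller needs the full CpG site list
  from the genome (`enumerate_cpg_sites()`), not just the observed track.

A domain is a stretch of ≥ 10 qualifying dyads containing at most 4
interleaved (nonqualifying **or** undetermined) dyads. The interleave limit
is read as a **total budget per domain**, the plain reading of the
definition; a consecutive-run variant is exposed as
`caller_params(interleaved_mode = "run")` for sensitivity analysis.
Domains begin and end on qualifying dyads; the half-open end coordinate is
the last qualifying C + 2 so the whole dyad is covered.

## Segmentation algorithm and tie-breaking

Maximal feasible intervals can overlap (e.g. ten qualifying dyads, three
interleaved, two qualifying, three interleaved, ten qualifying: the left
and right maximal stretches share the middle pair). Since domains of one
kind must not overlap, the caller resolves left-to-right: take the leftmost
position from which any feasible domain starts, extend it as far right as
the budget allows, emit, and continue strictly after it. The test suite
checks this scan against an independent brute-force oracle that enumerates
*all* feasible intervals and applies the same leftmost-longest rule, on a
thousand random classified tracks, and verifies that emitted domains are
never extendable by a single adjacent dyad.

Hypo- and hyperdomains are called independently over the same dyads;
overlaps between the two kinds are reported by `call_all()` but never
resolved, because under the strict thresholds with the interleave budget
both calls can be legitimate descriptions of noisy data.

# Sequence classification

`featurize()` maps a sequence to its 6-mer spectrum: counts of every
6-base window consisting solely of A/C/G/T. Choices fixed here (the
upstream tool's "default, recommended" behavior is not enumerated
anywhere citable, so these are this package's own defaults, all
config-exposed):

* reverse-complement collapsing ON (a domain has no orientation), giving
  (4096 + 64)/2 = 2080 canonical features;
* L2 normalization of each count vector (domains differ in length);
* soft-margin linear SVM with C = 1; the positive class receives weight
  w⁺ = n₋/n₊ recomputed from the actual input sizes (class sizes of
  231516 and 18435 reproduce the canonical 12.56), negatives weight 1.

No SVM implementation ships with the supported dependency set, so the
optimizer is written here: L2-regularized hinge-loss dual coordinate
descent (the standard linear-SVM algorithm), with the bias as an augmented
constant feature and a private xorshift generator for the visitation
order, so fits are reproducible from a seed and independent of R's RNG
state.

CpG masking (`mask_cpg()`, CG → NN) removes all CpG-density information
from the spectrum, because CpG density confounds domain classification:
windows containing N are simply not counted. Performance is measured by
stratified 10-fold cross-validation; the AUPRC estimator is average
precision with step interpolation (conservative under class imbalance;
tied decision values are grouped at one threshold). Both per-fold curves
and a pooled curve over all held-out decision values are reported, since
either convention appears in practice. The random baseline equals the
positive prevalence.

For the demethylated-vs-maintained CpG-context variant
(`cpg_context_dataset()`), a 22-bp window (±10 bp around the CG) is
extracted per matched CpG. The class rule is not threshold-defined
anywhere authoritative; the package reuses its own domain thresholds —
ectopic rate < 40% → demethylated, > 60% → maintained, middle excluded —
exposed as arguments.

# Endogenous vs ectopic methylation

`match_cpgs()` pairs every fragment CpG (genomic position = fragment
start + offset) with the endogenous call at the same position, dropping
and counting CpGs without a valid endogenous call. Matched CpGs keep
their fragment identity so that fragment-level operations remain possible;
`pool_matched_cpgs()` then sums counts per genomic CpG and library across
integration events — pooling counts rather than averaging per-event rates,
consistent with deeply sequenced pooled embryos. Kendall's τ is computed
tie-corrected (τ-b) because ectopic rates pile up at 0% and 100%.

DNase-hypersensitivity stratification is at CpG level (inside/outside),
except that fragments crossing a DHS boundary have all their CpGs labeled
`spanning_fragment` and the fraction of fully contained fragments is
reported. Fragment-level stratification classifies a fragment by its mean
endogenous CpG rate (< 40% hypomethylated, > 60% hypermethylated, middle
excluded and counted).

# Sanger trace quantification

On a bisulfite-converted amplicon, methylation rate = C ÷ (C + T) × 100%
from the two channel peak heights; the same height-ratio formula applied
to C vs G at the PAM third base (mutated NGC vs native NGG) yields the
per-site edited fraction. The locus editing rate aggregates PAM sites by
unweighted mean (median available as an option; the aggregation used
originally is not stated). The editing-normalized methylation rate divides
the methylation rate by the locus editing rate; quotients above 100% —
expected at low editing, where channel noise is large relative to the
edited-allele fraction — are capped at 100 and flagged rather than
silently truncated. Methylation sites are annotated on the
bisulfite-converted frame and PAM sites on the unconverted frame, so the
two peak tables are separate inputs; binary chromatogram parsing is out of
scope (the core consumes plain TSV peak tables).

# The synthetic world

The generators' defaults are the package's stated world and were fixed
before the acceptance checks were run:

* **Genome** (`genome_spec()`): background CpG density 10/kb with a 5-fold
  island enrichment (CG dinucleotides are planted directly, because CpG
  density is the quantity under study); background GC 0.40; island lengths
  lognormal around 800 bp, spacers around 3 kb. One 6-bp motif (`TGACCT`,
  CG-free so masking cannot erase it) is planted at ≈ 4 occurrences per
  island kb with 5-fold enrichment over background — the scale of a
  transcription-factor binding site enriched in regulatory islands. This
  gives the CpG-masked classifier a real but imperfect signal, strictly
  between chance and the unmasked CpG-density signal.
* **Methylome** (`methylome_spec()`): true rates Beta(1,9) in islands and
  Beta(9,1) in background (bimodal, skewed to 0%/100% as real methylomes
  are); coverage negative-binomial with mean 8 (the pipeline's post-filter
  mean coverage) and size 4, so a realistic minority of dyads falls below
  the 5× filter; observed counts binomial. Deeper means (30×, 100×) are
  used where an experiment needs the measurement not to dominate.
* **Capture**: MspI cuts C^CGG left to right; unfiltered fragments tile
  the chromosome; retention window 40–220 bp; adapter extension +144 bp
  (so retained molecules span 184–364 bp). Dam/DpnI counter-selection of
  unintegrated molecules is a purification step, abstracted away rather
  than simulated at sequence level. `tile_fragments()` provides an
  idealized window set when capture bias is not under study.
* **Integration** (`integration_model()`): maintenance flips a CpG's
  library state fully with probability γ (gain) or δ (loss), default 0.02
  each — δ is a free parameter, not calibrated to any measurement;
  sequence-determined re-establishes the endogenous true rate ± 5 points
  of Gaussian noise; default-hypermethylation drives every CpG to
  Beta(9,1) regardless of library.
* **Traces**: channel heights encode the allele mixture
  rate × editing / 100 at CpG rows and the editing fraction at PAM rows,
  with multiplicative lognormal noise; at zero noise the quantification
  formulas invert the generator exactly.

## The model-discrimination experiment

The experiment that separates maintenance from sequence determination is
run in a *balanced-capture* world: 120 islands in 650 kb, so islands hold
about half of all CpGs — mirroring the assay design property that
approximately equal numbers of hypo- and hyperdomain CpGs were
interrogated — with the endogenous methylome sequenced at 100× mean
coverage. The depth matters: rank correlations between two *measured*
rates are attenuated by sampling noise, and at 8× endogenous coverage the
attenuation, not the integration model, would dominate the coefficient.
With deep measurement the contrast is clean: maintenance gives |ρ| < 0.05
(the coefficient is insensitive to coverage, since independence survives
noise), while sequence determination with 5-point noise gives ρ ≥ 0.9.

## What a green test does and does not establish

The synthetic world contains exactly the structure the pipeline looks for:
two methylation states tied deterministically to island identity, iid
background sequence, a single planted motif, no repeats, no chromatin, no
strain variation, no bisulfite conversion failure, no mapping bias. Green
tests therefore establish that the implementation correctly recovers
parameters from data generated under its own assumptions — parameter
recovery, not biological validation. In particular real-data
benchmark values (classification AUPRC 0.83–0.84 unmasked / 0.53–0.56
masked, and the near-zero observed ectopic correlations) depend on the
real genome and injection libraries and are not reproducible from
synthetic data; the suite instead checks the qualitative orderings those
results rest on (unmasked > masked > chance; maintenance ≈ 0 vs
sequence-determined ≈ 1).

# Numerical and degenerate-input choices

* Rates are recomputed from counts whenever counts are present (inputs may
  round); a supplied rate more than 0.5 points from the count-derived
  value is an error, not a silent fix.
* Zero-coverage rows are accepted in tracks (and removed by any filter
  with `min_cov` ≥ 1); zero-signal trace sites are reported as
  undetermined rather than scored.
* Constant rate vectors make rank correlations undefined: flagged
  (`degenerate`), never NaN crashes.
* A rate of exactly 100% falls in the last 1% histogram bin `[99,100]`.
* k-mer weight ties in `top_kmers()` break lexicographically;
  fold assignment and the SVM visitation order are seed-deterministic.
* Chromosome names match by exact string equality; no alias table.

# Known limitations

* Realized domain coverage is not monotone in the interleave budget: a
  larger budget can merge a domain across a gap and then exhaust itself
  inside what would otherwise have been a second domain, stranding a tail
  below the ten-dyad minimum (e.g. ten qualifying dyads, five interleaved,
  then a ten-qualifying stretch containing four interleaved: budget 4
  covers 20 qualifying dyads, budget 5 covers 16). This is a property of
  any left-to-right segmentation with these constraints, not of this
  implementation; the feasible-interval *set* is monotone in the budget
  and the test suite asserts exactly that.
* The consecutive-run reading of the interleave limit is available but
  untested against any external reference; no such reference exists.
* `merge_dyad_strands()` trusts the genome for dyad context; calls at
  non-CG positions (assembly mismatches) are preserved and reported, not
  resolved.
* The SVM is linear only — by design, since the spectrum kernel with a
  linear machine is the standard setup — and dense; k > 8 is refused.
* Ectopic pooling assumes count-summing across integration events; if
  per-event rates were averaged originally, heavily covered events weigh
  differently. Both the pooled and per-fragment tables are exposed.
* The trace simulator models two-allele mixtures only (edited vs native),
  matching the quantification formulas' own assumption.
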