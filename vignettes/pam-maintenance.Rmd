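---
title: "Tumor-specific PAM targets and their maintenance across metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-specific PAM targets and their maintenance across metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamtrace)
```

## The problem

SpCas9 cuts DNA only next to an NGG protospacer adjacent motif (PAM). A
somatic single-base substitution (SBS) that turns a germline trinucleotide
into NGG therefore creates a cleavage site that exists in tumor cells and
nowhere in the patient's normal genome — a tumor-specific CRISPR target.
Most such substitutions are intergenic passengers inherited from the
cancer-initiating cell, so a set of them discovered in the primary tumor
should, in principle, be present in every metastasis. In practice tumors
are genomically unstable, and the central question this package addresses
is: *which* of these targets survive metastatic evolution, and what
predicts their loss?

`pamtrace` implements the computational workflow end to end:

1. **Discovery** (`subtract_somatic()`, `detect_novel_pams()`): tumor−normal
   subtraction of variant calls, followed by detection of SBS that create
   novel NGG PAMs.
2. **Zygosity and LOH scope** (`expected_vaf()`,
   `classify_segment_zygosity()`, `classify_loh_scope()`): a
   VAF–purity–copy-number model, per-segment zygosity calls, and
   classification of regions as truncal LOH (lost before lineage
   divergence, shared by all samples), private LOH (some samples only), or
   retained heterozygosity.
3. **Maintenance statistics** (`call_presence()`, `percent_truncal()`,
   `percent_maintained()`, `shared_by_all()`,
   `maintenance_by_loh_class()`): capture-style presence calling and the
   clonality summaries built on the PAM × sample presence matrix.
4. **Simulation** (`sim_config()`, `simulate_case()`,
   `simulate_scenario()`): a metastatic clonal-evolution simulator with
   explicit homolog tracking that provides ground truth for all of the
   above.

## PAM creation

A dinucleotide overlapping the mutated base must become GG (plus strand)
or CC (reported as a minus-strand NGG) while not having been GG/CC in the
germline. Because the mutated base itself must become G or C, only two of
the twelve substitution classes can create PAMs on each strand, and one
SBS can create at most two PAMs per strand class (left and right
dinucleotide). Enumerating all 4 × 3 × 16 = 192 (ref, alt, left, right)
combinations, 42 create at least one PAM: a 21.875% per-variant rate on
uniform sequence with a uniform spectrum. Observed per-genome yields are
lower (roughly 2–10% of passed somatic variants in real tumor–normal
subtractions) because base composition, the mutational spectrum, and
downstream mappability/probe-specificity filtering all reduce the rate;
this package deliberately reports the unfiltered rate and leaves
probe-level specificity filtering out of scope.

The N of the NGG window is irrelevant to creation (mutating N cannot
create a PAM where GG pre-existed) but the window must lie on the contig;
sites with N inside the window are skipped and counted rather than
errored, since assembly gaps are expected. Protospacers (20 bp 5′ of the
PAM on the PAM strand) are recorded, flagged when truncated at contig
ends, and are *not* filtered for genome-wide uniqueness.

## The VAF model and zygosity

For a somatic variant on `m` of `C_T` tumor copies in a sample of purity
`p`, with normal cells contributing `normal_cn` copies:

    E[VAF] = p·m / (p·C_T + (1 − p)·normal_cn)

At purity 1 this is `m / C_T`: heterozygous diploid sites sit at 0.5,
sites in LOH regions (copy-loss haploid, or copy-neutral with every copy
mutant) at 1, triploid multiplicity-1 sites at 1/3. A segment is called
LOH when at least 90% (`loh_fraction`) of its informative variants lie
within a depth-aware tolerance of the all-copies VAF — a fixed band of
0.05 at depth ≥ 30 (keeping the inclusive 95% convention at purity 1) and
three binomial standard deviations below that depth. The call needs at
least `min_support = 3` informative variants (depth ≥ 10), otherwise the
segment is indeterminate. The LOH mode follows the segment copy number:
copy-loss at CN ≤ 1, copy-neutral at CN ≥ 2.

Two design choices matter here:

* **Which variants vote.** Mutations acquired *after* a copy-neutral LOH
  event sit at VAF 0.5 and carry no information about the region's
  zygosity history; with enough of them a genuinely LOH region drops below
  the 90% high-VAF fraction. The pipeline therefore classifies zygosity
  from variants shared by at least two of the case's samples
  (`filter_shared_variants()`), which are trunk-derived to good
  approximation. With a single sample no filtering is possible and all
  variants vote.
* **Region granularity.** Scope classification runs on the union of
  segment breakpoints across samples (`GenomicRanges::disjoin`), so every
  region has exactly one copy-number state per sample; an arm-level
  aggregation (`per_arm_summary()`) reports maintenance, length-weighted
  mean CN and mean VAF per chromosome arm. Arm boundaries are an input,
  never computed.

A region is truncal LOH when every determinate sample is LOH, private LOH
when some but not all are, retained heterozygosity when none is.
Indeterminate samples leave the denominator; a region where determinate
samples agree on LOH but disagree on its mode still counts as truncal LOH
and is flagged `mixed_mode`. Purity is an input (default 1, appropriate
for cell lines); no purity/ploidy estimation is attempted, and
allele-specific copy-number inference from germline BAF is out of scope.

## Presence calling and maintenance statistics

Capture-style presence calling uses a 5% VAF cutoff (inclusive — just
above background artifactual noise) with a 20-read depth gate below which
a site is `no_call` rather than absent; 20 reads give binomial power to
see a 5% allele. No-call entries are excluded from numerators *and*
denominators of every statistic, so low coverage cannot masquerade as
target loss. Sample-level QC additionally excludes whole samples whose
mean on-target depth sits below the knee of the percent-truncal-vs-depth
curve: the knee is the breakpoint of a continuity-constrained two-segment
least-squares fit (hinge regression over candidate knots midway between
consecutive depths), with a hard floor of 30× and a fallback to the floor
alone when the fit is degenerate or shows no genuine rise. Continuity is
what keeps the breakpoint identifiable — two unconstrained lines fit any
2+2 split of four points exactly.

The truncal set is the union of panel PAMs present in any primary sample;
PAMs that are no-call in every primary are excluded and listed separately.
When a case has no primary sample, truncal PAMs are inferred as those
present in more than one metastasis. The panel itself is the union of PAMs
discovered in the *metastasis* samples — primaries only vote on
truncality, so a PAM private to one primary section never enters the
maintenance denominator.

From the presence matrix: **percent truncal** (per metastasis, fraction of
evaluable truncal PAMs present), **percent maintained** (per PAM, fraction
of evaluable metastases containing it), **shared-by-all** (fraction of
truncal PAMs present in every lesion), exact membership-region counts for
set overlaps, and maintenance summarized by LOH class. When no no-calls
exist, the mean of percent maintained over PAMs equals the mean of
percent truncal over metastases (both equal presence-cell count over
matrix size) — a counting identity the tests verify against brute-force
oracles. Group comparisons use the Mann-Whitney rank-sum test for two
groups (with an exact enumeration of all group assignments, using
midranks, whenever that is feasible — the normal approximation is poor for
the tiny tie-ridden groups these analyses produce) and Kruskal-Wallis plus
one-way ANOVA for three or more. Raw p-values are reported without
multiple-testing correction, and this is flagged in the report metadata.

## The simulator

`simulate_case()` models one patient as a star phylogeny around the
cancer-initiating cell: a diploid germline (homologs A and B per
chromosome) acquires events in this order:

1. **Trunk gains** (fresh copy labels — early aneuploidy precedes most of
   the passenger burden), so a triploid region offers three
   distinguishable copies;
2. **Trunk mutations**, each on one uniformly chosen copy of its region,
   multiplicity 1 at placement;
3. **Truncal LOH**, copy-loss (remove one uniformly chosen copy) or
   copy-neutral (remove one copy, duplicate a survivor — the duplicate
   shares its parent's label, so surviving mutations get multiplicity =
   CN). Because this precedes divergence, trunk mutations on the lost
   homolog vanish from *every* sample and survivors sit at VAF 1 in all of
   them;
4. **Divergence**: each sample applies its private LOH/gain events (the
   removed copy drawn once per event), then receives private mutations on
   one surviving copy.

This ordering is what produces the per-copy loss arithmetic: a private
copy-loss event in a diploid region removes each heterozygous trunk site
with probability 1/2 (the site's homolog was chosen uniformly), and
removing one of three homologs of a triploid region loses 1/3 of
multiplicity-1 sites. Read data are then sampled per site as
Poisson(mean depth) total reads and Binomial(depth, expected VAF) alt
reads; `capture` emission mode writes every PAM-creating somatic site of
the case — including sites a sample does not carry, which get zero alt
reads — so presence/absence calling is exercised, while `wgs` mode writes
only carried sites, emulating a caller. Germline heterozygous SNPs
(shared by the matched normal) provide the substrate for tumor−normal
subtraction. All randomness derives from the config seed with fixed
per-sample offsets, so identical configs give byte-identical outputs.

What the simulator does *not* model — and what passing tests therefore do
not establish about real data: sequencing error and FFPE artifact
chemistry (a 5% presence cutoff cannot be stressed by artifact noise that
is never generated), mapping bias and repeat-driven coverage loss,
subclonal structure within the primary (the star topology has no nested
clones), selection, and polyclonal seeding. The default substitution
spectrum is a 2:1 transition:transversion ratio and the default GC content
0.41; both are configurable.

The bundled scenario (`demo_case_config()`, also shipped as
`inst/extdata/scenarios/demo_case.yaml`) mirrors a multi-lesion pancreatic
cancer case in miniature: one primary section and three metastases at
purity 1 and 60× depth over 3 × 1 Mb chromosomes — one under truncal
copy-loss LOH, one under copy-loss LOH private to the first metastasis,
one fully heterozygous — with 300 trunk mutations, 40 private mutations
per sample and 120 germline SNPs. These sizes give ten-plus truncal PAMs
per LOH class and dozens of informative variants per region while keeping
a full simulate-discover-classify-maintain cycle in seconds. An FFPE-like
variant of the scenario sets purity near 0.3 and relies on the QC depth
filter to exclude under-powered samples.

```{r, eval = FALSE}
sc <- simulate_scenario(demo_case_config(seed = 1), "sim")
report <- run_pipeline(sc$manifest, outdir = "report")
report$maintenance$by_loh_class
```

On this scenario the truncal-LOH class shows mean maintenance 1.0 (every
truncal PAM in the truncal-LOH chromosome is present in every metastasis),
the private-LOH class is partially lost (one of three metastases loses
each heterozygous PAM with probability 1/2), and the retained-het class is
fully maintained at 60× depth.

## Numerical choices and degenerate inputs

* VAF is always recomputed from allelic depths (AD), never taken from an
  AF tag, because AF conventions differ between callers; multiallelic
  records are split per alternate allele with the site's summed depth as
  denominator.
* Subtraction keys on exact (chrom, pos, ref, alt); an SBS-only pipeline
  needs no left-alignment window. Germline variants failing the quality
  filter (MQ ≥ 20, depth ≥ 10, AF ≥ 0.05) do not subtract.
* Thresholds are inclusive at their boundaries (VAF 0.95 is high-VAF,
  VAF 0.05 is present).
* Empty inputs degrade explicitly: empty tumor sets subtract to empty with
  a warning; a PAM creation rate over zero variants is an error rather
  than NaN; zero evaluable PAMs yield `NA` statistics reported as missing;
  a region where every sample is indeterminate is a scope error (surfaced
  as `unclassified` in the case table).
* Internal coordinates are 0-based half-open everywhere except variant
  positions, which stay 1-based as in VCF; conversion happens only at
  format boundaries.

## Limitations

Zygosity is called from somatic VAFs plus an integer total-CN segment
input; without the segment file, copy-neutral LOH cannot be distinguished
from copy-loss LOH (both put shared variants at VAF 1). Purity below
roughly 0.3 at 60× compresses the VAF separation between heterozygous and
LOH states faster than the depth-aware tolerance widens, and such samples
should fail the QC depth filter rather than be classified. The maintenance
statistics assume the capture panel interrogates every truncal PAM in
every sample; panel dropout appears as no-calls, which the statistics
exclude rather than impute.
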