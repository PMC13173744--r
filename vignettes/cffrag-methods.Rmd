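---
title: "Methods: cfDNA fragmentomics with cffrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics with cffrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffrag)
```

This vignette documents the models and conventions behind `cffrag`: what
each stage computes, the assumptions it makes, the parameters that matter,
and the choices taken where the design was genuinely open. The companion
README shows the worked example; here we explain *why* the pieces look the
way they do.

## Fragment records and read filtering

A fragment is one retained primary alignment. Its length is the **reference
span** — the difference between the alignment's end and start coordinates on
the reference — so deletions lengthen a fragment, insertions do not, and
soft/hard-clipped bases never contribute. This is the right definition for
cfDNA, where the molecule's genomic footprint, not its read length, is the
biological quantity.

The default retention policy mirrors standard long-read cfDNA practice:
read-level basecall quality `qs ≥ 10`, mapping quality `mapq ≥ 20`, and
removal of records matching the flag mask `0xD04` (unmapped, secondary,
duplicate, supplementary). Two conventions are ours to declare:

* `qs` is taken from the alignment's `qs` tag when the basecaller provided
  one, and otherwise computed as the mean base quality of the record — the
  tag is producer-specific and not defined for all BAMs.
* Duplicates are removed (the mask includes them). Whether any analysis
  should retain marked duplicates is a judgment call; we default to the
  stricter choice and expose the mask in `read_filter_policy()`.

Length-range BAM splitting uses **closed intervals** in bp (`[75, 200]`
retains a 200 bp fragment), matching how such ranges are conventionally
written, and applies the same length definition as extraction, so stratified
counts always reconcile with fragment tables.

BAM anonymization restores every aligned mismatch to the reference base and
masks inserted bases to `N`, leaving coordinates, CIGARs, qualities, clips,
and deletions untouched. `MD`/`NM` tags are dropped rather than recomputed —
they would otherwise still encode the removed variants. The operation is
idempotent.

## The log-length grid

All length distributions live on a fixed grid of bin centers `10^x`, with
`x` advancing in exact steps of 0.01 between 1.70 and 4.70 (50 bp to
50 kb; 301 bins). A length maps to the bin whose exponent is `log10(length)`
rounded to the nearest step. Two numerical choices:

* The grid endpoints are the nearest step multiples of `log10(50)` and
  `log10(50000)`, which makes the grid closed under the rounding rule.
* Lengths outside the grid are **clamped** to the terminal bins rather than
  dropped. Fragment mass at the edges is real (ultra-long contamination
  reaches past 50 kb); discarding it would understate exactly the signal the
  ultra-long class is defined by.

Each sample yields two vectors over the grid: the **fragment proportion**
(bin count over total count) and the **DNA proportion** (bin base-pair sum
over total base pairs). Both sum to 1. The DNA-weighted form is what the
classifier consumes: a rare 20 kb fragment carries 100× the DNA of a
mononucleosome and is biologically 100× the contamination.

Interval metrics (`frac_dna_in_range()`, `frac_fragments_over()`) are
computed from **raw lengths**, not re-binned values, to avoid grid
quantization error. Quintile binning sorts samples ascending by the metric
(fraction of DNA in 900–4,300 bp by convention), breaks ties by sample id
for determinism, and makes bin sizes differ by at most one, earlier bins
taking the remainder (89 samples split 18/18/18/18/17).

## Adapter-anchored end motifs

A 5′ end-motif call requires positive evidence that the read captured the
true molecule end: the soft clip immediately preceding the aligned segment
must end with a perfect match to the final 5 bp of the sequencing adapter
(`CACCT`). The motif is then the first five aligned bases, in read
orientation; if any of the five has base quality below 20 the end is
rejected. Reads without base qualities are skipped and counted.

The two ends of a fragment are independent observations. The calling rule
is specified once, for the 5′ read end; for the 3′ read end we apply the
symmetric rule — terminal soft clip beginning with the reverse complement
of the adapter tail, last five aligned bases reverse-complemented into
5′→3′ fragment-end orientation. This symmetry is a declared convention, not
an external fact. Motifs are reported in read space (the adapter anchor
lives there); CC/CCCA classification is by prefix of the 5-mer, since CCCA
is a 4-mer property of a 5-mer call.

The uniform-sequence background for CCCA is `(1/4)^4 = 1/256 ≈ 0.0039`,
which the motif caller reproduces on uniform-random ends; nuclease-processed
fragments sit far above it.

## The synthetic cohort generator

The generator exists so that every downstream claim can be tested against
ground truth. Each fragmentation class is a mixture of length components:

* `gaussian_peak` — nucleosome-protected peaks (healthy: 167 ± 10 bp
  mononucleosome carrying 88% of DNA mass, 334 ± 20 bp dinucleosome 12%);
* `nucleosome_ladder` — `n × 167 + N(0, 25)` bp with `n` uniform on 5–25,
  the phased multi-nucleosome ladder of hypofragmented samples (45% of DNA
  mass by default, never tumor-derived);
* `log_uniform` — 7.5–50 kb lysis fragments (50% of DNA mass in the
  ultra-long class, never tumor-derived, uniform-random end motifs).

**Component weights are DNA-mass shares**, converted internally to
per-fragment draw probabilities by dividing by each component's mean length.
This is the natural scale for mixed short/long populations: a ladder
carrying 45% of a sample's DNA is only a few percent of its fragment
*count*, and quoting weights on the mass scale keeps them commensurate with
the DNA-proportion profiles and interval metrics the analysis reports. The
default ladder share places hypofragmented samples mid-envelope (roughly
40–50% of DNA in 900–4,300 bp), and varying it over 0.25–0.6 sweeps the
range the class definition spans.

The hyperfragmented class combines a 110 ± 18 bp sub-mononucleosomal peak
(45% of mass), a 270 ± 13 bp short-dinucleosome peak (15%), and the normal
mononucleosome (40%), with reduced motif probabilities (CC 0.18, CCCA 0.04
vs 0.30/0.10 for nuclease-processed classes). The motif levels of each class
are free parameters of the generator — they are conventions chosen to be
qualitatively right (enriched vs reduced vs background), and the tests
assert recovery of the *configured* values, never any particular published
curve. Motif draws use a rejection scheme so the configured CC- and
CCCA-prefix probabilities are exact, not approximate.

Tumor origin: each sample has a tumor fraction `tf`; a fragment from
component `c` is tumor-derived with probability `tf · m_c / z`, where `m_c`
is the component's tumor-share multiplier (0 for ladder and lysis
components — those are ex vivo blood products) and `z` normalizes so the
overall tumor share equals `tf`. Setting the hyperfragmented short
component's multiplier above 1 injects tumor-specific shortening; the
default of 1 encodes the null in which tumor and blood DNA share one length
distribution.

Positions come from a toy genome of four 10 Mb contigs with copy states
(2, 3, 1, 2) in tumor cells: one single-copy gain, one single-copy loss,
balanced so the genome-wide mean copy number is exactly 2. Tumor fragments
sample contigs proportional to `length × copy`; blood fragments proportional
to length. The balance makes the naive estimator below exactly unbiased.

Concentrations: cfDNA is lognormal per class (meanlog `log(7)` ng/mL
healthy; `log(35)` for the hypo- and hyperfragmented classes and `log(30)`
for ultra-long, encoding the elevated levels of both aberrant classes;
sdlog 0.5). H3.1 is `5 × cfDNA + N(0, σ²)` with `σ²` derived **analytically**
from the lognormal mixture moments so the population R² equals its target
(default 0.73). At `R² = 1` the noise is exactly zero. Because the noise is
additive, a sample can receive a (rare) negative H3.1 value; the generator
leaves these untouched so the calibration stays exact, and the pipeline's
features stage reports them as 0, as an immunoassay clips below its
detection limit.

The post-thaw high-speed spin is simulated as removal of a configured
proportion (default 0.85) of lysis-component fragments — the proportion is a
free parameter chosen to leave a visible residue of ultra-long DNA, as spins
reduce but do not eliminate the contamination.

What the generator deliberately does **not** emulate: sequence-level realism
(error profiles, homopolymers), methylation, double-strand nick structure,
GC and mappability coverage biases, and inter-sample variation in the
component shapes themselves. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well-calibrated on data with the assumed
statistical structure — not that real cohorts will be this clean.

## Classification

Profiles (DNA proportions) are z-normalized per bin against a designated
healthy reference: `z = (value − mean) / max(sd, floor)`. The SD floor
defaults to `1e-6 ×` the largest bin SD (absolute `1e-6` if all SDs are
zero) and exists because small references produce zero-SD bins. When a
cohort has no healthy set, the reference falls back to all-sample mean/SD —
the same method, applied self-referentially.

PCA is run **uncentered** on the z-matrix. The z-transformation has already
centered every bin at the healthy reference; re-centering at the cohort mean
would let an abundant abnormal class drag the origin toward itself, offset
the reference samples' scores from zero, and break the interpretation of a
score as "distance from healthy along this component". Uncentered, the
components are directions of departure from the healthy state and reference
samples score near zero by construction. Components are sign-oriented so the
bin with the largest absolute loading is positive — high scores then mean an
*excess* of the signature lengths. A zero-variance matrix (all samples
identical) yields all-zero scores with a warning rather than an error.

Which component carries which class varies with cohort composition, so the
mapping is recovered from the fitted loadings: each component is matched to
the class whose diagnostic window — 900–4,300 bp (hypofragmentation),
> 7.5 kb (ultra-long), 75–145 ∪ 245–295 bp (hyperfragmentation) — captures
the largest share of its positive loading mass, greedily and one-to-one.
A component's own length range (for "fraction of DNA in the component's
range") is the set of bins whose loading exceeds half the maximum loading;
the 0.5 quantile is a tunable with the usual trade-off (lower = wider,
more inclusive ranges).

Class assignment is reference-relative by default: a sample is high on a
component when its reference-mean-subtracted score exceeds `z_threshold`
(default 3) reference SDs — no absolute score scale survives contact with
varying cohort sizes and depths, so thresholds are expressed in units of
healthy variation. Where published absolute cutoffs exist for a specific
re-analysis (single-component mode), the absolute rule `score > 5 ⇒
hyperfragmented, score ≤ 5 ⇒ typical` is available with the boundary
exactly at 5 excluded. When several components exceed their threshold the
largest standardized score wins; samples high on none are healthy-like.

Tumor-fraction quality bins follow the printed boundaries: below LOD
`tf < 0.02`, low purity `0.02 ≤ tf ≤ 0.1` (both bounds inclusive — the three
inequalities then leave no gap), pass `tf > 0.1`.

## Cohort features

Decomposition of a concentration into tumor and non-tumor components is the
exact identity `tumor = total × tf`, `nontumor = total − tumor`; it is
invertible and propagates no uncertainty (point estimates only).

The naive tumor-fraction estimator is **synthetic-data plumbing**, standing
where a real CNA caller's estimates enter as inputs. On the balanced toy
genome the expected per-bp coverage of a segment with tumor copy `c`,
relative to neutral segments, is `(2 + tf(c − 2))/2`; inverting gives
`tf = 2(r − 1)` for a gain and `2(1 − r)` for a loss, averaged over altered
segments. It assumes uniform within-segment coverage and known segment
states, which the generator guarantees and real data does not.

Length-stratified enrichment is the ratio of tumor fractions measured in
short (75–145 bp) vs mononucleosome (75–200 bp) fragments; 1 means tumor
and blood DNA are equally fragmented, and the value is undefined (NA) when
the denominator is 0.

Feature clustering uses Spearman correlation over pairwise-complete
observations, distance `1 − ρ`, and **average linkage** — the linkage is an
open choice; average linkage is the conventional default for correlation
distances and is least sensitive to single tight pairs. Constant features
have no rank correlation and are masked with a warning. Undetectable tumor
fractions enter as 0 (a config choice, flagged in the interface) rather
than as missing values.

## Determinism and problem sizes

A single integer seed governs every stochastic stage; per-stage seeds are
derived from it, and identical configurations produce byte-identical
artifacts (the run manifest records the seed, the configuration, and MD5
checksums of every output). The test suite exercises the machinery at
deliberately desk-scale sizes — planted cohorts of 40 samples at 1,000–5,000
fragments each (20 independent seeds for recovery checks), 10⁵-fragment
samples where estimator calibration is asserted to ±0.03, and 10⁴–10⁵
motif draws where frequencies are asserted within three binomial standard
errors — sizes chosen so the whole suite completes in a few minutes while
keeping the Monte-Carlo error well inside each asserted tolerance.

## Known limitations

* The classifier assumes the healthy reference is genuinely typical;
  contaminated references (e.g. unspun aliquots) must be excluded by the
  caller, as the reference-building step cannot detect them.
* Illumina-style short-read data can be ingested only as precomputed length
  tables; insert-size inference and 4-mer end motifs without an adapter
  anchor are out of scope.
* The naive tumor-fraction estimator is not a CNA caller: no bins, no GC
  correction, no ploidy model, no panel of normals. Real tumor fractions
  should come from a dedicated tool and enter as metadata.
* Anonymization removes SNV and insertion evidence but necessarily leaves
  deletion and soft-clip structure visible.
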