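---
title: "Methods and modelling choices in tyGCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in tyGCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyGCR)
```

`tyGCR` implements an end-to-end analysis of gross chromosomal
rearrangements (GCRs) mediated by dispersed Ty1/Ty2 retrotransposon
repeats in budding yeast. The experimental design it models places a
counter-selectable cassette and a single full-length Ty1 element
("Ty912") on the left arm of chromosome V; rearrangements that delete
the cassette survive selection, and the surviving isolates are
characterised by fluctuation assays (how often GCRs arise), array-CGH
(what the rearranged chromosome looks like), and junction sequencing
(which repeats recombined). This vignette documents the statistical
and algorithmic choices behind each module, the defaults, and the
known limitations of the synthetic-data generator.

## 1. Fluctuation-assay rate estimation

GCR rates are estimated from Luria–Delbrück fluctuation assays by the
Lea–Coulson method of the median. Given the median mutant count
$\tilde r$ across parallel cultures, the expected number of mutational
events per culture $m$ solves

$$\frac{\tilde r}{m} - \ln m = 1.24,$$

and the rate is $\mu = m / N_t$ with $N_t$ the final cell count per
culture. `estimate_rate_lc_median()` solves this with
`stats::uniroot()` on $[10^{-6}, 10^{6}]$ at tolerance $10^{-10}$; the
equation is monotone in $m$ on that interval so the root is unique.
Two edge cases follow the conventions of the underlying assay
literature:

* a median of zero is replaced by 0.5 and the resulting rate reported
  as a **censored** upper bound (printed with a leading `<`);
* fewer than 14 cultures triggers a warning, because the order-statistic
  confidence interval below loses resolution for small $n$.

### Confidence intervals for the median

Rather than propagating an asymptotic standard error through the
nonlinear median equation, `median_ci95()` uses the exact
distribution-free order-statistic interval: for $n$ cultures, the
largest $k$ with

$$1 - 2\,P(\mathrm{Binom}(n, 1/2) \le k-1) \ge 0.95$$

gives the $(k^{\text{th}}, (n{+}1{-}k)^{\text{th}})$ order-statistic
pair. For the standard $n = 14$ design this is the (3rd, 12th) pair
with exact coverage 98.71%. The interval endpoints are then mapped
through the median equation and divided by $N_t$, so the reported rate
CI inherits the exact coverage of the median CI (the mapping
$r \mapsto m(r)/N_t$ is monotone). Fewer than six cultures cannot
achieve 95% coverage at any $k$ and is an error.

### Fold changes and mutant classes

`fold_change()` reproduces the mixed rounding precision conventional
in published rate tables: folds $\ge 10$ are rounded to integers,
smaller folds to one significant figure; the raw fold is always
returned alongside. `assign_mutation_class()` classifies a mutant by
comparing its CIs against wild type in the repeat-bearing and
repeat-free assays (elevated in both, elevated with repeats only, or
repeat-dependent suppression), splitting each into A/B subclasses by
effect size.

## 2. Repeat annotation and arm-relative orientation

Repeat elements are stored in 0-based half-open coordinates with a
strand, and every element is assigned an **arm-relative orientation**:
on a left arm, a Crick-strand element points toward the telomere
(`telomere_oriented`) and a Watson-strand element toward the
centromere; the rule mirrors on right arms. Orientation, not strand
per se, is what determines whether a recombination junction between
two repeats preserves one centromere or captures two, so this derived
label drives classification downstream. An element spanning its
centromere has no defined orientation and is an error.

Elements are grouped into **clusters** by chaining: a sorted scan
joins an element to the open cluster when the gap to the running
maximum end is at most 5 kb (default `window_bp = 5000`). Each cluster
carries an `orientation_summary` (`all_telomeric`, `all_centromeric`,
or `mixed`) consumed by the classifier. GFF3 and BED readers/writers
are provided via `rtracklayer`; GFF3 is 1-based on disk and converted
on the way in and out.

## 3. Synthetic data

The generator exists so that every analysis module can be tested
against known ground truth:

* `simulate_fluctuation_cultures()` grows cultures from $n_0$ to $N_t$
  cells in discrete generations, with mutations arising per division
  and expanding with the culture — reproducing the heavy-tailed
  "jackpot" distribution.
* `simulate_gcr_event()` draws a rearrangement of a requested class
  (I–V) on a compact multi-chromosome fixture genome: a Ty912-anchored
  terminal deletion of chromosome V plus class-appropriate
  amplifications bounded by annotated clusters and telomeres.
* `render_probe_signal()` converts an event into probe-level log2
  ratios on a regular grid (default 200 bp spacing), with Gaussian
  noise (`sigma = 0.25` by default, matched to the dispersion of real
  aCGH), a multiplicative base intensity, and additive background.
* `simulate_ty_pair()` / `synthesize_junction()` create two Ty
  paralogues differing at ~1/150 positions and splice them at chosen
  crossovers to make chimeric junctions.

**Realism limits.** Probe noise is i.i.d. Gaussian on the log2 scale;
real arrays show spatial autocorrelation and GC waves. Breakpoints in
the simulator land exactly at repeat boundaries, whereas real
junctions resolve anywhere inside a repeat. SNPs in the Ty pair are
i.i.d. rather than phylogenetically clustered. These simplifications
make ground truth unambiguous but mean recovery rates measured on
synthetic data are upper bounds.

## 4. Copy-number segmentation

`segment_isolate()` is deliberately simple and fully deterministic —
a thresholding segmenter tuned to the structure of repeat-mediated
events rather than a general-purpose CBS/HMM:

1. probes inside annotated repeats are masked (their signal reflects
   genome-wide repeat copy number, not local copy number);
2. runs of probes with $|\log_2| \ge$ `tau_log2` (default 0.4, midway
   between the expected 0 and 1) and at least `min_probes = 10`
   members become candidate segments, allowing `min_gap = 3`
   below-threshold probes inside a run and bridging physical gaps up
   to `gap_bp = 2000`;
3. adjacent candidates with equal rounded copy number
   ($\mathrm{copy} = \mathrm{round}(2^{\overline{\log_2}})$) merge
   when separated by at most `merge_gap_bp = 10000` **and** at most
   `min_gap` unmasked below-threshold probes — i.e. a segment may
   continue across a masked repeat block, but not across genuine
   normal-copy probes;
4. short opposite spikes up to `spike_tolerance = 5` probes inside
   deletions are absorbed;
5. chromosomes with $\ge 90\%$ elevated probes are flagged aneuploid
   and excluded from event segmentation.

`anchor_boundaries()` then labels each segment end as `telomere`,
`centromere`, `cluster` (within `tol_bp = 2000` of a repeat cluster,
recording the cluster's elements and orientation summary), or
`unanchored`.

## 5. Classification and mechanism inference

`classify_gcr()` applies the Class I–V taxonomy to anchored segments
(aneuploid chromosomes excluded):

* **Class I** — Ty912/terminal deletion with no amplification
  (de novo telomere addition);
* **Class II/III/IV** — the deletion plus exactly one amplified
  segment bounded by a telomere and a repeat cluster; the cluster's
  orientation summary decides the class: `all_telomeric` junctions
  are monocentric-compatible (Class II, homologous-recombination
  translocation), `all_centromeric` junctions create a dicentric
  (Class III, breakage–fusion–bridge), `mixed` is Class IV with an
  **ambiguous** mechanism — by design, the data cannot distinguish
  the two resolutions, so the package refuses to guess;
* **Class V** — two or more amplified segments, or copy number
  $\ge 3$; `infer_mechanism()` walks the amplification chain and
  issues a per-junction verdict using the **entry anchor** (the
  repeat-cluster anchor for a telomere-bounded segment, the
  centromeric-side anchor for an internal one): any dicentric-forming
  junction implies breakage–fusion–bridge, all monocentric-compatible
  junctions imply serial template switching, anything else is
  ambiguous.

`predict_chromosome_size()` closes the loop against pulsed-field gel
observations: predicted kb $= \mathrm{round}(624 - \text{deleted} +
\sum \text{len} \times (\text{copy}-1))$, with 624 kb the
repeat-bearing wild-type chromosome V. A positive residual against an
observed size is reported as evidence for extra Ty copies acquired at
the junctions.

## 6. Junction SNP attribution

`attribute_snps()` aligns a chimeric junction against two parental Ty
sequences, assigns each diagnostic (parent-discriminating) position to
parent A or B, collapses the assignments into parental blocks, and
reports each crossover as the interval between the last SNP of one
block and the first SNP of the next. Intervals are printed
exclusive-lower/inclusive-upper, `(last_A, first_B]`, by default: the
crossover cannot lie *at* the last fully A-matching position but may
lie at the first B position. The inclusive `[` policy is available via
`lower_bracket = "["` and changes only the notation, never the
numeric bounds. Runs of positions matching neither parent are
absorbed when short (default cap 3, tolerating sequencing error or
mutation) and reported as `neither_blocks` when longer, since a long
neither run suggests a third template. `find_microhomology()`
recovers the microhomology at a fusion from length arithmetic
($k = |d| + |a| - |f|$) and verifies it as a donor suffix equal to an
acceptor prefix. Coordinates here are 1-based within the junction
read, matching sequencing convention; note that published breakpoint
tables sometimes print the same interval in both 0- and 1-based
conventions, so the bundled annotation fixes Ty912 at 30081–35997 in
1-based GFF3 (0-based half-open 30080–35997).

## 7. Pipeline and problem sizes

`run_pipeline()` chains all modules under a single validated
configuration (defaults from `default_pipeline_config()`, overridable
by a nested list or YAML file; unknown keys are errors, reported with
their full path). Every output table carries the MD5 of the resolved
configuration so tables can be matched to the run that produced them,
and a fixed seed yields byte-identical outputs.

Typical costs on one core: a simulate→render→segment→classify cycle
takes well under 0.1 s, so the 1000-event recovery study in the test
suite runs in minutes; rate estimation and junction attribution are
effectively instant at realistic sizes ($n \le 100$ cultures, Ty-length
junctions of ~6 kb with ~40 diagnostic SNPs).
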