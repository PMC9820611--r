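---
title: "Inferring layered regulatory hierarchies by partial-correlation attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring layered regulatory hierarchies by partial-correlation attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiergrn)
```

## The problem

Stress-response transcription in plants is organised hierarchically: a
small set of master transcription factors (TFs) drives a second tier of
TFs, which in turn drives the structural genes that execute the
physiological response. Given a short time-course expression experiment —
typically a handful of stress time points against an unstressed 0 h
control, with a few biological replicates each — the goal is to
reconstruct that hierarchy as a directed three-layer network
TF → TF → structural gene.

`hiergrn` implements the complete desk-side pipeline: a
differential-expression filter that defines the gene universe, the
triple-gene partial-correlation attribution that proposes
regulator→target edges, the two-pass layering that assembles the
three-layer network, GO-term composition and enrichment of the bottom
layer, bookkeeping for bench validation of predicted edges (ChIP-PCR
binding and overexpression qRT-PCR), and a synthetic-data simulator with
a planted ground truth for benchmarking all of it.

## The core statistic

Two genes $x$ and $y$ are *co-expressed* when their Pearson correlation
over all samples passes

$$ r_{xy} \ge 0.8, \qquad p < 0.001 , $$

with the two-sided $p$-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. A candidate
regulator $z$ *explains* the pair when the first-order partial
correlation

$$ r_{xy|z} \;=\; \frac{r_{xy} - r_{xz}\, r_{yz}}
     {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}} $$

is small, $|r_{xy|z}| \le 0.3$: once the linear effect of $z$ is removed,
the pair's co-expression collapses, which is the signature of
co-regulation by $z$. $r_{xy|z}$ equals the correlation of the residuals
of $x$ and $y$ after regressing each on $z$; the test suite verifies this
equivalence against `lm()` residuals on thousands of random instances.

Every passing triple $(x, y, z)$ contributes the directed edges
$z \to x$ and $z \to y$ — co-regulation is symmetric in the pair — and a
pair may be explained by several regulators; all are kept, with edges
merged and support counted.

### Two-pass layering

The assignment of genes to layers is a two-pass construction:

* **Pass A** screens pairs among the structural DEGs and attributes them
  to any TF DEG. TFs that acquire at least one structural target form
  **layer 2**; targets with at least one incoming edge form **layer 3**.
* **Pass B** screens pairs among the layer-2 TFs and attributes them to
  the TFs *not* already in layer 2. TFs acquiring a layer-2 target form
  **layer 1**.

Because pass B conditions on the complement of layer 2, no TF can occupy
two layers. Middle-layer TFs without an upstream regulator are retained
(reported); TFs explaining nothing are dropped (reported). When pass A
leaves fewer than two middle-layer TFs no pair can be formed upstream and
a two-layer result is returned with an explicit flag. A single-target
upstream regulation (one TF driving exactly one TF) is undetectable by
construction, since the method only ever works on pairs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_min` | 0.8 | minimum pair correlation (signed; `use_absolute_r = TRUE` admits strong negative pairs for repression-aware screening) |
| `p_max` | 0.001 | raw correlation p-value gate; deliberately unadjusted, the classical usage |
| `partial_max` | 0.3 | attribution gate on the absolute partial correlation |
| `fdr_max`, `fc_up`, `fc_down` | 0.05, 1.5, 0.66 | DEG gates vs the 0 h control: BH-adjusted p < 0.05 and fold change strictly above 1.5 or strictly below 0.66 |

Correlations are computed across all samples (time points × replicates)
on log2 values, maximising $n$ for the p-value gate. Fold changes are
differences of replicate means on the log2 scale, exponentiated.

The default differential-expression test is a two-sided Welch $t$ on log2
values. This is a deliberate, documented simplification — count-based
negative-binomial modelling is a different tool's job — and externally
computed p-values can be injected via the `p_values` argument of
`call_degs()` when a count model is preferred.

## The synthetic benchmark

`generate_planted_grn()` plants a ground-truth hierarchy: layer sizes
and a target mean out-degree over regulators are given; connectivity is
forced (three distinct layer-1 parents per layer-2 TF when available, one
layer-2 parent per structural gene), then extra edges are sampled by
picking a regulator uniformly and giving it a new target until the
requested density is met. Edge weights are uniform on
$\pm[0.5, 1.5]$. Middle-layer TFs are multiply regulated by construction:
with a single parent a middle TF would be an exact noiseless copy of its
driver and hence statistically indistinguishable from it; the multiply
regulated middle layer also mirrors real layered stress networks, where
middle TFs typically have several upstream regulators.

`simulate_time_course()` gives each top-layer gene a smooth random
temporal profile (a sum of `driver_smoothness` random sinusoids,
standardised over the time grid); candidate drivers too collinear with an
already accepted one (|r| > 0.75) are redrawn within a bounded retry
budget, because near-duplicate drivers are biologically the same regulon
and make any planted truth unrecoverable. Each downstream gene's
noiseless profile is the weighted sum of its parents' noiseless profiles,
restandardised; observed log-expression adds i.i.d. Gaussian noise
(`noise_sd`, on the standardised scale, so it is directly a
noise-to-signal ratio) independently per replicate. Defaults emulate the
study design the package targets: seven time points (0, 1, 3, 5, 9, 12,
24 h), three replicates, giving 21 samples. An optional `pattern_drivers`
mode replaces the first three drivers with archetype stress profiles
(early-up/late-down, early-down/late-up, oscillating).

What the simulator deliberately does **not** model: sequencing counts and
their mean–variance structure, library-size or GC artifacts, time-lagged
propagation (an instantaneous linear mix is the method's own working
assumption), and gene-specific intrinsic noise. Passing benchmarks on
this generator therefore demonstrates correctness of the *inference
machinery* under its own model assumptions, not performance on real
RNA-seq data.

`score_recovery()` compares inferred and planted edge sets per layer
pair, ignoring weights and signs; empty inferred sets yield `NaN`
precision sentinels rather than errors.

## Numerical choices and degenerate inputs

* Perfectly correlated vectors return $p = 0$ exactly; partial
  correlations are clipped to $[-1, 1]$ against floating-point overshoot.
* A conditioning TF perfectly collinear with a pair member makes the
  partial-correlation formula 0/0. When the numerator cancels exactly
  ($r_{xy} = r_{xz} r_{yz}$, the noiseless single-parent limit) the
  partial correlation is 0 by continuity and the triple passes; any other
  collinear triple is skipped with a warning.
* Zero-variance genes abort correlation computations with the offending
  gene named; all-zero genes are dropped (with a reported count) before
  DE testing.
* BH adjustment is shared between the DEG and enrichment modules and is
  the standard step-up procedure, clipped to 1.
* The Wallenius non-central hypergeometric tail is computed by numerical
  integration of the standard integral representation and renormalised
  over the support to absorb quadrature error; with equal weights it
  reduces to the central hypergeometric (verified to 1e-6). Per-gene bias
  weights enter as the ratio of mean weights inside/outside the term,
  the usual sampling-odds reduction. GO annotations are used as flat
  sets; no DAG propagation is performed.
* Reported percentages round half away from zero to one decimal.
* All writers iterate in sorted order, making every output byte-stable
  for a fixed configuration and seed; generators restore the caller's
  RNG state and are pure functions of their seed.

## Validation bookkeeping

Bench validation of a predicted TF → target edge proceeds binding-first:
ChIP-PCR on the four 500-bp quarters of the 2000-bp promoter; any bound
fragment makes the interaction **direct** (multiple bound fragments count
the same as one). Unbound interactions are tested by overexpressing the
TF and measuring the target with qRT-PCR: fold change strictly > 2 with
p < 0.05 makes them **indirect**, otherwise **none**; unbound
interactions without qRT data stay **untested** and cannot enter a
summary. Relative expression from cycle thresholds uses the comparative
CT method, $2^{-\Delta\Delta C_t}$, normalised to an internal reference
gene and the control condition.

## Benchmark sizes and known limitations

The bundled benchmarks run the full pipeline on planted networks of
11/19/158 genes (the scale of the motivating study) with mean out-degree
8 at noise levels 0.05–1.0, averaged over 20 seeds — about a minute of
compute in total; unit tests use smaller topologies.

Three limitations of the method itself, established on the benchmark and
worth knowing before interpreting any inferred network:

1. **Errors in variables.** The conditioning TF is itself measured with
   noise. For two near-pure-copy targets of the same parent, the partial
   correlation given the *observed* parent converges to ~0.5 — not 0 —
   independently of the noise level, when the parent's measurement noise
   matches the targets'. Symmetric co-regulation triples therefore pass
   the 0.3 gate only through sampling fluctuation; most recovered edges
   arrive via asymmetric triples in which the conditioner is nearly
   collinear with one pair member. Averaging replicates of the
   conditioner shrinks the floor (to ~σ²/k-fractions) but cannot remove
   it.
2. **Profile crowding.** With seven time points the centered signal
   space has six dimensions. Thirty TF profiles cannot be mutually
   well-separated there, so some TF pairs always correlate above the 0.8
   gate; their targets form cross-family pairs that are attributed to
   both families' regulators. On the planted benchmark this caps
   layer-2→3 edge precision near 0.25 while recall stays around 0.85;
   the same crowding lets top-layer TFs acquire structural targets and
   be absorbed into the middle layer. More time points — not more
   replicates — are what would relieve this.
3. **Pairs only.** A regulator driving a single target is invisible, as
   is the top layer whenever middle-layer TFs are too well separated to
   form pairs — the flip side of point 2. Precision and top-layer
   recovery are in direct tension under this inference scheme.

None of these is a software defect; they are identifiability properties
of first-order partial-correlation attribution at short time courses,
and the simulator makes them measurable.
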