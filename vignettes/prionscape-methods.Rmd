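---
title: "prionscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prionscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionscape)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, and the choices we made where the design
was genuinely open. It states no empirical claim that the test suite or the
acceptance script does not itself compute.

## 1. The detection model

A prion-like domain (PrLD) has two independent signatures: a long stretch of
strongly Q/N-biased, disorder-promoting composition, and — under the "soft
amyloid core" hypothesis — a short window of moderate amyloid propensity that
can nucleate conformational conversion. The caller requires both.

**Stage 1 — compositional scan.** Every residue is scored with the
log-likelihood ratio `log(f_prion(r)/f_background(r))` between a prion-domain
composition and a background composition. The core statistic is the maximum
sum over all windows of exactly `core_length = 60` residues; a protein is a
candidate when this maximum is positive, i.e. when some 60-mer is more
plausible under the prion model than under the background. Sixty residues is
the canonical minimal prion-domain length used by compositional scanners.
The reported domain extends the best core window greedily in both directions
while the cumulative extension gain stays positive — a maximal-scoring-
subsequence heuristic that tracks how compositional scanners report domain
boundaries without implementing a full HMM parse. We deliberately implement
the windowed-LLR form and not an HMM: the windowed form is the documented
core of the compositional method, it is exactly testable against brute-force
enumeration, and numeric parity with released binaries is a non-goal.

**Stage 2 — amyloid-core scoring.** Each 21-mer of the candidate domain is
scored by a position weight matrix; the best window's raw sum is rescaled to
0–100 using the matrix's theoretical minimum and maximum 21-mer sums, and
the call passes when the score reaches the cutoff **60.00**. The 0–100 scale
and cutoff follow the published protocol. Two points were open and are
pinned here: the rescaling is per-window against theoretical matrix extremes
(so scores are comparable across domains and proteomes), and ties break to
the leftmost window everywhere.

**The shipped matrices.** Three tables back the default model, all
constructed in code:

* `background_frequencies()` — the long-run average amino-acid composition of
  the curated protein knowledgebase, shipped fixed for reproducibility;
  `estimate_background_frequencies()` re-estimates it from any input proteome
  (the published protocol used the scanned proteome itself as background).
* `prion_frequencies()` — a Q/N-dominated composition (Q+N mass 0.43)
  representing the yeast prion-domain bias that compositional scanners are
  trained on.
* `amyloid_matrix()` — a **synthetic stand-in**: per-residue β-aggregation
  propensities (high I/V/F/L/Y/W, near-zero P/D/E/K/R) modulated by a
  deterministic positional factor peaking at the window centre. The published
  amyloid matrix is not redistributable; the stand-in reproduces its
  operational behaviour — random proteome windows score ≈ 50/100 (asserted
  in the tests), planted
  cores comfortably above 60 — which is what every downstream statistic
  depends on. It is labelled synthetic in its documentation; conclusions
  about specific real proteins must not be drawn from it.

**Non-standard residues** (B, J, O, U, X, Z) score 0 in the LLR (they neither
create nor destroy candidates) and windows containing them are excluded from
amyloid scoring, avoiding spurious extremes from undefined weights.

**Coordinates** are 1-based inclusive throughout, in code and in files — the
natural R convention and the standard biological reporting convention. (An
earlier plan to use 0-based half-open coordinates internally was dropped: in
R it would manufacture off-by-one opportunities rather than remove them.)

## 2. Terminal localization

Proteins are segmented 25% / 50% / 25%. Segment sizes use banker's rounding
with the C segment sized first; the internal segment is the exact remainder,
so the three intervals always partition the sequence (property-tested over
1000 random lengths). The assignment of a PrLD that straddles segments is not
specified by the published text ("residues mapping in each segment counted");
we pin **plurality of residues, ties → internal**, which is conservative with
respect to terminal-enrichment claims, and expose `midpoint` and
`any_overlap` as alternative rules so the three tallies can be compared on
any dataset (the acceptance script prints all three when given the published
supplementary table). The C-vs-N imbalance test is a one-sample proportion
Z-test against 0.5 over terminal calls only; its normal approximation is
cross-checked against the exact binomial in the tests. The position histogram
maps each domain start and end to `floor((pos−1)/L · 20)` of 20
length-normalized bins.

## 3. Term enrichment

Enrichment uses the protein 2×2 table (set with/without term × rest of
background with/without term) and **two-sided** Fisher's exact test — the
published analysis reports both enrichment and depletion, so a one-sided test
would be inconsistent; direction is derived from the sample odds ratio.
Bonferroni correction uses the number of terms actually tested within the
namespace, matching the "three ontologies separately" design. The log-ratio
score `E = log(f_set) − log(f_bg)` uses **per-annotation** frequencies (term
occurrences over total annotation rows) — the literal reading of the
published formula's "Tot GO" denominators — with the per-protein variant
available via `freq_mode = "protein"`. Degenerate margins (a term annotating
every background protein, or none) yield an `NA` odds ratio and p = 1 rather
than an error. Pfam- and pathway-style enrichment are the same computation
under a different `namespace` label.

## 4. Expression coding and clustering

Textual ranks map none/low/medium/high → 0/1/2/3; unknown labels become
explicit missing values, never 0 ("not detected" is a synonym of "none").
Cell types are averaged into tissues *before* genes are averaged into set
profiles, following the stated order of operations. Deviation vectors
subtract the background (proteome-level) per-tissue mean from each gene's
row, so clustering operates on relative over/under-expression.

k-means uses Euclidean distance, 25 random restarts per k (best
within-cluster sum of squares kept), k = 3..10, and the mean silhouette
selects k, ties to the smaller k. Restart count and the seeded restart stream
are our choices — the published analysis names only the algorithm and
distance — and pin determinism for a fixed seed. Missing data: genes with
more than 50% missing tissues are excluded (and listed); remaining missing
entries are imputed with 0 on the deviation scale, i.e. "at the background
mean", the least-informative value. The silhouette implementation is
in-package and is verified against an independent double-loop implementation
in the tests.

## 5. Resampling significance

Both the disease and network modules share one engine: `n` random same-size
sets drawn **without replacement within each draw** (a protein set has
distinct members) from the background; Z-score with the n−1 standard
deviation; empirical p `(1 + #{null ≥ obs})/(n + 1)`, which never returns 0
from finite samples; nearest-rank percentiles; and an `above_95th` flag
matching the published figure's red-line criterion. Disease analysis defaults
to 100 samples and network analysis to 1000, mirroring the published
protocol; both are configurable upward.

Network statistics: mean member degree, intra-set edge count, LCC of the
induced subgraph, and MSD — defined, per the cited network-separation
measure, as the mean over set members of the full-graph shortest-path
distance to the *nearest other set member*. Members with no reachable
partner are excluded and counted; null draws whose statistic is undefined
are dropped from the null with a count. Null sets are sampled uniformly over
nodes (the published comparison uses plain "random sets of the same size",
not degree-matched nulls; degree-preserving rewiring is a possible future
option, not implemented). The "Wilcoxon p" mentioned alongside the empirical
p is implemented as a rank-sum test of set-member degrees against pooled
random-set member degrees.

## 6. The synthetic world

The generators produce every input format the pipeline reads, with ground
truth recorded separately from the data (`*.truth.tsv` sidecars), under these
stated conditions:

* **Proteome** (`generate_proteome`): default 500 proteins, 10% planted,
  lengths uniform on 140–600 residues. Background residues are i.i.d. from
  `background_frequencies()`. Planted proteins carry one 60-residue segment
  from `prion_frequencies()` with an embedded 21-mer core drawn from a
  high-propensity composition, rejected until it scores ≥ cutoff + 5 — the
  generator *certifies* its planted signals, as the separability requirement
  demands. The core sits at least 9 residues from the segment edges so a
  small shift of the best compositional window cannot clip it (observed
  failure mode during development: an edge-planted core lost to a 6-residue
  window shift). 80% of planted domains are terminal, 62.5% of those
  C-terminal — the C:N imbalance regime reported for the human survey. The
  140-residue length floor guarantees a terminal 60-mer holds the plurality
  of its quarter under the 25/50/25 classifier.
* **Annotations**: per-term background rates uniform on 0.02–0.2; enriched
  terms multiply the planted set's membership odds by the planted odds
  ratio; 30% of rows get the IEA evidence code so the filter is exercised.
* **Expression**: balanced planted clusters with ±`effect` latent offsets
  per tissue (default 1.5 on the 0–3 scale), Gaussian noise (sd 0.6), then
  discretization at the fixed quartile cut-points 0.75/1.5/2.25 of the
  latent scale — reproducing the ordinal atlas coding.
* **Disease labels**: independent Bernoulli per gene, default background
  rate 2.4% vs 13% in the planted set — the published OMIM regime.
* **Interactome**: Erdős–Rényi background with an elevated-probability
  planted module.

What the generators do **not** emulate: phylogenetic or domain-architecture
structure in sequences, annotation correlation structure (real GO terms are
nested and co-occur), isoform-level expression, tissue-tissue correlation,
scale-free degree distributions, and database-specific identifier formats. A
green test therefore establishes that the statistics recover *planted*
effects at the stated sizes under idealized noise — it does not certify
performance on any real proteome or database release, and dataset-level
reproduction of the published counts (70,940 → 431 → 242) is explicitly out
of reach without the versioned external databases.

## 7. Numerical and degenerate-input conventions

* All tie-breaks are leftmost (windows) or smallest (k), making every stage a
  pure function of inputs + seed; the pipeline derives per-stage seeds from
  the master seed through fixed offsets, so stages are reproducible
  independently of execution order.
* Frequencies are pseudocount-floored at 1e-6 and renormalized, keeping every
  log-ratio finite.
* No-calls are `NULL`/`NA` sentinels with reasons, not errors: sequences
  shorter than the core window, domains shorter than 21, constant resampling
  nulls (Z undefined), sets with no reachable network partner.
* Empirical p-values use the add-one estimator; percentiles the nearest-rank
  method; standard deviations the n−1 denominator.

## 8. Known limitations

* The compositional stage is a windowed LLR, not an HMM posterior parse;
  domains reported for proteins with multiple dispersed Q/N-rich regions may
  differ from HMM-based callers.
* The amyloid matrix is a behavioural stand-in (Section 1); absolute scores
  are not comparable to the released tool's scores even though the 0–100
  scale and cutoff semantics match.
* Uniform (not degree-matched) network nulls overstate significance for
  hub-rich sets on scale-free graphs; on the generator's Erdős–Rényi graphs
  this bias is absent by construction.
* The disease module treats associations as a flat gene → disease table;
  ontology structure beyond a free-text category column is out of scope.
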