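---
title: "Methods: differential cell-surface proteomics with surfacemap"
author: "surfacemap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential cell-surface proteomics with surfacemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfacemap)
```

## The analysis problem

`surfacemap` implements the computational half of a two-arm cell-surface
proteomics experiment comparing a KRas-activated epithelial cell line
("KRAS") against an empty-vector control ("EV"):

* **CSC arm** — hydrazide-based cell-surface capture enriches N-glycopeptides.
  After PNGase F release, each formerly glycosylated asparagine carries a
  +0.984 Da deamidation mark, and a genuine glycosite must sit in the
  N-glycosylation acceptor motif (sequon) **N-x-S/T**.
* **SGM arm** — shotgun profiling of the crude membrane fraction identifies
  membrane proteins regardless of glycosylation.

Both arms consume *scored peptide-spectrum matches* (PSMs) from a database
search; the package does not re-implement spectral scoring. Downstream it
provides peptide-level FDR filtering, glycosite validation, parsimonious
protein inference, spectral-counting differential statistics, subtractive
classification, annotation enrichment arithmetic, non-redundant two-platform
map merging, and targeted PRM quantitation against heavy-isotope internal
standards. A seeded synthetic-data generator emulates the whole experiment
with planted ground truth so every stage is testable without raw LC-MS data.

## Peptide FDR: target-decoy competition q-values

Percolator-style semi-supervised re-scoring is intentionally out of scope;
`estimate_qvalues()` substitutes plain target-decoy competition on the search
score. For every threshold $t$,

$$\widehat{\mathrm{FDR}}(t) = \frac{\#\{\text{decoys} \ge t\}}
  {\max(1, \#\{\text{targets} \ge t\})},$$

and a PSM's q-value is $\min_{t \le s} \widehat{\mathrm{FDR}}(t)$ over all
thresholds at or below its score $s$ — the best FDR at which it is still
accepted. Tied scores share one threshold. The estimator is verified against
brute-force enumeration of all thresholds in the test suite. With zero
decoys the FDR is uncontrolled; the function warns loudly and returns zeros.
Precomputed q-values in the input table are honored and not overwritten.

The default gate is `peptide_fdr_max = 0.01` (1% peptide FDR), applied to
target PSMs only.

## Glycosite validation

`map_deamidation_sites()` projects each deamidation (delta within
`deamidation_tolerance` = ±0.01 Da of +0.984, on an asparagine) onto the
protein via the **leftmost occurrence** of the peptide, then
`check_sequon()` tests N-x-S/T at the protein coordinate. Choices that were
genuinely open:

* The motif is applied exactly as written, with **any** residue at x;
  biologically, proline at x suppresses glycosylation almost completely, so
  a strict flag (`sequon_exclude_proline`) is available but off by default.
* The matching tolerance (±0.01 Da) is a package choice; the search engine
  delta is configured, not measured, so anything well below the 57.02 Da
  carbamidomethyl delta is safe.
* When a peptide occurs more than once in a protein, only the leftmost
  occurrence generates a site. Multi-occurrence reporting was considered and
  rejected: repeated tryptic peptides in one protein are rare and ambiguous
  evidence should not multiply.

In the CSC pipeline (`csc_glycoproteome()`), a PSM survives only if at least
one of its deamidation sites is sequon-valid; the stage order is fixed
(q-values → FDR gate → sequon gate → grouping → minimum-PSM gate).

## Protein inference

`group_proteins()` implements greedy set-cover parsimony: repeatedly pick
the accession explaining the most unexplained peptides (ties broken
lexicographically, for determinism), assign those peptides' PSMs to it;
never-selected accessions whose peptides were fully assigned to a single
lead are reported as its group members. Proteins supported by fewer than
`min_psm = 2` PSMs per condition are discarded — the single-PSM exclusion.
The rule is applied after pooling replicates within a condition: the
replicate structure (2 biological × 3 technical injections for CSC, 2
technical for SGM) exists to accumulate spectral evidence, and a
protein seen once in each of two replicates is better supported than one
seen twice in one.

## Spectral-counting differential statistics

For a protein with counts $a$ (KRAS) and $b$ (EV) and library sizes
$N_a, N_b$ (total retained PSMs), the null hypothesis of equal relative
abundance makes $a \sim \mathrm{Binomial}(a+b,\, p_0)$ with
$p_0 = N_a/(N_a+N_b)$. `binomial_test()` reports the exact two-sided
p-value under the minimum-likelihood rule (the sum of all outcome
probabilities not exceeding the observed one), `bh_fdr()` applies
Benjamini–Hochberg, and `surface_diff()` classifies:

* `UNIQUE_KRAS` / `UNIQUE_EV` — subtractive proteomics: zero counts in one
  condition and at least `min_psm_unique = 2` in the other. A single-PSM
  protein can never be condition-unique, mirroring the single-PSM exclusion.
* `UP_KRAS` / `UP_EV` — detected in both conditions with BH
  $q \le$ `alpha_fdr` (default 0.05; a deliberate choice — the prose the
  analysis mirrors reports "significantly upregulated" without printing its
  cutoff) and the matching fold direction. No additional fold-change cutoff
  is imposed.
* `SHARED` — everything else.

The log2 fold estimate is library-normalized and pseudocount-stabilized,
$\log_2\frac{(a+c)/N_a}{(b+c)/N_b}$ with $c = 0.5$; the pseudocount never
enters the test.

### Known limitation: composition bias

Total-count normalization assumes the differential proteins are a small mass
fraction of the library. When a large fraction of counts shifts to one
condition, the libraries themselves become unequal, every null protein's
relative share drops in the inflated library, and the test acquires a
directional bias (false `UP_EV` calls in the scenario above). The
calibration experiments in the test suite therefore fix equal normalization
depths when planting dense effects; with defaults (≈16 affected proteins of
100) the bias is negligible for the map classes, which only consume the
KRas-positive directions. Replicate-level dispersion modelling (negative
binomial GLMs) is explicitly out of scope; the generator's `negbin` count
model exists to demonstrate the binomial test's anti-conservatism under
overdispersion, not to fix it.

## Annotation arithmetic and the non-redundant map

`percent_overlap()` rounds **half-up** at the printed precision (integers
for overlap percentages, one decimal elsewhere) because that convention
reproduces every internally consistent published-style value;
`enrichment_report()` always stores the integer numerator and denominator so
any percentage regenerates exactly. `fold_enrichment()` divides an observed
annotated fraction by a whole-proteome baseline (e.g. CD molecules are ~2%
of the human proteome) and `fold_label()` rounds to the integer fold used in
prose.

`merge_nonredundant()` builds one entry per accession from both platforms,
keeping only KRas-positive classes. Cross-platform conflicts are resolved
conservatively: *unique* requires a zero EV count on **every** platform that
measured the protein; a unique call contradicted by EV detection elsewhere
is demoted to upregulated when the binomial evidence is significant on
either platform and dropped otherwise. Isoform accessions are collapsed to
their canonical root (suffix `-\d+` stripped) before merging, since the two
platforms may report different isoforms of one gene product.

## PRM quantitation

`digest_tryptic()` (cleave after K/R, not before P, up to 2 missed
cleavages), `mono_mass()` and `fragment_mz()` use the standard monoisotopic
residue masses, water 18.010565 Da and proton 1.007276 Da. The heavy
internal standard carries a C-terminal label:
$^{13}\mathrm{C}_6\,^{15}\mathrm{N}_4$-arginine at exactly **+10.00827 Da**
(the nominal "+10") or $^{13}\mathrm{C}_6\,^{15}\mathrm{N}_2$-lysine at
+8.01420 Da.

`prm_ratio()` predicts candidate transitions, extracts each XIC at 3 ppm
(`extract_xic()`, trapezoidal integration over scan time), ranks transitions
by **heavy** area — the internal standard's abundance is controlled, making
it the stable ranking channel — keeps the five most intense, and reports
$\sum \text{light areas} / \sum \text{heavy areas}$ over the kept
transitions. Candidates are restricted to singly-charged y-ions by default:
for a C-terminally labeled tryptic peptide every y-ion carries the label, so
light/heavy partners are mass-resolved, whereas b-ions below full length
have identical light and heavy m/z and their XICs cannot be attributed to
either channel. Precursor isolation windows are carried as scan metadata
only; no isolation simulation is performed. A zero heavy area is an error
(missing internal standard), not a zero ratio.

## The synthetic-data generator

`simulation_config()` fixes the emulated study conditions. Defaults:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 300 | desk-scale stand-in for a proteome search space |
| `frac_surface` | 0.5 | half the synthetic proteome is surface-resident |
| `frac_glyco` | 0.6 | CSC-visible fraction of surface proteins |
| `frac_cd` | 0.02 | the whole-proteome CD-molecule baseline |
| `n_true_up`, `n_true_unique` | 20, 20 | planted effect set |
| `planted_log2_fold` | 2 | 4-fold upregulation |
| `mean_count` | 30 | per-protein expected PSMs, adequate depth |
| `count_model` | poisson | `negbin` available to stress overdispersion |
| `decoy_score_shift` | 3 | decoy scores one good separation below targets |
| `prm_ratios` | 1.8 / 0.9 | a 2-fold KRas/EV surface upregulation |

Sequences are uniform-random over the 20 residues (90–160 aa — short, to
keep digestion and mapping fast); glyco proteins get 1–3 planted valid
sequons plus one planted non-sequon asparagine as a negative control for the
sequon gate, in disjoint windows so sites never collide. Decoys are
reversed sequences with the `DECOY_` prefix. PSM counts are Poisson with the
KRas mean scaled by the planted fold; CSC PSMs carry a deamidation at a
planted site (5% at the non-sequon control); decoy scores are drawn from the
target score distribution shifted down. PRM runs place exact light/heavy
y-ion peaks under a Gaussian elution profile with ≤1 ppm jitter plus uniform
noise peaks.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: realistic residue composition and homology
(shared peptides are rare here, so protein inference is rarely stressed),
score distributions from a real search engine, isotope envelopes and
co-isolation, retention-time drift, overdispersion between biological
replicates (under the default Poisson model), and annotation noise.

## Problem sizes and numerical choices in the verification suite

The suite verifies q-values against brute-force enumeration on 1,000 random
instances of up to ~400 PSMs; calibration on 200 null tables of 500
proteins; FDR control with 10% planted 4-fold effects over 100 tables;
end-to-end recovery over 50 seeded pipelines of 100 proteins each (≥95%
of planted proteins recovered, realized FDP ≤ 10%); and PRM round-trips
exact in the noiseless limit and within 5% with jitter and noise. These
sizes are the package's chosen verification scale: large enough for stable
rates, small enough to run comfortably on one core.

Degenerate inputs are defined, not special-cased ad hoc: zero counts give
p = 1; empty PSM sets give empty group lists; empty spectra give
zero-area traces; an empty annotation list is an error (always a mistake);
zero decoys warn; a missing heavy standard is an error.
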