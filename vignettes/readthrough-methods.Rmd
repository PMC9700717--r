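---
title: "Quantifying stop-codon readthrough from ribosome profiling: models and methods"
author: "ribortc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stop-codon readthrough from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribortc)
```

# Overview

`ribortc` quantifies translational readthrough at stop codons from aligned
ribosome-profiling footprints. A premature termination codon (PTC) such as
*TP53* R213X truncates translation; readthrough-inducing drugs let ribosomes
decode the PTC, and Ribo-seq sees this as in-frame footprint density between
the PTC and the canonical stop codon. The package implements the full
footprint-to-statistic chain — coordinate models, P-site calibration,
in-frame profiles, the PTC readthrough ratio and its translatome-wide
metagene analogue — plus two companion analyses from the same experimental
programme: a GI50 differential-sensitivity screen and logistic confluence
growth-curve fitting. Everything is exercised on seeded synthetic data with
known ground truth.

# Coordinate conventions

All internal coordinates are 0-based and half-open; GTF's 1-based closed
intervals are converted on read. Transcript coordinates increase 5' to 3' in
transcription direction on both strands. Codons are indexed 1-based with
codon 1 = start codon, so mutation nomenclature maps directly (R213X is codon
213). `canonical_stop_tx` is the transcript coordinate of the first
nucleotide of the canonical stop codon, which is counted as the last CDS
codon.

Annotations with `stop_codon` features (Ensembl-style, CDS excluding the
stop) and annotations whose CDS features include the stop codon are both
accepted: the CDS extent is the union of `CDS` and `stop_codon` features and
must be a positive multiple of 3; transcripts violating this are skipped and
tallied, never silently dropped.

For metagene analyses one representative transcript per gene (longest CDS)
is used — the standard convention to avoid double counting isoforms.

# The footprint model and the simulator

The synthetic generator (`sim_config()` / `simulate_footprints()`) emulates
the statistical structure of a high-quality Ribo-seq library rather than its
sequence content:

* **Footprint lengths** concentrated at 28–29 nt (`length_dist`, default
  0.5/0.5), matching the dominant monosome footprint sizes.
* **Codon-wise Poisson ribosome placement**: `lambda_pre` in-frame
  footprints per codon over the translated region (default 20), thinned to
  `rho_ptc * lambda_pre` after a PTC and `rho_canonical * lambda_pre` past a
  canonical stop. The rho parameters are the ground-truth readthrough
  fractions the estimators must recover.
* **3-nt periodicity**: a footprint lands exactly in frame with probability
  `pi_frame` (default 0.9, a high-periodicity library); the off-frame mass
  is shifted ±1 nt with equal probability — the simplest symmetric model of
  sub-codon blur.
* **Terminating-ribosome pileup**: the stop codon's intensity is multiplied
  by `stop_peak` (default 5), the footprint peak of ribosomes awaiting
  release.
* **Initiation pileup**: the start codon's intensity is multiplied by
  `start_peak` (default 5, symmetric with the stop peak). Real libraries
  show this initiation peak, and it is what makes P-site offset calibration
  identifiable: with a perfectly flat codon profile, candidate offsets
  differing by 3 nt are indistinguishable, because shifting by a whole codon
  preserves both the frame and the interior density.
* **Background** (`beta_bg`, default 0): uniform footprints per nt over the
  whole transcript, with random lengths and positions.
* The 5' end of each footprint is its P-site position minus the length's
  `true_offsets` entry (default 12 nt), so calibration has a known answer.

The generator is deterministic given `seed` (one seeded generator per call,
no global RNG leakage), and returns a ground-truth table plus per-read
category labels so tests can recount every placement exactly.

What the simulator deliberately does **not** model: nucleotide sequences and
sequence-dependent biases (ligation, PCR), UMIs, rRNA contamination, isoform
mixtures, and codon-specific dwell times. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every artefact of real libraries — the QC
operations (length histogram, periodicity, region fractions) are the tools
for judging real data quality.

# P-site calibration and QC

`calibrate_offsets()` scores each candidate offset in 10–14 nt (canonical
eukaryotic footprint geometry; default 12) by the number of P-sites landing
exactly on annotated start codons, tie-broken by the in-frame fraction of
CDS-internal P-sites. Lengths with fewer than `min_reads_per_length` (100)
reads fall back to the default offset; lengths whose best frame-0 fraction
is below 0.4 are marked failed and excluded downstream — the threshold must
clear the 1/3 aperiodic null with margin and is configurable. Footprint
lengths outside 25–35 nt are ignored, mirroring gel size selection.

`assign_psites()` computes P-site = 5' end + offset, tallies per-position
counts, per-codon in-frame counts (in the CDS frame extended into the
3'UTR), CDS frame counts (f0, f1, f2), and region classification by P-site
position (5'UTR / CDS / 3'UTR). Counts are conserved at every stage:
assigned + discarded (by reason) = input reads.

# The readthrough statistics

**PTC ratio** (`ptc_readthrough_ratio()`): with PTC at codon `p` and
canonical stop at codon `N`,

$$\mathrm{ratio} = \frac{n_{post}/L_{post}}{n_{pre}/L_{pre}},\qquad
n_{pre}=\sum_{i=1}^{p-1} c_i,\quad n_{post}=\sum_{i=p+1}^{N-1} c_i,$$

with $c_i$ the in-frame P-site count of codon $i$. The PTC codon and the
canonical stop are excluded from both regions by default: terminating
ribosomes pile up there and would bias the densities. Whether published
ratios include the boundary codons is genuinely ambiguous, so the choice is
exposed (`include_boundary = TRUE` folds the PTC into the upstream and the
canonical stop into the downstream region). A zero-count pre region is an
error (the ratio is undefined), not a silent zero.

**Metagene stop readthrough** (`metagene_stop_readthrough()`): genes with at
least `min_cds_reads` (default 32) in-frame CDS reads — "translated" genes
operationalised as a coverage threshold — are aligned at their stop codon;
in-frame counts are pooled into codon bins over ±50 codons (defaults; the
window and bin width are configurable, and the ratio is invariant to any
bin width dividing both window extents). Bin values are percentages of the
window total. The ratio is the pooled post-stop density over the pooled
pre-stop density, each normalised by the number of contributing
(gene, codon) slots, so genes with short 3'UTRs contribute only their
defined bins (a masked mean). The stop-codon bin is excluded from both
sides, and only in-frame (annotated-frame) 3'UTR P-sites are counted.

**Condition summaries** (`readthrough_report()`): per-condition median,
quartiles and a seeded percentile-bootstrap 95% CI of the median;
single-replicate conditions are flagged degenerate.

# The GI50 screen

`compute_ratios()` takes group means per tissue over available values —
arithmetic on the linear molar scale by default, with `log_mean = TRUE` for
geometric means, since "mean GI50" is ambiguous and NCI-60 data are often
stored as −log10 M. `select_compounds()` applies the two-ratio rule with
strict inequalities (ratio_mut > 4 and ratio_wt > 1.5) in every required
tissue; a compound unevaluable in a required tissue (no nonsense-line value)
is never selected. Selection is monotone in both thresholds and invariant to
compound/line order and to tissue-wise rescaling.

The simulator plants compounds with exact target ratios. Baseline potencies
are drawn log-normally around 1 µM and snapped to a power-of-two grid so
the noiseless construction is exact in floating point — boundary compounds
sit bit-exactly on their planted ratios, which is what makes the strict
rejection at ratios exactly (4, 1.5) a well-defined test.

# Logistic confluence analysis

The growth model is a 4-parameter logistic curve
$C(t) = A + (K-A)/(1+e^{-r(t-t_0)})$ — a growth model in percent
confluency, not binary-outcome logistic regression; the latter reading is
incompatible with reporting rates in %confluency/h. Fitting is bounded
least squares (`minpack.lm::nlsLM`; A ≥ 0, K ≤ 105 to allow slight
over-confluence, r > 0), initialised from the data (A = min, K = max, t0 at
the half-range crossing, r from the steepest finite-difference slope).
Constant series are flagged "no growth"; non-convergence is reported, never
silently returned.

The critical point `cp` is the control's inflection time `t0`, where its
growth rate $r(K-A)/4$ is maximal. Every condition's reported rate is its
own fitted $dC/dt$ evaluated at `cp`. Replicates are fitted independently;
condition summaries are mean ± SEM across replicates. Default sampling
follows live-cell imaging practice: every 3 h for 72 h (25 points; at least
6 are required to fit 4 parameters meaningfully).

# Numerical choices and problem sizes

* Offset candidates 10–14 nt; periodicity-failure threshold 0.4;
  footprint-length window 25–35 nt — all configurable.
* Ties in offset scoring are broken by the higher frame-0 fraction.
* `nlsLM` runs with ftol = ptol = 1e-12 so noiseless curves are recovered
  to ≤ 1e-6 relative error.
* Recovery tests run at the sizes a desk analysis of this design needs:
  20 replicate libraries per readthrough fraction at 20 footprints/codon on
  a 394-codon transcript; 200 genes for the metagene (≈ 6 × 10^5
  footprints); 5 × 10^3 reads per (length, offset) calibration cell over a
  5 × 6 grid; 1000-compound screens; 20-seed noisy growth fits. These sizes
  make the Monte-Carlo bounds used in the tests (Poisson/binomial 3σ bands)
  tight enough to be meaningful.

# Known limitations

* Genome-to-transcript projection requires reads fully contained in the
  exons of a transcript with consistent splicing; chimeric or soft-clipped
  alignments are discarded (and tallied), not rescued.
* The metagene treats the annotated frame as the readthrough frame;
  frameshifted readthrough products are invisible to it.
* The screen reproduces the selection rule, not any particular public
  screen's hit list, which depends on the database extract used.
* Published readthrough percentages from real libraries depend on the
  boundary-codon convention (see `include_boundary`) and on the annotation
  release; the package exposes both rather than fixing them silently.
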