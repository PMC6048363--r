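---
title: "Methods: screen normalization, splicing maps and enrichment in sasptools"
author: "sasptools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen normalization, splicing maps and enrichment in sasptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasptools)
```

# Scope

`sasptools` implements the statistical workflow used to find and
characterize regulators of the senescence-associated secretory
phenotype (SASP): plate-level normalization and hit calling for an
siRNA screen read out by IL-8/IL-6 immunofluorescence, K-means triage
of hits by their effect on senescence markers (p16, p21, BrdU),
percent-spliced-in (PSI) analysis of cassette exons after knockdown of
a splicing factor, RNA maps of RNA-binding-protein motif density around
regulated exons, preranked gene-set enrichment, and a cross-tissue
procedure that dichotomizes samples by regulator expression or by exon
inclusion and ranks genes for enrichment analysis.

Raw screen plates and the original sequencing data are not shipped or
downloaded. Instead the package carries synthetic-data generators with
known ground truth (`simulateScreen()`, `simulateSplicing()`,
`simulateTissueMatrix()`) that reproduce the statistical structure each
stage assumes, so every claim the test suite makes is checked against a
planted truth or an independent oracle.

# Plate normalization

## B-scores

A 96-well plate is modeled additively:
$$y_{ij} = \mu + R_i + C_j + \epsilon_{ij},$$
with row and column effects capturing positional artifacts (edge
evaporation, dispenser gradients). `medianPolish()` estimates
$\mu, R_i, C_j$ by alternating row and column median sweeps (rows
first), iterating until the total absolute residual changes by at most
`tol` ($10^{-6}$ by default, at most 100 iterations). Masked wells
(`NA`) are ignored by the medians; each row and column must retain at
least two observed wells.

The B-score of a well is its polish residual divided by
$1.4826 \times \mathrm{MAD}$ of the plate's sample-well residuals (the
constant makes the MAD consistent for a normal scale). The polish is
fitted on sample wells only: control wells sit at fixed positions and
would otherwise bias the positional estimates; they are scored through
the fitted effects, with a zero effect for a row or column that
contains no fitted wells (effects are median-centered, so zero is the
neutral value).

**Calibration caveat.** B-scores are often treated as z-scores, with
$\pm 2$ cutoffs read as the 2.3% normal tail. At 96-well scale this is
an idealization: a converged median polish leaves the median residual
of every row and column at zero, so a noticeable fraction of residuals
sits at or near zero, which biases the MAD low (about $0.74\sigma$
when the residual spread is about $0.94\sigma$). Under pure noise the
fraction of sample wells with $b \le -2$ is therefore about 6%, not
2.3%, and it decreases only slowly with plate size. The package
reports what the statistic actually does; the test suite pins this
behavior, and the hit-calling analyses below account for it.

## Normalized percent inhibition

`npi()` rescales each well between the plate's own control means:
$\mathrm{NPI}(x) = (x - \bar x_{\mathrm{pos}}) /
(\bar x_{\mathrm{neg}} - \bar x_{\mathrm{pos}})$, so 1 means
scramble-like and 0 means positive-control-like. With inhibitory
positive controls (e.g. RELA/CEBPB knockdown suppressing IL-8/IL-6),
the rule "NPI < 0.8" reads "at least 20% of the control inhibition" —
the only orientation under which that cutoff selects inhibitors.

# Hit calling and phenotype triage

`callPrimaryHits()` calls an siRNA a down-hit when $b \le -2$ in at
least 2 of 3 replicates for *both* cytokine readouts (up-hits
symmetrically at $+2$). The published wording of the rule ("a B score
of >−2 or <3") is internally inconsistent with the $\pm 2$ SD cutoff
lines drawn on the same figure; we default to the symmetric reading
and expose the literal one via `as_printed = TRUE` (down $< -2$, up
$> 3$). Both cutoffs are configurable.

`secondaryValidation()` compares each siRNA's three replicate NPI
values against all scramble values with an unpaired pooled-variance
(Student) t test, two-sided; Welch is available. A siRNA qualifies on
a readout iff its mean NPI is below 0.8 and $p \le 0.05$ (raw p, as
published; BH adjustment is optional), and a gene passes when at least
two sibling siRNAs qualify on both readouts. Note that with a single
scramble set the *conditional* type-I rate given that draw varies
substantially (the scramble mean and variance enter every test); the
5% level holds marginally over scramble draws, which is how the test
suite checks it.

`kmeansCluster()` runs Lloyd's algorithm (via `stats::kmeans`) with
k-means++ seeding and `n_init` restarts, keeping the lowest
within-cluster sum of squares; `k = 4` by default, matching the four
phenotype categories. Features are the per-replicate B-scores of p16,
p21 and BrdU (the quantities the triage is about); the cytokines can
be appended. `labelClusters()` assigns roles from centroid deviations:
arrest-reverted (BrdU up by ≥ 2 B-score units and p16 or p21 down by
≥ 2), arrest-exacerbated (p21 up by ≥ 2), SASP-only (all three inside
the margin), ties resolved reverted > exacerbated > SASP-only.

# Splicing analysis

A cassette exon has two inclusion junctions and one skipping junction.
`psiFromJunctions()` averages the inclusion junctions to correct their
two-vs-one length asymmetry: $I = (inc_1 + inc_2)/2$,
$\Psi = I/(I + s)$. For size-resolved RT-PCR products,
`psiFromConcentrations()` uses the concentration of the larger
(included) product over the sum of both.

`deltaPsiTest()` pools replicate counts per condition and tests the
2×2 table $[\,I\ \mathrm{(rounded\ half\mbox{-}up)},\ s\,] \times
[\,A, B\,]$ with Fisher's exact test (two-sided). This defined test
stands in for the likelihood-ratio machinery of external
junction-count tools, which is out of scope; the downstream cutoff
logic is the point and is retained exactly: `classifyRegulation()`
calls an event repressed when $\Delta\Psi \ge 0.2$ with BH FDR < 0.05
(inclusion rising upon knockdown of a repressor), enhanced at
$\Delta\Psi \le -0.2$. `shortlistEvents()` implements the two-tier
rule: events responding to regulator loss that also change in
senescence pass at the base cutoff (tier 1); events unchanged in
senescence must pass a stricter cutoff, default 0.3 — the source
analysis states that a stricter cutoff exists without printing it, so
the value is exposed in configuration.

`inclusionProportionTest()` is the one-sided Pearson chi-square test
of an observed inclusion-direction count against 0.5: the one-sided p
is half the $\chi^2_1$ tail when the proportion exceeds 0.5 and one
minus that half otherwise.

# RNA maps

`pwmScan()` scores every offset of a transcript-sense sequence with
the log-odds (bits) of a position probability matrix against its
background and assigns each score an exact p-value: the probability,
under the background model, that a random width-$w$ word scores at
least as high. For $w \le 8$ the full score distribution is enumerated
over achievable score sums ($4^w$ states); for wider motifs a
discretized dynamic program (1000 bins per position) is refined
adaptively until the tail probability is stable to $10^{-6}$ relative.
Scanning is single-stranded — RNA-binding motifs have no reverse
complement — and windows containing `N` are skipped. Matrices are
RNAcompete-style probability matrices over a canonicalized DNA
alphabet (U → T); a synthetic CU-rich example matrix ships as a
fixture and is a stand-in, not a published motif model.

`anchorOccurrences()` converts genomic occurrences to offsets relative
to the 3′ splice site (splice acceptor; negative = intronic) or the 5′
splice site, reflecting coordinates on the minus strand so offsets are
always in transcript orientation. Region extents default to 300 nt of
upstream intron and 50 nt into the exon (the published maps show, but
do not state, their extents; both are configurable).

`buildRnaMap()` compares exon groups (repressed / enhanced vs
unchanged after regulator knockdown). The per-position density is the
fraction of a group's exons with at least one occurrence overlapping
the position. For every 31-nt window (step 1, a window's offset is its
center) the sampling unit is the exon: the 2×2 table counts exons with
vs without an occurrence in the window, regulated vs unchanged group,
tested one-sided for enrichment (Fisher's exact test, evaluated as the
hypergeometric tail). Raw p-values are reported as in the published
maps; `windowSignificance(map, adjust = TRUE)` appends BH-adjusted
columns.

# Enrichment

`bhFdr()` is the step-up Benjamini–Hochberg adjustment (delegated to
`stats::p.adjust`) with domain validation.

`gseaPreranked()` implements the classic weighted Kolmogorov–Smirnov
running sum: walking the list from the top, set members add
$|s|^{p}/N_R$ (weight exponent $p = 1$ by default; $p = 0$ gives the
rank-only form) and non-members subtract $1/(N - N_h)$; the enrichment
score is the signed maximum deviation. The null comes from gene-label
permutations — random sets of equal size — with
$\mathrm{NES} = \mathrm{ES}/\overline{|\mathrm{ES}_{\mathrm{null}}|}$
over same-sign nulls, nominal p the same-sign exceedance fraction
(with the +1 permutation correction), and FDR q the standard
sign-stratified comparison of observed and pooled null NES across all
tested sets. Ties in the ranking are broken by gene id so results are
reproducible. The cited enrichment tool's exact FDR refinements across
its versions are not resolvable from the source analysis; the standard
published formulation is implemented, and the installed `fgsea`
package serves as an independent cross-check of the ES in the tests.

# Cross-tissue procedure

`cpmFilter()` keeps genes whose summed counts-per-million across all
samples strictly exceeds 10. `quantileNormalize()` delegates to
`limma::normalizeBetweenArrays(method = "quantile")` — the tool the
original cross-tissue analysis used — so ties receive the mean of the
reference values they span; a single-row matrix is returned unchanged
(documented convention). `dichotomizeByMean()` splits samples at the
arithmetic mean, boundary samples labeled high.
`densityMinimumCutoff()` estimates a Gaussian-kernel density
(Silverman's rule-of-thumb bandwidth, 512 grid points over [0, 1]) and
returns the minimum strictly between the two highest local maxima;
local maxima below 5% of the global density maximum are treated as
numerical ripple rather than modes, and a unimodal estimate raises a
bimodality error so the caller can fall back to a fixed cutoff.
`rankGenesByT()` ranks genes by the ordinary pooled-variance
t-statistic (high − low); the empirical-Bayes moderation of the
original fitting tool is deliberately not applied — on the synthetic
tissue data the downstream enrichment calls are insensitive to the
substitution, and re-implementing an external moderation fit is out of
scope. Zero-variance genes get $t = 0$ with a flag.

# Synthetic data: what it does and does not emulate

* `simulateScreen()` draws wells from the additive model the B-score
  removes — baseline + row artifact + column artifact + gene effect
  (sample wells only, in units of the within-plate noise SD) +
  Gaussian noise. Defaults: 8×12 plates with column 1 holding 4
  scramble and 4 positive-control wells, 3 replicates, noise SD 1,
  artifact SDs 0.5, positive-control effect −8 on the cytokine
  readouts. Gene-to-well assignment is randomized across the run, as
  arrayed libraries are; placing correlated effects in a full plate
  column would alias them with the positional artifacts and the polish
  would absorb them (the package's tests exercise exactly this
  distinction). Not emulated: cell-count covariates, transfection
  gradients beyond additive row/column terms, optical crosstalk.
* `simulateSplicing()` draws the three junction counts of each event
  binomially at the stated coverage from a true PSI per condition
  (repressed events gain `delta_psi` = 0.3 inclusion upon knockdown,
  enhanced lose it, baselines uniform with a 0.05 margin), and embeds
  one motif instance (sampled from the matrix, or a literal word) in
  the upstream intron of each repressed event inside the placement
  window, default [−60, −20) from the acceptor; other flanks are
  i.i.d. uniform background. Not emulated: read-level coverage
  heterogeneity, overdispersion between replicates, composition bias
  of real introns (real polypyrimidine tracts make the background
  CU-rich near acceptors for *all* exons — passing tests on uniform
  background do not show the map separates groups on real sequence).
* `simulateTissueMatrix()` assigns samples to two latent states;
  regulator expression is a two-component log-normal mixture (log2
  means 9 vs 5, SD 0.5), the exon PSI the anti-correlated mixture (0.2
  vs 0.8, SD 0.07), and 50 planted genes are up-shifted by 1 log2 unit
  in the high-skipping state; counts are multinomial draws at library
  size $10^6$. Not emulated: tissue substructure, covariates such as
  age or batch, mean–variance trends of real RNA-seq.

All generators fan a single seed into per-module substreams, so stages
are reproducible independently and jointly.

# Problem sizes and numerical choices

The test suite checks the pipeline at desk scale, chosen so the full
suite runs in about a minute: 100 random plates for the polish oracle,
50 pure-noise plates for tail calibration, 1,000 genes with 30 planted
inhibitors (at −4 SD) for hit recovery plus a $10^5$-siRNA null on
calibrated B-score draws, $10^4$ null siRNAs (500 scramble draws × 20)
for t calibration, 2,000 events at coverage 100 for the splicing
bounds, 400 events (≈100 repressed vs ≈300 unchanged) for RNA-map
localization, and 20 seeds of a 2,000-gene × 300-sample tissue matrix
with 50 decoy sets at 1,000 permutations for the enrichment property.
On those conditions the planted-inhibitor sensitivity is typically
0.97–1.0; occasional seeds fall to ≈0.93 because the polish partially
absorbs a planted well's own effect into its row/column medians — a
real property of B-scores worth knowing when reading screen hit lists.

Other conventions: rounding of pooled inclusion counts is half-up
(away from the banker's rounding of `round()`); Fisher windows are
evaluated as hypergeometric tails (identical to `fisher.test`'s
one-sided p, checked in the tests); k-means is deterministic under a
fixed seed; event coordinates are 0-based half-open with BED
conventions on disk; sequences are canonicalized to DNA letters so a
single alphabet serves motifs given over RNA.

# Known limitations

* The B-score normal-tail idealization discussed above: $\pm 2$
  cutoffs select ~6% of pure-noise wells at 96-well scale, not 2.3%.
  Consensus across replicates and two readouts is what keeps the
  false-positive rate of the hit caller low.
* The Fisher delta-PSI test treats pooled reads as independent
  Bernoulli trials; biological replicate overdispersion would make it
  anti-conservative on real data.
* Preranked GSEA with gene-label permutations ignores inter-gene
  correlation; FDR q-values on correlated expression data are
  optimistic, which is why the reporting thresholds (NES > 2,
  q < 0.05) are treated as shortlisting rules, not error guarantees.
* The RNA map tests presence/absence per exon; it does not model
  occurrence counts, motif clustering, or accessibility.
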