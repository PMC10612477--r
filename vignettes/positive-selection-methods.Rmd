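---
title: "Detecting positive selection across orthologous gene clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection across orthologous gene clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Positive (diversifying) selection leaves a measurable footprint in
protein-coding genes: nonsynonymous substitutions accumulate faster than
synonymous ones, so the rate ratio omega = dN/dS exceeds 1. Scanning whole
transcriptomes for this signal requires a chain of standard but fiddly
steps — orthology assignment, protein-guided codon alignment, gene trees,
codon-model likelihood fits, likelihood-ratio tests, multiple-testing
control — each traditionally handled by a separate external program.
`orthoselect` implements that chain end to end in one package, with no
external binaries, from per-species CDS + peptide FASTA files to a CSV of
tests and positively selected sites.

# Pipeline stages

## 1. Input validation

Each species contributes a CDS FASTA and a peptide FASTA with identical
header sets (a hard requirement; the run aborts otherwise). Per record we
strip terminal stop codons (and a trailing `*` on peptides), then require
an in-frame CDS, no internal stop codon, and exact agreement between the
translation and the supplied peptide, with `X` acting as a wildcard and
N-containing codons translating to `X`. Records that fail are excluded
individually and logged with a machine-readable reason — at genome scale a
handful of broken gene models should not kill a run, and the validation
report makes the exclusions auditable.

## 2. Orthology

All-vs-all cross-species protein similarity is computed by Smith-Waterman
local alignment (BLOSUM62, gap open 11 / extend 1); hits need score >= 50
and identity >= 25%. For each gene and each other species we keep the
*adaptive* best-hit set: every hit within 95% of the best score against
that species. Two genes are joined when each lies in the other's best-hit
set, and connected components of this reciprocal graph are candidate
clusters. The adaptive window (rather than a strict single best hit)
matters for the paralog rule below: a recent within-species duplicate
scores marginally below its source gene and would otherwise silently drop
out of the cluster instead of triggering rejection.

A component becomes an orthologous gene cluster (OGC) only if it spans at
least three species and contains exactly one gene per species. Components
with within-species paralogs are discarded entirely — we read the
one-to-one requirement as a cluster-level rejection rule, not a trimming
instruction, because trimming would silently pick one paralog and bias the
downstream dN/dS estimate. We do not further partition components
(spectral splitting would only matter for clusters the paralog rule
already rejects).

## 3. Alignment and gene tree

Peptides of each OGC are aligned progressively: pairwise alignment
distances feed a neighbor-joining guide tree and profiles are merged
postorder by global profile-profile alignment (BLOSUM62, affine gaps, open
10 / extend 0.5). The protein alignment is then back-translated codon by
codon, so gaps occur only as whole codons and degapping any row
reproduces the validated CDS byte-exactly — an invariant the test suite
enforces on simulated data.

Before likelihood work, codon columns containing a gap or ambiguity in any
taxon are removed (complete deletion, the `cleandata` analogue; the policy
is configurable). A map from surviving columns back to original 1-based
codon positions is kept so reported sites always use original
coordinates. Alignments left with fewer than 10 codons are flagged "too
short" and skipped — likelihood fits on shorter fragments are dominated by
noise.

The gene tree is neighbor joining on protein p-distances with the Kimura
correction d = -ln(1 - p - 0.2 p^2), saturated pairs capped at 5. NJ
branch lengths are only optimizer starting values: every model fit
re-estimates all branch lengths, so modest distance error is immaterial.
Trees are unrooted for all likelihood work (the models are
time-reversible, making the root unidentifiable).

## 4. Codon models

The substitution core is the Goldman-Yang codon model: instantaneous rate
from codon i to j is zero unless they differ at one nucleotide, and
otherwise proportional to pi_j times 1, kappa, omega, or omega * kappa for
synonymous transversions, synonymous transitions, nonsynonymous
transversions and nonsynonymous transitions respectively. Equilibrium
frequencies default to F3x4 (positional nucleotide frequencies estimated
from the alignment); F1x4, F61 and equal are available. Frequency
parameters are not counted as free parameters, so likelihood-ratio degrees
of freedom follow the conventional schedule.

Site models let omega vary over sites through a mixture: M0 (one ratio),
M1a (nearly neutral), M2a (adds a class with omega >= 1), M3 (three free
classes), M7 (beta-distributed omega, discretized into 10
equal-probability categories represented by their means), M8 (beta plus a
free omega_s >= 1) and M8a (M8 with omega_s pinned at 1). The branch model
BR2 gives one terminal foreground branch its own omega; branch-site model
A crosses two site classes with the foreground/background split and its
null fixes the foreground omega2 at 1.

**Branch-length units.** Each class's generator is normalized so that one
unit of branch length equals one expected substitution per codon *averaged
over site classes*: on every branch all class matrices share the scale
factor sum_k p_k * r(omega_k), with r the unscaled stationary rate. This
shared scaling is what preserves the rate contrast between omega classes —
normalizing each class separately would equalize class rates and severely
weaken mixture identifiability. The exported `rate_matrix()` (a single
generator) is normalized to unit rate, the natural convention for a
one-class model. The simulator uses the identical convention, so simulated
branch lengths and estimates are directly comparable.

Likelihoods are computed by Felsenstein pruning over the 61 sense codons
in compiled code, with per-pattern rescaling against underflow and site
patterns compressed before pruning. A 20-instance test bank checks the
pruning likelihood against exhaustive marginalization over internal-node
states to 1e-8, and collapse identities (M3 with equal omegas = M0;
M8 with vanishing extra-class weight = M7; BR2 with equal ratios = M0)
are verified to 1e-6.

## 5. Fitting

All free parameters — branch lengths included — are optimized jointly by
L-BFGS-B on transformed coordinates: rates and omegas on log scale,
proportions through stick-breaking coordinates in (0,1). Box constraints:
kappa in [0.01, 100], free omega in [1e-4, 50], positive-class omega in
[1, 50], beta shapes in [0.005, 99], branch lengths in [1e-6, 50].
Multi-start (default 3 starts; the pipeline default is 2) jitters the
starting vector with seeded Gaussian noise; every randomized choice in the
package flows from an explicit seed.

Nested models are fitted as chains with warm starts: M2a starts from the
M1a solution with the extra class entering at omega2 = 1, M8 from M8a with
omega_s = 1, branch-site model A from its null. Because the alternative
starts exactly at a parameter point whose likelihood equals the null
optimum, lnL(alt) >= lnL(null) holds by optimizer monotonicity and the
test statistic is never spuriously negative. Residual negative differences
from other causes are clamped to zero (with a warning beyond 0.01).

## 6. Tests, FDR, and site identification

The comparison schedule is M0-vs-M3 (4 df), M1a-vs-M2a (2 df), M7-vs-M8
(2 df), M8a-vs-M8 (1 df), plus per-foreground BR2-vs-M0 (1 df) and
model A vs its null (1 df). Twice the log-likelihood difference is
compared to the chi-square upper tail; the degrees of freedom are also
recomputed from the fitted parameter counts and asserted against the
schedule, so a model-wiring bug fails loudly. For the boundary tests
(M8a-vs-M8, branch-site) the plain chi-square is used by default, which is
conservative; a 50:50 chi-square mixture mode is available.

Benjamini-Hochberg FDR is applied per comparison family across OGCs
(pooling all families is available by flag); we chose per-family control
because the families answer different questions and their p-value
distributions differ systematically. An OGC is *called* positively
selected at the site level only when a positive-selection comparison is
significant after FDR *and* the corresponding positive-class omega
estimate exceeds 1 — significance alone can reflect misfit rather than
selection.

Sites are identified by naive empirical Bayes (NEB): the posterior
probability of the positive-selection class at the MLEs, reported in
original alignment coordinates and flagged at 0.95. Full Bayes empirical
Bayes (integrating over parameter uncertainty on a grid) is not
implemented; NEB is exact at the MLE and the difference matters mainly for
small, noisy data sets, where site identification is weak regardless (see
Limitations).

## 7. Orchestration

OGCs are independent work units: a worker pool (forked processes) pulls
the next pending OGC until the queue empties, and one OGC's failure marks
that OGC failed without aborting the run. Every OGC derives its RNG seed
deterministically from the global seed and its identifier, so all result
files are byte-identical for any worker count — the test suite compares
1-worker and 8-worker runs bitwise. Branch and branch-site scans run only
for OGCs whose M1a-vs-M2a or M7-vs-M8 test is significant after FDR
(configurable), with every terminal branch designated foreground in turn.
Per-OGC intermediates (alignments, trees in `.dnd` and `.dnd.GenTree.nex`
form, fit reports, CodeML-style control files) are archived so any single
OGC can be re-fitted manually — including against a replacement species
tree via `replace_tree()` / `rerun_ogc()`.

# The simulator

`sim_scenario()` / `evolve_alignment()` / `emit_pipeline_inputs()`
generate data with known truth: root codons from the stationary
distribution, a site class per site from the model's mixture, and
branch-wise substitution draws from the class transition matrices (the
matrix-exponential method — exactly the engine's distributional
assumptions, rather than an event-level simulation). Gene families become
per-species FASTA inputs, optionally with gene losses and with recent
within-species duplicates (extra branch 0.005) that deterministically
trigger the paralog filter. Defaults describe the bundled toy conditions:
three species at 0.2 substitutions per codon per branch, five families of
150 codons under purifying selection (omega 0.2, kappa 2), uniform codon
frequencies.

The simulator produces gap-free, in-frame, perfectly homologous families:
passing tests therefore validate the statistical machinery and the
plumbing, but say nothing about alignment error, assembly artifacts,
annotation errors or compositional heterogeneity in real data. Gap
handling is exercised separately by injecting synthetic gaps in the
alignment-module tests.

# Validation problem sizes

The shipped tests validate, among other things: exhaustive-oracle
likelihood equality on 20 small instances (3-4 taxa, 3-5 codons);
parameter recovery under M0 (20 replicates, 5 taxa, 500 codons: mean
omega-hat within 0.05, mean kappa-hat within 0.3); type-I error of
M1a-vs-M2a under the null (100 replicates, 100 codons: empirical rate at
nominal 0.05 must stay below 0.07 — the omega2 boundary makes the test
conservative); and power under strong selection (50 replicates, 300
codons, omega2 = 4 on 20% of sites: rejection after FDR in at least 80%).
The 5-taxon validation tree has total length about 2.2 expected
substitutions per codon — congeneric-nematode-scale CDS divergence.

# Known limitations

* **Site-level identification is weak with few lineages.** At the
  5-taxon validation conditions the mean fraction of true positive-class
  sites reaching NEB posterior 0.95 is about a third, essentially
  independent of tree depth, although flagged sites are almost always
  genuine (precision near 1). This is a property of the inference problem,
  not a defect of the arithmetic (which is oracle-checked): most sites in
  the positive class simply do not accumulate enough nonsynonymous
  evidence to overcome the neutral class at 0.95. Gene-level detection is
  far more sensitive than site-level localization; treat site lists from
  few-taxon analyses as candidates, not measurements.
* The progressive aligner is not phylogeny-aware; systematically
  gap-dense regions are better handled by importing an external protein
  alignment (`read_protein_alignment()`), which the pipeline accepts.
* One genetic code (universal); no rate variation beyond the omega
  mixtures; no clade models; no per-branch dN and dS decomposition.
* The branch test is BR2 against M0 and the branch-site test is model A
  against its omega2 = 1 null — the standard nested pairs with one degree
  of freedom. Descriptions of these tests sometimes name non-nested pairs;
  the fitted comparison is recorded explicitly in the output metadata.

# Numerical conventions

Beta mixtures use 10 equal-probability categories (category means).
Optimizer convergence is L-BFGS-B's default relative-likelihood criterion
(factr 1e7, about 1e-9 relative); fits report a converged flag and the
best lnL is retained even when flagged. Zero-count codon frequencies are
floored at 1e-6 and renormalized. NJ distances with p >= 0.85 are capped
at 5. Newick output carries 6 significant digits; the CodeML foreground
convention (`label #1` after the branch length) is emitted only on
request and exactly once.
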