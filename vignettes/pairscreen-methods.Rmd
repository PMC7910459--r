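---
title: "Scoring genetic interactions in paired-guide CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in paired-guide CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscreen)
library(dplyr)
```

## The experimental design

A combinatorial CRISPR dropout screen disrupts two genes in the same cell
using a single lentiviral cassette that expresses two gRNAs from two
promoters (a human U6 and a synthetic U6). For each gene pair, every guide
against gene A (under hU6) is combined with every guide against gene B
(under sU6) — with 5 guides per gene, 25 paired constructs. In addition,
every targeting guide is paired with a non-targeting firefly-luciferase
control guide (control under hU6, targeting guide under sU6), which measures
that guide's *single-gene* fitness effect. Cells are harvested for
sequencing at two screen timepoints (days 14 and 28, in triplicate), and
guide abundance before selection is fixed by transducing a Cas9-negative
line harvested at day 7 (the baseline, also in triplicate).

Crossing each screen replicate with each baseline replicate gives nine
comparisons per construct, and each comparison yields a per-construct
log2 fold change (log2FC).

## The interaction model

Under Bliss independence, co-disrupting two genes that do not interact
should produce the *sum* of their individual effects on the log2FC scale:

$$\mathrm{Expected\ log_2FC}(g_1g_2) \;=\;
  \mathrm{Observed\ log_2FC}(g_1) + \mathrm{Observed\ log_2FC}(g_2)$$

where $g_1$ and $g_2$ are the two guides measured in their single-targeting
constructs in the *same* comparison. A synthetic-lethal interaction makes
the paired construct drop out faster than this additive expectation.

Rather than scoring the raw difference, the package models the *population*
of paired constructs: for each comparison, observed log2FC is regressed on
expected log2FC by LOESS (tricube-weighted local polynomials, span 0.75,
degree 2, three robustifying iterations — the canonical defaults, since no
specific parameters are prescribed by the design). This absorbs genome-wide
nuisance structure — the fitness cost of double-strand breaks themselves,
single- versus double-cutting differences, and normalization offsets — that
would otherwise masquerade as interaction. The **residual** (observed minus
fitted, the vertical distance to the population trend) is the interaction
score of one construct in one comparison; negative means more lethal than
expected. With fewer than 30 points the fit falls back to an ordinary
least-squares line, and evaluation beyond the fitted range linearly extends
the boundary slope.

### Variance smoothing

Residual spread grows with the magnitude of the expected effect
(heteroscedasticity). Within each comparison, constructs are ranked by
expected log2FC and cut into bins of 200 (the final bin is merged into its
neighbour when shorter than a quarter bin); each residual is divided by its
bin's *variance* — the procedure as literally specified, kept as the
default. Note that dividing by the variance only equalizes spread when bin
variances are near 1; dividing by the bin *standard deviation*
(`divisor = "sd"`) is the variant that actually studentizes every bin to
unit variance, and it is what the equal-variance tests in this package
check. Both are exposed; the intent behind the literal wording is not
second-guessed. Bins are formed per comparison, consistent with the
per-comparison LOESS fits; `bin_index` is stored 1-based.

## Hit calling

Each gene pair accumulates up to $25 \times 9 = 225$ variance-adjusted
residuals. Two tests are run per pair:

* a t statistic, $t = \bar r / \sqrt{\mathrm{var}(r) / (n-1)}$, with
  p-value from the t distribution with $n-1$ degrees of freedom. The $n-1$
  (rather than $n$) inside the square root is intentional — the statistic
  is implemented exactly as the scoring scheme defines it, and the
  difference is absorbed where the package itself tests null uniformity;
* alpha robust rank aggregation (α-RRA): all adjusted residuals are pooled
  and ranked ascending; among a pair's normalized ranks at or below
  α = 0.10, the score ρ is the minimum Beta(j, n−j+1) tail probability over
  the order statistics, and significance comes from a permutation null
  (random rank sets of the same size, 10,000 permutations by default,
  p floored at 1/(n_perm+1)).

Both p-values are Bonferroni-corrected across the tested pairs and a pair
is a **hit** only if both tests pass the 0.1 threshold, its mean adjusted
residual is negative, and it survives filtering. Requiring the overlap of
the two tests enforces both size (t) and consistency (rank concentration)
of the effect. A two-sided t p-value plus the explicit negative-mean
requirement is used instead of a one-sided test; this is conservative and
keeps the direction explicit.

### Filtering genes lethal in isolation

Guides against genes that are lethal on their own behave more aggressively
under the hU6 promoter inside paired constructs, producing spuriously
significant residuals. Pairs containing such genes are therefore removed
from the hit list. The built-in caller ranks single-targeting constructs at
the *guide* level — each construct collapsed to its mean log2FC across the
nine day-14 comparisons — and applies the same α-RRA machinery per gene with
Bonferroni correction; treating the nine crossed comparisons as independent
observations here would inflate the null (see *Limitations*). An externally
supplied essential-gene list is merged with its own provenance label.

### Competitive-growth validation

`competitive_assay_residual()` scores the four-population co-culture assay
used to validate single pairs: each transduced population's phenotype is its
log2 depletion relative to the untransduced population between two
timepoints, and the residual is the double-positive phenotype minus the sum
of the two single-positive phenotypes.

## The synthetic screen generator

The real screen data this design comes from are controlled-access, so the
package ships a generator whose defaults mirror the stated study
conditions: gene pairs with 3–5 guides per gene (default 3 for compact test
screens; the full design uses 5), all-versus-all paired constructs plus one
single-targeting construct per guide, triplicate baselines (day 7, no
editing) and triplicate screens (days 14 and 28), and 500× sequencing
coverage.

The generative model inverts the scoring model. A paired construct with
guide efficiencies $e_i, e_j \in [0,1]$, promoter multipliers $m_{hU6} \ge
m_{sU6}$, gene fitness effects $f_A, f_B$ and pair interaction
$\varepsilon$ has true log2FC

$$ (e_i\, m_{hU6}\, f_A + e_j\, m_{sU6}\, f_B +
   e_i e_j\, \varepsilon)\cdot \tfrac{t}{28\ \mathrm{days}} $$

The interaction term carries $e_i e_j$ because epistasis requires both
genes to actually be cut; timepoint scaling is linear in days (the simplest
growth-rate model). Defaults: guide efficiency uniform on [0.6, 1];
promoter multipliers 1 and 0.9 (a subtle imbalance between the two
promoters); interaction −1.5 for synthetic-lethal pairs. Baseline abundance
is log-normal (sdlog 0.5) shared across samples; screen-sample means
multiply it by $2^{\text{true log2FC} + \text{noise}}$ with noise s.d.
$\sigma_0 + \sigma_1 |\text{true log2FC}|$ ($\sigma_0 = 0.15$,
$\sigma_1 = 0.1$ in log2FC units) — heteroscedastic by construction, since
no quantitative noise magnitudes are prescribed and greater spread at more
lethal expected effects is the qualitative feature the smoothing step
exists for. Counts are negative-binomial with dispersion 0.05 (a mid-range
value for screen technical replicates). Everything is reproducible from a
single seed.

`simulate_fastq()` additionally emits paired FASTQ files mimicking the
two-forward-read strategy: read 1 carries the hU6 spacer and read 2 the sU6
spacer, each at a fixed 10-nt offset inside constant vector sequence.
`count_reads()` inverts this by anchored (offset-fixed, not aligned)
matching at 0 or 1 mismatches, counting ambiguous or library-absent
combinations as unassigned; assigned + unassigned always equals the number
of read pairs.

What the generator does *not* emulate: PCR jackpotting, lentiviral
recombination swapping guides between promoter slots, copy-number-driven
cutting toxicity, or guide off-target effects. Passing tests on synthetic
screens therefore demonstrate correctness of the statistical machinery
under the stated generative assumptions, not robustness to every artefact
of real screens.

## Numerical and design choices

* **Normalization**: median-of-ratios (default) or total-count, with a
  pseudocount of 1 added after scaling; the upstream protocol does not
  prescribe one, and median-of-ratios is robust to the composition shifts
  dropout screens create. Constructs with raw baseline counts below 30 are
  flagged and excluded from scoring but retained for reporting.
* **Canonical pair orientation**: the lexicographically smaller gene
  occupies the hU6 slot when a library is enumerated; the design fixes one
  orientation without saying which, so this is a convention, not inferred
  intent.
* **Comparability of tests**: both tests consume the same pooled
  per-comparison residual set; residuals are never averaged before testing.
  Whether ranks should be pooled across the nine comparisons or formed per
  comparison is not specified; pooling is what yields the "up to 225"
  per-pair accounting and is used here.
* **Degenerate inputs**: all-identical expected values abort the fit; a
  zero-variance bin aborts variance adjustment naming the bin; pairs with
  fewer than 3 residuals or zero variance are flagged
  `insufficient_residuals` rather than tested; ties in ranks are averaged.
* **Problem sizes in the test-suite**: simulated screens of 200 pairs with
  3 guides per gene (1800 paired constructs, nine comparisons), 20 seeds
  for null calibration and 10 for recovery — sizes at which the binomial
  error of the measured proportions is small relative to the thresholds
  being checked.

## Limitations

The crossed-comparison design is pseudoreplicated: the nine comparisons
reuse three screen and three baseline samples, and the Bliss expectation
reuses each single-guide measurement across all of a pair's constructs, so
a pair's ≤225 residuals contain far fewer independent quantities. Both the
t test (which takes n as the residual count) and the RRA permutation null
(which treats pooled ranks as exchangeable) therefore understate the null
variance, and the raw per-pair p-values are anticonservative. On strict
null simulations the package's Bonferroni-intersection caller yields a
per-pair false-positive rate of roughly 4 × 10⁻³ — far below the nominal
0.1 proportion but well above what independent residuals would give. This
is a property of the published scoring scheme, reproduced faithfully;
consumers should treat the hit list as candidate-generating (as the
original screen did, followed by low-throughput validation) rather than as
strictly error-controlled. The planted-effect recovery results in
`scripts/acceptance.R` quantify the practical consequence: with strong
planted interactions the intersection caller attains high sensitivity at
zero observed false discoveries, while diffuse fitness backgrounds inflate
false calls through shared single-guide noise — the same mechanism the
lethal-in-isolation filter exists to counter.
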