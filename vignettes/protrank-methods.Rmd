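---
title: "Rank-based differential expression with missing values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based differential expression with missing values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrankr)
```

## The problem

Label-free proteomic and phosphoproteomic experiments report an intensity
("count") for each peptide in each sample, and a zero when the peptide was
not detected. Zeros are common — large datasets routinely carry 30–45% of
them — and they conflate technical dropout with genuine biological absence.
They are especially damaging in pairwise before/after comparisons where the
*other* count is large: no pseudocount of reasonable size can shrink a
change from an above-median intensity to zero, so such *irregular zeros*
dominate any analysis built on log fold changes. The usual remedy,
imputation (replacing zeros with draws from a shifted, scaled fitted
distribution), injects thousands of synthetic values and can reshape the
list of differentially expressed (DE) genes.

`protrankr` takes the rank-based route instead: fold changes are only ever
compared *within* a comparison, zeros are handled by a fixed virtual rank,
and no value is ever fabricated.

## The model

The input is a genes-by-samples matrix of nonnegative counts $n_{g,i}$ and
a *comparison design*: ordered pairs $(s^B, s^A)$ of before/after samples,
organised into $N$ groups $G_1, \dots, G_N$ of comparisons expected to move
in the same direction (e.g. replicates of the same treatment). For one
comparison, the log fold change of gene $g$ is

$$x_g(s^B \to s^A) = \log_2 \frac{n_{g,s^A} + n_0}{n_{g,s^B} + n_0},$$

with prior count $n_0 = 1$ by default. Among the $\Omega$ genes with
positive counts in both samples, the $x_g$ are ranked from largest
(rank 1) to smallest (rank $\Omega$) and rescaled to the rank score

$$\sigma_g = \frac{r_g - 0.5}{\Omega} \in (0, 1),$$

which is symmetric: the smallest score $0.5/\Omega$ sits as far from 0 as
the largest, $1 - 0.5/\Omega$, sits from 1, and the both-positive scores
average exactly 0.5. Comparisons in which the count goes from zero to
positive receive the fixed virtual score $\sigma_0$ (default 0.1 — the
same score as a both-positive pair at the 10th percentile of fold
changes); positive to zero receives $1 - \sigma_0$; both-zero pairs are
undefined and simply skipped. This is the entire treatment of missing
values: no distribution is fitted, nothing is imputed.

Scores are aggregated over comparisons with a per-group direction
assignment $D = \{d_1, \dots, d_N\}$, $d_n \in \{+1, -1\}$:

$$\mathrm{score}_g(D) = \prod_{n=1}^{N} \prod_{j=1}^{M_n}
  \left[ -\ln\!\left( \tfrac12 - \tfrac{d_n}{2}
  + d_n\, \sigma_g(s^B_{n,j} \to s^A_{n,j}) \right) \right],$$

where the inner term is $-\ln \sigma$ when $d_n = +1$ (rewarding
upregulation in group $n$) and $-\ln(1 - \sigma)$ when $d_n = -1$. The
log transform is what makes consistency count: a gene with extreme but
*opposite* scores $10^{-4}$ and $1 - 10^{-4}$ aggregates to
$\approx 9.2\times10^{-4}$, far below a gene with two concordant scores of
$10^{-2}$, which aggregates to $(\ln 100)^2 \approx 21.2$ — even though
the plain products of the two score pairs would be nearly equal. The final
score of a gene is the **best (largest) aggregate over all $2^N$
assignments**, and genes are ranked by final score, largest first.

### Direction combination

The best-over-assignments rule deserves a note, because "optimise over
directions" could also be read as keeping the *worst* assignment. Keeping
the best is the reading consistent with the method's purpose — finding
genes that move up in one group and down in another requires rewarding the
assignment that matches the gene — and with the multi-directional results
the method is designed to produce. We implement the best-aggregate rule as
the default and keep `direction_combine = "min"` as an audit switch; with
a single group the two rules differ only in whether up- and down-regulated
genes are sought simultaneously or not at all.

## Bootstrap false discovery rate

Significance is assessed with a nonparametric bootstrap. Each realization
permutes, independently within every comparison column, the defined rank
scores (virtual $\sigma_0$ entries included) among the genes that have a
defined score in that column; the undefined pattern is untouched, so each
column's score multiset is preserved exactly. Final scores are then
recomputed, *including* the search over the $2^N$ direction assignments,
so the null distribution accounts for the selection advantage that the
direction search confers. For a gene at real rank $r_g$, $N_g$ is the mean
number of bootstrap genes scoring strictly above the gene's real score
(ties do not count against it), and the raw FDR estimate is $N_g / r_g$,
capped at 1. Because this ratio can dip as one walks down the ranking,
each gene inherits the largest FDR seen at any better rank (a running
maximum), making the estimate monotone.

Defaults: 100 realizations (`n_boot`), FDR threshold 0.20. One root seed
draws per-realization child seeds, so runs are bit-reproducible and the
realizations are independently re-seedable. Permuting scores *before*
direction resolution (rather than permuting per-direction aggregates) is a
deliberate choice: it randomises the only exchangeable objects the method
defines, the per-comparison scores.

## The imputation baseline

For comparison studies the package ships the standard shift/scale
imputation. `fit_log_bulk()` estimates the mean $\mu_0$ and standard
deviation $s$ of the natural-log positive counts (an optional central
quantile trim is available but off by default — with log-normal bulk data
the plain moments are the maximum-likelihood fit). `impute_zeros()`
replaces each zero by $\exp(V)$,
$V \sim \mathcal{N}(\mu_0 + \delta s,\ \lambda s)$. $\delta = -1.8,
\lambda = 0.5$ is the down-shift recommended by the Perseus platform;
$\delta = 0, \lambda = 0$ — the package default — replaces every zero
with the bulk-level constant $e^{\mu_0}$, i.e. mean-level imputation.
(The constant-mean reading is chosen deliberately: "zero shift, scale one"
and "replace with the dataset's mean" are mutually exclusive descriptions
of the same baseline, and only the constant variant is deterministic and
seed-free, which makes it the cleaner reference point.)

## What the synthetic generator emulates — and what it does not

`simulate_counts()` produces tables with the features that matter to this
method:

* **log-normal intensities** — baseline $\lambda_g = \exp(\mathcal{N}(7.7,
  1.3))$, the bulk observed in phosphoproteomic intensity tables;
* **replicate noise** — multiplicative, log-normal, default sd 0.3 in
  log2 units (a typical replicate scatter for label-free quantification;
  no published replicate-noise model exists for these data, so this is a
  package choice);
* **planted DE genes** — a fraction `de_fraction` of genes whose "after"
  samples are multiplied by $2^{d_n \cdot \mathrm{effect}}$ with
  per-group planted directions, recorded in a truth table;
* **irregular zeros** — within each designed comparison, an entry whose
  partner exceeds the median positive count is zeroed with probability
  `irregular_zero_prob` (default 0.06);
* **uniform dropout** — remaining positive entries are zeroed with
  probability `zero_prob` (default 0.05).

With the defaults, the probability that the partner of an above-median
count is zero is $1 - 0.95 \times 0.94 \approx 0.107$, matching the
$\approx 0.11$ diagnostic of real phosphoproteomic data — the statistic
that motivates the method. The *overall* zero fraction of the defaults
(roughly 8%) is deliberately lower than the 30–45% of real datasets: with
uniform dropout one cannot match both numbers at once, because in real
data most zeros cluster among low-abundance peptides. We chose to match
the irregular-zero diagnostic, since that is the regime that
distinguishes the methods; users wanting heavier missingness can raise
`zero_prob`. Consequences for interpreting tests: recovery and
calibration results on these tables demonstrate correctness of the
machinery under the stated generative model, not performance on real data
with abundance-dependent dropout, batch structure, or correlated
peptides — none of which the generator attempts.

`add_random_zeros()` implements the perturbation protocol used for
robustness studies: it flips an exact, uniformly chosen fraction of
positive entries to zero, so the added zeros carry no DE signal by
construction.

## Numerical choices and degenerate inputs

* **Ties** in fold changes get average (midpoint) ranks; this preserves
  the rank-sum identity that makes both-positive scores average exactly
  0.5, at the cost of the extreme scores moving inward when the extremes
  themselves tie.
* **Tied final scores** are broken by input row order, so reruns are
  bit-identical.
* **Tied direction assignments** (equal aggregates) keep the first
  assignment in the fixed enumeration order (+1 before −1,
  lexicographic).
* $\sigma_0$ is constrained to $(0, 0.5)$: at 0.5 and beyond a
  zero$\to$positive change would no longer encode upregulation.
* Genes whose every designed comparison is both-zero are unrankable; they
  are excluded from ranking and FDR and reported separately. All-zero
  *rows* should be removed up front with `filter_all_zero_rows()`.
* Aggregates are computed as running products of $-\ln$ terms; with
  at most tens of comparisons neither overflow nor underflow is
  reachable in double precision.
* With $n_0 = 0$ and strictly positive counts the ranking is exactly
  invariant to per-sample scaling, which is why the method needs no
  normalisation step; with the default $n_0 = 1$ the invariance is
  approximate for counts well above 1.
* The direction enumeration is exhaustive in $2^N$ and therefore capped
  (default `max_groups = 12`) with a clear error beyond the cap.

## Problem sizes used by the test suite

The package's own checks run at sizes chosen to exercise every code path
while remaining quick on a laptop: oracle-equivalence on 200 random
8-gene × 4-sample tables against an independent loop-based
reimplementation; null FDR calibration on twenty 2000-gene, 4-comparison
all-positive tables at `n_boot = 100`; planted-DE recovery (50 genes,
$|\log_2|$ effect 3, one- and two-group designs) at the same size; the
random-zero robustness sweep on 1000-gene tables at perturbation
fractions 1–10%; and imputation parameter recovery at 50,000 draws.

## Known limitations

* The bootstrap is the computational bottleneck (`n_boot` full
  re-rankings); an analytic approximation to the null score distribution
  would remove it but is not implemented.
* The FDR estimate is a plug-in ratio, not a confidence bound; at small
  `n_boot` its resolution at rank $r$ is $1/(r \cdot n_\text{boot})$.
* Peptide-to-protein rollup, per-sample normalisation factors and
  dispersion modelling are out of scope: the method consumes a plain
  intensity table and a design.
* The generator's uniform dropout understates the abundance dependence of
  real missingness (see above).

## A minimal session

```{r example, eval = FALSE}
m <- read_counts("counts.tsv")
m <- filter_all_zero_rows(m)$counts
design <- parse_design("design.txt")   # or single_group_design(...)
data_stats(m, design)                  # zero structure diagnostics

rk <- rank_genes(m, design)            # sigma0 = 0.1, n0 = 1
fdr <- estimate_fdr(rk, n_boot = 100, seed = 1)
significant_genes(fdr, threshold = 0.20)
plot_rank_scores(fdr, top = 200)       # real vs bootstrap score decay
```
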