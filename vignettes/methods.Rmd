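---
title: "Methods: how glints prioritizes disease-specific SNVs"
author: "glints maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how glints prioritizes disease-specific SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glints)
```

## The problem

Exome sequencing of a patient yields thousands of candidate single
nucleotide variants (SNVs), a handful of which may cause the disease
under study. Two kinds of evidence speak to causality: *variant-level*
functional deleteriousness predictions (conservation, ensemble
classifiers, protein-impact scores) and *gene-level* evidence that the
host gene is plausibly associated with the query disease. glints turns
both into calibrated p-values and combines them into a single
per-variant significance, so that candidates can be ranked and
thresholded on a pFDR q-value.

The workflow has four stages.

## 1. Region classification

Candidates are classified against transcript models (BED12 or GFF3)
into:

* **Exon** — a coding substitution whose codon translates to a
  different amino acid (stop gain/loss counts by default, toggleable);
* **Splice site** — intronic offsets 1–2 bp from an exon/intron
  boundary (the canonical splice dinucleotides);
* **Intron** — intronic offsets 3–10 bp from the nearest boundary;
* **Promoter** — within 500 bp upstream of the strand-aware TSS
  (configurable via `promoter_window`), or inside a UTR;
* everything else (intergenic, deep intronic, synonymous coding) is
  discarded with a reason in a sidecar table.

All internal coordinates are 0-based half-open; VCF positions are
converted on read, which keeps the interval arithmetic unambiguous.
When several transcripts or classes apply, the most severe class wins
(Exon > Splice site > Intron > Promoter), mirroring common annotator
behaviour; a variant hosted by several *genes* is scored against each
and keeps its best combined p-value. Intronic offsets are measured
from the nearest boundary; for introns shorter than 20 bp the donor
and acceptor windows would overlap, which the toy gene models used in
testing avoid by construction.

## 2. Empirical calibration of functional scores

Raw scores are heterogeneous in scale and direction. Each score is
first *oriented* so that higher always means more deleterious (scores
declared `LOWER_WORSE` on a [0,1] scale are flipped as `1 - x`, e.g.
SIFT and LRT; other `LOWER_WORSE` scores are negated). An oriented
score is then compared with an empirical null panel — the sorted
scores of a background variant database with known causal variants
removed — and converted to the smoothed upper-tail rank p-value

$$p = \frac{r + 1}{n + 1}, \qquad r = \#\{\text{null} \ge s\}.$$

The `+1` smoothing keeps p strictly positive (required by the
`-2 log p` transform downstream) and converges to the raw exceedance
proportion as the panel grows; ties count as more extreme, which is
conservative. Gene-level analytical p-values are calibrated the same
way against the analytical p-values of *neutral* genes (genes not
associated with any disease), with "more extreme" meaning smaller.
Panels default to a single genome-wide database; per-region panels are
a matter of supplying different `null_panels`.

## 3. Gene–disease association regression

For a candidate gene $g$ and query disease $d$, every other disease
$e$ with known associated genes contributes one observation: the
response is the vector of $p$ phenotype similarities between $d$ and
$e$ (the package is agnostic to how the matrices were built; three
clinical-vocabulary measures is the typical setting), and the
covariate is the genotype similarity
$x_{de} = \sum_{g \in D}\sum_{h \in E} \varphi_{gh}$, the summed gene
functional similarity between the two diseases' gene sets — here with
$D = \{g\}$. The multivariate regression
$\mathbf{y}_{de} = \boldsymbol\alpha + x_{de}\boldsymbol\beta +
\boldsymbol\varepsilon_{de}$, $\boldsymbol\varepsilon \sim
N(\mathbf 0, \Sigma_\varepsilon)$, has the closed-form MLE

$$\hat{\boldsymbol\beta} = (x_c^T x_c)^{-1} x_c^T Y_c,\quad
\hat{\boldsymbol\alpha} = \bar{y} - \bar{x}\hat{\boldsymbol\beta},\quad
\hat\Sigma_\varepsilon = \frac{\hat E^T \hat E}{n - 2},$$

and the association test on the contrast
$H_0\!: \lambda^T\beta = 0$ vs $H_1\!: \lambda^T\beta > 0$ uses

$$T = \frac{\lambda^T\hat\beta}
{\sqrt{\lambda^T (x_c^Tx_c)^{-1}\hat\Sigma_\varepsilon \lambda}}
\sim t_{n-2} \text{ under } H_0,$$

with the one-sided upper-tail p-value. The default weights are
$\lambda = (1,\dots,1)^T$. Because the design has a single centred
covariate, no general matrix inversion is needed. Degenerate inputs —
fewer than 3 usable diseases, a constant covariate, zero residual
variance in the $\lambda$ direction — yield a *missing* association
score for that measure rather than aborting the variant, and the
number of combined sources shrinks accordingly. In the evaluation
protocol (`leave_out = TRUE`) the candidate gene and all known genes
of the query disease are removed from the other diseases' gene sets
before computing $x$, so no information about the planted association
leaks into the covariate. Diseases with no known genes are dropped
from the rows; including them as $x = 0$ rows would mix "no
information" with "no similarity".

## 4. Dependence-corrected Fisher combination and q-values

With $K$ calibrated p-values per variant (up to 14 functional + the
gene-level measures for coding variants; whole-genome scores only for
noncoding ones), Fisher's statistic is $U = \sum_i -2\log p_i$. The
sources are correlated, so $U$ is *not* $\chi^2_{2K}$; glints models
the null as a scaled chi-squared $\eta\chi^2_v$ with both moments
matched:

$$\eta v = 2K, \qquad 2\eta^2 v = \operatorname{Var}(U) =
\sum_{i,j} \operatorname{cov}(V_i, V_j)
\;\Rightarrow\; \eta = \frac{\operatorname{Var}(U)}{4K},\;
v = \frac{2K}{\eta}.$$

Pairwise covariances come from the quartic polynomial
$\operatorname{cov}(V_i,V_j) = 3.263119\,\tilde\rho + 0.709866\,
\tilde\rho^2 + 0.026589\,\tilde\rho^3 - (0.709866/n)\,\tilde\rho^4$
in the shrunk correlation
$\tilde\rho = \hat\rho\,(1 + (1-\hat\rho^2)/(2n-1))$ of the
probit-transformed p-values $z_i = \Phi^{-1}(1 - p_i)$, estimated
pairwise-complete over the candidate panel itself (a configurable
background). Two numerical choices matter:

* the *diagonal* of the covariance matrix is fixed at the analytic
  $\operatorname{Var}(\chi^2_2) = 4$ rather than the polynomial's
  $3.999574 - 0.709866/n$, which makes the reduction to classical
  Fisher *exact* when all correlations are zero (verified to < 1e-12
  in the tests);
* the moment equations are solved self-consistently as above. A
  literal reading of some presentations of this estimator divides the
  summed covariance by $K^2$, which cannot satisfy the variance
  equation it is derived from (under independence it would force
  $\operatorname{Var}(U) = 16$ for every $K$); the self-consistent
  solution recovers the textbook limits $(\eta, v) = (1, 2K)$ under
  independence and $(K, 2)$ under perfect dependence, and its
  empirical size at $\alpha = 0.05$ under a strongly equicorrelated
  copula ($\rho = 0.6$, $K = 10$) is 0.050 where naive Fisher rejects
  at 0.19.

Negative shrunk correlations pass through the polynomial (it is
odd-dominated); the total $\operatorname{Var}(U)$ is floored via
`eta_floor` (default 1e-6). Pairs with fewer than 3 complete
observations are treated as independent with a warning. Missing
sources simply reduce $K$; the scaled-chi-squared null is refitted per
distinct missingness pattern (cached within a run).

Combined p-values are converted to Storey pFDR q-values:
$\hat\pi_0$ from the smoother over
$\lambda \in \{0.05, \dots, 0.95\}$ (cubic smoothing spline, read at
the largest $\lambda$, clipped to $(0,1]$), then
$q_i = \hat\pi_0 \min_{p_j \ge p_i} p_j m / \text{rank}_j$. Setting
`pi0 = 1` reproduces Benjamini–Hochberg adjusted p-values bit-exactly,
which the tests assert against `p.adjust`. Final ties in combined p
are broken by larger $U$ first, then lexicographic variant key, so
reruns are byte-identical.

## The synthetic world

`synthetic_world()` generates every input at desk scale, fully
reproducible from one seed:

* **Gene models** — 20 loci on one random-sequence chromosome, 4 exons
  of 90 bp with 30 bp introns, 30 bp UTRs at both CDS ends, strands
  alternating, 3 kb apart (so 500 bp promoter windows stay
  intergenic).
* **Scores** — a 14-source Gaussian copula (8 whole-genome-like
  sources for all regions, 6 protein-like sources for coding only; one
  of them deliberately `LOWER_WORSE` to exercise orientation),
  equicorrelated at 0.3, standard-normal marginals, 5% missingness,
  4000-variant null panels. Causal variants get a +1.5 SD oriented
  mean shift on every source. The 0.3/1.5 pairing makes each single
  source a noticeably imperfect predictor (single-source mean rank
  ratios around 0.15) while their combination is strong — the regime
  the method is designed for.
* **Disease space** — 40 diseases; all but the query get 1–3 genes
  from a 40-gene pool disjoint from the loci. Phenotype similarities
  follow the generative regression $y = 0.2 + 0.15\,x + \varepsilon$,
  $\varepsilon \sim N(0, 0.1^2)$, truncated to [0,1] (parameters sit
  in the interior of the scale, so truncation bias is negligible),
  with $x$ computed from the query disease's *hidden* causal gene at
  the first locus; the released disease–gene map leaves the query
  empty. Loci 2–20 are associated with no disease and serve as the
  neutral-gene calibration panel.

What the generator does **not** emulate: real per-score marginal
distributions (CADD's phred scale etc. — marginals are standardized),
linkage between nearby variants, transcript diversity (one transcript
per gene), population structure, and realistic phenotype-similarity
geometry. Passing spike-in tests therefore demonstrates the
statistical machinery — calibration, dependence correction,
integration benefit — not performance on any real cohort.

## Evaluation

`compute_rank_metrics()` implements the spike-in metrics: the rank
ratio of a causal variant (its rank divided by the number of neutral
variants), the mean rank ratio (MRR), the rank ROC AUC (sweeping a
ratio threshold over all observed ratios, trapezoid area), and the
top-k count. Causal ranks use conservative competition ranking: ties
with neutral variants count against the causal one.
`enrichment_p()` is the hypergeometric upper tail
$P(X \ge x)$ — the one-sided Fisher exact test on the
top/rest × functional/other table — and is checked against exhaustive
enumeration of all top-lists for every parameter setting with
$N \le 12$.

The bundled spike-in benchmark (also run by `scripts/acceptance.R`)
performs 50 runs of 500 neutral + 1 causal variant cycling over the
four regions, with leave-out of the query disease's genes. Problem
sizes (500 neutrals, 50 runs, 4000-variant null panels, 2000-replicate
null-uniformity studies) were chosen so the entire suite characterizes
the estimators well while completing in minutes on one CPU. Under the
default world the combined ranking achieves MRR ≈ 0.02 and beats the
best single source (≈ 0.05) — the integration benefit the method
exists to deliver. Note the best *single* source here is typically a
gene-level measure whose p-values are shared by all variants of a
gene, so its apparent MRR is floored by within-gene ties.

## Parameter recovery and the 3-SE criterion

The recovery diagnostic re-simulates the generative regression with
known $(\alpha, \beta)$ and asks how often the fitted contrast
$\lambda^T\hat\beta$ falls within 3 standard errors (the test's own
denominator) of the truth. The criterion is evaluated on the tested
contrast rather than jointly on all $2p$ coefficients: the contrast is
what the association test actually uses, and a joint 3-SE box over six
estimates has nominal coverage below 99% even when every marginal
estimator is perfectly calibrated, so a joint criterion would conflate
multiplicity with miscalibration.

## Known limitations

* Single-nucleotide substitutions only; no indels or structural
  variants, no intergenic or deep-intronic assignment.
* The scaled chi-squared null is a two-moment approximation; extreme
  tail probabilities (far beyond the 0.05 regime tested) inherit its
  error.
* Empirical p-values are bounded below by $1/(n+1)$; ranking
  resolution saturates once many variants hit the panel floor, so
  panel size bounds the usable significance range.
* Gene-level evidence is shared by all variants of a gene and is
  treated as an ordinary source in the combination; no extra
  within-gene correlation adjustment beyond the estimated source
  correlations is applied.
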