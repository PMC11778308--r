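---
title: "Methods: scoring habitat preference and partitioning phylogeny versus habitat"
author: "phylohab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring habitat preference and partitioning phylogeny versus habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylohab)
```

phylohab quantifies where microbial lineages live and what shaped their
genomes. It consumes three kinds of tables that large public resources
already produce — per-dataset taxonomic profiles from marker-gene read
profiling (SingleM/Sandpiper style), a per-genome feature table, and a
binary metabolic-trait matrix (METABOLIC style) — and answers two
questions: which taxa prefer soil over other habitats and how broadly taxa
range across habitats; and how much of the variation in genome features and
metabolic traits is attributable to phylogeny (the class a genome belongs
to) versus habitat (the environment it was recovered from).

## Ecological metrics

Every dataset (one metagenome accession) carries exactly one of seven
habitat labels: soil, engineered, freshwater, host-associated, marine,
non-marine saline and alkaline, terrestrial non-soil. A taxon is *detected*
in a dataset when the profile reports any non-zero relative abundance;
absence is encoded by the absence of the row, so zero-abundance rows are
dropped at load time (with a logged count). For a taxon $t$ and habitat
$h$, with $n_h$ datasets of which $d_{th}$ contain a detection:

* **ubiquity** $U_{th} = 100\, d_{th} / n_h$ (percent of datasets);
* **mean relative abundance** $A_{th}$ = mean of the taxon's abundance over
  the datasets where it is detected (a detection-conditional mean; an
  over-all-datasets mean, counting absences as zero, is available via
  `abundance_over_detected = FALSE` because survey wording rarely
  distinguishes the two);
* **preference ratio** $R_t = U_{t,\text{soil}} / U_{t,\text{nonsoil}}$,
  where the non-soil pool aggregates *datasets* (never per-habitat
  percentages) over the five non-host non-soil habitats;
* **abundance ratio**: soil over pooled non-soil mean abundance.

Host-associated datasets are excluded from every soil/non-soil comparative
field because of their extreme overrepresentation in public archives, but
they still count in the seven-habitat breadth analysis and toward the
rare-taxon totals. A zero non-soil denominator with a positive soil signal
yields `Inf` with a `ratio_denom_zero` flag rather than a dropped row; a
habitat with no datasets has *undefined* (`NA`) ubiquity, not zero.

### Classifications

All cutoffs are strict (`>`), matching the survey conventions they encode,
and every one is overridable:

* soil-ubiquitous: $U_{t,\text{soil}} > 75$;
* soil-preferring: $R_t > 4$;
* soil-enriched: abundance ratio $> 1$ (the separate ">1% soil mean
  abundance" threshold is reported as `abundant_in_soil` but does not enter
  the summary);
* **SPL** (soil-preferring lineage): all three calls positive; **NSPL**:
  all three negative; anything mixed is *intermediate*; taxa detected in
  fewer than 250 studies are *rare* (the rarity override comes first, since
  percentages computed from a handful of detections are unstable).

A taxon sitting exactly on every cutoff therefore fails all three calls.
Habitat breadth has two independent criteria: from profiles, a *generalist*
is detected in all seven habitats (with the same <250-study rare
exclusion, reported both applied and not); from genome origins, a
generalist has genome representatives from two or more habitats, with taxa
represented by fewer than five genomes flagged instead of classified.

## Variance partitioning

### Type III ANOVA with percentage contributions

For each continuous feature $y$ the two-factor model
$y = \mu + \alpha_{class} + \beta_{habitat} + (\alpha\beta) + \varepsilon$
is fitted by least squares under sum-to-zero contrasts. The type III sum of
squares of a term is the increase in residual SS when that term's columns
are removed from the full model — `fit_type3_anova()` computes it exactly
that way (and the test suite verifies it, term by term, against explicit
Moore–Penrose projections and against `car::Anova(type = 3)`). The
**percentage contribution** of a term is $100\,SS_{term}/SS_{total}$ with
$SS_{total}$ the sum over all terms *including* the residual; the
explained-only denominator is available via `pct_denominator =
"explained"` and the choice is recorded in the result. Significance tiers
use fixed cutoffs — *strong* at $p < 10^{-5}$, *weak* at
$10^{-5} \le p < 0.05$ — with no multiplicity correction (an informational
Benjamini–Hochberg column accompanies the batch output).

Empty class-by-habitat cells (the default six-class design has nine,
including an almost entirely empty non-marine-saline column) make some
interaction columns unestimable; they are dropped from the full model via
QR rank detection and reported, rather than failing the fit. Genomes with a
missing value for a feature are excluded from that feature's fit only
(pairwise deletion), maximizing per-feature sample size.

**Interaction soak, and which model answers which question.** In a heavily
unbalanced design the retained interaction columns are strongly collinear
with the main-effect columns, so the type III main-effect SS under the
interaction model is only the *uniquely* attributable part — a pure class
effect that marginally explains 40% of the variance retains roughly a
third of that as unique SS. This is geometry, not noise (it persists with
the noise turned off). The package therefore uses the
interaction-accommodating fit for significance tiers (its p-values are
conservative for main effects) and, when the question is "how large are
the planted or assumed main-effect shares", the main-effects partition
(`include_interaction = FALSE`), which recovers planted shares to within a
few points at the default design size. The acceptance script reports both.

### Tukey–Kramer comparisons

`tukey_hsd()` performs all pairwise group comparisons with
studentized-range adjusted p-values using the pooled within-group
variance, the Kramer form for unequal group sizes:
$q = |\bar y_a - \bar y_b| / \sqrt{\tfrac{MSE}{2}(1/n_a + 1/n_b)}$,
$p = P(Q_{k,\nu} > q)$. With $k = 2$ this reduces exactly to the pooled
two-sided t-test. Groups that are identical constants give $p = 1$. It is
run one-way per factor for factors at least weak-tier significant.

### Logistic partition of binary traits

Each 0/1 trait is fitted by maximum-likelihood logistic regression on
class and habitat. The McFadden pseudo-$R^2$ is
$1 - \ell_{full}/\ell_{null}$; the **contribution** of a variable is the
pseudo-$R^2$ drop when that variable is removed, and term p-values come
from likelihood-ratio tests. The full model is *main-effects* by default:
with sparse class-by-habitat cells an interaction term quasi-separates in
near-empty cells and inflates every drop (in a null world the habitat drop
alone exceeds 0.02 at $n \approx 600$), defeating the purpose of the
partition; `include_interaction = TRUE` restores it for dense designs.
Complete or quasi-complete separation (non-convergence or runaway
coefficients, $|\hat\beta| > 15$) flags the result `unreliable` rather
than returning a silent number.

`batch_partition()` runs the ANOVA arm over the twelve continuous
features, oxygen preference encoded aerobic = 1, and the three-level
life-history strategy as one-vs-rest indicators (reporting the indicator
with the largest class SS); the logistic arm runs over every trait. Each
analysis is labelled lineage-specific, habitat-specific, both, or neither
from the strong tiers; per-feature failures are recorded in the summary,
never aborting the batch.

## Life-history strategies

Two scale-free investment indices place each genome in a plane:

* regulatory flexibility = transcription factors / total genes;
* resource acquisition = (secreted CAZymes + secreted proteases + secreted
  lipases + biosynthetic gene clusters) / membrane transporters.

A zero denominator leaves the index undefined and the profile flagged —
never silently zero. A labelled training set (canonically 27 genomes, 9
per strategy) is standardized per axis (z-scores fitted on the training
data; the two indices differ by orders of magnitude, and the scaling is
recorded in the model and switchable off) and clustered by k-means with
k = 3 and 25 seeded restarts. Each centroid takes the majority label of
its members (ties broken by the nearest training point); if the three
centroids do not end up with three distinct labels the training set is
rejected. Training rows are canonically sorted before clustering, so the
model is a pure function of the row *set*. New genomes are assigned to the
*fixed* trained centroids by Euclidean distance in the standardized space
— never re-clustered jointly — so assignments are stable as cohorts grow.
Exact ties are broken by the fixed label order (competitor, ruderal,
scarcity) and flagged. The shipped
`inst/extdata/training27_synthetic.tsv` is a synthetic stand-in generated
from the documented planted clusters; a real training table with the same
columns drops in directly.

## The synthetic-data generator

`simulate_profiles()` emulates a profile collection: per dataset and
taxon, detection is Bernoulli with a planted per-habitat probability, and
detected abundances are log-normal (right-skewed, like real relative
abundances) with a planted mean and dispersion, truncated at 100%. The
default dataset counts per habitat are the survey's (soil 10250,
engineered 16320, freshwater 11408, host-associated 165152, marine 13880,
non-marine saline and alkaline 1306, terrestrial non-soil 5039; freshwater
is derived from the pooled non-host non-soil total of 47953). The default
taxa plant two soil-preferring clades, a sediment-preferring clade, a
moderate generalist and a rare clade.

`simulate_genomes()` emulates the comparative-genomics inputs on the
default unbalanced six-class by seven-habitat design (1930 genomes,
including its empty cells, so empty-cell handling is exercised by
default). Continuous features are grand mean + class effect + habitat
effect + Gaussian noise. Because the factors are confounded in an
unbalanced design, an arbitrary class pattern would partly masquerade as a
habitat signal; the planted patterns are therefore the generalized
eigenvectors minimizing the share of each factor's variance explainable by
the other under the design-weighted metric, scaled so the genome-weighted
variances equal the requested percentage shares (out of a total of 100).
The emitted truth record carries the planted effects, the realized shares
and the residual class–habitat covariance, sufficient to compute expected
values of every downstream statistic without re-running the generator.
Binary features and traits are Bernoulli with planted logit terms (e.g. a
prevalence of 0.9 versus 0.1 is a 4.4-logit class offset); life-history
labels are drawn from a planted mixture with matching indices drawn from
the planted clusters.

What the generator does *not* emulate, and hence what green tests do not
establish about real data: compositional coupling between taxa within a
dataset (taxa are sampled independently), spatial/temporal autocorrelation
among datasets, sequencing-depth-dependent detection, taxonomy
misassignment, and correlated noise across genome features. Conclusions
about estimator behaviour under those violations require real-data
sensitivity analyses, not this suite.

## Numerical choices and problem sizes

* All randomized functions take explicit integer seeds, fan substreams out
  from them, and restore the caller's RNG state.
* Least squares uses QR with R's default rank tolerance; type III SS are
  clipped at zero against floating-point negatives.
* Reported percentages round half-up (2 decimals internally, 1 in
  reports); internal arithmetic is full precision.
* k-means: 25 restarts, 100 iterations; assignment ties compare squared
  distances within 1e-12.
* Test and acceptance problem sizes: 70–4000 datasets for profile
  properties and 10000 for the ubiquity-convergence check; the full
  1930-genome design for variance-share recovery and a ~600-genome
  scaled-down version for the logistic checks; 100 random small designs
  for the type III oracle; cohorts of 300–500 for strategy recovery.
  These sizes make the whole suite run in seconds while keeping binomial
  and F-distribution error bars well inside the asserted tolerances.

## Known limitations

* Type III main-effect percentages under the interaction model are
  unique-attribution shares, not marginal variance shares; with heavy
  unbalance the two differ substantially (see above), and results should
  always state which model produced them (the package records it in every
  result object).
* The empty-cell convention (drop unestimable interaction columns from the
  full model) matches R's `car::Anova` behaviour; other software resolves
  empty cells differently, and type III values there may differ.
* Genome-based breadth uses class-level taxonomy unless a full lineage
  column is supplied.
* The profile aggregation assumes sub-lineage abundances are additive
  within a dataset; profilers that report ranks independently may violate
  this, in which case aggregate at the rank of interest upstream.
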