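---
title: "Proximal pathway enrichment analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximal pathway enrichment analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxea)
```

## The problem

Conventional pathway enrichment calls a pathway relevant to a disease when
the disease's genes overlap the pathway's member list more than chance
would allow. Because disease-gene and pathway annotations are both sparse
and incomplete, this overlap criterion misses pathways whose genes sit
*next to* the disease genes in the protein-protein interaction network
(the interactome) without literally sharing members. This package takes
the network view: a pathway matters to a disease when its genes are
unusually *close* to the disease genes in the interactome, and a drug is a
candidate for a pair of comorbid diseases when the pathways its targets
are close to are the pathways the two diseases share.

## Closest-distance proximity and the degree-matched null

For gene sets $S$ (sources) and $T$ (targets) on an interactome $G(V,E)$,
the proximity is the average hop distance from each source gene to its
nearest target gene:

$$d(S,T) = \frac{1}{|S|}\sum_{u \in S}\min_{v \in T} d(u,v).$$

The measure is deliberately asymmetric; every caller in this package fixes
the direction first-argument → second-argument (disease → pathway, drug
targets → pathway). Raw distances are not comparable across sets because
high-degree proteins are close to everything, so the observed value is
standardized against random gene sets that match $S$ and $T$ in size and
degree:

$$z(S,T) = \frac{d(S,T) - \mu_{d_{random}}}{\sigma_{d_{random}}},$$

with both endpoints resampled in every one of `n_random` realizations
(default 1000). Degree matching is implemented by binning nodes by exact
degree and merging adjacent degree classes until every bin holds at least
`min_bin_size` nodes; a random counterpart of a gene is drawn uniformly,
without replacement, from the gene's bin. A pathway is *significantly
proximal* at $z \le -2$, and the set of such pathways is the disease's
**pathway span**.

Parameters that matter:

* `n_random` (default 1000) — realizations of the null. The Monte-Carlo
  error of $\mu$ shrinks as $1/\sqrt{n_{random}}$; tests use 100–300 on
  toy graphs to stay fast, which is enough to resolve $|z| \approx 2$.
* `min_bin_size` (default 100) — the convention of the proximity
  literature, tuned to genome-scale interactomes of ~10⁴ nodes. On
  desk-scale graphs (a few hundred nodes) 100 leaves only two or three
  bins, which cannot control for hubs; the planted-drug screen benchmark
  therefore uses 25. The choice trades null fidelity (small bins) against sampling
  diversity (large bins).
* `z_cut` (default −2) — the conventional significance threshold; exposed
  because span sizes are sensitive to it.

If every null realization returns the same distance ($\sigma = 0$, e.g.
when a set is alone in its degree bin on a symmetric graph), the z-score
is undefined; it is flagged `NA` and treated as not significant rather
than forced to $\pm\infty$.

Genes absent from the interactome are dropped with a warning and recorded
in the result (`dropped_genes`); the analysis proceeds while at least one
gene survives on each side.

### Performance

Scoring a pathway collection evaluates `n_random + 1` closest distances
per pathway. For graphs up to 5000 nodes the package precomputes the full
all-pairs distance matrix once ([precompute_distances()]) and runs the
null loop on integer vertex indices; beyond that size it streams
breadth-first searches, which is slower but needs no $O(n^2)$ memory.
Both paths compute the same statistic; they consume random numbers
differently, so fixed-seed results are reproducible within a path, not
across paths.

## Random walk with restart: the alternative engine

The second proximity engine propagates a unit of probability from the
source set: $s \leftarrow r\,e + (1-r)\,W^\top s$, with $W$ the
column-normalized adjacency, $e$ uniform over the seeds, restart
probability $r = 0.5$, and L1 convergence tolerance $10^{-6}$ (the
upstream walk-based tools do not publish their defaults; these are this
package's stand-ins, exposed as arguments). For a symmetric adjacency the
update is row-stochastic propagation, which does not conserve the L1 norm
exactly on irregular graphs, so the converged vector is renormalized to
sum to 1. The proximity statistic is the mean visit probability over $T$;
its z-score against the same degree-matched null is *negated* so that
"more proximal" is more negative and the single $z \le -2$ convention
serves both engines.

## PxEA: scoring drugs against shared disease pathways

Given a ranking $D$ of all pathways by proximity to a drug's targets
(most proximal first) and a pathway set of interest $C$ (typically the
intersection of two diseases' pathway spans), walk down the ranking and
accumulate

$$X_i = \begin{cases} \dfrac{|D|-|C|}{|C|} & p_i \in C\\[6pt]
-\dfrac{|C|}{|D|-|C|} & \text{otherwise.}\end{cases}$$

The enrichment score is the maximum prefix sum, floored at zero. The plain
total $\sum_i X_i = |D| - 2|C|$ is the same for every ranking, so only a
rank-sensitive reading of the running sum can discriminate drugs; the
maximum prefix sum is the GSEA-style choice and reproduces the published
score scale (bounded by $|D|-|C|$, attained exactly when all of $C$
occupies the top $|C|$ ranks). Ranking ties are broken by observed
distance and then pathway id so screens are bit-reproducible.

Significance comes from shuffling the ranking uniformly (`n_perm` =
10,000 by default): $p$ is the fraction of shuffles whose score *strictly
exceeds* the observed one, with no pseudocount, so the smallest reportable
nonzero p is $1/n_{perm} = 10^{-4}$ and an unbeatable score is stored as 0
and printed as a bound ("< 1e-4"). Whether ties should count toward p is
ambiguous; the strict inequality is applied literally. Across a drug
library, p-values are Benjamini–Hochberg adjusted and drugs sharing an
identical usable target set share one ranking and score.

## The diseasome builder

Disease–disease links are evaluated over four independent evidence
channels, each with its own statistic: shared genes and shared symptoms
(two-sided Fisher's exact test on the overlap, $p \le 0.05$; symptoms are
first filtered to literature-mining TF-IDF scores strictly above 3.5),
comorbidity (relative risk $RR = C_{ij}N/(P_iP_j) > 1$ from a claims
count table), and shared pathway spans (two-sided Fisher over the pathway
collection, $p < 0.05$, strict, following the published wording for this
channel). A pair is connected when any channel fires. Design choices the
sources leave open: the symptom universe is the union of post-filter
symptoms across the loaded profiles; the pathway universe is the size of
the pathway collection; relative risk is the plain ratio without
continuity correction; local clustering of degree-0/1 nodes is 0 so the
average is defined. Comorbidity is consumed as a count table, not raw
claims records.

## What the synthetic generators emulate

* `toy_interactome()` — Barabasi–Albert graphs reproduce the heavy-tailed
  degree distribution of real interactomes at desk scale;
  Erdos–Renyi graphs serve as the structureless control. Generation
  retries until connected, so the graph equals its own largest component.
* `plant_disease_module()` — snowball-sampled connected sets emulate the
  tendency of disease genes to aggregate in interactome neighborhoods.
  Benchmarks use modules of size 30 on 500-node graphs, a desk-scale
  stand-in for curated disease gene sets (tens of genes).
* `gold_standard_pathways()` — pathways that are true but incomplete:
  random $k\%$ subsets of a disease's genes ($k \in
  \{10,25,50,75,90\}$, 10 replicates each), with sizes rounded half-up
  and floored at one gene. Paired size-matched uniform-random controls
  carry no signal by construction (plain random, not degree-matched,
  following the published control design). With two diseases this yields
  the stated 100 gold pathways. Gold z-scores should sit below −2 at
  every $k$ and deepen as $k$ grows; control z-scores hover near zero.
* The planted-drug screen benchmark uses 30 *disjoint* 6-gene pathways,
  three of which form $C$; the planted drug targets four genes in each
  pathway of $C$ and decoys target random genes. Disjointness matters:
  when pathways are allowed to overlap the drug's targets by chance, a
  "random" pathway can legitimately contain targets and outrank members
  of $C$, which tests a property of the generator rather than of the
  method.

What a green synthetic suite does **not** establish: performance on real
interactomes (which are 40× larger, noisier, and have correlated
annotation errors), robustness to systematic study bias in disease-gene
data, or the clinical plausibility of any repurposing candidate. The
fixtures reproduce published summary numbers (network metrics, overlap
test, gene counts) exactly, but pathway spans and drug scores on public
databases depend on database releases and are out of scope here.

## Numerical conventions

* Fisher's exact test: one-sided enrichment is the upper hypergeometric
  tail; the two-sided p sums the probabilities of all same-margin tables
  whose point probability does not exceed the observed one (the mainstream
  convention; validated against exhaustive enumeration in the tests).
* Benjamini–Hochberg: standard step-up with monotonicity enforcement,
  capped at 1. Note BH is *not* idempotent — re-adjusting adjusted values
  inflates them further — so adjusted p-values are computed exactly once
  per family.
* Determinism: every stochastic function takes a `seed`; seeded calls
  restore the caller's RNG state. Wherever iteration order could leak RNG
  state (bins, node pools, pair enumeration) the order is fixed
  lexicographically.
* Degenerate inputs: empty sets after interactome filtering are errors;
  pathways with no gene in the graph are skipped with a warning; scoring
  an empty pathway set of interest is an error ($X_i$ undefined at
  $|C| \in \{0, |D|\}$).

## Known limitations

The closest-distance statistic ignores edge weights and interaction
direction; the degree-matched null controls degree only at bin
resolution; the RWR engine requires an explicit restart parameter that
published work leaves unstated; and the screen treats a drug as the set
of its targets, with no dosage, affinity, or adverse-event information.
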