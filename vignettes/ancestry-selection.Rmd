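---
title: "Detecting recent selection from local ancestry in admixed cohorts"
author: "admixsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent selection from local ancestry in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixsel)
```

## The problem

Recently admixed populations — Mexicans, for example, a roughly
50/45/5% mixture of Amerindian, European and African ancestry formed
over the last ~20 generations — offer a uniquely sensitive window on
very recent positive selection.  In the absence of selection, the
expected proportion of each ancestry is constant along the genome.  A
locus where one ancestry's frequency departs strongly from its
genome-wide average is therefore a candidate for selection acting since
admixture: selection on an allele that is common in one ancestral
population drags that ancestry's local frequency up with it, a signal
that accumulates over tens of generations rather than the thousands
required for classical sweeps.

`admixsel` implements this scan end to end: a forward simulator of
admixture under selection, a local-ancestry model whose fitting scheme
tolerates a missing reference panel, the standardized dosage scan, and
selection-coefficient estimation from the observed dosage excess.

## The two-layer cluster model

Local ancestry is inferred with a hierarchical haplotype-cluster hidden
Markov model.  The latent state at marker $m$ is a pair $(s, j)$: an
*upper* cluster $s \in \{1,\dots,S\}$ representing the ancestral
population of the segment, and a *lower* cluster $j$ — a contemporary
haplotype group — nested within that ancestry.  Emission is Bernoulli:
cluster $j$ carries an allele-1 frequency $\theta_{mj}$.  Between
adjacent markers at map distance $d$ Morgans the upper state switches
with probability $1 - e^{-g d}$, where $g$ is the number of generations
since admixture (default 20); the arrival ancestry is drawn from the
individual's admixture proportions, so upper-state switch points mark
ancestry breakpoints laid down by recombination since admixture.
Conditional on staying within an ancestry, the lower state switches
among that ancestry's clusters with probability $1 - e^{-\lambda d}$;
$\lambda$ (default 100 per Morgan) sets the haplotype-block scale of
background linkage disequilibrium.  Defaults are $S = 3$ upper and 15
lower clusters divided evenly (5/5/5), which works well for three-way
admixture at GWAS marker densities.

Unphased genotype input is handled exactly by an ordered product-state
chain over haplotype pairs with phase integrated out; phased input uses
the single chain and is the fast path.  Because a phasing switch error
merely exchanges the two haplotypes' suffixes, an individual's summed
ancestry dosage is essentially unaffected by switch errors — which is
why the simulator injects them and the tests verify the scan is robust
to them.

## Weighted EM and the missing-panel trick

Parameters are fitted by EM.  The M-step update of $\theta_{mj}$ is the
posterior-weighted allele frequency; with training (reference-panel)
haplotypes and cohort haplotypes fitted jointly, the update generalizes
to give training samples weight $w_t$ and cohort samples $w_c$:

$$
t_j \;=\; \frac{w_t \sum_{i \in T_1^{(t)}} q_{ij} + w_c \sum_{i \in T_1^{(c)}} q_{ij}}
               {w_t \sum_{i \in T_0^{(t)} \cup T_1^{(t)}} q_{ij} + w_c \sum_{i \in T_0^{(c)} \cup T_1^{(c)}} q_{ij}},
$$

where $q_{ij}$ is the marginal posterior that haplotype $i$ is emitted
from cluster $j$ at the marker and $T_k$ splits haplotypes by their
allele.  Two limits matter.  With $w_t = w_c$ the update reduces to the
ordinary unweighted estimator.  With no training haplotypes present in
a cluster the weight cancels entirely, so the frequencies of an
ancestry that has *no* reference panel are estimated purely from the
cohort.  This is what lets the model run with a panel absent: reliable
Amerindian reference haplotypes are scarce, so the model can learn the
Amerindian clusters from a Mexican cohort itself while European and
African panels anchor the other two ancestries.

The default weights are $w_t = 1$ and
$w_c = \min(0.1,\, n_\text{training} / n_\text{cohort})$.  The cap
matters: with $w_c$ comparable to $w_t$, cohort segments that leak into
an anchored ancestry's clusters drag those cluster frequencies away
from the panel, and we measured the African average-dosage error rising
from ~0.02 to ~0.24 on simulated three-way cohorts when the weights
were equal.  Keeping $w_c \ll w_t$ pins anchored clusters to their
panels while leaving unanchored ancestries (where the weight cancels)
untouched; users can override both weights.

### Initialization and restarts

EM on this model has real local optima, and the fit averages dosage
fields over `em_runs = 10` independent restarts of `em_steps = 20`
iterations (label switching among unanchored ancestries is resolved by
greedily matching dosage-field correlations across runs; anchored
ancestries are fixed by construction).  Initialization is chosen per
cluster:

* anchored clusters start at `0.7 * panel frequency + 0.3 * U(0.2, 0.8)`;
* in partial mode, each free cluster is seeded from a *randomly drawn
  cohort haplotype* (plus the same uniform jitter).  Seeding from real
  haplotypes gives the learned ancestry sharp, LD-coherent clusters
  from the first iteration.  This is not cosmetic: with diffuse random
  starts the training-anchored clusters are systematically "sharper"
  than the learned ones, the likelihood prefers solutions that assign
  Amerindian segments to African clusters, and the African dosage error
  at the selected locus triples;
* in structure mode (no panels at all) admixture proportions and free
  cluster frequencies are seeded from a k-means split of the cohort —
  from a flat start EM stalls at the symmetric saddle where no
  individual polarizes, while the k-means start separates merged
  source panels completely.

$\theta$ is clamped to $[10^{-4}, 1 - 10^{-4}]$ so no observation has
probability zero; clusters with zero occupancy at a marker retain their
previous frequency with a warning.  Per-individual admixture
proportions are re-estimated each M-step from posterior upper-state
occupancy (floored at $10^{-8}$); missing genotypes are marginalized
out of the emission.  The weighted observed-data log-likelihood is
non-decreasing across iterations up to these numerical floors, and the
test suite checks it.

## The scan

Per-individual ancestry dosages (expected count of haplotypes of each
ancestry, scale $[0,2]$, summing to the ploidy at every marker) are
averaged over individuals; with family data the package averages family
members first and then families, so each family counts once regardless
of size.  Per ancestry the scan computes the genome-wide mean and
sample standard deviation (ssd, denominator $n-1$) of the per-marker
averages and reports $z = (\text{avg} - \text{mean})/\text{ssd}$.  A
one-sided upper-tail normal p-value is attached as a descriptive
transform only — the z-score is the primary statistic, since average
dosages at linked markers are strongly dependent and the normal tail is
not a calibrated test.  The selected region (marker set A) is the set
of markers whose average dosage exceeds a threshold on the dosage
scale; the derived phenotype of an individual is its mean dosage over
A.  Genome-wide mean and ssd include the selected region by default
(matching the scan's genome-wide definition); an `exclude` option
supports sensitivity analysis.

## Estimating the selection coefficient

Let $p_0$ be the genome-wide mean of the selected ancestry's average
dosage — a proxy for its level before selection — and $p_1$ the peak
average dosage at the selected locus, $n$ generations after admixture.
Three deterministic constant-population models link them:

* **simple**: $p_1 = p_0 (1+s)^n$, solved in closed form as
  $s = \exp(\log(p_1/p_0)/n) - 1$.  Scale-invariant, and because the
  normalized models grow strictly slower, it is a *lower bound* for the
  other two estimates.
* **dominance** (het and favoured hom both $1+s$):
  $f' = f(1+s) / (1 + (2-f) f s)$.
* **additive** (het $1+s$, favoured hom $1+2s$):
  $f' = f(1+s+fs) / (1 + 2fs)$.

The dominance/additive recursions act on allele frequencies, so dosages
are halved first.  $s$ is found by interval bisection on the bracket
$[0, 1]$ (doubled upward if needed), exploiting the strict monotonicity
of $f_n(s)$ in $s$, to a frequency residual below
$\epsilon = 10^{-8}$; the ordering
$s_\text{simple} < s_\text{additive} < s_\text{dominance}$ holds for
every feasible input pair and is enforced by tests.  Reported values
are rounded to 3 decimals; the full-precision estimate stays in the
returned object.

## The simulator

The generator mirrors the study conditions end to end and retains
ground truth.

**Source populations.**  Three panels share a marker grid (default
3 Mb, 1 cM/Mb, 1000 SNPs/cM).  Per-SNP frequencies follow a
Balding–Nichols hierarchy around a shared ancestral frequency drawn
uniformly on $(0.05, 0.95)$, with per-population differentiation $F$
(default 0.12, a realistic continental value).  Haplotypes are built by
a founder-mosaic copying process over a small founder panel (default
20), switching founders at rate 100/Morgan, and founder alleles follow
a latent AR(1) Gaussian copula along the map, so the panels carry both
haplotype-sharing structure and genuine marker-to-marker LD while
keeping exact Balding–Nichols marginals.  Because the founder panel is
itself a finite draw, the realized Hudson-style $F_{ST}$ between two
panels is approximately the mean of their $F$ values plus $(1-F)/K$
founder drift; the tests verify this.

**Admixture and selection.**  After setting aside 200 training
haplotypes per population, generation 0 draws a 50,000-haplotype pool
at proportions 0.50/0.45/0.05.  The region is split into three segments
by two recombination hotspots (per-generation crossover probabilities
configurable; study values 0.1, 0.2, 0.5), so a haplotype is a triple
of founder segments and ancestry labels propagate exactly.  Each
generation, 25,000 times: draw two haplotypes with replacement —
weighting a haplotype $1+s$ if its mid-section ancestry is the selected
(African-proxy) one, i.e. haploid viability selection, consistent with
resampling haplotypes rather than diplotypes — cross over independently
at each hotspot, and emit both recombinants.  After 20 generations,
2,000 haplotypes are drawn without replacement and paired consecutively
into 1,000 cohort diplotypes.  The mid-section (selected) segment is
0.5 Mb by default — the harder of the two study sizes.  Switch errors
are injected by initiating, at each heterozygous site left to right
with the configured probability (2% cohort/Amerindian-proxy panel, 1%
European/African-proxy panels), an exchange of the two haplotypes'
suffixes; genotypes are provably unchanged.

The pool-level frequency of the selected ancestry's mid-section follows
the haploid recursion $p' = p(1+s)/(1+ps)$ up to drift; the tests
check agreement within three accumulated-drift standard errors, where
early-generation binomial noise is propagated through the recursion
(naively summing per-generation variances would understate the spread,
since drift that arises early is amplified by later selective growth).
Hitchhiking is real but mild: with crossover probability 0.2 and
$s = 0.10$ the flanking segments' African frequency rises by about
0.03 — worth remembering when treating the flanks as a neutral
baseline.

**What the simulator does not emulate.**  No mutation, no population
growth, no multi-pulse admixture, no sex chromosomes, and recombination
only at the two hotspots; the source populations are a parametric
stand-in, not a demographic model of the out-of-Africa expansion.
Passing tests on these simulations show the estimator recovers truth
under the model's own assumptions — they do not certify performance
under real LD landscapes, array ascertainment, or genotyping error.

## Problem sizes used by the test suite

The package's documented reduced scale is a 5,000-haplotype pool, 600
markers (200 SNPs/cM over 3 Mb), 200 cohort diplotypes and 200 training
haplotypes per population, with crossover probability 0.2.  At that
scale, inference with the Amerindian-proxy panel withheld recovers the
mid-section African average dosage within 0.05 of truth for
$s \in \{0.02, 0.05\}$, while at $s = 0.10$ any residual bias is
downward — conservative for detecting selection.  Most unit tests run
smaller still (300 markers, 100–150 diplotypes, 2–6 EM runs); the
simulator calibration check runs at the full 50,000-haplotype pool,
which is cheap because haplotypes stay segment-coded until cohort
materialization.

## The pipeline's region rule

At desk scale the real-data rule "flag markers more than 4 ssd from the
mean" is uninformative: the simulated selected region is one sixth of
the whole region, so it inflates the genome-wide ssd itself and caps
attainable z-scores near 2.  The pipeline therefore calls the region on
a lightly smoothed average-dosage track (default window ~1/120 of the
markers, at least 5): if the smoothed peak exceeds the genome-wide
median by less than a margin (default 0.10 dosage units, comfortably
above neutral drift at the reduced scale) it reports *no
positive-selection signal*; otherwise it calls all markers above the
midpoint of median and peak, takes $p_0$ as the genome-wide mean,
$p_1$ as the smoothed peak, and estimates $s$ under all three models.
An explicit dosage threshold can replace the adaptive rule — on real
data, where the selected region is a tiny fraction of the genome, a
fixed threshold such as "average dosage above 0.30" is the natural
choice.

## Known limitations

* The transition parameterization (exponential switch rates, fixed
  $\lambda$) is a standard admixture-HMM form chosen for this
  implementation; it is not calibrated to any particular software's
  internals, and no recombination-map estimation is exposed.
* Selection-coefficient estimates are deterministic inversions: no
  drift correction, no confidence intervals, no time-series modelling.
  With 20 generations and realistic cohort sizes the dominant error is
  in $p_0$ and $p_1$ themselves.
* Partial-mode estimates are averaged over EM restarts; individual
  restarts can still find poor optima, and at the strongest selection
  simulated ($s = 0.10$) the learned-ancestry fit biases the African
  peak downward rather than upward.
* The scan's p-values are descriptive transforms of z, not calibrated
  tail probabilities.
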