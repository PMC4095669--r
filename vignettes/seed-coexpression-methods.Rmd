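---
title: "Seed-set coexpression analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-set coexpression analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcoex)
```

## The question the method answers

Groups of genes that work as one physical machine — the canonical example
being the subunits of the mitochondrial respiratory complexes (MRC),
complexes I–V of oxidative phosphorylation — tend to be transcribed in a
coordinated way. seedcoex treats such a group as a single *seed set* and
asks, for every other gene in the transcriptome, whether its coexpression
neighbourhood overlaps the seed set more than chance allows. Genes that
pass are the seed set's coexpression *friends*: candidates for shared
regulation, assembly factors, or pathway partners. Running the same
analysis on a second condition (say, chemically treated hepatocytes versus
a panel of normal tissues) and differencing the friend sets shows which
parts of the coordinated program a perturbation dismantles.

## Network model

Given a gene-by-sample expression matrix, all pairwise Spearman rank
correlations $\rho_{gh}$ are computed, and an undirected edge is placed
between $g$ and $h$ when $\rho_{gh} \ge t$ with threshold $t = 0.3$ by
default. Two readings of that rule are possible and both are exposed:

* `edge_rule = "signed"` (default): literally $\rho \ge t$, so strong
  *negative* correlations never form edges;
* `edge_rule = "absolute"`: $|\rho| \ge t$, admitting them.

Spearman is the default because rank correlation is invariant under any
monotone rescaling of each gene — a useful robustness property across
heterogeneous tissue panels — with Pearson selectable via `method`. Ties
are handled by average ranks, the standard convention. Isolated genes stay
in the network universe: the universe is "genes assessed", and its size $N$
is exactly the population size used by the statistic below.

Two data-hygiene rules keep every pairwise correlation comparable: rows
with any missing value are dropped at read time (so each pair is computed
over the same samples and $N$ is unambiguous), and constant rows are
removed (`filter_uninformative()`) because rank correlation is undefined
for them. When several probes map to one symbol, the probe with the highest
mean expression is kept, ties broken by probe id — a deterministic rule
that needs no state beyond the platform map.

## The seed-connectivity statistic

For a gene with degree $n$, of which $k$ neighbours lie in the seed set,
significance is the upper tail of the hypergeometric distribution,

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

i.e. the probability of drawing at least $k$ seed genes when the gene's $n$
neighbours are sampled without replacement from the $N$-gene universe
containing $K$ seeds. Three conventions are fixed here:

* **Self-exclusion.** A gene is never its own neighbour, so it is removed
  from its own population: $N_\mathrm{eff} = N - 1$, and for a seed gene
  also $K_\mathrm{eff} = K - 1$. Seed genes are therefore scored against
  the *other* seeds, which is what makes the *seed self-connectivity*
  analysis (which seeds belong to the coordinated core of their own
  module) well defined.
* **Inclusive upper tail.** $P(X \ge k)$ includes the observed count — the
  standard enrichment reading.
* **Strict cutoff.** A gene is a friend when $p < \alpha$ with
  $\alpha = 10^{-8}$ by default; no multiple-testing correction is applied
  to the call, matching the fixed-threshold convention for this statistic.
  Benjamini–Hochberg values are attached as a `q_value` column for users
  who want them, and a `log10_p` column preserves magnitudes past
  floating-point underflow.

The tail is evaluated in log space from log-gamma binomial coefficients,
so p-values far below $10^{-300}$ remain meaningful (seed-scale instances
routinely reach $10^{-50}$ and below). The test suite holds this
implementation to an independent exact-integer enumeration of the same sum
(error-free double-double arithmetic over Pascal-triangle binomials) across
every valid instance with $N \le 60$, at relative error below $10^{-10}$.

$K$ is always the *effective* seed size $|{\rm seed} \cap {\rm universe}|$
and $N$ the actual universe size — not nominal platform counts — so the
test is conditional on what was actually measured.

## Differential comparison

Friend calling is a thresholded decision, and the cross-condition
comparison respects that: a gene is "lost under treatment" when it is a
friend in condition A and not in B, by set arithmetic on the two member
lists (`compare_friend_sets()`), with the same partition applied to seed
self-connectivity (`compare_seed_self_connectivity()`). No significance
test is attached to the difference itself — a gene sitting at
$p = 10^{-8.1}$ versus $10^{-7.9}$ is a borderline flip, and the package
deliberately reports it as such rather than dressing the partition up as
inference. For graded inspection, `compare_pvalues()` emits the per-gene
$\log_{10}$ p-value shift as a supplementary table.

Genes measured in only one condition cannot be classified — absence of
evidence is not loss of coexpression — so they are flagged
`unassessable` instead of being binned into a condition-specific set.

## Enrichment

Friend lists are annotated by over-representation against user-supplied
GMT collections. The test is the one-sided Fisher exact probability of the
$2\times 2$ table — the same hypergeometric tail with arguments
(overlap, list size, term size, population size) — with the EASE
modification on by default: one observed success is removed before taking
the tail, the conservative convention of the DAVID annotation tool, whose
practical effect is that a single-gene overlap can never look significant.
The population defaults to the gene universe actually assessed by the
network, not the whole annotation namespace; terms are restricted to that
population before counting, overlaps below `min_count = 2` are dropped,
and Benjamini–Hochberg adjustment is computed over the reported rows.
Ontology structure (GO DAG propagation, pathway topology) is out of scope:
collections are treated as flat gene sets.

## The synthetic data generator

Real tissue-panel and treated-hepatocyte matrices are large external
downloads, so validation runs on a generator whose ground truth is known
exactly. The model is a single shared factor: per sample,
$f \sim \mathcal N(0,1)$ and each gene has expression
$a_g f + \varepsilon$, $\varepsilon \sim \mathcal N(0, \sigma^2)$, with
$a_g$ = `loading_seed` for seed genes, `loading_friend` for designated
friend genes, 0 for background. This is the simplest generative law that
produces the block-correlated module the analysis assumes, and it gives
closed-form pairwise correlations for testing:
$\mathrm{corr}(g,h) = a_g a_h / \sqrt{(a_g^2+\sigma^2)(a_h^2+\sigma^2)}$.

Defaults are the study conditions the generator emulates: 65 samples in
the normal condition and 130 in the treated one (the scale of a
65-tissue expression panel versus a 130-compound treatment profile), a
56-gene seed set, 200 true friends, loadings 0.9 (seed) and 0.8 (friend),
unit noise. The universe defaults to 2,000 genes — large enough that
background genes dominate and the hypergeometric population is realistic,
small enough that a full paired replicate (two networks plus two
genome-wide test passes) runs in about a second, which is what lets the
test suite afford 20-replicate recovery experiments and the acceptance
script 10. Loadings have no measured counterpart in real MRC data; 0.9/0.8
were chosen once as "strong module, slightly weaker periphery" and are not
revisited.

Treatment is modelled as decoupling: disrupted genes have their loading
set to zero in the treated matrix (coexpression *disappears*, rather than
being noised). Which genes are disrupted is deterministic — the first
$\lceil d \cdot |{\rm seeds}| \rceil$ seed genes and the first
$\lceil d \cdot |{\rm friends}| \rceil$ friend genes in sorted id order —
so truth is reproducible from the configuration alone, and a partial
disruption always leaves both intact and disrupted genes in *each* role;
a prefix over the pooled module would let moderate fractions wipe out one
role entirely and make the disrupted-seed recovery analysis degenerate.

What the generator does **not** emulate: probe-level artifacts,
normalization and batch effects, dose–response structure across
treatments, negative correlation blocks, and any between-gene dependence
beyond the one factor. Passing recovery tests on this model therefore
demonstrates that the pipeline's bookkeeping and statistics are right, not
that the thresholds are optimal for any particular real platform.

## Finite-sample behaviour worth knowing about

With 65 samples, the sampling standard deviation of a correlation between
a pure-noise gene and the latent factor is roughly $1/\sqrt{62} \approx
0.13$. Out of ~1,700 background genes, a handful per replicate will
therefore align with the factor at $\hat\rho \gtrsim 0.3$ by chance — and
because that alignment is with the *factor*, such a gene gains edges to
dozens of seed genes at once and reaches a very small hypergeometric
p-value. The package's replicated recovery tests show this directly: seed
and friend recall exceed 0.9 comfortably, while the background
false-positive count at $\alpha = 10^{-8}$ is a few genes per replicate,
never zero. These genes are genuinely coexpressed with the module *in the
realized sample*; the statistic is exact conditional on the network (the
pure-null simulation, with no module at all, yields zero calls at
$10^{-8}$ across 20 replicates). The practical reading: at tissue-panel
sample sizes, a friend list is a high-recall candidate list whose tail can
contain factor-aligned noise genes, and raising the sample count — not the
cutoff — is what shrinks that tail.

## Numerical and degenerate-input choices

* Tail sums use running log-sum-exp anchored at the largest term;
  $P(X \ge 0)$ is returned as exactly 1.
* `p_value` may underflow to 0 below about $10^{-320}$; `log10_p` is the
  authoritative magnitude and is written to every friend table.
* Constant vectors are an error in `spearman_rho()` (not `NA`): callers
  must filter first, which keeps silent `NA` edges out of the network.
* Threshold bounds are $(0, 1]$; a zero threshold would connect everything
  and is rejected as a configuration error.
* Edge files store pairs in canonical lexicographic order with a comment
  header carrying the build settings, and the node list is written
  alongside so isolated genes survive a round trip.
* All randomness flows from one integer seed per run; identical
  configurations reproduce byte-identical outputs (this is asserted, not
  aspirational).

## Known limitations

* The comparison is threshold-based, so hard-to-call genes near
  $\alpha$ flip between conditions; consult `compare_pvalues()` before
  interpreting small condition-specific sets.
* Edges are binary once thresholded; correlation strength does not weight
  the statistic.
* No WGCNA-style soft thresholding, module detection, or edge p-values —
  deliberately out of scope.
* Enrichment ignores ontology structure and treats terms independently.
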