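---
title: "Curating orthogroups for phylogenomic inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating orthogroups for phylogenomic inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogcurator)
library(dplyr)
```

## The problem

Phylogenomic datasets assembled from hundreds of single-copy orthogroups
(OGs) are only as reliable as their weakest genes. Three artifact classes
dominate in practice:

* **long-branch genes** — an ortholog misassignment, contamination, or a
  burst of rate acceleration stretches one terminal branch far beyond the
  rest of the tree, priming long-branch-attraction artifacts;
* **strongly supported clan violations** — a gene tree that breaks the
  monophyly of a taxonomic order *with high bootstrap support* usually
  reflects hidden paralogy or noise rather than genuine discordance;
* **saturated or low-diversity genes** — multiple substitutions per site
  erase signal, and near-invariant genes carry none to begin with.

`ogcurator` implements the corresponding three-stage screen, builds the
partitioned supermatrix from the survivors, and ships the companion
diagnostics used to sanity-check a finished phylogeny: posterior-predictive
adequacy statistics, gene concordance factors, pairwise Ka/Ks summaries and
Fisher-exact macrosynteny blocks. A seeded synthetic-data generator plants
each artifact class with truth labels so the whole cascade can be
benchmarked end to end.

## The curation cascade

### Stage 1: long terminal branches

For a gene tree with branch-length set $B$ (terminal and internal,
zero-length branches included), let $m = \mathrm{median}(B)$ (even counts
use the mean of the two central values). The gene is excluded when any
*terminal* branch not leading to an outgroup taxon has length
$\ell \ge r \cdot m$ with ratio threshold $r = 20$ by default; the
threshold is inclusive ("20 times or longer"). Internal branches never
trigger exclusion: the screen targets terminal-branch artifacts, and long
internal branches are legitimate signal. Outgroup terminals are exempt
because outgroups are expected to be distant.

Degenerate cases are explicit rather than silent: a tree whose branches
are all zero is retained (no signal, but no long branch either), while a
zero median alongside a positive ingroup terminal is excluded with reason
`"degenerate median"` — the ratio is unbounded and the tree is
pathological. The statistic recorded in the verdict is the maximum
terminal/median ratio, which makes the filter scale-invariant: multiplying
every branch by a constant changes nothing.

### Stage 2: clan monophyly

A *clan* is the unrooted analogue of a monophyletic group: one side of a
branch bipartition. Each taxonomic order with two or more sampled species
is declared a clan. A bipartition $X \mid Y$ is *incompatible* with clan
$C$ when clan members sit on both sides and non-members are mixed among
them on both sides (formally: $C \cap X$, $C \setminus X$,
$X \setminus C$ and $Y \setminus C$ all non-empty). The verdict per clan:

* **satisfied** — no bipartition is incompatible (for binary trees this is
  exactly "the clan is one side of some branch");
* **strong violation** — some incompatible branch has support $> 50$;
  equivalently, the clan is still not realizable after collapsing all
  weakly supported branches into polytomies;
* **weak violation** — every incompatible branch is weak
  (support $\le 50$).

Strong violations are excluded (high support means the conflict is real —
likely paralogy), weak violations retained (low support means the conflict
is probably noise). Support exactly 50 counts as weak: exclusion requires
support *above* the threshold. Missing support on an internal branch is
treated as 0 and logged — the conservative reading that matches the
benefit-of-the-doubt retention rule. A gene is excluded when *any* clan is
strongly violated; clans are evaluated independently. When several
branches conflict, the recorded statistic is the maximum conflicting
support — one consistent reading of an underspecified convention, chosen
because it is the support that actually drove a strong verdict.

The cascade short-circuits: a gene excluded at stage 1 receives no clan
verdict, so each exclusion has exactly one responsible stage.

### Stage 3: saturation ranking

After trimming alignment columns whose gap fraction reaches 0.5 ("half or
more of the taxa"), every ingroup taxon pair $(i, j)$ of a gene yields an
observed difference proportion $p_{ij}$ over comparable columns (both
residues real — neither gap nor `X`), hence a percent identity
$100(1 - p_{ij})$ and a multiple-hit-corrected distance under the
20-state symmetric (Poisson-type) model:

$$d_{ij} = -\tfrac{19}{20}\,\ln\!\bigl(1 - \tfrac{20}{19}\,p_{ij}\bigr),
  \qquad p_{ij} < \tfrac{19}{20}.$$

The saturation statistic is the OLS slope of identity (%) regressed on
$d$. The regression orientation is a design decision the source convention
leaves open; identity-on-distance is used because it makes "lowest slope =
identity decays fastest per unit distance = least saturated, most diverse"
internally consistent. A clean gene loses identity steeply with distance
(strongly negative slope); a saturated gene's identity flattens near its
random-expectation floor (slope near zero). Saturated pairs
($p \ge 19/20$) are dropped, not clamped — clamping would fabricate
high-leverage points. Outgroup pairs are excluded throughout.

Genes with a defined slope are sorted ascending (ties broken
lexicographically by gene id, for determinism) and the first
$\lfloor 0.5\,m \rfloor$ of the $m$ defined-slope genes are retained.
Undefined slopes (all-identical alignments, fewer than two usable pairs)
are never retained. The cut applies to the post-screening survivors, the
reading consistent with ranking "the top 50%" of an already-screened set.

In the original workflow the distances come from ML pairwise estimates and
the identities from local protein alignment; here both are computed from
the alignment itself. The ranking behaviour of the slope — not its
absolute value — is what drives retention, and the in-repo definition
keeps the statistic self-contained and exactly testable.

### Supermatrix

Retained genes are concatenated in input order over the union taxon set;
missing taxa are gap-filled per partition. Partition ranges are 1-based
inclusive (the RAxML partition-file convention), and the matrix reports
per-taxon occupancy plus variable and parsimony-informative site counts. A
column is variable with $\ge 2$ residue states, informative with $\ge 2$
states each in $\ge 2$ taxa; gaps and `X` are never states.

## Diagnostics

### Posterior-predictive adequacy

Two statistics summarize how well a substitution model's simulated
replicates reproduce the data:

* **site diversity** (`ppa_div`): mean number of distinct residue states
  per column;
* **compositional heterogeneity** (`ppa_max`): for each taxon $t$ with
  residue frequencies $f_{t,a}$ and global frequencies $\bar f_a$,
  $D_t = \sum_a |f_{t,a} - \bar f_a|$, maximized over taxa.

The package never runs an MCMC: replicate ensembles are supplied as
alignments (from files or the simulator), and adequacy is judged by
$Z = (\text{obs} - \overline{\text{rep}}) / \mathrm{sd}(\text{rep})$, with
smaller $|Z|$ indicating better fit. The $L_1$-max form of the
heterogeneity statistic is stated explicitly so results are reproducible;
it is a transparent stand-in for tool-specific variants of the same idea.

### Concordance factors

For each internal branch of a binary reference tree, with incident
subtrees $(S_1, S_2 \mid Y_1, Y_2)$, a gene tree is decisive when it
carries at least one taxon from each of the four subtrees. Among decisive
trees, gCF is the percentage displaying the reference split, gDF1/gDF2 the
percentages displaying the two nearest-neighbour-interchange alternatives,
and gDFP the paraphyletic remainder; the four always sum to 100. The
one-taxon decisiveness rule is the standard one; numeric parity with
IQ-TREE's implementation is expected on full-taxon binary gene trees.
`classify_discordance()` applies the same logic per gene at one focal
branch, yielding the `gD1`/`gD2` gene classes used to build
alternative-topology datasets.

### Pairwise Ka/Ks

Rates are estimated with the Nei–Gojobori (1986) pathway-counting method
plus Jukes–Cantor correction. Conventions that matter:

* each codon position contributes one site, split synonymous :
  non-synonymous by the fraction of its possible single-nucleotide changes
  that preserve the amino acid, **nonsense changes disregarded** — the
  original formulation. This keeps $S + N = 3$ per codon exactly and makes
  neutral simulation (which must reject stop-producing mutations to stay
  in coding space) centre on $K_a/K_s = 1$;
* observed differences average over all minimal substitution pathways with
  equal weights; pathways through stop codons are excluded, and a codon
  pair whose pathways all hit stops is skipped;
* codons containing gaps, `N` or stops are skipped pairwise;
* $K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$, likewise $K_a$;
  $p \ge 3/4$ is an overflow, flagged rather than clamped.

The iterative Yang–Nielsen estimator is deliberately not re-implemented:
for ranking lineage-level rate differences, pathway counting preserves the
ordering at a fraction of the machinery, and the report records the
estimator name. Study-style discard rules ($K_s > 98$ or $K_s < 0.01$)
are applied after estimation with the reason stored — never silently.
Lineage means pool all gene-by-pair estimates (no per-gene averaging
first); with pairs as the unit of interest, pooling weights every
comparison equally and is the simpler estimand.

### Macrosynteny

For two genomes with one-to-one orthologs assigned to chromosomes, every
chromosome pair sharing at least one ortholog is tested for enrichment
with the one-sided Fisher exact test (upper hypergeometric tail), followed
by Benjamini–Hochberg correction across tested pairs at
$\alpha = 0.05$. One-sided because the question is conserved linkage
(enrichment), never depletion; BH because hundreds of pairs are tested and
false-discovery control is the convention for this screen; both choices
are recorded in the output. Pairs sharing zero orthologs are untested,
which keeps the correction burden honest. Gene order within chromosomes is
ignored — this is macrosynteny, not collinearity.

Significant links form a bipartite graph whose connected components are
classified: 1:1 components are conserved chromosomes, one B-chromosome
absorbing $\ge 2$ A-chromosomes is a fusion, one A-chromosome spread over
$\ge 2$ B-chromosomes is a fission, and anything more tangled is a
translocation candidate.

## The synthetic-data generator

The generator emulates exactly the statistical structure the screens
assume, with truth labels:

* **species trees** with uniform random topologies and exponential branch
  lengths (mean 0.08 substitutions/site by default — a typical
  intra-clade protein divergence scale), optionally constrained so every
  declared clan is monophyletic;
* **gene trees** as the species tree with mild lognormal rate jitter
  (sdlog 0.2), then one planted artifact per gene: a terminal stretched to
  25× the median (vs the 20× screen), a clan member regrafted outside its
  clan with all supports at 90 (strong) or 40 (weak) (vs the 50 rule), or
  all branches scaled 5× (saturated). Planted artifacts must be separable
  from background variation *by construction*, so natural terminal
  branches are clamped at 10× the median — a two-fold margin below the
  screen — before planting; only a planted long branch can cross the
  threshold. Supports are assigned, not estimated: the screens are
  agnostic to support provenance, and embedding a bootstrap engine would
  buy nothing;
* **alignments** evolved under the 20-state symmetric process, whose
  closed form $p = \tfrac{19}{20}(1 - e^{-20 d/19})$ is exactly inverted
  by the package's distance correction — the tests exploit this identity.
  An optional per-taxon composition skew (half the taxon's sites resampled
  from a 5-residue-concentrated pool) plants strong compositional
  heterogeneity for the adequacy tests;
* **codon pairs** evolved by proposal–acceptance: single-nucleotide
  proposals, stop-producing ones rejected, non-synonymous ones accepted
  with probability $\min(1, \omega)$ (and synonymous with
  $\min(1, 1/\omega)$), so $\omega = 1$ is neutral and $\omega = 0$ gives
  $K_a = 0$ exactly;
* **karyotypes** descending from an $n = 46$ ancestor (the chromosome
  number conserved across most of the decapodiform genomes that motivate
  this pipeline) with planted fusion, fission and translocation events —
  one fusion yields $n = 45$, one fission $n = 47$.

Everything is deterministic under a single integer seed; per-gene seeds
derive from (seed, gene index) so any subset regenerates identically, and
file outputs are byte-reproducible.

**What the generator does not emulate** — and hence what passing
benchmarks do and do not show: no indels (gaps only arise from missing
taxa), no among-site rate variation, no empirical amino-acid
exchangeabilities (LG-like structure), no incomplete lineage sorting
(gene trees differ from the species tree only through planted artifacts
and length jitter), and no support estimation error. Clean separation of
planted classes on this benchmark demonstrates that the filters implement
their definitions correctly, not that real data are this well-behaved;
on real alignments the slope ranking and support thresholds inherit all
the noise of the upstream inference.

## Numerical choices and degenerate inputs

* thresholds are inclusive where the source rule says "or longer" /
  "half or more" (long-branch ratio, gap fraction) and exclusive-above
  where it says "more than" (support 50);
* the 50% retention cut takes $\lfloor 0.5\,m \rfloor$ with
  lexicographic tie-breaks — deterministic by construction;
* undefined statistics (slopes, Ks) propagate as `NA` with a recorded
  reason and are never retained/used silently;
* all coordinates are 1-based inclusive; taxon matching is exact and
  case-sensitive (silent case-folding creates cross-file mismatches);
* Newick supports on a 0–1 scale are stored verbatim with a warning,
  never rescaled — a 0–1 file usually signals a unit mix-up upstream and
  silent rescaling would hide it.

## Problem sizes

The shipped tests benchmark 50 genes per artifact class (14 ingroup taxa,
two outgroups, 300-column alignments), 200 paired draws for the
saturation direction property, 200 runs for the adequacy null and skew
ensembles (8 taxa, 200 columns, 20 replicates each), margins up to 30 for
exact Fisher enumeration, and $n = 46$ chromosomes with 50 genes each for
synteny recovery — sizes at which every stochastic property is measured
with comfortable Monte-Carlo margins while the whole suite runs in under
a minute.

## Limitations

The in-repo saturation slope uses alignment-derived distances, so its
absolute values are not comparable to slopes computed from ML distances —
only the ranking is. The clan check reports the maximum conflicting
support, one reading of an underspecified convention. NG86 underestimates
rates relative to YN00 when transition/transversion bias or codon-usage
bias is strong; the package reports which estimator produced its numbers.
Concordance factors on gene trees with many missing taxa depend on the
restricted-split convention; parity with other implementations is only
guaranteed for full-taxon binary gene trees. The event caller classifies
connected components of significant links; overlapping rearrangements in
the same component are reported as translocation candidates rather than
resolved into an event history.
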