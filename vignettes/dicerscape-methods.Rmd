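---
title: "Models and design choices in dicerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dicerscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicerscape)
library(dplyr)
```

`dicerscape` implements the computational core of a clade-wide fungal Dicer
survey: rule-based Dicer identification from profile-HMM hit tables,
six-category domain-architecture classification, PAZ-region extraction,
similarity-network clustering, equal-rates Mk ancestral reconstruction of
canonical-PAZ presence, structure-derived molecular-ruler distances, and
detection benchmarking. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The Dicer gate and the category rule table

Dicers are RNase III-family endonucleases that dice double-stranded RNA
into small RNAs. The gate used here admits a protein as a putative Dicer
iff its filtered architecture carries (1) at least two retained,
non-overlapping RNase III hits — the intramolecular IIIa/IIIb cleavage
dimer, with the 5′-most hit taken as IIIa — and (2) at least one
RNA-binding domain among the helicase subdomains (DEAD/DExD-box, ResIII,
Helicase-C), DUF283, PAZ, or dsRBD. "Tandem" is implemented as a count
(≥ 2 retained hits), not an adjacency constraint: no maximum spacing
between the two RNase III envelopes is imposed, because any such distance
cutoff would be arbitrary and the two-copy requirement already excludes
bacterial-type single-RNase III proteins.

Classification then looks only at four *domain units* — HEL (present iff
any of the three helicase subdomains is detected), DUF283, PAZ, dsRBD —
and the set $M$ of missing units:

| $M$              | category      |
|------------------|---------------|
| $\varnothing$    | canonical     |
| {dsRBD}          | non-canonical A |
| {PAZ}            | non-canonical B |
| {HEL, dsRBD}     | non-canonical C |
| {PAZ, dsRBD}     | non-canonical D |
| anything else    | non-canonical E |

The five named patterns plus the catch-all partition all $2^4$ unit
patterns, so classification is total and unambiguous on gate-passing
architectures (the test suite proves this by enumeration). Treating E as
the catch-all is a design decision: the named categories A–D are defined by
exact missing-sets, and patterns such as "missing DUF283 and PAZ" belong to
no named category; folding them into E (alongside all patterns with three
or more missing units) keeps the partition exhaustive. Helicase-subdomain
*completeness* (all three subdomains present) is recorded as metadata but
never drives the category, so a Dicer with only Helicase-C still has its
HEL unit.

Two percentages reported by `summarize_categories()` deserve comment.
Percentages are rounded half-up to one decimal (base R's `round()` is
round-half-even, which is not how survey tables are typically typeset).
On the published per-category counts (35, 80, 356, 273, 1825, 342 of
2911), this reproduces 1.2 / 2.7 / 12.2 / 9.4 / 62.7 for canonical–D and
86.7 % for the cPAZ-lacking aggregate (B + D + E); category E is 11.7485 %,
which half-up rounding renders 11.7.

## Hit parsing and overlap resolution

The parser consumes the HMMER per-domain table (`domtblout`) in either the
`hmmscan` (model-as-target) or `hmmsearch` (model-as-query) layout,
deciding per row by which side's accession maps into the seven-domain
vocabulary (PF00270/PF04851/PF00271/PF03368/PF02170/PF00636/PF00035 and
their InterPro aliases). Three conventions are fixed once and enforced
everywhere:

* **Envelope coordinates** (`env from`/`env to`), not alignment
  coordinates, because envelopes bound the full homologous region — the
  right object for region extraction.
* **Independent per-domain E-values** (`i-Evalue`), thresholded
  *inclusively* at $10^{-3}$ by default. The full-sequence E-value is a
  per-protein quantity and would let one strong domain drag weak spurious
  ones through the filter.
* **1-based inclusive** amino-acid coordinates (the HMMER convention).

Overlapping same-protein hits are resolved greedily: ascending E-value,
ties broken by higher bit score then smaller start; "overlap" means any
shared residue (tolerance 0 aa — the simplest testable rule, and nothing
in domain biology motivates a permissive overlap window at this stage).
When overlapping hits all overlap each other this greedy choice provably
attains the maximum retained-hit count; for overlap *chains* it is maximal
rather than maximum, which is the desired behaviour — a best-evidence hit
should never be discarded to make room for two weaker flanking ones.

## PAZ regions

For PAZ-bearing architectures the canonical PAZ (cPAZ) region is the hit
envelope itself. For architectures with DUF283 and RNase III but no PAZ
hit, the inferred fungal PAZ (fPAZ) is the inter-domain span
`(DUF283.end + 1)`–`(RNaseIII.start − 1)`, bounded by the *first* (5′-most)
RNase III hit since IIIa is by definition the upstream copy. An empty span
(adjacent or overlapping anchors) yields no region. No minimum fPAZ length
is imposed: downstream alignment tooling is the right place to drop
uninformatively short regions, and any cutoff here would silently change
the region census.

## Similarity networks

Sequence networks: self-hits are removed, reciprocal rows of the same
unordered pair are merged keeping the maximum identity, and an edge is
kept iff identity ≥ 50 % *and* the coverage of **both** sequences is
≥ 80 % (all thresholds inclusive). Requiring coverage on both sides is the
conservative reading of an undirected "80 % coverage" criterion and
prevents short proteins from attaching to long ones through one-sided
alignments. Structure networks: models with mean pLDDT < 70 are excluded
*before* edges are formed; asymmetric TM-scores for a pair are averaged
(mTM-align-style normalization differences between directions are not
resolvable downstream of the score table); edges require averaged
TM ≥ 0.9.

Clusters are connected components, numbered by descending size with ties
broken by the lexicographically smallest member; each cluster's hub is its
maximum-degree node (lexicographic tie-break), matching the
"most connected node" used to pick structural representatives. Singletons
are kept and flagged rather than dropped, so the clustering remains a
partition of the node set; callers can filter on the flag to reproduce the
convention of reporting only proteins that met the edge criteria.
Raising thresholds can only refine (never merge) this clustering, a
property the test suite verifies on random graphs, alongside equivalence
with a brute-force transitive-closure oracle.

## The ER-Mk model

Canonical-PAZ presence is a binary character on a rooted tree. Under the
equal-rates (ER) two-state Markov model with rate $q$, the transition
probability over a branch of length $t$ is

$$P(\text{switch}) = \tfrac{1}{2}\left(1 - e^{-2qt}\right), \qquad
  P(\text{stay}) = \tfrac{1}{2}\left(1 + e^{-2qt}\right).$$

The likelihood is computed by Felsenstein's pruning recursion in a
post-order pass, with each node's partial-likelihood vector rescaled to
sum to one and the log scaling factors accumulated — necessary for
thousands-of-tips trees whose raw partial likelihoods underflow double
precision. The root is combined with a uniform prior $(0.5, 0.5)$: this is
the ER stationary distribution, and it is what makes the likelihood
invariant to root placement (reversibility), consistent with analysing
mid-point-rooted trees. Polytomies need no special handling (the recursion
multiplies over any number of children) and zero-length branches simply
contribute identity transition tables.

The rate MLE maximizes this likelihood over
$q \in [10^{-8},\, 100/\bar t\,]$ where $\bar t$ is the mean branch
length, with convergence tolerance $10^{-8}$ on $q$. One numerical subtlety:
as $q \to \infty$ the likelihood flattens onto the saturation plateau
$n \log \tfrac12$, and a plain golden-section search over the full interval
can stall on that plateau. The optimizer therefore first brackets the
optimum on a 40-point log-spaced grid and then refines within the
bracketing interval. When all tips share one state the MLE is the
no-change boundary: $\hat q$ is pinned at the lower bound and the fit is
flagged rather than silently reported.

Marginal ancestral reconstructions use the standard two-pass scheme: the
post-order partials ("below" the node) are combined with a pre-order
outside message ("above" the node, equivalent to re-rooting at that node
under reversibility), and the product is normalized per node. Marginals
condition on the point estimate $\hat q$ only; rate uncertainty is not
propagated. Exactness is tested against full enumeration over all
internal-node state assignments on trees of up to five tips
($|\Delta| < 10^{-10}$), and the fitted rate and log-likelihood are
cross-checked against an independent implementation (`phytools::fitMk`).

## Structure metrics

Structure models are read from PDB text (first chain, CA trace), with the
B-factor column interpreted as AlphaFold-style per-residue pLDDT. The mean
pLDDT filter is inclusive at 70. The molecular-ruler metric is the
Euclidean distance between the CA of the *first residue* of the PAZ/fPAZ
segment and the CA of the first residue of the RNase IIIa segment —
"N-terminus of the domain" is taken as the first residue of its interval,
the simplest convention consistent with envelope coordinates. This spacing
(≈ 50–55 Å in Dicer models) is the physical ruler that sets small-RNA
product length. Note that PDB coordinates carry three decimals, so
distances computed from written files are exact only to about
$1.5\times10^{-3}$ Å; planted-distance tests therefore use anchor
coordinates exactly representable at that precision.

## Detection benchmarking

`evaluate_detection()` scores an arbitrary detection id set against
labeled positives and negatives, per group and overall:
sensitivity $= TP/(TP+FN)$, precision $= TP/(TP+FP)$ reported only when
$TP + FP > 0$ and *undefined* otherwise (never coerced to 0 or 100).
The module never runs the HMM search itself; decoupling the metric from
the search engine is what keeps the benchmark testable offline and
engine-agnostic. The test suite exercises the Argonaute-control pattern — a
236-member negative set with zero detections — which probes the precision
convention at its degenerate corner.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has inputs with known ground
truth. Its defaults are the study conditions of the survey it serves:

* The category mix follows the observed survey composition
  (35 : 80 : 356 : 273 : 1825 : 342 across canonical–E), scaled to leave
  20 % of proteins as non-Dicer decoys — RNase III-containing proteins
  that fail the gate either by a single RNase III (plus PAZ) or by tandem
  RNase III with no RNA-binding domain, the two realistic failure modes.
* Domain segment lengths follow typical Pfam envelope sizes (e.g. ~100 aa
  RNase III, ~110 aa PAZ, ~80 aa DUF283) with inter-domain gaps of
  20–120 aa, giving canonical proteins of ~1900 aa, in the range of real
  Dicers.
* Planted hits carry E-values of $10^{-50}$–$10^{-5}$; decoy hits carry
  E-values strictly above $10^{-3}$ and are placed only in gaps that do
  not intersect planted segments, so gate/classifier ground truth is
  unambiguous by construction.
* Binary characters are simulated branch-by-branch with the *exact*
  closed-form ER flip probability, and similarity tables are written
  directly as pair rows with planted within/between-cluster identities —
  no alignment is simulated.
* Toy structures place the first residue of each segment exactly on its
  anchor coordinate, so planted inter-segment distances are recovered to
  the PDB's decimal precision.

What passing tests on these data *show* is that the rules, recursions and
thresholds are implemented exactly as specified. What they do *not* show
is robustness to the messiness of real proteomes: biologically realistic
amino-acid composition and indel structure, overlapping true domains,
borderline E-values, fragmented gene models, or genuinely divergent
domains that HMMs miss — sequence content here is i.i.d. uniform over the
20 amino acids and is never consulted by the classifier, which sees only
coordinates. Conclusions about real fungal proteomes still require real
hit tables.

## Problem sizes and determinism

Every stochastic function takes an explicit integer seed and is
deterministic given it (`withr::with_seed`, so the caller's RNG state is
untouched). The shipped validation workloads use a 500-protein proteome
for classifier recovery, 100 random ≤ 5-tip trees for the enumeration
oracle, 50 replicates each of 50/200/800-tip trees for rate recovery
(median $\hat q$ and its monotone error decrease), 100 random 30–50-node
graphs for the component oracle, and a four-cluster similarity plan for
planted recovery — sizes chosen so the full suite exercises every
asymptotic claim while remaining a coffee-break run on one core.

## Known limitations

* The classifier is sequence-blind: a divergent domain invisible to the
  upstream HMM search is missing here too — that is the phenomenon the
  fPAZ analysis quantifies, not one the package can correct.
* Deduplication requires species, sequence and UniProt metadata; records
  missing any of these pass through untouched (logged), which can leave
  residual redundancy in sparsely annotated proteomes.
* The Mk machinery is two-state ER only; all-rates-different or covarion
  models, and uncertainty propagation from $\hat q$ into the marginals,
  are out of scope.
* TM-score normalization direction and BLAST coverage direction are
  consumed as given; if the upstream tool defines them asymmetrically the
  symmetric treatment here (averaging, two-sided minimum) is the
  conservative interpretation.
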