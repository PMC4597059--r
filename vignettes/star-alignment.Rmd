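---
title: "Star-based multiple alignment of protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-based multiple alignment of protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmna)
library(dplyr)
```

## The problem and the approach

Aligning protein–protein interaction networks (PPINs) across species —
matching each protein and interaction with its closest analogue elsewhere —
is NP-hard already for two networks, and native multiple-network aligners
are scarce, slow, and degrade as networks are added. `starmna` takes the
star-alignment route familiar from multiple sequence alignment: designate
one network as the *scaffold* (the star's centre), align every other
network to it pairwise with whatever pairwise aligner fits the study, and
combine the pairwise results into a single multiple network alignment
(MNA) expressed relative to the scaffold's nodes and edges. The expensive
step — the pairwise alignments — is external and embarrassingly parallel;
the combination itself is linear in the number of networks.

Three structural properties follow directly from the construction and are
enforced by the test suite rather than merely claimed:

* **Order invariance** — the combination is a union of sets per scaffold
  node, so any permutation of the input alignments gives the identical
  result.
* **Persistence** — adding a network never removes or alters an existing
  correspondence.
* **Measure consistency** — the scaffold-centric statistics of any single
  constituent pairwise alignment are unchanged inside the combined MNA.

## The model

Let $G_s = (V_s, E_s)$ be the scaffold and $G_j$ the other networks. For a
scaffold node $v$, each pairwise alignment contributes a co-alignment
cluster $B_{sj}(v)$ (the union of all its clusters containing $v$; just
$\{v\}$ if none). The combined cluster is

$$B(v) = \{v\} \cup \bigcup_j B_{sj}(v),$$

and the node alignment is the set $V^* = \{B(v) : v \in V_s\}$, keyed by
scaffold node. When a many-to-many pairwise cluster contains several
scaffold nodes, it is registered under *each* of them and the clusters are
never merged — this is deliberate duplication, not a bug: a cluster
$\{u, v, a\}$ from species A and $\{u, w, b\}$ from species B yield three
rooted clusters $B(u)=\{u,v,w,a,b\}$, $B(v)=\{v,u,a\}$, $B(w)=\{w,u,b\}$
(see `fixture_duplication()`).

For a scaffold edge $(u, v)$, the induced (conserved) edge cluster is

$$E(u,v) = \{(s,t) \in B(u) \times B(v) : (s,t) \in E_j \text{ for some } j\},$$

with $j$ ranging over all loaded networks including the scaffold, so the
root edge is always a member of its own cluster. An edge is *conserved in
k species* when members of its cluster come from at least $k-1$ distinct
non-scaffold species; the per-$k$ counts (`ea_k()`) are non-increasing and
anchored at $|E_s|$ for $k=1$.

Interactions are undirected and unweighted throughout; weights in input
files are validated and discarded. Self-interactions are legal edges and
participate in every measure.

## Assessment measures

Two indicator functions ground the biological measures: $F(k,l) = 1$ when
the funSim functional-similarity score of the pair strictly exceeds a
threshold (default 0.5), and $H(k,l) = 1$ when the two proteins share a
homolog-group identifier. Both consume precomputed tables; a missing pair
scores 0, which treats incomplete annotation as absence of evidence rather
than excluding the pair from denominators.

Each node measure comes in two flavours. The scaffold-centric (`_s`)
variant counts pairs (root, member): a cluster of size $m$ contributes
$m-1$ to `NA_s` and its indicator-weighted analogues to `NF_s`, `NH_s`,
`NForH_s` (with $\min(1, F+H)$ for the combined measure). The all-pairs
variant counts every unordered member pair, $\binom{m}{2}$ per cluster,
capturing also the *implied* correspondences between non-scaffold nodes
that were never directly aligned to each other (weak correspondence
transitivity). Edge measures mirror this on edge clusters: `EA_s` sums
cluster sizes minus one, `EA` sums unordered member pairs, and `EF`/`EH`
weight by products of endpoint indicators.

The precision of the implied correspondences is
$(X - X_s)/(D - D_s)$ with $D$ = `NA` for node measures and `EA` for edge
measures; when nothing is implied ($D = D_s$) the value is reported as
undefined rather than 0/0. `relative_precision_change()` compares two such
precisions, e.g. the star-combined MNA against a scaffoldized native MNA.

```{r figure-example}
fx <- fixture_figure2()
mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks) |>
  compute_conserved_edges()
alignment_measures(mna, fx$tables)
```

## Design choices where the design was open

Several points are not forced by the construction; the package commits to
one reading and documents it:

* **A node in several clusters of one pairwise alignment.** Many-to-many
  aligners can place a scaffold node in more than one cluster.
  $B_{sj}(v)$ is defined as the union of all of them — set semantics,
  consistent with the union in $B(v)$ itself.
* **Undirected edge matching with stored orientation.** The product
  $B(u) \times B(v)$ is ordered, but interactions are not; a member is
  accepted if either orientation of the interaction lands in the product,
  and the matching orientation (first endpoint in $B(u)$) is stored because
  the endpoint-indicator measures `EF_s`/`EH_s` need it. A member admitted
  under both orientations is stored once, canonically. Without this rule,
  results would depend on the arbitrary orientation of edge-list files.
* **Endpoint pairing in all-pairs edge measures.** Two undirected member
  edges have no canonical endpoint correspondence. Both cross-pairings are
  tested and the pair counts if either satisfies the indicator product.
  This is symmetric and orientation-independent; it can count strictly more
  pairs than any fixed pairing.
* **Combined edge measure.** The combined scaffold-centric edge measure is
  computed as $\min(1, (F+H)\cdot(F+H))$ over the two endpoint pairs, the
  "functionally similar or homologous" reading used by its node
  counterpart. Note that unlike the node chain
  $\max(NF,NH) \le NForH \le NF+NH$, the edge analogue only guarantees the
  lower bound: an edge pair can satisfy $F$ on one endpoint pair and $H$ on
  the other, contributing to `EForH` but to neither `EF` nor `EH`.
* **Conservation breadth excludes the scaffold.** A second scaffold edge
  inside a cluster is a legitimate member (and counts in `EA`), but the
  scaffold is the baseline species of the breadth count: conserved-in-$k$
  means $k-1$ *other* species.
* **Scaffold selection.** The abstract pairwise similarity $S_{ij}$ is
  instantiated four ways: a candidate's own node or edge count (the
  "most complete network" heuristic; the default), the pairwise minimum of
  those counts (a symmetric, conservative proxy), the count of BLAST pairs
  below an E-value threshold (default $10^{-5}$), and a user-supplied
  per-pair alignment-quality measure. Ties break to the lexicographically
  smallest species identifier, deterministically. Domain knowledge can
  always override: every downstream function takes the scaffold
  explicitly.
* **Distinct-cluster counting.** When scaffold nodes appear in each
  other's clusters, identical clusters are counted once per root by
  default (this matches how the headline per-node enumeration is defined);
  `distinct = TRUE` deduplicates identical member sets first. Distinct-mode
  values are never larger.
* **Annotation keying.** The funSim/homolog/BLAST file formats carry bare
  accessions, so the tables are keyed by accession, not by
  (species, accession); network files, by contrast, namespace accessions
  per species, and ambiguous bare accessions in cluster files are a hard
  error rather than a silent guess.

## The synthetic generator

`simulate_family()` provides the statistical ground truth the property
tests run against. An ancestral scaffold is drawn as a uniform random
graph; each other species is a degraded copy: nodes survive with
probability `node_retention` (default 0.8), surviving edges are kept with
probability `edge_retention` (0.7), spurious edges are added at
`extra_edge_rate` (0.1 of the scaffold edge count in expectation), and
surviving nodes are duplicated with probability `duplication_rate`
(default 0, switched on to exercise many-to-many semantics). True ortholog
pairs hit the functional-similarity indicator with probability
`funsim_signal` (0.8) and the homology indicator with `homolog_signal`
(0.6); unrelated pairs hit either at `background_rate` (0.02), so
precision has non-trivial values. The defaults are one fixed choice of
moderately noisy, moderately conserved conditions — retention well above
half so conservation is common but not saturated, signal rates below one
so indicator counts differ from alignment counts — and are not tuned per
test.

Under this model a scaffold edge survives in a given species with
probability `node_retention`² × `edge_retention` independently per
species, which gives the closed-form expectation the Monte-Carlo
calibration test checks (mean per-edge breadth =
(n_species − 1) · nr² · er, within three standard errors over 200
replicate families of 30 scaffold nodes).

The generator serves testing, not biology: degree distributions are
binomial rather than heavy-tailed, there is no duplication–divergence
dynamics, annotation noise is independent across pairs, and accessions
are globally unique by construction. Passing tests therefore demonstrate
algebraic correctness of the combination and the measures — not that any
particular biological conclusion transfers to real interactomes, where
aligner errors are correlated with network topology and annotation
incompleteness is highly non-uniform.

## Numerical and degenerate cases

Everything is exact integer counting; there are no tolerances except in
the Monte-Carlo calibration described above. Degenerate inputs are
defined, not errors: an empty alignment list gives singleton clusters
everywhere and zero on every measure; an edgeless scaffold gives an empty
edge alignment; a self-loop scaffold edge induces within-cluster
interactions via $B(u) \times B(u)$; undefined precision is a flagged
state. Iteration is in lexicographic order throughout, so identical
inputs produce byte-identical output files; the generator restores the
RNG state it found.

Validation problem sizes: the randomized suites use scaffolds of 4–30
nodes with 2–4 species (200 instances for the brute-force oracle checks,
200 replicate families for the calibration), exhaustive permutation checks
up to 4 alignments, and the published eight-interactome node counts for
the scaffold-selection check. These sizes keep the brute-force reference
implementations — quadratic double loops with scalar lookups — exact and
fast; the package code itself is join-based and scales far beyond them.

## Limitations

* The pairwise alignments are inputs. The package neither runs external
  aligners nor judges their quality beyond the measures above.
* Correspondences among non-scaffold species that no pairwise alignment
  routes through a scaffold node are invisible to a scaffold-rooted MNA;
  `scaffoldize()` makes the same restriction explicit for native MNAs
  (clusters without a scaffold member are dropped).
* funSim scores and homolog groups are consumed, not computed; there are
  no retrieval clients for annotation databases.
* Graphlet-based network similarity for scaffold selection is an extension
  point, not implemented.
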