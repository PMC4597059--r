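# starmna

Scaffold-based ("star") multiple alignment of protein–protein interaction
networks (PPINs) in R.

Comparing interactomes across species requires aligning their networks —
matching proteins and interactions with their closest analogues elsewhere.
Pairwise network aligners are plentiful; usable multiple-network aligners
are not. `starmna` closes that gap for any pairwise aligner: pick one
network as the **scaffold**, align every other network to it pairwise with
the aligner of your choice, and let this package combine the results into
a single multiple network alignment (MNA), compute the conserved
interactions, and score the result. The combination is linear in the
number of networks, invariant to their order, and preserves every
correspondence (and every pairwise statistic) as networks are added.

It is aimed at computational and systems biologists who already have
pairwise alignment output (one-to-one pairs or many-to-many clusters) and
want a multi-species view rooted in a reference interactome.

## The model in brief

For each scaffold node *v*, its co-alignment cluster is the union of its
clusters across the pairwise alignments,

    B(v) = {v} ∪ ⋃ⱼ Bₛⱼ(v),

and the node alignment is V\* = {B(v) : v ∈ Vₛ}. Clusters containing
several scaffold nodes are registered under each of them (duplication
semantics for many-to-many input). For each scaffold edge (u, v), the
conserved-interaction cluster is

    E(u,v) = {(s,t) ∈ B(u) × B(v) : (s,t) is an edge in some network},

matched undirectedly, always containing (u, v) itself. An edge is
conserved in *k* species when its cluster draws members from ≥ k−1
non-scaffold species (EA-k).

The measure suite counts aligned nodes and conserved edges in two scopes —
scaffold-centric (`NA_s`, `EA_s`, …: pairs involving the root) and
all-pairs (`NA`, `EA`, …: every unordered pair, including implied
correspondences) — optionally weighted by a funSim
functional-similarity indicator F (score > threshold, default 0.5), a
shared-homolog-group indicator H, or their combination. The precision of
implied correspondences is (X − X_s)/(D − D_s) with D = NA or EA.

## Worked example

The built-in `fixture_figure2()` reproduces a fully worked two-species
scenario: scaffold S with one interaction (u, v); species A with
interactions (o, p) and (q, r); species B with two non-interacting
proteins s, t; alignments mapping o, q, s → u and p, r, t → v.

```r
library(starmna)

fx  <- fixture_figure2()
mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks) |>
  compute_conserved_edges()
alignment_measures(mna, fx$tables)
#> <mna_report> funSim threshold 0.5, per-scaffold-node cluster counting
#>                   A F H ForH EA EF EH EForH
#> scaffold-centric  6 3 1    4  2  1  0     1
#> all-pairs        12 4 2    6  3  1  0     1
#> EA-k:  k=1:1  k=2:1  k=3:0
```

Reading the report: the two clusters B(u) = {u, o, q, s} and
B(v) = {v, p, r, t} each contribute 3 scaffold-rooted pairs (`NA_s` = 6)
and 6 member pairs (`NA` = 12). Four pairs are functionally similar
(`NF` = 4), three of them involving a root (`NF_s` = 3); two pairs are
homologous (`NH` = 2), one through the root (`NH_s` = 1). The single
scaffold edge induces a cluster of three conserved interactions, adding 2
to `EA_s` and 3 to `EA`; both induced edges come from one species, so the
edge is conserved in two species (EA-2 = 1) but not three (EA-3 = 0).

`tidy()`, `glance()` and `autoplot()` give the report as a long tibble, a
one-row summary, and a measure bar chart; `select_scaffold()` ranks
candidate scaffolds; `scaffoldize()` converts a native MNA cluster file
into the same rooted form for like-for-like comparison;
`simulate_family()` generates synthetic multi-species families with
planted orthology. A command-line front end
(`inst/cli/starmna.R`, subcommands `align`, `evaluate`, `select-scaffold`,
`scaffoldize`, `simulate`) wraps the same functions for shell use.

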