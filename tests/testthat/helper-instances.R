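# Randomised test instances drawn from the synthetic generator under varied
# regimes (one-to-one and many-to-many, sparse and dense).

random_instance <- function(seed, max_size = 12, duplication = NULL) {
  set.seed(seed)
  size <- sample(4:max_size, 1)
  n_species <- sample(2:4, 1)
  dup <- if (is.null(duplication)) sample(c(0, 0.3), 1) else duplication
  spec <- family_spec(
    scaffold_size = size,
    edge_prob = stats::runif(1, 0.1, 0.4),
    n_species = n_species,
    node_retention = stats::runif(1, 0.5, 1),
    edge_retention = stats::runif(1, 0.3, 1),
    extra_edge_rate = sample(c(0, 0.3), 1),
    duplication_rate = dup,
    background_rate = 0.05,
    seed = seed + 1L
  )
  simulate_family(spec)
}

# exhaustive permutation enumerator for order-invariance checks
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

build_mna <- function(fam) {
  compute_conserved_edges(
    combine_alignments(fam$scaffold, fam$alignments, fam$networks)
  )
}
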