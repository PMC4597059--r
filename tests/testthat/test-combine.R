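members_of <- function(mna, root) {
  cl <- mna$node_clusters[mna$node_clusters$root == root, ]
  paste(cl$species, cl$accession, sep = ":")
}

test_that("a node's pairwise co-alignment cluster is the union over containing clusters", {
  fx <- fixture_duplication()
  b <- bsj_for_node(fx$alignments[[1]], "u", fx$scaffold)
  expect_setequal(paste(b$species, b$accession), c("S u", "S v", "A a"))
  # node in no cluster: minimum content {w} under the A alignment? w is in no
  # cluster of alignment 1
  b_w <- bsj_for_node(fx$alignments[[1]], "w", fx$scaffold)
  expect_equal(paste(b_w$species, b_w$accession), "S w")
  expect_error(bsj_for_node(fx$alignments[[1]], "zzz", fx$scaffold), "not a node")

  # membership in two clusters of one alignment unions
  scaffold <- ppi_network(tibble::tibble(from = character(), to = character()),
                          "S", nodes = "u")
  other <- ppi_network(tibble::tibble(from = character(), to = character()),
                       "A", nodes = c("a", "b"))
  al <- pairwise_alignment(
    tibble::tibble(cluster_id = c(1L, 1L, 2L, 2L),
                   species = c("S", "A", "S", "A"),
                   accession = c("u", "a", "u", "b")),
    "S", "A")
  b_u <- bsj_for_node(al, "u", scaffold)
  expect_setequal(b_u$accession, c("u", "a", "b"))
})

test_that("many-to-many clusters duplicate under each contained scaffold node", {
  fx <- fixture_duplication()
  mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks)
  expect_equal(dplyr::n_distinct(mna$node_clusters$root), 3)
  expect_setequal(members_of(mna, "u"), c("S:u", "S:v", "S:w", "A:a", "B:b"))
  expect_setequal(members_of(mna, "v"), c("S:v", "S:u", "A:a"))
  expect_setequal(members_of(mna, "w"), c("S:w", "S:u", "B:b"))
})

test_that("zero alignments give singleton clusters; invalid inputs error", {
  fx <- fixture_duplication()
  mna <- combine_alignments(fx$scaffold, list())
  expect_true(all(table(mna$node_clusters$root) == 1))
  expect_error(
    combine_alignments(fx$scaffold, fx$alignments[c(1, 1)]),
    "duplicate aligned species"
  )
  other_scaffold <- ppi_network(tibble::tibble(from = character(), to = character()),
                                "X", nodes = "x")
  al <- pairwise_alignment(
    tibble::tibble(cluster_id = 1L, species = "X", accession = "x"), "X", "A")
  expect_error(combine_alignments(fx$scaffold, list(al)), "scaffold species")
})

test_that("combination is invariant under every permutation of the alignments", {
  for (seed in c(11, 12, 13)) {
    fam <- random_instance(seed)
    n <- length(fam$alignments)
    ref <- combine_alignments(fam$scaffold, fam$alignments, fam$networks)
    perms <- matrix(unlist(combinat_perms(seq_len(n))), ncol = n, byrow = TRUE)
    for (p in seq_len(nrow(perms))) {
      got <- combine_alignments(fam$scaffold, fam$alignments[perms[p, ]],
                                fam$networks)
      expect_equal(got$node_clusters, ref$node_clusters)
    }
  }
})

test_that("every scaffold node roots exactly one cluster containing itself", {
  for (seed in 21:26) {
    fam <- random_instance(seed)
    mna <- combine_alignments(fam$scaffold, fam$alignments, fam$networks)
    expect_setequal(unique(mna$node_clusters$root), fam$scaffold$nodes$accession)
    roots_in_own <- mna$node_clusters %>%
      dplyr::filter(species == fam$scaffold$species, accession == root)
    expect_equal(sort(roots_in_own$root), sort(fam$scaffold$nodes$accession))
  }
})

test_that("one-to-one inputs stay one-to-one and persist as alignments accumulate", {
  for (seed in 31:35) {
    fam <- random_instance(seed, duplication = 0)
    mna <- combine_alignments(fam$scaffold, fam$alignments, fam$networks)
    per_species <- mna$node_clusters %>%
      dplyr::filter(species != fam$scaffold$species) %>%
      dplyr::count(root, species)
    expect_true(all(per_species$n <= 1))
    # persistence: correspondences from a prefix of alignments survive intact
    if (length(fam$alignments) >= 2) {
      partial <- combine_alignments(fam$scaffold, fam$alignments[1],
                                    fam$networks[1])
      full_pairs <- paste(mna$node_clusters$root, mna$node_clusters$species,
                          mna$node_clusters$accession)
      part_pairs <- paste(partial$node_clusters$root, partial$node_clusters$species,
                          partial$node_clusters$accession)
      expect_true(all(part_pairs %in% full_pairs))
    }
  }
})

test_that("restricting to one species recovers the single-alignment combination", {
  fx <- fixture_duplication()
  mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks)
  ra <- restrict_to_pair(mna, "A")
  expect_setequal(members_of(ra, "u"), c("S:u", "S:v", "S:w", "A:a"))
  expect_error(restrict_to_pair(mna, "Z"), "unknown species")
  # degenerate: restrict to the scaffold itself
  rs <- restrict_to_pair(mna, "S")
  expect_true(all(rs$node_clusters$species == "S"))

  for (seed in 41:43) {
    fam <- random_instance(seed, duplication = 0)
    if (length(fam$alignments) < 2) next
    mna <- build_mna(fam)
    sp1 <- fam$alignments[[1]]$other_species
    restricted <- restrict_to_pair(mna, sp1)
    direct <- compute_conserved_edges(
      combine_alignments(fam$scaffold, fam$alignments[1], fam$networks)
    )
    # one-to-one generator clusters contain a single scaffold node, so the
    # restriction matches the direct pairwise combination exactly
    expect_equal(restricted$node_clusters, direct$node_clusters)
  }
})
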