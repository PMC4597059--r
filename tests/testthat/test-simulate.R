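test_that("identical family specifications reproduce byte-identical files", {
  spec <- family_spec(scaffold_size = 15, n_species = 3, duplication_rate = 0.2,
                      seed = 77)
  fam1 <- simulate_family(spec)
  fam2 <- simulate_family(spec)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (i in seq_along(fam1$networks)) {
    write_ppi_network(fam1$networks[[i]], file.path(d1, paste0("n", i)))
    write_ppi_network(fam2$networks[[i]], file.path(d2, paste0("n", i)))
    write_alignment_clusters(fam1$alignments[[i]], file.path(d1, paste0("a", i)))
    write_alignment_clusters(fam2$alignments[[i]], file.path(d2, paste0("a", i)))
  }
  write_annotations(fam1$tables, file.path(d1, "f"), file.path(d1, "h"))
  write_annotations(fam2$tables, file.path(d2, "f"), file.path(d2, "h"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed, different draw
  fam3 <- simulate_family(family_spec(scaffold_size = 15, n_species = 3,
                                      duplication_rate = 0.2, seed = 78))
  expect_false(identical(fam1$networks[[1]]$edges, fam3$networks[[1]]$edges))
})

test_that("specification validation rejects infeasible families", {
  expect_error(family_spec(node_retention = 1.2), "\\[0, 1\\]")
  expect_error(family_spec(scaffold_size = 10, n_edges = 46), "exceeds")
  expect_error(family_spec(extra_edge_rate = -1), "non-negative")
  expect_error(family_spec(n_species = 1), "at least 2")
})

test_that("perfect retention conserves every scaffold edge in every species", {
  fam <- simulate_family(family_spec(
    scaffold_size = 12, edge_prob = 0.3, n_species = 4,
    node_retention = 1, edge_retention = 1, extra_edge_rate = 0,
    duplication_rate = 0, background_rate = 0, seed = 5
  ))
  mna <- build_mna(fam)
  kk <- ea_k(mna)
  expect_true(all(kk$count == nrow(fam$scaffold$edges)))
})

test_that("zero edge retention conserves nothing beyond the scaffold", {
  fam <- simulate_family(family_spec(
    scaffold_size = 12, edge_prob = 0.3, n_species = 4,
    node_retention = 1, edge_retention = 0, extra_edge_rate = 0,
    duplication_rate = 0, background_rate = 0, seed = 6
  ))
  mna <- build_mna(fam)
  kk <- ea_k(mna)
  expect_true(all(kk$count[kk$k >= 2] == 0))
  expect_equal(kk$count[1], nrow(fam$scaffold$edges))
})

test_that("pipeline conservation counts match the planted-truth record", {
  for (seed in 211:218) {
    fam <- random_instance(seed)
    mna <- build_mna(fam)
    kk <- ea_k(mna)
    truth_breadth <- fam$truth %>% dplyr::count(root_from, root_to)
    for (k in kk$k) {
      want <- if (k == 1) nrow(fam$scaffold$edges) else
        sum(truth_breadth$n >= k - 1)
      expect_equal(kk$count[kk$k == k], want)
    }
  }
})

test_that("ground-truth one-to-one alignments reconstruct the planted clusters", {
  fam <- simulate_family(family_spec(scaffold_size = 20, n_species = 4,
                                     duplication_rate = 0, seed = 31))
  mna <- combine_alignments(fam$scaffold, fam$alignments, fam$networks)
  planted <- dplyr::bind_rows(
    tibble::tibble(root = fam$scaffold$nodes$accession,
                   species = "s0", accession = fam$scaffold$nodes$accession),
    dplyr::transmute(fam$mapping, root = source, species = species,
                     accession = accession)
  ) %>% dplyr::arrange(root, species, accession)
  expect_equal(mna$node_clusters, planted)
})

test_that("duplication produces many-to-many clusters aligned to one source", {
  fam <- simulate_family(family_spec(scaffold_size = 25, n_species = 3,
                                     duplication_rate = 0.5, seed = 41))
  dups <- fam$mapping %>% dplyr::count(species, source) %>% dplyr::filter(n > 1)
  expect_gt(nrow(dups), 0)
  mna <- combine_alignments(fam$scaffold, fam$alignments, fam$networks)
  sizes <- mna$node_clusters %>%
    dplyr::filter(species != "s0") %>%
    dplyr::count(root, species)
  expect_gt(max(sizes$n), 1)
})

test_that("conservation tracks the analytic survival probability monotonically", {
  rates <- c(0.2, 0.6, 1)
  observed <- vapply(rates, function(er) {
    fam <- simulate_family(family_spec(
      scaffold_size = 25, edge_prob = 0.25, n_species = 3,
      node_retention = 1, edge_retention = er, extra_edge_rate = 0,
      duplication_rate = 0, background_rate = 0, seed = 55
    ))
    kk <- ea_k(build_mna(fam))
    kk$count[kk$k == 2] / nrow(fam$scaffold$edges)
  }, numeric(1))
  expect_true(all(diff(observed) >= 0))
})
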