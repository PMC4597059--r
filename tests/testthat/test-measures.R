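test_that("functional-similarity indicator is strict at the threshold", {
  tab <- annotation_tables(funsim = tibble::tibble(
    acc_a = c("P30876", "P19388", "x"),
    acc_b = c("Q8CFI7", "P20434", "y"),
    score = c(0.95, 0.48, 0.5)
  ))
  expect_equal(indicator_f(tab, "Q8CFI7", "P30876"), 1L)
  expect_equal(indicator_f(tab, "P19388", "P20434"), 0L)
  expect_equal(indicator_f(tab, "x", "y"), 0L)  # equality does not pass
  expect_equal(indicator_f(tab, "x", "y", threshold = 0.49), 1L)
  expect_equal(indicator_f(tab, "missing", "pair"), 0L)
})

test_that("homology indicator detects shared groups, matching a set oracle", {
  tab <- annotation_tables(homolog = tibble::tibble(
    accession = c("a", "b", "b", "c"),
    group = c("h77", "h77", "h90", "h91")
  ))
  expect_equal(indicator_h(tab, "a", "b"), 1L)
  expect_equal(indicator_h(tab, "a", "c"), 0L)
  expect_equal(indicator_h(tab, "a", "zzz"), 0L)
  set.seed(3)
  accs <- paste0("p", 1:15)
  rnd <- annotation_tables(homolog = tibble::tibble(
    accession = sample(accs, 40, replace = TRUE),
    group = sample(paste0("g", 1:8), 40, replace = TRUE)
  ))
  a <- sample(accs, 30, replace = TRUE)
  b <- sample(accs, 30, replace = TRUE)
  got <- indicator_h(rnd, a, b)
  want <- mapply(function(x, y) oracle_h(rnd, x, y), a, b, USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("worked-example node and edge measures match the figure legend", {
  fx <- fixture_figure2()
  mna <- compute_conserved_edges(
    combine_alignments(fx$scaffold, fx$alignments, fx$networks)
  )
  nm <- node_measures(mna, fx$tables)
  # each of the two clusters contributes 3 to NA_s and 6 to NA
  expect_equal(unname(nm["NA_s"]), 6)
  expect_equal(unname(nm["NA"]), 12)
  expect_equal(unname(nm[c("NF_s", "NF", "NH_s", "NH")]), c(3, 4, 1, 2))
  em <- edge_measures(mna, fx$tables)
  expect_equal(unname(em[c("EA_s", "EA")]), c(2, 3))
  expect_equal(unname(em[c("EF_s", "EH_s")]), c(1, 0))
  kk <- ea_k(mna)
  expect_equal(kk$count[kk$k == 2], 1)
  expect_equal(kk$count[kk$k == 3], 0)
})

test_that("all-singleton alignments score zero on every measure", {
  scaffold <- ppi_network(tibble::tibble(from = "a", to = "b"), "S")
  mna <- compute_conserved_edges(combine_alignments(scaffold, list()))
  expect_true(all(node_measures(mna) == 0))
  em <- edge_measures(mna)
  expect_true(all(em == 0))
})

test_that("measures equal the loop-based oracle on random instances", {
  for (seed in 111:122) {
    fam <- random_instance(seed)
    mna <- build_mna(fam)
    expect_equal(node_measures(mna, fam$tables),
                 oracle_node_measures(mna, fam$tables))
    expect_equal(edge_measures(mna, fam$tables),
                 oracle_edge_measures(mna, fam$tables))
  }
})

test_that("raising the funSim threshold never increases any F-based measure", {
  fam <- random_instance(131)
  mna <- build_mna(fam)
  lo <- c(node_measures(mna, fam$tables, threshold = 0.2),
          edge_measures(mna, fam$tables, threshold = 0.2))
  hi <- c(node_measures(mna, fam$tables, threshold = 0.8),
          edge_measures(mna, fam$tables, threshold = 0.8))
  fmeas <- c("NF_s", "NF", "EF_s", "EF")
  expect_true(all(hi[fmeas] <= lo[fmeas]))
})

test_that("combined measures obey their bound chains", {
  for (seed in 141:146) {
    fam <- random_instance(seed)
    mna <- build_mna(fam)
    v <- c(node_measures(mna, fam$tables), edge_measures(mna, fam$tables))
    expect_lte(max(v["NF"], v["NH"]), v["NForH"])
    expect_lte(v["NForH"], v["NF"] + v["NH"])
    expect_lte(max(v["NF_s"], v["NH_s"]), v["NForH_s"])
    expect_lte(v["NForH_s"], v["NF_s"] + v["NH_s"])
    expect_lte(max(v["EF"], v["EH"]), v["EForH"])
    expect_lte(v["EForH"], v["EA"])
    expect_lte(max(v["EF_s"], v["EH_s"]), v["EForH_s"])
    expect_lte(v["EForH_s"], v["EA_s"])
    expect_lte(v["NF_s"], v["NA_s"]); expect_lte(v["NF"], v["NA"])
    expect_lte(v["NH_s"], v["NA_s"]); expect_lte(v["NH"], v["NA"])
  }
})

test_that("scaffold-centric measures inside the combined alignment equal the pairwise ones", {
  for (seed in 151:154) {
    fam <- random_instance(seed)
    single <- compute_conserved_edges(combine_alignments(
      fam$scaffold, fam$alignments[1], fam$networks[1]
    ))
    v <- node_measures(single, fam$tables)
    # direct enumeration on the pairwise alignment itself
    al <- fam$alignments[[1]]
    direct_na <- direct_nf <- 0L
    for (r in fam$scaffold$nodes$accession) {
      b <- bsj_for_node(al, r, fam$scaffold)
      others <- b[!(b$species == "s0" & b$accession == r), ]
      direct_na <- direct_na + nrow(others)
      for (i in seq_len(nrow(others))) {
        direct_nf <- direct_nf + oracle_f(fam$tables, r, others$accession[i])
      }
    }
    expect_equal(unname(v["NA_s"]), direct_na)
    expect_equal(unname(v["NF_s"]), direct_nf)
  }
})

test_that("EA-k is non-increasing and anchored at the scaffold edge count", {
  for (seed in 161:166) {
    fam <- random_instance(seed)
    mna <- build_mna(fam)
    kk <- ea_k(mna)
    expect_equal(kk$count[1], nrow(fam$scaffold$edges))
    expect_true(all(diff(kk$count) <= 0))
  }
})

test_that("distinct-cluster counting never exceeds per-node counting", {
  fx <- fixture_duplication()
  mna <- compute_conserved_edges(
    combine_alignments(fx$scaffold, fx$alignments, fx$networks)
  )
  for (seed in 171:174) {
    fam <- random_instance(seed, duplication = 0.4)
    m <- build_mna(fam)
    dflt <- c(node_measures(m, fam$tables), edge_measures(m, fam$tables))
    dd <- c(node_measures(m, fam$tables, distinct = TRUE),
            edge_measures(m, fam$tables, distinct = TRUE))
    expect_true(all(dd <= dflt))
  }
  # identical clusters would need identical member sets; the duplication
  # example's clusters differ, so nothing is merged
  expect_equal(node_measures(mna)["NA_s"],
               node_measures(mna, distinct = TRUE)["NA_s"])
})

test_that("precision is the implied-correspondence ratio, undefined without implied pairs", {
  rep_fake <- list(values = c(NForH = 10, NForH_s = 6, "NA" = 20, NA_s = 12,
                              NF = 0, NF_s = 0, NH = 0, NH_s = 0,
                              EF = 0, EF_s = 0, EH = 0, EH_s = 0,
                              EForH = 0, EForH_s = 0, EA = 5, EA_s = 5))
  prec <- alignment_precision(rep_fake)
  expect_equal(prec$precision[prec$measure == "NForH"], 0.5)
  expect_false(prec$defined[prec$measure == "EForH"])
  expect_true(is.na(prec$precision[prec$measure == "EForH"]))

  # recomputation oracle on a random instance
  fam <- random_instance(181)
  mna <- build_mna(fam)
  report <- alignment_measures(mna, fam$tables)
  v <- report$values
  p <- report$precision
  for (m in c("NF", "NH", "NForH")) {
    expect_equal(p$precision[p$measure == m],
                 unname((v[m] - v[paste0(m, "_s")]) / (v["NA"] - v["NA_s"])))
  }
})

test_that("relative precision change is a signed ratio with guarded degeneracies", {
  expect_equal(relative_precision_change(0.5, 0.5), 0)
  expect_equal(relative_precision_change(0.935, 1.0), -0.065)
  expect_true(is.na(relative_precision_change(0.5, 0)))
  expect_true(is.na(relative_precision_change(NA_real_, 0.5)))
  set.seed(19)
  p <- stats::runif(20)
  q <- stats::runif(20, 0.01, 1)
  expect_equal(relative_precision_change(p, q), (p - q) / q)
})

test_that("report object tidies, glances and plots", {
  fx <- fixture_figure2()
  mna <- compute_conserved_edges(
    combine_alignments(fx$scaffold, fx$alignments, fx$networks)
  )
  report <- alignment_measures(mna, fx$tables)
  td <- tidy(report)
  expect_true(all(c("measure", "scope", "value") %in% names(td)))
  expect_equal(td$value[td$measure == "EA-2"], 1)
  gl <- glance(report)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$NF, 4)
  expect_s3_class(autoplot(report), "ggplot")
  expect_s3_class(plot_conservation(mna), "ggplot")
})
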