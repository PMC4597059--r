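#' Node-level alignment measures
#'
#' Computes the aligned-node counts of a scaffold-rooted multiple network
#' alignment. Scaffold-centric (`_s`) variants count pairs (root, member)
#' with member != root, so each cluster of size m contributes m - 1;
#' all-pairs variants count every unordered member pair, contributing
#' choose(m, 2). Counts weighted by the functional-similarity indicator F
#' (funSim score strictly above `threshold`), the homology indicator H
#' (shared homolog group), and their combination min(1, F + H) give the
#' NF/NH/NForH families. Clusters are enumerated once per scaffold node, so
#' a cluster shared by several scaffold nodes is counted once per node
#' unless `distinct = TRUE`, which deduplicates clusters with identical
#' member sets first.
#'
#' @param mna An `mna` from [combine_alignments()] or [scaffoldize()].
#' @param tables An [annotation_tables()].
#' @param threshold funSim indicator threshold (strict), default 0.5.
#' @param distinct Deduplicate identical clusters before counting.
#' @return Named numeric vector: `NA_s`, `NA`, `NF_s`, `NF`, `NH_s`, `NH`,
#'   `NForH_s`, `NForH`.
#' @export
node_measures <- function(mna, tables = annotation_tables(), threshold = 0.5,
                          distinct = FALSE) {
  clusters <- mna$node_clusters
  if (distinct) clusters <- distinct_node_clusters(clusters, mna$scaffold$species)

  rooted <- clusters %>%
    dplyr::filter(!(.data$species == mna$scaffold$species & .data$accession == .data$root))
  f_s <- indicator_f(tables, rooted$root, rooted$accession, threshold)
  h_s <- indicator_h(tables, rooted$root, rooted$accession)

  members <- clusters %>%
    dplyr::mutate(key = node_key(.data$species, .data$accession))
  pairs <- dplyr::inner_join(
    members, members, by = "root", relationship = "many-to-many",
    suffix = c(".a", ".b")
  ) %>%
    dplyr::filter(.data$key.a < .data$key.b)
  f_all <- indicator_f(tables, pairs$accession.a, pairs$accession.b, threshold)
  h_all <- indicator_h(tables, pairs$accession.a, pairs$accession.b)

  c(
    NA_s = nrow(rooted),
    "NA" = nrow(pairs),
    NF_s = sum(f_s),
    NF = sum(f_all),
    NH_s = sum(h_s),
    NH = sum(h_all),
    NForH_s = sum(pmin(1L, f_s + h_s)),
    NForH = sum(pmin(1L, f_all + h_all))
  )
}

# Keep one representative root per identical member set (smallest root).
distinct_node_clusters <- function(clusters, scaffold_species) {
  sig <- clusters %>%
    dplyr::group_by(.data$root) %>%
    dplyr::summarise(
      signature = paste(sort(node_key(.data$species, .data$accession)), collapse = ""),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$root) %>%
    dplyr::distinct(.data$signature, .keep_all = TRUE)
  dplyr::semi_join(clusters, sig, by = "root")
}

#' Edge-level alignment measures
#'
#' Computes conserved-interaction counts from the per-scaffold-edge induced
#' edge clusters. `EA_s` sums cluster sizes minus one (members aligned to
#' the scaffold interaction); `EA` sums all unordered member pairs,
#' including pairs involving the scaffold interaction itself. `EF`/`EH`
#' variants weight a member by the product of endpoint indicators: a member
#' (s, t) of the cluster of (u, v) counts toward `EF_s` when F(u, s) and
#' F(v, t) both hold under the member's stored orientation. For all-pairs
#' variants the two member interactions have no canonical endpoint order,
#' so both cross-pairings are tested and the pair counts if either pairing
#' satisfies the indicator product.
#'
#' @inheritParams node_measures
#' @return Named numeric vector: `EA_s`, `EA`, `EF_s`, `EF`, `EH_s`, `EH`,
#'   `EForH_s`, `EForH`.
#' @export
edge_measures <- function(mna, tables = annotation_tables(), threshold = 0.5,
                          distinct = FALSE) {
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  ec <- mna$edge_clusters
  if (distinct) ec <- distinct_edge_clusters(ec)
  sp <- mna$scaffold$species

  is_root <- ec$species == sp & ec$from == ec$root_from & ec$to == ec$root_to
  nonroot <- ec[!is_root, ]
  f1 <- indicator_f(tables, nonroot$root_from, nonroot$from, threshold)
  f2 <- indicator_f(tables, nonroot$root_to, nonroot$to, threshold)
  h1 <- indicator_h(tables, nonroot$root_from, nonroot$from)
  h2 <- indicator_h(tables, nonroot$root_to, nonroot$to)

  members <- ec %>%
    dplyr::mutate(key = paste0(.data$species, ":", pmin(.data$from, .data$to),
                               "--", pmax(.data$from, .data$to)))
  pairs <- dplyr::inner_join(
    members, members, by = c("root_from", "root_to"),
    relationship = "many-to-many", suffix = c(".a", ".b")
  ) %>%
    dplyr::filter(.data$key.a < .data$key.b)
  # straight pairing: B(u)-side endpoints together, B(v)-side together;
  # cross pairing covers members whose stored orientation is ambiguous
  pf <- (indicator_f(tables, pairs$from.a, pairs$from.b, threshold) *
           indicator_f(tables, pairs$to.a, pairs$to.b, threshold)) |
    (indicator_f(tables, pairs$from.a, pairs$to.b, threshold) *
       indicator_f(tables, pairs$to.a, pairs$from.b, threshold))
  ph <- (indicator_h(tables, pairs$from.a, pairs$from.b) *
           indicator_h(tables, pairs$to.a, pairs$to.b)) |
    (indicator_h(tables, pairs$from.a, pairs$to.b) *
       indicator_h(tables, pairs$to.a, pairs$from.b))
  forh <- function(a, b) {
    pmin(1L, indicator_f(tables, a, b, threshold) + indicator_h(tables, a, b))
  }
  pfh <- (forh(pairs$from.a, pairs$from.b) * forh(pairs$to.a, pairs$to.b)) |
    (forh(pairs$from.a, pairs$to.b) * forh(pairs$to.a, pairs$from.b))

  c(
    EA_s = nrow(nonroot),
    EA = nrow(pairs),
    EF_s = sum(f1 * f2),
    EF = sum(pf),
    EH_s = sum(h1 * h2),
    EH = sum(ph),
    EForH_s = sum(pmin(1L, (f1 + h1) * (f2 + h2))),
    EForH = sum(pfh)
  )
}

distinct_edge_clusters <- function(ec) {
  sig <- ec %>%
    dplyr::group_by(.data$root_from, .data$root_to) %>%
    dplyr::summarise(
      signature = paste(sort(paste0(.data$species, ":", pmin(.data$from, .data$to),
                                    "--", pmax(.data$from, .data$to))),
                        collapse = ""),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$root_from, .data$root_to) %>%
    dplyr::distinct(.data$signature, .keep_all = TRUE)
  dplyr::semi_join(ec, sig, by = c("root_from", "root_to"))
}

#' Interactions conserved in at least k species
#'
#' Counts scaffold edges whose induced-edge cluster draws members from at
#' least k - 1 distinct non-scaffold species. k = 1 is tautological (every
#' scaffold edge); the counts are non-increasing in k.
#'
#' @param mna An `mna` (edge clusters computed on the fly if needed).
#' @param k_max Largest k to report; defaults to the number of aligned
#'   species including the scaffold.
#' @return Tibble with columns `k` and `count`.
#' @export
ea_k <- function(mna, k_max = NULL) {
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  if (is.null(k_max)) k_max <- length(mna$networks) + 1L
  breadth <- conserved_breadth(mna)$breadth
  tibble::tibble(
    k = seq_len(max(1L, k_max)),
    count = vapply(seq_len(max(1L, k_max)),
                   function(k) sum(breadth >= k - 1L), integer(1))
  )
}

#' Full assessment report for a multiple network alignment
#'
#' Bundles the node measures, edge measures, conservation-breadth counts
#' (EA-k) and precision of implied correspondences into one report object
#' with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams node_measures
#' @return An object of class `mna_report` with elements `values` (named
#'   numeric), `ea_k` (tibble), `precision` (tibble), `threshold`,
#'   `distinct`, `n_species`.
#' @export
#' @examples
#' fx <- fixture_figure2()
#' mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks)
#' rep <- alignment_measures(mna, fx$tables)
#' tidy(rep)
alignment_measures <- function(mna, tables = annotation_tables(),
                               threshold = 0.5, distinct = FALSE) {
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  values <- c(
    node_measures(mna, tables, threshold, distinct),
    edge_measures(mna, tables, threshold, distinct)
  )
  report <- structure(
    list(
      values = values,
      ea_k = ea_k(mna),
      precision = NULL,
      threshold = threshold,
      distinct = distinct,
      n_species = length(mna$networks) + 1L
    ),
    class = "mna_report"
  )
  report$precision <- alignment_precision(report)
  report
}

#' Precision of implied correspondences
#'
#' The ratio of biologically supported implied alignments to all implied
#' alignments: (X - X_s) / (D - D_s), where D is `NA` for node measures and
#' `EA` for edge measures. Implied alignments are the pairs present in the
#' all-pairs measures but absent from the scaffold-centric ones. When no
#' correspondences are implied (D = D_s) the precision is undefined and
#' reported as `NA` with `defined = FALSE`.
#'
#' @param report An `mna_report` (or any list with a `values` element).
#' @param measures Which measures to compute precision for.
#' @return Tibble with columns `measure`, `precision`, `defined`.
#' @export
alignment_precision <- function(report,
                                measures = c("NF", "NH", "NForH",
                                             "EF", "EH", "EForH")) {
  v <- report$values
  purrr::map_dfr(measures, function(m) {
    denom_name <- if (startsWith(m, "N")) "NA" else "EA"
    d <- unname(v[denom_name] - v[paste0(denom_name, "_s")])
    x <- unname(v[m] - v[paste0(m, "_s")])
    tibble::tibble(
      measure = m,
      precision = if (d > 0) x / d else NA_real_,
      defined = d > 0
    )
  })
}

#' Relative change in precision between two alignments
#'
#' (p - p_ref) / p_ref, e.g. comparing a star-combined alignment to a
#' scaffoldized native multiple alignment. Undefined (`NA`) when the
#' reference precision is zero, missing or undefined.
#'
#' @param p Precision of the alignment under study.
#' @param p_ref Reference precision.
#' @return Signed ratio, or `NA` when undefined.
#' @export
relative_precision_change <- function(p, p_ref) {
  ifelse(is.na(p) | is.na(p_ref) | p_ref <= 0, NA_real_, (p - p_ref) / p_ref)
}

#' @export
print.mna_report <- function(x, ...) {
  cat(sprintf("<mna_report> funSim threshold %s, %s cluster counting\n",
              format(x$threshold),
              if (x$distinct) "distinct" else "per-scaffold-node"))
  v <- x$values
  mat <- matrix(v[c("NA_s", "NF_s", "NH_s", "NForH_s", "EA_s", "EF_s", "EH_s", "EForH_s",
                    "NA", "NF", "NH", "NForH", "EA", "EF", "EH", "EForH")],
                nrow = 2, byrow = TRUE,
                dimnames = list(c("scaffold-centric", "all-pairs"),
                                c("A", "F", "H", "ForH", "EA", "EF", "EH", "EForH")))
  print(mat)
  kk <- x$ea_k
  cat("EA-k: ", paste(sprintf("k=%d:%d", kk$k, kk$count), collapse = "  "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an alignment measure report
#'
#' @param x An `mna_report`.
#' @param ... Unused.
#' @return Tibble with columns `measure`, `scope` (`"scaffold"` or
#'   `"all_pairs"`), `family` and `value`, plus one row per EA-k entry
#'   (scope `"breadth"`).
#' @method tidy mna_report
#' @export
tidy.mna_report <- function(x, ...) {
  v <- x$values
  base <- tibble::tibble(measure = names(v), value = unname(v)) %>%
    dplyr::mutate(
      scope = ifelse(endsWith(.data$measure, "_s"), "scaffold", "all_pairs"),
      family = sub("_s$", "", .data$measure)
    )
  kk <- x$ea_k %>%
    dplyr::transmute(
      measure = paste0("EA-", .data$k), value = as.numeric(.data$count),
      scope = "breadth", family = "EA-k"
    )
  dplyr::bind_rows(base, kk) %>%
    dplyr::select("measure", "scope", "family", "value")
}

#' One-row summary of an alignment report
#'
#' @param x An `mna_report`.
#' @param ... Unused.
#' @return One-row tibble with all measures and node/edge precision.
#' @method glance mna_report
#' @export
glance.mna_report <- function(x, ...) {
  prec <- x$precision
  out <- tibble::as_tibble(as.list(x$values))
  out$precision_NForH <- prec$precision[prec$measure == "NForH"]
  out$precision_EForH <- prec$precision[prec$measure == "EForH"]
  out$threshold <- x$threshold
  out$distinct <- x$distinct
  out
}

#' Plot an alignment measure report
#'
#' Bar panel of scaffold-centric versus all-pairs counts for each measure
#' family, plus the EA-k breadth profile.
#'
#' @param object An `mna_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mna_report
#' @export
autoplot.mna_report <- function(object, ...) {
  df <- tidy(object)
  counts <- df %>% dplyr::filter(.data$scope != "breadth")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$family, y = .data$value,
                                       fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  title = "Alignment measures") +
    ggplot2::theme_minimal()
}

#' Plot the conservation-breadth profile
#'
#' @param mna An `mna`.
#' @param ... Unused.
#' @return A ggplot object showing EA-k versus k.
#' @export
plot_conservation <- function(mna, ...) {
  kk <- ea_k(mna)
  ggplot2::ggplot(kk, ggplot2::aes(x = .data$k, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = kk$k) +
    ggplot2::labs(x = "k (species)", y = "edges conserved in ≥ k species",
                  title = "Conservation breadth") +
    ggplot2::theme_minimal()
}
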