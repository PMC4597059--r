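#' Compute conserved (induced) edge clusters for every scaffold edge
#'
#' For each scaffold edge (u, v), the edge co-alignment cluster collects
#' every interaction (s, t) with s in B(u) and t in B(v) that exists in any
#' loaded network, the scaffold included — these are the conserved
#' interactions associated with (u, v). Matching is undirected: an
#' interaction qualifies if either orientation lands in B(u) x B(v), and the
#' matching orientation is stored (first endpoint in B(u), second in B(v)).
#' An interaction admitted under both orientations is stored once, in
#' canonical (lexicographic) orientation. The scaffold edge itself is always
#' a member of its own cluster.
#'
#' @param mna An `mna` from [combine_alignments()] or [scaffoldize()].
#' @return The `mna` with `edge_clusters` filled: a tibble with one row per
#'   cluster member, columns `root_from`, `root_to` (the scaffold edge,
#'   canonical order), `species`, `from`, `to` (the member interaction,
#'   oriented so `from` is in B(`root_from`) and `to` in B(`root_to`)).
#'   Every scaffold edge has at least its own row.
#' @export
compute_conserved_edges <- function(mna) {
  stopifnot(inherits(mna, "mna"))
  edges_all <- all_edges_table(c(list(mna$scaffold), unname(mna$networks)))
  scaffold_edges <- mna$scaffold$edges %>%
    dplyr::select(root_from = "from", root_to = "to")
  if (nrow(scaffold_edges) == 0) {
    mna$edge_clusters <- tibble::tibble(
      root_from = character(), root_to = character(), species = character(),
      from = character(), to = character()
    )
    return(mna)
  }
  bu <- mna$node_clusters %>%
    dplyr::select(root_from = "root", "species", from = "accession")
  bv <- mna$node_clusters %>%
    dplyr::select(root_to = "root", "species", to = "accession")
  # candidate pairs: B(u) x B(v) restricted to a single species (an
  # interaction always lies within one network), then kept if the pair is an
  # edge of that species under either orientation
  cand <- scaffold_edges %>%
    dplyr::inner_join(bu, by = "root_from", relationship = "many-to-many") %>%
    dplyr::inner_join(bv, by = c("root_to", "species"),
                      relationship = "many-to-many") %>%
    dplyr::mutate(lo = pmin(.data$from, .data$to), hi = pmax(.data$from, .data$to)) %>%
    dplyr::semi_join(edges_all, by = c("species", "lo" = "from", "hi" = "to"))
  # one stored orientation per member: canonical when both orientations match
  clusters <- cand %>%
    dplyr::arrange(.data$root_from, .data$root_to, .data$species, .data$lo,
                   .data$hi, dplyr::desc(.data$from == .data$lo)) %>%
    dplyr::distinct(.data$root_from, .data$root_to, .data$species, .data$lo,
                    .data$hi, .keep_all = TRUE) %>%
    dplyr::select("root_from", "root_to", "species", "from", "to")
  mna$edge_clusters <- clusters
  mna
}

#' Conserved-edge cluster of one scaffold edge
#'
#' @param mna An `mna` with edge clusters computed (they are computed on the
#'   fly otherwise).
#' @param u,v Scaffold accessions of an existing scaffold edge (order
#'   irrelevant).
#' @return Tibble of cluster members (columns as in
#'   [compute_conserved_edges()]).
#' @export
edge_cluster <- function(mna, u, v) {
  lo <- pmin(u, v)
  hi <- pmax(u, v)
  is_edge <- any(mna$scaffold$edges$from == lo & mna$scaffold$edges$to == hi)
  if (!is_edge) {
    stop("(", u, ", ", v, ") is not an edge of the scaffold network")
  }
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  mna$edge_clusters %>%
    dplyr::filter(.data$root_from == lo, .data$root_to == hi)
}

#' Conservation breadth of scaffold edges
#'
#' For every scaffold edge, the number of distinct non-scaffold species
#' contributing at least one induced interaction to its cluster. Scaffold
#' interactions (including the root edge) do not count: breadth measures
#' conservation beyond the scaffold, so an edge with breadth b counts as
#' conserved in b + 1 species.
#'
#' @param mna An `mna` with edge clusters computed.
#' @return Tibble with columns `root_from`, `root_to`, `breadth`, one row
#'   per scaffold edge.
#' @export
conserved_breadth <- function(mna) {
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  mna$scaffold$edges %>%
    dplyr::select(root_from = "from", root_to = "to") %>%
    dplyr::left_join(
      mna$edge_clusters %>%
        dplyr::filter(.data$species != mna$scaffold$species) %>%
        dplyr::group_by(.data$root_from, .data$root_to) %>%
        dplyr::summarise(breadth = dplyr::n_distinct(.data$species), .groups = "drop"),
      by = c("root_from", "root_to")
    ) %>%
    dplyr::mutate(breadth = dplyr::coalesce(.data$breadth, 0L))
}
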