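#' Scaffoldize a native multiple network alignment
#'
#' Converts clusters produced by a native multiple-network aligner into the
#' scaffold-rooted form used by the rest of the package, so both kinds of
#' alignment can be scored with the same measures. Clusters with no
#' scaffold-species member are dropped; a cluster containing m scaffold
#' nodes is duplicated into m rooted clusters with identical member sets;
#' scaffold nodes absent from every retained cluster receive singleton
#' clusters. A scaffold node occurring in several native clusters roots the
#' union of their members.
#'
#' @param native_clusters Tibble with columns `cluster_id`, `species`,
#'   `accession` (e.g. from [read_native_mna()]).
#' @param scaffold The scaffold [ppi_network()].
#' @param networks List of non-scaffold [ppi_network()]s.
#' @return An `mna` (edge clusters not yet computed; see
#'   [compute_conserved_edges()]).
#' @export
scaffoldize <- function(native_clusters, scaffold, networks = list()) {
  stopifnot(inherits(scaffold, "ppi_network"))
  networks <- normalize_member_networks(networks, scaffold)
  clusters <- tibble::as_tibble(native_clusters)
  stopifnot(all(c("cluster_id", "species", "accession") %in% names(clusters)))
  known_sp <- c(scaffold$species, names(networks))
  if (!all(clusters$species %in% known_sp)) {
    stop("cluster member species '",
         setdiff(clusters$species, known_sp)[1], "' has no loaded network")
  }

  roots <- clusters %>%
    dplyr::filter(.data$species == scaffold$species) %>%
    dplyr::select("cluster_id", root = "accession")
  n_dropped <- dplyr::n_distinct(clusters$cluster_id) -
    dplyr::n_distinct(roots$cluster_id)
  if (n_dropped > 0) {
    message(n_dropped, " cluster(s) without a scaffold node dropped")
  }
  rooted <- dplyr::inner_join(roots, clusters, by = "cluster_id",
                              relationship = "many-to-many") %>%
    dplyr::select("root", "species", "accession")
  base <- tibble::tibble(
    root = scaffold$nodes$accession,
    species = scaffold$species,
    accession = scaffold$nodes$accession
  )
  node_clusters <- dplyr::bind_rows(base, rooted) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$root, .data$species, .data$accession)

  structure(
    list(
      scaffold = scaffold,
      networks = networks,
      node_clusters = node_clusters,
      edge_clusters = NULL
    ),
    class = "mna"
  )
}

#' Flatten a scaffold-rooted alignment back into plain clusters
#'
#' The inverse direction of [scaffoldize()]: returns each rooted cluster as
#' a plain cluster record (one per scaffold node).
#'
#' @param mna An `mna`.
#' @return Tibble with columns `cluster_id`, `species`, `accession`.
#' @export
flatten_clusters <- function(mna) {
  mna$node_clusters %>%
    dplyr::mutate(cluster_id = match(.data$root, unique(.data$root))) %>%
    dplyr::select("cluster_id", "species", "accession") %>%
    dplyr::distinct()
}
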