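#' Combine pairwise alignments into a star-based multiple network alignment
#'
#' Builds the node alignment of a scaffold-rooted multiple network
#' alignment: for every scaffold node v, its co-alignment cluster B(v) is
#' the union of v itself with the co-alignment clusters of v from each
#' pairwise alignment. Clusters sharing scaffold nodes are registered under
#' each contained scaffold node and are never merged, so a many-to-many
#' pairwise cluster with two scaffold nodes duplicates its members into two
#' rooted clusters. The result is invariant to the order of `alignments`.
#'
#' @param scaffold The scaffold [ppi_network()].
#' @param alignments List of [pairwise_alignment()]s, all against
#'   `scaffold` and with pairwise-distinct other species.
#' @param networks List of the non-scaffold [ppi_network()]s (needed later
#'   for conserved-edge computation). Defaults to empty, in which case only
#'   node clusters are meaningful.
#' @return An object of class `mna`: a list with the scaffold, the member
#'   networks (named by species), and `node_clusters`, a tibble with one row
#'   per (root, member) pair, columns `root`, `species`, `accession`. The
#'   root itself is a member of its own cluster. `edge_clusters` is `NULL`
#'   until [compute_conserved_edges()] fills it.
#' @seealso [compute_conserved_edges()], [alignment_measures()]
#' @export
#' @examples
#' fx <- fixture_duplication()
#' mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks)
#' mna$node_clusters
combine_alignments <- function(scaffold, alignments, networks = list()) {
  stopifnot(inherits(scaffold, "ppi_network"))
  other_sp <- purrr::map_chr(alignments, "other_species")
  if (anyDuplicated(other_sp)) {
    stop("duplicate aligned species: ", other_sp[duplicated(other_sp)][1],
         "; each species may contribute one pairwise alignment")
  }
  bad <- purrr::map_chr(alignments, "scaffold_species") != scaffold$species
  if (any(bad)) {
    stop("alignment ", which(bad)[1], " has scaffold species '",
         purrr::map_chr(alignments, "scaffold_species")[bad][1],
         "' but the scaffold network is '", scaffold$species, "'")
  }
  networks <- normalize_member_networks(networks, scaffold)

  contributed <- purrr::map_dfr(alignments, function(al) {
    roots <- al$clusters %>%
      dplyr::filter(.data$species == scaffold$species) %>%
      dplyr::select("cluster_id", root = "accession")
    dplyr::inner_join(roots, al$clusters, by = "cluster_id",
                      relationship = "many-to-many") %>%
      dplyr::select("root", "species", "accession")
  })
  base <- tibble::tibble(
    root = scaffold$nodes$accession,
    species = scaffold$species,
    accession = scaffold$nodes$accession
  )
  node_clusters <- dplyr::bind_rows(base, contributed) %>%
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

# Member networks keyed by species, scaffold excluded; validates species.
normalize_member_networks <- function(networks, scaffold) {
  networks <- purrr::keep(networks, function(n) n$species != scaffold$species)
  names(networks) <- purrr::map_chr(networks, "species")
  if (anyDuplicated(names(networks))) {
    stop("duplicate member network species: ",
         names(networks)[duplicated(names(networks))][1])
  }
  networks
}

#' @export
print.mna <- function(x, ...) {
  n_edge <- if (is.null(x$edge_clusters)) "not computed" else
    as.character(dplyr::n_distinct(x$edge_clusters[c("root_from", "root_to")]))
  cat(sprintf(
    paste0("<mna> scaffold '%s' (%d nodes, %d edges), %d member network(s)\n",
           "  node clusters: %d   edge clusters: %s\n"),
    x$scaffold$species, nrow(x$scaffold$nodes), nrow(x$scaffold$edges),
    length(x$networks), dplyr::n_distinct(x$node_clusters$root), n_edge
  ))
  invisible(x)
}

#' Restrict a multiple alignment to the scaffold and one member species
#'
#' Filters every co-alignment cluster to scaffold-species and
#' `other_species` members and recomputes the conserved-edge clusters (if
#' they had been computed). Useful for checking that a constituent pairwise
#' alignment's statistics are unchanged inside the combined alignment.
#'
#' @param mna An [combine_alignments()] result.
#' @param other_species A member-network species identifier, or the scaffold
#'   species itself (degenerate: clusters keep only scaffold members).
#' @return An `mna` restricted to the two species.
#' @export
restrict_to_pair <- function(mna, other_species) {
  known <- c(mna$scaffold$species, names(mna$networks))
  if (!other_species %in% known) {
    stop("unknown species '", other_species, "'; loaded: ",
         paste(known, collapse = ", "))
  }
  keep_sp <- unique(c(mna$scaffold$species, other_species))
  out <- mna
  out$node_clusters <- mna$node_clusters %>%
    dplyr::filter(.data$species %in% keep_sp)
  out$networks <- mna$networks[intersect(names(mna$networks), other_species)]
  if (!is.null(mna$edge_clusters)) {
    out <- compute_conserved_edges(out)
  } else {
    out$edge_clusters <- NULL
  }
  out
}
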