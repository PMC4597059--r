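#' Write alignment results to a directory
#'
#' Writes up to three files: `node_alignment.tsv` (one line per scaffold
#' node: root accession, then the cluster members as
#' `species:accession`, tab-separated, root included), `conserved_edges.tsv`
#' (one line per scaffold edge: `u--v`, then the induced interactions as
#' `species:from--to` in their stored orientation) and, when a report is
#' given, `measures.tsv` (machine-readable `measure TAB value`) plus
#' `report.txt` (human-readable). The node and edge files round-trip
#' losslessly through [read_alignment_result()].
#'
#' @param mna An `mna` with at least node clusters; edge clusters are
#'   computed if missing.
#' @param out_dir Output directory (created if needed).
#' @param report Optional `mna_report` from [alignment_measures()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(mna, out_dir, report = NULL) {
  stopifnot(inherits(mna, "mna"))
  if (nrow(mna$scaffold$nodes) == 0) {
    stop("refusing to write an alignment with an empty scaffold")
  }
  if (is.null(mna$edge_clusters)) mna <- compute_conserved_edges(mna)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  node_lines <- mna$node_clusters %>%
    dplyr::mutate(member = node_key(.data$species, .data$accession)) %>%
    dplyr::arrange(.data$root, .data$member) %>%
    dplyr::group_by(.data$root) %>%
    dplyr::summarise(line = paste(c(.data$root[1], .data$member), collapse = "\t"),
                     .groups = "drop") %>%
    dplyr::arrange(.data$root)
  node_path <- file.path(out_dir, "node_alignment.tsv")
  readr::write_lines(node_lines$line, node_path)

  edge_lines <- mna$scaffold$edges %>%
    dplyr::select(root_from = "from", root_to = "to") %>%
    dplyr::left_join(
      mna$edge_clusters %>%
        dplyr::mutate(member = paste0(.data$species, ":", .data$from, "--", .data$to)),
      by = c("root_from", "root_to")
    ) %>%
    dplyr::arrange(.data$root_from, .data$root_to, .data$member) %>%
    dplyr::group_by(.data$root_from, .data$root_to) %>%
    dplyr::summarise(
      line = paste(c(paste0(.data$root_from[1], "--", .data$root_to[1]),
                     stats::na.omit(.data$member)), collapse = "\t"),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$root_from, .data$root_to)
  edge_path <- file.path(out_dir, "conserved_edges.tsv")
  readr::write_lines(edge_lines$line, edge_path)

  paths <- c(node_path, edge_path)
  if (!is.null(report)) {
    measures_path <- file.path(out_dir, "measures.tsv")
    tidy_rep <- tidy(report) %>% dplyr::select("measure", "value")
    readr::write_tsv(tidy_rep, measures_path)
    txt_path <- file.path(out_dir, "report.txt")
    writeLines(utils::capture.output(print(report)), txt_path)
    paths <- c(paths, measures_path, txt_path)
  }
  invisible(paths)
}

#' Read back an alignment written by [write_results()]
#'
#' Reconstructs the `mna` (node clusters and oriented edge clusters) from
#' the two alignment files.
#'
#' @param out_dir Directory written by [write_results()].
#' @param scaffold The scaffold [ppi_network()].
#' @param networks List of non-scaffold [ppi_network()]s.
#' @return An `mna`.
#' @export
read_alignment_result <- function(out_dir, scaffold, networks = list()) {
  node_path <- file.path(out_dir, "node_alignment.tsv")
  edge_path <- file.path(out_dir, "conserved_edges.tsv")
  ntoks <- parse_token_lines(node_path)
  node_clusters <- purrr::map_dfr(ntoks$tokens, function(tok) {
    members <- split_key(tok[-1])
    tibble::tibble(root = tok[1], species = members$species,
                   accession = members$accession)
  }) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$root, .data$species, .data$accession)

  etoks <- parse_token_lines(edge_path)
  edge_clusters <- purrr::map_dfr(etoks$tokens, function(tok) {
    root <- stringr::str_split_fixed(tok[1], stringr::fixed("--"), 2)
    if (length(tok) == 1) {
      return(tibble::tibble(root_from = character(), root_to = character(),
                            species = character(), from = character(),
                            to = character()))
    }
    sp_edge <- stringr::str_split_fixed(tok[-1], stringr::fixed(":"), 2)
    ends <- stringr::str_split_fixed(sp_edge[, 2], stringr::fixed("--"), 2)
    tibble::tibble(
      root_from = root[1, 1], root_to = root[1, 2],
      species = sp_edge[, 1], from = ends[, 1], to = ends[, 2]
    )
  }) %>%
    dplyr::arrange(.data$root_from, .data$root_to, .data$species,
                   pmin(.data$from, .data$to), pmax(.data$from, .data$to))

  structure(
    list(
      scaffold = scaffold,
      networks = normalize_member_networks(networks, scaffold),
      node_clusters = node_clusters,
      edge_clusters = edge_clusters
    ),
    class = "mna"
  )
}

#' Write a species network as a tab-separated edge list
#'
#' Isolated nodes are written as single-column lines, matching
#' [read_ppi_network()].
#'
#' @param network A [ppi_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ppi_network <- function(network, path) {
  edge_lines <- paste(network$edges$from, network$edges$to, sep = "\t")
  touched <- unique(c(network$edges$from, network$edges$to))
  isolated <- setdiff(network$nodes$accession, touched)
  readr::write_lines(c(edge_lines, isolated), path)
  invisible(path)
}

#' Write a pairwise alignment in the clusters dialect
#'
#' One whitespace-separated cluster per line, members as
#' `species:accession`.
#'
#' @param alignment A [pairwise_alignment()] (or any tibble with
#'   `cluster_id`, `species`, `accession`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_clusters <- function(alignment, path) {
  clusters <- if (inherits(alignment, "pairwise_alignment")) {
    alignment$clusters
  } else {
    tibble::as_tibble(alignment)
  }
  lines <- clusters %>%
    dplyr::mutate(member = node_key(.data$species, .data$accession)) %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(line = paste(sort(.data$member), collapse = "\t"),
                     .groups = "drop") %>%
    dplyr::arrange(.data$cluster_id)
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Write annotation tables as TSV files
#'
#' @param tables An [annotation_tables()].
#' @param funsim_path,homolog_path,blast_path Output paths; `NULL` skips a
#'   table.
#' @return Invisibly, the paths written.
#' @export
write_annotations <- function(tables, funsim_path = NULL, homolog_path = NULL,
                              blast_path = NULL) {
  paths <- character()
  if (!is.null(funsim_path)) {
    readr::write_tsv(tables$funsim, funsim_path, col_names = FALSE)
    paths <- c(paths, funsim_path)
  }
  if (!is.null(homolog_path)) {
    readr::write_tsv(tables$homolog, homolog_path, col_names = FALSE)
    paths <- c(paths, homolog_path)
  }
  if (!is.null(blast_path)) {
    readr::write_tsv(tables$blast, blast_path, col_names = FALSE)
    paths <- c(paths, blast_path)
  }
  invisible(paths)
}
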