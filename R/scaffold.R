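#' Pairwise network similarity for scaffold selection
#'
#' Concrete instances of the abstract similarity S_ij used to pick the
#' scaffold. `node_count` and `edge_count` score a candidate by its own
#' size against every partner (the "most complete network" heuristic);
#' `node_count_min`/`edge_count_min` use the smaller of the two networks'
#' counts (a symmetric, conservative proxy); `blast_pair_count` counts
#' cross-species protein pairs with BLAST E-value below `evalue`;
#' `alignment_measure` looks up a user-supplied quality value per network
#' pair, e.g. a measure computed on precomputed pairwise alignments.
#' `node_count`/`edge_count` are asymmetric: the score is attributed to the
#' candidate `a`.
#'
#' @param a,b Two [ppi_network()]s; `a` is the scaffold candidate.
#' @param method One of `"node_count"`, `"edge_count"`, `"node_count_min"`,
#'   `"edge_count_min"`, `"blast_pair_count"`, `"alignment_measure"`.
#' @param tables An [annotation_tables()] with a BLAST table (required for
#'   `blast_pair_count`).
#' @param evalue E-value threshold (strictly below), default `1e-5`.
#' @param measure_table For `alignment_measure`: data frame with columns
#'   `species_a`, `species_b`, `value` (orientation-independent lookup).
#' @return A non-negative similarity score.
#' @export
pairwise_similarity <- function(a, b,
                                method = c("node_count", "edge_count",
                                           "node_count_min", "edge_count_min",
                                           "blast_pair_count", "alignment_measure"),
                                tables = NULL, evalue = 1e-5,
                                measure_table = NULL) {
  method <- match.arg(method)
  stopifnot(evalue > 0)
  switch(method,
    node_count = nrow(a$nodes),
    edge_count = nrow(a$edges),
    node_count_min = min(nrow(a$nodes), nrow(b$nodes)),
    edge_count_min = min(nrow(a$edges), nrow(b$edges)),
    blast_pair_count = {
      if (is.null(tables) || nrow(tables$blast) == 0) {
        stop("blast_pair_count requires a loaded BLAST table")
      }
      hits <- tables$blast %>%
        dplyr::filter(.data$evalue < .env$evalue) %>%
        dplyr::filter(
          (.data$acc_a %in% a$nodes$accession & .data$acc_b %in% b$nodes$accession) |
            (.data$acc_a %in% b$nodes$accession & .data$acc_b %in% a$nodes$accession)
        )
      nrow(hits)
    },
    alignment_measure = {
      if (is.null(measure_table)) {
        stop("alignment_measure requires a measure_table with per-pair values")
      }
      mt <- tibble::as_tibble(measure_table)
      hit <- mt$value[(mt$species_a == a$species & mt$species_b == b$species) |
                        (mt$species_a == b$species & mt$species_b == a$species)]
      if (length(hit) == 0) {
        stop("no alignment measure supplied for pair (", a$species, ", ",
             b$species, ")")
      }
      hit[1]
    }
  )
}

#' Select the scaffold network
#'
#' Chooses the network i maximizing the row sum over partners j of the
#' pairwise similarity S_ij. Ties are broken by lexicographically smallest
#' species identifier. A precomputed score table can be supplied directly
#' via `scores` (columns `species_a`, `species_b`, `value`, interpreted as
#' S_ab for the ordered pair; missing orientations fall back to the
#' reverse), bypassing `method`.
#'
#' @param networks List of at least two [ppi_network()]s.
#' @inheritParams pairwise_similarity
#' @param scores Optional precomputed pairwise score table overriding
#'   `method`.
#' @return Object of class `scaffold_selection`: list with `species` (the
#'   winner) and `scores`, a tibble of per-candidate row sums with the
#'   winner flagged. [generics::tidy()] returns the score table.
#' @export
#' @examples
#' n1 <- ppi_network(data.frame(from = "a", to = "b"), "sp1")
#' n2 <- ppi_network(data.frame(from = c("x", "y"), to = c("y", "z")), "sp2")
#' select_scaffold(list(n1, n2), method = "node_count")
select_scaffold <- function(networks, method = "node_count",
                            tables = NULL, evalue = 1e-5,
                            measure_table = NULL, scores = NULL) {
  if (is.null(scores)) {
    if (length(networks) < 2) stop("scaffold selection needs at least 2 networks")
    ids <- purrr::map_chr(networks, "species")
    if (anyDuplicated(ids)) stop("duplicate species among candidate networks")
    grid <- tidyr::expand_grid(i = seq_along(networks), j = seq_along(networks)) %>%
      dplyr::filter(.data$i != .data$j)
    scores <- purrr::map2_dfr(grid$i, grid$j, function(i, j) {
      tibble::tibble(
        species_a = ids[i], species_b = ids[j],
        value = pairwise_similarity(networks[[i]], networks[[j]], method,
                                    tables = tables, evalue = evalue,
                                    measure_table = measure_table)
      )
    })
  } else {
    scores <- tibble::as_tibble(scores)
    stopifnot(all(c("species_a", "species_b", "value") %in% names(scores)))
  }
  directed <- dplyr::bind_rows(
    scores,
    dplyr::rename(scores, species_a = "species_b", species_b = "species_a")
  ) %>%
    dplyr::filter(.data$species_a != .data$species_b) %>%
    dplyr::distinct(.data$species_a, .data$species_b, .keep_all = TRUE)
  totals <- directed %>%
    dplyr::group_by(species = .data$species_a) %>%
    dplyr::summarise(total = sum(.data$value), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$species)
  if (nrow(totals) < 2) stop("scaffold selection needs at least 2 networks")
  winner <- totals$species[1]
  totals$selected <- totals$species == winner
  structure(
    list(species = winner, scores = totals, pair_scores = directed),
    class = "scaffold_selection"
  )
}

#' @export
print.scaffold_selection <- function(x, ...) {
  cat("<scaffold_selection> scaffold:", x$species, "\n")
  print(x$scores)
  invisible(x)
}

#' @rdname select_scaffold
#' @param x A `scaffold_selection`.
#' @param ... Unused.
#' @method tidy scaffold_selection
#' @export
tidy.scaffold_selection <- function(x, ...) {
  x$scores
}

#' @rdname select_scaffold
#' @param object A `scaffold_selection`.
#' @method autoplot scaffold_selection
#' @export
autoplot.scaffold_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = stats::reorder(.data$species, .data$total),
                               y = .data$total, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "summed pairwise similarity",
                  title = "Scaffold candidates") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
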