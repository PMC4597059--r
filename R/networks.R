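#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Global node identity: a protein is (species, accession). Keys are used for
# ordering and set operations; ":" is reserved as the separator.
node_key <- function(species, accession) paste(species, accession, sep = ":")

split_key <- function(key) {
  parts <- stringr::str_split_fixed(key, stringr::fixed(":"), 2)
  tibble::tibble(species = parts[, 1], accession = parts[, 2])
}

#' Construct a species interaction network
#'
#' A `ppi_network` holds one species' protein-protein interaction network:
#' a node table and an undirected edge table. Edges are stored canonically
#' (endpoints in lexicographic order) and deduplicated; self-interactions are
#' retained and stored once. Isolated proteins (no interaction partner) are
#' legal nodes.
#'
#' @param edges A data frame with columns `from` and `to` (protein
#'   accessions). May have zero rows.
#' @param species Species identifier (non-empty string).
#' @param nodes Optional character vector of accessions; the union with all
#'   edge endpoints forms the node set.
#'
#' @return An object of class `ppi_network`: a list with elements `species`
#'   (string), `nodes` (tibble with columns `species`, `accession`) and
#'   `edges` (tibble with columns `species`, `from`, `to`, canonical order).
#' @export
#' @examples
#' net <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C")), "sp1")
#' net
ppi_network <- function(edges, species, nodes = character()) {
  stopifnot(is.character(species), length(species) == 1, nzchar(species))
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges <- tibble::tibble(
      species = species,
      from = pmin(as.character(edges$from), as.character(edges$to)),
      to = pmax(as.character(edges$from), as.character(edges$to))
    ) %>%
      dplyr::distinct() %>%
      dplyr::arrange(.data$from, .data$to)
  } else {
    edges <- tibble::tibble(species = character(), from = character(), to = character())
  }
  accs <- sort(unique(c(nodes, edges$from, edges$to)))
  if (any(!nzchar(accs))) stop("empty accession in network '", species, "'")
  structure(
    list(
      species = species,
      nodes = tibble::tibble(species = species, accession = accs),
      edges = edges
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> species '%s': %d proteins, %d interactions\n",
    x$species, nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Read a species network from a tab-separated edge list
#'
#' Accepts 1-3 whitespace-separated columns per non-comment line:
#' `accession_a accession_b [weight]`. Single-column lines declare isolated
#' nodes. Duplicate records and reversed orientations collapse to one
#' undirected edge; self-interactions are kept. Weights are validated as
#' numeric and then discarded: every downstream definition is unweighted.
#'
#' @param path Path to the edge-list file. Lines starting with `#` and blank
#'   lines are skipped.
#' @param species Species identifier assigned to every node in the file.
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path, species) {
  toks <- parse_token_lines(path)
  if (length(toks$tokens) == 0) {
    warning("network file '", path, "' is empty; returning an empty network")
    return(ppi_network(tibble::tibble(from = character(), to = character()), species))
  }
  nfield <- lengths(toks$tokens)
  bad <- which(nfield > 3)
  if (length(bad) > 0) {
    stop("malformed network line ", toks$lineno[bad[1]], " in '", path,
         "': expected at most 3 fields, found ", nfield[bad[1]])
  }
  w_lines <- which(nfield == 3)
  if (length(w_lines) > 0) {
    w <- vapply(toks$tokens[w_lines], `[`, character(1), 3)
    suppressWarnings(wn <- as.numeric(w))
    if (anyNA(wn)) {
      i <- w_lines[which(is.na(wn))[1]]
      stop("malformed network line ", toks$lineno[i], " in '", path,
           "': non-numeric weight '", vapply(toks$tokens[i], `[`, character(1), 3), "'")
    }
  }
  singles <- vapply(toks$tokens[nfield == 1], `[`, character(1), 1)
  pair_tok <- toks$tokens[nfield >= 2]
  edges <- tibble::tibble(
    from = vapply(pair_tok, `[`, character(1), 1),
    to = vapply(pair_tok, `[`, character(1), 2)
  )
  ppi_network(edges, species, nodes = singles)
}

# Shared low-level line tokenizer: drops blank and "#"-comment lines, returns
# tokens plus original line numbers for error reporting.
parse_token_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readr::read_lines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  tokens <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  list(tokens = tokens, lineno = lineno)
}

# Does this network contain the accession?
has_node <- function(network, accession) {
  accession %in% network$nodes$accession
}

# Undirected edge membership lookup table across a list of networks.
all_edges_table <- function(networks) {
  purrr::map_dfr(networks, function(n) n$edges)
}
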