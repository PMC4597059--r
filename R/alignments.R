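#' Construct a pairwise alignment against the scaffold
#'
#' Wraps the clusters produced by one pairwise aligner run between the
#' scaffold network and one other species. Clusters that contain no scaffold
#' node carry no information for a scaffold-rooted alignment and are dropped
#' (with a message reporting how many).
#'
#' @param clusters A data frame with columns `cluster_id`, `species`,
#'   `accession`; one row per cluster member.
#' @param scaffold_species,other_species Species identifiers of the two
#'   aligned networks.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(clusters, scaffold_species, other_species) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("cluster_id", "species", "accession") %in% names(clusters)))
  ok_species <- clusters$species %in% c(scaffold_species, other_species)
  if (!all(ok_species)) {
    stop("cluster member from species '", clusters$species[!ok_species][1],
         "' is neither scaffold ('", scaffold_species, "') nor aligned species ('",
         other_species, "')")
  }
  clusters <- dplyr::distinct(clusters)
  with_scaffold <- clusters %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::filter(any(.data$species == .env$scaffold_species)) %>%
    dplyr::ungroup()
  n_dropped <- dplyr::n_distinct(clusters$cluster_id) -
    dplyr::n_distinct(with_scaffold$cluster_id)
  if (n_dropped > 0) {
    message(n_dropped, " cluster(s) without a scaffold node dropped")
  }
  structure(
    list(
      scaffold_species = scaffold_species,
      other_species = other_species,
      clusters = dplyr::arrange(with_scaffold, .data$cluster_id, .data$species, .data$accession),
      n_dropped_scaffoldless = n_dropped
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> %s ~ %s: %d clusters, %d members\n",
    x$scaffold_species, x$other_species,
    dplyr::n_distinct(x$clusters$cluster_id), nrow(x$clusters)
  ))
  invisible(x)
}

# Resolve accession tokens against a set of networks. Tokens may be bare
# accessions or "species:accession". Bare tokens found in more than one
# network are an unresolvable ambiguity; tokens found in none are dropped.
# Returns list(rows = tibble(line, species, accession), n_unknown = count).
resolve_tokens <- function(tokens, networks, lineno, path) {
  by_species <- purrr::map(networks, function(n) n$nodes$accession)
  names(by_species) <- purrr::map_chr(networks, "species")
  species_ids <- names(by_species)
  n_unknown <- 0L
  rows <- purrr::map2_dfr(tokens, lineno, function(tok, ln) {
    pref <- stringr::str_split_fixed(tok, stringr::fixed(":"), 2)
    has_prefix <- nzchar(pref[, 2]) & pref[, 1] %in% species_ids
    sp <- character(length(tok))
    keep <- logical(length(tok))
    for (i in seq_along(tok)) {
      if (has_prefix[i]) {
        sp[i] <- pref[i, 1]
        tok[i] <- pref[i, 2]
        keep[i] <- tok[i] %in% by_species[[sp[i]]]
      } else {
        hits <- species_ids[vapply(by_species, function(a) tok[i] %in% a, logical(1))]
        if (length(hits) > 1) {
          stop("ambiguous accession '", tok[i], "' on line ", ln, " of '", path,
               "': present in species ", paste(hits, collapse = ", "),
               "; disambiguate with a 'species:accession' prefix")
        }
        keep[i] <- length(hits) == 1
        sp[i] <- if (keep[i]) hits else NA_character_
      }
    }
    n_unknown <<- n_unknown + sum(!keep)
    tibble::tibble(line = ln, species = sp[keep], accession = tok[keep])
  })
  list(rows = rows, n_unknown = n_unknown)
}

#' Read a pairwise alignment file
#'
#' Two dialects are supported. `"pairs"`: two whitespace-separated columns
#' per line, scaffold accession then other-species accession, as emitted by
#' one-to-one aligners. `"clusters"`: one whitespace-separated co-alignment
#' cluster per line, as emitted by many-to-many aligners; members may come
#' from either species and may be prefixed `species:accession`. Accessions
#' absent from both networks are dropped (with a message); bare accessions
#' present in both networks raise an ambiguity error.
#'
#' @param path Path to the alignment file.
#' @param scaffold,other The two [ppi_network()]s being aligned.
#' @param dialect `"pairs"` or `"clusters"`.
#' @return A [pairwise_alignment()].
#' @export
read_pairwise_alignment <- function(path, scaffold, other,
                                    dialect = c("pairs", "clusters")) {
  dialect <- match.arg(dialect)
  toks <- parse_token_lines(path)
  networks <- list(scaffold, other)
  if (length(toks$tokens) == 0) {
    return(pairwise_alignment(
      tibble::tibble(cluster_id = integer(), species = character(), accession = character()),
      scaffold$species, other$species
    ))
  }
  if (dialect == "pairs") {
    nfield <- lengths(toks$tokens)
    if (any(nfield < 2)) {
      i <- which(nfield < 2)[1]
      stop("malformed pairs line ", toks$lineno[i], " in '", path, "': need 2 columns")
    }
    a <- vapply(toks$tokens, `[`, character(1), 1)
    b <- vapply(toks$tokens, `[`, character(1), 2)
    df <- tibble::tibble(
      cluster_id = rep(seq_along(a), 2),
      species = rep(c(scaffold$species, other$species), each = length(a)),
      accession = c(a, b)
    )
    known <- dplyr::bind_rows(scaffold$nodes, other$nodes)
    resolved <- dplyr::semi_join(df, known, by = c("species", "accession"))
    n_unknown <- nrow(df) - nrow(resolved)
    if (n_unknown > 0) message(n_unknown, " unknown accession(s) dropped")
    return(pairwise_alignment(resolved, scaffold$species, other$species))
  }
  resolved <- resolve_tokens(toks$tokens, networks, toks$lineno, path)
  if (resolved$n_unknown > 0) {
    message(resolved$n_unknown, " unknown accession(s) dropped")
  }
  clusters <- resolved$rows %>%
    dplyr::mutate(cluster_id = match(.data$line, unique(.data$line))) %>%
    dplyr::select("cluster_id", "species", "accession")
  pairwise_alignment(clusters, scaffold$species, other$species)
}

#' Read a native multiple-network-alignment cluster file
#'
#' One whitespace-separated cluster per line; members may span any subset of
#' the loaded species. Unlike pairwise inputs, clusters without a scaffold
#' node are retained here: [scaffoldize()] decides their fate.
#'
#' @param path Path to the cluster file.
#' @param networks List of [ppi_network()]s the accessions resolve against.
#' @return A tibble with columns `cluster_id`, `species`, `accession`, with
#'   attribute `n_unknown` counting dropped accessions.
#' @export
read_native_mna <- function(path, networks) {
  toks <- parse_token_lines(path)
  if (length(toks$tokens) == 0) {
    out <- tibble::tibble(cluster_id = integer(), species = character(), accession = character())
    attr(out, "n_unknown") <- 0L
    return(out)
  }
  resolved <- resolve_tokens(toks$tokens, networks, toks$lineno, path)
  if (resolved$n_unknown > 0) {
    message(resolved$n_unknown, " unknown accession(s) dropped")
  }
  out <- resolved$rows %>%
    dplyr::mutate(cluster_id = match(.data$line, unique(.data$line))) %>%
    dplyr::select("cluster_id", "species", "accession") %>%
    dplyr::distinct()
  attr(out, "n_unknown") <- resolved$n_unknown
  out
}

#' Co-alignment cluster of a scaffold node in one pairwise alignment
#'
#' Returns the union of all clusters of `alignment` containing the scaffold
#' node `v`; at minimum `{v}` itself.
#'
#' @param alignment A [pairwise_alignment()].
#' @param v Scaffold accession.
#' @param scaffold The scaffold [ppi_network()] (used to validate `v`).
#' @return A tibble with columns `species`, `accession`.
#' @export
bsj_for_node <- function(alignment, v, scaffold) {
  if (!has_node(scaffold, v)) {
    stop("'", v, "' is not a node of the scaffold network '", scaffold$species, "'")
  }
  own <- tibble::tibble(species = scaffold$species, accession = v)
  hits <- alignment$clusters %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::filter(any(.data$species == alignment$scaffold_species & .data$accession == .env$v)) %>%
    dplyr::ungroup() %>%
    dplyr::select("species", "accession")
  dplyr::bind_rows(own, hits) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$species, .data$accession)
}
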