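#' Worked-example fixture: one scaffold edge, two aligned species
#'
#' Reproduces the canonical two-cluster scenario used throughout the
#' measure documentation: scaffold S with a single interaction (u, v);
#' species A with proteins o, p, q, r and interactions (o, p) and (q, r);
#' species B with non-interacting proteins s and t. The pairwise alignments
#' map o, q and s to u, and p, r and t to v, so B(u) = \{u, o, q, s\} and
#' B(v) = \{v, p, r, t\} and the induced-edge cluster of (u, v) is
#' \{(u, v), (o, p), (q, r)\}. The annotation tables realise the
#' functional-similarity indicator exactly for the pairs u:o, v:p, v:r and
#' p:r, and the homology indicator exactly for q:s and v:t.
#'
#' @return List with elements `scaffold`, `networks` (species A and B),
#'   `alignments` (two [pairwise_alignment()]s) and `tables`
#'   ([annotation_tables()]).
#' @export
#' @examples
#' fx <- fixture_figure2()
#' mna <- combine_alignments(fx$scaffold, fx$alignments, fx$networks)
#' alignment_measures(mna, fx$tables)
fixture_figure2 <- function() {
  scaffold <- ppi_network(tibble::tibble(from = "u", to = "v"), "S")
  net_a <- ppi_network(tibble::tibble(from = c("o", "q"), to = c("p", "r")), "A")
  net_b <- ppi_network(tibble::tibble(from = character(), to = character()),
                       "B", nodes = c("s", "t"))
  al_a <- pairwise_alignment(
    tibble::tibble(
      cluster_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
      species = rep(c("S", "A"), 4),
      accession = c("u", "o", "u", "q", "v", "p", "v", "r")
    ),
    "S", "A"
  )
  al_b <- pairwise_alignment(
    tibble::tibble(
      cluster_id = c(1L, 1L, 2L, 2L),
      species = rep(c("S", "B"), 2),
      accession = c("u", "s", "v", "t")
    ),
    "S", "B"
  )
  tables <- annotation_tables(
    funsim = tibble::tibble(
      acc_a = c("u", "v", "v", "p"),
      acc_b = c("o", "p", "r", "r"),
      score = 0.9
    ),
    homolog = tibble::tibble(
      accession = c("q", "s", "v", "t"),
      group = c("g1", "g1", "g2", "g2")
    )
  )
  list(scaffold = scaffold, networks = list(net_a, net_b),
       alignments = list(al_a, al_b), tables = tables)
}

#' Worked-example fixture: duplication through many-to-many clusters
#'
#' Two pairwise clusters each containing two scaffold nodes:
#' \{u, v, a\} from species A and \{u, w, b\} from species B. Star
#' combination registers each cluster under every contained scaffold node,
#' giving exactly three rooted clusters: B(u) = \{u, v, w, a, b\},
#' B(v) = \{v, u, a\} and B(w) = \{w, u, b\}.
#'
#' @return List with `scaffold`, `networks` and `alignments`.
#' @export
fixture_duplication <- function() {
  scaffold <- ppi_network(tibble::tibble(from = character(), to = character()),
                          "S", nodes = c("u", "v", "w"))
  net_a <- ppi_network(tibble::tibble(from = character(), to = character()),
                       "A", nodes = "a")
  net_b <- ppi_network(tibble::tibble(from = character(), to = character()),
                       "B", nodes = "b")
  al_a <- pairwise_alignment(
    tibble::tibble(cluster_id = 1L, species = c("S", "S", "A"),
                   accession = c("u", "v", "a")),
    "S", "A"
  )
  al_b <- pairwise_alignment(
    tibble::tibble(cluster_id = 1L, species = c("S", "S", "B"),
                   accession = c("u", "w", "b")),
    "S", "B"
  )
  list(scaffold = scaffold, networks = list(net_a, net_b),
       alignments = list(al_a, al_b))
}

#' Specification of a synthetic multi-species network family
#'
#' Defines the generative model for [simulate_family()]: an ancestral
#' scaffold network is drawn as a uniform random graph; each of the
#' `n_species - 1` other species is a degraded, relabelled copy of it.
#' Nodes survive with probability `node_retention`; an edge survives when
#' both endpoints survive, with probability `edge_retention`; spurious
#' edges are added at rate `extra_edge_rate` (expected fraction of the
#' scaffold edge count); a surviving node is duplicated with probability
#' `duplication_rate`, the duplicate inheriting its edges and joining the
#' same co-alignment cluster (producing many-to-many alignments). True
#' ortholog pairs receive a funSim score above 0.5 with probability
#' `funsim_signal` and share a homolog group with probability
#' `homolog_signal`; unrelated pairs hit either indicator at
#' `background_rate`.
#'
#' @param scaffold_size Number of scaffold nodes.
#' @param edge_prob Independent probability of each scaffold edge (ignored
#'   if `n_edges` given).
#' @param n_edges Exact scaffold edge count (optional).
#' @param n_species Total number of species including the scaffold.
#' @param node_retention,edge_retention Survival probabilities in \[0,1\].
#' @param extra_edge_rate Non-negative spurious-edge rate.
#' @param duplication_rate Probability a surviving node is duplicated.
#' @param funsim_signal,homolog_signal Indicator hit rates on true pairs.
#' @param background_rate Indicator hit rate on unrelated pairs.
#' @param seed Integer seed; identical specs give identical output.
#' @return A `family_spec` list.
#' @export
family_spec <- function(scaffold_size = 30, edge_prob = 0.15, n_edges = NULL,
                        n_species = 4, node_retention = 0.8,
                        edge_retention = 0.7, extra_edge_rate = 0.1,
                        duplication_rate = 0, funsim_signal = 0.8,
                        homolog_signal = 0.6, background_rate = 0.02,
                        seed = 1) {
  probs <- c(edge_prob, node_retention, edge_retention, duplication_rate,
             funsim_signal, homolog_signal, background_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (scaffold_size < 1 || n_species < 2) {
    stop("need a positive scaffold size and at least 2 species")
  }
  if (extra_edge_rate < 0) stop("extra_edge_rate must be non-negative")
  max_edges <- choose(scaffold_size, 2)
  if (!is.null(n_edges) && n_edges > max_edges) {
    stop("n_edges = ", n_edges, " exceeds the complete graph (", max_edges, ")")
  }
  structure(
    list(scaffold_size = scaffold_size, edge_prob = edge_prob,
         n_edges = n_edges, n_species = n_species,
         node_retention = node_retention, edge_retention = edge_retention,
         extra_edge_rate = extra_edge_rate, duplication_rate = duplication_rate,
         funsim_signal = funsim_signal, homolog_signal = homolog_signal,
         background_rate = background_rate, seed = as.integer(seed)),
    class = "family_spec"
  )
}

# Run code under a seeded, restored RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic network family with planted orthology
#'
#' Draws the family described by a [family_spec()]: the scaffold, the
#' degraded species copies, the ground-truth pairwise alignments, the
#' annotation tables, and a planted-truth record listing, for every
#' scaffold edge, the species in which a copy of it survives (including
#' survivals created by spurious extra edges between aligned copies).
#'
#' @param spec A [family_spec()].
#' @return List with `scaffold`, `networks`, `alignments`, `tables`,
#'   `truth` (tibble `root_from`, `root_to`, `species`), `mapping` (tibble
#'   `species`, `source`, `accession` of every planted copy) and `spec`.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    n <- spec$scaffold_size
    accs <- sprintf("n%03d", seq_len(n))
    all_pairs <- if (n > 1) {
      idx <- utils::combn(n, 2)
      tibble::tibble(from = accs[idx[1, ]], to = accs[idx[2, ]])
    } else {
      tibble::tibble(from = character(), to = character())
    }
    edges <- if (!is.null(spec$n_edges)) {
      all_pairs[sample.int(nrow(all_pairs), spec$n_edges), ]
    } else {
      all_pairs[stats::runif(nrow(all_pairs)) < spec$edge_prob, ]
    }
    scaffold <- ppi_network(edges, "s0", nodes = accs)

    networks <- list()
    alignments <- list()
    mapping <- list()
    for (j in seq_len(spec$n_species - 1)) {
      sp <- paste0("s", j)
      kept <- accs[stats::runif(n) < spec$node_retention]
      copies <- tibble::tibble(
        source = kept,
        accession = paste0(sp, "_", kept),
        dup = FALSE
      )
      dup_sel <- kept[stats::runif(length(kept)) < spec$duplication_rate]
      if (length(dup_sel) > 0) {
        copies <- dplyr::bind_rows(copies, tibble::tibble(
          source = dup_sel,
          accession = paste0(sp, "_", dup_sel, "_d"),
          dup = TRUE
        ))
      }
      # retained ancestral edges between primary copies
      retained <- scaffold$edges %>%
        dplyr::filter(.data$from %in% kept, .data$to %in% kept) %>%
        dplyr::filter(stats::runif(dplyr::n()) < spec$edge_retention) %>%
        dplyr::transmute(from = paste0(sp, "_", .data$from),
                         to = paste0(sp, "_", .data$to))
      # duplicates inherit the retained edges of their primary copy
      if (length(dup_sel) > 0 && nrow(retained) > 0) {
        prim <- paste0(sp, "_", dup_sel)
        dup_edges <- dplyr::bind_rows(
          retained %>% dplyr::filter(.data$from %in% prim) %>%
            dplyr::mutate(from = paste0(.data$from, "_d")),
          retained %>% dplyr::filter(.data$to %in% prim) %>%
            dplyr::mutate(to = paste0(.data$to, "_d"))
        )
        retained <- dplyr::bind_rows(retained, dup_edges)
      }
      # spurious extra edges among this species' proteins
      n_extra <- stats::rpois(1, spec$extra_edge_rate * nrow(scaffold$edges))
      if (n_extra > 0 && nrow(copies) > 1) {
        a <- sample(copies$accession, n_extra, replace = TRUE)
        b <- sample(copies$accession, n_extra, replace = TRUE)
        extra <- tibble::tibble(from = pmin(a, b), to = pmax(a, b)) %>%
          dplyr::filter(.data$from != .data$to) %>%
          dplyr::distinct()
        retained <- dplyr::bind_rows(retained, extra)
      }
      net <- ppi_network(retained, sp, nodes = copies$accession)
      clusters <- dplyr::bind_rows(
        tibble::tibble(cluster_id = match(copies$source, kept),
                       species = "s0", accession = copies$source),
        tibble::tibble(cluster_id = match(copies$source, kept),
                       species = sp, accession = copies$accession)
      ) %>% dplyr::distinct()
      networks[[sp]] <- net
      alignments[[sp]] <- pairwise_alignment(clusters, "s0", sp)
      mapping[[sp]] <- dplyr::mutate(copies, species = sp)
    }
    mapping <- dplyr::bind_rows(mapping) %>%
      dplyr::select("species", "source", "accession")

    truth <- planted_truth(scaffold, networks, mapping)
    tables <- planted_annotations(scaffold, networks, mapping, spec)

    list(scaffold = scaffold, networks = unname(networks),
         alignments = unname(alignments), tables = tables,
         truth = truth, mapping = mapping, spec = spec)
  })
}

# For every scaffold edge and species: does any copy-level edge realise it?
# Derived from the generator's own copy mapping, independent of the
# alignment machinery.
planted_truth <- function(scaffold, networks, mapping) {
  purrr::map_dfr(networks, function(net) {
    sp <- net$species
    m <- mapping[mapping$species == sp, ]
    realized <- net$edges %>%
      dplyr::inner_join(dplyr::select(m, src_a = "source", from = "accession"),
                        by = "from", relationship = "many-to-many") %>%
      dplyr::inner_join(dplyr::select(m, src_b = "source", to = "accession"),
                        by = "to", relationship = "many-to-many") %>%
      dplyr::transmute(root_from = pmin(.data$src_a, .data$src_b),
                       root_to = pmax(.data$src_a, .data$src_b)) %>%
      dplyr::distinct()
    dplyr::semi_join(
      scaffold$edges %>% dplyr::select(root_from = "from", root_to = "to"),
      realized, by = c("root_from", "root_to")
    ) %>% dplyr::mutate(species = sp)
  })
}

planted_annotations <- function(scaffold, networks, mapping, spec) {
  true_pairs <- tibble::tibble(acc_a = mapping$source, acc_b = mapping$accession)
  hit <- stats::runif(nrow(true_pairs)) < spec$funsim_signal
  fun_scores <- ifelse(hit, stats::runif(nrow(true_pairs), 0.55, 1),
                       stats::runif(nrow(true_pairs), 0, 0.45))
  all_accs <- sort(unlist(c(
    list(scaffold$nodes$accession),
    purrr::map(networks, function(n) n$nodes$accession)
  ), use.names = FALSE))
  n_bg <- stats::rpois(1, spec$background_rate * length(all_accs))
  funsim <- tibble::tibble(acc_a = true_pairs$acc_a, acc_b = true_pairs$acc_b,
                           score = fun_scores)
  if (n_bg > 0 && length(all_accs) > 1) {
    a <- sample(all_accs, n_bg, replace = TRUE)
    b <- sample(all_accs, n_bg, replace = TRUE)
    bg <- tibble::tibble(acc_a = pmin(a, b), acc_b = pmax(a, b),
                         score = stats::runif(n_bg, 0.55, 1)) %>%
      dplyr::filter(.data$acc_a != .data$acc_b)
    funsim <- dplyr::bind_rows(funsim, bg) %>%
      dplyr::distinct(.data$acc_a, .data$acc_b, .keep_all = TRUE)
  }
  homolog <- dplyr::bind_rows(
    tibble::tibble(accession = scaffold$nodes$accession,
                   group = paste0("g_", scaffold$nodes$accession)),
    {
      keep <- stats::runif(nrow(mapping)) < spec$homolog_signal
      tibble::tibble(accession = mapping$accession[keep],
                     group = paste0("g_", mapping$source[keep]))
    }
  )
  n_bg_h <- stats::rpois(1, spec$background_rate * length(all_accs))
  if (n_bg_h > 0) {
    homolog <- dplyr::bind_rows(homolog, tibble::tibble(
      accession = sample(all_accs, n_bg_h, replace = TRUE),
      group = paste0("g_", sample(scaffold$nodes$accession, n_bg_h,
                                  replace = TRUE))
    ))
  }
  annotation_tables(funsim = funsim, homolog = homolog)
}
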