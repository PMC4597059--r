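# Independent, loop-based reference implementations used to cross-check the
# vectorised package code. Deliberately naive: scalar lookups, explicit
# double/triple loops, no shared code with the package internals.

oracle_f <- function(tables, a, b, threshold = 0.5) {
  fs <- tables$funsim
  hit <- which((fs$acc_a == a & fs$acc_b == b) | (fs$acc_a == b & fs$acc_b == a))
  s <- if (length(hit) > 0) fs$score[hit[1]] else 0
  as.integer(s > threshold)
}

oracle_h <- function(tables, a, b) {
  g <- tables$homolog
  ga <- g$group[g$accession == a]
  gb <- g$group[g$accession == b]
  as.integer(length(intersect(ga, gb)) > 0)
}

oracle_forh <- function(tables, a, b, threshold = 0.5) {
  min(1L, oracle_f(tables, a, b, threshold) + oracle_h(tables, a, b))
}

# Brute-force edge co-alignment cluster of scaffold edge (u, v): double loop
# over B(u) x B(v) with an undirected membership test in every network.
# Returns members with the spec'd orientation (first endpoint in B(u)),
# canonical orientation when both match.
oracle_edge_cluster <- function(mna, u, v) {
  nets <- c(list(mna$scaffold), unname(mna$networks))
  bu <- mna$node_clusters[mna$node_clusters$root == u, ]
  bv <- mna$node_clusters[mna$node_clusters$root == v, ]
  seen <- character()
  rows <- list()
  for (i in seq_len(nrow(bu))) {
    for (j in seq_len(nrow(bv))) {
      if (bu$species[i] != bv$species[j]) next
      s <- bu$accession[i]
      t <- bv$accession[j]
      lo <- min(s, t)
      hi <- max(s, t)
      exists <- FALSE
      for (net in nets) {
        if (net$species == bu$species[i] &&
            any(net$edges$from == lo & net$edges$to == hi)) {
          exists <- TRUE
          break
        }
      }
      if (!exists) next
      id <- paste(bu$species[i], lo, hi)
      if (id %in% seen) {
        # second orientation also matches: force canonical
        k <- which(vapply(rows, function(r) r$id == id, logical(1)))
        rows[[k]]$from <- lo
        rows[[k]]$to <- hi
      } else {
        seen <- c(seen, id)
        rows[[length(rows) + 1]] <- list(id = id, species = bu$species[i],
                                         from = s, to = t)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(species = character(), from = character(),
                          to = character()))
  }
  out <- tibble::tibble(
    species = vapply(rows, function(r) r$species, character(1)),
    from = vapply(rows, function(r) r$from, character(1)),
    to = vapply(rows, function(r) r$to, character(1))
  )
  out[order(out$species, pmin(out$from, out$to), pmax(out$from, out$to)), ]
}

# Loop-based node measures over the rooted clusters.
oracle_node_measures <- function(mna, tables, threshold = 0.5) {
  sp <- mna$scaffold$species
  roots <- unique(mna$node_clusters$root)
  na_s <- na_all <- nf_s <- nf <- nh_s <- nh <- nfh_s <- nfh <- 0L
  for (r in roots) {
    cl <- mna$node_clusters[mna$node_clusters$root == r, ]
    keys <- paste(cl$species, cl$accession, sep = ":")
    root_i <- which(cl$species == sp & cl$accession == r)
    for (i in seq_len(nrow(cl))) {
      if (i == root_i) next
      na_s <- na_s + 1L
      nf_s <- nf_s + oracle_f(tables, r, cl$accession[i], threshold)
      nh_s <- nh_s + oracle_h(tables, r, cl$accession[i])
      nfh_s <- nfh_s + oracle_forh(tables, r, cl$accession[i], threshold)
    }
    if (nrow(cl) >= 2) {
      for (i in seq_len(nrow(cl) - 1)) {
        for (j in seq(i + 1, nrow(cl))) {
          na_all <- na_all + 1L
          nf <- nf + oracle_f(tables, cl$accession[i], cl$accession[j], threshold)
          nh <- nh + oracle_h(tables, cl$accession[i], cl$accession[j])
          nfh <- nfh + oracle_forh(tables, cl$accession[i], cl$accession[j],
                                   threshold)
        }
      }
    }
  }
  c(NA_s = na_s, "NA" = na_all, NF_s = nf_s, NF = nf, NH_s = nh_s, NH = nh,
    NForH_s = nfh_s, NForH = nfh)
}

# Loop-based edge measures built on oracle_edge_cluster.
oracle_edge_measures <- function(mna, tables, threshold = 0.5) {
  sp <- mna$scaffold$species
  ea_s <- ea <- ef_s <- ef <- eh_s <- eh <- efh_s <- efh <- 0L
  for (e in seq_len(nrow(mna$scaffold$edges))) {
    u <- mna$scaffold$edges$from[e]
    v <- mna$scaffold$edges$to[e]
    cl <- oracle_edge_cluster(mna, u, v)
    is_root <- cl$species == sp & cl$from == u & cl$to == v
    for (i in which(!is_root)) {
      ea_s <- ea_s + 1L
      f1 <- oracle_f(tables, u, cl$from[i], threshold)
      f2 <- oracle_f(tables, v, cl$to[i], threshold)
      h1 <- oracle_h(tables, u, cl$from[i])
      h2 <- oracle_h(tables, v, cl$to[i])
      ef_s <- ef_s + f1 * f2
      eh_s <- eh_s + h1 * h2
      efh_s <- efh_s + min(1L, (f1 + h1) * (f2 + h2))
    }
    if (nrow(cl) >= 2) {
      for (i in seq_len(nrow(cl) - 1)) {
        for (j in seq(i + 1, nrow(cl))) {
          ea <- ea + 1L
          straight_f <- oracle_f(tables, cl$from[i], cl$from[j], threshold) *
            oracle_f(tables, cl$to[i], cl$to[j], threshold)
          cross_f <- oracle_f(tables, cl$from[i], cl$to[j], threshold) *
            oracle_f(tables, cl$to[i], cl$from[j], threshold)
          ef <- ef + as.integer(straight_f + cross_f > 0)
          straight_h <- oracle_h(tables, cl$from[i], cl$from[j]) *
            oracle_h(tables, cl$to[i], cl$to[j])
          cross_h <- oracle_h(tables, cl$from[i], cl$to[j]) *
            oracle_h(tables, cl$to[i], cl$from[j])
          eh <- eh + as.integer(straight_h + cross_h > 0)
          straight_fh <- oracle_forh(tables, cl$from[i], cl$from[j], threshold) *
            oracle_forh(tables, cl$to[i], cl$to[j], threshold)
          cross_fh <- oracle_forh(tables, cl$from[i], cl$to[j], threshold) *
            oracle_forh(tables, cl$to[i], cl$from[j], threshold)
          efh <- efh + as.integer(straight_fh + cross_fh > 0)
        }
      }
    }
  }
  c(EA_s = ea_s, EA = ea, EF_s = ef_s, EF = ef, EH_s = eh_s, EH = eh,
    EForH_s = efh_s, EForH = efh)
}

# Species breadth by direct set cardinality.
oracle_breadth <- function(mna, u, v) {
  cl <- oracle_edge_cluster(mna, u, v)
  length(unique(cl$species[cl$species != mna$scaffold$species]))
}
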