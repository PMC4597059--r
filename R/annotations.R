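#' Construct annotation tables
#'
#' Bundles the three annotation inputs used by the assessment measures:
#' pairwise functional-similarity (funSim-style) scores in \[0,1\], protein
#' to homolog-group assignments, and BLAST pair records. Lookups are keyed
#' by accession and are orientation-independent; a pair absent from the
#' funSim table scores 0 and a protein absent from the homolog table has no
#' groups.
#'
#' @param funsim Data frame with columns `acc_a`, `acc_b`, `score`.
#' @param homolog Data frame with columns `accession`, `group`; repeated
#'   rows per protein accumulate groups.
#' @param blast Data frame with columns `acc_a`, `acc_b`, `bitscore`,
#'   `evalue`. All pairs are retained; E-value filtering happens downstream.
#' @return An object of class `annotation_tables`.
#' @export
annotation_tables <- function(funsim = NULL, homolog = NULL, blast = NULL) {
  if (is.null(funsim)) {
    funsim <- tibble::tibble(acc_a = character(), acc_b = character(), score = numeric())
  }
  funsim <- tibble::as_tibble(funsim)
  stopifnot(all(c("acc_a", "acc_b", "score") %in% names(funsim)))
  if (!is.numeric(funsim$score)) stop("funSim scores must be numeric")
  if (nrow(funsim) > 0 && (min(funsim$score) < 0 || max(funsim$score) > 1)) {
    stop("funSim scores must lie in [0, 1]")
  }
  funsim <- tibble::tibble(
    acc_a = pmin(as.character(funsim$acc_a), as.character(funsim$acc_b)),
    acc_b = pmax(as.character(funsim$acc_a), as.character(funsim$acc_b)),
    score = funsim$score
  ) %>%
    dplyr::distinct(.data$acc_a, .data$acc_b, .keep_all = TRUE)

  if (is.null(homolog)) {
    homolog <- tibble::tibble(accession = character(), group = character())
  }
  homolog <- tibble::as_tibble(homolog)
  stopifnot(all(c("accession", "group") %in% names(homolog)))
  homolog <- homolog %>%
    dplyr::mutate(accession = as.character(.data$accession),
                  group = as.character(.data$group)) %>%
    dplyr::distinct()

  if (is.null(blast)) {
    blast <- tibble::tibble(acc_a = character(), acc_b = character(),
                            bitscore = numeric(), evalue = numeric())
  }
  blast <- tibble::as_tibble(blast)
  stopifnot(all(c("acc_a", "acc_b", "bitscore", "evalue") %in% names(blast)))
  blast <- tibble::tibble(
    acc_a = pmin(as.character(blast$acc_a), as.character(blast$acc_b)),
    acc_b = pmax(as.character(blast$acc_a), as.character(blast$acc_b)),
    bitscore = as.numeric(blast$bitscore),
    evalue = as.numeric(blast$evalue)
  ) %>%
    dplyr::distinct(.data$acc_a, .data$acc_b, .keep_all = TRUE)

  structure(list(funsim = funsim, homolog = homolog, blast = blast),
            class = "annotation_tables")
}

#' @export
print.annotation_tables <- function(x, ...) {
  cat(sprintf(
    "<annotation_tables> %d funSim pairs, %d homolog-group assignments, %d BLAST pairs\n",
    nrow(x$funsim), nrow(x$homolog), nrow(x$blast)
  ))
  invisible(x)
}

#' Read annotation tables from TSV files
#'
#' Each argument is optional; omitted tables are empty. Formats:
#' funSim `acc_a TAB acc_b TAB score` (score in \[0,1\]);
#' homolog `accession TAB group`, repeated lines allowed;
#' BLAST `acc_a TAB acc_b TAB bitscore TAB evalue`.
#'
#' @param funsim_path,homolog_path,blast_path File paths or `NULL`.
#' @return An [annotation_tables()].
#' @export
read_annotations <- function(funsim_path = NULL, homolog_path = NULL,
                             blast_path = NULL) {
  funsim <- homolog <- blast <- NULL
  if (!is.null(funsim_path)) {
    toks <- parse_token_lines(funsim_path)
    check_fields(toks, 3, funsim_path, "funSim")
    score_chr <- vapply(toks$tokens, `[`, character(1), 3)
    suppressWarnings(score <- as.numeric(score_chr))
    if (anyNA(score)) {
      i <- which(is.na(score))[1]
      stop("non-numeric funSim score '", score_chr[i], "' on line ",
           toks$lineno[i], " of '", funsim_path, "'")
    }
    funsim <- tibble::tibble(
      acc_a = vapply(toks$tokens, `[`, character(1), 1),
      acc_b = vapply(toks$tokens, `[`, character(1), 2),
      score = score
    )
  }
  if (!is.null(homolog_path)) {
    toks <- parse_token_lines(homolog_path)
    check_fields(toks, 2, homolog_path, "homolog")
    homolog <- tibble::tibble(
      accession = vapply(toks$tokens, `[`, character(1), 1),
      group = vapply(toks$tokens, `[`, character(1), 2)
    )
  }
  if (!is.null(blast_path)) {
    toks <- parse_token_lines(blast_path)
    check_fields(toks, 4, blast_path, "BLAST")
    blast <- tibble::tibble(
      acc_a = vapply(toks$tokens, `[`, character(1), 1),
      acc_b = vapply(toks$tokens, `[`, character(1), 2),
      bitscore = as.numeric(vapply(toks$tokens, `[`, character(1), 3)),
      evalue = as.numeric(vapply(toks$tokens, `[`, character(1), 4))
    )
  }
  annotation_tables(funsim = funsim, homolog = homolog, blast = blast)
}

check_fields <- function(toks, n, path, what) {
  if (length(toks$tokens) == 0) return(invisible())
  bad <- which(lengths(toks$tokens) < n)
  if (length(bad) > 0) {
    stop("malformed ", what, " line ", toks$lineno[bad[1]], " in '", path,
         "': expected ", n, " fields")
  }
}

#' Look up funSim scores for accession pairs
#'
#' Vectorised, orientation-independent; missing pairs score 0.
#'
#' @param tables An [annotation_tables()].
#' @param acc_a,acc_b Character vectors of accessions (recycled pairwise).
#' @return Numeric vector of scores in \[0,1\].
#' @export
funsim_score <- function(tables, acc_a, acc_b) {
  lo <- pmin(acc_a, acc_b)
  hi <- pmax(acc_a, acc_b)
  df <- tibble::tibble(acc_a = lo, acc_b = hi)
  out <- dplyr::left_join(df, tables$funsim, by = c("acc_a", "acc_b"))
  dplyr::coalesce(out$score, 0)
}

#' Functional-similarity indicator
#'
#' 1 when the pair's funSim score strictly exceeds `threshold`, else 0. The
#' conventional threshold is 0.5; lower values capture more correspondences
#' at some cost in specificity.
#'
#' @inheritParams funsim_score
#' @param threshold Number in \[0,1\]; strict comparison.
#' @return Integer vector of 0/1.
#' @export
indicator_f <- function(tables, acc_a, acc_b, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  as.integer(funsim_score(tables, acc_a, acc_b) > threshold)
}

#' Homology indicator
#'
#' 1 when the two proteins share at least one homolog-group identifier.
#'
#' @inheritParams funsim_score
#' @return Integer vector of 0/1.
#' @export
indicator_h <- function(tables, acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  if (length(acc_a) == 0) return(integer())
  df <- tibble::tibble(.row = seq_along(acc_a), acc_a = acc_a, acc_b = acc_b)
  hits <- df %>%
    dplyr::inner_join(tables$homolog, by = c("acc_a" = "accession"),
                      relationship = "many-to-many") %>%
    dplyr::inner_join(tables$homolog, by = c("group" = "group", "acc_b" = "accession"),
                      relationship = "many-to-many") %>%
    dplyr::distinct(.data$.row)
  as.integer(df$.row %in% hits$.row)
}

# min(1, F + H): "functionally similar or homologous" indicator.
indicator_forh <- function(tables, acc_a, acc_b, threshold = 0.5) {
  pmin(1L, indicator_f(tables, acc_a, acc_b, threshold) +
         indicator_h(tables, acc_a, acc_b))
}
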