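#' Run the full alignment pipeline from files
#'
#' Convenience driver used by the command-line interface: reads the
#' scaffold and member networks, the pairwise alignment files, and optional
#' annotation tables; combines the alignments, computes conserved edges and
#' the measure report; optionally writes everything to `out_dir`. Outputs
#' are deterministic given identical inputs.
#'
#' @param scaffold_file Path to the scaffold edge list.
#' @param scaffold_species Scaffold species identifier.
#' @param network_files Named character vector: species identifier ->
#'   edge-list path, one per non-scaffold species.
#' @param alignment_files Named character vector: species identifier ->
#'   pairwise alignment path (aligned against the scaffold).
#' @param dialect Alignment file dialect, `"pairs"` or `"clusters"`.
#' @param funsim_file,homolog_file Optional annotation table paths.
#' @param threshold funSim indicator threshold.
#' @param distinct Deduplicate identical clusters in the measures.
#' @param out_dir Optional output directory for [write_results()].
#' @return List with elements `mna` and `report`.
#' @export
run_pipeline <- function(scaffold_file, scaffold_species,
                         network_files, alignment_files,
                         dialect = c("pairs", "clusters"),
                         funsim_file = NULL, homolog_file = NULL,
                         threshold = 0.5, distinct = FALSE,
                         out_dir = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(names(network_files)) || any(!nzchar(names(network_files)))) {
    stop("network_files must be named by species")
  }
  missing_al <- setdiff(names(alignment_files), names(network_files))
  if (length(missing_al) > 0) {
    stop("alignment for unknown species '", missing_al[1],
         "': no network file given")
  }
  scaffold <- read_ppi_network(scaffold_file, scaffold_species)
  networks <- purrr::imap(network_files, function(p, sp) read_ppi_network(p, sp))
  alignments <- purrr::imap(alignment_files, function(p, sp) {
    read_pairwise_alignment(p, scaffold, networks[[sp]], dialect = dialect)
  })
  mna <- combine_alignments(scaffold, unname(alignments), unname(networks))
  mna <- compute_conserved_edges(mna)
  tables <- read_annotations(funsim_path = funsim_file,
                             homolog_path = homolog_file)
  report <- alignment_measures(mna, tables, threshold = threshold,
                               distinct = distinct)
  if (!is.null(out_dir)) {
    write_results(mna, out_dir, report = report)
  }
  list(mna = mna, report = report)
}
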