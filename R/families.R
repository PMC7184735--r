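#' Single-linkage homolog families from pairwise scores
#'
#' Builds families as connected components of the graph whose edges are
#' score pairs passing both thresholds (both inclusive: `e_value <= e_max`
#' and `query_coverage >= cov_min`), the loose homolog-set definition used
#' for CheA neighbourhood genes (1e-40 / 0.95; anti-sigma factor
#' antagonists use the relaxed 1e-5 / 0.50). Family ids are deterministic:
#' the lexicographically smallest member.
#'
#' @param scores data frame with columns `query_id`, `subject_id`,
#'   `e_value`, `query_coverage` (fraction in \[0, 1\]).
#' @param e_max inclusive E-value ceiling.
#' @param cov_min inclusive query-coverage floor.
#' @param seeds optional ids; only families containing a seed are returned.
#' @return Tibble: `protein_id`, `family_id`.
#' @export
link_families <- function(scores, e_max = 1e-40, cov_min = 0.95,
                          seeds = NULL) {
  scores <- as_tibble(scores)
  if (nrow(scores) == 0) {
    return(tibble(protein_id = character(), family_id = character()))
  }
  ids <- sort(unique(c(scores$query_id, scores$subject_id)))
  pass <- scores$e_value <= e_max & scores$query_coverage >= cov_min
  edges <- scores[pass, c("query_id", "subject_id")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)
  membership <- comp$membership
  fam <- tibble(protein_id = names(membership),
                component = as.integer(membership)) |>
    group_by(.data$component) |>
    mutate(family_id = min(.data$protein_id)) |>
    ungroup() |>
    select("protein_id", "family_id") |>
    arrange(.data$protein_id)
  if (!is.null(seeds)) {
    keep <- fam$family_id[fam$protein_id %in% seeds]
    fam <- fam[fam$family_id %in% keep, , drop = FALSE]
  }
  fam
}

#' Pairwise-score table input (BLAST outfmt 6 style)
#'
#' Reads a tab-separated score table. Columns can be named explicitly; the
#' default matches `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore qcovs`, with `qcovs` given in percent.
#'
#' @param path file path.
#' @param col_names column names of the table.
#' @return Tibble with `query_id`, `subject_id`, `e_value`,
#'   `query_coverage` (fraction).
#' @export
read_pair_scores <- function(path,
                             col_names = c("qseqid", "sseqid", "pident",
                                           "length", "mismatch", "gapopen",
                                           "qstart", "qend", "sstart",
                                           "send", "evalue", "bitscore",
                                           "qcovs")) {
  df <- readr::read_tsv(path, col_names = col_names, show_col_types = FALSE)
  tibble(
    query_id = as.character(df$qseqid),
    subject_id = as.character(df$sseqid),
    e_value = as.numeric(df$evalue),
    query_coverage = as.numeric(df$qcovs) / 100
  )
}

#' Extract the gene neighbourhood around an anchor gene
#'
#' Returns up to `k` genes on each side of the anchor on the same replicon
#' (truncated at replicon ends), order preserved — the CheA-neighbourhood
#' windows used for system mapping (k = 10 for CheB/CheR search, k = 15
#' for cluster display).
#'
#' @param genome gene tibble (see [gen_stage_cluster()] for columns).
#' @param anchor_id gene id of the anchor (must be present).
#' @param k window half-width in genes.
#' @return Gene tibble of the neighbourhood, with attribute `anchor`.
#' @export
extract_neighborhood <- function(genome, anchor_id, k = 10) {
  genome <- as_tibble(genome)
  hit <- genome[genome$gene_id == anchor_id, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("anchor '%s' %s in the genome.", anchor_id,
                  if (nrow(hit) == 0) "is absent" else "is duplicated"))
  }
  out <- genome |>
    filter(.data$replicon_id == hit$replicon_id,
           abs(.data$position_index - hit$position_index) <= k) |>
    arrange(.data$position_index)
  attr(out, "anchor") <- anchor_id
  out
}
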