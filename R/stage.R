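#' F7 gene-cluster stage templates
#'
#' The five characteristic F7 gene-cluster arrangements, as ordered family
#' labels. Stage 1 is the ancestral form (anti-sigma factor antagonist,
#' cheY, cheA, two cheW-like genes, an aer2-like receptor, cheR, cheD,
#' cheB, an mcpA-like receptor, a second anti-sigma factor antagonist and a
#' serine phosphatase); stage 5 is the enteric, E. coli-like arrangement
#' with the flagellar flhD/flhC/motA/motB block in front, a duplicated
#' tar-like receptor, and the F6-derived cheY/cheZ pair at the back.
#'
#' @return Named list of character vectors, `S1` ... `S5`.
#' @export
stage_templates <- function() {
  list(
    S1 = c("asfa", "cheY", "cheA", "cheW", "cheW", "aer2", "cheR", "cheD",
           "cheB", "mcpA", "asfa", "sp"),
    S2 = c("mcpA", "asfa", "sp", "cheY", "cheA", "cheW", "aer2", "cheR",
           "cheD", "cheB"),
    S3 = c("cheY", "cheA", "cheW", "tar", "cheR", "cheD", "cheB"),
    S4 = c("flhD", "flhC", "motA", "motB", "cheY", "cheA", "cheW", "tar",
           "cheR", "cheD", "cheB", "cheY", "cheZ"),
    S5 = c("flhD", "flhC", "motA", "motB", "cheA", "cheW", "tar", "tar",
           "cheR", "cheB", "cheY", "cheZ")
  )
}

# union of all template labels: the "relevant" alphabet kept when matching
template_alphabet <- function(templates = stage_templates()) {
  sort(unique(unlist(templates)))
}

# encode label sequences as single characters so utils::adist computes a
# token-level Levenshtein distance
encode_labels <- function(labels, alphabet) {
  chr <- rawToChar(as.raw(65L + seq_along(alphabet) - 1L), multiple = TRUE)
  paste(chr[match(labels, alphabet)], collapse = "")
}

#' Classify an F7 gene cluster into an evolutionary stage
#'
#' Drops background (non-template) family labels, then computes the
#' token-level Levenshtein distance between the cluster's label sequence
#' and each stage template, in both orientations. The call is the stage at
#' minimal distance; ties across stages give `"ambiguous"`, a cluster with
#' no relevant labels gives `"none"`.
#'
#' @param cluster a gene tibble with a `family_label` column (e.g. from
#'   [gen_stage_cluster()] or [extract_neighborhood()]), or a character
#'   vector of family labels.
#' @param templates stage templates, as [stage_templates()].
#' @param relevant labels retained for matching; defaults to the union of
#'   template alphabets.
#' @return One-row tibble: `stage` (`"1"`..`"5"`, `"ambiguous"` or
#'   `"none"`), `edit_distance`, `reversed`, and a `distances` list-column
#'   of per-stage forward/reverse distances.
#' @export
classify_stage <- function(cluster, templates = stage_templates(),
                           relevant = NULL) {
  labels <- if (is.character(cluster)) cluster else cluster$family_label
  labels <- labels[!is.na(labels)]
  relevant <- relevant %||% template_alphabet(templates)
  labels <- labels[labels %in% relevant]
  if (!length(labels)) {
    return(tibble(stage = "none", edit_distance = NA_integer_,
                  reversed = NA, distances = list(NULL)))
  }
  alphabet <- sort(unique(c(relevant, unlist(templates))))
  q_fwd <- encode_labels(labels, alphabet)
  q_rev <- encode_labels(rev(labels), alphabet)
  per_stage <- purrr::imap(templates, function(tpl, nm) {
    t_enc <- encode_labels(tpl, alphabet)
    tibble(
      stage = sub("^S", "", nm),
      forward = as.integer(adist(q_fwd, t_enc)),
      reverse = as.integer(adist(q_rev, t_enc))
    )
  }) |> bind_rows() |>
    mutate(best = pmin(.data$forward, .data$reverse))
  dmin <- min(per_stage$best)
  winners <- per_stage$stage[per_stage$best == dmin]
  if (length(winners) > 1L) {
    return(tibble(stage = "ambiguous", edit_distance = dmin,
                  reversed = NA, distances = list(per_stage)))
  }
  row <- per_stage[per_stage$stage == winners, ]
  tibble(
    stage = winners,
    edit_distance = dmin,
    reversed = row$reverse < row$forward,
    distances = list(per_stage)
  )
}
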