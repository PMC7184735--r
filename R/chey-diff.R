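#' Per-column consensus of one alignment group
#'
#' For each column: the modal non-gap residue and its frequency over the
#' group's non-gap residues. A column is flagged conserved when that
#' frequency reaches `threshold` and the gap fraction does not exceed 0.5;
#' all-gap columns have `NA` consensus. Modal ties break alphabetically so
#' results are deterministic.
#'
#' @param alignment a [grouped_alignment()].
#' @param group group name.
#' @param threshold conservation threshold on the modal frequency, in
#'   (0.5, 1].
#' @return Tibble: `group`, `column` (1-based), `consensus_residue`,
#'   `consensus_frequency`, `gap_fraction`, `conserved`.
#' @export
column_consensus <- function(alignment, group, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must be in (0.5, 1].")
  }
  mat <- group_rows(alignment, group)
  n <- nrow(mat)
  per_col <- function(j) {
    col <- mat[, j]
    gaps <- col %in% c("-", ".")
    res <- col[!gaps]
    if (!length(res)) {
      return(tibble(consensus_residue = NA_character_,
                    consensus_frequency = NA_real_,
                    gap_fraction = 1, conserved = FALSE))
    }
    tab <- sort(table(res), decreasing = TRUE)
    top <- sort(names(tab)[tab == max(tab)])[1]
    freq <- max(tab) / length(res)
    gf <- sum(gaps) / n
    tibble(consensus_residue = top, consensus_frequency = freq,
           gap_fraction = gf,
           conserved = freq >= threshold && gf <= 0.5)
  }
  purrr::map(seq_len(ncol(mat)), per_col) |>
    bind_rows() |>
    mutate(group = group, column = seq_len(ncol(mat)), .before = 1)
}

#' Map alignment columns to reference residue numbers
#'
#' A column maps to the count of non-gap reference residues up to and
#' including it; columns where the reference is gapped map to `NA`.
#'
#' @param alignment a [grouped_alignment()].
#' @param reference_id reference row; defaults to the alignment's.
#' @return Tibble: `column`, `reference_position` (1-based, `NA` at
#'   reference gaps).
#' @export
map_columns_to_reference <- function(alignment, reference_id = NULL) {
  reference_id <- reference_id %||% alignment$reference_id
  if (!reference_id %in% rownames(alignment$matrix)) {
    abort(sprintf("reference row '%s' is not in the alignment.", reference_id))
  }
  ref <- alignment$matrix[reference_id, ]
  nongap <- !(ref %in% c("-", "."))
  pos <- cumsum(nongap)
  pos[!nongap] <- NA_integer_
  tibble(column = seq_along(ref), reference_position = as.integer(pos))
}

# consensus tables for a reference group plus stage groups, joined wide
group_consensus_table <- function(alignment, reference_group, stage_groups,
                                  threshold) {
  all_groups <- c(reference_group, stage_groups)
  known <- unique(alignment$groups$group)
  missing <- setdiff(all_groups, known)
  if (length(missing)) {
    abort(sprintf("unknown group(s): %s (known: %s)",
                  paste(missing, collapse = ", "),
                  paste(known, collapse = ", ")))
  }
  purrr::map(all_groups, function(g) {
    column_consensus(alignment, g, threshold) |>
      select("column", "group", "consensus_residue", "conserved")
  }) |> bind_rows()
}

#' Positions conserved in all groups but different in the reference group
#'
#' A column qualifies when it is conserved (modal frequency >= `threshold`,
#' gap fraction <= 0.5) in the reference group and in every stage group,
#' the stage-group consensus residues are mutually identical, and they
#' differ from the reference-group consensus. Labels are built as
#' reference-consensus + reference residue number + stage consensus
#' (e.g. `M45K`). Columns where the reference row is gapped are reported
#' with `NA` reference position and a warning.
#'
#' @param alignment a [grouped_alignment()].
#' @param reference_group group holding the ancestral consensus
#'   (default `"F6"`).
#' @param stage_groups groups whose shared consensus defines the derived
#'   state.
#' @param threshold conservation threshold (see [column_consensus()]).
#' @return Tibble sorted by reference position: `column`,
#'   `reference_position`, `f6_residue`, `stage_residue`, `label`,
#'   `charge_reversal` (`FALSE` here; see [charge_reversals()]).
#' @export
differential_positions <- function(alignment, reference_group = "F6",
                                   stage_groups = c("stage3", "stage4", "stage5"),
                                   threshold = 0.9) {
  cons <- group_consensus_table(alignment, reference_group, stage_groups,
                                threshold)
  wide <- tidyr::pivot_wider(cons, names_from = "group",
                             values_from = c("consensus_residue", "conserved"))
  res_cols <- paste0("consensus_residue_", stage_groups)
  con_cols <- paste0("conserved_", c(reference_group, stage_groups))
  ref_col <- paste0("consensus_residue_", reference_group)
  all_conserved <- rowSums(!as.matrix(wide[con_cols])) == 0
  stage_mat <- as.matrix(wide[res_cols])
  stage_same <- apply(stage_mat, 1, function(r) length(unique(r)) == 1L)
  qualifies <- all_conserved & stage_same &
    wide[[ref_col]] != stage_mat[, 1]
  out <- tibble(
    column = wide$column[qualifies],
    f6_residue = wide[[ref_col]][qualifies],
    stage_residue = stage_mat[qualifies, 1]
  )
  finish_positions(out, alignment, charge_reversal = FALSE)
}

#' Charge-reversal positions between the reference group and stage groups
#'
#' Like [differential_positions()] but keeps columns where the
#' reference-group consensus charge sign (K/R, optionally H, positive;
#' D/E negative) is opposite to the consensus charge of every stage group,
#' even when the stage residues differ among themselves (E and D both
#' count as the same reversal). The reported stage residue is the modal
#' stage consensus.
#'
#' @inheritParams differential_positions
#' @param histidine_positive treat H as positively charged.
#' @return Tibble as in [differential_positions()], with
#'   `charge_reversal = TRUE`.
#' @export
charge_reversals <- function(alignment, reference_group = "F6",
                             stage_groups = c("stage3", "stage4", "stage5"),
                             threshold = 0.9, histidine_positive = TRUE) {
  cons <- group_consensus_table(alignment, reference_group, stage_groups,
                                threshold)
  wide <- tidyr::pivot_wider(cons, names_from = "group",
                             values_from = c("consensus_residue", "conserved"))
  res_cols <- paste0("consensus_residue_", stage_groups)
  con_cols <- paste0("conserved_", c(reference_group, stage_groups))
  ref_col <- paste0("consensus_residue_", reference_group)
  all_conserved <- rowSums(!as.matrix(wide[con_cols])) == 0
  ref_charge <- residue_charge(wide[[ref_col]], histidine_positive)
  stage_mat <- as.matrix(wide[res_cols])
  stage_charge <- apply(stage_mat, 2, residue_charge, histidine_positive)
  reversed <- ref_charge != 0 &
    apply(stage_charge == -ref_charge, 1, all)
  qualifies <- all_conserved & reversed
  modal_stage <- apply(stage_mat[qualifies, , drop = FALSE], 1, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    sort(names(tab)[tab == max(tab)])[1]
  })
  out <- tibble(
    column = wide$column[qualifies],
    f6_residue = wide[[ref_col]][qualifies],
    stage_residue = as.character(modal_stage)
  )
  finish_positions(out, alignment, charge_reversal = TRUE)
}

residue_charge <- function(res, histidine_positive = TRUE) {
  pos <- c("K", "R", if (histidine_positive) "H")
  ifelse(res %in% pos, 1L, ifelse(res %in% c("D", "E"), -1L, 0L))
}

finish_positions <- function(out, alignment, charge_reversal) {
  if (nrow(out) == 0) {
    return(tibble(column = integer(), reference_position = integer(),
                  f6_residue = character(), stage_residue = character(),
                  label = character(), charge_reversal = logical()))
  }
  refmap <- map_columns_to_reference(alignment)
  out <- left_join(out, refmap, by = "column")
  if (anyNA(out$reference_position)) {
    warn(sprintf("reference row gapped at qualifying column(s) %s; reported with NA position.",
                 paste(out$column[is.na(out$reference_position)], collapse = ", ")))
  }
  out |>
    mutate(
      label = paste0(.data$f6_residue,
                     ifelse(is.na(.data$reference_position), "?",
                            .data$reference_position),
                     .data$stage_residue),
      charge_reversal = charge_reversal
    ) |>
    select("column", "reference_position", "f6_residue", "stage_residue",
           "label", "charge_reversal") |>
    arrange(.data$reference_position)
}
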