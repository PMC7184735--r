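#' Grouped protein alignment
#'
#' One fixed-width protein alignment whose rows are partitioned into named
#' groups (e.g. CheY-F6 and the stage-3/4/5 CheY-F6-like groups), with one
#' row nominated as the numbering reference (e.g. E. coli CheY).
#'
#' @param sequences named character vector of aligned sequences (equal
#'   width; `-` for gaps), or a character matrix with row names.
#' @param groups data frame with columns `id` and `group`, covering every
#'   sequence exactly once, or a named character vector.
#' @param reference_id row used for residue numbering; defaults to the
#'   first sequence.
#' @return A `grouped_alignment` object.
#' @export
grouped_alignment <- function(sequences, groups, reference_id = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences))) abort("`sequences` must be named.")
    widths <- nchar(sequences)
    if (length(unique(widths)) != 1L) {
      abort("aligned sequences must share one width.")
    }
    mat <- do.call(rbind, strsplit(sequences, ""))
    rownames(mat) <- names(sequences)
  }
  if (is.character(groups) && !is.data.frame(groups)) {
    groups <- tibble(id = names(groups), group = unname(groups))
  }
  groups <- as_tibble(groups)[, c("id", "group")]
  missing <- setdiff(rownames(mat), groups$id)
  if (length(missing)) {
    abort(sprintf("rows without a group: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(groups$id)) abort("each row must belong to exactly one group.")
  if (length(unique(groups$group)) < 2) {
    abort("a grouped alignment needs at least 2 groups.")
  }
  reference_id <- reference_id %||% rownames(mat)[1]
  if (!reference_id %in% rownames(mat)) {
    abort(sprintf("reference row '%s' is not in the alignment.", reference_id))
  }
  structure(
    list(matrix = mat, groups = groups, reference_id = reference_id,
         width = ncol(mat)),
    class = "grouped_alignment"
  )
}

#' @export
print.grouped_alignment <- function(x, ...) {
  sizes <- table(x$groups$group)
  cat(sprintf("<grouped_alignment> %d sequences x %d columns; reference %s\n",
              nrow(x$matrix), x$width, x$reference_id))
  cat("groups:", paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy grouped_alignment
#' @export
tidy.grouped_alignment <- function(x, ...) {
  tibble(
    id = rownames(x$matrix),
    sequence = apply(x$matrix, 1, paste, collapse = "")
  ) |> left_join(x$groups, by = "id") |>
    select("id", "group", "sequence")
}

#' @method glance grouped_alignment
#' @export
glance.grouped_alignment <- function(x, ...) {
  tibble(n_sequences = nrow(x$matrix), width = x$width,
         n_groups = length(unique(x$groups$group)),
         reference_id = x$reference_id)
}

# rows of the alignment matrix belonging to one group
group_rows <- function(alignment, group) {
  ids <- alignment$groups$id[alignment$groups$group == group]
  if (!length(ids)) abort(sprintf("group '%s' is empty or unknown.", group))
  alignment$matrix[ids, , drop = FALSE]
}

#' Read and write grouped alignments
#'
#' Alignments travel as aligned FASTA plus a two-column (id, group) TSV.
#' Requires the Biostrings package for FASTA parsing.
#'
#' @param alignment a [grouped_alignment()].
#' @param fasta,groups_tsv file paths.
#' @param reference_id numbering reference (defaults to first row on read).
#' @return `read_grouped_alignment()` returns a [grouped_alignment()].
#' @export
write_grouped_alignment <- function(alignment, fasta, groups_tsv) {
  df <- tidy(alignment)
  writeLines(paste0(">", df$id, "\n", df$sequence), fasta)
  readr::write_tsv(df[, c("id", "group")], groups_tsv)
  invisible(fasta)
}

#' @rdname write_grouped_alignment
#' @export
read_grouped_alignment <- function(fasta, groups_tsv, reference_id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package.")
  }
  aa <- Biostrings::readAAStringSet(fasta)
  seqs <- setNames(as.character(aa), names(aa))
  groups <- readr::read_tsv(groups_tsv, show_col_types = FALSE)
  grouped_alignment(seqs, groups, reference_id = reference_id)
}
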