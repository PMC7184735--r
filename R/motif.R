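#' Scan protein C-termini for the pentapeptide CheR-tether motif
#'
#' Tests the final five residues of each sequence against the tether motif
#' `x-[HFYW]-x-x-[HFYW]`: positions 2 and 5 of the window must be aromatic
#' (H, F, Y or W). Ambiguity codes (B, Z, X) never satisfy the aromatic
#' constraint. With `search_tail > 5`, any five-residue window ending
#' within the last `search_tail` residues may match (tolerance for sloppy
#' C-terminal annotation); the reported pentapeptide and failure position
#' always describe the terminal window.
#'
#' @param sequences tibble with `id` and `sequence` columns, or a (named)
#'   character vector of protein sequences.
#' @param search_tail number of terminal residues searched (default 5:
#'   strictly the C-terminal pentapeptide).
#' @return Tibble: `id`, `matched`, `pentapeptide` (terminal window),
#'   `failure_position` (first failing constrained position, 2 or 5; `NA`
#'   when matched).
#' @export
scan_pentapeptide <- function(sequences, search_tail = 5) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    seqs <- sequences$sequence
  } else {
    seqs <- unname(sequences)
    ids <- names(sequences) %||% sprintf("seq_%03d", seq_along(seqs))
  }
  if (search_tail < 5) abort("`search_tail` must be at least 5.")
  if (any(nchar(seqs) < 5)) {
    abort("all sequences must be at least 5 residues long.")
  }
  window_ok <- function(w) {
    ch <- strsplit(w, "")[[1]]
    ch[2] %in% AROMATIC && ch[5] %in% AROMATIC
  }
  scan_one <- function(s) {
    n <- nchar(s)
    terminal <- substr(s, n - 4, n)
    tail_len <- min(search_tail, n)
    starts <- seq(n - tail_len + 1, n - 4)
    matched <- any(vapply(starts, function(st) {
      window_ok(substr(s, st, st + 4))
    }, logical(1)))
    failure <- NA_integer_
    if (!matched) {
      ch <- strsplit(terminal, "")[[1]]
      failure <- if (!ch[2] %in% AROMATIC) 2L else 5L
    }
    tibble(matched = matched, pentapeptide = terminal,
           failure_position = failure)
  }
  purrr::map(seqs, scan_one) |>
    bind_rows() |>
    mutate(id = ids, .before = 1)
}

#' C-terminal conservation summary (sequence-logo data)
#'
#' Per-column residue frequencies and information content over the last
#' `window` columns of an alignment. Gaps are excluded from the frequency
#' denominator and reported separately; information content is
#' `log2(20) - H` with `H` the Shannon entropy of the residue frequencies
#' (no small-sample correction). All-gap columns get `NA` information.
#'
#' @param alignment character vector of aligned sequences (equal width), a
#'   character matrix, or a [grouped_alignment()].
#' @param window number of terminal columns summarised; `NULL` for all.
#' @return Tibble with one row per column and residue:
#'   `column` (1-based, original alignment coordinates), `residue`,
#'   `frequency`, plus per-column `gap_fraction` and `ic_bits`.
#' @export
cterm_logo <- function(alignment, window = NULL) {
  mat <- if (inherits(alignment, "grouped_alignment")) {
    alignment$matrix
  } else if (is.matrix(alignment)) {
    alignment
  } else {
    if (!length(alignment)) abort("alignment is empty.")
    if (length(unique(nchar(alignment))) != 1L) {
      abort("aligned sequences must share one width.")
    }
    do.call(rbind, strsplit(unname(alignment), ""))
  }
  w <- ncol(mat)
  cols <- if (is.null(window)) seq_len(w) else seq(max(1L, w - window + 1L), w)
  purrr::map(cols, function(j) {
    col <- mat[, j]
    gaps <- col %in% c("-", ".")
    res <- col[!gaps]
    gf <- mean(gaps)
    if (!length(res)) {
      return(tibble(column = j, residue = NA_character_,
                    frequency = NA_real_, gap_fraction = gf,
                    ic_bits = NA_real_))
    }
    tab <- table(factor(res, levels = AA20))
    freq <- as.numeric(tab) / length(res)
    nz <- freq > 0
    ic <- log2(20) + sum(freq[nz] * log2(freq[nz]))
    tibble(column = j, residue = AA20[nz], frequency = freq[nz],
           gap_fraction = gf, ic_bits = ic)
  }) |> bind_rows()
}
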