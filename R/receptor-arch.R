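#' Parse a receptor domain-architecture string
#'
#' Splits a hyphen-separated domain string into ordered tokens and
#' normalises case-insensitive synonyms (`MCP_signal`, `MA` ->
#' `MCPsignal`; `PAS`, `HAMP`, `TM` canonical case). Unknown tokens are
#' preserved as `other:<name>` with a warning.
#'
#' @param domain_string non-empty string, e.g.
#'   `"PAS-PAS-HAMP-HAMP-MCPsignal"`.
#' @param sequence_id optional id carried into the result.
#' @param heptad_class optional heptad class carried into the result
#'   attribute.
#' @return Tibble: `sequence_id`, `position`, `domain`; attribute
#'   `heptad_class`.
#' @export
parse_architecture <- function(domain_string, sequence_id = NA_character_,
                               heptad_class = NULL) {
  if (is.null(domain_string) || is.na(domain_string) ||
      !nzchar(domain_string)) {
    abort("`domain_string` must be a non-empty hyphen-separated string.")
  }
  toks <- strsplit(domain_string, "-", fixed = TRUE)[[1]]
  canon <- c(pas = "PAS", hamp = "HAMP", tm = "TM",
             mcpsignal = "MCPsignal", mcp_signal = "MCPsignal",
             ma = "MCPsignal")
  norm <- vapply(toks, function(tk) {
    hit <- canon[tolower(tk)]
    if (!is.na(hit)) return(unname(hit))
    warn(sprintf("unknown domain token '%s' kept as other:%s.", tk, tk))
    paste0("other:", tk)
  }, character(1), USE.NAMES = FALSE)
  out <- tibble(sequence_id = sequence_id,
                position = seq_along(norm), domain = norm)
  attr(out, "heptad_class") <- heptad_class
  out
}

#' Expected array height bands by receptor heptad class
#'
#' The default table relates signalling-domain heptad class to the
#' expected inner-membrane-to-baseplate distance: 40H receptors form
#' ~24 nm arrays, 34H (two-TM F8 topology) ~22 nm, and 36H Aer2-like
#' receptors the tall 33-41 nm F7 arrays (an envelope over the four
#' measured species, which is why the table is data rather than a printed
#' constant).
#'
#' @return Tibble: `heptad_class`, `expected_nm`, `window_nm`, `note`.
#' @export
default_height_bands <- function() {
  tibble(
    heptad_class = c("40H", "34H", "36H"),
    expected_nm = c(24, 22, 37),
    window_nm = c(3, 3, 4),
    note = c("40H receptors, short flagellar-control arrays",
             "34H two-TM topology, expected ~22 nm (not observed)",
             "36H Aer2-like receptors, envelope of the four tall F7 arrays")
  )
}

#' Look up the expected height band for a heptad class
#'
#' @param heptad_class class label, e.g. `"40H"`.
#' @param table height-band table (defaults to [default_height_bands()]);
#'   can also be loaded from JSON with [read_height_bands()].
#' @return One-row tibble (the band).
#' @export
expected_height <- function(heptad_class, table = default_height_bands()) {
  hit <- table[table$heptad_class == heptad_class, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("unknown heptad class '%s'; table has: %s.",
                  heptad_class, paste(table$heptad_class, collapse = ", ")))
  }
  hit
}

#' @rdname expected_height
#' @param path JSON file with fields `heptad_class`, `expected_nm`,
#'   `window_nm`, `note`.
#' @export
read_height_bands <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname expected_height
#' @param bands a height-band tibble to serialise.
#' @export
write_height_bands <- function(bands, path) {
  jsonlite::write_json(bands, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Correlate measured density layers with receptor domain positions
#'
#' Greedy one-to-one nearest-neighbour assignment of measured layers to
#' user-supplied domain positions (both in nm above the baseplate),
#' within a tolerance. When the current closest separation is achieved by
#' more than one pair, all tied pairs are reported as `ambiguous` rather
#' than chosen arbitrarily; layers with no domain within tolerance are
#' `unassigned`.
#'
#' @param measured a `layer_report` from [measure_layers()], or a tibble
#'   with `label` and `distance_nm` columns.
#' @param domain_positions tibble with `domain` and `position_nm` columns.
#' @param tolerance_nm maximum layer-domain separation for assignment.
#' @return Tibble: `layer`, `domain`, `separation_nm`, `status`
#'   (`assigned`, `ambiguous` or `unassigned`).
#' @export
correlate_layers <- function(measured, domain_positions, tolerance_nm = 3) {
  layers <- if (inherits(measured, "layer_report")) {
    measured$distances
  } else {
    as_tibble(measured)
  }
  domains <- as_tibble(domain_positions)
  if (nrow(layers) == 0 || nrow(domains) == 0) {
    out <- tibble(layer = layers$label %||% character(),
                  domain = NA_character_, separation_nm = NA_real_,
                  status = if (nrow(layers)) "unassigned" else character())
    return(out)
  }
  pairs <- tidyr::expand_grid(
    li = seq_len(nrow(layers)), di = seq_len(nrow(domains))
  ) |>
    mutate(
      layer = layers$label[.data$li],
      domain = domains$domain[.data$di],
      separation_nm = abs(layers$distance_nm[.data$li] -
                            domains$position_nm[.data$di])
    ) |>
    filter(.data$separation_nm <= tolerance_nm)

  out <- list()
  while (nrow(pairs) > 0) {
    dmin <- min(pairs$separation_nm)
    cand <- pairs[abs(pairs$separation_nm - dmin) < 1e-9, ]
    if (nrow(cand) == 1L) {
      out[[length(out) + 1]] <- mutate(cand, status = "assigned")
    } else {
      out[[length(out) + 1]] <- mutate(cand, status = "ambiguous")
    }
    pairs <- pairs[!(pairs$li %in% cand$li) & !(pairs$di %in% cand$di), ]
  }
  assigned <- if (length(out)) {
    bind_rows(out) |> select("layer", "domain", "separation_nm", "status")
  } else {
    tibble(layer = character(), domain = character(),
           separation_nm = numeric(), status = character())
  }
  left_out <- setdiff(layers$label, assigned$layer)
  bind_rows(
    assigned,
    tibble(layer = left_out, domain = NA_character_,
           separation_nm = NA_real_,
           status = rep("unassigned", length(left_out)))
  )
}
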