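#' Phylogenetic profile of chemosensory systems in a genome
#'
#' For each chemosensory class (F6, F7, ...) with labelled genes, reports
#' whether the system is `complete` (every core component present),
#' `absent` (no genes of the class at all) or `partial` (some genes but
#' not all core components). The default core trio is CheA, CheB, CheR —
#' the proteins whose concatenated alignment defines system phylogeny.
#'
#' @param genome gene tibble with `gene_id` and `family_label` columns.
#' @param class_labels data frame (`gene_id`, `class`) or named character
#'   vector mapping gene id to chemosensory class.
#' @param core_components named list mapping class to its core family
#'   labels; classes not named get the default core.
#' @param default_core core labels used when a class has no entry.
#' @return Tibble: `genome_id`, `class`, `status`, plus list-columns
#'   `present_core` and `evidence` (gene ids per present core component).
#' @export
profile_chemosensory_systems <- function(genome, class_labels,
                                         core_components = list(),
                                         default_core = c("cheA", "cheB", "cheR")) {
  genome <- as_tibble(genome)
  if (is.character(class_labels) && !is.data.frame(class_labels)) {
    class_labels <- tibble(gene_id = names(class_labels),
                           class = unname(class_labels))
  }
  class_labels <- as_tibble(class_labels)
  # an explicit core_components map acts as the class registry: labels
  # referring to classes outside it are rejected
  if (length(core_components)) {
    bad <- setdiff(unique(class_labels$class), names(core_components))
    if (length(bad)) {
      abort(sprintf("unknown class name(s) %s; known classes: %s.",
                    paste(bad, collapse = ", "),
                    paste(names(core_components), collapse = ", ")))
    }
  }
  genes <- left_join(genome, class_labels, by = "gene_id")
  classes <- sort(unique(c(class_labels$class, names(core_components))))
  if (!length(classes)) {
    abort(sprintf("no chemosensory classes given (known classes: %s).",
                  paste(known, collapse = ", ")))
  }
  gid <- unique(genome$genome_id) %||% NA_character_
  purrr::map(classes, function(cl) {
    core <- core_components[[cl]] %||% default_core
    cls_genes <- genes[!is.na(genes$class) & genes$class == cl, ]
    present <- intersect(core, cls_genes$family_label)
    status <- if (nrow(cls_genes) == 0) {
      "absent"
    } else if (length(present) == length(core)) {
      "complete"
    } else {
      "partial"
    }
    evidence <- lapply(setNames(present, present), function(lbl) {
      cls_genes$gene_id[cls_genes$family_label == lbl]
    })
    tibble(genome_id = gid[1], class = cl, status = status,
           present_core = list(present), evidence = list(evidence))
  }) |> bind_rows()
}

#' Filter proteins to single response-regulator domains
#'
#' Keeps proteins whose domain architecture is exactly one `Response_reg`
#' domain and nothing else, with no predicted transmembrane helices — the
#' stand-alone CheY candidates (hybrid kinases, methylesterases and
#' multi-domain regulators are dropped).
#'
#' @param proteins data frame with `id`, `domain_string` (hyphen-separated
#'   tokens) and `tm_count` columns.
#' @return The qualifying rows of `proteins`.
#' @export
filter_single_domain_response_regulators <- function(proteins) {
  proteins <- as_tibble(proteins)
  keep <- vapply(seq_len(nrow(proteins)), function(i) {
    toks <- strsplit(proteins$domain_string[i], "-", fixed = TRUE)[[1]]
    identical(toks, "Response_reg") && proteins$tm_count[i] == 0
  }, logical(1))
  proteins[keep, , drop = FALSE]
}

#' Locate CheY partners adjacent to cheZ marker genes
#'
#' CheZ is the marker used to find F6-like CheYs in F7-containing genomes:
#' for each cheZ gene, the genes one position upstream and one downstream
#' on the same replicon are candidates, kept only when they belong to the
#' flagellar CheY clade.
#'
#' @param genome gene tibble.
#' @param cheZ_ids gene ids of cheZ markers.
#' @param clade_members gene ids known to sit in the flagellar CheY clade.
#' @return Tibble: `cheZ_id`, `partner_id`, `offset` (-1/+1). cheZ ids
#'   absent from the genome produce a warning and no rows.
#' @export
locate_cheY_partners <- function(genome, cheZ_ids, clade_members) {
  genome <- as_tibble(genome)
  purrr::map(cheZ_ids, function(cz) {
    row <- genome[genome$gene_id == cz, ]
    if (nrow(row) == 0) {
      warn(sprintf("cheZ gene '%s' absent from the genome.", cz))
      return(NULL)
    }
    nb <- genome |>
      filter(.data$replicon_id == row$replicon_id[1],
             abs(.data$position_index - row$position_index[1]) == 1)
    nb <- nb[nb$gene_id %in% clade_members, ]
    if (nrow(nb) == 0) return(NULL)
    tibble(cheZ_id = cz, partner_id = nb$gene_id,
           offset = nb$position_index - row$position_index[1])
  }) |> bind_rows()
}
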