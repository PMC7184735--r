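#' @rdname gen_stage_cluster
#' @export
background_labels <- function() sprintf("bg%02d", 1:50)

#' Generate a synthetic F7 gene cluster at a given evolutionary stage
#'
#' Takes the stage template ([stage_templates()]), applies seeded random
#' perturbations (`"insert"`: a random template-alphabet label at a random
#' position; `"delete"`: a random core gene; `"swap"`: two adjacent core
#' genes), optionally reverses the cluster (flipping strands), and embeds
#' it between `n_flanking` background genes on each side. Background gene
#' labels come from a fixed 50-name alphabet disjoint from the template
#' labels, so they can never shadow a template match.
#'
#' @param stage integer 1-5.
#' @param n_flanking background genes on each side of the core.
#' @param perturbations character vector drawn from
#'   `c("insert", "delete", "swap")`; applied in order.
#' @param reversed reverse the whole cluster (strands flipped).
#' @param seed integer seed.
#' @param genome_id,replicon_id identifiers written into the gene table.
#' @return A gene tibble (`genome_id`, `replicon_id`, `position_index`,
#'   `strand`, `gene_id`, `family_label`, `domain_string`) with a `truth`
#'   attribute recording the stage, core labels and anchor gene.
#' @export
gen_stage_cluster <- function(stage, n_flanking = 5,
                              perturbations = character(), reversed = FALSE,
                              seed = 1L, genome_id = "synth",
                              replicon_id = "r1") {
  if (!stage %in% 1:5) abort("`stage` must be in 1..5.")
  n_del <- sum(perturbations == "delete")
  core <- stage_templates()[[paste0("S", stage)]]
  if (n_del >= length(core)) {
    abort(sprintf("%d deletions exceed the stage-%d template length (%d).",
                  n_del, stage, length(core)))
  }
  withr::with_seed(seed, {
    for (p in perturbations) {
      if (p == "insert") {
        lab <- sample(template_alphabet(), 1)
        pos <- sample(length(core) + 1, 1)
        core <- append(core, lab, after = pos - 1)
      } else if (p == "delete") {
        core <- core[-sample(length(core), 1)]
      } else if (p == "swap") {
        if (length(core) >= 2) {
          i <- sample(length(core) - 1, 1)
          core[c(i, i + 1)] <- core[c(i + 1, i)]
        }
      } else {
        abort(sprintf("unknown perturbation '%s'.", p))
      }
    }
    core_strand <- rep(if (reversed) "-" else "+", length(core))
    if (reversed) core <- rev(core)
    flank <- function(n) sample(background_labels(), n, replace = TRUE)
    labels <- c(flank(n_flanking), core, flank(n_flanking))
    strands <- c(sample(c("+", "-"), n_flanking, replace = TRUE),
                 core_strand,
                 sample(c("+", "-"), n_flanking, replace = TRUE))
    genes <- tibble(
      genome_id = genome_id,
      replicon_id = replicon_id,
      position_index = seq_along(labels) - 1L,
      strand = strands,
      gene_id = sprintf("%s_g%03d", genome_id, seq_along(labels)),
      family_label = labels,
      domain_string = NA_character_
    )
    anchor <- genes$gene_id[which(genes$family_label == "cheA")[1]]
    attr(genes, "truth") <- list(
      stage = stage, core_labels = core, reversed = reversed,
      anchor = anchor, n_perturbations = length(perturbations)
    )
    genes
  })
}

#' Generate group-structured CheY-like alignments
#'
#' Builds one fixed-width gapless protein alignment partitioned into named
#' groups. Every group shares a background consensus sequence, overridden
#' at specified columns per group; each sequence position equals its
#' group's consensus with probability `conservation`, otherwise a uniform
#' draw from the other 19 residues. Default group sizes follow the four
#' CheY groups used for the group-logo comparison (62 F6 after removal of
#' two gap-opening sequences, 22 stage3, 27 stage4, 24 stage5).
#'
#' @param length alignment width in columns.
#' @param groups tibble with columns `name` and `n`; default the four CheY
#'   groups.
#' @param consensus_overrides named list: for each group name, a named
#'   character vector mapping column index to residue.
#' @param conservation per-column probability of the consensus residue,
#'   in (0, 1].
#' @param background_consensus residue string of length `length`; random
#'   (seeded) when `NULL`.
#' @param seed integer seed.
#' @return A [grouped_alignment()] whose `reference_id` is the first F6 (or
#'   first group's) sequence; attribute `truth` records each group's
#'   consensus and the override columns.
#' @export
gen_group_alignments <- function(length = 120,
                                 groups = tibble(
                                   name = c("F6", "stage3", "stage4", "stage5"),
                                   n = c(62L, 22L, 27L, 24L)
                                 ),
                                 consensus_overrides = list(),
                                 conservation = 0.95,
                                 background_consensus = NULL,
                                 seed = 1L) {
  if (conservation <= 0 || conservation > 1) {
    abort("`conservation` must be in (0, 1].")
  }
  if (anyDuplicated(groups$name)) abort("group names must be unique.")
  for (g in names(consensus_overrides)) {
    ov <- consensus_overrides[[g]]
    cols <- as.integer(names(ov))
    if (any(cols < 1 | cols > length)) {
      abort(sprintf("override column outside alignment for group '%s'.", g))
    }
    if (!all(ov %in% AA20)) {
      abort(sprintf("override residue not a standard amino acid in group '%s'.", g))
    }
  }
  withr::with_seed(seed, {
    bg <- background_consensus %||%
      paste(sample(AA20, length, replace = TRUE), collapse = "")
    bg_vec <- strsplit(bg, "")[[1]]
    stopifnot(length(bg_vec) == length)
    seqs <- character(0)
    grp <- tibble(id = character(), group = character())
    truth_cons <- list()
    for (gi in seq_len(nrow(groups))) {
      gname <- groups$name[gi]
      cons <- bg_vec
      ov <- consensus_overrides[[gname]]
      if (!is.null(ov)) cons[as.integer(names(ov))] <- unname(ov)
      truth_cons[[gname]] <- paste(cons, collapse = "")
      for (si in seq_len(groups$n[gi])) {
        keep <- runif(length) < conservation
        row <- cons
        if (any(!keep)) {
          row[!keep] <- vapply(cons[!keep], function(cr) {
            sample(setdiff(AA20, cr), 1)
          }, character(1))
        }
        id <- sprintf("%s_%03d", gname, si)
        seqs[id] <- paste(row, collapse = "")
        grp <- bind_rows(grp, tibble(id = id, group = gname))
      }
    }
    aln <- grouped_alignment(seqs, grp, reference_id = grp$id[1])
    attr(aln, "truth") <- list(
      background_consensus = bg,
      group_consensus = truth_cons,
      overrides = consensus_overrides,
      conservation = conservation
    )
    aln
  })
}

#' Generate a synthetic receptor set with and without the pentapeptide tether
#'
#' Random protein sequences where exactly `n_with_tether` end in a
#' pentapeptide matching `x-[HFYW]-x-x-[HFYW]` and the rest carry a valine
#' at motif position 2 (the McpA-like negative control), with an aromatic
#' residue still at position 5 so the motif fails at position 2 alone.
#'
#' @param n_with_tether,n_without sequence counts (>= 0).
#' @param seed integer seed.
#' @param length sequence length.
#' @return Tibble (`id`, `sequence`, `tethered`), the truth flag being
#'   `tethered`.
#' @export
gen_receptor_set <- function(n_with_tether, n_without, seed = 1L,
                             length = 300) {
  stopifnot(n_with_tether >= 0, n_without >= 0)
  withr::with_seed(seed, {
    non_aromatic <- setdiff(AA20, AROMATIC)
    make_seq <- function(tethered) {
      body <- sample(AA20, length - 5, replace = TRUE)
      p2 <- if (tethered) sample(AROMATIC, 1) else "V"
      penta <- c(sample(AA20, 1), p2, sample(AA20, 2, replace = TRUE),
                 sample(AROMATIC, 1))
      paste(c(body, penta), collapse = "")
    }
    flags <- c(rep(TRUE, n_with_tether), rep(FALSE, n_without))
    tibble(
      id = sprintf("rcpt_%03d", seq_along(flags)),
      sequence = vapply(flags, make_seq, character(1)),
      tethered = flags
    )
  })
}

#' Genome gene-table input/output
#'
#' Gene tables are tab-separated with columns `genome_id`, `replicon_id`,
#' `position_index`, `strand`, `gene_id`, `family_label`, `domain_string`.
#'
#' @param genes a gene tibble.
#' @param path file path.
#' @return `read_genome_table()` returns a tibble.
#' @export
write_genome_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' @rdname write_genome_table
#' @export
read_genome_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    position_index = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}
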