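# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# phantom with the cross-species layer geometry (baseplate 37 nm above the
# membrane midplane, layers 17.5 / 24.5 / 30.1 nm above the baseplate)
layered_phantom_spec <- function(noise_sigma = 0, seed = 1, tilt = 0,
                                 dims = c(96, 40, 40)) {
  phantom_spec(
    dims = dims, voxel_size = 1, membrane_position = 46,
    baseplate_offset = 37, layer_offsets = c(17.5, 24.5, 30.1),
    layer_sigma = 2, noise_sigma = noise_sigma, tilt_degrees = tilt,
    seed = seed
  )
}

# full measurement pipeline: phantom -> profile -> labelled peaks -> report;
# the profile extent spans the expected structure plus a small margin
measure_phantom <- function(spec, extent_nm = NULL, min_prominence = 0.05,
                            min_separation_nm = 4) {
  # span the structure plus margin, capped by the volume's membrane-side
  # extent (membrane midplane sits 46 nm into the 96 nm volume)
  if (is.null(extent_nm)) extent_nm <- min(spec$baseplate_offset + 8, 45)
  ph <- gen_layer_volume(spec)
  pr <- collapse_profile(ph$volume, ph$trace, extent_nm = extent_nm,
                         bin_width_nm = 1)
  pk <- label_peaks(detect_peaks(pr, min_prominence = min_prominence,
                                 min_separation_nm = min_separation_nm))
  tidy(measure_layers(pk, "AW"))
}

# the ten F6 -> stage consensus substitutions at E. coli CheY coordinates
chey_substitutions <- function() {
  tibble::tribble(
    ~position, ~f6, ~stage,
    22L, "K", "R",
    26L, "R", "K",
    27L, "D", "E",
    37L, "D", "E",
    45L, "M", "K",
    56L, "T", "S",
    62L, "G", "N",
    92L, "R", "K",
    94L, "Q", "N",
    103L, "V", "A"
  )
}

# grouped CheY alignment embedding the ten substitutions and, optionally,
# the K117(E/D/E) charge reversal
chey_alignment <- function(conservation = 0.95, seed = 1,
                           with_charge_reversal = TRUE, length = 129) {
  subs <- chey_substitutions()
  ov_f6 <- stats::setNames(subs$f6, subs$position)
  ov_st <- stats::setNames(subs$stage, subs$position)
  ov_st3 <- ov_st; ov_st4 <- ov_st; ov_st5 <- ov_st
  if (with_charge_reversal) {
    ov_f6 <- c(ov_f6, "117" = "K")
    ov_st3 <- c(ov_st3, "117" = "E")
    ov_st4 <- c(ov_st4, "117" = "D")
    ov_st5 <- c(ov_st5, "117" = "E")
  }
  gen_group_alignments(
    length = length,
    consensus_overrides = list(F6 = ov_f6, stage3 = ov_st3,
                               stage4 = ov_st4, stage5 = ov_st5),
    conservation = conservation, seed = seed
  )
}

# brute-force single-linkage oracle: transitive closure over passing edges
union_find_oracle <- function(scores, e_max, cov_min) {
  ids <- sort(unique(c(scores$query_id, scores$subject_id)))
  n <- length(ids)
  adj <- diag(TRUE, n)
  pass <- scores$e_value <= e_max & scores$query_coverage >= cov_min
  for (r in which(pass)) {
    i <- match(scores$query_id[r], ids)
    j <- match(scores$subject_id[r], ids)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- apply(adj, 1, function(row) min(ids[row]))
  tibble::tibble(protein_id = ids, family_id = unname(comp))
}

# random pairwise-score table over n proteins
random_scores <- function(n, n_edges, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n))
    tibble::tibble(
      query_id = sample(ids, n_edges, replace = TRUE),
      subject_id = sample(ids, n_edges, replace = TRUE),
      e_value = 10^stats::runif(n_edges, -60, -20),
      query_coverage = stats::runif(n_edges, 0.8, 1)
    )
  })
}
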