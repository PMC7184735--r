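make_aln <- function(rows, groups, reference_id = NULL) {
  grouped_alignment(rows, groups, reference_id = reference_id)
}

test_that("column consensus counts match a direct tally, boundary inclusive", {
  rows <- c(a1 = "KKKA", a2 = "KKRA", a3 = "KRRA",
            b1 = "KKKK", b2 = "KKKK")
  grp <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  aln <- make_aln(rows, grp)
  cc <- column_consensus(aln, "A", threshold = 0.9)
  expect_equal(cc$consensus_residue, c("K", "K", "R", "A"))
  expect_equal(cc$consensus_frequency, c(1, 2 / 3, 2 / 3, 1))
  expect_equal(cc$conserved, c(TRUE, FALSE, FALSE, TRUE))

  # 9 K + 1 R at threshold 0.9: boundary is inclusive
  rows2 <- setNames(c(rep("K", 9), "R"), sprintf("s%02d", 1:10))
  grp2 <- setNames(c(rep("X", 9), "Y"), names(rows2))
  # need two groups: put the R row in its own group and test group X + R row
  rows3 <- setNames(c(rep("K", 9), "R", "K"), sprintf("s%02d", 1:11))
  grp3 <- setNames(c(rep("X", 10), "Y"), names(rows3))
  cc3 <- column_consensus(make_aln(rows3, grp3), "X", threshold = 0.9)
  expect_true(cc3$conserved)
  expect_equal(cc3$consensus_frequency, 0.9)

  expect_error(column_consensus(make_aln(rows, grp), "nope"), "empty or unknown")
  expect_error(column_consensus(make_aln(rows, grp), "A", threshold = 0.4),
               "threshold")
})

test_that("consensus frequencies agree with a brute-force count on random data", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(4:10, 1); w <- sample(3:8, 1)
      mat <- matrix(sample(c(aa20, "-"), n * w, replace = TRUE), nrow = n)
      rownames(mat) <- sprintf("r%02d", seq_len(n))
      grp <- setNames(c("G", rep(c("G", "H"), length.out = n - 1)),
                      rownames(mat))
      aln <- grouped_alignment(mat, grp)
      cc <- column_consensus(aln, "G", threshold = 0.51)
      gmat <- mat[names(grp)[grp == "G"], , drop = FALSE]
      for (j in seq_len(w)) {
        col <- gmat[, j]; col <- col[col != "-"]
        if (!length(col)) {
          expect_true(is.na(cc$consensus_frequency[j]))
        } else {
          tab <- table(col)
          expect_equal(cc$consensus_frequency[j],
                       max(tab) / length(col))
        }
      }
    }
  })
})

test_that("column-to-reference mapping follows cumulative non-gap counts", {
  rows <- c(ref = "-MK", oth = "AMK", o2 = "AAA")
  grp <- c(ref = "A", oth = "B", o2 = "B")
  aln <- make_aln(rows, grp, reference_id = "ref")
  m <- map_columns_to_reference(aln)
  expect_equal(m$reference_position, c(NA, 1L, 2L))

  # gapless reference: column i maps to residue i
  rows2 <- c(r = "MKLV", s = "MKLV")
  aln2 <- make_aln(rows2, c(r = "A", s = "B"), "r")
  expect_equal(map_columns_to_reference(aln2)$reference_position, 1:4)

  # random gapped rows against a cumulative-count oracle
  withr::with_seed(23, {
    for (i in 1:10) {
      ref <- sample(c(aa20, "-"), 12, replace = TRUE)
      rows3 <- c(ref = paste(ref, collapse = ""),
                 o = paste(sample(aa20, 12, replace = TRUE), collapse = ""))
      aln3 <- make_aln(rows3, c(ref = "A", o = "B"), "ref")
      got <- map_columns_to_reference(aln3)$reference_position
      want <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-"))
      expect_equal(got, as.integer(want))
    }
  })
})

test_that("the ten embedded substitutions are recovered exactly at full conservation", {
  aln <- chey_alignment(conservation = 1, seed = 3,
                        with_charge_reversal = FALSE)
  dp <- differential_positions(aln, threshold = 0.9)
  subs <- chey_substitutions()
  expect_equal(dp$reference_position, subs$position)
  expect_equal(dp$label, paste0(subs$f6, subs$position, subs$stage))
  expect_false(any(dp$charge_reversal))
})

test_that("identical groups yield no differential positions", {
  aln <- gen_group_alignments(length = 30, conservation = 1, seed = 4)
  expect_equal(nrow(differential_positions(aln)), 0L)
  expect_equal(nrow(charge_reversals(aln)), 0L)
})

test_that("a stage group breaking the shared consensus excludes the column", {
  rows <- c(f1 = "AKA", f2 = "AKA",
            s3 = "ARA", s4 = "ANA", s5 = "ARA")
  grp <- c(f1 = "F6", f2 = "F6", s3 = "stage3", s4 = "stage4", s5 = "stage5")
  aln <- make_aln(rows, grp, reference_id = "s5")
  dp <- differential_positions(aln, threshold = 0.9)
  expect_equal(nrow(dp), 0L)
  # restoring agreement re-admits it
  rows2 <- rows; rows2["s4"] <- "ARA"
  dp2 <- differential_positions(make_aln(rows2, grp, "s5"), threshold = 0.9)
  expect_equal(dp2$label, "K2R")
})

test_that("charge reversals allow differing acidic stage residues", {
  rows <- c(f1 = "AKA", f2 = "AKA",
            s3 = "AEA", s4 = "ADA", s5 = "AEA")
  grp <- c(f1 = "F6", f2 = "F6", s3 = "stage3", s4 = "stage4", s5 = "stage5")
  aln <- make_aln(rows, grp, reference_id = "s5")
  # mixed E/D stage consensus is not a differential position...
  expect_equal(nrow(differential_positions(aln, threshold = 0.9)), 0L)
  # ...but is a charge reversal, labelled with the modal stage residue
  cr <- charge_reversals(aln, threshold = 0.9)
  expect_equal(cr$label, "K2E")
  expect_true(cr$charge_reversal)

  # same-sign substitution is not a reversal
  rows_r <- c(f1 = "AKA", f2 = "AKA", s3 = "ARA", s4 = "ARA", s5 = "ARA")
  expect_equal(nrow(charge_reversals(make_aln(rows_r, grp, "s5"),
                                     threshold = 0.9)), 0L)
  # neutral stage residue is not a reversal
  rows_s <- c(f1 = "AKA", f2 = "AKA", s3 = "ASA", s4 = "ASA", s5 = "ASA")
  expect_equal(nrow(charge_reversals(make_aln(rows_s, grp, "s5"),
                                     threshold = 0.9)), 0L)
})

test_that("K117-type reversal is recovered from the generated alignment", {
  aln <- chey_alignment(conservation = 1, seed = 5)
  cr <- charge_reversals(aln, threshold = 0.9)
  expect_equal(cr$reference_position, 117L)
  expect_equal(cr$label, "K117E")
})

test_that("results are invariant under row order", {
  aln <- chey_alignment(conservation = 0.95, seed = 9)
  dp <- differential_positions(aln, threshold = 0.75)
  perm <- withr::with_seed(1, sample(nrow(aln$matrix)))
  aln2 <- grouped_alignment(aln$matrix[perm, , drop = FALSE],
                            aln$groups[match(rownames(aln$matrix)[perm],
                                             aln$groups$id), ],
                            reference_id = aln$reference_id)
  expect_equal(differential_positions(aln2, threshold = 0.75), dp)
})

test_that("raising the threshold never adds positions", {
  aln <- chey_alignment(conservation = 0.9, seed = 13)
  lo <- differential_positions(aln, threshold = 0.75)
  mid <- differential_positions(aln, threshold = 0.85)
  hi <- differential_positions(aln, threshold = 0.95)
  expect_true(all(mid$column %in% lo$column))
  expect_true(all(hi$column %in% mid$column))
})

test_that("a gapped reference column is reported with NA position and warning", {
  rows <- c(f1 = "AKA", f2 = "AKA", s3 = "ARA", s4 = "ARA",
            s5a = "A-A", s5b = "ARA")
  grp <- c(f1 = "F6", f2 = "F6", s3 = "stage3", s4 = "stage4",
           s5a = "stage5", s5b = "stage5")
  aln <- make_aln(rows, grp, reference_id = "s5a")
  expect_warning(dp <- differential_positions(aln, threshold = 0.9), "gapped")
  expect_true(any(is.na(dp$reference_position)))
  expect_true(any(grepl("\\?", dp$label)))
})
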