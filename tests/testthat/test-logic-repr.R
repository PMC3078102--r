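test_that("bin_percentage is the decile-plus-one map", {
  expect_identical(bin_percentage(0), 1L)
  expect_identical(bin_percentage(15), 2L)   # "between 10 and 20 percent"
  expect_identical(bin_percentage(100), 11L)
  expect_identical(bin_percentage(c(9.99, 10)), c(1L, 2L))
  expect_error(bin_percentage(101), "out of range")
  expect_error(bin_percentage(-1), "out of range")
})

test_that("the 16 property groups have the published memberships", {
  g <- property_groups()
  expect_length(g, 16)
  expect_setequal(g$small, c("A", "G", "S", "T"))
  expect_setequal(g$tiny, c("A", "G"))
  expect_setequal(g$hydrophobic, c("I", "L", "M", "V"))
  # the unusual published "charged" membership, kept verbatim
  expect_setequal(g$charged, c("D", "E", "H", "I", "K", "L", "R", "V"))
  expect_setequal(g$polar,
                  c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"))
})

test_that("sequential_atoms computes binned composition features", {
  a <- sequential_atoms("IIII")
  expect_true("hydrophobic(11)" %in% a)       # 100% -> bin 11
  expect_true("aminoacidRatio(i,11)" %in% a)
  expect_true("aminoacidPairRatio(ii,11)" %in% a)
  # exactly one atom per property group
  preds <- sub("\\(.*$", "", a)
  expect_equal(sum(preds %in% names(property_groups())), 16L)

  b <- sequential_atoms("AG")
  expect_true(all(c("tiny(11)", "small(11)") %in% b))

  # an adjacent CG dimer yields a lower-cased pair constant
  d <- sequential_atoms(paste0("CG", strrep("A", 18)))
  expect_true(any(grepl("^aminoacidPairRatio\\(cg,", d)))
})

test_that("non-standard residues count toward length only", {
  # "AXAX": 2 A of length 4 -> 50% -> bin 6; X excluded everywhere
  a <- sequential_atoms("AXAX")
  expect_true("aminoacidRatio(a,6)" %in% a)
  expect_false(any(grepl("x", a)))
  expect_true("tiny(6)" %in% a)  # A only, still over length 4
  # no dimer has a non-canonical member ("AX", "XA" skipped)
  expect_false(any(grepl("^aminoacidPairRatio", a)))
})

test_that("property bins are composition-only (shuffle-invariant)", {
  s <- random_query(60, seed = 9)
  shuf <- withr::with_seed(10, paste(sample(strsplit(s, "")[[1]]),
                                     collapse = ""))
  keep <- function(x) sort(grep("^aminoacidPairRatio", x,
                                invert = TRUE, value = TRUE))
  expect_identical(keep(sequential_atoms(s)), keep(sequential_atoms(shuf)))
})

test_that("alignment_atoms_train emits one atom per non-gap cell", {
  aln <- as_alignment(c(s1 = "VC-D", s2 = "VCED"))
  atoms <- alignment_atoms_train(aln)
  expect_true("col(v,1)" %in% atoms$s1)
  expect_false(any(grepl(",3\\)$", atoms$s1)))  # gap cell: no atom
  expect_length(atoms$s1, 3)
  expect_length(atoms$s2, 4)
})

test_that("physchem_column_atoms is the group image of col atoms", {
  out <- physchem_column_atoms("col(a,34)")
  expect_true(all(c("colProp(small,34)", "colProp(tiny,34)",
                    "colProp(neutralWeakHydrophobic,34)") %in% out))
  expect_false("colProp(polar,34)" %in% out)

  out7 <- physchem_column_atoms("col(i,7)")
  expect_true("colProp(hydrophobic,7)" %in% out7)
  expect_false("colProp(small,7)" %in% out7)

  # output size equals total group memberships of the input residues
  lits <- c("col(a,1)", "col(i,2)", "col(w,3)")
  n_memb <- sum(vapply(c("A", "I", "W"), function(r)
    sum(vapply(property_groups(), function(g) r %in% g, logical(1))),
    numeric(1)))
  expect_length(physchem_column_atoms(lits), n_memb)

  expect_error(physchem_column_atoms("hydrophobic(2)"), "not a col")

  # independent recomputation over a random alignment
  aln <- random_alignment(3, 6, p_gap = 0.2, seed = 31)
  atoms <- alignment_atoms_train(aln)
  for (id in names(atoms)) {
    derived <- physchem_column_atoms(atoms[[id]])
    manual <- character(0)
    for (lit in atoms[[id]]) {
      res <- toupper(sub("^col\\(([a-z]),.*$", "\\1", lit))
      z <- sub("^col\\([a-z],([0-9]+)\\)$", "\\1", lit)
      for (g in names(property_groups()))
        if (res %in% property_groups()[[g]])
          manual <- c(manual, sprintf("colProp(%s,%s)", g, z))
    }
    expect_setequal(derived, unique(manual))
  }
})

test_that("alignment_atoms_query projects through the model", {
  aln <- as_alignment(c(s1 = "ACDEF", s2 = "ACDEF", s3 = "ACDEF"))
  ph <- build_phmm(aln)
  q <- alignment_atoms_query(ph, "ACDEF")
  expect_setequal(q, c("col(a,1)", "col(c,2)", "col(d,3)",
                       "col(e,4)", "col(f,5)"))
  expect_lte(length(alignment_atoms_query(ph, "AF")), ph$n_nodes)
})

test_that("build_kb selects and unions representations", {
  seqs <- data.frame(id = c("s1", "s2"),
                     residues = c("ACDEF", "ACDEF"))
  aln <- as_alignment(c(s1 = "ACDEF", s2 = "ACDEF"))
  ph <- build_phmm(aln)

  kb_seq <- build_kb(seqs, "Seq")
  expect_false(any(grepl("^col", unlist(kb_seq$atoms))))

  kb_all <- build_kb(seqs, c("Seq", "Aln_cons", "Aln_pc"),
                     phmm = ph, alignment = aln)
  manual <- sort(unique(c(sequential_atoms("ACDEF"),
                          alignment_atoms_train(aln)$s1,
                          physchem_column_atoms(
                            alignment_atoms_train(aln)$s1))))
  expect_identical(kb_all$atoms$s1, manual)

  # determinism
  kb_all2 <- build_kb(seqs, c("Seq", "Aln_cons", "Aln_pc"),
                      phmm = ph, alignment = aln)
  expect_identical(kb_all$atoms, kb_all2$atoms)

  expect_error(build_kb(seqs, "Aln_cons"), "phmm")
})

test_that("knowledge bases round-trip through the Prolog-like format", {
  seqs <- data.frame(id = c("s1", "s2"), residues = c("ACDEF", "AMDEF"))
  aln <- as_alignment(c(s1 = "ACDEF", s2 = "AMDEF"))
  kb <- build_kb(seqs, c("Seq", "Aln_cons"), alignment = aln,
                 labels = c(s1 = "positive", s2 = "negative"))
  f <- withr::local_tempfile(fileext = ".pl")
  write_kb(kb, f)
  expect_true(any(grepl("^col\\(s1,a,1\\)\\.$", readLines(f))))
  kb2 <- read_kb(f)
  expect_identical(kb2$atoms[order(names(kb2$atoms))],
                   kb$atoms[order(names(kb$atoms))])
  expect_equal(kb2$labels[["s1"]], "positive")
})
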