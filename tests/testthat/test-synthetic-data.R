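test_that("family_spec validates its fields", {
  expect_error(family_spec(length = 5, n_conserved_columns = 10),
               "must not exceed")
  expect_error(family_spec(substitution_rate = 1.2), "rates")
  expect_error(family_spec(conserved_column_spec = data.frame(
    column = 1, type = "group", value = "nope")), "unknown property group")
})

test_that("zero substitution rate yields identical family members", {
  spec <- family_spec(n_families = 1, seqs_per_family = 4, length = 30,
                      substitution_rate = 0,
                      conserved_column_spec = data.frame(
                        column = c(5, 10), type = "fixed",
                        value = c("C", "K")),
                      n_conserved_columns = 2,
                      n_decoy_families = 1, decoy_seqs_per_family = 2,
                      seed = 3)
  gen <- generate_superfamily(spec)
  fam <- gen$dataset$sequences
  fam <- fam$residues[fam$superfamily == "SF1"]
  expect_length(unique(fam), 1L)
})

test_that("planted fixed and group columns are honored", {
  gen <- small_benchmark(seed = 5)
  planted <- gen$truth$planted
  seqs <- gen$dataset$sequences
  members <- seqs[seqs$superfamily == "SF1", ]
  rows <- gen$msa$rows
  for (i in seq_len(nrow(planted))) {
    col <- planted$msa_column[i]
    residues <- toupper(substr(rows[members$id], col, col))
    if (planted$type[i] == "fixed") {
      expect_true(all(residues == toupper(planted$value[i])))
    } else {
      expect_true(all(residues %in% property_groups()[[planted$value[i]]]))
    }
  }
})

test_that("planted columns are recovered as confidence-1 rules", {
  gen <- small_benchmark(seed = 5)
  seqs <- gen$dataset$sequences
  pos <- seqs[seqs$superfamily == "SF1", c("id", "residues")]
  aln <- as_alignment(gen$msa$rows[pos$id])
  kb <- build_kb(pos, c("Aln_cons", "Aln_pc"), alignment = aln)
  rules <- mine_representations(kb, c("Aln_cons", "Aln_pc"),
                                max_length = 1)
  keys <- vapply(rules, function(p) p$body, character(1))
  confs <- stats::setNames(
    vapply(rules, `[[`, numeric(1), "confidence"), keys)
  planted <- gen$truth$planted
  anc <- strsplit(gen$truth$ancestor, "")[[1]]
  for (i in seq_len(nrow(planted))) {
    col <- planted$msa_column[i]
    if (planted$type[i] == "fixed") {
      lit <- sprintf("col(%s,%d)", tolower(planted$value[i]), col)
    } else {
      lit <- sprintf("colProp(%s,%d)", planted$value[i], col)
    }
    expect_true(lit %in% keys, info = lit)
    expect_equal(unname(confs[lit]), 1, info = lit)
  }
})

test_that("decoy coverage of planted rules is near chance", {
  gen <- small_benchmark(seed = 9)
  seqs <- gen$dataset$sequences
  planted <- gen$truth$planted
  fixed <- planted[planted$type == "fixed", ]
  decoys <- seqs[grepl("^DSF", seqs$superfamily), c("id", "residues")]
  pos <- seqs[seqs$superfamily == "SF1", c("id", "residues")]
  aln <- as_alignment(gen$msa$rows[pos$id])
  ph <- build_phmm(aln)
  kb <- build_kb(decoys, "Aln_cons", phmm = ph)
  hits <- vapply(seq_len(nrow(fixed)), function(i) {
    lit <- sprintf("col(%s,%d)", tolower(fixed$value[i]),
                   fixed$msa_column[i])
    mean(vapply(kb$examples, function(id)
      lit %in% kb$atoms[[id]], logical(1)))
  }, numeric(1))
  # a decoy residue matches a specific planted residue ~ 1/20 of the time
  expect_lt(mean(hits), 0.3)
})

test_that("generation is deterministic given the seed", {
  g1 <- small_benchmark(seed = 13)
  g2 <- small_benchmark(seed = 13)
  g3 <- small_benchmark(seed = 14)
  expect_identical(g1$dataset$sequences, g2$dataset$sequences)
  expect_false(identical(g1$dataset$sequences$residues,
                         g3$dataset$sequences$residues))
})

test_that("calibrate_identity hits targets and reports the floor", {
  spec <- family_spec(n_families = 1, seqs_per_family = 8, length = 100,
                      n_conserved_columns = 10, n_decoy_families = 0,
                      seed = 17)
  hi <- calibrate_identity(spec, 95)
  expect_lt(hi$substitution_rate, 0.1)
  g_hi <- generate_superfamily(hi)
  expect_gte(remhom:::mean_within_family_identity(g_hi), 90)

  lo <- calibrate_identity(spec, 25)
  g_lo <- generate_superfamily(lo)
  ident <- remhom:::mean_within_family_identity(g_lo)
  expect_gte(ident, 20)
  expect_lte(ident, 30)

  # all-fixed planted columns bound identity from below
  rigid <- family_spec(n_families = 1, seqs_per_family = 8, length = 20,
                       n_conserved_columns = 8,
                       conserved_column_spec = data.frame(
                         column = 2:9, type = "fixed",
                         value = rep(c("C", "K"), 4)),
                       n_decoy_families = 0, seed = 18)
  expect_error(calibrate_identity(rigid, 5), "floor")
})

test_that("indels keep the true MSA consistent with the sequences", {
  spec <- family_spec(n_families = 1, seqs_per_family = 5, length = 40,
                      n_conserved_columns = 4, substitution_rate = 0.3,
                      indel_rate = 0.05, n_decoy_families = 1,
                      decoy_seqs_per_family = 2, seed = 21)
  gen <- generate_superfamily(spec)
  seqs <- gen$dataset$sequences
  for (id in names(gen$msa$rows)) {
    degapped <- gsub("-", "", gen$msa$rows[[id]])
    expect_equal(degapped, seqs$residues[seqs$id == id])
  }
})

test_that("write_benchmark emits readable artifacts", {
  gen <- small_benchmark(seed = 23)
  dir <- withr::local_tempdir()
  paths <- write_benchmark(gen, dir)
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(paths["fasta"])
  expect_equal(nrow(fa), nrow(gen$dataset$sequences))
  man <- read_manifest(paths["manifest"])
  expect_equal(man$id, gen$dataset$sequences$id)
  aln <- read_alignment(paths["msa"])
  expect_equal(aln$length, gen$msa$length)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, gen$truth$seed)
})
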