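test_that("read_fasta parses, canonicalizes and validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "VCK", ">s2", "acd"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs$id, c("s1", "s2"))
  expect_equal(seqs$residues, c("VCK", "ACD"))

  # non-standard residues are retained (policy: length yes, counts no)
  writeLines(c(">s1", "VXCK"), fa)
  expect_equal(read_fasta(fa)$residues, "VXCK")

  writeLines(c(">s1", "VC*K"), fa)
  expect_error(read_fasta(fa), "invalid residue")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "no records")

  writeLines(c(">s1", "VCK", ">s1", "ACD"), fa)
  expect_error(read_fasta(fa), "duplicate")
})

test_that("homology_dataset validates the hierarchy", {
  seqs <- data.frame(id = c("a", "b"), residues = c("ACD", "ACE"),
                     family = c("f1", "f2"),
                     superfamily = c("s1", "s1"))
  ds <- homology_dataset(seqs)
  expect_s3_class(ds, "homology_dataset")
  expect_equal(unname(ds$hierarchy[["f1"]]), "s1")

  bad <- rbind(seqs, data.frame(id = "c", residues = "ACD",
                                family = "f1", superfamily = "s2"))
  expect_error(homology_dataset(bad), "more than one superfamily")
})

make_toy_dataset <- function(n_a = 3, n_b = 2, n_out = 20) {
  n <- n_a + n_b + n_out
  data.frame(
    id = sprintf("q%02d", seq_len(n)),
    residues = replicate(n, random_query(12, seed = sample.int(1e6, 1))),
    family = c(rep("A", n_a), rep("B", n_b),
               rep(sprintf("out%d", seq_len(max(1, n_out %/% 2))),
                   length.out = n_out)),
    superfamily = c(rep("S", n_a + n_b),
                    rep(sprintf("os%d", seq_len(max(1, n_out %/% 2))),
                        length.out = n_out)))
}

test_that("make_family_split partitions the dataset", {
  ds <- withr::with_seed(1, homology_dataset(make_toy_dataset()))
  sp <- make_family_split(ds, "A")
  expect_length(sp$positive_test, 3)
  expect_length(sp$positive_train, 2)
  expect_length(sp$remaining_pool, 20)
  # pairwise disjoint, union = dataset
  all_ids <- c(sp$positive_test, sp$positive_train, sp$remaining_pool)
  expect_equal(sort(all_ids), sort(ds$sequences$id))
  expect_equal(anyDuplicated(all_ids), 0L)

  expect_error(make_family_split(ds, "nope"), "unknown family")
  # a family alone in its superfamily is degenerate
  solo <- ds$sequences
  solo$superfamily[solo$family == "A"] <- "solo_sf"
  expect_error(make_family_split(homology_dataset(solo), "A"),
               "degenerate family")
})

test_that("compute_T implements the ceiling cover rule", {
  expect_identical(compute_T(100, 10, 10), 4L)
  expect_identical(compute_T(21, 10, 10), 1L)
  expect_identical(compute_T(40, 10, 10), 1L)  # D = 2*(Tr+Te)
  expect_error(compute_T(20, 10, 10), "remaining pool")
  # monotone non-increasing in the positive size for fixed D
  ts <- vapply(2:40, function(p) compute_T(100, p, p), integer(1))
  expect_true(all(diff(ts) <= 0))
})

test_that("sample_negatives is balanced, disjoint and seeded", {
  ds <- withr::with_seed(2, homology_dataset(make_toy_dataset()))
  sp <- make_family_split(ds, "A")
  r1 <- sample_negatives(sp, 1, seed = 7)
  r1b <- sample_negatives(sp, 1, seed = 7)
  r2 <- sample_negatives(sp, 2, seed = 7)
  expect_identical(r1, r1b)
  expect_false(identical(r1$negative_train, r2$negative_train))
  expect_length(r1$negative_train, length(sp$positive_train))
  expect_length(r1$negative_test, length(sp$positive_test))
  expect_length(intersect(r1$negative_train, r1$negative_test), 0)
  expect_true(all(c(r1$negative_train, r1$negative_test) %in%
                    sp$remaining_pool))

  tiny <- sp
  tiny$remaining_pool <- tiny$remaining_pool[1:3]
  expect_error(sample_negatives(tiny, 1, 7), "smaller than")
})

test_that("T resamples cover most of the pool", {
  ds <- withr::with_seed(3, homology_dataset(make_toy_dataset(5, 5, 40)))
  sp <- make_family_split(ds, "A")
  # T ~ pool / draw: expect coverage of at least 1 - 1/e of the pool
  T_cover <- ceiling(length(sp$remaining_pool) /
                       (length(sp$positive_train) +
                          length(sp$positive_test)))
  seen <- unique(unlist(lapply(seq_len(T_cover), function(t) {
    r <- sample_negatives(sp, t, seed = 11)
    c(r$negative_train, r$negative_test)
  })))
  expect_gte(length(seen) / length(sp$remaining_pool), 1 - 1 / exp(1))
})

test_that("pairwise_identity matches the global-alignment definition", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  a <- "ACDEFWKL"; b <- "ACDFWKL"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("", "ACD"), "empty")
})

test_that("filter_by_identity is greedy and valid", {
  same <- homology_dataset(data.frame(
    id = c("a", "b", "c"), residues = rep("ACDEFGHIKL", 3),
    family = "f", superfamily = "s"))
  out <- filter_by_identity(same, 30, min_family_size = 1)
  expect_equal(nrow(out$sequences), 1L)

  # all pairs below threshold: unchanged
  div <- homology_dataset(data.frame(
    id = c("a", "b"), residues = c("AAAAAAAA", "CCCCCCCC"),
    family = c("f", "f"), superfamily = "s"))
  expect_equal(nrow(filter_by_identity(div, 30)$sequences), 2L)

  # greedy output never contains a pair at/above threshold
  seqs <- withr::with_seed(4, data.frame(
    id = sprintf("s%d", 1:6),
    residues = c(rep("ACDEFGHIKLMNPQRS", 2),
                 replicate(4, random_query(16, sample.int(1e6, 1)))),
    family = "f", superfamily = "s"))
  out <- filter_by_identity(homology_dataset(seqs), 90,
                            min_family_size = 1)
  kept <- out$sequences$residues
  if (length(kept) > 1) {
    for (i in seq_len(length(kept) - 1))
      for (j in (i + 1):length(kept))
        expect_lt(pairwise_identity(kept[i], kept[j]), 90)
  }
})

test_that("split JSON serialization works", {
  ds <- withr::with_seed(5, homology_dataset(make_toy_dataset()))
  sp <- make_family_split(ds, "A")
  f <- withr::local_tempfile(fileext = ".json")
  write_split_json(sp, list(sample_negatives(sp, 1, 3)), f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$target_family, "A")
  expect_length(obj$resamples, 1)
})
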