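test_that("FASTA reading normalizes case, maps ambiguity codes and keeps file order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "ACGTACGTAA",
               ">s2", "acgtacgtaa",
               ">s3", "ACGRACGT-N"), path)
  aln <- read_alignment(path, "toy")
  expect_s3_class(aln, "locus_alignment")
  expect_identical(dim(aln$seqs), c(3L, 10L))
  expect_identical(aln$sample_ids, c("s1", "s2", "s3"))
  expect_identical(paste0(aln$seqs[2, ], collapse = ""), "ACGTACGTAA")
  # R (purine) is not representable: stored as N
  expect_identical(unname(aln$seqs[3, 4]), "N")
  expect_identical(unname(aln$seqs[3, 9]), "-")
})

test_that("ragged alignments and duplicate ids are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGTAA", ">s2", "ACGT"), path)
  expect_error(read_alignment(path), "ragged")
  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), path)
  expect_error(read_alignment(path), "duplicate")
})

test_that("mononucleotide-repeat filtering masks only polymorphic run columns", {
  # identical monomorphic run: nothing masked
  aln <- make_aln(c("AAAAAAGCGT", "AAAAAAGCGT"))
  expect_identical(filter_mononucleotide_repeats(aln)$usable_mask,
                   rep(TRUE, 10))

  # length-variant A-run >= 5: the polymorphic run column is masked,
  # monomorphic run columns stay usable
  aln2 <- make_aln(c("AAAAATGGCC", "AAAAT-GGCC"))
  f2 <- filter_mononucleotide_repeats(aln2, min_run = 5)
  expect_identical(which(!f2$usable_mask), 5L)

  # min_run larger than any run: identity
  aln3 <- make_aln(c("AACCGGTTAG", "AACCGGTTAG"))
  expect_identical(filter_mononucleotide_repeats(aln3, min_run = 3)$usable_mask,
                   rep(TRUE, 10))

  # idempotence
  once <- filter_mononucleotide_repeats(aln2, min_run = 5)
  twice <- filter_mononucleotide_repeats(once, min_run = 5)
  expect_identical(once$usable_mask, twice$usable_mask)
})

test_that("indel coding turns each distinct gap interval into one binary character", {
  rows <- c("ACGT-----ACG", "ACGT-----ACG", "ACGTTTTTAACG", "ACGTTTTTAACG")
  aln <- code_indels(make_aln(rows))
  expect_identical(ncol(aln$indel_states), 1L)
  expect_identical(unname(aln$indel_states[, 1]), c(1L, 1L, 0L, 0L))
  # usable length reduced by the 5 gapped columns, plus 1 indel character
  expect_identical(sum(aln$usable_mask), 12L - 5L)
  expect_identical(usable_sites(aln), 8L)

  # no gaps: identity
  aln2 <- code_indels(make_aln(c("ACGT", "ACGT")))
  expect_identical(ncol(aln2$indel_states), 0L)
  expect_true(all(aln2$usable_mask))

  # two gap intervals with different endpoints: two characters
  aln3 <- code_indels(make_aln(c("A--TACGT", "ACGTA--T", "ACGTACGT")))
  expect_identical(ncol(aln3$indel_states), 2L)

  # idempotence
  again <- code_indels(aln)
  expect_identical(again$indel_states, aln$indel_states)
  expect_identical(again$usable_mask, aln$usable_mask)
})

test_that("concatenation is additive, id-checked, and independent of row order", {
  a <- make_aln(c("ACGTACGTAC", "ACGTACGTAA"), ids = c("x", "y"), locus = "a")
  b <- make_aln(strrep(c("AC", "GT"), 10), ids = c("x", "y"), locus = "b")
  cc <- make_aln(strrep(c("A", "T"), 30), ids = c("x", "y"), locus = "c")
  cat3 <- concatenate_loci(list(a, b, cc))
  expect_identical(ncol(cat3$seqs), 10L + 20L + 30L)
  expect_identical(concatenate_loci(list(a)), a)

  # permuted rows in the second locus: realigned by id
  b_perm <- make_aln(strrep(c("GT", "AC"), 10), ids = c("y", "x"), locus = "b")
  expect_identical(concatenate_loci(list(a, b_perm))$seqs,
                   concatenate_loci(list(a, b))$seqs)

  bad <- make_aln(c("AC", "GT"), ids = c("x", "z"))
  expect_error(concatenate_loci(list(a, bad)), "id sets differ")

  # locus order does not change the haplotype count
  k1 <- collapse_haplotypes(concatenate_loci(list(a, b)))$k
  k2 <- collapse_haplotypes(concatenate_loci(list(b, a)))$k
  expect_identical(k1, k2)
})

test_that("haplotype collapsing matches brute-force identity grouping", {
  aln <- make_aln(c("AAA", "AAT", "AAA"))
  hs <- collapse_haplotypes(aln)
  expect_identical(hs$k, 2L)
  expect_identical(haplotype_counts(hs), c(2L, 1L))

  expect_identical(collapse_haplotypes(make_aln(rep("ACGT", 5)))$k, 1L)

  set.seed(7)
  mat <- matrix(sample(c("A", "C", "G", "T"), 20 * 50, replace = TRUE,
                       prob = c(0.9, 0.05, 0.03, 0.02)), 20, 50)
  rownames(mat) <- paste0("s", 1:20)
  hs2 <- collapse_haplotypes(locus_alignment(mat, "rand"))
  oracle <- brute_force_groups(mat)
  expect_identical(length(unique(oracle)), hs2$k)
  # identical partition of samples into haplotype classes
  expect_true(all(outer(hs2$assignment, hs2$assignment, "==") ==
                  outer(oracle, oracle, "==")))
})

test_that("collapse respects the population map and round-trips sample counts", {
  aln <- make_aln(c("AAA", "AAT", "AAA", "TTT"),
                  ids = c("a1", "a2", "b1", "b2"))
  pm <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                   population = c("A", "A", "B", "B"),
                   lat = c(-10, -10, -12, -12), lon = c(-45, -45, -47, -47))
  hs <- collapse_haplotypes(aln, pm)
  expect_equal(sum(hs$counts), 4)
  expect_equal(unname(colSums(hs$counts)), c(2, 2))
  expect_identical(sum(haplotype_counts(hs)), hs$n)

  pm_bad <- pm[-2, ]
  expect_error(collapse_haplotypes(aln, pm_bad), "missing from population map")
})
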