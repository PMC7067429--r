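# Progressive MSA and the gap-run recovery classification with its
# tabulations.

test_that("progressive MSA handles identity, indels and single input", {
  s <- stats::setNames(rep(paste0("M", r_random_protein(30)), 3),
                       c("a", "b", "c"))
  m <- progressive_msa(s)
  expect_false(any(grepl("-", m$aln)))
  expect_equal(unname(nchar(m$aln)), rep(31, 3))

  m2 <- progressive_msa(c(x = "PEPTIDE", y = "PEPDE"))
  gapped <- m2$aln[["y"]]
  expect_equal(nchar(m2$aln[["x"]]), nchar(gapped))
  runs <- regmatches(gapped, gregexpr("-+", gapped))[[1]]
  expect_equal(sum(nchar(runs)), 2)
  expect_length(runs, 1)  # one contiguous 2-column gap

  m1 <- progressive_msa(c(solo = "MKTW"))
  expect_equal(m1$aln[["solo"]], "MKTW")
  expect_error(progressive_msa(character()))
})

test_that("degapping MSA rows recovers the input sequences", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    base <- paste0("M", r_random_protein(40))
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      drop <- sample(seq_along(s), sample(0:6, 1))
      if (length(drop)) s <- s[-drop]
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("r", seq_len(n))
    m <- progressive_msa(seqs)
    expect_equal(gsub("-", "", unname(m$aln)), unname(seqs))
    expect_equal(length(unique(nchar(m$aln))), 1)
  }
})

test_that("gap runs and recovery classes follow the boundary rules", {
  rows <- c(a = "AC-GT", b = "A----C", c = "ACGTT")
  expect_equal(max_gap_run(rows, "a"), 1)
  expect_equal(max_gap_run(rows, "b"), 4)
  expect_equal(max_gap_run(rows, "c"), 0)

  expect_equal(classify_recovery(rows, "c")$class, "Exact")
  expect_equal(classify_recovery(rows, "b")$class, "Close")   # run of 4
  expect_equal(classify_recovery(c(p = "A-----C"), "p")$class,
               "Partial")                                      # run of 5
  expect_equal(classify_recovery(c(p = "A-------C"), "p")$class,
               "Partial")
  expect_equal(classify_recovery(NULL, "absent", absent = TRUE)$class,
               "Missed")
  # terminal runs count
  expect_equal(classify_recovery(c(t = "------ACGTAA"), "t")$class,
               "Partial")
})

test_that("classification is invariant to MSA row order", {
  seqs <- c(a = "MKTWWQRSTV", b = "MKTWWQRS", c = "MKTWWQRSTV")
  m1 <- progressive_msa(seqs)
  m2 <- progressive_msa(seqs[c(3, 1, 2)])
  for (lb in names(seqs))
    expect_equal(classify_recovery(m1, lb)$class,
                 classify_recovery(m2, lb)$class)
})

test_that("assembly comparison categories are exclusive and exhaustive", {
  p1 <- c(i1 = "MKT", i2 = "MKT", i3 = "MKTAA", i4 = "", i5 = "MKT")
  p2 <- c(i1 = "MKT", i2 = "MRT", i3 = "MKT", i4 = "MKT", i6 = "MKT")
  cmp <- compare_assemblies(p1, p2)
  got <- stats::setNames(cmp$category, cmp$isoform)
  expect_equal(unname(got["i1"]), "Identity")
  expect_equal(unname(got["i2"]), "Variant")
  expect_equal(unname(got["i3"]), "GapSp2")
  expect_equal(unname(got["i4"]), "MissingSp1")
  expect_equal(unname(got["i5"]), "MissingSp2")
  expect_equal(unname(got["i6"]), "MissingSp1")
  expect_equal(nrow(cmp), 6)
})

test_that("recovery tabulations conserve the isoform total", {
  calls <- expand.grid(assembly_id = c("a1", "a2", "a3"),
                       isoform = c("g1|iso1", "g2|iso1", "g3|iso1"),
                       stringsAsFactors = FALSE)
  calls$class <- c("Exact", "Exact", "Close",
                   "Partial", "Missed", "Exact",
                   "Missed", "Missed", "Missed")
  t1 <- tabulate_recovery(calls, "by_assembly")
  expect_true(all(t1$total == 3))
  expect_equal(sum(t1$E + t1$C + t1$P + t1$M), nrow(calls))

  t3 <- tabulate_recovery(calls, "by_isoform")
  expect_equal(sum(t3$per_isoform$complete + t3$per_isoform$partial +
                     t3$per_isoform$missing), nrow(calls))
  expect_equal(sum(t3$buckets$n), 3)  # every isoform in exactly one bucket
})

test_that("published recovery buckets reproduce the headline counts", {
  tab <- read_recovery_buckets()
  expect_equal(sum(tab$total), 175)
  expect_equal(sum(tab$missing_0), 65)
  expect_equal(sum(tab$missing_1_2), 66)
  expect_equal(sum(tab$missing_3p), 44)
  expect_equal(isoforms_complete_in_at_least(tab, 2), 128)
  expect_equal(isoforms_complete_in_at_least(tab, 3), 110)
  expect_equal(isoforms_complete_in_at_least(tab, 0), 175)
})
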