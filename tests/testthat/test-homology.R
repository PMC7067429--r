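# Homology search and prediction: six-frame translation, pairwise
# alignment vs independent oracles, frameshift DP behavior, assembly
# search coordinates, ORF extraction and evidence merging.

test_that("six-frame translation covers all frames and edge cases", {
  fr <- six_frame_translate("ATGGCCTAA")
  expect_equal(fr[1], "MA*")
  expect_equal(six_frame_translate("CAT")[4], "M")  # revcomp ATG
  expect_equal(six_frame_translate("AT"), rep("", 6))
  # frame consistency with Biostrings on a random sequence
  set.seed(7)
  dna <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  fr <- six_frame_translate(dna)
  expect_equal(fr[2], as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 2, 100)),   # 99 nt, 33 codons
    no.init.codon = TRUE)))
})

test_that("local alignment matches BLOSUM62 expectations and the oracle", {
  r <- local_align_protein("MKT", "MKT")
  expect_equal(r$score, 15)  # 5 + 5 + 5 on the matrix diagonal
  expect_equal(r$q_aln, "MKT")
  expect_equal(local_align_protein("MKT", "DDDDDD")$score, 0)

  set.seed(11)
  for (i in 1:60) {
    a <- r_random_protein(sample(5:30, 1))
    b <- r_random_protein(sample(5:30, 1))
    expect_equal(local_align_protein(a, b)$score,
                 r_affine_score(a, b, local = TRUE),
                 info = paste(a, b))
  }
})

test_that("local/global alignment agrees with Biostrings pairwiseAlignment", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(23)
  for (i in 1:25) {
    a <- r_random_protein(sample(8:40, 1))
    b <- r_random_protein(sample(8:40, 1))
    bs_local <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = BLOSUM62, gapOpening = 11,
      gapExtension = 1, type = "local", scoreOnly = TRUE)
    expect_equal(local_align_protein(a, b)$score, max(0, bs_local))
    bs_global <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = BLOSUM62, gapOpening = 11,
      gapExtension = 1, type = "global", scoreOnly = TRUE)
    expect_equal(global_align_protein(a, b)$score, bs_global)
  }
})

test_that("global alignment of aligned pairs strips to the inputs", {
  g <- global_align_protein("PEPTIDE", "PEPDE")
  expect_equal(gsub("-", "", g$a_aln), "PEPTIDE")
  expect_equal(gsub("-", "", g$b_aln), "PEPDE")
  expect_equal(nchar(g$a_aln), nchar(g$b_aln))
})

test_that("frameshift DP predicts through indels and flags stops", {
  q <- "MADKLVHEWRQSTP"
  cds <- reverse_translate(q, seed = 5)
  body <- substr(cds, 1, nchar(cds) - 3)
  # clean CDS inside on-grid flanks
  r <- align_protein_to_dna_frameshift(q, paste0("GCGCGA", cds, "ATATAT"))
  expect_equal(r$seq, q)
  expect_equal(r$completeness, "complete")
  expect_length(r$frameshifts, 0)
  expect_length(r$premature_stops, 0)

  # internal 1-nt insertion: full protein recovered, 1 frameshift
  ins <- paste0(substr(body, 1, 9), "G", substring(body, 10))
  r2 <- align_protein_to_dna_frameshift(q, ins)
  expect_equal(r2$seq, q)
  expect_length(r2$frameshifts, 1)
  # the slip may sit anywhere within a run of identical nucleotides
  expect_lte(abs(r2$frameshifts - 9), 2)

  # codon 3 replaced by TAA: stop retained as '*', flagged, partial
  stp <- paste0(substr(body, 1, 6), "TAA", substring(body, 10))
  r3 <- align_protein_to_dna_frameshift(q, stp)
  expect_equal(r3$premature_stops, 2)
  expect_match(r3$seq, "\\*")
  expect_equal(r3$completeness, "partial")

  expect_equal(align_protein_to_dna_frameshift(q, "AT")$completeness,
               "absent")
})

test_that("frameshift DP score matches the independent R oracle", {
  set.seed(17)
  params <- align_params()
  for (i in 1:60) {
    q <- r_random_protein(sample(4:10, 1))
    n <- sample(9:33, 1)
    dna <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    got <- align_protein_to_dna_frameshift(q, dna, params)$score
    want <- max(0, r_frameshift_score(q, dna))
    expect_equal(got, want, info = paste(q, dna))
  }
})

test_that("assembly search maps hits to forward coordinates on both strands", {
  set.seed(3)
  q <- paste0("M", r_random_protein(49))
  cds <- reverse_translate(q, seed = 8)
  fl5 <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  fl3 <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
  contig <- paste0(fl5, cds, fl3)
  recs <- data.frame(id = "c1", seq = contig, stringsAsFactors = FALSE)
  h <- search_assembly(q, recs)
  expect_gte(nrow(h), 1)
  expect_equal(h$strand[1], "+")
  expect_equal(h$score[1], self_score(q))
  expect_true(h$start[1] >= 120 && h$end[1] <= 120 + nchar(cds))

  recs_rc <- data.frame(id = "c1", seq = revcomp(contig),
                        stringsAsFactors = FALSE)
  h2 <- search_assembly(q, recs_rc)
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$score[1], h$score[1])
  expect_lt(h2$start[1], h2$end[1])

  # decoy-only contigs above-threshold: empty
  decoy <- data.frame(id = "d", seq = paste(
    sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
    stringsAsFactors = FALSE)
  expect_equal(nrow(search_assembly(q, decoy)), 0)

  # monotonicity: raising min_score never increases the hit count
  ms <- 0.2 * self_score(q)
  n1 <- nrow(search_assembly(q, recs, min_score = ms))
  n2 <- nrow(search_assembly(q, recs, min_score = 2 * ms))
  expect_lte(n2, n1)
})

test_that("strand symmetry: reverse-complemented assemblies give the same proteins", {
  cfg <- simulation_config(n_species = 3, seed = 21,
                           root_proteins = data.frame(
                             gene = "gA", family = "f1", length = 60),
                           rate_per_gene = c(gA = 0.1),
                           assembly_types = "G")
  sim <- simulate_clade(cfg)
  a <- sim$assemblies[[1]]
  r1 <- annotate_assembly(sim$queries, a)
  a_rc <- a
  a_rc$records$seq <- vapply(a$records$seq, revcomp, character(1))
  r2 <- annotate_assembly(sim$queries, a_rc)
  expect_equal(r1$predictions$seq, r2$predictions$seq)
})

test_that("ORF extraction recovers full and truncated transcripts", {
  q <- paste0("M", r_random_protein(59))
  cds <- reverse_translate(q, seed = 12)
  set.seed(13)
  utr5 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
  tx <- paste0(utr5, cds, utr3)
  r <- extract_orf_from_transcript(tx, q)
  expect_equal(r$seq, q)
  expect_equal(r$completeness, "complete")

  # 5'-truncated (first 30% removed): partial, a suffix of the truth
  tx5 <- substring(tx, floor(0.3 * nchar(tx)))
  r5 <- extract_orf_from_transcript(tx5, q)
  expect_equal(r5$completeness, "partial")
  expect_true(endsWith(q, r5$seq))
  expect_lt(nchar(r5$seq), nchar(q))

  # antisense orientation gives the identical result
  ra <- extract_orf_from_transcript(revcomp(tx), q)
  expect_equal(ra$seq, r$seq)
  expect_equal(ra$completeness, "complete")

  expect_equal(extract_orf_from_transcript("ACGT", q)$completeness,
               "absent")
})

test_that("evidence merging prefers coverage and splices complements", {
  row <- function(seq, qs, qe, gaps, ty, aid, comp = "partial") {
    data.frame(seq = seq, q_start = qs, q_end = qe, n_gaps = gaps,
               assembly_type = ty, assembly_id = aid,
               completeness = comp, evidence = "genome",
               stringsAsFactors = FALSE)
  }
  truth <- paste0("M", r_random_protein(59))
  full <- row(truth, 0, 60, 0, "G", "a1", "complete")
  part <- row(substring(truth, 21), 20, 60, 20, "T", "a2")
  m <- merge_evidence(rbind(full, part))
  expect_equal(m$seq, truth)
  expect_equal(m$evidence, "genome")

  # complementary halves with a 10-aa exact overlap splice to the truth
  headp <- row(substr(truth, 1, 40), 0, 40, 20, "G", "a1")
  tailp <- row(substring(truth, 31), 30, 60, 30, "T", "a2")
  m2 <- merge_evidence(rbind(headp, tailp))
  expect_equal(m2$seq, truth)
  expect_equal(m2$evidence, "merged")
  expect_equal(m2$completeness, "complete")

  expect_equal(merge_evidence(part)$seq, part$seq)
  expect_null(merge_evidence(part[0, ]))
})
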