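# Distances, neighbor joining, MeaPED, Robinson-Foulds, nRF, Pedges,
# family summaries and the duplicate-fate screen.

test_that("p-distances count mutually covered columns, with correction", {
  rows <- c(a = "MKTW", b = "MKTW")
  expect_equal(pdistance_matrix(rows, "none")["a", "b"], 0)
  rows2 <- c(a = "MKTW", b = "MRTF")      # 2 of 4 differ
  expect_equal(pdistance_matrix(rows2, "none")["a", "b"], 0.5)
  expect_equal(pdistance_matrix(rows2, "poisson")["a", "b"], -log(0.5),
               tolerance = 1e-12)
  rows3 <- c(a = "MKTW--", b = "M-TWAA")  # only 3 shared columns
  d3 <- pdistance_matrix(rows3, "none")
  expect_equal(d3["a", "b"], 0)
  expect_true(attr(d3, "unreliable")["a", "b"])
})

test_that("NJ recovers closed-form and additive branch lengths", {
  # 3 taxa: b_A = (d_AB + d_AC - d_BC) / 2
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pat <- stats::cophenetic(tr)
  expect_equal(pat["A", "B"], 0.3, tolerance = 1e-9)
  expect_equal(pat["A", "C"], 0.5, tolerance = 1e-9)
  bA <- tr$edge.length[tr$edge[, 2] == match("A", tr$tip.label)]
  expect_equal(bA, (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)

  # additive 4-taxon matrix from a known tree is reproduced exactly
  gen <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.07);")
  dm <- stats::cophenetic(gen)
  tr4 <- nj_tree(dm)
  expect_equal(robinson_foulds(tr4, gen), 0)
  expect_equal(stats::cophenetic(tr4)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)

  # equal distances still produce additive, non-negative trees
  de <- matrix(0.4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  tre <- nj_tree(de)
  expect_true(all(tre$edge.length >= 0))
  pe <- stats::cophenetic(tre)
  expect_equal(max(abs(pe[upper.tri(pe)] - 0.4)), 0, tolerance = 1e-9)

  # degenerate 2-leaf tree preserves the distance
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.8)
})

test_that("MeaPED is the scaled mean patristic distance", {
  two <- parse_newick("(L1:0.2,L2:0.1);")
  seqs <- c(L1 = r_random_protein(100), L2 = r_random_protein(100))
  expect_equal(meaped(two, seqs), 100 * 0.3 / 100)

  zero <- parse_newick("(L1:0,L2:0,L3:0);")
  expect_equal(meaped(zero, c(L1 = "MK", L2 = "MK", L3 = "MK")), 0)

  # 4-leaf brute-force path enumeration oracle
  t4 <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.07);")
  s4 <- stats::setNames(vapply(c(30, 30, 40, 40), r_random_protein,
                               character(1)), c("A", "B", "C", "D"))
  pat <- stats::cophenetic(t4)
  want <- 100 * mean(pat[upper.tri(pat)]) / stats::median(c(30, 30, 40,
                                                            40))
  expect_equal(meaped(t4, s4), want, tolerance = 1e-12)

  # scale equivariance: multiplying branch lengths by c scales MeaPED
  t4c <- t4; t4c$edge.length <- t4$edge.length * 3.5
  expect_equal(meaped(t4c, s4), 3.5 * meaped(t4, s4), tolerance = 1e-12)

  # fewer than 2 scope labels: undefined, not zero
  expect_true(is.na(meaped(t4, s4, scope_labels = "A")))
})

test_that("Robinson-Foulds matches enumeration and is a metric", {
  ta <- parse_newick("((A,B),(C,D));")
  tb <- parse_newick("((A,C),(B,D));")
  expect_equal(robinson_foulds(ta, ta), 0)
  expect_equal(robinson_foulds(ta, tb), 2)

  cat1 <- parse_newick("((((A,B),C),D),E);")
  cat2 <- parse_newick("((((E,C),A),D),B);")
  expect_equal(robinson_foulds(cat1, cat2), r_rf(cat1, cat2))

  set.seed(53)
  for (i in 1:40) {
    t1 <- ape::rtree(6)
    t2 <- ape::rtree(6)
    t3 <- ape::rtree(6)
    expect_equal(robinson_foulds(t1, t2), r_rf(t1, t2))
    expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))
    expect_equal(robinson_foulds(t1, t1), 0)
    expect_lte(robinson_foulds(t1, t3),
               robinson_foulds(t1, t2) + robinson_foulds(t2, t3))
  }
})

test_that("nRF normalizes by observed max or theoretical max", {
  expect_equal(nrf(c(2, 4)), c(0.5, 1.0))
  expect_equal(nrf(0), 0)
  expect_equal(nrf(c(0, 0)), c(0, 0))
  expect_equal(nrf(6, mode = "possible", n = 6), 1.0)
  expect_equal(nrf(3, mode = "possible", n = 6), 0.5)
})

test_that("shared-edge proportion handles identity, conflict and stars", {
  ta <- parse_newick("((A,B),(C,D),E);")
  expect_equal(shared_edges_proportion(ta, ta), 1.0)
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  expect_equal(shared_edges_proportion(q1, q2), 0.0)
  star <- parse_newick("(A,B,C,D);")
  expect_equal(shared_edges_proportion(q1, star), 0.0)
  set.seed(59)
  for (i in 1:20) {
    t1 <- ape::rtree(6); t2 <- ape::rtree(6)
    p <- shared_edges_proportion(t1, t2)
    expect_gte(p, 0); expect_lte(p, 1)
    rv <- robinson_foulds(t1, t2)
    expect_gte(rv, 0); expect_lte(nrf(rv, "possible", n = 6), 1)
  }
})

test_that("family summaries average member isoforms with a Total row", {
  rec <- data.frame(
    gene = c("g1", "g2", "g3"), isoform_id = "iso1", scope = "All",
    meaped = c(0.1, 0.3, 0.5), rf = c(2, 2, 4), nrf = c(0.5, 0.5, 1),
    pedges = c(0.8, 0.6, 0.4), n_taxa = 6, median_length = 100,
    stringsAsFactors = FALSE)
  fam <- c(g1 = "famA", g2 = "famA", g3 = "famB")
  out <- family_summary(rec, fam)
  a <- out[out$family == "famA", ]
  expect_equal(a$meaped, 0.2)
  expect_equal(a$n_isoforms, 2)
  b <- out[out$family == "famB", ]
  expect_equal(b$meaped, 0.5)
  tot <- out[out$family == "Total", ]
  expect_equal(tot$meaped, mean(rec$meaped))
  expect_equal(tot$n_isoforms, 3)
  # min_isoforms filter drops small families but keeps the Total
  out2 <- family_summary(rec, fam, min_isoforms = 2)
  expect_false("famB" %in% out2$family)
  expect_true("Total" %in% out2$family)
})

test_that("duplicate fates split at the 5x MeaPED ratio", {
  f <- classify_duplicate_fates(c(a = 0.01, b = 0.06))
  expect_equal(f$fate, "divergent")
  expect_equal(f$ratio, 6)
  expect_equal(classify_duplicate_fates(c(a = 0.02, b = 0.03))$fate,
               "similar")
  expect_equal(classify_duplicate_fates(c(a = 0, b = 0))$fate, "similar")
  expect_equal(classify_duplicate_fates(c(a = 0, b = 0.1))$fate,
               "divergent")
  f3 <- classify_duplicate_fates(c(a = 0.01, b = 0.02, c = 0.2))
  expect_equal(nrow(f3), 3)
})
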