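# Synthetic clade generator: tree, substitution model (with closed-form
# oracles), reverse translation, assemblies and the truth ledger.

small_config <- function(...) {
  simulation_config(
    n_species = 4,
    root_proteins = data.frame(gene = c("gA", "gB"),
                               family = c("f1", "f1"), length = 60),
    rate_per_gene = c(gA = 0.1, gB = 0.1), ...)
}

test_that("species tree simulation is sized, scaled and deterministic", {
  cfg <- simulation_config(n_species = 3, seed = 1)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1.0, tolerance = 1e-9)

  tr2 <- simulate_species_tree(simulation_config(n_species = 3, seed = 1))
  expect_identical(write_newick(tr), write_newick(tr2))

  fx <- simulate_species_tree(simulation_config(
    n_species = 16, tree_mode = "fixed_fixture", seed = 1))
  expect_equal(length(fx$tip.label), 16)
  expect_error(simulate_species_tree(list(n_species = 2,
                                          tree_mode = "yule", seed = 1)))
})

test_that("protein evolution follows the per-site substitution model", {
  tr <- simulate_species_tree(simulation_config(n_species = 4, seed = 5))
  root <- r_random_protein(100)

  leaves0 <- evolve_protein(root, tr, rate = 0, seed = 9)
  expect_true(all(leaves0 == root))

  # saturation: under near-infinite rate every branch randomizes a site,
  # so the pairwise p-distance approaches 19/20
  rootL <- r_random_protein(10000)
  sat <- evolve_protein(rootL, tr, rate = 1e6, seed = 2)
  a <- strsplit(sat[[1]], "")[[1]]; b <- strsplit(sat[[2]], "")[[1]]
  expect_lt(abs(mean(a != b) - 19 / 20), 0.01)

  # two-leaf comparison against a brute-force per-site oracle of the same
  # branch process: substitute w.p. 1-exp(-r t), uniform replacement
  two <- parse_newick("(L1:0.3,L2:0.2);")
  r <- 0.8
  obs <- evolve_protein(rootL, two, rate = r, seed = 31)
  p_obs <- mean(strsplit(obs[["L1"]], "")[[1]] !=
                  strsplit(obs[["L2"]], "")[[1]])
  set.seed(99)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sim_site <- function() {
    x <- sample(AA, 1)
    ev <- function(s, t) if (runif(1) < 1 - exp(-r * t))
      sample(setdiff(AA, s), 1) else s
    ev(x, 0.3) != ev(x, 0.2)
  }
  p_oracle <- mean(replicate(10000, sim_site()))
  se <- sqrt(p_oracle * (1 - p_oracle) / 10000)
  expect_lt(abs(p_obs - p_oracle), 6 * se)
})

test_that("reverse translation is codon-faithful and round-trips", {
  expect_equal(substr(reverse_translate("M", seed = 1), 1, 3), "ATG")
  expect_equal(substr(reverse_translate("MW", seed = 1), 1, 6), "ATGTGG")
  expect_equal(nchar(reverse_translate("MW", seed = 1)), 9)
  expect_error(reverse_translate("MK*"), "\\*")
  set.seed(4)
  for (i in 1:25) {
    p <- r_random_protein(sample(10:60, 1))
    cds <- reverse_translate(p)
    expect_equal(translate_dna(substr(cds, 1, nchar(cds) - 3)), p)
    expect_true(translate_dna(cds) ==
                  paste0(p, "*"))
  }
})

test_that("genome assemblies record artifacts faithfully in the truth", {
  genes <- data.frame(gene = c("gA", "gB"), isoform = "i1",
                      seq = c(r_random_protein(59), r_random_protein(59)),
                      stringsAsFactors = FALSE)
  genes$seq <- paste0("M", genes$seq)
  cfg <- small_config()
  b <- build_genome_assembly("spX", genes, cfg, seed = 3)
  expect_true(all(b$truth$truth_class == "Exact"))
  expect_true(all(b$truth$artifacts == ""))
  expect_equal(nrow(b$records), 2)

  cfg2 <- small_config(genome_artifacts = list(p_gene_missing = 1))
  b2 <- build_genome_assembly("spX", genes, cfg2, seed = 3)
  expect_true(all(b2$truth$truth_class == "Missed"))
  expect_true(all(grepl("decoy", b2$records$desc)))

  cfg3 <- small_config(genome_artifacts = list(p_frameshift_indel = 1))
  b3 <- build_genome_assembly("spX", genes, cfg3, seed = 3)
  expect_true(all(grepl("frameshift_(ins|del)@\\d+", b3$truth$artifacts)))
  expect_true(all(vapply(strsplit(b3$truth$artifacts, ";"), length,
                         integer(1)) == 1))

  cfg4 <- small_config(genome_artifacts = list(p_contig_break = 1))
  b4 <- build_genome_assembly("spX", genes, cfg4, seed = 3)
  expect_true(all(b4$truth$truth_class == "Partial"))
  expect_equal(nrow(b4$records), 4)  # two contigs per broken gene
})

test_that("transcriptome assemblies model dropout and truncation", {
  genes <- data.frame(gene = "gA", isoform = "i1",
                      seq = paste0("M", r_random_protein(59)),
                      stringsAsFactors = FALSE)
  cfg <- small_config(transcriptome_artifacts = list(p_dropout = 1))
  b <- build_transcriptome_assembly("spX", genes, NULL, cfg, seed = 2)
  expect_equal(nrow(b$records), 0)
  expect_true(all(b$truth$truth_class == "Missed"))

  cfg2 <- small_config()
  b2 <- build_transcriptome_assembly("spX", genes, NULL, cfg2, seed = 2)
  expect_equal(nrow(b2$records), 1)
  expect_true(all(b2$truth$truth_class == "Exact"))

  cfg3 <- small_config(transcriptome_artifacts = list(
    p_truncate_5p = 1, truncate_frac_range = c(0.4, 0.5)))
  b3 <- build_transcriptome_assembly("spX", genes, NULL, cfg3, seed = 2)
  expect_true(all(b3$truth$truth_class == "Partial"))
  expect_true(all(b3$truth$kept_start > 0))

  # forced tissue-specific dropout
  b4 <- build_transcriptome_assembly("spX", genes, c(gA = FALSE), cfg2,
                                     seed = 2)
  expect_equal(nrow(b4$records), 0)
  expect_match(b4$truth$artifacts, "not_expressed")
})

test_that("duplication injection names, sizes and diverges copies", {
  genes <- data.frame(gene = "gA", family = "f1",
                      seq = paste0("M", r_random_protein(59)), rate = 0.1,
                      stringsAsFactors = FALSE)
  expect_identical(inject_duplication(genes, "gA", 1, 0.1, seed = 1),
                   genes)
  g0 <- inject_duplication(genes, "gA", 2, 0, seed = 1)
  expect_equal(sort(g0$gene), c("gAA", "gAB"))
  expect_equal(g0$seq[1], g0$seq[2])
  g3 <- inject_duplication(genes, "gA", 3, 0.3, seed = 1)
  expect_equal(nrow(g3), 3)
  expect_equal(anyDuplicated(g3$gene), 0)
  expect_gt(length(unique(g3$seq)), 1)
})

test_that("the clade simulator is deterministic and conserves truth rows", {
  cfg <- simulation_config(n_species = 5, seed = 13,
                           loss_events = data.frame(gene = "gene02",
                                                    clade_node = "n3"))
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  for (aid in names(s1$assemblies))
    expect_identical(s1$assemblies[[aid]]$records,
                     s2$assemblies[[aid]]$records)
  # conservation: truth rows = assemblies x resident gene-isoforms
  n_lost <- nrow(s1$lost_pairs)  # species x gene pairs removed
  expected <- 0
  for (a in s1$assemblies) {
    sp_prot <- s1$proteins[s1$proteins$species == a$species, ]
    expected <- expected +
      if (a$type == "T") nrow(sp_prot) else
        sum(sp_prot$isoform == "i1")
  }
  expect_equal(nrow(s1$truth), expected)
  expect_gt(n_lost, 0)
  expect_false(any(paste(s1$truth$species, s1$truth$gene) %in%
                     paste(s1$lost_pairs$species, s1$lost_pairs$gene)))
})
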