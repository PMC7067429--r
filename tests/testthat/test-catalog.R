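# Isoform cataloguing, representative selection, accounting, gene loss
# and duplicate screening.

pred_row <- function(gene, species, seq, aid, ty, evid = "genome",
                     comp = "complete", gaps = 0, qs = 0,
                     qe = nchar(seq)) {
  data.frame(species = species, assembly_id = aid, assembly_type = ty,
             gene = gene, isoform_id = NA_character_, candidate = "c",
             seq = seq, q_start = qs, q_end = qe, n_gaps = gaps,
             frameshifts = "", premature_stops = "", completeness = comp,
             evidence = evid, score = nchar(seq) * 5, start = 0L,
             end = 3L * nchar(seq), strand = "+",
             stringsAsFactors = FALSE)
}

test_that("isoform identification follows the coverage-aware rule", {
  base <- paste0("M", r_random_protein(79))
  # identical across species: one isoform
  p1 <- rbind(pred_row("g1", "sp1", base, "sp1_G", "G"),
              pred_row("g1", "sp2", base, "sp2_G", "G"))
  c1 <- identify_isoforms(p1)
  expect_equal(length(unique(c1$entries$isoform_id)), 1)

  # a transcript-supported variant lacking an internal 12-aa segment
  # splits into a second isoform
  var <- paste0(substr(base, 1, 30), substring(base, 43))
  p2 <- rbind(p1,
              pred_row("g1", "sp1", var, "sp1_T", "T", "transcript"),
              pred_row("g1", "sp2", var, "sp2_T", "T", "transcript"))
  c2 <- identify_isoforms(p2)
  expect_equal(length(unique(c2$entries$isoform_id)), 2)

  # a genome-only incomplete variant differing within its own uncovered
  # region does not split (X placeholders mark the uncovered run)
  gappy <- paste0(substr(base, 1, 30), strrep("X", 12), substring(base, 43))
  p3 <- rbind(p1, pred_row("g1", "sp3", gappy, "sp3_G", "G",
                           comp = "partial", gaps = 12))
  c3 <- identify_isoforms(p3)
  expect_equal(length(unique(c3$entries$isoform_id)), 1)

  # idempotence: re-identifying from the catalog's own entries is a
  # fixed point
  c4 <- identify_isoforms(c2$entries)
  tab_before <- table(c2$entries$gene, c2$entries$isoform_id)
  tab_after <- table(c4$entries$gene, c4$entries$isoform_id)
  expect_equal(tab_before, tab_after)
})

test_that("representative selection minimizes gaps with typed tie-breaks", {
  s <- paste0("M", r_random_protein(39))
  cand <- rbind(pred_row("g", "sp", s, "a_G", "G", gaps = 0),
                pred_row("g", "sp", s, "a_T", "T", gaps = 2))
  expect_equal(select_representative(cand)$assembly_type, "G")
  tie <- rbind(pred_row("g", "sp", s, "a_I", "I", gaps = 1),
               pred_row("g", "sp", s, "a_H", "H", gaps = 1))
  expect_equal(select_representative(tie)$assembly_type, "H")
  one <- pred_row("g", "sp", s, "a_T", "T", gaps = 5)
  expect_equal(select_representative(one)$assembly_id, "a_T")
  expect_null(select_representative(one[0, ]))
})

test_that("count summary enforces the accounting identity", {
  mk <- function(g, iso, sp) data.frame(gene = g, isoform_id = iso,
                                        species = sp,
                                        stringsAsFactors = FALSE)
  df <- rbind(mk("gA", "iso1", "sp1"),
              mk("gB", "iso1", "sp1"), mk("gB", "iso2", "sp1"),
              do.call(rbind, lapply(1:5, function(k)
                mk("gC", paste0("iso", k), "sp1"))))
  s <- count_summary(df)
  expect_equal(s$n_genes, 3)
  expect_equal(s$n_isoforms, 8)
  expect_equal(as.integer(s$histogram[c("1", "2", "5")]), c(1, 1, 1))
  s0 <- count_summary(df[0, ])
  expect_equal(s0$n_genes, 0)
  expect_equal(s0$n_isoforms, 0)
})

test_that("clade-level loss is called at the correct maximal node", {
  cfg <- simulation_config(
    n_species = 6, seed = 29,
    root_proteins = data.frame(gene = sprintf("g%d", 1:3),
                               family = "f1", length = 80),
    rate_per_gene = stats::setNames(rep(0.05, 3), sprintf("g%d", 1:3)),
    loss_events = data.frame(gene = "g2", clade_node = "n3"),
    assembly_types = "G")
  sim <- simulate_clade(cfg)
  ann <- annotate_assemblies(sim$queries, sim$assemblies)
  cat_ <- identify_isoforms(ann$predictions,
                            families = sim$genes[, c("gene", "family")])
  loss <- detect_gene_loss(cat_, sim$tree)
  expect_equal(nrow(loss$calls), 1)
  expect_equal(loss$calls$gene, "g2")
  expect_equal(loss$calls$clade_node, "n3")
  expect_true(loss$calls$supported)
  # species-level absence of a clade-lost gene is flagged per species
  expect_true(all(clade_leaves(sim$tree, "n3") %in%
                    loss$species_absences$species[
                      loss$species_absences$gene == "g2"]))
  # genes present everywhere produce no calls
  expect_false(any(loss$calls$gene %in% c("g1", "g3")))
})

test_that("duplicate loci and expanded families are reported", {
  cfg <- simulation_config(
    n_species = 4, seed = 31,
    root_proteins = data.frame(gene = c("gD", "gS"), family = "f1",
                               length = 80),
    rate_per_gene = c(gD = 0.05, gS = 0.05),
    duplication_events = data.frame(gene = "gD", n_copies = 3,
                                    divergence_scale = 0.05),
    assembly_types = "G")
  sim <- simulate_clade(cfg)
  ann <- annotate_assemblies(sim$queries, sim$assemblies)
  cat_ <- identify_isoforms(ann$predictions,
                            families = sim$genes[, c("gene", "family")])
  dup <- detect_duplicate_family(ann$hits, cat_)
  d <- dup$loci[dup$loci$gene == "gD", ]
  expect_equal(nrow(d), 4)            # every carrier species
  expect_true(all(d$copy_count == 3))
  expect_false("gS" %in% dup$loci$gene)
})

test_that("a tagged catalog FASTA audits back to its own accounting", {
  f <- withr::local_tempfile(fileext = ".fa")
  recs <- do.call(rbind, lapply(1:4, function(k) {
    n_iso <- c(1, 1, 2, 3)[k]
    do.call(rbind, lapply(seq_len(n_iso), function(i) data.frame(
      id = sprintf("g%d|iso%d|sp1", k, i),
      desc = make_tags(species = "sp1", gene = sprintf("g%d", k),
                       isoform = sprintf("iso%d", i), family = "famZ"),
      seq = r_random_protein(30), stringsAsFactors = FALSE)))
  }))
  write_fasta(recs, f)
  audit <- audit_catalog_fasta(f)
  expect_equal(audit$n_genes, 4)
  expect_equal(audit$n_isoforms, 7)
  expect_equal(as.integer(audit$histogram[c("1", "2", "3")]), c(2, 1, 1))
  expect_equal(as.integer(audit$genes_per_family[["famZ"]]), 4)
})
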