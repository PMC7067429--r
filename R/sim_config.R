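# Simulation configuration for the synthetic fish clade.

#' Build a simulation configuration
#'
#' Defines a fully ground-truthed synthetic clade: a species tree, a root
#' prohormone complement with per-gene evolutionary rates, optional
#' clade-level gene losses, tandem duplications and splice isoforms, and
#' per-assembly artifact probabilities. The same configuration (including
#' `seed`) always yields byte-identical simulated FASTA output.
#'
#' @param n_species Number of species (>= 3).
#' @param tree_mode `"yule"` (simulated pure-birth tree, depth scaled to 1
#'   substitution-time unit) or `"fixed_fixture"` (shipped 16-leaf
#'   damselfish-shaped topology).
#' @param root_proteins data.frame with columns `gene`, `family`, `length`
#'   describing the root complement. Default: 8 genes of length 120 across
#'   4 families.
#' @param rate_per_gene Named numeric, expected substitutions/site along a
#'   unit branch, per gene. Default 0.1 for every gene.
#' @param loss_events data.frame with columns `gene`, `clade_node` (an
#'   internal node label such as `"n3"`); the gene is absent from every
#'   species descending from that node.
#' @param duplication_events data.frame with columns `gene`, `n_copies`,
#'   `divergence_scale`.
#' @param isoform_events data.frame with columns `gene`, `indel_len`: a
#'   second, transcript-only isoform lacking an internal segment of
#'   `indel_len` residues.
#' @param genome_artifacts List of probabilities: `p_substitution` (per
#'   nucleotide), `p_frameshift_indel`, `p_inframe_indel`, `p_stop_codon`,
#'   `p_contig_break`, `p_gene_missing` (per gene copy).
#' @param transcriptome_artifacts List: `p_dropout`, `p_truncate_5p`,
#'   `p_truncate_3p` (per transcript), `truncate_frac_range` (length-2
#'   numeric in (0,1)).
#' @param assembly_types Character vector of assembly types generated per
#'   species, from `G` (genome), `H`/`I` (alternative/de novo genome),
#'   `T` (transcriptome). Default `c("G", "T")`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 6,
                              tree_mode = c("yule", "fixed_fixture"),
                              root_proteins = NULL,
                              rate_per_gene = NULL,
                              loss_events = NULL,
                              duplication_events = NULL,
                              isoform_events = NULL,
                              genome_artifacts = list(),
                              transcriptome_artifacts = list(),
                              assembly_types = c("G", "T"),
                              seed = 1L) {
  tree_mode <- match.arg(tree_mode)
  if (n_species < 3) stop("n_species must be >= 3")
  if (is.null(root_proteins)) {
    root_proteins <- data.frame(
      gene = sprintf("gene%02d", 1:8),
      family = rep(sprintf("fam%d", 1:4), each = 2),
      length = 120L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "family", "length") %in% names(root_proteins)),
            !anyDuplicated(root_proteins$gene),
            all(root_proteins$length >= 30))
  if (is.null(rate_per_gene))
    rate_per_gene <- stats::setNames(rep(0.1, nrow(root_proteins)),
                                     root_proteins$gene)
  if (any(rate_per_gene < 0)) stop("rates must be >= 0")
  if (!all(root_proteins$gene %in% names(rate_per_gene)))
    stop("rate_per_gene must cover every gene")
  ga <- utils::modifyList(list(p_substitution = 0, p_frameshift_indel = 0,
                               p_inframe_indel = 0, p_stop_codon = 0,
                               p_contig_break = 0, p_gene_missing = 0),
                          genome_artifacts)
  ta <- utils::modifyList(list(p_dropout = 0, p_truncate_5p = 0,
                               p_truncate_3p = 0,
                               truncate_frac_range = c(0.1, 0.4)),
                          transcriptome_artifacts)
  probs <- c(unlist(ga[startsWith(names(ga), "p_")]),
             unlist(ta[startsWith(names(ta), "p_")]))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  stopifnot(all(assembly_types %in% c("G", "H", "I", "T")))
  cfg <- list(n_species = as.integer(n_species), tree_mode = tree_mode,
              root_proteins = root_proteins, rate_per_gene = rate_per_gene,
              loss_events = loss_events,
              duplication_events = duplication_events,
              isoform_events = isoform_events,
              genome_artifacts = ga, transcriptome_artifacts = ta,
              assembly_types = assembly_types, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}
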