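# Assembly generation with ground-truthed artifacts. Every emitted gene
# copy has one truth row; artifact positions are recorded so they can be
# verified by diffing the emitted contig against the clean CDS.

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.truth_row <- function(species, assembly_id, type, gene, isoform,
                       true_protein, truth_class, artifacts = character(),
                       contig = NA_character_, kept_start = 0L,
                       kept_end = nchar(true_protein)) {
  data.frame(species = species, assembly_id = assembly_id, type = type,
             gene = gene, isoform = isoform, true_protein = true_protein,
             truth_class = truth_class,
             artifacts = paste(artifacts, collapse = ";"),
             contig = contig, kept_start = kept_start, kept_end = kept_end,
             stringsAsFactors = FALSE)
}

#' Build a synthetic genome assembly for one species
#'
#' Each gene is embedded intronless in a contig with >= 200 nt of random
#' flank on both sides. Artifacts are applied per the configured
#' probabilities: per-nucleotide substitutions; 1-2 nt frameshifting
#' indels; in-frame 3 nt indels; codon-to-stop edits; a contig break inside
#' the gene (truth class Partial); whole-gene omission (truth Missed).
#' Truth classes otherwise: small deletions that cost residues give Close,
#' everything else Exact (artifact list retained either way).
#'
#' @param species Species name.
#' @param genes data.frame with columns `gene`, `isoform`, `seq` (the
#'   species' true proteins to embed; genomic copies use isoform `i1`).
#' @param config A `sim_config`.
#' @param seed Integer seed for this assembly.
#' @param assembly_id Assembly identifier.
#' @param type Assembly type, one of `G`, `H`, `I`.
#' @return list(records = contig data.frame, truth = truth data.frame).
#' @export
build_genome_assembly <- function(species, genes, config, seed,
                                  assembly_id = paste0(species, "_G"),
                                  type = "G") {
  set.seed(seed)
  ga <- config$genome_artifacts
  recs <- list(); truth <- list(); ctg <- 0L
  new_ctg <- function() {
    ctg <<- ctg + 1L
    sprintf("%s_ctg%03d", assembly_id, ctg)
  }
  genes <- genes[order(genes$gene), , drop = FALSE]
  for (k in seq_len(nrow(genes))) {
    g <- genes$gene[k]; prot <- genes$seq[k]
    tags <- make_tags(species = species, assembly = assembly_id,
                      type = type)
    if (stats::runif(1) < ga$p_gene_missing) {
      id <- new_ctg()
      recs[[length(recs) + 1]] <- data.frame(
        id = id, desc = paste(tags, "decoy=1"), seq = random_dna(400),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- .truth_row(
        species, assembly_id, type, g, "i1", prot, "Missed",
        "gene_missing@NA", contig = NA_character_, kept_start = 0L,
        kept_end = 0L)
      next
    }
    cds <- reverse_translate(prot)
    arts <- character()
    cls <- "Exact"
    # per-nucleotide substitutions (may incidentally create stops)
    if (ga$p_substitution > 0) {
      hit <- which(stats::runif(nchar(cds)) < ga$p_substitution)
      if (length(hit)) {
        s <- strsplit(cds, "")[[1]]
        for (i in hit) s[i] <- sample(setdiff(c("A","C","G","T"), s[i]), 1)
        cds <- paste(s, collapse = "")
        arts <- c(arts, paste0("substitution@", hit - 1L))
      }
    }
    # in-frame 3 nt indel at a codon boundary
    if (stats::runif(1) < ga$p_inframe_indel) {
      ncod <- nchar(cds) / 3
      cod <- sample(2:(ncod - 2), 1)
      at <- 3 * (cod - 1)
      if (stats::runif(1) < 0.5) {
        cds <- paste0(substr(cds, 1, at), random_dna(3),
                      substr(cds, at + 1, nchar(cds)))
        arts <- c(arts, paste0("inframe_ins@", at))
      } else {
        cds <- paste0(substr(cds, 1, at), substr(cds, at + 4, nchar(cds)))
        arts <- c(arts, paste0("inframe_del@", at))
        cls <- "Close"
      }
    }
    # 1-2 nt frameshifting indel
    if (stats::runif(1) < ga$p_frameshift_indel) {
      w <- sample(1:2, 1)
      at <- sample(6:(nchar(cds) - 9), 1)
      if (stats::runif(1) < 0.5) {
        cds <- paste0(substr(cds, 1, at), random_dna(w),
                      substr(cds, at + 1, nchar(cds)))
        arts <- c(arts, paste0("frameshift_ins@", at))
      } else {
        cds <- paste0(substr(cds, 1, at), substr(cds, at + w + 1,
                                                 nchar(cds)))
        arts <- c(arts, paste0("frameshift_del@", at))
        cls <- "Close"
      }
    }
    # codon -> premature stop
    if (stats::runif(1) < ga$p_stop_codon) {
      ncod <- floor(nchar(cds) / 3)
      cod <- sample(2:(ncod - 2), 1)
      at <- 3 * (cod - 1)
      cds <- paste0(substr(cds, 1, at), "TAA",
                    substr(cds, at + 4, nchar(cds)))
      arts <- c(arts, paste0("stop@", at))
    }
    fl5 <- random_dna(200 + sample(0:100, 1))
    fl3 <- random_dna(200 + sample(0:100, 1))
    if (stats::runif(1) < ga$p_contig_break) {
      br <- sample(seq(floor(0.1 * nchar(cds)), ceiling(0.9 * nchar(cds))),
                   1)
      id1 <- new_ctg(); id2 <- new_ctg()
      recs[[length(recs) + 1]] <- data.frame(
        id = id1, desc = tags, seq = paste0(fl5, substr(cds, 1, br)),
        stringsAsFactors = FALSE)
      recs[[length(recs) + 1]] <- data.frame(
        id = id2, desc = tags,
        seq = paste0(substr(cds, br + 1, nchar(cds)), fl3),
        stringsAsFactors = FALSE)
      arts <- c(arts, paste0("contig_break@", br))
      truth[[length(truth) + 1]] <- .truth_row(
        species, assembly_id, type, g, "i1", prot, "Partial", arts,
        contig = id1)
    } else {
      id <- new_ctg()
      recs[[length(recs) + 1]] <- data.frame(
        id = id, desc = tags, seq = paste0(fl5, cds, fl3),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- .truth_row(
        species, assembly_id, type, g, "i1", prot, cls, arts, contig = id)
    }
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' Build a synthetic transcriptome assembly for one species
#'
#' Per gene-isoform, a transcript (CDS plus short UTRs) is emitted with
#' probability `1 - p_dropout`; an `expression_profile` can force
#' gene-specific dropout (emulating tissue-restricted expression).
#' Truncation clips a uniform fraction from the 5' or 3' end (truth class
#' Partial when coding residues are lost). Transcripts are emitted on a
#' random strand.
#'
#' @param species Species name.
#' @param genes data.frame with columns `gene`, `isoform`, `seq`.
#' @param expression_profile Optional named logical vector by gene;
#'   `FALSE` forces dropout of every isoform of that gene.
#' @param config A `sim_config`.
#' @param seed Integer seed for this assembly.
#' @param assembly_id Assembly identifier.
#' @return list(records, truth) as in [build_genome_assembly()].
#' @export
build_transcriptome_assembly <- function(species, genes,
                                         expression_profile = NULL,
                                         config, seed,
                                         assembly_id = paste0(species,
                                                              "_T")) {
  set.seed(seed)
  ta <- config$transcriptome_artifacts
  recs <- list(); truth <- list(); tx <- 0L
  genes <- genes[order(genes$gene, genes$isoform), , drop = FALSE]
  for (k in seq_len(nrow(genes))) {
    g <- genes$gene[k]; iso <- genes$isoform[k]; prot <- genes$seq[k]
    forced_off <- !is.null(expression_profile) &&
      g %in% names(expression_profile) && !expression_profile[[g]]
    if (forced_off || stats::runif(1) < ta$p_dropout) {
      truth[[length(truth) + 1]] <- .truth_row(
        species, assembly_id, "T", g, iso, prot, "Missed",
        if (forced_off) "not_expressed@NA" else "dropout@NA",
        kept_start = 0L, kept_end = 0L)
      next
    }
    cds <- reverse_translate(prot)
    utr5 <- random_dna(30 + sample(0:40, 1))
    utr3 <- random_dna(30 + sample(0:40, 1))
    transcript <- paste0(utr5, cds, utr3)
    kept <- c(0L, nchar(prot)); cls <- "Exact"; arts <- character()
    if (stats::runif(1) < ta$p_truncate_5p) {
      frac <- stats::runif(1, ta$truncate_frac_range[1],
                           ta$truncate_frac_range[2])
      cut <- floor(frac * nchar(transcript))
      transcript <- substr(transcript, cut + 1, nchar(transcript))
      lost_aa <- max(0L, as.integer(ceiling((cut - nchar(utr5)) / 3)))
      arts <- c(arts, paste0("truncate_5p@", cut))
      if (lost_aa > 0) {
        kept[1] <- lost_aa
        cls <- "Partial"
      }
      utr5_len <- max(0L, nchar(utr5) - cut)
    } else utr5_len <- nchar(utr5)
    if (stats::runif(1) < ta$p_truncate_3p) {
      frac <- stats::runif(1, ta$truncate_frac_range[1],
                           ta$truncate_frac_range[2])
      cut <- floor(frac * nchar(transcript))
      lost_nt <- cut - nchar(utr3)
      transcript <- substr(transcript, 1, nchar(transcript) - cut)
      lost_aa <- max(0L, as.integer(ceiling(lost_nt / 3)))
      arts <- c(arts, paste0("truncate_3p@", cut))
      if (lost_aa > 0) {
        kept[2] <- nchar(prot) - lost_aa
        cls <- "Partial"
      }
    }
    tx <- tx + 1L
    id <- sprintf("%s_tx%03d", assembly_id, tx)
    if (stats::runif(1) < 0.5) transcript <- revcomp(transcript)
    recs[[length(recs) + 1]] <- data.frame(
      id = id, desc = make_tags(species = species, assembly = assembly_id,
                                type = "T"),
      seq = transcript, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- .truth_row(
      species, assembly_id, "T", g, iso, prot, cls, arts, contig = id,
      kept_start = kept[1], kept_end = kept[2])
  }
  list(records = if (length(recs)) do.call(rbind, recs) else
         data.frame(id = character(), desc = character(),
                    seq = character(), stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

#' Simulate a complete synthetic clade
#'
#' Runs the full generator: species tree, root complement, duplications,
#' per-gene evolution, splice isoforms, clade-level losses, and one
#' assembly per configured type per species, with a unified truth ledger.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_clade`: `tree`, `genes` (root set),
#'   `proteins` (species x gene x isoform truth proteins), `assemblies`
#'   (list of per-assembly record sets), `truth` (ledger data.frame),
#'   `lost_pairs` (species/gene combinations removed by loss events),
#'   `queries` (root complement as the reference query set), `config`.
#' @export
simulate_clade <- function(config) {
  tree <- simulate_species_tree(config)
  species <- tree$tip.label
  set.seed(config$seed)
  rp <- config$root_proteins
  genes <- data.frame(gene = rp$gene, family = rp$family,
                      seq = vapply(rp$length, random_protein, character(1)),
                      rate = unname(config$rate_per_gene[rp$gene]),
                      stringsAsFactors = FALSE)
  queries <- data.frame(gene = genes$gene, family = genes$family,
                        species_of_origin = "root", seq = genes$seq,
                        stringsAsFactors = FALSE)
  if (!is.null(config$duplication_events)) {
    for (k in seq_len(nrow(config$duplication_events))) {
      ev <- config$duplication_events[k, ]
      genes <- inject_duplication(genes, ev$gene, ev$n_copies,
                                  ev$divergence_scale,
                                  seed = config$seed + 1000L + k)
    }
  }
  # evolve every gene (copy) down the tree
  prot_rows <- list()
  for (k in seq_len(nrow(genes))) {
    leaves <- evolve_protein(genes$seq[k], tree, genes$rate[k],
                             seed = config$seed + 17L * k)
    substr(leaves, 1, 1) <- "M"  # the start codon is part of the gene model
    prot_rows[[k]] <- data.frame(species = names(leaves),
                                 gene = genes$gene[k], isoform = "i1",
                                 seq = unname(leaves),
                                 stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)
  # transcript-only splice isoforms: an internal segment deleted at the
  # same (root-chosen) position in every species
  if (!is.null(config$isoform_events)) {
    set.seed(config$seed + 7L)
    for (k in seq_len(nrow(config$isoform_events))) {
      ev <- config$isoform_events[k, ]
      base <- proteins[proteins$gene == ev$gene &
                         proteins$isoform == "i1", ]
      L <- nchar(base$seq[1])
      at <- sample(seq(10, L - 10 - ev$indel_len), 1)
      iso2 <- base
      iso2$isoform <- "i2"
      iso2$seq <- paste0(substr(base$seq, 1, at),
                         substring(base$seq, at + ev$indel_len + 1))
      proteins <- rbind(proteins, iso2)
    }
  }
  # clade-level gene loss
  lost_pairs <- data.frame(species = character(), gene = character(),
                           clade_node = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(config$loss_events)) {
    for (k in seq_len(nrow(config$loss_events))) {
      ev <- config$loss_events[k, ]
      lv <- clade_leaves(tree, ev$clade_node)
      lost_pairs <- rbind(lost_pairs,
                          data.frame(species = lv, gene = ev$gene,
                                     clade_node = ev$clade_node,
                                     stringsAsFactors = FALSE))
    }
    keep <- !(paste(proteins$species, proteins$gene) %in%
                paste(lost_pairs$species, lost_pairs$gene))
    proteins <- proteins[keep, , drop = FALSE]
  }
  assemblies <- list(); truth <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    sp_prot <- proteins[proteins$species == sp, , drop = FALSE]
    for (ti in seq_along(config$assembly_types)) {
      ty <- config$assembly_types[ti]
      aid <- paste0(sp, "_", ty)
      seed_a <- config$seed + 100000L + si * 1000L + ti
      if (ty %in% c("G", "H", "I")) {
        gg <- sp_prot[sp_prot$isoform == "i1", , drop = FALSE]
        built <- build_genome_assembly(sp, gg, config, seed_a,
                                       assembly_id = aid, type = ty)
      } else {
        built <- build_transcriptome_assembly(sp, sp_prot, NULL, config,
                                              seed_a, assembly_id = aid)
      }
      assemblies[[aid]] <- list(species = sp, assembly_id = aid,
                                type = ty, records = built$records)
      truth[[aid]] <- built$truth
    }
  }
  out <- list(tree = tree, genes = genes, proteins = proteins,
              assemblies = assemblies,
              truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
              lost_pairs = lost_pairs, queries = queries, config = config)
  class(out) <- "sim_clade"
  out
}
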