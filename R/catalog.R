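# Cross-assembly, cross-species isoform cataloguing, gene-loss calls and
# duplicate-family screening.
#
# Isoform rule: within a gene, two predictions are the same isoform when
# their global alignment differs only by substitutions, terminal coverage
# gaps, or placeholder (X) regions; an internal indel at mutually covered
# positions separates isoforms. A new (non-primary) isoform additionally
# requires transcript evidence in at least one species, or presence as a
# distinct locus in at least `min_genome_assemblies` genome assemblies —
# this blocks assembly-error isoforms.

# TRUE when the aligned pair shows no internal indel at mutually covered
# positions (terminal gap runs are coverage, not isoform differences).
.same_isoform_alignment <- function(a, b, params = align_params()) {
  if (identical(a, b)) return(TRUE)
  ga <- global_align_protein(a, b, params)
  ra <- strsplit(ga$a_aln, "")[[1]]
  rb <- strsplit(ga$b_aln, "")[[1]]
  gap <- ra == "-" | rb == "-"
  if (!any(gap)) return(TRUE)
  n <- length(ra)
  lead <- cumsum(!gap) == 0
  trail <- rev(cumsum(rev(!gap)) == 0)
  internal <- gap & !lead & !trail
  !any(internal)
}

#' Identify isoforms across predictions
#'
#' Clusters per-gene candidate predictions into isoforms (see the rule in
#' the package vignette), assigns deterministic isoform ids (`iso1`,
#' `iso2`, ... by descending prevalence, ties broken by lexicographic
#' exemplar sequence), and selects per-species representatives.
#'
#' @param predictions Prediction data.frame from [annotate_assemblies()].
#' @param families Optional data.frame (`gene`, `family`).
#' @param min_genome_assemblies Distinct genome assemblies required to
#'   accept a transcript-free new isoform.
#' @param require_transcript If `FALSE`, new isoforms are accepted without
#'   transcript or multi-genome support (the permissive reading).
#' @param params Alignment parameters.
#' @return A list of class `isoform_catalog`: `entries` (all non-absent
#'   predictions with `isoform_id`), `representatives` (one row per gene x
#'   isoform x species), `families` (named vector), `absent` (the absent
#'   prediction rows), `assemblies_meta`.
#' @export
identify_isoforms <- function(predictions, families = NULL,
                              min_genome_assemblies = 2,
                              require_transcript = TRUE,
                              params = align_params()) {
  present <- predictions[nzchar(predictions$seq), , drop = FALSE]
  absent <- predictions[!nzchar(predictions$seq), , drop = FALSE]
  out <- list()
  for (g in sort(unique(present$gene))) {
    cand <- present[present$gene == g, , drop = FALSE]
    comp <- cand$completeness == "complete"
    cand <- cand[order(!comp, cand$n_gaps, cand$seq), , drop = FALSE]
    clusters <- list()
    assign_to <- integer(nrow(cand))
    deferred <- integer()
    for (i in seq_len(nrow(cand))) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        if (.same_isoform_alignment(cand$seq[i],
                                    clusters[[ci]]$exemplar, params)) {
          clusters[[ci]]$members <- c(clusters[[ci]]$members, i)
          assign_to[i] <- ci
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # only complete predictions may found a new isoform cluster:
        # differences in incomplete sequences can be coverage artifacts
        if (cand$completeness[i] == "complete" || !length(clusters)) {
          clusters[[length(clusters) + 1]] <- list(
            exemplar = cand$seq[i], members = i)
          assign_to[i] <- length(clusters)
        } else deferred <- c(deferred, i)
      }
    }
    for (i in deferred) {
      sc <- vapply(seq_along(clusters), function(cj)
        global_align_protein(cand$seq[i], clusters[[cj]]$exemplar,
                             params)$score, numeric(1))
      ci <- which.max(sc)
      clusters[[ci]]$members <- c(clusters[[ci]]$members, i)
      assign_to[i] <- ci
    }
    # evidence rule: the primary (most prevalent) cluster is always
    # accepted; secondary clusters need transcript or multi-genome support
    sizes <- vapply(clusters, function(cl)
      length(unique(cand$species[cl$members])), integer(1))
    exems <- vapply(clusters, `[[`, character(1), "exemplar")
    ord <- order(-sizes, exems)
    accepted <- logical(length(clusters))
    accepted[ord[1]] <- TRUE
    for (ci in ord[-1]) {
      mem <- clusters[[ci]]$members
      has_tx <- any(cand$evidence[mem] == "transcript")
      n_gen <- length(unique(cand$assembly_id[mem][
        cand$assembly_type[mem] %in% c("G", "H", "I")]))
      accepted[ci] <- !require_transcript || has_tx ||
        n_gen >= min_genome_assemblies
    }
    # reassign members of rejected clusters to the best accepted cluster
    for (ci in which(!accepted)) {
      for (i in clusters[[ci]]$members) {
        sc <- vapply(which(accepted), function(cj)
          global_align_protein(cand$seq[i], clusters[[cj]]$exemplar,
                               params)$score, numeric(1))
        assign_to[i] <- which(accepted)[which.max(sc)]
      }
    }
    acc_ord <- ord[accepted[ord]]
    iso_ids <- stats::setNames(sprintf("iso%d", seq_along(acc_ord)),
                               as.character(acc_ord))
    cand$isoform_id <- iso_ids[as.character(assign_to)]
    out[[g]] <- cand
  }
  entries <- if (length(out)) do.call(rbind, out) else present
  rownames(entries) <- NULL
  fam <- if (!is.null(families))
    stats::setNames(families$family, families$gene) else
      stats::setNames(rep("unassigned", length(unique(entries$gene))),
                      unique(entries$gene))
  reps <- list()
  if (nrow(entries)) {
    key <- paste(entries$gene, entries$isoform_id, entries$species)
    for (k in unique(key)) {
      reps[[k]] <- select_representative(entries[key == k, , drop = FALSE])
    }
  }
  meta <- unique(predictions[, c("assembly_id", "species",
                                 "assembly_type")])
  cat <- list(entries = entries,
              representatives = if (length(reps))
                do.call(rbind, c(reps, list(make.row.names = FALSE))) else
                  entries,
              families = fam, absent = absent, assemblies_meta = meta)
  class(cat) <- "isoform_catalog"
  cat
}

#' Select the representative prediction among candidates
#'
#' Fewest uncovered/gap positions wins; ties break by assembly-type
#' priority G > H > I > T, then lexicographic assembly id.
#'
#' @param candidates data.frame of prediction rows.
#' @return The selected row, or `NULL` if empty.
#' @export
select_representative <- function(candidates) {
  candidates <- candidates[nzchar(candidates$seq), , drop = FALSE]
  if (!nrow(candidates)) return(NULL)
  pri <- match(candidates$assembly_type, c("G", "H", "I", "T"))
  pri[is.na(pri)] <- 5L
  candidates[order(candidates$n_gaps, pri, candidates$assembly_id), ,
             drop = FALSE][1, , drop = FALSE]
}

#' Catalog count summary
#'
#' Totals, the isoforms-per-gene histogram and per-family counts; enforces
#' the accounting identity sum(k * genes_with_k_isoforms) == n_isoforms.
#'
#' @param catalog An `isoform_catalog` (or a data.frame with `gene`,
#'   `isoform_id` and optionally `family` columns).
#' @return list(n_genes, n_isoforms, histogram, per_family).
#' @export
count_summary <- function(catalog) {
  if (inherits(catalog, "isoform_catalog")) {
    df <- catalog$entries
    fam <- catalog$families
  } else {
    df <- catalog
    fam <- if ("family" %in% names(df))
      stats::setNames(df$family, df$gene) else NULL
  }
  if (!nrow(df))
    return(list(n_genes = 0L, n_isoforms = 0L,
                histogram = integer(), per_family = data.frame()))
  gi <- unique(df[, c("gene", "isoform_id")])
  per_gene <- table(gi$gene)
  hist <- table(factor(as.integer(per_gene)))
  n_iso <- nrow(gi)
  stopifnot(sum(as.integer(names(hist)) * as.integer(hist)) == n_iso)
  per_family <- NULL
  if (!is.null(fam)) {
    gi$family <- unname(fam[gi$gene])
    per_family <- as.data.frame(table(family = gi$family),
                                stringsAsFactors = FALSE)
    names(per_family) <- c("family", "n_isoforms")
  }
  list(n_genes = length(per_gene), n_isoforms = n_iso,
       histogram = hist, per_family = per_family)
}

#' Detect clade-level gene loss
#'
#' For each gene, finds maximal clades in which every member carrying a
#' genome-type assembly lacks the gene (and no member shows it at all),
#' while at least one species outside the clade has it. Clades without any
#' genome-type member are reported as unsupported (absence of expression
#' cannot prove loss). Single-species absences are returned separately.
#'
#' @param catalog An `isoform_catalog`.
#' @param tree Species tree (`phylo` with node labels).
#' @return list(calls = data.frame(gene, clade_node, n_species,
#'   n_genome_species, supported), species_absences = data.frame).
#' @export
detect_gene_loss <- function(catalog, tree) {
  meta <- catalog$assemblies_meta
  species <- tree$tip.label
  has_genome <- vapply(species, function(sp)
    any(meta$species == sp & meta$assembly_type %in% c("G", "H", "I")),
    logical(1))
  genes <- sort(unique(c(catalog$entries$gene, catalog$absent$gene)))
  present_tab <- unique(catalog$entries[, c("species", "gene")])
  calls <- list(); absentees <- list()
  for (g in genes) {
    present_sp <- present_tab$species[present_tab$gene == g]
    absent_sp <- setdiff(species, present_sp)
    if (!length(absent_sp)) next
    for (sp in absent_sp)
      absentees[[length(absentees) + 1]] <- data.frame(
        gene = g, species = sp, genome_backed = unname(has_genome[sp]),
        stringsAsFactors = FALSE)
    if (is.null(tree$node.label)) next
    cand_nodes <- list()
    for (idx in seq_len(tree$Nnode)[-1]) {  # skip root: outgroup needed
      lab <- tree$node.label[idx]
      leaves <- clade_leaves(tree, lab)
      if (!all(leaves %in% absent_sp)) next
      if (!any(present_sp %in% setdiff(species, leaves))) next
      cand_nodes[[lab]] <- leaves
    }
    if (!length(cand_nodes)) next
    # maximal clades only
    labs <- names(cand_nodes)
    keep <- vapply(labs, function(l1)
      !any(vapply(labs, function(l2)
        l1 != l2 && all(cand_nodes[[l1]] %in% cand_nodes[[l2]]),
        logical(1))), logical(1))
    for (lab in labs[keep]) {
      leaves <- cand_nodes[[lab]]
      n_gen <- sum(has_genome[leaves])
      calls[[length(calls) + 1]] <- data.frame(
        gene = g, clade_node = lab, n_species = length(leaves),
        n_genome_species = n_gen, supported = n_gen > 0,
        stringsAsFactors = FALSE)
    }
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else
         data.frame(gene = character(), clade_node = character(),
                    n_species = integer(), n_genome_species = integer(),
                    supported = logical(), stringsAsFactors = FALSE),
       species_absences = if (length(absentees))
         do.call(rbind, absentees) else
           data.frame(gene = character(), species = character(),
                      genome_backed = logical(), stringsAsFactors = FALSE))
}

#' Screen for duplicated genes and expanded families
#'
#' A gene is reported when any genome assembly contains two or more
#' disjoint high-scoring loci for its query, with per-species copy counts;
#' families with two or more catalogued genes are reported as expansions.
#'
#' @param hits Hit table from [annotate_assemblies()].
#' @param catalog An `isoform_catalog`.
#' @param min_copies Minimum locus count to report.
#' @return list(loci = data.frame(gene, species, copy_count),
#'   families = data.frame(family, n_genes)).
#' @export
detect_duplicate_family <- function(hits, catalog, min_copies = 2) {
  loci <- NULL
  if (!is.null(hits) && nrow(hits)) {
    gh <- hits[hits$assembly_type %in% c("G", "H", "I"), , drop = FALSE]
    if (nrow(gh)) {
      cnt <- stats::aggregate(contig_id ~ gene + species + assembly_id,
                              data = gh, FUN = length)
      names(cnt)[4] <- "copy_count"
      per_sp <- stats::aggregate(copy_count ~ gene + species, data = cnt,
                                 FUN = max)
      dup_genes <- unique(per_sp$gene[per_sp$copy_count >= min_copies])
      loci <- per_sp[per_sp$gene %in% dup_genes, , drop = FALSE]
      loci <- loci[order(loci$gene, loci$species), , drop = FALSE]
      rownames(loci) <- NULL
    }
  }
  fam_tab <- NULL
  if (length(catalog$families)) {
    genes <- unique(catalog$entries$gene)
    ft <- table(unname(catalog$families[genes]))
    ft <- ft[ft >= 2]
    if (length(ft))
      fam_tab <- data.frame(family = names(ft),
                            n_genes = as.integer(ft),
                            stringsAsFactors = FALSE)
  }
  list(loci = if (is.null(loci))
         data.frame(gene = character(), species = character(),
                    copy_count = integer(), stringsAsFactors = FALSE) else
           loci,
       families = if (is.null(fam_tab))
         data.frame(family = character(), n_genes = integer(),
                    stringsAsFactors = FALSE) else fam_tab)
}

#' Write a catalog as tagged protein FASTA
#'
#' One record per gene/isoform/species representative, with
#' machine-readable tags in the description.
#'
#' @param catalog An `isoform_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog_fasta <- function(catalog, path) {
  reps <- catalog$representatives
  recs <- data.frame(
    id = paste(reps$gene, reps$isoform_id, reps$species, sep = "|"),
    desc = vapply(seq_len(nrow(reps)), function(i)
      make_tags(species = reps$species[i], gene = reps$gene[i],
                isoform = reps$isoform_id[i],
                family = unname(catalog$families[reps$gene[i]]),
                assembly = reps$assembly_id[i],
                type = reps$assembly_type[i]), character(1)),
    seq = reps$seq, stringsAsFactors = FALSE)
  write_fasta(recs, path)
}

#' Audit a tagged catalog FASTA
#'
#' Recomputes the complement accounting (gene and isoform totals, the
#' isoforms-per-gene histogram, per-family gene counts) from a tagged
#' protein FASTA, e.g. a serialized catalog or a supplement-style file
#' carrying `gene=`/`isoform=` tags.
#'
#' @param path Path to a tagged protein FASTA.
#' @return list(n_genes, n_isoforms, histogram, genes_per_family).
#' @export
audit_catalog_fasta <- function(path) {
  recs <- read_fasta(path, "protein", allow_gaps = TRUE)
  tags <- lapply(recs$desc, parse_tags)
  gene <- vapply(tags, function(t) t[["gene"]], character(1))
  iso <- vapply(tags, function(t)
    if ("isoform" %in% names(t)) t[["isoform"]] else "iso1", character(1))
  fam <- vapply(tags, function(t)
    if ("family" %in% names(t)) t[["family"]] else "unassigned",
    character(1))
  gi <- unique(data.frame(gene = gene, isoform = iso, family = fam,
                          stringsAsFactors = FALSE))
  per_gene <- table(gi$gene)
  hist <- table(factor(as.integer(per_gene)))
  fam_genes <- unique(gi[, c("gene", "family")])
  list(n_genes = length(per_gene), n_isoforms = nrow(gi),
       histogram = hist,
       genes_per_family = table(fam_genes$family))
}
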