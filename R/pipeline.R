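# End-to-end pipeline: simulate -> annotate -> catalog -> classify ->
# features -> stats -> report. Stages communicate via files in the output
# directory so each stage can be rerun independently; a manifest records
# the configuration hash and seed for byte-identical reruns.

#' Build a pipeline configuration
#'
#' Either give a `sim_config` in `simulate` (synthetic mode), or paths to
#' a query protein FASTA and assembly FASTA files (annotation mode).
#'
#' @param simulate A `sim_config`, or `NULL` for file-based input.
#' @param queries_path Protein FASTA of reference queries (file mode).
#' @param assembly_paths Named character vector of nucleotide FASTA paths;
#'   names are assembly ids formatted `species_TYPE` (file mode).
#' @param scopes Named list of species vectors for the statistics stage
#'   (default: one `All` scope).
#' @param params Alignment parameters.
#' @param min_score_frac Search threshold fraction of query self-score.
#' @param min_family_isoforms Minimum member isoforms for the family
#'   summary.
#' @param seed Integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, queries_path = NULL,
                            assembly_paths = NULL, scopes = NULL,
                            params = align_params(),
                            min_score_frac = 0.4,
                            min_family_isoforms = 1, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(queries_path) || is.null(assembly_paths))
      stop("either 'simulate' or both 'queries_path' and ",
           "'assembly_paths' must be given")
    if (!file.exists(queries_path))
      stop("query file does not exist: ", queries_path)
    missing <- assembly_paths[!file.exists(assembly_paths)]
    if (length(missing))
      stop("assembly file does not exist: ", missing[1])
  }
  cfg <- list(simulate = simulate, queries_path = queries_path,
              assembly_paths = assembly_paths, scopes = scopes,
              params = params, min_score_frac = min_score_frac,
              min_family_isoforms = min_family_isoforms,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `seed`, `min_score_frac`, `min_family_isoforms`,
#' `queries`, `assemblies` (mapping id -> path), `scopes` (mapping name ->
#' species list), and `simulate` (mapping of [simulation_config()]
#' arguments).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sa <- y$simulate
    if (!is.null(sa$root_proteins))
      sa$root_proteins <- do.call(rbind, lapply(sa$root_proteins,
                                                as.data.frame))
    if (!is.null(sa$rate_per_gene))
      sa$rate_per_gene <- unlist(sa$rate_per_gene)
    if (!is.null(sa$loss_events))
      sa$loss_events <- do.call(rbind, lapply(sa$loss_events,
                                              as.data.frame))
    if (!is.null(sa$duplication_events))
      sa$duplication_events <- do.call(rbind,
                                       lapply(sa$duplication_events,
                                              as.data.frame))
    if (!is.null(sa$assembly_types)) sa$assembly_types <-
        unlist(sa$assembly_types)
    sim <- do.call(simulation_config, sa)
  }
  pipeline_config(
    simulate = sim,
    queries_path = y$queries,
    assembly_paths = if (!is.null(y$assemblies)) unlist(y$assemblies),
    scopes = y$scopes,
    min_score_frac = if (!is.null(y$min_score_frac)) y$min_score_frac
      else 0.4,
    min_family_isoforms = if (!is.null(y$min_family_isoforms))
      y$min_family_isoforms else 1,
    seed = if (!is.null(y$seed)) y$seed else 1L)
}

.load_assemblies_from_files <- function(paths) {
  out <- list()
  for (aid in names(paths)) {
    recs <- read_fasta(paths[[aid]], "dna")
    toks <- strsplit(aid, "_")[[1]]
    ty <- toks[length(toks)]
    sp <- paste(toks[-length(toks)], collapse = "_")
    if (!ty %in% c("G", "H", "I", "T"))
      stop("assembly id must end in _G/_H/_I/_T: ", aid)
    out[[aid]] <- list(species = sp, assembly_id = aid, type = ty,
                       records = recs)
  }
  out
}

#' Run the full pipeline
#'
#' Produces, under `out_dir`: simulated assemblies and truth ledger (in
#' synthetic mode), prediction FASTA/TSV, the isoform catalog (tagged
#' FASTA + TSV), loss and duplication reports, recovery tables (per
#' assembly and per isoform), peptide products, per-isoform evolutionary
#' statistics and the family summary, plus a JSON run manifest.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coord_note <- "coordinates are 0-based half-open on the forward strand"
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                                    paste0(...)))
  # --- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_clade(config$simulate)
    queries <- sim$queries
    assemblies <- sim$assemblies
    tree <- sim$tree
    for (a in assemblies)
      write_fasta(a$records, file.path(out_dir,
                                       paste0(a$assembly_id, ".fa")))
    write_report(sim$truth, file.path(out_dir, "truth.tsv"),
                 comment = coord_note)
    write_newick(tree, file.path(out_dir, "species_tree.nwk"))
    families <- sim$genes[, c("gene", "family")]
    log_stage("simulate", length(assemblies), " assemblies, ",
              nrow(sim$truth), " truth entries")
  } else {
    qr <- read_fasta(config$queries_path, "protein")
    fam <- vapply(qr$desc, function(d) {
      t <- parse_tags(d)
      if ("family" %in% names(t)) t[["family"]] else "unassigned"
    }, character(1))
    queries <- data.frame(gene = qr$id, family = unname(fam),
                          species_of_origin = "reference", seq = qr$seq,
                          stringsAsFactors = FALSE)
    assemblies <- .load_assemblies_from_files(config$assembly_paths)
    tree <- NULL
    families <- queries[, c("gene", "family")]
    sim <- NULL
    log_stage("input", nrow(queries), " queries, ", length(assemblies),
              " assemblies")
  }
  # --- annotation ---------------------------------------------------
  ann <- annotate_assemblies(queries, assemblies, config$params,
                             min_score_frac = config$min_score_frac)
  preds <- ann$predictions
  write_report(preds, file.path(out_dir, "predictions.tsv"),
               comment = coord_note)
  found <- preds[nzchar(preds$seq), , drop = FALSE]
  if (nrow(found))
    write_fasta(data.frame(
      id = paste(found$gene, found$assembly_id, sep = "|"),
      desc = vapply(seq_len(nrow(found)), function(i)
        make_tags(species = found$species[i], gene = found$gene[i],
                  assembly = found$assembly_id[i],
                  type = found$assembly_type[i]), character(1)),
      seq = found$seq, stringsAsFactors = FALSE),
      file.path(out_dir, "predictions.fa"))
  log_stage("annotate", nrow(found), "/", nrow(preds),
            " predictions non-absent")
  # --- catalog ------------------------------------------------------
  catalog <- identify_isoforms(preds, families = families,
                               params = config$params)
  write_catalog_fasta(catalog, file.path(out_dir, "catalog.fa"))
  write_report(catalog$entries, file.path(out_dir, "catalog.tsv"),
               comment = coord_note)
  summary <- count_summary(catalog)
  log_stage("catalog", summary$n_genes, " genes, ", summary$n_isoforms,
            " isoforms")
  dup <- detect_duplicate_family(ann$hits, catalog)
  write_report(dup$loci, file.path(out_dir, "duplications.tsv"))
  loss <- NULL
  if (!is.null(tree)) {
    loss <- detect_gene_loss(catalog, tree)
    write_report(loss$calls, file.path(out_dir, "gene_loss.tsv"))
  }
  # --- recovery classification -------------------------------------
  calls <- catalog_recovery_calls(catalog, params = config$params)
  write_report(calls, file.path(out_dir, "recovery_calls.tsv"))
  tab1 <- tabulate_recovery(calls, "by_assembly")
  write_report(tab1, file.path(out_dir, "recovery_by_assembly.tsv"))
  tab3 <- tabulate_recovery(calls, "by_isoform")
  write_report(tab3$per_isoform,
               file.path(out_dir, "recovery_by_isoform.tsv"))
  write_report(tab3$buckets,
               file.path(out_dir, "recovery_buckets.tsv"))
  log_stage("classify", nrow(calls), " recovery calls")
  # --- peptide features --------------------------------------------
  reps <- catalog$representatives
  pep_rows <- list()
  for (i in seq_len(nrow(reps))) {
    p <- gsub("[X*-]", "", reps$seq[i])
    if (nchar(p) < 4) next
    pp <- derive_peptides(p)
    if (!nrow(pp)) next
    pp <- pp[pp$kept, , drop = FALSE]
    if (!nrow(pp)) next
    pp$gene <- reps$gene[i]; pp$isoform_id <- reps$isoform_id[i]
    pp$species <- reps$species[i]
    pep_rows[[length(pep_rows) + 1]] <- pp
  }
  peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else NULL
  if (!is.null(peptides))
    write_report(peptides, file.path(out_dir, "peptides.tsv"),
                 comment = coord_note)
  log_stage("features", if (is.null(peptides)) 0 else nrow(peptides),
            " peptide products")
  # --- evolutionary statistics -------------------------------------
  stats_df <- NULL; famsum <- NULL
  if (!is.null(tree)) {
    scopes <- config$scopes
    if (is.null(scopes)) scopes <- list(All = tree$tip.label)
    stats_df <- evol_stats(catalog, tree, scopes, config$params)
    if (!is.null(stats_df)) {
      write_report(stats_df, file.path(out_dir, "evolstats.tsv"))
      famsum <- family_summary(stats_df, catalog$families,
                               config$min_family_isoforms)
      write_report(famsum, file.path(out_dir, "family_summary.tsv"))
      log_stage("stats", nrow(stats_df), " isoform x scope records")
    }
  }
  # --- manifest -----------------------------------------------------
  manifest <- list(
    package = "prohoscan",
    version = as.character(utils::packageVersion("prohoscan")),
    seed = config$seed,
    synthetic = !is.null(config$simulate),
    n_queries = nrow(queries), n_assemblies = length(assemblies),
    n_genes = summary$n_genes, n_isoforms = summary$n_isoforms,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, queries = queries, predictions = preds,
                 hits = ann$hits, catalog = catalog, summary = summary,
                 calls = calls, tab1 = tab1, tab3 = tab3,
                 duplications = dup, loss = loss, peptides = peptides,
                 evolstats = stats_df, family_summary = famsum,
                 tree = tree))
}
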