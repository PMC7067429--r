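# Per-isoform phylogenetics and the evolutionary statistics: corrected
# p-distances, neighbor-joining trees, MeaPED, Robinson-Foulds (raw and
# normalized), shared-edge proportions, family summaries and the
# duplicate-fate screen.

#' Pairwise distance matrix from an alignment
#'
#' Proportion of differing residues over columns where both rows are
#' ungapped (placeholder `X` columns are excluded as missing data);
#' optional Poisson correction d = -ln(1 - p). Pairs sharing fewer than 10
#' columns are flagged unreliable in the `unreliable` attribute.
#'
#' @param msa An `msa` object or named character of aligned rows.
#' @param correction `"none"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal; attribute
#'   `unreliable` is a logical matrix.
#' @export
pdistance_matrix <- function(msa, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  rows <- if (inherits(msa, "msa")) msa$aln else msa
  labs <- names(rows)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  unrel <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  ok <- mat != "-" & mat != "X"
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq((i + 1), n)) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns < 10) unrel[i, j] <- unrel[j, i] <- TRUE
      p <- if (ns == 0) 0 else sum(mat[i, shared] != mat[j, shared]) / ns
      if (correction == "poisson") {
        p <- min(p, 0.999)
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  attr(d, "unreliable") <- unrel
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via ape) with negative branch lengths
#' clamped to zero and the deficit moved to the sibling branch. For fewer
#' than 3 labels a degenerate tree is returned (2-leaf cherry preserving
#' the distance, or a single-leaf stub).
#'
#' @param dist Symmetric distance matrix with labels.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(dist) {
  labs <- rownames(dist)
  n <- length(labs)
  if (n < 2) {
    tree <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = labs,
                 edge.length = 0, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 tip.label = labs,
                 edge.length = rep(dist[1, 2] / 2, 2), Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(dist))
  # clamp negative branches, moving the deficit to the sibling edge
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent &
                   seq_len(nrow(tree$edge)) != e)
    if (length(sib))
      tree$edge.length[sib[1]] <- max(0, tree$edge.length[sib[1]] +
                                        deficit)
  }
  tree
}

#' Mean Protein Evolutionary Distance (MeaPED)
#'
#' 100 times the mean patristic (tree-path) distance over all unordered
#' pairs of in-scope leaves, divided by the median ungapped sequence
#' length of those leaves. The median of an even count is the mean of the
#' central pair.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param sequences Named character of (possibly aligned) sequences; gaps
#'   are stripped before lengths are taken.
#' @param scope_labels Leaf labels defining the scope (default: all).
#' @return MeaPED value, or `NA` when fewer than 2 scope leaves are in
#'   the tree.
#' @export
meaped <- function(tree, sequences, scope_labels = NULL) {
  labs <- tree$tip.label
  if (!is.null(scope_labels)) labs <- intersect(labs, scope_labels)
  labs <- intersect(labs, names(sequences))
  if (length(labs) < 2) return(NA_real_)
  pat <- stats::cophenetic(tree)[labs, labs, drop = FALSE]
  md <- mean(pat[upper.tri(pat)])
  lens <- nchar(gsub("-", "", sequences[labs]))
  100 * md / stats::median(lens)
}

# non-trivial bipartitions of an unrooted tree, as canonical strings
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character())
  tips <- sort(tree$tip.label)
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next  # trivial split
    below <- ape::extract.clade(tree, child)$tip.label
    side <- sort(below)
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (tips[1] %in% side) other else side
    out <- c(out, paste(sort(canon), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' trees. Trees with different leaf sets are first restricted to their
#' shared leaves.
#'
#' @param t1,t2 `phylo` trees.
#' @return Integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < length(t1$tip.label))
    t1 <- ape::keep.tip(t1, shared)
  if (length(shared) < length(t2$tip.label))
    t2 <- ape::keep.tip(t2, shared)
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Normalized Robinson-Foulds
#'
#' `mode = "observed"` (default): each value divided by the maximum of the
#' supplied collection (all zero when the maximum is 0).
#' `mode = "possible"`: divided by 2(n - 3) for n shared leaves.
#'
#' @param rf_values Numeric vector of RF distances.
#' @param mode `"observed"` or `"possible"`.
#' @param n Number of shared leaves (required for `"possible"`).
#' @return Numeric vector in [0, 1].
#' @export
nrf <- function(rf_values, mode = c("observed", "possible"), n = NULL) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    mx <- max(rf_values, 0)
    if (mx == 0) return(rep(0, length(rf_values)))
    return(rf_values / mx)
  }
  if (is.null(n)) stop("mode 'possible' needs the leaf count n")
  denom <- 2 * (n - 3)
  if (denom <= 0) return(rep(0, length(rf_values)))
  pmin(rf_values / denom, 1)
}

#' Proportion of shared edges between two trees
#'
#' Mean of the two directed ratios |shared non-trivial bipartitions| /
#' |non-trivial bipartitions of each tree|; a star tree (no non-trivial
#' edges) contributes 0 on its side.
#'
#' @param t1,t2 `phylo` trees (restricted to shared leaves first).
#' @return Value in [0, 1].
#' @export
shared_edges_proportion <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < length(t1$tip.label))
    t1 <- ape::keep.tip(t1, shared)
  if (length(shared) < length(t2$tip.label))
    t2 <- ape::keep.tip(t2, shared)
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  common <- length(intersect(b1, b2))
  r1 <- if (length(b1)) common / length(b1) else 0
  r2 <- if (length(b2)) common / length(b2) else 0
  mean(c(r1, r2))
}

#' Per-isoform evolutionary statistics
#'
#' For each gene/isoform, aligns the per-species representatives, builds a
#' neighbor-joining tree from Poisson-corrected p-distances, and computes
#' MeaPED, RF/nRF and Pedges against the reference species tree, per
#' taxonomic scope.
#'
#' @param catalog An `isoform_catalog`.
#' @param reference_tree Species tree (`phylo`).
#' @param scopes Named list of species vectors; default
#'   `list(All = <all species>)`.
#' @param params Alignment parameters.
#' @param nrf_mode Normalization mode for [nrf()].
#' @return data.frame(gene, isoform_id, scope, meaped, rf, nrf, pedges,
#'   n_taxa, median_length).
#' @export
evol_stats <- function(catalog, reference_tree, scopes = NULL,
                       params = align_params(),
                       nrf_mode = "observed") {
  reps <- catalog$representatives
  if (is.null(scopes))
    scopes <- list(All = reference_tree$tip.label)
  rows <- list()
  keys <- sort(unique(paste(reps$gene, reps$isoform_id, sep = "|")))
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rr <- reps[reps$gene == parts[1] & reps$isoform_id == parts[2], ,
               drop = FALSE]
    seqs <- stats::setNames(gsub("-", "", rr$seq), rr$species)
    seqs <- seqs[nzchar(seqs)]
    if (length(seqs) < 2) next
    msa <- progressive_msa(seqs, params)
    dd <- pdistance_matrix(msa, "poisson")
    tree <- nj_tree(dd)
    for (sc in names(scopes)) {
      labs <- intersect(scopes[[sc]], names(seqs))
      if (length(labs) < 2) next
      mp <- meaped(tree, msa$aln, labs)
      rfv <- pe <- NA_real_
      nt <- length(labs)
      if (nt >= 4) {
        sub <- ape::keep.tip(tree, labs)
        ref <- ape::keep.tip(reference_tree,
                             intersect(reference_tree$tip.label, labs))
        rfv <- robinson_foulds(sub, ref)
        pe <- shared_edges_proportion(sub, ref)
      }
      lens <- nchar(gsub("-", "", msa$aln[labs]))
      rows[[length(rows) + 1]] <- data.frame(
        gene = parts[1], isoform_id = parts[2], scope = sc, meaped = mp,
        rf = rfv, nrf = NA_real_, pedges = pe, n_taxa = nt,
        median_length = stats::median(lens), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  for (sc in unique(out$scope)) {
    sel <- out$scope == sc & !is.na(out$rf)
    if (any(sel)) out$nrf[sel] <- nrf(out$rf[sel], nrf_mode,
                                      n = max(out$n_taxa[sel]))
  }
  rownames(out) <- NULL
  out
}

#' Family-level summary of evolutionary statistics
#'
#' Per family x scope, arithmetic means of member-isoform MeaPED, nRF and
#' Pedges, with a Total row per scope; families below `min_isoforms`
#' member isoforms are dropped.
#'
#' @param records Output of [evol_stats()].
#' @param family_map Named vector gene -> family.
#' @param min_isoforms Minimum isoform count to keep a family.
#' @return data.frame(family, scope, n_isoforms, meaped, nrf, pedges).
#' @export
family_summary <- function(records, family_map, min_isoforms = 1) {
  records$family <- unname(family_map[records$gene])
  records$family[is.na(records$family)] <- "unassigned"
  agg <- function(d, fam) data.frame(
    family = fam, scope = d$scope[1], n_isoforms = nrow(d),
    meaped = mean(d$meaped, na.rm = TRUE),
    nrf = if (all(is.na(d$nrf))) NA_real_ else mean(d$nrf, na.rm = TRUE),
    pedges = if (all(is.na(d$pedges))) NA_real_ else
      mean(d$pedges, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out <- list()
  for (sc in unique(records$scope)) {
    rs <- records[records$scope == sc, , drop = FALSE]
    for (fam in sort(unique(rs$family))) {
      d <- rs[rs$family == fam, , drop = FALSE]
      if (nrow(d) < min_isoforms) next
      out[[length(out) + 1]] <- agg(d, fam)
    }
    out[[length(out) + 1]] <- agg(rs, "Total")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify duplicate-gene fates by MeaPED ratio
#'
#' Within a family, a gene pair whose MeaPED ratio (max/min) exceeds
#' `ratio_threshold` is a degradation/neofunctionalization candidate
#' ("divergent"); otherwise "similar" (subfunctionalization candidate).
#' A zero denominator with nonzero numerator is divergent; both zero is
#' similar.
#'
#' @param meaped_by_gene Named numeric of per-gene MeaPED within one
#'   family.
#' @param ratio_threshold Ratio above which a pair is divergent.
#' @return data.frame(gene1, gene2, ratio, fate).
#' @export
classify_duplicate_fates <- function(meaped_by_gene, ratio_threshold = 5) {
  genes <- names(meaped_by_gene)
  if (length(genes) < 2)
    return(data.frame(gene1 = character(), gene2 = character(),
                      ratio = numeric(), fate = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(length(genes) - 1)) {
    for (j in seq(i + 1, length(genes))) {
      a <- meaped_by_gene[[i]]; b <- meaped_by_gene[[j]]
      hi <- max(a, b); lo <- min(a, b)
      if (hi == 0 && lo == 0) { ratio <- 1; fate <- "similar" }
      else if (lo == 0) { ratio <- Inf; fate <- "divergent" }
      else {
        ratio <- hi / lo
        fate <- if (ratio > ratio_threshold) "divergent" else "similar"
      }
      out[[length(out) + 1]] <- data.frame(
        gene1 = genes[i], gene2 = genes[j], ratio = ratio, fate = fate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
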