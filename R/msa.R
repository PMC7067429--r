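# Progressive multiple sequence alignment and the gap-run recovery
# classification (Exact / Close / Partial / Missed) with the
# Table-1/2/3-shaped tabulations.

.kmer_set <- function(seq, k = 3) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# k-mer dissimilarity used for the guide tree
.kmer_dist <- function(seqs, k = 3) {
  n <- length(seqs)
  sets <- lapply(seqs, .kmer_set, k = k)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
    }
  }
  d
}

.profile_of <- function(aln_rows, alphabet) {
  alpha <- strsplit(alphabet, "")[[1]]
  mat <- do.call(rbind, strsplit(unname(aln_rows), ""))
  prof <- matrix(0, nrow = length(alpha), ncol = ncol(mat))
  for (col in seq_len(ncol(mat)))
    prof[, col] <- as.integer(table(factor(mat[, col], levels = alpha)))
  prof
}

.apply_cols <- function(rows, cols) {
  # cols: per output column, source column index (0 = gap)
  vapply(rows, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(ifelse(cols == 0, "-", ch[pmax(cols, 1)]), collapse = "")
  }, character(1))
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from k-mer (k = 3) dissimilarity and neighbor joining;
#' profiles merged by affine-gap profile-profile dynamic programming with
#' sum-of-pairs BLOSUM62 scoring. Deterministic for a fixed input order.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param params Alignment parameters.
#' @param k Guide-tree k-mer size.
#' @return An object of class `msa`: list(aln = named character of equal
#'   length, n_columns).
#' @export
progressive_msa <- function(seqs, params = align_params(), k = 3) {
  if (!length(seqs)) stop("progressive_msa needs at least one sequence")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence labels")
  alphabet <- .matrix_alphabet(params$matrix)
  if (length(seqs) == 1) {
    out <- list(aln = seqs, n_columns = nchar(seqs[[1]]))
    class(out) <- "msa"
    return(out)
  }
  merge_two <- function(rowsA, rowsB) {
    pa <- .profile_of(rowsA, alphabet)
    pb <- .profile_of(rowsB, alphabet)
    r <- cpp_profile_align(pa, pb, params$matrix, alphabet,
                           length(rowsA), length(rowsB),
                           params$gap_open, params$gap_extend)
    c(.apply_cols(rowsA, r$a_cols), .apply_cols(rowsB, r$b_cols))
  }
  if (length(seqs) == 2) {
    aln <- merge_two(seqs[1], seqs[2])
  } else {
    d <- .kmer_dist(seqs, k)
    guide <- ape::nj(stats::as.dist(d))
    guide <- ape::root(guide, outgroup = guide$tip.label[1],
                       resolve.root = TRUE)
    align_node <- function(node) {
      ntip <- length(guide$tip.label)
      if (node <= ntip) return(seqs[guide$tip.label[node]])
      children <- guide$edge[guide$edge[, 1] == node, 2]
      sub <- lapply(children, align_node)
      rows <- sub[[1]]
      for (i in seq_along(sub)[-1]) rows <- merge_two(rows, sub[[i]])
      rows
    }
    aln <- align_node(length(guide$tip.label) + 1)
    aln <- aln[names(seqs)]  # restore input order
  }
  out <- list(aln = aln, n_columns = nchar(aln[[1]]))
  class(out) <- "msa"
  out
}

#' Longest gap run in one alignment row
#'
#' All runs count, including terminal ones (terminal truncations are
#' incomplete recovery).
#'
#' @param msa An `msa` object (or named character of aligned rows).
#' @param label Row label.
#' @return Integer, the longest run of `-`.
#' @export
max_gap_run <- function(msa, label) {
  rows <- if (inherits(msa, "msa")) msa$aln else msa
  if (!label %in% names(rows)) stop("no such row: ", label)
  runs <- regmatches(rows[[label]], gregexpr("-+", rows[[label]]))[[1]]
  if (!length(runs)) 0L else max(nchar(runs))
}

#' Classify recovery of one sequence from its alignment row
#'
#' Absent sequences are Missed; an ungapped row is Exact; a longest gap
#' run of 1-4 is Close; 5 or more is Partial.
#'
#' @param msa An `msa` object or named character of rows; may be `NULL`
#'   when `absent = TRUE`.
#' @param label Row label.
#' @param absent Set `TRUE` for sequences with no prediction.
#' @return list(label, class, max_gap_run).
#' @export
classify_recovery <- function(msa, label, absent = FALSE) {
  if (absent || is.null(msa) ||
      !(label %in% names(if (inherits(msa, "msa")) msa$aln else msa)))
    return(list(label = label, class = "Missed",
                max_gap_run = NA_integer_))
  run <- max_gap_run(msa, label)
  cls <- if (run == 0) "Exact" else if (run <= 4) "Close" else "Partial"
  list(label = label, class = cls, max_gap_run = run)
}

#' Compare predictions from two assemblies
#'
#' Per isoform: both absent is MissingBoth, one absent MissingSp1/Sp2;
#' both present are pairwise-aligned -- identical without gaps is
#' Identity, substitutions only is Variant, gap columns yield
#' GapBoth/GapSp1/GapSp2 by which row(s) carry gaps.
#'
#' @param preds_sp1,preds_sp2 Named character vectors of predicted
#'   sequences by isoform key (`""`/missing = absent).
#' @param params Alignment parameters.
#' @return data.frame(isoform, category).
#' @export
compare_assemblies <- function(preds_sp1, preds_sp2,
                               params = align_params()) {
  keys <- sort(union(names(preds_sp1), names(preds_sp2)))
  cat_of <- function(key) {
    s1 <- if (key %in% names(preds_sp1)) preds_sp1[[key]] else ""
    s2 <- if (key %in% names(preds_sp2)) preds_sp2[[key]] else ""
    if (!nzchar(s1) && !nzchar(s2)) return("MissingBoth")
    if (!nzchar(s1)) return("MissingSp1")
    if (!nzchar(s2)) return("MissingSp2")
    ga <- global_align_protein(s1, s2, params)
    r1 <- strsplit(ga$a_aln, "")[[1]]
    r2 <- strsplit(ga$b_aln, "")[[1]]
    g1 <- any(r1 == "-"); g2 <- any(r2 == "-")
    if (g1 && g2) return("GapBoth")
    if (g1) return("GapSp1")
    if (g2) return("GapSp2")
    if (identical(s1, s2)) "Identity" else "Variant"
  }
  data.frame(isoform = keys,
             category = vapply(keys, cat_of, character(1)),
             stringsAsFactors = FALSE)
}

#' Tabulate recovery calls
#'
#' `style = "by_assembly"` (Table-1 shape): per assembly, counts of
#' Exact/Close/Partial/Missed over isoforms, plus row totals.
#' `style = "by_isoform"` (Table-3 shape): per isoform, the number of
#' assemblies in which it was completely (Exact or Close), partially, or
#' not recovered, plus the bucketed histogram over isoforms
#' (complete 3+/2/1/0; missing 0/1-2/3+).
#'
#' @param calls data.frame with columns `assembly_id`, `isoform`
#'   (gene|isoform key) and `class`.
#' @param style `"by_assembly"` or `"by_isoform"`.
#' @return A data.frame; for `"by_isoform"` a list(per_isoform, buckets).
#' @export
tabulate_recovery <- function(calls,
                              style = c("by_assembly", "by_isoform")) {
  style <- match.arg(style)
  lv <- c("Exact", "Close", "Partial", "Missed")
  if (style == "by_assembly") {
    tab <- table(calls$assembly_id, factor(calls$class, levels = lv))
    out <- data.frame(assembly_id = rownames(tab),
                      E = as.integer(tab[, "Exact"]),
                      C = as.integer(tab[, "Close"]),
                      P = as.integer(tab[, "Partial"]),
                      M = as.integer(tab[, "Missed"]),
                      stringsAsFactors = FALSE)
    out$total <- out$E + out$C + out$P + out$M
    rownames(out) <- NULL
    return(out)
  }
  per <- lapply(split(calls, calls$isoform), function(d) {
    data.frame(isoform = d$isoform[1],
               complete = sum(d$class %in% c("Exact", "Close")),
               partial = sum(d$class == "Partial"),
               missing = sum(d$class == "Missed"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  bucket_c <- function(x) ifelse(x >= 3, "3+", as.character(x))
  bucket_m <- function(x) ifelse(x >= 3, "3+",
                                 ifelse(x >= 1, "1-2", "0"))
  buckets <- stats::aggregate(
    list(n = per$isoform),
    by = list(complete = bucket_c(per$complete),
              partial = bucket_c(per$partial),
              missing = bucket_m(per$missing)),
    FUN = length)
  list(per_isoform = per, buckets = buckets)
}

#' Recovery calls for a catalog over its assemblies
#'
#' For each gene/isoform, aligns all non-absent predictions across
#' assemblies (per-isoform MSA) and classifies every assembly row by its
#' gap runs; assemblies without a prediction for that isoform are Missed.
#'
#' @param catalog An `isoform_catalog`.
#' @param assembly_ids Assemblies to classify (default: all in the
#'   catalog metadata).
#' @param params Alignment parameters.
#' @return data.frame(assembly_id, species, gene, isoform_id, isoform
#'   (key), class, max_gap_run).
#' @export
catalog_recovery_calls <- function(catalog, assembly_ids = NULL,
                                   params = align_params()) {
  meta <- catalog$assemblies_meta
  if (is.null(assembly_ids)) assembly_ids <- sort(meta$assembly_id)
  ent <- catalog$entries
  out <- list()
  for (key in sort(unique(paste(ent$gene, ent$isoform_id, sep = "|")))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rows <- ent[ent$gene == parts[1] & ent$isoform_id == parts[2], ,
                drop = FALSE]
    # one row per assembly: the best candidate within that assembly
    rows <- do.call(rbind, lapply(split(rows, rows$assembly_id),
                                  select_representative))
    seqs <- stats::setNames(gsub("-", "", rows$seq), rows$assembly_id)
    seqs <- seqs[nzchar(seqs)]
    msa <- if (length(seqs)) progressive_msa(seqs, params) else NULL
    for (aid in assembly_ids) {
      cl <- classify_recovery(msa, aid, absent = !(aid %in% names(seqs)))
      out[[length(out) + 1]] <- data.frame(
        assembly_id = aid,
        species = meta$species[match(aid, meta$assembly_id)],
        gene = parts[1], isoform_id = parts[2], isoform = key,
        class = cl$class, max_gap_run = cl$max_gap_run,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
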