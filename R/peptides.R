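# Rule-based signal-peptide and cleavage-site prediction, and derivation
# of peptide products. These stages are transparent rule-based predictors
# (the rule that fired is recorded); they are not trained models.

#' Predict a signal peptide (rule-based)
#'
#' Scans candidate cleavage positions 10-40 and requires the classic
#' tripartite architecture: at least one K/R in the first 5 residues
#' (n-region), a hydrophobic stretch of >= 6 residues from {AILMFVW}
#' (h-region), and small residues {A,G,S,C,T} at the -3 and -1 positions
#' of the candidate cut (c-region). The highest-scoring window wins;
#' proteins shorter than 15 aa are never called.
#'
#' @param protein Protein string.
#' @return list(present, cleavage_pos (0-based position after the last
#'   signal residue), score).
#' @export
predict_signal_peptide <- function(protein) {
  n <- nchar(protein)
  if (n < 15) return(list(present = FALSE, cleavage_pos = NA_integer_,
                          score = 0))
  res <- strsplit(protein, "")[[1]]
  small <- c("A", "G", "S", "C", "T")
  hydro <- c("A", "I", "L", "M", "F", "V", "W")
  n_basic <- sum(res[1:5] %in% c("K", "R"))
  if (n_basic == 0) return(list(present = FALSE,
                                cleavage_pos = NA_integer_, score = 0))
  # longest hydrophobic run within a prefix
  hydro_run_before <- function(pos) {
    runs <- rle(res[seq_len(pos)] %in% hydro)
    mx <- 0
    if (any(runs$values)) mx <- max(runs$lengths[runs$values])
    mx
  }
  best <- NULL
  for (cut in 10:min(40, n - 1)) {
    if (!(res[cut - 2] %in% small && res[cut] %in% small)) next
    hr <- hydro_run_before(cut)
    if (hr < 6) next
    score <- hr + 2 * sum(res[c(cut - 2, cut)] %in% small) + n_basic
    if (is.null(best) || score > best$score)
      best <- list(present = TRUE, cleavage_pos = cut, score = score)
  }
  if (is.null(best)) list(present = FALSE, cleavage_pos = NA_integer_,
                          score = 0) else best
}

#' Predict prohormone convertase cleavage sites (known-motif rules)
#'
#' Default rules: dibasic KR, RR, KK, RK cut after the second basic;
#' monobasic R cuts when another basic occupies the -3, -5 or -7 position.
#' Sites immediately followed by P are suppressed, as are sites inside
#' the signal peptide.
#'
#' @param protein Protein string.
#' @param signal Optional result of [predict_signal_peptide()]; sites at
#'   or before its cleavage position are suppressed.
#' @return data.frame(pos (0-based index of the residue C-terminal to the
#'   cut), motif).
#' @export
predict_cleavage_sites <- function(protein, signal = NULL) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  basic <- res %in% c("K", "R")
  sig_end <- if (!is.null(signal) && isTRUE(signal$present))
    signal$cleavage_pos else 0L
  sites <- list()
  add <- function(pos, motif) {
    if (pos >= n) return()           # cut at the C-terminus: no site
    if (pos < n && res[pos + 1] == "P") return()  # proline suppression
    if (pos <= sig_end) return()     # inside the signal peptide
    sites[[length(sites) + 1]] <<- data.frame(pos = pos, motif = motif,
                                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1)) {
    pair <- paste0(res[i], res[i + 1])
    if (pair %in% c("KR", "RR", "KK", "RK")) add(i + 1L, pair)
  }
  dib_pos <- vapply(sites, function(s) s$pos, numeric(1))
  for (i in which(res == "R")) {
    if ((i + 0L) %in% dib_pos) next
    prev <- i - c(2, 4, 6)           # 1-based indices of -3, -5, -7
    prev <- prev[prev >= 1]
    if (any(basic[prev])) add(i + 0L, "monobasic-R")
  }
  if (!length(sites))
    return(data.frame(pos = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, sites)
  out <- out[!duplicated(out$pos), , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive peptide products from a prohormone
#'
#' Splits the mature protein (after the signal cut) at the predicted
#' cleavage sites, trims C-terminal basic residues from each product, and
#' flags potential amidation (product ending in G after basic trimming).
#' Segments shorter than 2 aa are retained in the table but marked
#' `kept = FALSE`; concatenating all segments with their trimmed basics
#' plus the signal peptide reconstructs the input exactly.
#'
#' @param protein Protein string.
#' @param signal Result of [predict_signal_peptide()] (or `NULL`).
#' @param sites Result of [predict_cleavage_sites()] (or `NULL` to
#'   predict here).
#' @return data.frame(start, end (0-based half-open on the input), seq,
#'   trimmed_basics, motif, potential_amide, kept).
#' @export
derive_peptides <- function(protein, signal = NULL, sites = NULL) {
  if (is.null(signal)) signal <- predict_signal_peptide(protein)
  if (is.null(sites)) sites <- predict_cleavage_sites(protein, signal)
  n <- nchar(protein)
  sig_end <- if (isTRUE(signal$present)) signal$cleavage_pos else 0L
  bounds <- sort(unique(c(sig_end, sites$pos, n)))
  bounds <- bounds[bounds >= sig_end]
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    s <- bounds[k]; e <- bounds[k + 1]
    seg <- substr(protein, s + 1, e)
    core <- sub("[KR]+$", "", seg)
    trimmed <- substring(seg, nchar(core) + 1)
    amide <- nchar(core) > 0 && substring(core, nchar(core)) == "G"
    motif <- if (k < length(bounds) - 1)
      sites$motif[match(e, sites$pos)] else ""
    out[[length(out) + 1]] <- data.frame(
      start = s, end = e, seq = core, trimmed_basics = trimmed,
      motif = ifelse(is.na(motif), "", motif),
      potential_amide = amide, kept = nchar(core) >= 2,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      seq = character(), trimmed_basics = character(),
                      motif = character(), potential_amide = logical(),
                      kept = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
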