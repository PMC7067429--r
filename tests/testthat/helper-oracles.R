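# Independent reference implementations used as oracles. These mirror the
# documented scoring semantics in plain R, written separately from the
# compiled kernels they check.

# classic Gotoh affine alignment score (local or global); gap of length k
# costs gap_open + k * gap_ext
r_affine_score <- function(a, b, mat = blosum62(), gap_open = 11,
                           gap_ext = 1, local = TRUE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  go <- gap_open + gap_ext
  M <- matrix(NEG, m + 1, n + 1)
  Ia <- matrix(NEG, m + 1, n + 1)
  Ib <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    for (i in 2:(m + 1)) Ia[i, 1] <- -(gap_open + (i - 1) * gap_ext)
    for (j in 2:(n + 1)) Ib[1, j] <- -(gap_open + (j - 1) * gap_ext)
  }
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      d <- max(M[i - 1, j - 1], Ia[i - 1, j - 1], Ib[i - 1, j - 1]) + s
      M[i, j] <- if (local) max(0, d) else d
      Ia[i, j] <- max(M[i - 1, j] - go, Ia[i - 1, j] - gap_ext,
                      Ib[i - 1, j] - go)
      Ib[i, j] <- max(M[i, j - 1] - go, Ib[i, j - 1] - gap_ext,
                      Ia[i, j - 1] - go)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[m + 1, n + 1], Ia[m + 1, n + 1],
                           Ib[m + 1, n + 1])
}

# frameshift-aware protein-to-DNA score, mirroring the documented state
# semantics: codon advance, 1-2 nt slips (penalty fs), affine query/codon
# gaps, stop penalty, query-global with free on-grid DNA flanks
r_frameshift_score <- function(q, dna, mat = blosum62(), gap_open = 11,
                               gap_ext = 1, fs = 15, stop_pen = 10) {
  Q <- strsplit(q, "")[[1]]
  m <- length(Q); n <- nchar(dna)
  if (m == 0 || n < 3) return(0)
  go <- gap_open + gap_ext
  NEG <- -1e9
  aa_at <- rep(NA_character_, n)
  for (j in 3:n)
    aa_at[j] <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, j - 2, j)),
      no.init.codon = TRUE))
  M <- matrix(NEG, m + 1, n + 1)
  Iq <- matrix(NEG, m + 1, n + 1)
  Id <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1:m) {
    for (j in 0:n) {
      Iq[i + 1, j + 1] <- max(M[i, j + 1] - go, Iq[i, j + 1] - gap_ext,
                              Id[i, j + 1] - go)
      if (j < 3) next
      aa <- aa_at[j]
      s <- if (aa == "*") -stop_pen else mat[Q[i], aa]
      fresh <- (if (i == 1) 0 else -(gap_open + (i - 1) * gap_ext)) -
        (if ((j - 3) %% 3 != 0) fs else 0)
      cand <- fresh
      for (k in 0:2) {
        jj <- j - 3 - k
        if (jj < 0) next
        pen <- if (k == 0) 0 else fs
        cand <- max(cand, M[i, jj + 1] - pen, Iq[i, jj + 1] - pen,
                    Id[i, jj + 1] - pen)
      }
      M[i + 1, j + 1] <- cand + s
      dv <- max(M[i + 1, j - 2] - go, Id[i + 1, j - 2] - gap_ext,
                Iq[i + 1, j - 2] - go)
      if (aa == "*" && dv > NEG / 2) dv <- dv - stop_pen
      Id[i + 1, j + 1] <- dv
      total <- M[i + 1, j + 1] -
        (if (i < m) gap_open + (m - i) * gap_ext else 0)
      if (total > best) best <- total
    }
  }
  best
}

# non-trivial bipartitions by direct recursion over the edge matrix
r_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character())
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  tips <- sort(tree$tip.label)
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- sort(below(child))
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (tips[1] %in% side) other else side
    out <- c(out, paste(sort(canon), collapse = "|"))
  }
  unique(out)
}

r_rf <- function(t1, t2) {
  b1 <- r_bipartitions(t1); b2 <- r_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# random protein over the 20-residue alphabet
r_random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
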