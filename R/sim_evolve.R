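# Protein evolution along the species tree, reverse translation, and
# tandem duplication. The substitution model is deliberately simple: along
# a branch of length t each site substitutes independently with probability
# 1 - exp(-rate * t), the replacement drawn uniformly from the 19 other
# residues. This gives closed-form expectations used by the test oracles.

#' Generate a random root protein
#'
#' Starts with `M` followed by residues drawn uniformly from the 20-letter
#' alphabet.
#'
#' @param length Protein length (>= 2).
#' @return A protein string.
#' @export
random_protein <- function(length) {
  stopifnot(length >= 2)
  paste0("M", paste(sample(AA20, length - 1, replace = TRUE), collapse = ""))
}

#' Evolve a protein down a species tree
#'
#' Indel-free site-wise substitution: along each branch of length t, each
#' site substitutes with probability `1 - exp(-rate * t)`, replacement
#' uniform over the 19 other residues.
#'
#' @param root_seq Root protein over the 20-residue alphabet.
#' @param tree A `phylo` species tree.
#' @param rate Expected substitutions/site along a unit branch (>= 0).
#' @param seed Integer seed.
#' @return Named character vector of leaf proteins.
#' @export
evolve_protein <- function(root_seq, tree, rate, seed) {
  stopifnot(rate >= 0)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", root_seq))
    stop("root_seq must use the 20-residue alphabet")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(root_seq, "")[[1]]
  # preorder: ape edge matrix rows are usable in order after reorder()
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    t_br <- tr$edge.length[k]
    s <- seqs[[par]]
    p <- 1 - exp(-rate * t_br)
    hit <- which(stats::runif(length(s)) < p)
    if (length(hit)) {
      for (i in hit) {
        s[i] <- sample(setdiff(AA20, s[i]), 1)
      }
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}

# codon table: residue -> codons (derived from the standard genetic code)
.codon_table <- function() {
  if (is.null(.pkg_env$CODONS)) {
    b <- c("A", "C", "G", "T")
    cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
    aas <- vapply(cods, translate_dna, character(1))
    .pkg_env$CODONS <- split(cods, aas)
  }
  .pkg_env$CODONS
}

#' Reverse-translate a protein to a CDS
#'
#' Codons are chosen uniformly among synonymous codons; a stop codon
#' (TAA/TAG/TGA, uniform) is appended, so the result has length
#' `3 * nchar(protein) + 3`.
#'
#' @param protein Protein string without `*`.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
reverse_translate <- function(protein, seed = NULL) {
  if (grepl("[*]", protein)) stop("protein must not contain '*'")
  res <- strsplit(protein, "")[[1]]
  if (!all(res %in% AA20)) stop("residue outside the 20-letter alphabet")
  if (!is.null(seed)) set.seed(seed)
  tab <- .codon_table()
  cods <- vapply(res, function(a) {
    cc <- tab[[a]]
    if (length(cc) == 1) cc else sample(cc, 1)
  }, character(1))
  stop_cod <- sample(c("TAA", "TAG", "TGA"), 1)
  paste0(paste(cods, collapse = ""), stop_cod)
}

#' Translate DNA (first forward frame)
#'
#' Standard genetic code; stops render `*`; codons containing non-ACGT
#' characters render `X`; the trailing partial codon is dropped.
#'
#' @param dna DNA string.
#' @return Protein string.
#' @export
translate_dna <- function(dna) cpp_translate(dna)

#' Reverse complement
#'
#' @param dna DNA string (non-ACGT characters become `N`).
#' @return Reverse-complemented DNA string.
#' @export
revcomp <- function(dna) cpp_revcomp(dna)

#' Inject a tandem duplication into a gene set
#'
#' The gene is replaced by `n_copies` copies named `<gene>A`, `<gene>B`, ...
#' Each copy's root sequence is diverged from the original by
#' [evolve_protein()] on a star tree of branch length `divergence_scale`,
#' and each copy draws an independent rate multiplier in [1/2, 2]
#' (log-uniform).
#'
#' @param genes data.frame with columns `gene`, `family`, `seq`, `rate`.
#' @param gene Name of the gene to duplicate.
#' @param n_copies Number of copies (>= 1; 1 leaves the set unchanged).
#' @param divergence_scale Star branch length for copy divergence.
#' @param seed Integer seed.
#' @return The modified gene set data.frame.
#' @export
inject_duplication <- function(genes, gene, n_copies, divergence_scale,
                               seed) {
  stopifnot(gene %in% genes$gene, n_copies >= 1)
  if (n_copies == 1) return(genes)
  row <- genes[genes$gene == gene, ]
  set.seed(seed)
  mult <- 2^stats::runif(n_copies, -1, 1)
  copies <- lapply(seq_len(n_copies), function(k) {
    seq_k <- if (divergence_scale > 0) {
      star <- ape::read.tree(text = sprintf("(a:%g,b:%g,c:%g);",
                                            divergence_scale,
                                            divergence_scale,
                                            divergence_scale))
      s <- evolve_protein(row$seq, star, rate = 1, seed = seed + k)[["a"]]
      substr(s, 1, 1) <- "M"  # copies keep their start codon
      s
    } else row$seq
    data.frame(gene = paste0(gene, LETTERS[k]), family = row$family,
               seq = seq_k, rate = row$rate * mult[k],
               stringsAsFactors = FALSE)
  })
  rbind(genes[genes$gene != gene, ], do.call(rbind, copies))
}
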