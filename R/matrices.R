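# Scoring matrices and shared alignment parameter defaults.

.pkg_env <- new.env(parent = emptyenv())

#' BLOSUM62 protein scoring matrix
#'
#' Returns the BLOSUM62 substitution matrix (from Biostrings), the default
#' scoring matrix for all protein alignment stages.
#'
#' @return Integer matrix with residue dimnames (includes `X` and `*`).
#' @export
blosum62 <- function() {
  if (is.null(.pkg_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_env$BLOSUM62
}

#' Default alignment parameters
#'
#' BLAST-family conventions: BLOSUM62, gap open 11, gap extend 1 (a gap of
#' length k costs `gap_open + k * gap_extend`), frameshift penalty 15,
#' premature-stop penalty 10.
#'
#' @param gap_open Gap opening penalty (non-negative).
#' @param gap_extend Gap extension penalty (non-negative, `<= gap_open`).
#' @param frameshift Penalty for a 1-2 nt slip in protein-to-DNA alignment.
#' @param stop Penalty for aligning a query residue to a stop codon.
#' @param matrix Protein scoring matrix.
#' @return A list of alignment parameters.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1, frameshift = 15,
                         stop = 10, matrix = blosum62()) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  list(gap_open = gap_open, gap_extend = gap_extend, frameshift = frameshift,
       stop = stop, matrix = matrix)
}

# 20-residue alphabet used by the simulator
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

.matrix_alphabet <- function(mat) paste(rownames(mat), collapse = "")
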