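# Readers/writers for FASTA, Newick and tabular reports, plus the
# machine-readable header tags ("species=... gene=... isoform=...
# assembly=... type=...") carried in FASTA descriptions.

PROTEIN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file
#'
#' Parses a (multi-line) FASTA file via Biostrings. The first whitespace
#' token of each header is the record id; the remainder is the description,
#' which may carry `key=value` tags (see [parse_tags()]).
#'
#' @param path Path to the FASTA file.
#' @param moltype `"protein"` or `"dna"`; record sequences are validated
#'   against the corresponding alphabet (protein: the 20 residues plus `X`
#'   and `*`; dna: `ACGTN`).
#' @param allow_gaps Accept `-` characters (aligned FASTA).
#' @return A data.frame with columns `id`, `desc`, `seq`, `moltype`, one row
#'   per record in file order.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna"),
                       allow_gaps = FALSE) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), desc = character(),
                      seq = character(), moltype = character(),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- toupper(as.character(set))
  if (any(id == "")) stop("FASTA record with empty id in ", path)
  alpha <- if (moltype == "protein") PROTEIN_ALPHABET else DNA_ALPHABET
  if (allow_gaps) alpha <- c(alpha, "-")
  bad <- !grepl(paste0("^[", paste(gsub("\\*", "\\\\*", alpha),
                                   collapse = ""), "]*$"), seq)
  if (any(bad))
    stop("sequence(s) with characters outside the ", moltype,
         " alphabet: ", paste(utils::head(id[bad], 3), collapse = ", "))
  data.frame(id = id, desc = desc, seq = unname(seq), moltype = moltype,
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  desc <- if ("desc" %in% names(records)) records$desc else
    rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else
      records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    if (nchar(s) == 0) next
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Parse key=value tags from a FASTA description
#'
#' @param desc Description string with space-separated `key=value` tags.
#' @return Named character vector of tags (empty if none).
#' @export
parse_tags <- function(desc) {
  if (is.na(desc) || !nzchar(desc)) return(character())
  toks <- strsplit(desc, "\\s+")[[1]]
  kv <- toks[grepl("=", toks, fixed = TRUE)]
  if (!length(kv)) return(character())
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

#' Format tags into a FASTA description
#'
#' @param ... Named values (or a single named vector/list).
#' @return A single `key=value key=value ...` string.
#' @export
make_tags <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all tag values must be named")
  paste(paste0(names(x), "=", as.character(x)), collapse = " ")
}

#' Parse a Newick string into an ape phylo tree
#'
#' Unquoted labels only; internal node labels are ignored on read; missing
#' branch lengths default to 0.
#'
#' @param text Newick string.
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1)
    stop("text must be a single Newick string")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("Newick parse error: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read tree")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in Newick")
  if (any(tree$edge.length < 0)) stop("negative branch length in Newick")
  tree
}

#' Write a phylo tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when given the string is also written out.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a rectangular table as a TSV report
#'
#' Tab-delimited, UTF-8, Unix newlines, rows in the given order. Coordinate
#' columns in pipeline reports are 0-based half-open; pass a `comment`
#' documenting this where applicable.
#'
#' @param table A data.frame (or matrix with column names).
#' @param path Output path.
#' @param comment Optional character vector written as leading `# ` lines.
#' @return Invisibly, `path`.
#' @export
write_report <- function(table, path, comment = NULL) {
  if (is.matrix(table)) table <- as.data.frame(table)
  if (!is.data.frame(table)) {
    if (is.list(table)) {
      lens <- lengths(table)
      if (length(unique(lens)) > 1) stop("ragged rows in report table")
      table <- as.data.frame(do.call(rbind, table))
    } else stop("table must be a data.frame, matrix or list of rows")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  lines <- c(paste(names(table), collapse = "\t"),
             if (nrow(table))
               do.call(paste, c(lapply(table, as.character), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
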