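# Homology-guided annotation: six-frame translated search of each query
# protein against each assembly, frameshift-aware protein-to-DNA
# prediction for genome hits, ORF extraction for transcript hits, and
# evidence merging across assemblies. All coordinates are 0-based
# half-open on the forward strand.

#' Six-frame translation
#'
#' @param dna DNA string over `ACGTN`.
#' @return Character vector of 6 protein strings in frame order
#'   `+0, +1, +2, -0, -1, -2` (reverse frames on the reverse complement).
#' @export
six_frame_translate <- function(dna) {
  rc <- revcomp(dna)
  fr <- function(s, f) {
    if (nchar(s) - f < 3) "" else cpp_translate(substring(s, f + 1))
  }
  c(fr(dna, 0), fr(dna, 1), fr(dna, 2), fr(rc, 0), fr(rc, 1), fr(rc, 2))
}

#' Local (Smith-Waterman) protein alignment with affine gaps
#'
#' A gap of length k costs `gap_open + k * gap_extend`; scores are floored
#' at 0. Coordinates are 0-based half-open.
#'
#' @param query,target Protein strings.
#' @param params Alignment parameters from [align_params()].
#' @return list(score, q_aln, t_aln, q_start, q_end, t_start, t_end).
#' @export
local_align_protein <- function(query, target, params = align_params()) {
  r <- cpp_pair_align(query, target, params$matrix,
                      .matrix_alphabet(params$matrix), params$gap_open,
                      params$gap_extend, TRUE)
  list(score = r$score, q_aln = r$a_aln, t_aln = r$b_aln,
       q_start = r$a_start, q_end = r$a_end,
       t_start = r$b_start, t_end = r$b_end)
}

#' Global (Needleman-Wunsch) protein alignment with affine gaps
#'
#' @inheritParams local_align_protein
#' @param a,b Protein strings.
#' @return list(score, a_aln, b_aln).
#' @export
global_align_protein <- function(a, b, params = align_params()) {
  r <- cpp_pair_align(a, b, params$matrix, .matrix_alphabet(params$matrix),
                      params$gap_open, params$gap_extend, FALSE)
  list(score = r$score, a_aln = r$a_aln, b_aln = r$b_aln)
}

#' Self-alignment score of a protein
#'
#' The score of aligning the sequence to itself without gaps; the default
#' search threshold is a fraction of this.
#'
#' @param seq Protein string.
#' @param matrix Scoring matrix.
#' @return Integer score.
#' @export
self_score <- function(seq, matrix = blosum62()) {
  res <- strsplit(seq, "")[[1]]
  sum(matrix[cbind(res, res)])
}

#' Search an assembly with a protein query
#'
#' Smith-Waterman of the query against all six frame translations of every
#' contig; hits at or above `min_score` are mapped back to forward-strand
#' nucleotide coordinates (0-based half-open). Overlapping hits on the same
#' contig are merged keeping the best, so surviving hits are disjoint loci.
#'
#' @param query Protein string.
#' @param records Assembly contig data.frame (`id`, `seq`).
#' @param min_score Score threshold; default 40 percent of the query
#'   self-score.
#' @param params Alignment parameters.
#' @return data.frame of hits sorted by descending score: `contig_id`,
#'   `start`, `end`, `strand`, `frame`, `score`, `q_start`, `q_end`.
#' @export
search_assembly <- function(query, records, min_score = NULL,
                            params = align_params()) {
  if (is.null(min_score)) min_score <- 0.4 * self_score(query,
                                                        params$matrix)
  hits <- list()
  for (i in seq_len(nrow(records))) {
    dna <- records$seq[i]
    L <- nchar(dna)
    rc <- revcomp(dna)
    for (fi in 0:5) {
      strand <- if (fi < 3) "+" else "-"
      f <- fi %% 3
      s <- if (strand == "+") dna else rc
      if (nchar(s) - f < 3) next
      prot <- cpp_translate(substring(s, f + 1))
      if (nchar(prot) < 3) next
      r <- cpp_pair_align(query, prot, params$matrix,
                          .matrix_alphabet(params$matrix),
                          params$gap_open, params$gap_extend, TRUE)
      if (r$score < min_score) next
      if (strand == "+") {
        nt_start <- f + 3 * r$b_start
        nt_end <- f + 3 * r$b_end
      } else {
        nt_start <- L - (f + 3 * r$b_end)
        nt_end <- L - (f + 3 * r$b_start)
      }
      hits[[length(hits) + 1]] <- data.frame(
        contig_id = records$id[i], start = nt_start, end = nt_end,
        strand = strand, frame = f, score = r$score,
        q_start = r$a_start, q_end = r$a_end, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), score = numeric(),
                      q_start = integer(), q_end = integer(),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$contig_id, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      for (j in seq(i + 1, nrow(h))) {
        if (!keep[j]) next
        if (h$contig_id[j] == h$contig_id[i] &&
            h$start[j] < h$end[i] && h$end[j] > h$start[i])
          keep[j] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Frameshift-aware protein-to-DNA alignment
#'
#' GeneWise-style dynamic program over (query position x nucleotide
#' position) allowing codon advances, 1-2 nt slips (penalty
#' `params$frameshift`, recorded as frameshifts), query/codon gaps (affine)
#' and stop codons (penalty `params$stop`, retained in the prediction as
#' `*` and flagged, not truncated).
#'
#' @param query Protein string.
#' @param dna_region Forward-oriented DNA region containing the putative
#'   gene (already reverse-complemented for minus-strand hits).
#' @param params Alignment parameters.
#' @return list with `seq` (predicted protein; internal uncovered query
#'   positions rendered as `X` placeholders), `raw_seq` (as emitted by the
#'   DP), `frameshifts` (0-based nt positions in `dna_region`),
#'   `premature_stops` (0-based query positions), `q_start`, `q_end`,
#'   `q_gaps`, `dna_start`, `dna_end`, `n_gaps` (uncovered query
#'   positions), `completeness`, `score`.
#' @export
align_protein_to_dna_frameshift <- function(query, dna_region,
                                            params = align_params()) {
  m <- nchar(query)
  if (nchar(dna_region) < 3 || m == 0)
    return(list(seq = "", raw_seq = "", frameshifts = integer(),
                premature_stops = integer(), q_start = 0L, q_end = 0L,
                q_gaps = integer(), dna_start = 0L, dna_end = 0L,
                n_gaps = m, completeness = "absent", score = 0))
  r <- cpp_frameshift_align(query, dna_region, params$matrix,
                            .matrix_alphabet(params$matrix),
                            params$gap_open, params$gap_extend,
                            params$frameshift, params$stop)
  if (r$score <= 0 || !nzchar(r$protein))
    return(list(seq = "", raw_seq = "", frameshifts = integer(),
                premature_stops = integer(), q_start = 0L, q_end = 0L,
                q_gaps = integer(), dna_start = 0L, dna_end = 0L,
                n_gaps = m, completeness = "absent", score = 0))
  # X-fill internal uncovered (gapped) query positions so that catalog
  # comparison can tell coverage gaps from real isoform differences
  p <- strsplit(r$p_aln, "")[[1]]
  q <- strsplit(r$q_aln, "")[[1]]
  filled <- p
  filled[p == "-" & q != "-"] <- "X"
  filled <- paste(filled[filled != "-"], collapse = "")
  n_gaps <- r$q_start + (m - r$q_end) + length(r$q_gaps)
  stops <- r$premature_stops[r$premature_stops >= 0]
  complete <- r$q_start == 0 && r$q_end == m && !length(r$q_gaps) &&
    !length(stops)
  list(seq = filled, raw_seq = r$protein, frameshifts = r$frameshifts,
       premature_stops = stops, q_start = r$q_start, q_end = r$q_end,
       q_gaps = r$q_gaps, dna_start = r$dna_start, dna_end = r$dna_end,
       n_gaps = n_gaps, completeness = if (complete) "complete" else
         "partial", score = r$score)
}

#' Extract the prohormone ORF from a transcript
#'
#' Finds the best-scoring frame for the query, expands the matched region
#' to the enclosing ORF (flanking stops), anchors the start at the
#' initiator M expected from the query alignment, and reports completeness:
#' complete iff an initiator M is present and the ORF ends at a stop codon
#' within the transcript.
#'
#' @param transcript Transcript DNA string (either orientation).
#' @param query Protein string.
#' @param min_score Minimum Smith-Waterman score (default 40 percent of
#'   query self-score).
#' @param params Alignment parameters.
#' @return list as in [align_protein_to_dna_frameshift()] (no frameshift
#'   fields populated).
#' @export
extract_orf_from_transcript <- function(transcript, query,
                                        min_score = NULL,
                                        params = align_params()) {
  m <- nchar(query)
  absent <- list(seq = "", frameshifts = integer(),
                 premature_stops = integer(), q_start = 0L, q_end = 0L,
                 q_gaps = integer(), n_gaps = m, completeness = "absent",
                 score = 0)
  if (is.null(min_score)) min_score <- 0.4 * self_score(query,
                                                        params$matrix)
  frames <- six_frame_translate(transcript)
  best <- NULL; best_fi <- 0
  for (fi in seq_along(frames)) {
    if (nchar(frames[fi]) < 3) next
    r <- cpp_pair_align(query, frames[fi], params$matrix,
                        .matrix_alphabet(params$matrix), params$gap_open,
                        params$gap_extend, TRUE)
    if (is.null(best) || r$score > best$score) { best <- r; best_fi <- fi }
  }
  if (is.null(best) || best$score < min_score) return(absent)
  prot <- strsplit(frames[best_fi], "")[[1]]
  t_start <- best$b_start; t_end <- best$b_end  # 0-based half-open
  # expand left to the previous stop, right to the next stop
  orf_start <- 0L
  p <- t_start - 1L
  while (p >= 0) {
    if (prot[p + 1] == "*") { orf_start <- p + 1L; break }
    p <- p - 1L
  }
  orf_end <- t_end
  has_stop <- FALSE
  while (orf_end < length(prot)) {
    if (prot[orf_end + 1] == "*") { has_stop <- TRUE; break }
    orf_end <- orf_end + 1
  }
  # anchor the start at the initiator M implied by the query alignment
  anchor <- t_start - best$a_start  # expected 0-based position of query[1]
  start_at <- NA_integer_
  has_m <- FALSE
  if (anchor >= orf_start && anchor >= 0 && anchor < length(prot) &&
      prot[anchor + 1] == "M") {
    start_at <- anchor; has_m <- TRUE
  } else {
    cand <- which(prot == "M") - 1L
    cand <- cand[cand >= orf_start & cand <= t_start]
    if (length(cand)) { start_at <- max(cand); has_m <- TRUE }
    else start_at <- max(orf_start, t_start)
  }
  pred <- paste(prot[(start_at + 1):orf_end], collapse = "")
  if (!nzchar(pred)) return(absent)
  # uncovered query positions via global alignment of prediction vs query
  ga <- global_align_protein(pred, query, params)
  qa <- strsplit(ga$b_aln, "")[[1]]; pa <- strsplit(ga$a_aln, "")[[1]]
  n_gaps <- sum(qa != "-" & pa == "-")
  complete <- has_m && has_stop
  list(seq = pred, frameshifts = integer(), premature_stops = integer(),
       q_start = best$a_start, q_end = best$a_end, q_gaps = integer(),
       n_gaps = n_gaps, completeness = if (complete) "complete" else
         "partial", score = best$score)
}

#' Merge prediction evidence for one species/gene/isoform
#'
#' Chooses the candidate with the fewest uncovered query positions; when
#' two candidates cover complementary regions (non-overlapping uncovered
#' regions) and agree exactly on at least `min_overlap` flanking residues,
#' they are spliced into a single merged prediction. Ties break by
#' assembly-type priority G > H > I > T, then lexicographic assembly id.
#'
#' @param candidates data.frame of prediction rows (columns `seq`,
#'   `q_start`, `q_end`, `n_gaps`, `assembly_type`, `assembly_id`,
#'   `completeness`, `evidence`).
#' @param min_overlap Minimum exact overlap for splicing.
#' @return A single prediction row (data.frame) with evidence possibly
#'   `"merged"`, or `NULL` for an empty candidate list.
#' @export
merge_evidence <- function(candidates, min_overlap = 10) {
  candidates <- candidates[nzchar(candidates$seq), , drop = FALSE]
  if (!nrow(candidates)) return(NULL)
  pri <- match(candidates$assembly_type, c("G", "H", "I", "T"))
  ord <- order(candidates$n_gaps, pri, candidates$assembly_id)
  best <- candidates[ord[1], , drop = FALSE]
  if (best$n_gaps == 0 || nrow(candidates) < 2) return(best)
  # try splicing a prefix-covering and a suffix-covering candidate
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(candidates))) {
      if (i == j) next
      A <- candidates[i, ]; B <- candidates[j, ]
      if (A$q_start > 0 || B$q_start <= A$q_start) next
      if (B$q_end <= A$q_end) next
      ov <- A$q_end - B$q_start
      if (ov < min_overlap) next
      offA <- B$q_start - A$q_start
      sA <- substr(A$seq, offA + 1, offA + ov)
      sB <- substr(B$seq, 1, ov)
      if (!identical(sA, sB) || !nzchar(sA)) next
      merged <- best
      merged$seq <- paste0(A$seq, substring(B$seq, ov + 1))
      merged$q_start <- A$q_start
      merged$q_end <- B$q_end
      merged$n_gaps <- 0L
      merged$completeness <- "complete"
      merged$evidence <- "merged"
      merged$assembly_id <- paste(A$assembly_id, B$assembly_id, sep = "+")
      return(merged)
    }
  }
  best
}

.empty_prediction <- function(species, assembly_id, type, gene) {
  data.frame(species = species, assembly_id = assembly_id,
             assembly_type = type, gene = gene, isoform_id = NA_character_,
             candidate = NA_character_, seq = "", q_start = 0L,
             q_end = 0L, n_gaps = NA_integer_, frameshifts = "",
             premature_stops = "", completeness = "absent",
             evidence = if (type == "T") "transcript" else "genome",
             score = 0, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, stringsAsFactors = FALSE)
}

#' Annotate one assembly with a query set
#'
#' Runs the search and prediction stages for every query against one
#' assembly. Genome-type assemblies use the frameshift-aware DP on the
#' best locus (secondary disjoint loci are retained in the hit table for
#' duplication screening); transcriptome assemblies extract an ORF from
#' every matching transcript, yielding one candidate per transcript.
#'
#' @param queries Query data.frame (`gene`, `seq`).
#' @param assembly list with `species`, `assembly_id`, `type`, `records`.
#' @param params Alignment parameters.
#' @param min_score_frac Search threshold as a fraction of query
#'   self-score.
#' @param margin Nucleotide margin added around genome hits before the
#'   frameshift DP.
#' @param min_score_abs Absolute score threshold overriding
#'   `min_score_frac` (used by the targeted rescue pass).
#' @return list(predictions = data.frame, hits = data.frame of disjoint
#'   loci per gene).
#' @export
annotate_assembly <- function(queries, assembly, params = align_params(),
                              min_score_frac = 0.4, margin = 45,
                              min_score_abs = NULL) {
  preds <- list(); all_hits <- list()
  recs <- assembly$records
  for (k in seq_len(nrow(queries))) {
    g <- queries$gene[k]; qseq <- queries$seq[k]
    ms <- if (!is.null(min_score_abs)) min_score_abs else
      min_score_frac * self_score(qseq, params$matrix)
    if (is.null(recs) || !nrow(recs)) {
      preds[[length(preds) + 1]] <- .empty_prediction(
        assembly$species, assembly$assembly_id, assembly$type, g)
      next
    }
    hits <- search_assembly(qseq, recs, min_score = ms, params = params)
    if (nrow(hits)) {
      hh <- hits
      hh$gene <- g
      hh$species <- assembly$species
      hh$assembly_id <- assembly$assembly_id
      hh$assembly_type <- assembly$type
      all_hits[[length(all_hits) + 1]] <- hh
    }
    if (!nrow(hits)) {
      preds[[length(preds) + 1]] <- .empty_prediction(
        assembly$species, assembly$assembly_id, assembly$type, g)
      next
    }
    if (assembly$type %in% c("G", "H", "I")) {
      # candidates: best locus per contig (contig breaks split a gene
      # across contigs; evidence merging can splice them back)
      cand_rows <- list()
      contigs <- unique(hits$contig_id)
      for (cid in contigs) {
        hit <- hits[hits$contig_id == cid, ][1, ]
        dna <- recs$seq[recs$id == cid]
        L <- nchar(dna)
        # keep the region codon-aligned to the hit frame on the side the
        # frameshift DP anchors its grid on (the region 5' end)
        if (hit$strand == "+") {
          lead <- min(margin, hit$start)
          lead <- lead - (lead %% 3)
          rs <- hit$start - lead
          re <- min(L, hit$end + margin)
        } else {
          lead <- min(margin, L - hit$end)
          lead <- lead - (lead %% 3)
          re <- hit$end + lead
          rs <- max(0, hit$start - margin)
        }
        region <- substr(dna, rs + 1, re)
        if (hit$strand == "-") region <- revcomp(region)
        fr <- align_protein_to_dna_frameshift(qseq, region, params)
        if (fr$completeness == "absent") next
        fs_fwd <- if (hit$strand == "+") rs + fr$frameshifts else
          rs + (nchar(region) - 1 - fr$frameshifts)
        cand_rows[[length(cand_rows) + 1]] <- data.frame(
          species = assembly$species, assembly_id = assembly$assembly_id,
          assembly_type = assembly$type, gene = g,
          isoform_id = NA_character_, candidate = cid, seq = fr$seq,
          q_start = fr$q_start, q_end = fr$q_end, n_gaps = fr$n_gaps,
          frameshifts = paste(fs_fwd, collapse = ","),
          premature_stops = paste(fr$premature_stops, collapse = ","),
          completeness = fr$completeness, evidence = "genome",
          score = fr$score, start = hit$start, end = hit$end,
          strand = hit$strand, stringsAsFactors = FALSE)
      }
      if (!length(cand_rows)) {
        preds[[length(preds) + 1]] <- .empty_prediction(
          assembly$species, assembly$assembly_id, assembly$type, g)
        next
      }
      cand <- do.call(rbind, cand_rows)
      merged <- merge_evidence(cand)
      preds[[length(preds) + 1]] <- merged
    } else {
      # transcriptome: one ORF candidate per matching transcript
      any_row <- FALSE
      for (cid in unique(hits$contig_id)) {
        dna <- recs$seq[recs$id == cid]
        orf <- extract_orf_from_transcript(dna, qseq, min_score = ms,
                                           params = params)
        if (orf$completeness == "absent") next
        any_row <- TRUE
        preds[[length(preds) + 1]] <- data.frame(
          species = assembly$species, assembly_id = assembly$assembly_id,
          assembly_type = assembly$type, gene = g,
          isoform_id = NA_character_, candidate = cid, seq = orf$seq,
          q_start = orf$q_start, q_end = orf$q_end, n_gaps = orf$n_gaps,
          frameshifts = "", premature_stops = "",
          completeness = orf$completeness, evidence = "transcript",
          score = orf$score,
          start = hits$start[hits$contig_id == cid][1],
          end = hits$end[hits$contig_id == cid][1],
          strand = hits$strand[hits$contig_id == cid][1],
          stringsAsFactors = FALSE)
      }
      if (!any_row)
        preds[[length(preds) + 1]] <- .empty_prediction(
          assembly$species, assembly$assembly_id, assembly$type, g)
    }
  }
  list(predictions = do.call(rbind, preds),
       hits = if (length(all_hits)) do.call(rbind, all_hits) else NULL)
}

#' Annotate a set of assemblies
#'
#' After the first pass with the reference queries, genes that remained
#' undetected in some assemblies are re-searched using the best complete
#' predictions recovered from the other species as queries (`rescue`);
#' distant reference queries often miss fast-evolving genes that a close
#' relative's sequence finds.
#'
#' @param queries Query data.frame (`gene`, `seq`).
#' @param assemblies Named list of assemblies (as in `sim_clade`).
#' @param params Alignment parameters.
#' @param rescue Run the cross-species rescue pass.
#' @param max_donors Donor sequences tried per absent gene/assembly.
#' @param min_score_frac First-pass search threshold (fraction of query
#'   self-score).
#' @param rescue_min_score Absolute score floor for the targeted rescue
#'   pass (a raw score of 60 corresponds to roughly E < 0.01 at this
#'   search-space size). Rescue candidates must additionally cover at
#'   least `rescue_min_coverage` of the query and be reciprocal best
#'   hits: the rescued protein, aligned back against the whole reference
#'   query set, must match its own gene best — together these keep the
#'   permissive floor from admitting cross-gene or decoy matches.
#' @param rescue_min_coverage Minimum fraction of the rescue query that
#'   the accepted alignment must span.
#' @param margin Nucleotide margin around genome hits.
#' @return list(predictions, hits) combined across assemblies.
#' @export
annotate_assemblies <- function(queries, assemblies,
                                params = align_params(), rescue = TRUE,
                                max_donors = 3, min_score_frac = 0.4,
                                rescue_min_score = 60,
                                rescue_min_coverage = 0.4, margin = 45) {
  preds <- list(); hits <- list()
  for (a in assemblies) {
    r <- annotate_assembly(queries, a, params,
                           min_score_frac = min_score_frac,
                           margin = margin)
    preds[[length(preds) + 1]] <- r$predictions
    if (!is.null(r$hits)) hits[[length(hits) + 1]] <- r$hits
  }
  preds <- do.call(rbind, preds)
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  if (rescue && !is.null(preds)) {
    names(assemblies) <- vapply(assemblies, `[[`, character(1),
                                "assembly_id")
    # iterate: a sequence rescued in one species can be the donor that
    # finds the gene in its neighbor on the next round
    for (round in 1:4) {
      changed <- FALSE
      for (g in unique(preds$gene)) {
      rows <- preds[preds$gene == g, , drop = FALSE]
      absent_ids <- unique(rows$assembly_id[!nzchar(rows$seq)])
      donors <- rows[nzchar(rows$seq) &
                       rows$completeness == "complete", , drop = FALSE]
      if (!length(absent_ids)) next
      donors <- donors[order(-donors$score), , drop = FALSE]
      donors <- donors[!duplicated(donors$species), , drop = FALSE]
      donors <- donors[seq_len(min(max_donors, nrow(donors))), ,
                       drop = FALSE]
      donor_seqs <- c(gsub("[X*]", "", donors$seq),
                      queries$seq[match(g, queries$gene)])
      donor_aids <- c(donors$assembly_id, "")
      for (aid in absent_ids) {
        a <- assemblies[[aid]]
        for (d in seq_along(donor_seqs)) {
          if (donor_aids[d] == aid) next
          q2 <- data.frame(gene = g, seq = donor_seqs[d],
                           stringsAsFactors = FALSE)
          r2 <- annotate_assembly(q2, a, params,
                                  min_score_abs = rescue_min_score,
                                  margin = margin)
          pr <- r2$predictions[nzchar(r2$predictions$seq), ,
                               drop = FALSE]
          if (nrow(pr)) {
            # coverage + reciprocal-best-hit check vs the full query set
            ok <- vapply(seq_len(nrow(pr)), function(ri) {
              cov <- (pr$q_end[ri] - pr$q_start[ri]) / nchar(q2$seq)
              if (cov < rescue_min_coverage) return(FALSE)
              s <- gsub("[X*-]", "", pr$seq[ri])
              if (nchar(s) < 10) return(FALSE)
              sc <- vapply(queries$seq, function(qs)
                local_align_protein(s, qs, params)$score, numeric(1))
              queries$gene[which.max(sc)] == g &&
                max(sc) >= rescue_min_score
            }, logical(1))
            pr <- pr[ok, , drop = FALSE]
          }
          if (!nrow(pr)) next
          drop <- preds$gene == g & preds$assembly_id == aid &
            !nzchar(preds$seq)
          preds <- rbind(preds[!drop, , drop = FALSE], pr)
          # keep the rescue hits only where the gene had none before
          if (!is.null(r2$hits) &&
              (is.null(hits) || !any(hits$gene == g &
                                       hits$assembly_id == aid)))
            hits <- rbind(hits, r2$hits)
          changed <- TRUE
          break
        }
      }
      }
      if (!changed) break
    }
  }
  list(predictions = preds, hits = hits)
}
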