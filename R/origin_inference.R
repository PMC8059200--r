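## Assembly of the evidence distinguishing de novo birth from divergence or
## truncation of an older gene: synteny context, intron length modulo-3
## logic, conserved-stop-codon frame analysis and the distant-outgroup
## start-codon check, synthesised into a final classification.

#' Flanking synteny context of a candidate region
#'
#' For each species with an alignable region, lists the nearest annotated
#' genes up- and downstream of the region (up to `window_genes` each side),
#' plus any host gene whose span contains the region (a candidate lying in
#' the intron of a conserved gene counts that gene as context). Genes are
#' mapped to their homology families; synteny is satisfied when at least
#' one flanking family is shared by all species with regions.
#'
#' @param regions Data frame (species, seq_region, start, end, strand).
#' @param genomes Named list of genomes.
#' @param families Families from [build_families()] (used to label flanking
#'   genes).
#' @param window_genes Number of genes considered on each side (default 3).
#' @return List: `synteny_ok` (logical), `shared_families` (character),
#'   `per_species` (data frame of flanking gene/family pairs).
#' @export
synteny_context <- function(regions, genomes, families, window_genes = 3L) {
  fam_of <- list()
  for (fid in names(families)) {
    m <- families[[fid]]
    for (i in seq_len(nrow(m)))
      fam_of[[paste(m$species[[i]], m$gene_id[[i]], sep = "|")]] <- fid
  }
  per <- list(); fam_sets <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    gen <- genomes[[r$species]]
    gs <- Filter(function(g) g$seq_region == r$seq_region, gen$genes)
    if (length(gs) == 0L) next
    spans <- t(vapply(gs, gene_span, c(start = 0L, end = 0L)))
    ids <- vapply(gs, `[[`, character(1L), "gene_id")
    up <- which(spans[, "end"] <= r$start)
    down <- which(spans[, "start"] >= r$end)
    host <- which(spans[, "start"] < r$start & spans[, "end"] > r$end)
    pick <- c(tail(up[order(spans[up, "end"])], window_genes),
              head(down[order(spans[down, "start"])], window_genes),
              host)
    fams <- character(0L)
    for (j in pick) {
      fid <- fam_of[[paste(r$species, ids[[j]], sep = "|")]]
      if (is.null(fid)) fid <- NA_character_
      fams <- c(fams, fid)
      per[[length(per) + 1L]] <- data.frame(
        species = r$species, gene_id = ids[[j]], family = fid,
        side = if (j %in% host) "host" else if (j %in% up) "up" else "down",
        stringsAsFactors = FALSE)
    }
    fam_sets[[r$species]] <- unique(fams[!is.na(fams)])
  }
  shared <- if (length(fam_sets)) Reduce(intersect, fam_sets) else character(0L)
  list(synteny_ok = length(shared) >= 1L,
       shared_families = shared,
       per_species = if (length(per)) do.call(rbind, per)
                     else data.frame(species = character(0L),
                                     gene_id = character(0L),
                                     family = character(0L),
                                     side = character(0L)))
}

#' Intron length modulo-3 test
#'
#' An intron whose length is not a multiple of three is likely to predate
#' the ORF it interrupts: had it been intronized after the ORF existed, the
#' insertion would have caused a frameshift. A length that is a multiple of
#' three is inconclusive (it is not evidence of later intronization).
#'
#' @param intron_length_nt Intron length in nucleotides (>= 4; shorter
#'   introns cannot carry splice sites and are an error).
#' @return `"predates_orf"` or `"inconclusive"`.
#' @export
intron_mod3_test <- function(intron_length_nt) {
  if (intron_length_nt < 4L)
    stop("intron length ", intron_length_nt, " below minimum of 4 nt")
  if (intron_length_nt %% 3L != 0L) "predates_orf" else "inconclusive"
}

#' Anchor a frame convention on an alignment
#'
#' The codon frame containing the anchor column (a designated start codon)
#' is labelled +1; the other two frames on the same strand are +2 and +3.
#' Frames in other rows are assigned through each row's ungapped offset
#' relative to the anchor column, so interior indels shift a row's frame
#' assignment downstream of the indel.
#'
#' @param alignment A [region_alignment()].
#' @param anchor_row Row name carrying the anchor start codon.
#' @param anchor_col Alignment column (1-based) of the first base of the
#'   anchor codon.
#' @return A `frame_convention` object.
#' @export
frame_convention <- function(alignment, anchor_row, anchor_col) {
  if (is.null(alignment$aligned[[anchor_row]])) stop("anchor row not found")
  if (anchor_col < 1L || anchor_col > alignment$ncol)
    stop("anchor column out of range")
  structure(list(anchor_row = anchor_row, anchor_col = anchor_col),
            class = "frame_convention")
}

## ungapped index (1-based) of each column within a row; NA on gaps
.ungapped_index <- function(alignment, row) {
  chars <- strsplit(alignment$aligned[[row]], "")[[1L]]
  idx <- cumsum(chars != "-")
  idx[chars == "-"] <- NA_integer_
  idx
}

## nearest non-gap ungapped index at or after a column
.ungapped_at_or_after <- function(idx, col) {
  v <- idx[col:length(idx)]
  v <- v[!is.na(v)]
  if (length(v)) v[[1L]] else NA_integer_
}

#' Count conserved stop codons per frame
#'
#' A conserved stop is a gap-free codon column triple (three consecutive
#' alignment columns, non-gap in every row) that reads as a stop codon in
#' every row. Each conserved stop is assigned a frame per row from the
#' row's cumulative ungapped offset relative to the anchor (+1 = in frame
#' with the anchor codon); stops whose frame assignment differs across rows
#' — the signature of interior non-triplet indels — are reported as
#' frame-ambiguous rather than counted. Frames with zero conserved stops
#' are the open frames.
#'
#' @param alignment A [region_alignment()].
#' @param convention A [frame_convention()].
#' @param interval_columns Columns to scan (1-based; default all).
#' @return List: `counts` (named vector for +1/+2/+3), `ambiguous` (count),
#'   `open_frames` (character), `stops` (data frame: col, frame).
#' @export
conserved_stop_frames <- function(alignment, convention,
                                  interval_columns = seq_len(alignment$ncol)) {
  rows <- names(alignment$aligned)
  mats <- lapply(rows, function(r) strsplit(alignment$aligned[[r]], "")[[1L]])
  names(mats) <- rows
  idxs <- lapply(rows, function(r) .ungapped_index(alignment, r))
  names(idxs) <- rows
  anchors <- vapply(rows, function(r)
    .ungapped_at_or_after(idxs[[r]], convention$anchor_col), integer(1L))
  ncol <- alignment$ncol
  counts <- c(`+1` = 0L, `+2` = 0L, `+3` = 0L)
  ambiguous <- 0L
  stops <- list()
  cols <- interval_columns[interval_columns + 2L <= ncol]
  for (cc in cols) {
    triple <- cc:(cc + 2L)
    all_stop <- TRUE
    for (r in rows) {
      ch <- mats[[r]][triple]
      if (any(ch == "-") || !(paste0(ch, collapse = "") %in% STOP_CODONS)) {
        all_stop <- FALSE; break
      }
    }
    if (!all_stop) next
    frames <- vapply(rows, function(r) {
      off <- (idxs[[r]][[cc]] - anchors[[r]]) %% 3L
      off
    }, integer(1L))
    if (length(unique(frames)) == 1L) {
      lab <- c("+1", "+2", "+3")[[frames[[1L]] + 1L]]
      counts[[lab]] <- counts[[lab]] + 1L
      stops[[length(stops) + 1L]] <- data.frame(col = cc, frame = lab)
    } else {
      ambiguous <- ambiguous + 1L
      stops[[length(stops) + 1L]] <- data.frame(col = cc, frame = "ambiguous")
    }
  }
  list(counts = counts, ambiguous = ambiguous,
       open_frames = names(counts)[counts == 0L],
       stops = if (length(stops)) do.call(rbind, stops)
               else data.frame(col = integer(0L), frame = character(0L)))
}

#' Start-codon presence in distant outgroup rows
#'
#' For each distant outgroup row, reports whether an ATG exists within
#' `slack` columns of the candidate's start column, in the candidate's
#' frame (ungapped offset congruent to 0 modulo 3 relative to the
#' candidate's start). With no alignable distant region the result is
#' `"unavailable"` and classification falls back to ingroup evidence.
#'
#' @param alignment A [region_alignment()].
#' @param candidate_row Row carrying the candidate.
#' @param start_col Column (1-based) of the candidate start codon's first
#'   base.
#' @param distant_rows Row names of distant outgroups present in the
#'   alignment.
#' @param slack Column window around the start (default 30).
#' @return List: `status` (`"absent"`, `"present"` or `"unavailable"`),
#'   `per_species` (named logical).
#' @export
distant_outgroup_start_check <- function(alignment, candidate_row, start_col,
                                         distant_rows, slack = 30L) {
  distant_rows <- intersect(distant_rows, names(alignment$aligned))
  if (length(distant_rows) == 0L)
    return(list(status = "unavailable", per_species = logical(0L)))
  cand_idx <- .ungapped_index(alignment, candidate_row)
  cand_anchor <- .ungapped_at_or_after(cand_idx, start_col)
  res <- logical(0L)
  for (sp in distant_rows) {
    chars <- strsplit(alignment$aligned[[sp]], "")[[1L]]
    idx <- .ungapped_index(alignment, sp)
    anchor <- .ungapped_at_or_after(idx, start_col)
    found <- FALSE
    lo <- max(1L, start_col - slack); hi <- min(alignment$ncol - 2L, start_col + slack)
    for (cc in lo:hi) {
      if (is.na(idx[[cc]])) next
      if ((idx[[cc]] - anchor) %% 3L != 0L) next
      triple <- chars[cc:(cc + 2L)]
      if (any(triple == "-")) next
      if (paste0(triple, collapse = "") == "ATG") { found <- TRUE; break }
    }
    res[[sp]] <- found
  }
  list(status = if (any(res)) "present" else "absent", per_species = res)
}

#' Classify the evolutionary origin of a candidate family
#'
#' Decision table over the assembled evidence:
#' \itemize{
#'   \item no continuous outgroup alignment -> `undetermined`;
#'   \item a conserved outgroup ORF covering the candidate: if it shares the
#'     candidate's reading frame (open-frame analysis) the family is a
#'     `diverged_ancestor` (e.g. a truncated older gene), otherwise an
#'     `earlier_origin`;
#'   \item otherwise, when the alignable outgroup regions are noncoding
#'     (disrupted by stops or frameshifts), synteny is conserved, the
#'     distant-outgroup start-codon check is absent or unavailable, and
#'     there are no unexplained intragenomic duplicates -> `de_novo`;
#'   \item a distant-outgroup start codon is never compatible with a
#'     `de_novo` call: it downgrades to `undetermined`;
#'   \item any other conflict -> `undetermined`, with the conflict named in
#'     the rationale.
#' }
#'
#' @param evidence List with elements `continuous` (logical),
#'   `outgroup_orf_flag` (logical), `outgroup_orf_same_frame` (logical),
#'   `outgroup_disrupted` (logical: all alignable outgroup rows carry
#'   in-frame stops or frameshifting indels), `synteny_ok` (logical),
#'   `distant_start` (`"absent"`, `"present"`, `"unavailable"`),
#'   `intragenomic_duplicates` (logical).
#' @return List: `classification` (one of `de_novo`, `earlier_origin`,
#'   `diverged_ancestor`, `undetermined`) and `rationale` (character).
#' @export
classify_origin <- function(evidence) {
  rat <- character(0L)
  if (!isTRUE(evidence$continuous))
    return(list(classification = "undetermined",
                rationale = "no continuous alignment of outgroup regions"))
  if (isTRUE(evidence$outgroup_orf_flag)) {
    if (isTRUE(evidence$outgroup_orf_same_frame))
      return(list(classification = "diverged_ancestor",
                  rationale = "conserved outgroup ORF shares the candidate reading frame"))
    return(list(classification = "earlier_origin",
                rationale = "conserved outgroup ORF covers >= 50% of the candidate ORF"))
  }
  if (identical(evidence$distant_start, "present"))
    return(list(classification = "undetermined",
                rationale = "start codon present in distant outgroup region"))
  if (isTRUE(evidence$outgroup_disrupted) && isTRUE(evidence$synteny_ok) &&
      !isTRUE(evidence$intragenomic_duplicates)) {
    rat <- c("outgroup regions noncoding (disrupted ORF)",
             "synteny conserved across species",
             if (identical(evidence$distant_start, "absent"))
               "no start codon in distant outgroups"
             else "distant outgroups unavailable; ingroup evidence only")
    return(list(classification = "de_novo", rationale = paste(rat, collapse = "; ")))
  }
  conflicts <- c(
    if (!isTRUE(evidence$outgroup_disrupted)) "outgroup region not clearly noncoding",
    if (!isTRUE(evidence$synteny_ok)) "synteny not conserved",
    if (isTRUE(evidence$intragenomic_duplicates)) "unexplained intragenomic duplicates")
  list(classification = "undetermined",
       rationale = paste(conflicts, collapse = "; "))
}
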