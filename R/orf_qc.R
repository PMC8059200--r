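## ORF detection, the outgroup ORF-conservation filter, splice-signal checks
## and the codified annotation-consistency QC.

#' Find maximal open reading frames in a sequence
#'
#' Scans the three reading frames of the given strand. An ORF runs from the
#' first ATG after the previous stop codon through the next in-frame stop
#' codon (inclusive); ORFs without a terminal stop are not called, and any
#' ORF containing an `N` is skipped. Results are deterministic, ordered by
#' start position then frame.
#'
#' @param seq Nucleotide string.
#' @param min_orf_codons Minimum length in codons, including the stop
#'   (default 50).
#' @return Data frame: `frame` (0..2), `start`, `end` (0-based half-open nt
#'   interval covering ATG..stop), `codons`.
#' @export
find_orfs <- function(seq, min_orf_codons = 50L) {
  .assert_dna(seq)
  out <- list()
  n <- nchar(seq)
  for (f in 0L:2L) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < 2L) next
    starts <- f + 3L * (seq_len(n_codons) - 1L) + 1L   # 1-based codon starts
    codons <- substring(seq, starts, starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    atg_idx <- which(codons == "ATG")
    prev_stop <- 0L
    for (s in stop_idx) {
      a <- atg_idx[atg_idx > prev_stop & atg_idx < s]
      if (length(a) > 0L) {
        a <- a[[1L]]
        len <- s - a + 1L
        if (len >= min_orf_codons) {
          nt_start <- f + 3L * (a - 1L)
          nt_end <- f + 3L * s
          orf_seq <- substr(seq, nt_start + 1L, nt_end)
          if (!grepl("N", orf_seq, fixed = TRUE))
            out[[length(out) + 1L]] <- data.frame(
              frame = f, start = nt_start, end = nt_end, codons = len)
        }
      }
      prev_stop <- s
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(0L), start = integer(0L),
                      end = integer(0L), codons = integer(0L)))
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

#' Test for a conserved ORF in outgroup alignment rows
#'
#' For each outgroup row, ORFs are called on the de-gapped row sequence,
#' mapped back to alignment columns, and their overlap with the candidate
#' ORF's columns is divided by the candidate ORF's column span. The flag is
#' raised when at least `min_species` outgroup rows contain an ORF reaching
#' coverage `threshold` (boundary inclusive). A raised flag is evidence that
#' the family originated before the focal clade's speciation.
#'
#' When the candidate gene contains introns, pass the intron's alignment
#' columns as `exclude_columns`: outgroup rows are then scanned in spliced
#' coordinates (intron columns removed), so an outgroup ORF that is
#' interrupted by the homolog of the candidate's intron is still detected.
#'
#' @param alignment A [region_alignment()].
#' @param candidate_row Row name carrying the candidate ORF.
#' @param candidate_interval 0-based half-open genomic interval of the
#'   candidate ORF on that row.
#' @param outgroup_rows Row names of the outgroup species.
#' @param threshold Minimum coverage of the candidate ORF (default 0.5).
#' @param min_species Number of outgroup rows required (default 1).
#' @param min_orf_codons Minimum outgroup ORF size in codons (default 50).
#' @param exclude_columns Alignment columns spliced out before ORF calling
#'   (typically the candidate's intron columns).
#' @return List: `flag` (logical), `evidence` (data frame per outgroup row:
#'   best coverage and ORF count).
#' @export
outgroup_orf_conservation <- function(alignment, candidate_row,
                                      candidate_interval, outgroup_rows,
                                      threshold = 0.5, min_species = 1L,
                                      min_orf_codons = 50L,
                                      exclude_columns = integer(0L)) {
  cand_cols <- interval_to_columns(alignment, candidate_row, candidate_interval)
  cand_cols <- setdiff(cand_cols, exclude_columns)
  if (length(cand_cols) == 0L)
    stop("candidate interval does not map into the alignment")
  rows <- list(); n_reaching <- 0L
  for (sp in outgroup_rows) {
    gapped <- alignment$aligned[[sp]]
    if (is.null(gapped)) next
    chars <- strsplit(gapped, "")[[1L]]
    nongap_cols <- setdiff(which(chars != "-"), exclude_columns)
    degapped <- paste0(chars[nongap_cols], collapse = "")
    orfs <- find_orfs(degapped, min_orf_codons)
    best <- 0
    if (nrow(orfs) > 0L) {
      for (i in seq_len(nrow(orfs))) {
        orf_cols <- nongap_cols[(orfs$start[[i]] + 1L):orfs$end[[i]]]
        cov <- length(intersect(orf_cols, cand_cols)) / length(cand_cols)
        best <- max(best, cov)
      }
    }
    if (best >= threshold) n_reaching <- n_reaching + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, best_coverage = best, n_orfs = nrow(orfs),
      stringsAsFactors = FALSE)
  }
  list(flag = n_reaching >= min_species,
       evidence = if (length(rows)) do.call(rbind, rows)
                  else data.frame(species = character(0L),
                                  best_coverage = numeric(0L),
                                  n_orfs = integer(0L)))
}

#' Canonical splice-signal check
#'
#' An intron is canonical when its first two bases are GT and its last two
#' AG (DNA alphabet), after strand adjustment. Introns shorter than 4 nt
#' are flagged invalid.
#'
#' @param genome An [annotated_genome()].
#' @param gene A [gene_model()] (or gene id) with at least one intron.
#' @return Data frame: `intron` (transcription-order index), `length`,
#'   `canonical` (NA when invalid).
#' @export
splice_signal_check <- function(genome, gene) {
  if (is.character(gene)) gene <- genome$genes[[gene]]
  iv <- introns(gene)
  if (nrow(iv) == 0L) stop("gene ", gene$gene_id, " has no intron")
  n <- nrow(iv)
  res <- lapply(seq_len(n), function(k) {
    s <- extract_feature_sequence(genome, gene, paste0("intron_", k))
    len <- nchar(s)
    canonical <- if (len < 4L) NA else
      substr(s, 1L, 2L) == "GT" && substr(s, len - 1L, len) == "AG"
    data.frame(intron = k, length = len, canonical = canonical)
  })
  do.call(rbind, res)
}

#' Codified annotation-consistency QC for a candidate family
#'
#' Structural checks per member (CDS begins with ATG, ends with a stop, no
#' internal stop, CDS segments must not overlap each other in different
#' frames, splice signals canonical) plus cross-species consistency when an
#' alignment is supplied: the aligned start-codon, stop-codon and splice
#' columns of all members must coincide within `col_slack` columns. A
#' family fails QC when any flag is raised.
#'
#' @param family Data frame with `species`, `gene_id`.
#' @param genomes Named list of genomes.
#' @param alignment Optional [region_alignment()] with one row per member
#'   species.
#' @param col_slack Allowed column offset across species (default 0).
#' @return A `qc_report`: list with `pass` (logical) and `flags` (data
#'   frame: species, gene_id, flag).
#' @export
annotation_consistency <- function(family, genomes, alignment = NULL,
                                   col_slack = 0L) {
  flags <- list()
  note <- function(sp, gid, flag)
    flags[[length(flags) + 1L]] <<- data.frame(
      species = sp, gene_id = gid, flag = flag, stringsAsFactors = FALSE)

  start_cols <- c(); stop_cols <- c(); splice_sig <- c()
  for (i in seq_len(nrow(family))) {
    sp <- family$species[[i]]; gid <- family$gene_id[[i]]
    gen <- genomes[[sp]]; gene <- gen$genes[[gid]]
    if (is.null(gene)) stop("member ", sp, ":", gid, " not annotated")
    cds <- extract_feature_sequence(gen, gene, "cds")
    if (substr(cds, 1L, 3L) != "ATG") note(sp, gid, "missing_start")
    if (nchar(cds) %% 3L != 0L) {
      note(sp, gid, "cds_length_not_multiple_of_3")
    } else {
      aa <- translate_cds(cds, strict = FALSE)
      if (substr(aa, nchar(aa), nchar(aa)) != "*") note(sp, gid, "missing_stop")
      if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        note(sp, gid, "internal_stop")
    }
    ## CDS segments overlapping each other (alternative-frame overlap)
    if (nrow(gene$cds) > 1L) {
      cd <- gene$cds[order(gene$cds[, "start"]), , drop = FALSE]
      if (any(cd[-1L, "start"] < cd[-nrow(cd), "end"]))
        note(sp, gid, "exons_overlap_alternative_frames")
    }
    if (nrow(introns(gene)) > 0L) {
      ssc <- splice_signal_check(gen, gene)
      if (any(is.na(ssc$canonical)) || !all(ssc$canonical, na.rm = TRUE))
        note(sp, gid, "noncanonical_splice")
      splice_sig <- c(splice_sig, paste(ssc$canonical, collapse = ","))
    }
    ## map start/stop codons into alignment columns
    if (!is.null(alignment) && sp %in% names(alignment$aligned)) {
      cd <- gene$cds[order(gene$cds[, "start"]), , drop = FALSE]
      if (gene$strand == "+") {
        start_pos <- cd[1L, "start"]; stop_pos <- cd[nrow(cd), "end"] - 1L
      } else {
        start_pos <- cd[nrow(cd), "end"] - 1L; stop_pos <- cd[1L, "start"]
      }
      sc <- interval_to_columns(alignment, sp, c(start_pos, start_pos + 1L))
      ec <- interval_to_columns(alignment, sp, c(stop_pos, stop_pos + 1L))
      if (length(sc)) start_cols <- c(start_cols, sc[[1L]])
      if (length(ec)) stop_cols <- c(stop_cols, ec[[1L]])
    }
  }
  if (length(start_cols) >= 2L && diff(range(start_cols)) > col_slack)
    note("*", "*", "inconsistent_start")
  if (length(stop_cols) >= 2L && diff(range(stop_cols)) > col_slack)
    note("*", "*", "inconsistent_stop")
  if (length(unique(splice_sig)) > 1L)
    note("*", "*", "inconsistent_splice")

  flags_df <- if (length(flags)) do.call(rbind, flags)
    else data.frame(species = character(0L), gene_id = character(0L),
                    flag = character(0L))
  structure(list(pass = nrow(flags_df) == 0L, flags = flags_df),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("annotation QC:", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}
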