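## Discovery and multiple alignment of homologous DNA regions for candidate
## families: nucleotide search with both whole-gene and spliced-CDS queries,
## hit post-processing, and a multiple sequence alignment with per-row
## genome-coordinate maps. The MSA engine is MAFFT (called as an external
## process); the contract -- equal-length gapped rows that de-gap back to
## their genomic substrings -- is what the rest of the pipeline relies on,
## not the particular algorithm.

#' Find homologous genomic regions for a candidate family
#'
#' For every member gene both the whole gene sequence and the spliced CDS
#' are used as nucleotide queries against all genomes. Hits failing the
#' e-value/coverage thresholds per query form are dropped, overlapping hits
#' amalgamated and oversized hit lists capped. Hits of a whole-gene query
#' that touch only intronic query positions are discarded (they cover parts
#' of introns, not the gene). A self-hit for each member gene is guaranteed.
#' Per species the best surviving hit (lowest e-value, then highest score)
#' is extended by `flank` nt on both sides and returned as that species'
#' candidate region.
#'
#' @param family Data frame with `species`, `gene_id` columns (a family from
#'   [build_families()]).
#' @param genomes Named list of [annotated_genome()] objects.
#' @param scheme Nucleotide [scoring_scheme()].
#' @param max_e,min_cov Hit thresholds.
#' @param total_limit,per_species_keep Capping parameters.
#' @param flank Extension of the selected region (default 500 nt).
#' @return List with `hits` (full hit table) and `regions` (data frame:
#'   species, seq_region, start, end, strand — one row per species with a
#'   detectable region).
#' @export
find_homologous_regions <- function(family, genomes,
                                    scheme = nucleotide_scheme(),
                                    max_e = 1e-3, min_cov = 0.5,
                                    total_limit = 1000L, per_species_keep = 5L,
                                    flank = 500L) {
  all_hits <- list()
  for (i in seq_len(nrow(family))) {
    sp <- family$species[[i]]; gid <- family$gene_id[[i]]
    gen <- genomes[[sp]]
    if (is.null(gen) || !gid %in% names(gen$genes))
      stop("member gene ", sp, ":", gid, " missing from genomes")
    gene <- gen$genes[[gid]]
    queries <- list(gene = extract_feature_sequence(gen, gene, "gene"))
    if (nrow(gene$cds) > 0L)
      queries$cds <- extract_feature_sequence(gen, gene, "cds")
    for (qform in names(queries)) {
      qid <- paste(sp, gid, qform, sep = ":")
      h <- search_genomes(queries[[qform]], genomes, scheme, max_e, min_cov,
                          query_id = qid)
      if (qform == "gene" && nrow(h) > 0L)
        h <- .drop_intron_only_hits(h, gene)
      all_hits[[length(all_hits) + 1L]] <- h
    }
    ## guarantee the self-hit
    span <- gene_span(gene)
    qid <- paste(sp, gid, "gene", sep = ":")
    have_self <- any(vapply(all_hits, function(h) {
      any(h$query_id == qid & h$genome == sp & h$seq_region == gene$seq_region &
            h$s_start <= span[["start"]] & h$s_end >= span[["end"]])
    }, logical(1L)))
    if (!have_self) {
      qlen <- span[["end"]] - span[["start"]]
      all_hits[[length(all_hits) + 1L]] <- data.frame(
        query_id = qid, genome = sp, seq_region = gene$seq_region,
        s_start = span[["start"]], s_end = span[["end"]], strand = gene$strand,
        q_start = 0L, q_end = qlen, q_len = qlen,
        score = qlen, evalue = 0, coverage = 1, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, all_hits)
  hits <- amalgamate_hits(hits)
  hits <- cap_hits(hits, total_limit, per_species_keep)
  regions <- .best_region_per_species(hits, genomes, flank)
  list(hits = hits, regions = regions)
}

## drop hits of the whole-gene query whose query interval lies wholly inside
## intronic positions of the gene (no overlap with any exon)
.drop_intron_only_hits <- function(hits, gene) {
  span <- gene_span(gene)
  ex_rel <- gene$exons - span[["start"]]
  if (gene$strand == "-") {
    qlen <- span[["end"]] - span[["start"]]
    ex_rel <- cbind(qlen - ex_rel[, 2L], qlen - ex_rel[, 1L])
  }
  touches_exon <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$q_start[[i]] < ex_rel[, 2L] & hits$q_end[[i]] > ex_rel[, 1L])
  }, logical(1L))
  hits[touches_exon, , drop = FALSE]
}

.best_region_per_species <- function(hits, genomes, flank) {
  rows <- list()
  for (sp in names(genomes)) {
    h <- hits[hits$genome == sp, , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[order(h$evalue, -h$score, h$seq_region, h$s_start), , drop = FALSE]
    best <- h[1L, ]
    L <- nchar(genomes[[sp]]$sequences[[best$seq_region]])
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, seq_region = best$seq_region,
      start = max(0L, best$s_start - flank),
      end = min(L, best$s_end + flank),
      strand = best$strand, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(species = character(0L), seq_region = character(0L),
                      start = integer(0L), end = integer(0L),
                      strand = character(0L)))
  do.call(rbind, rows)
}

#' Multiple alignment of homologous regions
#'
#' Extracts each region's sequence (minus-strand regions are
#' reverse-complemented before alignment, so all rows share one
#' orientation), aligns them with MAFFT and returns a `region_alignment`
#' whose gapped rows de-gap exactly back to the extracted genomic
#' substrings. Requires at least two regions.
#'
#' @param regions Data frame as returned in `$regions` by
#'   [find_homologous_regions()].
#' @param genomes Named list of [annotated_genome()] objects.
#' @param mafft_args Character vector of MAFFT arguments (default E-INS-i
#'   style: generalized affine pairs with iterative refinement).
#' @return A `region_alignment` object: list with `rows` (the input data
#'   frame) and `aligned` (named character vector of equal-length gapped
#'   sequences, names = species).
#' @export
align_regions <- function(regions, genomes,
                          mafft_args = c("--genafpair", "--maxiterate", "1000",
                                         "--quiet")) {
  if (nrow(regions) < 2L) stop("need at least two regions to align")
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    s <- substr(genomes[[r$species]]$sequences[[r$seq_region]],
                r$start + 1L, r$end)
    if (r$strand == "-") reverse_complement(s) else s
  }, character(1L))
  names(seqs) <- regions$species
  aligned <- run_mafft(seqs, mafft_args)
  region_alignment(regions, aligned)
}

#' Run MAFFT on a set of named sequences
#'
#' Thin wrapper over the `mafft` executable; preserves input order and
#' upper-cases the output.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param args MAFFT command-line arguments.
#' @return Named character vector of gapped sequences.
#' @export
run_mafft <- function(seqs, args = c("--auto", "--quiet")) {
  if (Sys.which("mafft") == "")
    stop("mafft executable not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  nm <- sprintf("row%03d", seq_along(seqs))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, nm)), fin)
  status <- system2("mafft", c(args, shQuote(fin)), stdout = fout,
                    stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  out <- Biostrings::readBStringSet(fout)
  gapped <- toupper(as.character(out))
  names(gapped) <- names(seqs)[match(sub("\\s.*$", "", names(out)), nm)]
  gapped[names(seqs)]
}

#' Construct (and validate) a region alignment
#'
#' @param rows Data frame: species, seq_region, start, end, strand.
#' @param aligned Named character vector of gapped rows (equal lengths).
#' @return A `region_alignment` object.
#' @export
region_alignment <- function(rows, aligned) {
  if (length(unique(nchar(aligned))) != 1L)
    stop("gapped rows have unequal lengths")
  obj <- structure(list(rows = rows, aligned = aligned,
                        ncol = nchar(aligned[[1L]])),
                   class = "region_alignment")
  obj
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("region_alignment: ", length(x$aligned), " rows x ", x$ncol,
      " columns\n", sep = "")
  invisible(x)
}

#' Check that a row de-gaps to its genomic substring
#'
#' @param alignment A [region_alignment()].
#' @param genomes Named list of genomes.
#' @return Logical vector, one per row.
#' @export
rows_degap_ok <- function(alignment, genomes) {
  vapply(seq_len(nrow(alignment$rows)), function(i) {
    r <- alignment$rows[i, ]
    s <- substr(genomes[[r$species]]$sequences[[r$seq_region]],
                r$start + 1L, r$end)
    if (r$strand == "-") s <- reverse_complement(s)
    gsub("-", "", alignment$aligned[[r$species]], fixed = TRUE) == s
  }, logical(1L))
}

#' Column-to-genomic-position map for a row
#'
#' For each alignment column, the 0-based genomic position of the base in
#' that column, or `NA` for gap columns. Positions are strictly monotone
#' over non-gap columns (increasing for plus-strand rows, decreasing for
#' minus-strand rows).
#'
#' @param alignment A [region_alignment()].
#' @param species Row name.
#' @return Integer vector of length `ncol`.
#' @export
column_positions <- function(alignment, species) {
  row <- alignment$aligned[[species]]
  if (is.null(row)) stop("row '", species, "' not in alignment")
  r <- alignment$rows[alignment$rows$species == species, ]
  chars <- strsplit(row, "")[[1L]]
  nongap <- chars != "-"
  idx <- cumsum(nongap)          # 1-based index within the extracted sequence
  pos <- rep(NA_integer_, length(chars))
  if (r$strand == "+") {
    pos[nongap] <- r$start + idx[nongap] - 1L
  } else {
    pos[nongap] <- r$end - idx[nongap]
  }
  pos
}

#' Map a genomic interval into alignment columns
#'
#' @param alignment A [region_alignment()].
#' @param species Row name.
#' @param interval 0-based half-open genomic interval.
#' @return Integer vector of column indices (1-based) whose bases fall in
#'   the interval.
#' @export
interval_to_columns <- function(alignment, species, interval) {
  pos <- column_positions(alignment, species)
  which(!is.na(pos) & pos >= interval[[1L]] & pos < interval[[2L]])
}

#' Percent identity between two alignment rows
#'
#' Matches divided by the number of comparable (both non-gap) columns;
#' columns where exactly one row is gapped are indel columns and excluded
#' when `exclude_indels` is `TRUE` (they are counted and reported).
#'
#' @param alignment A [region_alignment()] (or any object with an `aligned`
#'   named character vector).
#' @param row_a,row_b Row names.
#' @param exclude_indels Logical (default `TRUE`).
#' @return List: `identity`, `matches`, `comparable_columns`,
#'   `indel_columns`, `total_columns`.
#' @export
percent_identity <- function(alignment, row_a, row_b, exclude_indels = TRUE) {
  a <- strsplit(alignment$aligned[[row_a]], "")[[1L]]
  b <- strsplit(alignment$aligned[[row_b]], "")[[1L]]
  both <- a != "-" & b != "-"
  indel <- xor(a == "-", b == "-")
  comparable <- if (exclude_indels) both else both | indel
  matches <- sum(a == b & both)
  list(identity = if (sum(comparable)) matches / sum(comparable) else NA_real_,
       matches = matches,
       comparable_columns = sum(comparable),
       indel_columns = sum(indel),
       total_columns = length(a))
}

#' Continuity of an alignment over the candidate span
#'
#' Operational definition of a "continuous alignment": within the candidate
#' gene's alignment span every row must be non-gap over at least
#' `min_row_cov` of the columns and contain no gap run longer than
#' `max_gap_run` columns.
#'
#' @param alignment A [region_alignment()].
#' @param span_cols Integer vector of columns covered by the candidate gene.
#' @param min_row_cov Minimum non-gap fraction per row (default 0.8).
#' @param max_gap_run Maximum gap-block length in columns (default 50).
#' @return List: `continuous` (logical) and `per_row` data frame.
#' @export
alignment_continuity <- function(alignment, span_cols, min_row_cov = 0.8,
                                 max_gap_run = 50L) {
  res <- lapply(names(alignment$aligned), function(sp) {
    chars <- strsplit(alignment$aligned[[sp]], "")[[1L]][span_cols]
    gaps <- chars == "-"
    runs <- rle(gaps)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    data.frame(species = sp, nongap_frac = mean(!gaps), max_gap_run = max_run,
               ok = mean(!gaps) >= min_row_cov && max_run <= max_gap_run,
               stringsAsFactors = FALSE)
  })
  per_row <- do.call(rbind, res)
  list(continuous = all(per_row$ok), per_row = per_row)
}
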