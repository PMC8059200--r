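## Genome + annotation data model and standard-format I/O.
##
## All intervals are stored 0-based half-open; the GFF3 reader/writer converts
## to and from the 1-based inclusive convention at the I/O boundary only.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L)
    stop(what, " must be a single character string")
  if (nchar(seq) > 0L && grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

.iv_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(x), ncol = 2L, byrow = FALSE)
  colnames(m) <- c("start", "end")
  if (any(m[, "end"] <= m[, "start"])) stop("empty or reversed interval")
  m[order(m[, "start"]), , drop = FALSE]
}

#' Construct a gene model
#'
#' A gene model holds one transcript's exon and CDS structure on a sequence
#' region. Intervals are 0-based half-open and exons must be disjoint and
#' sorted; introns are always derived from the exons (see [introns()]), never
#' stored.
#'
#' @param gene_id Gene identifier.
#' @param seq_region Identifier of the sequence region the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals, 0-based
#'   half-open.
#' @param cds Two-column matrix of CDS intervals; must lie within the exon
#'   union. May have zero rows for non-coding biotypes.
#' @param biotype One of `"protein_coding"`, `"pseudogene"`, `"ncRNA"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_region, strand, exons, cds = NULL,
                       biotype = "protein_coding") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  biotype <- match.arg(biotype, c("protein_coding", "pseudogene", "ncRNA"))
  exons <- .iv_matrix(exons)
  cds <- .iv_matrix(cds)
  if (nrow(exons) == 0L) stop("gene must have at least one exon")
  if (nrow(exons) > 1L && any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("exons overlap within gene ", gene_id)
  ## every CDS segment must be contained in some exon
  if (nrow(cds) > 0L) {
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, "start"] >= exons[, "start"] & cds[i, "end"] <= exons[, "end"])
    }, logical(1L))
    if (!all(ok)) stop("CDS segment outside exon space in gene ", gene_id)
  }
  if (biotype == "protein_coding" && sum(cds[, "end"] - cds[, "start"]) < 3L)
    stop("protein_coding gene ", gene_id, " has concatenated CDS length < 3")
  structure(list(gene_id = gene_id, seq_region = seq_region, strand = strand,
                 exons = exons, cds = cds, biotype = biotype),
            class = "gene_model")
}

#' Derive intron intervals of a gene
#'
#' Introns are the gaps between consecutive exons, in genomic coordinate
#' order (0-based half-open).
#'
#' @param gene A [gene_model()].
#' @return Two-column matrix of intron intervals (possibly zero rows).
#' @export
introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  m <- cbind(start = ex[-nrow(ex), "end"], end = ex[-1L, "start"])
  m
}

gene_span <- function(gene) {
  c(start = unname(gene$exons[1L, "start"]),
    end = unname(gene$exons[nrow(gene$exons), "end"]))
}

#' Construct an annotated genome
#'
#' @param species_id Short species label.
#' @param sequences Named character vector of nucleotide sequences over
#'   \{A,C,G,T,N\}, one element per sequence region.
#' @param genes List of [gene_model()] objects.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(species_id, sequences, genes = list()) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be a named character vector")
  for (nm in names(sequences)) .assert_dna(sequences[[nm]], paste0("sequence '", nm, "'"))
  for (g in genes) {
    if (!inherits(g, "gene_model")) stop("genes must be gene_model objects")
    if (!g$seq_region %in% names(sequences))
      stop("gene ", g$gene_id, " references missing sequence region '",
           g$seq_region, "'")
    sp <- gene_span(g)
    if (sp["start"] < 0L || sp["end"] > nchar(sequences[[g$seq_region]]))
      stop("gene ", g$gene_id, " extends beyond its sequence region")
  }
  names(genes) <- vapply(genes, `[[`, character(1L), "gene_id")
  if (anyDuplicated(names(genes))) stop("duplicate gene ids")
  if (length(genes) > 1L) {
    ## canonical gene order: by region, start coordinate, then id
    ord <- order(vapply(genes, `[[`, character(1L), "seq_region"),
                 vapply(genes, function(g) gene_span(g)[["start"]], integer(1L)),
                 names(genes))
    genes <- genes[ord]
  }
  structure(list(species_id = species_id, sequences = sequences, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome '", x$species_id, "': ", length(x$sequences),
      " region(s), ", sum(nchar(x$sequences)), " bp, ", length(x$genes),
      " gene(s)\n", sep = "")
  invisible(x)
}

#' Reverse-complement a nucleotide sequence
#'
#' @param seq Character string over \{A,C,G,T,N\}.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(seq) {
  .assert_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence
#'
#' Uses the standard genetic code; stop codons are encoded as `"*"`. In
#' strict mode the sequence length must be a multiple of three and ambiguous
#' bases are an error; in lenient mode a trailing partial codon is dropped
#' and codons containing `N` translate to `"X"`.
#'
#' @param cds_seq Nucleotide string.
#' @param strict Logical; enforce length and alphabet (default `TRUE`).
#' @return Protein string.
#' @export
translate_cds <- function(cds_seq, strict = TRUE) {
  .assert_dna(cds_seq, "cds_seq")
  n <- nchar(cds_seq)
  if (strict && n %% 3L != 0L)
    stop("CDS length ", n, " is not a multiple of 3")
  if (strict && grepl("N", cds_seq))
    stop("ambiguous base in CDS (strict mode)")
  n <- n - n %% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds_seq, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

## standard genetic code as a fast lookup (stops as "*")
.codon_env <- new.env(parent = emptyenv())
.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    tab <- Biostrings::GENETIC_CODE
    .codon_env$tab <- setNames(as.character(tab), names(tab))
  }
  .codon_env$tab
}

#' Extract the sequence of a gene feature
#'
#' Strand-aware extraction: minus-strand features are reverse-complemented,
#' CDS segments are concatenated in translation order, and introns are
#' indexed in transcription order (`intron_1` is the 5'-most intron).
#'
#' @param genome An [annotated_genome()].
#' @param gene A [gene_model()] belonging to `genome`, or a gene id.
#' @param part `"gene"` (whole genomic span), `"cds"` (spliced CDS) or
#'   `"intron_<k>"`.
#' @return Nucleotide string.
#' @export
extract_feature_sequence <- function(genome, gene, part = "gene") {
  if (is.character(gene)) {
    if (!gene %in% names(genome$genes)) stop("gene '", gene, "' not in genome")
    gene <- genome$genes[[gene]]
  }
  seq <- genome$sequences[[gene$seq_region]]
  if (is.null(seq)) stop("gene region not in genome")
  take <- function(iv) substr(seq, iv[1L] + 1L, iv[2L])
  if (part == "gene") {
    sp <- gene_span(gene)
    s <- take(sp)
    if (gene$strand == "-") s <- reverse_complement(s)
    return(s)
  }
  if (part == "cds") {
    if (nrow(gene$cds) == 0L) stop("gene ", gene$gene_id, " has no CDS")
    pieces <- vapply(seq_len(nrow(gene$cds)),
                     function(i) take(gene$cds[i, ]), character(1L))
    s <- paste0(pieces, collapse = "")
    if (gene$strand == "-") s <- reverse_complement(s)
    return(s)
  }
  if (grepl("^intron_[0-9]+$", part)) {
    k <- as.integer(sub("^intron_", "", part))
    iv <- introns(gene)
    if (k < 1L || k > nrow(iv)) stop("intron index ", k, " out of range")
    idx <- if (gene$strand == "+") k else nrow(iv) - k + 1L
    s <- take(iv[idx, ])
    if (gene$strand == "-") s <- reverse_complement(s)
    return(s)
  }
  stop("unknown part '", part, "'")
}

## ---- GFF3 I/O --------------------------------------------------------------

.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, found ",
           length(f))
    s <- suppressWarnings(as.integer(f[[4L]]))
    e <- suppressWarnings(as.integer(f[[5L]]))
    if (is.na(s) || is.na(e) || s < 1L || e < s)
      stop("malformed GFF3 at line ", i, ": invalid coordinates '",
           f[[4L]], "'..'", f[[5L]], "'")
  }
  invisible(TRUE)
}

.first_or_na <- function(x) if (length(x) >= 1L) x[[1L]] else NA_character_

#' Read a genome from FASTA and GFF3
#'
#' Parses a FASTA file with [Biostrings::readDNAStringSet()] and a GFF3
#' annotation with [rtracklayer::import()], assembles gene/mRNA/exon/CDS
#' hierarchies and returns a validated [annotated_genome()]. When a gene has
#' several transcripts, the transcript with the longest total CDS is kept
#' (ties broken by transcript id) and a message notes the choice.
#'
#' @param fasta_path Path to a (multi-)FASTA file.
#' @param gff3_path Path to a GFF3 file with ID/Parent attributes.
#' @param species_id Species label; defaults to the FASTA file stem.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(fasta_path, gff3_path, species_id = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (is.null(species_id))
    species_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  dss <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- setNames(toupper(as.character(dss)),
                   sub("\\s.*$", "", names(dss)))
  .validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$parent <- vapply(as.list(gr$Parent), .first_or_na, character(1L))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  gene_rows <- df[df$type %in% c("gene", "pseudogene"), , drop = FALSE]
  tx_rows <- df[df$type %in% c("mRNA", "transcript", "pseudogenic_transcript"),
                , drop = FALSE]
  part_rows <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]

  genes <- list()
  for (i in seq_len(nrow(gene_rows))) {
    g <- gene_rows[i, ]
    if (is.na(g$ID)) stop("gene feature without ID in ", gff3_path)
    if (!g$seqnames %in% names(seqs))
      stop("gene ", g$ID, " references sequence region '", g$seqnames,
           "' absent from FASTA")
    biotype <- if (!is.null(g$gene_biotype) && !is.na(g$gene_biotype))
      as.character(g$gene_biotype)
    else if (g$type == "pseudogene") "pseudogene" else "protein_coding"
    txs <- tx_rows[!is.na(tx_rows$parent) & tx_rows$parent == g$ID, , drop = FALSE]
    tx_ids <- if (nrow(txs) > 0L) sort(txs$ID) else g$ID
    ## choose transcript with the longest total CDS
    pick <- NULL; pick_len <- -1L
    for (tid in tx_ids) {
      p <- part_rows[!is.na(part_rows$parent) & part_rows$parent == tid, , drop = FALSE]
      len <- sum(p$width[p$type == "CDS"])
      if (len > pick_len) { pick <- tid; pick_len <- len }
    }
    if (length(tx_ids) > 1L)
      message("gene ", g$ID, ": ", length(tx_ids),
              " transcripts; keeping longest CDS (", pick, ")")
    p <- part_rows[!is.na(part_rows$parent) & part_rows$parent == pick, , drop = FALSE]
    ex <- p[p$type == "exon", , drop = FALSE]
    cd <- p[p$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- g   # gene with no explicit exon rows
    exons <- cbind(ex$start - 1L, ex$end)
    cds <- if (nrow(cd) > 0L) cbind(cd$start - 1L, cd$end) else NULL
    genes[[length(genes) + 1L]] <-
      gene_model(g$ID, g$seqnames, g$strand, exons, cds, biotype)
  }
  annotated_genome(species_id, seqs, genes)
}

#' Write a genome to FASTA and GFF3
#'
#' Emits deterministic output: sequence regions in name order, genes sorted
#' by region and start coordinate. Internal 0-based half-open intervals are
#' converted to 1-based inclusive GFF3 coordinates; CDS phase is computed
#' from the cumulative coding length.
#'
#' @param genome An [annotated_genome()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  seqs <- genome$sequences[order(names(genome$sequences))]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)

  recs <- list()
  add <- function(seqid, type, start0, end0, strand, id, parent = NA, extra = NA) {
    recs[[length(recs) + 1L]] <<- data.frame(
      seqid = seqid, source = "trgscout", type = type,
      start = start0 + 1L, end = end0, strand = strand,
      id = id, parent = parent, extra = extra,
      phase = NA_integer_, stringsAsFactors = FALSE)
  }
  genes <- genome$genes
  if (length(genes) > 0L) {
    ord <- order(vapply(genes, `[[`, character(1L), "seq_region"),
                 vapply(genes, function(g) gene_span(g)[["start"]], integer(1L)),
                 vapply(genes, `[[`, character(1L), "gene_id"))
    genes <- genes[ord]
  }
  for (g in genes) {
    sp <- gene_span(g)
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    add(g$seq_region, if (g$biotype == "pseudogene") "pseudogene" else "gene",
        sp[["start"]], sp[["end"]], g$strand, gid, extra = g$biotype)
    add(g$seq_region, "mRNA", sp[["start"]], sp[["end"]], g$strand, tid, gid)
    for (i in seq_len(nrow(g$exons)))
      add(g$seq_region, "exon", g$exons[i, "start"], g$exons[i, "end"],
          g$strand, paste0(tid, ".exon", i), tid)
    if (nrow(g$cds) > 0L) {
      ## phase: number of bases to skip before the first full codon
      widths <- g$cds[, "end"] - g$cds[, "start"]
      ord_tx <- if (g$strand == "+") seq_len(nrow(g$cds)) else rev(seq_len(nrow(g$cds)))
      cum <- c(0L, cumsum(widths[ord_tx]))[seq_len(nrow(g$cds))]
      phase_tx <- (3L - cum %% 3L) %% 3L
      phase <- integer(nrow(g$cds))
      phase[ord_tx] <- phase_tx
      for (i in seq_len(nrow(g$cds))) {
        add(g$seq_region, "CDS", g$cds[i, "start"], g$cds[i, "end"],
            g$strand, paste0(tid, ".cds", i), tid)
        recs[[length(recs)]]$phase <- phase[[i]]
      }
    }
  }
  if (length(recs) == 0L) {
    writeLines("##gff-version 3", gff3_path)
    return(invisible(genome))
  }
  tab <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$id
  gr$Parent <- ifelse(is.na(tab$parent), NA_character_, tab$parent)
  gr$gene_biotype <- tab$extra
  gr$phase <- tab$phase
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(genome)
}

#' Structural validation of a genome's coding genes
#'
#' Checks that every protein-coding gene's spliced CDS starts with ATG, ends
#' with a stop codon, has length divisible by three and no internal stop.
#' Returns a data frame of violations (zero rows when clean); validation is
#' reporting only, the genome is not modified.
#'
#' @param genome An [annotated_genome()].
#' @return Data frame with columns `gene_id` and `problem`.
#' @export
validate_coding_genes <- function(genome) {
  out <- list()
  for (g in genome$genes) {
    if (g$biotype != "protein_coding") next
    cds <- extract_feature_sequence(genome, g, "cds")
    probs <- character(0L)
    if (nchar(cds) %% 3L != 0L) probs <- c(probs, "cds_length_not_multiple_of_3")
    if (substr(cds, 1L, 3L) != "ATG") probs <- c(probs, "missing_start_codon")
    if (nchar(cds) %% 3L == 0L) {
      aa <- translate_cds(cds, strict = FALSE)
      if (substr(aa, nchar(aa), nchar(aa)) != "*") probs <- c(probs, "missing_stop_codon")
      if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        probs <- c(probs, "internal_stop_codon")
    }
    for (p in probs)
      out[[length(out) + 1L]] <- data.frame(gene_id = g$gene_id, problem = p,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0L), problem = character(0L)))
  do.call(rbind, out)
}

#' Extract the annotated proteome of a genome
#'
#' Translations of the spliced CDS of every protein-coding gene (terminal
#' stop removed).
#'
#' @param genome An [annotated_genome()].
#' @return Named character vector of protein sequences (names = gene ids).
#' @export
proteome <- function(genome) {
  coding <- Filter(function(g) g$biotype == "protein_coding", genome$genes)
  if (length(coding) == 0L) return(setNames(character(0L), character(0L)))
  prots <- vapply(coding, function(g) {
    aa <- translate_cds(extract_feature_sequence(genome, g, "cds"), strict = FALSE)
    sub("\\*$", "", aa)
  }, character(1L))
  setNames(prots, vapply(coding, `[[`, character(1L), "gene_id"))
}
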