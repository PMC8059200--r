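# Independent oracles and shared fixtures. The oracles deliberately use
# different code paths from the package implementation.

# Plain-R affine-gap local alignment score (Gotoh recurrences, three
# matrices), independent of the C engine behind smith_waterman(). A gap of
# length L costs gap_open + L * gap_ext, matching the package's scheme.
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(E[i, j - 1L] - gap_ext, H[i, j - 1L] - gap_open - gap_ext)
      F[i, j] <- max(F[i - 1L, j] - gap_ext, H[i - 1L, j] - gap_open - gap_ext)
      s <- if (A[[i - 1L]] == B[[j - 1L]]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Naive codon-walking ORF scanner (stateful loop, unlike the vectorised
# implementation): maximal ORFs, ATG..stop inclusive, no N allowed.
naive_orf_scan <- function(seq, min_codons) {
  chars <- strsplit(seq, "")[[1L]]
  out <- list()
  for (f in 0:2) {
    i <- f + 1L
    atg <- NA_integer_
    while (i + 2L <= length(chars)) {
      codon <- paste0(chars[i:(i + 2L)], collapse = "")
      if (is.na(atg) && codon == "ATG") atg <- i
      if (codon %in% c("TAA", "TAG", "TGA")) {
        if (!is.na(atg)) {
          ncod <- (i + 3L - atg) %/% 3L
          orf <- paste0(chars[atg:(i + 2L)], collapse = "")
          if (ncod >= min_codons && !grepl("N", orf, fixed = TRUE))
            out[[length(out) + 1L]] <- c(frame = f, start = atg - 1L,
                                         end = i + 2L, codons = ncod)
        }
        atg <- NA_integer_
      }
      i <- i + 3L
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0L), start = integer(0L),
                      end = integer(0L), codons = integer(0L)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$frame), , drop = FALSE]
}

# Naive six-frame conserved-stop counter on a gapless equal-row alignment:
# a position p (0-based) holds a conserved stop if every row reads a stop
# codon at p; its frame label relative to anchor position a is
# (p - a) mod 3 -> +1/+2/+3.
naive_conserved_stops <- function(rows, anchor_pos) {
  L <- nchar(rows[[1L]])
  counts <- c(`+1` = 0L, `+2` = 0L, `+3` = 0L)
  for (p in 0:(L - 3L)) {
    codons <- vapply(rows, function(r) substr(r, p + 1L, p + 3L), character(1L))
    if (all(codons %in% c("TAA", "TAG", "TGA"))) {
      lab <- c("+1", "+2", "+3")[[(p - anchor_pos) %% 3L + 1L]]
      counts[[lab]] <- counts[[lab]] + 1L
    }
  }
  counts
}

# A 120-nt row: ATG anchor at position 0, no stops in the anchor (+1)
# frame, planted universal stops at +2 and +3 offsets.
frame_fixture_row <- function() {
  chars <- rep("C", 120L)
  chars[1:3] <- c("A", "T", "G")
  for (p in c(13L, 25L, 37L, 49L))        # 0-based p %% 3 == 1  -> +2 frame
    chars[(p + 1L):(p + 3L)] <- c("T", "A", "A")
  for (p in c(62L, 74L))                  # 0-based p %% 3 == 2  -> +3 frame
    chars[(p + 1L):(p + 3L)] <- c("T", "A", "A")
  paste0(chars, collapse = "")
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# A tiny two-gene genome used across genome_io tests: one plus-strand
# two-exon gene and one minus-strand single-exon gene.
tiny_genome <- function() {
  # layout: AAA | ATGCCC GTAAAG CCCGGGTAA | TTT | TTATTTCAT | CCC
  #          0     3..9    9..15   15..24   24.27  27..36     36..39
  chr1 <- paste0("AAA", "ATGCCC", "GTAAAG", "CCCGGGTAA", "TTT",
                 "TTATTTCAT", "CCC")
  # plus gene: two exons, canonical GT..AG intron; CDS = ATGCCCCCCGGGTAA
  gplus <- gene_model("gp", "chr1", "+", rbind(c(3, 9), c(15, 24)),
                      rbind(c(3, 9), c(15, 24)))
  # minus gene: genomic TTATTTCAT reads ATGAAATAA on the minus strand
  gminus <- gene_model("gm", "chr1", "-", rbind(c(27, 36)), rbind(c(27, 36)))
  annotated_genome("tiny", c(chr1 = chr1), list(gplus, gminus))
}

# Shared simulated clade (cached per test run): 20 conserved genes plus the
# three default planted events.
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_clade(n_genes = 20L, events = default_events(20L),
                               seed = 42L)
    cache
  }
})

# Gapless region_alignment built directly from rows of equal length; the
# coordinate table is synthetic (plus strand, starting at 0).
manual_alignment <- function(rows) {
  df <- data.frame(species = names(rows), seq_region = "chr1",
                   start = 0L, end = nchar(gsub("-", "", rows, fixed = TRUE)),
                   strand = "+", stringsAsFactors = FALSE)
  region_alignment(df, rows)
}
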