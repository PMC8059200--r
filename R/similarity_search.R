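## Local pairwise alignment with Karlin-Altschul significance, plus the hit
## post-processing used throughout the pipeline: coverage filtering,
## amalgamation of overlapping hits, and per-species capping. The alignment
## engine is seeded local dynamic programming: exact k-mer seeds locate
## candidate windows, each of which is resolved by affine-gap Smith-Waterman
## (Biostrings::pairwiseAlignment). A gap of length L costs
## gap_open + L * gap_extend.

#' Build a scoring scheme
#'
#' Bundles the substitution scores, affine gap penalties and Karlin-Altschul
#' parameters (lambda, K) used for local alignment significance. Defaults
#' mirror common BLAST settings: nucleotide +1/-2 with gap 5/2
#' (lambda = 1.28, K = 0.46), protein BLOSUM62 with gap 11/1
#' (lambda = 0.267, K = 0.041).
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param matrix Protein substitution matrix name (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (non-negative costs).
#' @param lambda,K Karlin-Altschul parameters; must be positive.
#' @param seed_k Word size for seeded search (11 nt / 4 aa by default).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 1, mismatch = -2,
                           matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL, seed_k = NULL) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    if (match <= 0 || mismatch >= 0) stop("need match > 0 and mismatch < 0")
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
    ## N scores 0 against everything: never seeds a positive alignment
    submat["N", ] <- 0; submat[, "N"] <- 0
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
    if (is.null(lambda)) lambda <- 1.28
    if (is.null(K)) K <- 0.46
    if (is.null(seed_k)) seed_k <- 11L
  } else {
    submat <- get(data(list = matrix, package = "Biostrings",
                       envir = environment()))
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
    if (is.null(seed_k)) seed_k <- 4L
  }
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(alphabet = alphabet, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, seed_k = as.integer(seed_k)),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
nucleotide_scheme <- function(...) scoring_scheme("nucleotide", ...)

#' @rdname scoring_scheme
#' @export
protein_scheme <- function(...) scoring_scheme("protein", ...)

.as_xstring <- function(s, scheme) {
  if (scheme$alphabet == "nucleotide") Biostrings::DNAString(s)
  else Biostrings::AAString(s)
}

#' Best local alignment of two sequences
#'
#' Affine-gap Smith-Waterman. When no cell scores positively the result is
#' the empty alignment with score 0. Intervals are 0-based half-open on the
#' input sequences.
#'
#' @param a,b Sequences (character strings) over the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @return List with `score`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `aligned_a`, `aligned_b`, `alignment_length` (number of columns).
#' @export
smith_waterman <- function(a, b, scheme) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    .as_xstring(a, scheme), .as_xstring(b, scheme), type = "local",
    substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  pat <- Biostrings::pattern(pa)
  if (sc <= 0 || nchar(as.character(pat)) == 0L)
    return(list(score = 0, a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                aligned_a = "", aligned_b = "", alignment_length = 0L))
  subj <- Biostrings::subject(pa)
  list(score = sc,
       a_start = Biostrings::start(pat) - 1L, a_end = Biostrings::end(pat),
       b_start = Biostrings::start(subj) - 1L, b_end = Biostrings::end(subj),
       aligned_a = as.character(pat), aligned_b = as.character(subj),
       alignment_length = nchar(as.character(pat)))
}

#' Karlin-Altschul expected hit count
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment of score `S`
#' between a query of length `m` and a search space of length `n`.
#'
#' @param score Alignment score (vectorised).
#' @param m,n Query length and search-space size; both positive.
#' @param scheme A [scoring_scheme()].
#' @return Expected number of chance hits of at least this score.
#' @export
evalue <- function(score, m, n, scheme) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

.empty_hits <- function() {
  data.frame(query_id = character(0L), genome = character(0L),
             seq_region = character(0L), s_start = integer(0L),
             s_end = integer(0L), strand = character(0L),
             q_start = integer(0L), q_end = integer(0L),
             q_len = integer(0L), score = numeric(0L),
             evalue = numeric(0L), coverage = numeric(0L),
             stringsAsFactors = FALSE)
}

## Precompute the k-mer seed dictionary of a query (built once per query
## orientation, reused across all subject regions).
.query_seeds <- function(query, k) {
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(query, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) return(list(empty = TRUE))
  km <- unique(kmers[keep])
  list(empty = FALSE, km = km, qpos = split(starts[keep], kmers[keep]),
       pd = Biostrings::PDict(Biostrings::DNAStringSet(km)), qlen = qlen)
}

## Seeded scan of one plus-strand region string; returns window intervals
## (0-based half-open) that share exact k-mers with the query.
.seed_windows <- function(seeds, qlen, region, k, band = 32L) {
  if (is.null(seeds)) {                      # query shorter than the word size
    return(if (nchar(region) <= 4L * qlen)
      matrix(c(0L, nchar(region)), ncol = 2L)
      else matrix(integer(0L), ncol = 2L))
  }
  if (seeds$empty || nchar(region) < k) return(matrix(integer(0L), ncol = 2L))
  km <- seeds$km
  qpos <- seeds$qpos
  mi <- Biostrings::matchPDict(seeds$pd, Biostrings::DNAString(region))
  sidx <- Biostrings::startIndex(mi)
  diag <- integer(0L); spos <- integer(0L)
  for (i in seq_along(km)) {
    s <- sidx[[i]]
    if (length(s) == 0L) next
    qp <- qpos[[km[[i]]]]
    grid <- expand.grid(s = s, q = qp)
    diag <- c(diag, grid$s - grid$q)
    spos <- c(spos, grid$s)
  }
  if (length(diag) == 0L) return(matrix(integer(0L), ncol = 2L))
  ## group nearby diagonals (indel tolerance ~2 bands); one window per group,
  ## never merged across distant diagonals so tandem copies stay separable
  bucket <- diag %/% band
  ub <- sort(unique(bucket))
  grp_id <- cumsum(c(1L, diff(ub) > 2L))
  grp_of <- setNames(grp_id, ub)
  grp <- grp_of[as.character(bucket)]
  qlen <- seeds$qlen
  iv <- do.call(rbind, lapply(split(spos, grp), function(s) {
    r <- range(s)
    c(max(0L, r[[1L]] - 1L - qlen), min(nchar(region), r[[2L]] + k - 1L + qlen))
  }))
  unique(iv)
}

.search_one_strand <- function(query, query_id, genome, region_id, region,
                               strand, n_space, scheme, max_e, min_cov,
                               seeds) {
  qlen <- nchar(query)
  q <- if (strand == "-") reverse_complement(query) else query
  wins <- .seed_windows(seeds, qlen, region, scheme$seed_k)
  hits <- list()
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    sw <- smith_waterman(q, substr(region, w[[1L]] + 1L, w[[2L]]), scheme)
    if (sw$score <= 0) next
    s_start <- w[[1L]] + sw$b_start
    s_end <- w[[1L]] + sw$b_end
    if (strand == "-") {
      q_start <- qlen - sw$a_end; q_end <- qlen - sw$a_start
    } else {
      q_start <- sw$a_start; q_end <- sw$a_end
    }
    e <- evalue(sw$score, qlen, n_space, scheme)
    cov <- (q_end - q_start) / qlen
    if (e > max_e || cov < min_cov) next
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = query_id, genome = genome, seq_region = region_id,
      s_start = s_start, s_end = s_end, strand = strand,
      q_start = q_start, q_end = q_end, q_len = qlen,
      score = sw$score, evalue = e, coverage = cov, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(.empty_hits())
  res <- do.call(rbind, hits)
  ## overlapping windows from distinct diagonal groups can rediscover the
  ## same alignment; keep one copy
  res[!duplicated(res[, c("s_start", "s_end", "q_start", "q_end")]), ,
      drop = FALSE]
}

#' Search a nucleotide query against genome databases
#'
#' Seeded local alignment of `query` against every sequence region of every
#' genome in `subjects`, on both strands. Minus-strand hits are reported in
#' plus-strand subject coordinates with `strand == "-"` and the query
#' interval reflected accordingly. Hits failing the e-value or query-coverage
#' thresholds are dropped (both boundaries inclusive: coverage exactly at
#' `min_cov` passes).
#'
#' @param query Nucleotide string.
#' @param subjects Named list of [annotated_genome()] objects.
#' @param scheme A nucleotide [scoring_scheme()].
#' @param max_e E-value threshold (default 1e-3).
#' @param min_cov Minimum query coverage (default 0.5).
#' @param query_id Label recorded in the hit table.
#' @return Hit table (one row per hit) with 0-based half-open intervals.
#' @export
search_genomes <- function(query, subjects, scheme = nucleotide_scheme(),
                           max_e = 1e-3, min_cov = 0.5, query_id = "query") {
  .assert_dna(query, "query")
  if (!nzchar(query)) stop("query must be non-empty")
  if (length(subjects) == 0L) return(.empty_hits())
  seeds <- list(`+` = .query_seeds(query, scheme$seed_k),
                `-` = .query_seeds(reverse_complement(query), scheme$seed_k))
  out <- list()
  for (gname in names(subjects)) {
    gen <- subjects[[gname]]
    n_space <- sum(nchar(gen$sequences))
    for (rid in names(gen$sequences)) {
      region <- gen$sequences[[rid]]
      for (strand in c("+", "-")) {
        out[[length(out) + 1L]] <- .search_one_strand(
          query, query_id, gname, rid, region, strand, n_space,
          scheme, max_e, min_cov, seeds[[strand]])
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$genome, res$seq_region, res$strand, res$s_start,
            res$s_end), , drop = FALSE]
}

#' Search a protein query against protein databases
#'
#' Scores the query against every subject protein (vectorised local DP),
#' keeps subjects whose e-value and query coverage pass the thresholds.
#' The search space `n` is the total residue count of the database.
#'
#' @param query Protein string.
#' @param subjects Named list (species -> named character vector of
#'   proteins).
#' @param scheme A protein [scoring_scheme()].
#' @inheritParams search_genomes
#' @return Data frame: `query_id`, `species`, `subject_id`, `score`,
#'   `evalue`, `coverage`.
#' @export
search_proteins <- function(query, subjects, scheme = protein_scheme(),
                            max_e = 1e-3, min_cov = 0.5, query_id = "query") {
  if (!nzchar(query)) stop("query must be non-empty")
  empty <- data.frame(query_id = character(0L), species = character(0L),
                      subject_id = character(0L), score = numeric(0L),
                      evalue = numeric(0L), coverage = numeric(0L),
                      stringsAsFactors = FALSE)
  if (length(subjects) == 0L) return(empty)
  db_species <- rep(names(subjects), lengths(subjects))
  db_ids <- unlist(lapply(subjects, names), use.names = FALSE)
  db_seqs <- unlist(subjects, use.names = FALSE)
  if (length(db_seqs) == 0L) return(empty)
  n_space <- sum(nchar(db_seqs))
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db_seqs), Biostrings::AAString(query),
    type = "local", substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  e <- evalue(pmax(scores, 0), nchar(query), n_space, scheme)
  cand <- which(scores > 0 & e <= max_e)
  rows <- list()
  for (i in cand) {
    sw <- smith_waterman(query, db_seqs[[i]], scheme)
    cov <- (sw$a_end - sw$a_start) / nchar(query)
    if (cov < min_cov) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = query_id, species = db_species[[i]], subject_id = db_ids[[i]],
      score = sw$score, evalue = e[[i]], coverage = cov,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  res[order(res$evalue, -res$score, res$species, res$subject_id), , drop = FALSE]
}

#' Amalgamate overlapping hits
#'
#' Hits from the same query on the same genome, sequence region and strand
#' whose subject intervals overlap or are bookended are merged into their
#' union. The merged hit keeps the minimum e-value and maximum score; its
#' coverage is recomputed from the merged hits' aligned query span. The
#' operation is idempotent and independent of input order.
#'
#' @param hits Hit table from [search_genomes()].
#' @return Merged hit table, sorted.
#' @export
amalgamate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$query_id, hits$genome, hits$seq_region, hits$strand,
               sep = "\r")
  out <- lapply(split(hits, key), function(h) {
    ir <- IRanges::IRanges(start = h$s_start + 1L, end = h$s_end)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    do.call(rbind, lapply(seq_along(red), function(j) {
      sub <- h[grp == j, , drop = FALSE]
      qs <- min(sub$q_start); qe <- max(sub$q_end)
      data.frame(query_id = sub$query_id[[1L]], genome = sub$genome[[1L]],
                 seq_region = sub$seq_region[[1L]],
                 s_start = IRanges::start(red)[[j]] - 1L,
                 s_end = IRanges::end(red)[[j]],
                 strand = sub$strand[[1L]],
                 q_start = qs, q_end = qe, q_len = sub$q_len[[1L]],
                 score = max(sub$score), evalue = min(sub$evalue),
                 coverage = (qe - qs) / sub$q_len[[1L]],
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query_id, res$genome, res$seq_region, res$strand,
            res$s_start, res$s_end), , drop = FALSE]
}

#' Cap an oversized hit list
#'
#' When the total number of hits exceeds `total_limit`, hits are ordered by
#' e-value and only the `per_species_keep` best hits per subject species are
#' retained (ties broken by higher score, then by coordinates). At or below
#' the limit the input is returned unchanged.
#'
#' @param hits Hit table with `genome` (or `species`) and `evalue` columns.
#' @param total_limit Threshold above which capping triggers (default 1000).
#' @param per_species_keep Hits kept per species when capping (default 5).
#' @return Possibly reduced hit table.
#' @export
cap_hits <- function(hits, total_limit = 1000L, per_species_keep = 5L) {
  if (nrow(hits) <= total_limit) return(hits)
  sp_col <- if ("genome" %in% names(hits)) "genome" else "species"
  parts <- split(hits, hits[[sp_col]])
  kept <- lapply(parts, function(h) {
    ord <- order(h$evalue, -h$score,
                 if ("s_start" %in% names(h)) h$s_start else seq_len(nrow(h)))
    h[head(ord, per_species_keep), , drop = FALSE]
  })
  res <- do.call(rbind, kept)
  rownames(res) <- NULL
  res
}

#' Intragenomic duplicates of a genomic region
#'
#' Searches a region of a genome against that same genome and reports all
#' non-self hits (hits overlapping the source interval on the same region
#' are excluded). A non-empty result flags a duplication-and-loss risk for
#' the origin classifier.
#'
#' @param genome An [annotated_genome()].
#' @param seq_region Region id within the genome.
#' @param interval Length-2 integer vector, 0-based half-open.
#' @param scheme A nucleotide [scoring_scheme()].
#' @inheritParams search_genomes
#' @return Hit table of non-self hits.
#' @export
intragenomic_duplicates <- function(genome, seq_region, interval,
                                    scheme = nucleotide_scheme(),
                                    max_e = 1e-3, min_cov = 0.5) {
  seqs <- genome$sequences
  if (!seq_region %in% names(seqs)) stop("unknown sequence region")
  region <- substr(seqs[[seq_region]], interval[[1L]] + 1L, interval[[2L]])
  hits <- search_genomes(region, setNames(list(genome), genome$species_id),
                         scheme, max_e, min_cov, query_id = "region")
  self <- hits$seq_region == seq_region &
    hits$s_start < interval[[2L]] & hits$s_end > interval[[1L]]
  hits[!self, , drop = FALSE]
}

#' Write hits as a BLAST-like tab-separated table
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
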