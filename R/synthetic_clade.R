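## Synthetic clade generator: evolves an annotated ancestral genome down a
## species tree (Jukes-Cantor substitutions plus Poisson indels with
## geometric lengths) while lifting annotation coordinates through every
## indel, and plants evolutionary events -- de novo ORF birth, duplication
## followed by accelerated divergence, pseudogenization, gene loss -- each
## recorded in a ground-truth table. Coding sequence evolves under a simple
## purifying-selection emulation: a reduced substitution rate, rejection of
## stop-creating changes, frozen start/stop codons and splice dinucleotides,
## and no indels inside CDS.

DNA_BASES <- c("A", "C", "G", "T")

.jc_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))

.random_dna_chars <- function(n) sample(DNA_BASES, n, replace = TRUE)

.non_stop_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
                collapse = "")
  setdiff(all3, STOP_CODONS)
}

## Random ORF of n_codons codons (ATG ... TAA), with a guaranteed internal
## Met at ~40% so that truncation scenarios retain a downstream start.
.random_cds <- function(n_codons) {
  pool <- setdiff(.non_stop_codons(), "ATG")
  body <- sample(pool, n_codons - 2L, replace = TRUE)
  body[[max(1L, round(0.4 * n_codons))]] <- "ATG"
  c("ATG", body, "TAA")
}

## Gene sequence with optional single intron (canonical GT..AG) inserted
## between two codons. Returns chars plus exon/cds intervals relative to the
## gene start (0-based half-open).
.make_gene_parts <- function(n_codons, intron_len = 0L) {
  codons <- .random_cds(n_codons)
  cds_len <- 3L * n_codons
  if (intron_len <= 0L) {
    chars <- unlist(strsplit(paste0(codons, collapse = ""), ""))
    return(list(chars = chars,
                exons = matrix(c(0L, cds_len), ncol = 2L),
                cds = matrix(c(0L, cds_len), ncol = 2L)))
  }
  if (intron_len < 4L) stop("intron_len must be 0 or >= 4")
  k <- max(1L, n_codons %/% 2L)          # split after codon k
  left <- paste0(codons[seq_len(k)], collapse = "")
  right <- paste0(codons[(k + 1L):n_codons], collapse = "")
  intr <- paste0("GT", paste0(.random_dna_chars(intron_len - 4L), collapse = ""), "AG")
  chars <- unlist(strsplit(paste0(left, intr, right), ""))
  e1 <- c(0L, 3L * k)
  e2 <- c(3L * k + intron_len, 3L * k + intron_len + nchar(right))
  list(chars = chars,
       exons = rbind(e1, e2, deparse.level = 0L),
       cds = rbind(e1, e2, deparse.level = 0L))
}

#' Default five-species tree of the study clade
#'
#' A rooted binary tree with the focal pair (dsim, dsec) splitting ~0.5 time
#' units ago, their split from dmel ~1.4 units ago and the split from the
#' (dyak, dere) outgroup clade ~3.3 units ago. Time units are mapped to
#' branch lengths in expected substitutions per site by `subst_per_unit`.
#' Internal nodes are labelled (`simsec`, `simsecmel`, `yakere`, `root`) so
#' that events can target branches by the label of the child node.
#'
#' @param subst_per_unit Expected neutral substitutions per site per time
#'   unit (default 0.03).
#' @return An [ape::phylo] tree.
#' @export
default_species_tree <- function(subst_per_unit = 0.03) {
  nwk <- paste0("(((dsim:0.5,dsec:0.5)simsec:0.9,dmel:1.4)simsecmel:1.9,",
                "(dyak:1.4,dere:1.4)yakere:1.9)root;")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * subst_per_unit
  tr
}

#' Specify a planted evolutionary event
#'
#' @param type One of `"de_novo_birth"`, `"duplication_divergence"`,
#'   `"pseudogenization"`, `"gene_loss"`.
#' @param branch Label of the node whose incoming branch carries the event
#'   (`"root"` places it in the common ancestor).
#' @param locus_id Identifier of the planted locus; becomes the gene id for
#'   births and duplicate copies.
#' @param orf_codons,intron_len De novo ORF size (codons, incl. stop) and
#'   intron length in nt (0 = intronless; 52 by default, deliberately not a
#'   multiple of 3).
#' @param n_ancestral_stops Number of in-frame stop codons planted in the
#'   ancestral (pre-birth) copy of a de novo locus. The default of 6 for a
#'   120-codon locus approximates the stop density of random noncoding
#'   sequence (about one stop per 21 codons per frame).
#' @param src_gene Existing gene acted on (duplication source,
#'   pseudogenization or loss target).
#' @param insert_after Gene after whose downstream intergenic gap new
#'   sequence is inserted (births and duplications).
#' @param rate_mult Substitution rate multiplier for a diverging duplicate.
#' @return An `event_spec` list.
#' @export
event_spec <- function(type, branch, locus_id,
                       orf_codons = 120L, intron_len = 52L,
                       n_ancestral_stops = 6L,
                       src_gene = NULL, insert_after = NULL,
                       rate_mult = 10) {
  type <- match.arg(type, c("de_novo_birth", "duplication_divergence",
                            "pseudogenization", "gene_loss"))
  structure(list(type = type, branch = branch, locus_id = locus_id,
                 orf_codons = as.integer(orf_codons),
                 intron_len = as.integer(intron_len),
                 n_ancestral_stops = as.integer(n_ancestral_stops),
                 src_gene = src_gene, insert_after = insert_after,
                 rate_mult = rate_mult),
            class = "event_spec")
}

#' Default planted events for a benchmark clade
#'
#' One de novo birth on the focal (dsim, dsec) stem, one duplicate copied in
#' the common ancestor and diverging at ten times the coding rate, and one
#' pseudogenization on the (dyak, dere) stem that mimics an apparent TRGF.
#'
#' @param n_genes Number of conserved background genes in the clade.
#' @return List of [event_spec()] objects.
#' @export
default_events <- function(n_genes = 50L) {
  g <- function(i) sprintf("g%03d", i)
  list(
    event_spec("de_novo_birth", "simsec", "trg1",
               insert_after = g(max(1L, n_genes %/% 3L))),
    event_spec("duplication_divergence", "root", "dup1",
               src_gene = g(max(1L, n_genes %/% 2L)),
               insert_after = g(max(1L, (4L * n_genes) %/% 5L)),
               rate_mult = 10),
    event_spec("pseudogenization", "yakere", "ps1",
               src_gene = g(max(1L, n_genes %/% 4L)))
  )
}

#' Evolve a bare nucleotide sequence along a branch
#'
#' Jukes-Cantor substitutions (per-site endpoint sampling at divergence
#' `branch_length`, in expected substitutions per site) plus indels arising
#' as Poisson events at `indel_rate` times the substitution rate with
#' geometric lengths (mean `indel_mean_len`). Deterministic given the RNG
#' state (use `set.seed()` before calling, or pass `seed`).
#'
#' @param seq Nucleotide string.
#' @param branch_length Expected substitutions per site; must be >= 0.
#' @param indel_rate Indel events per substitution (default 0.1).
#' @param indel_mean_len Mean indel length in nt (default 3).
#' @param seed Optional integer seed.
#' @return List with `seq` (evolved string) and `log` (data frame of
#'   mutation events: type, pos, from, to, length).
#' @export
evolve_sequence <- function(seq, branch_length, indel_rate = 0.1,
                            indel_mean_len = 3, seed = NULL) {
  .assert_dna(seq)
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (indel_rate < 0 || indel_mean_len <= 0) stop("negative rates not allowed")
  if (!is.null(seed)) set.seed(seed)
  chars <- if (nchar(seq)) unlist(strsplit(seq, "")) else character(0L)
  log <- list()
  if (branch_length == 0 || length(chars) == 0L)
    return(list(seq = seq, log = data.frame(type = character(0L), pos = integer(0L),
                                            from = character(0L), to = character(0L),
                                            length = integer(0L))))
  ## substitutions
  p <- .jc_p(branch_length)
  hit <- which(runif(length(chars)) < p & chars %in% DNA_BASES)
  for (i in hit) {
    new <- sample(setdiff(DNA_BASES, chars[[i]]), 1L)
    log[[length(log) + 1L]] <- data.frame(type = "substitution", pos = i - 1L,
                                          from = chars[[i]], to = new, length = 1L)
    chars[[i]] <- new
  }
  ## indels
  n_ind <- rpois(1L, indel_rate * branch_length * length(chars))
  if (n_ind > 0L) {
    pos <- sort(sample.int(length(chars), min(n_ind, length(chars))),
                decreasing = TRUE)
    for (pp in pos) {
      len <- min(rgeom(1L, 1 / indel_mean_len) + 1L, 4L * indel_mean_len)
      if (runif(1L) < 0.5) {           # insertion before pp (1-based)
        ins <- .random_dna_chars(len)
        chars <- append(chars, ins, after = pp - 1L)
        log[[length(log) + 1L]] <- data.frame(type = "insertion", pos = pp - 1L,
                                              from = "", to = paste0(ins, collapse = ""),
                                              length = len)
      } else {
        d2 <- min(pp + len - 1L, length(chars))
        log[[length(log) + 1L]] <- data.frame(type = "deletion", pos = pp - 1L,
                                              from = paste0(chars[pp:d2], collapse = ""),
                                              to = "", length = d2 - pp + 1L)
        chars <- chars[-(pp:d2)]
      }
    }
  }
  list(seq = paste0(chars, collapse = ""),
       log = if (length(log)) do.call(rbind, rev(log))
             else data.frame(type = character(0L), pos = integer(0L),
                             from = character(0L), to = character(0L),
                             length = integer(0L)))
}

## ---- internal simulation state --------------------------------------------
## state$seq   character vector of single bases
## state$feats data.frame(gene_id, kind(exon|cds), start, end)  0-based h.o.
## state$genes data.frame(gene_id, strand, biotype, protected, rate_mult)
## state$loci  data.frame(locus_id, event, start, end)

.lift_insert <- function(df, pos, len) {
  if (nrow(df) == 0L) return(df)
  df$start <- ifelse(df$start >= pos, df$start + len, df$start)
  df$end <- ifelse(df$end > pos, df$end + len, df$end)
  df
}

.lift_delete <- function(df, d1, d2) {
  if (nrow(df) == 0L) return(df)
  df$start <- df$start - (pmin(df$start, d2) - pmin(df$start, d1))
  df$end <- df$end - (pmin(df$end, d2) - pmin(df$end, d1))
  df[df$end > df$start, , drop = FALSE]
}

## positions (1-based indices into state$seq) of the spliced CDS of a gene,
## in translation order (simulated genes are plus-strand)
.cds_positions <- function(state, gid) {
  cd <- state$feats[state$feats$gene_id == gid & state$feats$kind == "cds", ,
                    drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  unlist(lapply(seq_len(nrow(cd)), function(i) (cd$start[[i]] + 1L):cd$end[[i]]))
}

.splice_positions <- function(state) {
  out <- integer(0L)
  for (gid in unique(state$feats$gene_id)) {
    ex <- state$feats[state$feats$gene_id == gid & state$feats$kind == "exon", ,
                      drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      i_start <- ex$end[[i]]; i_end <- ex$start[[i + 1L]]
      if (i_end - i_start >= 4L)
        out <- c(out, i_start + 1L, i_start + 2L, i_end - 1L, i_end)
    }
  }
  out
}

.evolve_state <- function(state, bl, cfg) {
  if (bl == 0) return(state)
  L <- length(state$seq)
  coding <- logical(L); frozen <- logical(L)
  coding_genes <- state$genes$gene_id[state$genes$biotype == "protein_coding" &
                                        state$genes$protected]
  cds_pos <- lapply(setNames(nm = coding_genes), .cds_positions, state = state)
  for (gid in coding_genes) {
    sp <- cds_pos[[gid]]
    coding[sp] <- TRUE
    frozen[c(head(sp, 3L), tail(sp, 3L))] <- TRUE   # start + stop codons
  }
  frozen[.splice_positions(state)] <- TRUE

  ## noncoding substitutions
  p_nc <- .jc_p(bl)
  idx <- which(!coding & !frozen)
  hit <- idx[runif(length(idx)) < p_nc]
  hit <- hit[state$seq[hit] %in% DNA_BASES]
  if (length(hit)) {
    cur <- state$seq[hit]
    state$seq[hit] <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                             character(1L), USE.NAMES = FALSE)
  }

  ## coding substitutions with stop-codon rejection
  for (gid in coding_genes) {
    gmeta <- state$genes[state$genes$gene_id == gid, ]
    d <- bl * cfg$cds_rate_factor * gmeta$rate_mult
    sp <- cds_pos[[gid]]
    body <- sp[-c(seq_len(3L), (length(sp) - 2L):length(sp))]
    cand <- body[runif(length(body)) < .jc_p(d)]
    for (pos in cand) {
      i <- match(pos, sp)
      ci <- (i - 1L) %/% 3L
      cpos <- sp[(3L * ci + 1L):(3L * ci + 3L)]
      new <- sample(setdiff(DNA_BASES, state$seq[[pos]]), 1L)
      codon <- state$seq[cpos]
      codon[[match(pos, cpos)]] <- new
      if (paste0(codon, collapse = "") %in% STOP_CODONS) next
      state$seq[[pos]] <- new
    }
  }

  ## indels in noncoding, non-frozen sequence
  allowed <- !coding & !frozen
  n_ind <- rpois(1L, cfg$indel_rate_factor * bl * L)
  if (n_ind > 0L) {
    ok <- which(allowed)
    pos <- sort(sample(ok, min(n_ind, length(ok))), decreasing = TRUE)
    ## events are applied right to left so that original coordinates stay
    ## valid; min_touched caps each deletion below the previous event's span
    min_touched <- L + 1L
    for (pp in pos) {
      len <- min(rgeom(1L, 1 / cfg$indel_mean_len) + 1L, cfg$indel_max_len)
      if (runif(1L) < 0.5) {
        state$seq <- append(state$seq, .random_dna_chars(len), after = pp - 1L)
        state$feats <- .lift_insert(state$feats, pp - 1L, len)
        state$loci <- .lift_insert(state$loci, pp - 1L, len)
      } else {
        d2 <- pp
        while (d2 - pp + 1L < len && d2 + 1L < min_touched &&
               d2 + 1L <= L && allowed[[d2 + 1L]]) d2 <- d2 + 1L
        state$seq <- state$seq[-(pp:d2)]
        state$feats <- .lift_delete(state$feats, pp - 1L, d2)
        state$loci <- .lift_delete(state$loci, pp - 1L, d2)
      }
      min_touched <- pp
    }
  }
  state
}

## replace [s,e) with new_chars, lifting everything downstream
.replace_span <- function(state, s, e, new_chars) {
  L <- length(state$seq)
  state$seq <- c(if (s > 0L) state$seq[seq_len(s)] else character(0L),
                 new_chars,
                 if (e < L) state$seq[(e + 1L):L] else character(0L))
  delta <- length(new_chars) - (e - s)
  if (delta != 0L) {
    shift <- function(df) {
      if (nrow(df) == 0L) return(df)
      df$start <- ifelse(df$start >= e, df$start + delta, df$start)
      df$end <- ifelse(df$end >= e, df$end + delta, df$end)
      df
    }
    state$feats <- shift(state$feats)
    state$loci <- shift(state$loci)
  }
  state
}

.add_gene_feats <- function(state, gid, offset, parts) {
  for (i in seq_len(nrow(parts$exons)))
    state$feats <- rbind(state$feats, data.frame(
      gene_id = gid, kind = "exon",
      start = offset + parts$exons[i, 1L], end = offset + parts$exons[i, 2L]))
  for (i in seq_len(nrow(parts$cds)))
    state$feats <- rbind(state$feats, data.frame(
      gene_id = gid, kind = "cds",
      start = offset + parts$cds[i, 1L], end = offset + parts$cds[i, 2L]))
  state
}

.gene_span_state <- function(state, gid) {
  f <- state$feats[state$feats$gene_id == gid, , drop = FALSE]
  if (nrow(f) == 0L) stop("gene ", gid, " not in state")
  c(min(f$start), max(f$end))
}

## midpoint of the intergenic gap downstream of gene gid
.gap_after <- function(state, gid) {
  sp <- .gene_span_state(state, gid)
  ends <- state$feats$end
  starts <- state$feats$start
  nxt <- suppressWarnings(min(starts[starts >= sp[[2L]]]))
  if (!is.finite(nxt)) nxt <- length(state$seq)
  as.integer((sp[[2L]] + nxt) %/% 2L)
}

.apply_event <- function(state, ev, planted) {
  if (ev$type == "de_novo_birth") {
    li <- which(state$loci$locus_id == ev$locus_id)
    s <- state$loci$start[[li]]; e <- state$loci$end[[li]]
    parts <- planted[[ev$locus_id]]$parts
    state <- .replace_span(state, s, e, parts$chars)
    state$loci$end[[li]] <- s + length(parts$chars)
    state <- .add_gene_feats(state, ev$locus_id, s, parts)
    state$genes <- rbind(state$genes, data.frame(
      gene_id = ev$locus_id, strand = "+", biotype = "protein_coding",
      protected = TRUE, rate_mult = 1))
  } else if (ev$type == "duplication_divergence") {
    sp <- .gene_span_state(state, ev$src_gene)
    chars <- state$seq[(sp[[1L]] + 1L):sp[[2L]]]
    f <- state$feats[state$feats$gene_id == ev$src_gene, , drop = FALSE]
    parts <- list(chars = chars,
                  exons = as.matrix(cbind(f$start[f$kind == "exon"],
                                          f$end[f$kind == "exon"])) - sp[[1L]],
                  cds = as.matrix(cbind(f$start[f$kind == "cds"],
                                        f$end[f$kind == "cds"])) - sp[[1L]])
    pos <- .gap_after(state, ev$insert_after)
    state <- .replace_span(state, pos, pos, chars)
    state <- .add_gene_feats(state, ev$locus_id, pos, parts)
    state$genes <- rbind(state$genes, data.frame(
      gene_id = ev$locus_id, strand = "+", biotype = "protein_coding",
      protected = TRUE, rate_mult = ev$rate_mult))
    state$loci <- rbind(state$loci, data.frame(
      locus_id = ev$locus_id, event = ev$type,
      start = pos, end = pos + length(chars)))
  } else if (ev$type == "pseudogenization") {
    sp0 <- .cds_positions(state, ev$src_gene)
    n_codons <- length(sp0) %/% 3L
    ci <- max(2L, round(0.35 * n_codons))
    cpos <- sp0[(3L * (ci - 1L) + 1L):(3L * ci)]
    state$seq[cpos] <- c("T", "A", "A")          # premature stop
    gi <- which(state$genes$gene_id == ev$src_gene)
    state$genes$biotype[[gi]] <- "pseudogene"
    state$genes$protected[[gi]] <- FALSE
    state$feats <- state$feats[!(state$feats$gene_id == ev$src_gene &
                                   state$feats$kind == "cds"), , drop = FALSE]
    sp <- .gene_span_state(state, ev$src_gene)
    state$loci <- rbind(state$loci, data.frame(
      locus_id = ev$locus_id, event = ev$type, start = sp[[1L]], end = sp[[2L]]))
  } else if (ev$type == "gene_loss") {
    sp <- .gene_span_state(state, ev$src_gene)
    state$feats <- state$feats[state$feats$gene_id != ev$src_gene, , drop = FALSE]
    state$genes <- state$genes[state$genes$gene_id != ev$src_gene, , drop = FALSE]
    state <- .replace_span(state, sp[[1L]], sp[[2L]], character(0L))
    state$loci <- rbind(state$loci, data.frame(
      locus_id = ev$locus_id, event = ev$type, start = sp[[1L]], end = sp[[1L]] + 1L))
  }
  state
}

.state_to_genome <- function(state, species_id) {
  seq <- paste0(state$seq, collapse = "")
  genes <- list()
  for (i in seq_len(nrow(state$genes))) {
    gm <- state$genes[i, ]
    f <- state$feats[state$feats$gene_id == gm$gene_id, , drop = FALSE]
    ex <- f[f$kind == "exon", , drop = FALSE]
    cd <- f[f$kind == "cds", , drop = FALSE]
    genes[[length(genes) + 1L]] <- gene_model(
      gm$gene_id, "chr1", gm$strand,
      cbind(ex$start, ex$end),
      if (nrow(cd)) cbind(cd$start, cd$end) else NULL,
      gm$biotype)
  }
  annotated_genome(species_id, c(chr1 = seq), genes)
}

#' Simulate an annotated genome clade with planted events
#'
#' Builds a random ancestral genome (`n_genes` conserved protein-coding
#' genes, about half of them with a single canonical intron, separated by
#' random intergenic spacers), plants the proto-loci required by the events,
#' then evolves the genome down `tree`. A de novo birth locus exists at the
#' root as a disrupted, unannotated sequence (its ORF broken by
#' `n_ancestral_stops` stop codons and a mutated start); on the event branch
#' the intact ORF replaces it ("enabling mutations") and the gene is
#' annotated in all descendant species, while the other species carry the
#' still-degrading homologous noncoding sequence.
#'
#' @param tree Species tree from [default_species_tree()] (branch lengths in
#'   expected substitutions per site, nodes labelled).
#' @param n_genes Number of conserved background genes (default 50).
#' @param events List of [event_spec()] (default [default_events()]).
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @param cds_rate_factor Coding vs neutral substitution rate ratio
#'   (default 0.2).
#' @param indel_rate_factor Indel events per substitution (default 0.1).
#' @param indel_mean_len,indel_max_len Geometric indel length mean and cap.
#' @param intergenic_mean Mean intergenic spacer length in nt (default 300).
#' @param orf_codon_range Range of conserved-gene ORF lengths in codons.
#' @param intron_prob Probability a background gene has an intron.
#' @param intron_len_range Range of background intron lengths in nt.
#' @return List with `genomes` (named list of [annotated_genome()]), `truth`
#'   (data frame: locus_id, event, species, seq_region, start, end, coding)
#'   and `events`.
#' @export
simulate_clade <- function(tree = default_species_tree(), n_genes = 50L,
                           events = default_events(n_genes), seed = 1L,
                           cds_rate_factor = 0.2, indel_rate_factor = 0.1,
                           indel_mean_len = 3, indel_max_len = 12L,
                           intergenic_mean = 300L,
                           orf_codon_range = c(100L, 140L),
                           intron_prob = 0.5,
                           intron_len_range = c(50L, 70L)) {
  set.seed(seed)
  cfg <- list(cds_rate_factor = cds_rate_factor,
              indel_rate_factor = indel_rate_factor,
              indel_mean_len = indel_mean_len, indel_max_len = indel_max_len)
  labels <- c(tree$tip.label, tree$node.label)
  ev_branches <- vapply(events, `[[`, character(1L), "branch")
  bad <- setdiff(ev_branches, labels)
  if (length(bad)) stop("event branch(es) not in tree: ", paste(bad, collapse = ", "))

  ## ancestral genome
  state <- list(seq = character(0L),
                feats = data.frame(gene_id = character(0L), kind = character(0L),
                                   start = integer(0L), end = integer(0L)),
                genes = data.frame(gene_id = character(0L), strand = character(0L),
                                   biotype = character(0L), protected = logical(0L),
                                   rate_mult = numeric(0L)),
                loci = data.frame(locus_id = character(0L), event = character(0L),
                                  start = integer(0L), end = integer(0L)))
  for (i in seq_len(n_genes)) {
    spacer <- .random_dna_chars(intergenic_mean + sample(-50L:50L, 1L))
    state$seq <- c(state$seq, spacer)
    n_cod <- sample(orf_codon_range[[1L]]:orf_codon_range[[2L]], 1L)
    ilen <- if (runif(1L) < intron_prob)
      sample(intron_len_range[[1L]]:intron_len_range[[2L]], 1L) else 0L
    parts <- .make_gene_parts(n_cod, ilen)
    gid <- sprintf("g%03d", i)
    offset <- length(state$seq)
    state$seq <- c(state$seq, parts$chars)
    state <- .add_gene_feats(state, gid, offset, parts)
    state$genes <- rbind(state$genes, data.frame(
      gene_id = gid, strand = "+", biotype = "protein_coding",
      protected = TRUE, rate_mult = 1))
  }
  state$seq <- c(state$seq, .random_dna_chars(intergenic_mean))

  ## plant proto-loci for de novo births; pristine parts kept aside
  planted <- list()
  for (ev in events) {
    if (ev$type != "de_novo_birth") next
    parts <- .make_gene_parts(ev$orf_codons, ev$intron_len)
    planted[[ev$locus_id]] <- list(parts = parts)
    ## ancestral (pre-birth) version: broken start + planted in-frame stops
    anc <- parts$chars
    cds_rel <- unlist(lapply(seq_len(nrow(parts$cds)),
                             function(i) (parts$cds[i, 1L] + 1L):parts$cds[i, 2L]))
    anc[[cds_rel[[3L]]]] <- "A"                      # ATG -> ATA
    n_cod <- length(cds_rel) %/% 3L
    stop_at <- round(seq(0.1, 0.9, length.out = max(1L, ev$n_ancestral_stops)) * n_cod)
    for (ci in stop_at) {
      cpos <- cds_rel[(3L * (ci - 1L) + 1L):(3L * ci)]
      anc[cpos] <- unlist(strsplit(sample(STOP_CODONS, 1L), ""))
    }
    pos <- .gap_after(state, ev$insert_after)
    state <- .replace_span(state, pos, pos, anc)
    state$loci <- rbind(state$loci, data.frame(
      locus_id = ev$locus_id, event = ev$type,
      start = pos, end = pos + length(anc)))
  }

  ## events on the root apply to the ancestor itself
  for (ev in events) if (ev$branch == "root") state <- .apply_event(state, ev, planted)

  ## recursion down the tree
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  edge_len <- setNames(tree$edge.length, tree$edge[, 2L])
  node_label <- function(n) if (n <= ntip) tree$tip.label[[n]] else
    tree$node.label[[n - ntip]]
  genomes <- list(); truths <- list()

  descend <- function(node, state) {
    lab <- node_label(node)
    if (node <= ntip) {
      genomes[[lab]] <<- .state_to_genome(state, lab)
      for (ev in events) {
        li <- which(state$loci$locus_id == ev$locus_id)
        if (length(li) == 1L) {
          coding <- ev$locus_id %in% state$genes$gene_id[
            state$genes$biotype == "protein_coding"]
          if (ev$type == "pseudogenization") coding <- FALSE
          truths[[length(truths) + 1L]] <<- data.frame(
            locus_id = ev$locus_id, event = ev$type, species = lab,
            seq_region = "chr1",
            start = state$loci$start[[li]], end = state$loci$end[[li]],
            coding = coding)
        } else if (ev$type %in% c("pseudogenization", "gene_loss")) {
          ## event not on this lineage: report the intact source gene
          if (ev$src_gene %in% state$genes$gene_id) {
            sp <- .gene_span_state(state, ev$src_gene)
            truths[[length(truths) + 1L]] <<- data.frame(
              locus_id = ev$locus_id, event = ev$type, species = lab,
              seq_region = "chr1", start = sp[[1L]], end = sp[[2L]],
              coding = TRUE)
          }
        }
      }
      return(invisible(NULL))
    }
    for (child in children[[as.character(node)]]) {
      st <- .evolve_state(state, edge_len[[as.character(child)]], cfg)
      clab <- node_label(child)
      for (ev in events)
        if (ev$branch == clab) st <- .apply_event(st, ev, planted)
      descend(child, st)
    }
  }
  descend(ntip + 1L, state)

  genomes <- genomes[tree$tip.label]
  truth <- if (length(truths)) do.call(rbind, truths)
    else data.frame(locus_id = character(0L), event = character(0L),
                    species = character(0L), seq_region = character(0L),
                    start = integer(0L), end = integer(0L),
                    coding = logical(0L))
  truth <- truth[order(truth$locus_id, truth$species), , drop = FALSE]
  rownames(truth) <- NULL
  sim <- list(genomes = genomes, truth = truth, events = events, seed = seed)
  check_simulation(sim)
  sim
}

#' Verify simulator ground truth against the emitted annotations
#'
#' Checks that (i) every annotated protein-coding CDS in every leaf genome
#' translates without internal stop codons, (ii) every truth-table row
#' marked coding corresponds to an annotated protein-coding gene whose span
#' matches the recorded coordinates, and (iii) pseudogenized rows are
#' annotated with the pseudogene biotype.
#'
#' @param sim Result of [simulate_clade()].
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
check_simulation <- function(sim) {
  for (sp in names(sim$genomes)) {
    v <- validate_coding_genes(sim$genomes[[sp]])
    if (nrow(v) > 0L)
      stop("simulation emitted invalid coding gene(s) in ", sp, ": ",
           paste(unique(v$gene_id), collapse = ", "))
  }
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    gen <- sim$genomes[[row$species]]
    ev <- Filter(function(e) e$locus_id == row$locus_id, sim$events)[[1L]]
    gid <- if (ev$type %in% c("pseudogenization", "gene_loss")) ev$src_gene
           else ev$locus_id
    if (row$coding) {
      g <- gen$genes[[gid]]
      if (is.null(g)) stop("truth row ", i, ": gene ", gid, " missing in ",
                           row$species)
      sp <- gene_span(g)
      if (ev$type %in% c("de_novo_birth")) {
        if (sp[["start"]] < row$start || sp[["end"]] > row$end)
          stop("truth row ", i, ": coordinates disagree with annotation")
      }
    } else if (ev$type == "pseudogenization" &&
               row$species %in% .species_under(sim, ev$branch)) {
      g <- gen$genes[[gid]]
      if (is.null(g) || g$biotype != "pseudogene")
        stop("truth row ", i, ": expected pseudogene annotation in ", row$species)
    }
  }
  invisible(TRUE)
}

## leaves under the branch ending at label `lab` (the label's clade)
.species_under <- function(sim, lab) {
  clades <- list(dsim = "dsim", dsec = "dsec", dmel = "dmel", dyak = "dyak",
                 dere = "dere",
                 simsec = c("dsim", "dsec"),
                 simsecmel = c("dsim", "dsec", "dmel"),
                 yakere = c("dyak", "dere"),
                 root = c("dsim", "dsec", "dmel", "dyak", "dere"))
  if (!is.null(clades[[lab]])) return(clades[[lab]])
  names(sim$genomes)
}

#' Write a simulated clade to disk
#'
#' Emits per-species FASTA and GFF3 files plus a tab-separated `truth.tsv`
#' ground-truth table.
#'
#' @param sim Result of [simulate_clade()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    write_genome(sim$genomes[[sp]],
                 file.path(dir, paste0(sp, ".fa")),
                 file.path(dir, paste0(sp, ".gff3")))
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
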