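## Homology family construction across species and TRGF candidate selection.
## All-vs-all protein alignment builds a graph of accepted homologous pairs
## (significant local alignment + length-tolerance rule); families are its
## connected components.

#' Length-tolerance rule for a homologous pair
#'
#' A putative pair is rejected when the alignment length is below
#' `tolerance` times the length of the shorter protein; the boundary is
#' inclusive (a ratio exactly at the tolerance is accepted).
#'
#' @param alignment_length Number of alignment columns.
#' @param len_a,len_b Protein lengths.
#' @param tolerance Minimum ratio (default 0.61).
#' @return Logical.
#' @export
length_tolerance_ok <- function(alignment_length, len_a, len_b,
                                tolerance = 0.61) {
  alignment_length / min(len_a, len_b) >= tolerance
}

#' Test whether two proteins are homologous
#'
#' Requires a significant local alignment (e-value at most `max_e` with the
#' two sequence lengths as the search space) whose length passes
#' [length_tolerance_ok()].
#'
#' @param protein_a,protein_b Protein strings.
#' @param scheme A protein [scoring_scheme()].
#' @param length_tolerance Minimum alignment length / shorter protein ratio.
#' @param max_e Significance threshold (default 1e-3).
#' @return Logical.
#' @export
pairwise_homologous <- function(protein_a, protein_b,
                                scheme = protein_scheme(),
                                length_tolerance = 0.61, max_e = 1e-3) {
  if (!nzchar(protein_a) || !nzchar(protein_b)) stop("empty protein sequence")
  sw <- smith_waterman(protein_a, protein_b, scheme)
  if (sw$score <= 0) return(FALSE)
  e <- evalue(sw$score, nchar(protein_a), nchar(protein_b), scheme)
  e <= max_e && length_tolerance_ok(sw$alignment_length,
                                    nchar(protein_a), nchar(protein_b),
                                    length_tolerance)
}

#' Build homology families across proteomes
#'
#' All-vs-all protein comparison (including within-species pairs, so that
#' duplicate copies join their parent family). Accepted pairs form a graph
#' whose connected components are the families; proteins with no accepted
#' partner form singleton families. Family ids are deterministic: families
#' are sorted by their lexicographically smallest member key.
#'
#' @param proteomes Named list (species -> named character vector of
#'   proteins).
#' @param scheme A protein [scoring_scheme()].
#' @param length_tolerance Length-tolerance ratio (default 0.61).
#' @param max_e Pair significance threshold.
#' @return List of families; each a data frame with columns `species` and
#'   `gene_id`, the list named by family id.
#' @export
build_families <- function(proteomes, scheme = protein_scheme(),
                           length_tolerance = 0.61, max_e = 1e-3) {
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  species <- rep(names(proteomes), lengths(proteomes))
  gene_ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  seqs <- unlist(proteomes, use.names = FALSE)
  n <- length(seqs)
  keys <- paste(species, gene_ids, sep = "|")
  if (anyDuplicated(keys)) stop("duplicate (species, gene_id) pairs")
  edges <- character(0L)
  if (n >= 2L) {
    set <- Biostrings::AAStringSet(seqs)
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      scores <- Biostrings::pairwiseAlignment(
        set[rest], Biostrings::AAString(seqs[[i]]), type = "local",
        substitutionMatrix = scheme$submat,
        gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
        scoreOnly = TRUE)
      e <- evalue(pmax(scores, 0), nchar(seqs[[i]]), nchar(seqs[rest]), scheme)
      cand <- rest[scores > 0 & e <= max_e]
      for (j in cand) {
        sw <- smith_waterman(seqs[[i]], seqs[[j]], scheme)
        if (length_tolerance_ok(sw$alignment_length, nchar(seqs[[i]]),
                                nchar(seqs[[j]]), length_tolerance))
          edges <- c(edges, keys[[i]], keys[[j]])
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(keys)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)$membership
  fams <- split(seq_len(n), comp[keys])
  members <- lapply(fams, function(idx) {
    m <- data.frame(species = species[idx], gene_id = gene_ids[idx],
                    stringsAsFactors = FALSE)
    m[order(m$species, m$gene_id), , drop = FALSE]
  })
  ord <- order(vapply(members, function(m)
    paste(m$species[[1L]], m$gene_id[[1L]], sep = "|"), character(1L)))
  members <- members[ord]
  names(members) <- sprintf("F%04d", seq_along(members))
  members
}

#' Define the clade partition of the analysis
#'
#' @param focal_species Species inside the focal clade (>= 2).
#' @param ingroup_outgroups Closest outgroup species (used for the ORF
#'   conservation test).
#' @param distant_outgroups More distant outgroups, ordered by divergence
#'   (used for the start-codon absence check; may be empty).
#' @return A `clade_partition` object.
#' @export
clade_partition <- function(focal_species, ingroup_outgroups,
                            distant_outgroups = character(0L)) {
  if (length(focal_species) < 2L) stop("focal clade needs >= 2 species")
  all <- c(focal_species, ingroup_outgroups, distant_outgroups)
  if (anyDuplicated(all)) stop("partition sets must be disjoint")
  structure(list(focal_species = focal_species,
                 ingroup_outgroups = ingroup_outgroups,
                 distant_outgroups = distant_outgroups),
            class = "clade_partition")
}

#' Select clade-restricted candidate families
#'
#' Keeps exactly the families with annotated members in at least two
#' distinct focal-clade species and no members outside the focal clade.
#' Families restricted to a single species are excluded: without
#' cross-species conservation there is insufficient evidence of
#' functionality.
#'
#' @param families Output of [build_families()].
#' @param partition A [clade_partition()].
#' @return Subset of `families` (same structure).
#' @export
select_trgf_candidates <- function(families, partition) {
  keep <- vapply(families, function(m) {
    inside <- m$species %in% partition$focal_species
    all(inside) && length(unique(m$species[inside])) >= 2L
  }, logical(1L))
  families[keep]
}

#' Screen candidate families against outgroup proteins
#'
#' A family is removed if and only if every one of its member proteins has
#' at least one qualifying hit (e-value and coverage thresholds) to a
#' protein outside the focal clade; if any member lacks such a hit the
#' family is retained. Removal reasons are reported per family.
#'
#' @param candidates Families from [select_trgf_candidates()].
#' @param member_proteins Named list (species -> named protein vector)
#'   covering the candidate members.
#' @param outgroup_proteins Named list (species -> named protein vector) of
#'   proteins outside the focal clade.
#' @param scheme A protein [scoring_scheme()].
#' @param max_e,min_cov Hit thresholds (defaults 1e-3 and 0.5).
#' @return List with `kept` (families) and `removed` (named character
#'   vector of reasons).
#' @export
protein_screen <- function(candidates, member_proteins, outgroup_proteins,
                           scheme = protein_scheme(),
                           max_e = 1e-3, min_cov = 0.5) {
  kept <- list(); removed <- character(0L)
  for (fid in names(candidates)) {
    fam <- candidates[[fid]]
    member_has_hit <- vapply(seq_len(nrow(fam)), function(i) {
      prot <- member_proteins[[fam$species[[i]]]][[fam$gene_id[[i]]]]
      if (is.null(prot)) stop("missing protein for ", fam$species[[i]], ":",
                              fam$gene_id[[i]])
      hits <- search_proteins(prot, outgroup_proteins, scheme, max_e, min_cov,
                              query_id = fam$gene_id[[i]])
      nrow(hits) > 0L
    }, logical(1L))
    if (all(member_has_hit)) {
      removed[[fid]] <- "all members hit outgroup proteins (diverged homolog outside clade)"
    } else {
      kept[[fid]] <- fam
    }
  }
  list(kept = kept, removed = removed)
}
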