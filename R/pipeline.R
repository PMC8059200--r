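## Orchestration of the candidate funnel: homology families, clade
## restriction, protein screen, DNA-region homology, outgroup ORF filter,
## alignment continuity, annotation QC and origin inference, with a
## deterministic per-candidate disposition report.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: the 61\% length-tolerance
#' ratio, the e-value cutoff 1e-3, the 50\% query-coverage rule, the
#' 1000-hit cap with 5 best hits per species, the 50-codon minimum ORF, the
#' 50\% outgroup-ORF coverage threshold, and the operational continuity
#' definition (>= 80\% row coverage, gap blocks <= 50 columns).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(length_tolerance = 0.61,
       max_e = 1e-3,
       min_cov = 0.5,
       hit_cap_total = 1000L,
       hit_cap_per_species = 5L,
       min_orf_codons = 50L,
       orf_cov_threshold = 0.5,
       orf_min_species = 1L,
       min_row_cov = 0.8,
       max_gap_run = 50L,
       region_flank = 500L,
       start_col_slack = 30L,
       window_genes = 3L,
       col_slack = 0L)
}

#' Default clade partition for the five-species benchmark clade
#'
#' @return A [clade_partition()] with focal clade (dsim, dsec, dmel) and
#'   ingroup outgroups (dyak, dere).
#' @export
default_partition <- function() {
  clade_partition(focal_species = c("dsim", "dsec", "dmel"),
                  ingroup_outgroups = c("dyak", "dere"))
}

## per-row disruption evidence for an outgroup row over the candidate span;
## exclude_columns (the candidate's intron columns) are spliced out first
.outgroup_row_disruption <- function(alignment, row, cand_row,
                                     start_col, end_col,
                                     exclude_columns = integer(0L)) {
  chars <- strsplit(alignment$aligned[[row]], "")[[1L]]
  cchars <- strsplit(alignment$aligned[[cand_row]], "")[[1L]]
  span <- setdiff(start_col:end_col, exclude_columns)
  deg <- paste0(chars[span][chars[span] != "-"], collapse = "")
  cdeg_len <- sum(cchars[span] != "-")
  has_start <- FALSE
  if (nchar(deg) >= 3L) {
    first_codons <- substring(deg, seq(1L, min(45L, nchar(deg) - 2L), by = 3L),
                              seq(3L, min(47L, nchar(deg)), by = 3L))
    has_start <- "ATG" %in% first_codons
  }
  n_stops <- 0L
  if (nchar(deg) >= 6L) {
    aa <- translate_cds(deg, strict = FALSE)
    body <- substr(aa, 1L, nchar(aa) - 1L)       # terminal stop is expected
    n_stops <- lengths(regmatches(body, gregexpr("\\*", body)))
  }
  frameshift <- (nchar(deg) - cdeg_len) %% 3L != 0L
  list(stops = n_stops, frameshift = frameshift, has_start = has_start,
       disrupted = n_stops >= 1L || frameshift || !has_start)
}

## does any flagged outgroup ORF share the candidate's reading frame?
## Works in spliced coordinates: exclude_columns are removed before ORF
## calling and frame offsets are computed over the retained columns.
.flagged_orf_same_frame <- function(alignment, orf_res, cand_row, start_col,
                                    min_orf_codons, threshold = 0.5,
                                    exclude_columns = integer(0L)) {
  spliced_index <- function(sp) {
    chars <- strsplit(alignment$aligned[[sp]], "")[[1L]]
    keep <- chars != "-"
    keep[exclude_columns] <- FALSE
    idx <- cumsum(keep)
    idx[!keep] <- NA_integer_
    idx
  }
  for (i in seq_len(nrow(orf_res$evidence))) {
    sp <- orf_res$evidence$species[[i]]
    if (orf_res$evidence$best_coverage[[i]] < threshold) next
    chars <- strsplit(alignment$aligned[[sp]], "")[[1L]]
    keep_cols <- setdiff(which(chars != "-"), exclude_columns)
    degapped <- paste0(chars[keep_cols], collapse = "")
    orfs <- find_orfs(degapped, min_orf_codons)
    idx <- spliced_index(sp)
    anchor <- .ungapped_at_or_after(idx, start_col)
    for (j in seq_len(nrow(orfs))) {
      if ((orfs$start[[j]] + 1L - anchor) %% 3L == 0L) return(TRUE)
    }
  }
  FALSE
}

#' Run the TRGF discovery funnel
#'
#' Executes the stages in order: homology families, clade-restriction
#' filter, protein screen against outgroup proteomes, homologous-region
#' discovery and alignment, outgroup ORF-conservation filter, alignment
#' continuity filter, annotation QC, and origin inference. Fully
#' deterministic given the genomes and configuration.
#'
#' @param genomes Named list of [annotated_genome()] covering every species
#'   in the partition.
#' @param partition A [clade_partition()].
#' @param config Configuration list (see [default_config()]).
#' @param protein_sch,nucleotide_sch Scoring schemes.
#' @return A `funnel_report`: list with `stage_counts`, `dispositions`
#'   (data frame), `dossiers` (per-candidate evidence) and `config`.
#' @export
run_pipeline <- function(genomes, partition, config = default_config(),
                         protein_sch = protein_scheme(),
                         nucleotide_sch = nucleotide_scheme()) {
  needed <- c(partition$focal_species, partition$ingroup_outgroups,
              partition$distant_outgroups)
  missing <- setdiff(needed, names(genomes))
  if (length(missing))
    stop("partition species absent from inputs: ", paste(missing, collapse = ", "))

  proteomes <- lapply(genomes, proteome)
  families <- build_families(proteomes, protein_sch,
                             config$length_tolerance, config$max_e)
  candidates <- select_trgf_candidates(families, partition)

  outgroup_species <- setdiff(names(genomes), partition$focal_species)
  screen <- protein_screen(candidates, proteomes[partition$focal_species],
                           proteomes[outgroup_species], protein_sch,
                           config$max_e, config$min_cov)

  dispositions <- list(); dossiers <- list()
  dispose <- function(fid, fam, stage, reason, classification = "") {
    dispositions[[fid]] <<- data.frame(
      family_id = fid,
      members = paste(paste(fam$species, fam$gene_id, sep = ":"), collapse = ","),
      stage_removed = stage, reason = reason,
      classification = classification, stringsAsFactors = FALSE)
  }
  for (fid in names(families)) {
    if (!fid %in% names(candidates))
      dispose(fid, families[[fid]], "clade_filter",
              "members outside focal clade or < 2 focal species")
  }
  for (fid in names(screen$removed))
    dispose(fid, candidates[[fid]], "protein_screen", screen$removed[[fid]])

  n_orf_kept <- 0L; n_continuous <- 0L; n_qc <- 0L; n_denovo <- 0L
  for (fid in names(screen$kept)) {
    fam <- screen$kept[[fid]]
    rh <- find_homologous_regions(fam, genomes, nucleotide_sch,
                                  config$max_e, config$min_cov,
                                  config$hit_cap_total,
                                  config$hit_cap_per_species,
                                  config$region_flank)
    regions <- rh$regions
    ## representative member: longest CDS
    cds_len <- vapply(seq_len(nrow(fam)), function(i) {
      g <- genomes[[fam$species[[i]]]]$genes[[fam$gene_id[[i]]]]
      sum(g$cds[, "end"] - g$cds[, "start"])
    }, integer(1L))
    rep_i <- which.max(cds_len)
    rep_sp <- fam$species[[rep_i]]
    rep_gene <- genomes[[rep_sp]]$genes[[fam$gene_id[[rep_i]]]]

    outgroup_present <- intersect(outgroup_species, regions$species)
    if (nrow(regions) < 2L || length(outgroup_present) == 0L) {
      n_orf_kept <- n_orf_kept + 1L
      dispose(fid, fam, "continuity_filter",
              "no alignable outgroup region", "undetermined")
      next
    }
    aln <- align_regions(regions, genomes)
    stopifnot(all(rows_degap_ok(aln, genomes)))

    span <- gene_span(rep_gene)
    span_cols <- interval_to_columns(aln, rep_sp, span)
    cd <- rep_gene$cds[order(rep_gene$cds[, "start"]), , drop = FALSE]
    orf_iv <- c(cd[1L, "start"], cd[nrow(cd), "end"])
    orf_cols <- interval_to_columns(aln, rep_sp, orf_iv)
    start_col <- min(orf_cols)
    end_col <- max(orf_cols)
    ## candidate intron columns are spliced out of all frame/ORF analyses
    intron_iv <- introns(rep_gene)
    intron_cols <- unlist(lapply(seq_len(nrow(intron_iv)), function(k)
      interval_to_columns(aln, rep_sp, intron_iv[k, ])))

    ingroup_rows <- intersect(partition$ingroup_outgroups, names(aln$aligned))
    orf_res <- outgroup_orf_conservation(
      aln, rep_sp, orf_iv, ingroup_rows,
      config$orf_cov_threshold, config$orf_min_species, config$min_orf_codons,
      exclude_columns = intron_cols)
    if (orf_res$flag) {
      same_frame <- .flagged_orf_same_frame(aln, orf_res, rep_sp, start_col,
                                            config$min_orf_codons,
                                            config$orf_cov_threshold,
                                            intron_cols)
      cls <- if (same_frame) "diverged_ancestor" else "earlier_origin"
      dispose(fid, fam, "outgroup_orf_filter",
              "conserved outgroup ORF covers >= 50% of candidate ORF", cls)
      next
    }
    n_orf_kept <- n_orf_kept + 1L

    cont <- alignment_continuity(aln, span_cols, config$min_row_cov,
                                 config$max_gap_run)
    if (!cont$continuous) {
      dispose(fid, fam, "continuity_filter",
              "no continuous alignment of homologous regions", "undetermined")
      next
    }
    n_continuous <- n_continuous + 1L

    qc <- annotation_consistency(fam, genomes, aln, config$col_slack)
    if (!qc$pass) {
      dispose(fid, fam, "annotation_qc",
              paste("annotation flags:",
                    paste(unique(qc$flags$flag), collapse = ",")))
      next
    }
    n_qc <- n_qc + 1L

    ## origin evidence
    disr <- lapply(ingroup_rows, function(sp)
      .outgroup_row_disruption(aln, sp, rep_sp, start_col, end_col,
                               intron_cols))
    outgroup_disrupted <- length(disr) > 0L &&
      all(vapply(disr, `[[`, logical(1L), "disrupted"))
    syn <- synteny_context(regions, genomes, families, config$window_genes)
    dup <- intragenomic_duplicates(genomes[[rep_sp]], rep_gene$seq_region,
                                   span, nucleotide_sch,
                                   config$max_e, config$min_cov)
    distant_rows <- intersect(partition$distant_outgroups, names(aln$aligned))
    dstart <- distant_outgroup_start_check(aln, rep_sp, start_col,
                                           distant_rows,
                                           config$start_col_slack)
    conv <- frame_convention(aln, rep_sp, start_col)
    frames <- conserved_stop_frames(aln, conv, min(orf_cols):max(orf_cols))
    intron_tests <- if (nrow(introns(rep_gene)) > 0L) {
      iv <- introns(rep_gene)
      vapply(iv[, "end"] - iv[, "start"], intron_mod3_test, character(1L))
    } else character(0L)

    evidence <- list(continuous = TRUE,
                     outgroup_orf_flag = FALSE,
                     outgroup_orf_same_frame = FALSE,
                     outgroup_disrupted = outgroup_disrupted,
                     synteny_ok = syn$synteny_ok,
                     distant_start = dstart$status,
                     intragenomic_duplicates = nrow(dup) > 0L)
    cls <- classify_origin(evidence)
    if (cls$classification == "de_novo") n_denovo <- n_denovo + 1L
    dispose(fid, fam, "", cls$rationale, cls$classification)
    dossiers[[fid]] <- list(evidence = evidence, synteny = syn,
                            outgroup_orf = orf_res,
                            disruption = setNames(disr, ingroup_rows),
                            frame_analysis = frames,
                            intron_tests = intron_tests,
                            distant_start = dstart,
                            regions = regions)
  }

  stage_counts <- c(families = length(families),
                    clade_restricted = length(candidates),
                    after_protein_screen = length(screen$kept),
                    after_outgroup_orf = n_orf_kept,
                    after_continuity = n_continuous,
                    after_annotation_qc = n_qc,
                    de_novo = n_denovo)
  stopifnot(all(diff(stage_counts) <= 0))      # funnel monotonicity

  disp <- do.call(rbind, dispositions[sort(names(dispositions))])
  rownames(disp) <- NULL
  structure(list(stage_counts = stage_counts, dispositions = disp,
                 dossiers = dossiers, config = config),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("TRGF candidate funnel:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-22s %d\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}

#' Serialize a funnel report as deterministic JSON
#'
#' @param report A `funnel_report`.
#' @return A JSON string; identical inputs yield byte-identical output.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(stage_counts = as.list(report$stage_counts),
         dispositions = report$dispositions,
         config = report$config),
    auto_unbox = TRUE, digits = 10, dataframe = "rows", pretty = TRUE))
}

#' Benchmark the pipeline on simulated clades
#'
#' Simulates `n_replicates` clades (seeds `seed + 1 ... seed + n`), runs the
#' full pipeline on each and scores recovery against the ground truth:
#' the fraction of planted de novo births classified `de_novo`
#' (sensitivity) and the fraction of planted diverged duplicates or
#' pseudogenizations ever classified `de_novo` (should be zero). Binomial
#' confidence intervals are exact (Clopper-Pearson).
#'
#' @param n_replicates Number of simulated clades (>= 1).
#' @param seed Base seed.
#' @param sim_args List of extra arguments to [simulate_clade()].
#' @param config Pipeline configuration.
#' @param partition Clade partition (default [default_partition()]).
#' @return List with `table` (per event type: n, recovered, proportion,
#'   ci_lo, ci_hi) and `details` (per replicate classifications).
#' @export
benchmark_pipeline <- function(n_replicates = 20L, seed = 1L,
                               sim_args = list(), config = default_config(),
                               partition = default_partition()) {
  stopifnot(n_replicates >= 1L)
  details <- list()
  for (i in seq_len(n_replicates)) {
    sim <- do.call(simulate_clade, c(list(seed = seed + i), sim_args))
    rep <- run_pipeline(sim$genomes, partition, config)
    for (ev in sim$events) {
      cls <- .classification_of_locus(rep, sim, ev)
      details[[length(details) + 1L]] <- data.frame(
        replicate = i, locus_id = ev$locus_id, event = ev$type,
        classification = cls, stringsAsFactors = FALSE)
    }
  }
  det <- do.call(rbind, details)
  tab <- do.call(rbind, lapply(split(det, det$event), function(d) {
    target <- if (d$event[[1L]] == "de_novo_birth") "de_novo" else NA
    hit <- if (is.na(target)) d$classification == "de_novo"
           else d$classification == target
    n <- nrow(d); k <- sum(hit)
    ci <- binom.test(k, n)$conf.int
    data.frame(event = d$event[[1L]], n = n,
               outcome = if (is.na(target)) "classified_de_novo" else "recovered",
               count = k, proportion = k / n,
               ci_lo = ci[[1L]], ci_hi = ci[[2L]], stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, details = det)
}

## classification assigned to the family containing a planted locus
.classification_of_locus <- function(report, sim, ev) {
  gid <- if (ev$type %in% c("pseudogenization", "gene_loss")) ev$src_gene
         else ev$locus_id
  pat <- paste0(":", gid, "(,|$)")
  hit <- grepl(pat, report$dispositions$members)
  if (!any(hit)) return("not_in_families")
  cls <- report$dispositions$classification[hit]
  stage <- report$dispositions$stage_removed[hit]
  out <- ifelse(cls != "", cls, paste0("removed_at_", stage))
  paste(unique(out), collapse = "|")
}
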