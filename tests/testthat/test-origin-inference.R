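test_that("conserved-stop frame analysis reproduces the (0, 4, 2) pattern", {
  row <- frame_fixture_row()
  rows <- setNames(rep(row, 5L), paste0("sp", 1:5))
  aln <- manual_alignment(rows)
  conv <- frame_convention(aln, "sp1", 1L)
  res <- conserved_stop_frames(aln, conv)
  expect_equal(unname(res$counts), c(0L, 4L, 2L))
  expect_equal(res$open_frames, "+1")
  expect_equal(res$ambiguous, 0L)
  # cross-check against the naive per-row six-frame scanner
  naive <- naive_conserved_stops(as.list(rows), anchor_pos = 0L)
  expect_equal(res$counts, naive)
  # no conserved stop is ever assigned to an open frame
  expect_false(any(res$stops$frame %in% res$open_frames))
})

test_that("frame counts are invariant to row order and full-gap padding", {
  row <- frame_fixture_row()
  rows <- setNames(rep(row, 5L), paste0("sp", 1:5))
  aln <- manual_alignment(rows)
  res <- conserved_stop_frames(aln, frame_convention(aln, "sp1", 1L))
  shuffled <- manual_alignment(rows[c(3, 1, 5, 2, 4)])
  res2 <- conserved_stop_frames(shuffled, frame_convention(shuffled, "sp3", 1L))
  expect_equal(res2$counts, res$counts)
  # pad every row with a full-gap block between the anchor and the stops
  padded_rows <- setNames(vapply(rows, function(r)
    paste0(substr(r, 1, 6), "----", substr(r, 7, nchar(r))), character(1L)),
    names(rows))
  padded <- manual_alignment(padded_rows)
  res3 <- conserved_stop_frames(padded, frame_convention(padded, "sp1", 1L))
  expect_equal(res3$counts, res$counts)
})

test_that("a single divergent row prevents a stop from counting as conserved", {
  row <- frame_fixture_row()
  weak <- row
  substr(weak, 14, 16) <- "TAC"           # first +2 stop broken in one row
  aln <- manual_alignment(c(a = row, b = row, c = row, d = row, e = weak))
  res <- conserved_stop_frames(aln, frame_convention(aln, "a", 1L))
  expect_equal(unname(res$counts), c(0L, 3L, 2L))
})

test_that("the intron modulo-3 test matches its published interpretation", {
  expect_equal(intron_mod3_test(52), "predates_orf")
  expect_equal(intron_mod3_test(51), "inconclusive")
  expect_error(intron_mod3_test(3), "minimum")
})

test_that("distant-outgroup start check distinguishes absent/present/unavailable", {
  cand <- paste0(strrep("C", 9), "ATG", strrep("C", 48))
  no_atg <- strrep("C", 60)
  atg_inframe <- cand
  atg_offframe <- paste0(strrep("C", 11), "ATG", strrep("C", 46))
  aln <- manual_alignment(c(cand = cand, d1 = no_atg))
  expect_equal(distant_outgroup_start_check(aln, "cand", 10L, "d1")$status,
               "absent")
  aln2 <- manual_alignment(c(cand = cand, d1 = atg_inframe))
  expect_equal(distant_outgroup_start_check(aln2, "cand", 10L, "d1")$status,
               "present")
  aln3 <- manual_alignment(c(cand = cand, d1 = atg_offframe))
  expect_equal(distant_outgroup_start_check(aln3, "cand", 10L, "d1")$status,
               "absent")
  expect_equal(distant_outgroup_start_check(aln, "cand", 10L, character(0L))$status,
               "unavailable")
})

test_that("the origin decision table is conservative", {
  base <- list(continuous = TRUE, outgroup_orf_flag = FALSE,
               outgroup_orf_same_frame = FALSE, outgroup_disrupted = TRUE,
               synteny_ok = TRUE, distant_start = "unavailable",
               intragenomic_duplicates = FALSE)
  expect_equal(classify_origin(base)$classification, "de_novo")
  expect_equal(classify_origin(modifyList(base, list(continuous = FALSE)))$classification,
               "undetermined")
  expect_equal(classify_origin(modifyList(base, list(outgroup_orf_flag = TRUE)))$classification,
               "earlier_origin")
  expect_equal(classify_origin(modifyList(
    base, list(outgroup_orf_flag = TRUE,
               outgroup_orf_same_frame = TRUE)))$classification,
    "diverged_ancestor")
  # a distant start codon always blocks a de novo call
  expect_equal(classify_origin(modifyList(base, list(distant_start = "present")))$classification,
               "undetermined")
  expect_equal(classify_origin(modifyList(base, list(intragenomic_duplicates = TRUE)))$classification,
               "undetermined")
  expect_equal(classify_origin(modifyList(base, list(distant_start = "absent")))$classification,
               "de_novo")
})

test_that("synteny context detects shared flanking families", {
  geneseq <- paste0("ATG", strrep("AAC", 29), "TAA")   # 93 nt
  mk <- function(sp, lid, rid) {
    seq <- paste0(geneseq, strrep("T", 200), geneseq)
    annotated_genome(sp, c(chr1 = seq), list(
      gene_model(lid, "chr1", "+", rbind(c(0, 93)), rbind(c(0, 93))),
      gene_model(rid, "chr1", "+", rbind(c(293, 386)), rbind(c(293, 386)))))
  }
  gens <- list(a = mk("a", "L", "R"), b = mk("b", "L", "R"))
  families <- list(FL = data.frame(species = c("a", "b"), gene_id = "L"),
                   FR = data.frame(species = c("a", "b"), gene_id = "R"))
  regions <- data.frame(species = c("a", "b"), seq_region = "chr1",
                        start = 120L, end = 280L, strand = "+",
                        stringsAsFactors = FALSE)
  syn <- synteny_context(regions, gens, families)
  expect_true(syn$synteny_ok)
  expect_setequal(syn$shared_families, c("FL", "FR"))
  # unshared flanks break synteny
  gens2 <- list(a = mk("a", "L", "R"), b = mk("b", "L2", "R2"))
  families2 <- list(FL = data.frame(species = "a", gene_id = "L"),
                    FR = data.frame(species = "a", gene_id = "R"),
                    FL2 = data.frame(species = "b", gene_id = "L2"),
                    FR2 = data.frame(species = "b", gene_id = "R2"))
  expect_false(synteny_context(regions, gens2, families2)$synteny_ok)
})
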