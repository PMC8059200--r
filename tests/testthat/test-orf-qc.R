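test_that("maximal ORF calling follows the ATG..stop definition", {
  orfs <- find_orfs("ATGAAATAA", min_orf_codons = 2L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$codons, 3L)                 # stop codon included
  expect_equal(c(orfs$start, orfs$end), c(0L, 9L))
  expect_equal(nrow(find_orfs("ATGAA", 2L)), 0L)       # no terminal stop
  expect_equal(nrow(find_orfs("ATGANATAA", 2L)), 0L)   # N inside ORF
  # maximality: the first ATG after the previous stop opens the ORF
  orfs2 <- find_orfs("ATGATGAAATAA", 2L)
  expect_equal(orfs2$start, 0L)
})

test_that("ORF calls agree with a naive codon-walking scanner", {
  set.seed(51)
  for (min_c in c(5L, 25L)) {
    chars <- strsplit(random_dna(10000), "")[[1L]]
    chars[sample(10000, 15)] <- "N"
    s <- paste0(chars, collapse = "")
    got <- find_orfs(s, min_c)
    want <- naive_orf_scan(s, min_c)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("min_codons", min_c))
  }
})

test_that("outgroup ORF conservation respects the 50% coverage boundary", {
  cand <- paste0("ATG", strrep("CCC", 58), "TAA")            # 180 nt ORF
  out50 <- paste0(strrep("C", 90), "ATG", strrep("CCC", 28), "TAA")
  out49 <- paste0(strrep("C", 93), "ATG", strrep("CCC", 27), "TAA")
  aln50 <- manual_alignment(c(cand = cand, out = out50))
  aln49 <- manual_alignment(c(cand = cand, out = out49))
  r50 <- outgroup_orf_conservation(aln50, "cand", c(0L, 180L), "out",
                                   min_orf_codons = 10L)
  r49 <- outgroup_orf_conservation(aln49, "cand", c(0L, 180L), "out",
                                   min_orf_codons = 10L)
  expect_equal(r50$evidence$best_coverage, 0.5)
  expect_true(r50$flag)
  expect_false(r49$flag)
  # an outgroup row identical to the candidate covers it fully
  self <- outgroup_orf_conservation(manual_alignment(c(cand = cand, out = cand)),
                                    "cand", c(0L, 180L), "out",
                                    min_orf_codons = 10L)
  expect_equal(self$evidence$best_coverage, 1)
  expect_true(self$flag)
  # monotone in the threshold: raising it never flags more
  expect_true(outgroup_orf_conservation(aln50, "cand", c(0L, 180L), "out",
                                        threshold = 0.4,
                                        min_orf_codons = 10L)$flag)
  expect_false(outgroup_orf_conservation(aln50, "cand", c(0L, 180L), "out",
                                         threshold = 0.6,
                                         min_orf_codons = 10L)$flag)
})

test_that("splice signals are checked canonically and strand-aware", {
  gen <- tiny_genome()
  ssc <- splice_signal_check(gen, "gp")
  expect_true(ssc$canonical[[1L]])
  expect_equal(ssc$length[[1L]], 6L)
  # non-canonical GC..AG donor
  chr <- paste0("AAA", "ATGCCC", "GCAAAG", "CCCGGGTAA", "TTT")
  bad <- annotated_genome("x", c(chr1 = chr), list(
    gene_model("b", "chr1", "+", rbind(c(3, 9), c(15, 24)),
               rbind(c(3, 9), c(15, 24)))))
  expect_false(splice_signal_check(bad, "b")$canonical[[1L]])
  # minus strand: genomic CT..AC reads GT..AG after strand adjustment
  mseq <- paste0("GGGGG", "TTA", "CTTTAC", "TTTCAT", "GGGGG")
  mg <- annotated_genome("m", c(chr1 = mseq), list(
    gene_model("gm2", "chr1", "-", rbind(c(5, 8), c(14, 20)),
               rbind(c(5, 8), c(14, 20)))))
  msc <- splice_signal_check(mg, "gm2")
  expect_true(msc$canonical[[1L]])
  expect_equal(extract_feature_sequence(mg, "gm2", "cds"), "ATGAAATAA")
})

test_that("annotation QC flags structural and cross-species inconsistencies", {
  geneseq <- paste0("ATG", strrep("CCC", 38), "TAA")     # 120 nt
  ga <- annotated_genome("a", c(chr1 = paste0(geneseq, strrep("A", 60))),
                         list(gene_model("ga", "chr1", "+",
                                         rbind(c(0, 120)), rbind(c(0, 120)))))
  gb_clean <- annotated_genome("b", c(chr1 = paste0(geneseq, strrep("A", 60))),
                               list(gene_model("gb", "chr1", "+",
                                               rbind(c(0, 120)), rbind(c(0, 120)))))
  fam <- data.frame(species = c("a", "b"), gene_id = c("ga", "gb"),
                    stringsAsFactors = FALSE)
  aln_clean <- manual_alignment(c(
    a = paste0(geneseq, strrep("A", 60)), b = paste0(geneseq, strrep("A", 60))))
  qc <- annotation_consistency(fam, list(a = ga, b = gb_clean), aln_clean)
  expect_true(qc$pass)
  # shifted start: the two start codons map 30 columns apart
  gb_shift <- annotated_genome("b", c(chr1 = paste0(strrep("A", 30), geneseq,
                                                    strrep("A", 30))),
                               list(gene_model("gb", "chr1", "+",
                                               rbind(c(30, 150)),
                                               rbind(c(30, 150)))))
  aln_shift <- manual_alignment(c(
    a = paste0(geneseq, strrep("A", 60)),
    b = paste0(strrep("A", 30), geneseq, strrep("A", 30))))
  qc2 <- annotation_consistency(fam, list(a = ga, b = gb_shift), aln_shift)
  expect_false(qc2$pass)
  expect_true("inconsistent_start" %in% qc2$flags$flag)
  # missing start codon
  noatg <- paste0("GTG", strrep("CCC", 38), "TAA")
  gb_bad <- annotated_genome("b", c(chr1 = paste0(noatg, strrep("A", 60))),
                             list(gene_model("gb", "chr1", "+",
                                             rbind(c(0, 120)), rbind(c(0, 120)))))
  qc3 <- annotation_consistency(fam, list(a = ga, b = gb_bad), NULL)
  expect_false(qc3$pass)
  expect_true("missing_start" %in% qc3$flags$flag)
  # QC verdict is invariant to member order
  qc4 <- annotation_consistency(fam[2:1, ], list(a = ga, b = gb_bad), NULL)
  expect_equal(qc4$pass, qc3$pass)
})
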