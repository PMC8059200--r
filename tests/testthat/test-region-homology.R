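test_that("aligning identical regions yields a gapless identity alignment", {
  set.seed(41)
  unit <- random_dna(300)
  gens <- list(
    a = annotated_genome("a", c(chr1 = paste0(random_dna(50), unit, random_dna(50)))),
    b = annotated_genome("b", c(chr1 = paste0(random_dna(80), unit, random_dna(20)))))
  regions <- data.frame(species = c("a", "b"), seq_region = "chr1",
                        start = c(50L, 80L), end = c(350L, 380L),
                        strand = "+", stringsAsFactors = FALSE)
  aln <- align_regions(regions, gens)
  expect_true(all(rows_degap_ok(aln, gens)))
  pid <- percent_identity(aln, "a", "b")
  expect_equal(pid$identity, 1)
  expect_equal(pid$indel_columns, 0L)
  expect_error(align_regions(regions[1L, ], gens), "at least two")
})

test_that("minus-strand rows are auto-oriented before alignment", {
  set.seed(42)
  unit <- random_dna(300)
  gens <- list(
    a = annotated_genome("a", c(chr1 = paste0(random_dna(50), unit, random_dna(50)))),
    b = annotated_genome("b", c(chr1 = paste0(random_dna(30),
                                              reverse_complement(unit),
                                              random_dna(70)))))
  regions <- data.frame(species = c("a", "b"), seq_region = "chr1",
                        start = c(50L, 30L), end = c(350L, 330L),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
  aln <- align_regions(regions, gens)
  expect_true(all(rows_degap_ok(aln, gens)))
  expect_equal(percent_identity(aln, "a", "b")$identity, 1)
})

test_that("percent identity excludes indel columns as counted columns", {
  aln <- manual_alignment(c(a = "AC-GT", b = "ACAGT"))
  pid <- percent_identity(aln, "a", "b")
  expect_equal(pid$identity, 1)
  expect_equal(pid$comparable_columns, 4L)
  expect_equal(pid$indel_columns, 1L)
  expect_equal(pid$total_columns, 5L)
  aln2 <- manual_alignment(c(a = "ACGT", b = "ACTT"))
  expect_equal(percent_identity(aln2, "a", "b")$identity, 0.75)
})

test_that("coordinate maps are invertible and strand-aware", {
  rows <- data.frame(species = c("p", "m"), seq_region = "chr1",
                     start = c(100L, 200L), end = c(104L, 204L),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  aln <- region_alignment(rows, c(p = "AC-GT", m = "ACAGT"))
  expect_equal(column_positions(aln, "p"), c(100L, 101L, NA, 102L, 103L))
  expect_equal(column_positions(aln, "m"), c(203L, 202L, 201L, 200L, 199L))
  expect_equal(interval_to_columns(aln, "p", c(101L, 103L)), c(2L, 4L))
  # mapping an interval to columns and back is the identity
  cols <- interval_to_columns(aln, "p", c(100L, 104L))
  pos <- column_positions(aln, "p")[cols]
  expect_equal(range(pos), c(100L, 103L))
})

test_that("continuity requires dense rows without long gap blocks", {
  good <- manual_alignment(c(a = strrep("A", 100), b = strrep("A", 100)))
  expect_true(alignment_continuity(good, 1:100)$continuous)
  gappy <- manual_alignment(c(a = strrep("A", 100),
                              b = paste0(strrep("A", 20), strrep("-", 60),
                                         strrep("A", 20))))
  res <- alignment_continuity(gappy, 1:100)
  expect_false(res$continuous)
  expect_equal(res$per_row$max_gap_run[res$per_row$species == "b"], 60L)
  # the same row passes under a permissive gap-run limit but fails coverage
  res2 <- alignment_continuity(gappy, 1:100, min_row_cov = 0.3, max_gap_run = 70L)
  expect_true(res2$continuous)
})

test_that("homologous regions of a planted locus are recovered in all species", {
  sim <- fixture_sim()
  fam <- data.frame(species = c("dsim", "dsec"), gene_id = "trg1",
                    stringsAsFactors = FALSE)
  rh <- find_homologous_regions(fam, sim$genomes)
  expect_setequal(rh$regions$species, names(sim$genomes))
  ## each species' region covers the truth locus coordinates
  for (i in seq_len(nrow(rh$regions))) {
    r <- rh$regions[i, ]
    tr <- sim$truth[sim$truth$locus_id == "trg1" &
                      sim$truth$species == r$species, ]
    expect_lte(r$start, tr$start)
    expect_gte(r$end, tr$end)
  }
  ## the self-hit of each member gene is present
  for (i in 1:2) {
    g <- sim$genomes[[fam$species[[i]]]]$genes[["trg1"]]
    sp <- c(g$exons[1L, "start"], g$exons[nrow(g$exons), "end"])
    own <- rh$hits[rh$hits$genome == fam$species[[i]], ]
    expect_true(any(own$s_start <= sp[[1L]] & own$s_end >= sp[[2L]]))
  }
  aln <- align_regions(rh$regions, sim$genomes)
  expect_true(all(rows_degap_ok(aln, sim$genomes)))
  expect_error(find_homologous_regions(
    data.frame(species = "dsim", gene_id = "nope"), sim$genomes), "missing")
})
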