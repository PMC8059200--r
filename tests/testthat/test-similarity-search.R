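simple_scheme <- function()
  nucleotide_scheme(match = 1, mismatch = -1, gap_open = 1, gap_extend = 1)

test_that("local alignment handles self-alignment and hopeless pairs", {
  sch <- simple_scheme()
  sw <- smith_waterman("ACGT", "ACGT", sch)
  expect_equal(sw$score, 4)
  expect_equal(c(sw$a_start, sw$a_end, sw$b_start, sw$b_end), c(0L, 4L, 0L, 4L))
  sw0 <- smith_waterman("AAAA", "TTTT", sch)
  expect_equal(sw0$score, 0)
  expect_equal(sw0$alignment_length, 0L)
  expect_error(smith_waterman("", "ACGT", sch), "non-empty")
})

test_that("alignment scores match an independent plain-R DP oracle", {
  set.seed(101)
  sch <- nucleotide_scheme()          # +1/-2, gap 5/2
  for (i in 1:200) {
    a <- random_dna(sample(1:8, 1))
    b <- random_dna(sample(1:8, 1))
    expect_equal(smith_waterman(a, b, sch)$score,
                 oracle_local_score(a, b, 1, -2, 5, 2),
                 info = paste(a, b))
  }
})

test_that("e-values follow the Karlin-Altschul form", {
  sch <- scoring_scheme("protein")    # lambda 0.267, K 0.041
  expect_equal(evalue(40, 100, 100, sch), 0.041 * 1e4 * exp(-0.267 * 40))
  s <- seq(10, 60, by = 5)
  expect_true(all(diff(evalue(s, 100, 100, sch)) < 0))
  expect_equal(evalue(40, 100, 200, sch), 2 * evalue(40, 100, 100, sch))
  expect_error(evalue(40, 0, 100, sch), "positive")
})

test_that("genome search finds planted queries on both strands", {
  set.seed(7)
  query <- random_dna(120)
  left <- random_dna(400); right <- random_dna(400)
  gplus <- annotated_genome("sp", c(chr1 = paste0(left, query, right)))
  hits <- search_genomes(query, list(sp = gplus))
  plus <- hits[hits$strand == "+", ]
  expect_gte(nrow(plus), 1L)
  expect_equal(plus$s_start[[1L]], 400L)
  expect_equal(plus$s_end[[1L]], 520L)
  expect_equal(plus$coverage[[1L]], 1)
  # reverse-complement planting: same interval, minus strand
  gminus <- annotated_genome("sp", c(chr1 = paste0(
    left, reverse_complement(query), right)))
  hits2 <- search_genomes(query, list(sp = gminus))
  minus <- hits2[hits2$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  expect_equal(minus$s_start[[1L]], 400L)
  expect_equal(minus$s_end[[1L]], 520L)
})

test_that("strand invariance: reverse-complementing the subject reflects hits", {
  set.seed(8)
  query <- random_dna(100)
  seq <- paste0(random_dna(200), query, random_dna(300))
  g1 <- annotated_genome("sp", c(chr1 = seq))
  g2 <- annotated_genome("sp", c(chr1 = reverse_complement(seq)))
  h1 <- search_genomes(query, list(sp = g1))
  h2 <- search_genomes(query, list(sp = g2))
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(seq)
  h2_reflected <- data.frame(s_start = L - h2$s_end, s_end = L - h2$s_start,
                             strand = ifelse(h2$strand == "+", "-", "+"))
  o1 <- order(h1$s_start); o2 <- order(h2_reflected$s_start)
  expect_equal(h1$s_start[o1], h2_reflected$s_start[o2])
  expect_equal(h1$strand[o1], h2_reflected$strand[o2])
})

test_that("query coverage boundary is inclusive at exactly 50%", {
  query <- strrep("AC", 50)                    # length 100, A/C alphabet
  block49 <- substr(query, 1, 49)
  block50 <- substr(query, 1, 50)
  pad <- strrep("G", 80)                       # G never matches the query
  g49 <- annotated_genome("sp", c(chr1 = paste0(pad, block49, pad)))
  g50 <- annotated_genome("sp", c(chr1 = paste0(pad, block50, pad)))
  expect_equal(nrow(search_genomes(query, list(sp = g49))), 0L)
  h <- search_genomes(query, list(sp = g50))
  expect_gte(nrow(h), 1L)
  expect_equal(h$coverage[[1L]], 0.5)
})

test_that("filters are monotone in their thresholds", {
  set.seed(9)
  query <- random_dna(80)
  gen <- annotated_genome("sp", c(chr1 = paste0(
    random_dna(100), query, random_dna(100),
    substr(query, 1, 60), random_dna(100))))
  loose <- search_genomes(query, list(sp = gen), max_e = 1e-3, min_cov = 0.5)
  tighter_e <- search_genomes(query, list(sp = gen), max_e = 1e-10, min_cov = 0.5)
  tighter_cov <- search_genomes(query, list(sp = gen), max_e = 1e-3, min_cov = 0.9)
  expect_lte(nrow(tighter_e), nrow(loose))
  expect_lte(nrow(tighter_cov), nrow(loose))
})

test_that("amalgamation merges overlapping and bookended hits idempotently", {
  mk <- function(s, e, qs, qe) data.frame(
    query_id = "q", genome = "sp", seq_region = "chr1",
    s_start = s, s_end = e, strand = "+", q_start = qs, q_end = qe,
    q_len = 200L, score = e - s, evalue = 1e-5 / (e - s), coverage = (qe - qs) / 200,
    stringsAsFactors = FALSE)
  h <- rbind(mk(100L, 200L, 0L, 100L), mk(150L, 250L, 50L, 150L),
             mk(300L, 400L, 0L, 100L))
  m <- amalgamate_hits(h)
  expect_equal(nrow(m), 2L)
  expect_equal(m$s_start, c(100L, 300L))
  expect_equal(m$s_end, c(250L, 400L))
  expect_equal(m$coverage[[1L]], 150 / 200)       # merged aligned query span
  expect_equal(m$evalue[[1L]], min(h$evalue[1:2]))
  # idempotent and order-invariant
  expect_equal(amalgamate_hits(m), m)
  expect_equal(amalgamate_hits(h[c(3, 1, 2), ]), m)
  # bookended intervals merge
  b <- rbind(mk(100L, 200L, 0L, 100L), mk(200L, 300L, 100L, 200L))
  expect_equal(nrow(amalgamate_hits(b)), 1L)
})

test_that("hit capping triggers strictly above the total limit", {
  mk_many <- function(n) data.frame(
    query_id = "q", genome = rep(paste0("sp", 1:5), length.out = n),
    seq_region = "chr1", s_start = seq_len(n), s_end = seq_len(n) + 10L,
    strand = "+", q_start = 0L, q_end = 10L, q_len = 10L,
    score = 10, evalue = seq_len(n) * 1e-6, coverage = 1,
    stringsAsFactors = FALSE)
  at_limit <- mk_many(1000L)
  expect_identical(cap_hits(at_limit), at_limit)
  over <- mk_many(1001L)
  capped <- cap_hits(over)
  expect_lte(nrow(capped), 25L)
  expect_true(all(table(capped$genome) == 5L))
  # a species with fewer hits than the cap keeps them all
  few <- rbind(mk_many(1000L),
               within(mk_many(3L), genome <- "rare"))
  kept <- cap_hits(few)
  expect_equal(sum(kept$genome == "rare"), 3L)
})

test_that("intragenomic duplicate scan reports only non-self hits", {
  set.seed(10)
  unit <- random_dna(150)
  gen1 <- annotated_genome("sp", c(chr1 = paste0(random_dna(200), unit,
                                                 random_dna(200))))
  expect_equal(nrow(intragenomic_duplicates(gen1, "chr1", c(200L, 350L))), 0L)
  gen2 <- annotated_genome("sp", c(chr1 = paste0(
    random_dna(200), unit, random_dna(200), unit, random_dna(200))))
  dup <- intragenomic_duplicates(gen2, "chr1", c(200L, 350L))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$s_start[[1L]], 550L)
})
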