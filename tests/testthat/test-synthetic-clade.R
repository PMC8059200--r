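test_that("sequence evolution is deterministic and degenerate at zero length", {
  s <- random_dna(500)
  r0 <- evolve_sequence(s, 0)
  expect_identical(r0$seq, s)
  expect_equal(nrow(r0$log), 0L)
  r1 <- evolve_sequence(s, 0.1, seed = 5)
  r2 <- evolve_sequence(s, 0.1, seed = 5)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$log, r2$log)
  expect_error(evolve_sequence(s, -0.1), ">= 0")
  expect_error(evolve_sequence(s, 0.1, indel_rate = -1), "negative")
})

test_that("substitution-only evolution tracks the Jukes-Cantor expectation", {
  set.seed(21)
  d <- 0.1
  L <- 4000L
  p_expected <- 0.75 * (1 - exp(-4 * d / 3))
  diffs <- replicate(30, {
    s <- random_dna(L)
    r <- evolve_sequence(s, d, indel_rate = 0)
    mean(strsplit(s, "")[[1L]] != strsplit(r$seq, "")[[1L]])
  })
  se <- sqrt(p_expected * (1 - p_expected) / (L * 30))
  expect_lt(abs(mean(diffs) - p_expected), 4 * se)
})

test_that("a simulated clade plants the de novo gene in exactly the focal pair", {
  sim <- fixture_sim()
  expect_named(sim$genomes, c("dsim", "dsec", "dmel", "dyak", "dere"))
  for (sp in c("dsim", "dsec")) {
    g <- sim$genomes[[sp]]$genes[["trg1"]]
    expect_false(is.null(g))
    expect_equal(g$biotype, "protein_coding")
    expect_equal(nrow(g$exons), 2L)        # planted intron retained
  }
  for (sp in c("dmel", "dyak", "dere"))
    expect_null(sim$genomes[[sp]]$genes[["trg1"]])
  # but the homologous noncoding locus exists in the truth table for all five
  tr <- sim$truth[sim$truth$locus_id == "trg1", ]
  expect_setequal(tr$species, names(sim$genomes))
  expect_setequal(tr$species[tr$coding], c("dsim", "dsec"))
  # the diverged duplicate is present and coding in all five leaves
  dup <- sim$truth[sim$truth$locus_id == "dup1", ]
  expect_setequal(dup$species[dup$coding], names(sim$genomes))
  # pseudogenization hit the outgroup (dyak, dere) lineage only
  ps <- sim$truth[sim$truth$locus_id == "ps1", ]
  expect_setequal(ps$species[!ps$coding], c("dyak", "dere"))
})

test_that("truth-table coordinates match the emitted annotations", {
  sim <- fixture_sim()
  expect_true(check_simulation(sim))
  tr <- sim$truth[sim$truth$locus_id == "trg1" & sim$truth$coding, ]
  for (i in seq_len(nrow(tr))) {
    g <- sim$genomes[[tr$species[[i]]]]$genes[["trg1"]]
    sp <- c(g$exons[1L, "start"], g$exons[nrow(g$exons), "end"])
    expect_gte(sp[[1L]], tr$start[[i]])
    expect_lte(sp[[2L]], tr$end[[i]])
    cds <- extract_feature_sequence(sim$genomes[[tr$species[[i]]]], g, "cds")
    aa <- translate_cds(cds)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("every annotated CDS in every leaf translates cleanly", {
  sim <- fixture_sim()
  for (sp in names(sim$genomes))
    expect_equal(nrow(validate_coding_genes(sim$genomes[[sp]])), 0L,
                 info = sp)
})

test_that("zero branch lengths and no events reproduce the ancestor everywhere", {
  sim <- simulate_clade(tree = default_species_tree(0), n_genes = 5L,
                        events = list(), seed = 3L)
  seqs <- vapply(sim$genomes, function(g) g$sequences[["chr1"]], character(1L))
  expect_equal(length(unique(seqs)), 1L)
  expect_true(all(vapply(sim$genomes, function(g) length(g$genes), integer(1L)) == 5L))
})

test_that("simulation is reproducible and event branches are validated", {
  s1 <- simulate_clade(n_genes = 8L, events = default_events(8L), seed = 9L)
  s2 <- simulate_clade(n_genes = 8L, events = default_events(8L), seed = 9L)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  bad <- list(event_spec("de_novo_birth", "nosuchbranch", "x",
                         insert_after = "g002"))
  expect_error(simulate_clade(n_genes = 8L, events = bad, seed = 1L),
               "not in tree")
})

test_that("clade files round-trip through FASTA/GFF3 on disk", {
  sim <- fixture_sim()
  dir <- withr::local_tempdir()
  write_clade(sim, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_genome(file.path(dir, "dsim.fa"), file.path(dir, "dsim.gff3"),
                      species_id = "dsim")
  expect_identical(back$genes, sim$genomes$dsim$genes)
})
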