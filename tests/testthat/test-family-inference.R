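test_that("length-tolerance boundary is inclusive at the printed threshold", {
  expect_false(length_tolerance_ok(6099, 10000, 12000))   # ratio 0.6099
  expect_true(length_tolerance_ok(6100, 10000, 12000))    # ratio 0.61 exactly
  # the two rejected gene pairs' published ratios fall below the threshold
  expect_false(length_tolerance_ok(4306, 10000, 10000))   # 43.06%
  expect_false(length_tolerance_ok(5417, 10000, 10000))   # 54.17%
})

test_that("pairwise homology requires both significance and length tolerance", {
  set.seed(31)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  p <- paste0(sample(aas, 120, replace = TRUE), collapse = "")
  expect_true(pairwise_homologous(p, p))
  q <- paste0(sample(aas, 120, replace = TRUE), collapse = "")
  expect_false(pairwise_homologous(p, q))
  # a strong but short alignment fails the 61% rule: share only 40 residues
  shared <- substr(p, 1, 40)
  r <- paste0(shared, paste0(sample(aas, 80, replace = TRUE), collapse = ""))
  expect_false(pairwise_homologous(p, r, length_tolerance = 0.61))
  expect_true(pairwise_homologous(p, r, length_tolerance = 0.3))
})

test_that("families are connected components over accepted pairs", {
  set.seed(32)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  base <- paste0(sample(aas, 100, replace = TRUE), collapse = "")
  other <- paste0(sample(aas, 100, replace = TRUE), collapse = "")
  proteomes <- list(sp1 = c(a = base), sp2 = c(b = base), sp3 = c(c = base,
                                                                  d = other))
  fams <- build_families(proteomes)
  expect_equal(length(fams), 2L)
  sizes <- sort(unname(vapply(fams, nrow, integer(1L))))
  expect_equal(sizes, c(1L, 3L))
  # no links: everything a singleton
  p1 <- paste0(rep("AW", 50), collapse = "")
  p2 <- paste0(rep("CH", 50), collapse = "")
  fams2 <- build_families(list(sp1 = c(a = p1), sp2 = c(b = p2)))
  expect_equal(length(fams2), 2L)
  # partition property: disjoint and covering
  all_keys <- unlist(lapply(fams, function(m) paste(m$species, m$gene_id)))
  expect_equal(anyDuplicated(all_keys), 0L)
  expect_equal(length(all_keys), 4L)
})

test_that("a background-only simulated clade yields one five-species family per gene", {
  sim <- simulate_clade(n_genes = 10L, events = list(), seed = 5L)
  proteomes <- lapply(sim$genomes, proteome)
  fams <- build_families(proteomes)
  expect_equal(length(fams), 10L)
  expect_true(all(vapply(fams, function(m) length(unique(m$species)),
                         integer(1L)) == 5L))
})

test_that("candidate selection keeps focal-restricted multi-species families only", {
  part <- clade_partition(c("dsim", "dsec", "dmel"), c("dyak", "dere"))
  fam <- function(...) {
    sp <- c(...)
    data.frame(species = sp, gene_id = paste0("g", seq_along(sp)),
               stringsAsFactors = FALSE)
  }
  families <- list(F1 = fam("dsim", "dsec"),
                   F2 = fam("dsim"),
                   F3 = fam("dsim", "dyak"),
                   F4 = fam("dsim", "dsec", "dmel", "dyak", "dere"),
                   F5 = fam("dsec", "dmel"))
  sel <- select_trgf_candidates(families, part)
  expect_setequal(names(sel), c("F1", "F5"))
  # invariant to the order species appear in the family table
  families_rev <- lapply(families, function(m) m[rev(seq_len(nrow(m))), ])
  expect_setequal(names(select_trgf_candidates(families_rev, part)),
                  c("F1", "F5"))
})

test_that("protein screen removes a family only when every member hits outside", {
  set.seed(33)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  shared <- paste0(sample(aas, 110, replace = TRUE), collapse = "")
  novel <- paste0(sample(aas, 110, replace = TRUE), collapse = "")
  members <- list(dsim = c(x = shared, y = novel), dsec = c(z = shared))
  outgroups <- list(dyak = c(h = shared))
  fam_all_hit <- list(FA = data.frame(species = c("dsim", "dsec"),
                                      gene_id = c("x", "z")))
  fam_partial <- list(FB = data.frame(species = c("dsim", "dsim"),
                                      gene_id = c("x", "y")))
  resA <- protein_screen(fam_all_hit, members, outgroups)
  expect_equal(names(resA$removed), "FA")
  resB <- protein_screen(fam_partial, members, outgroups)
  expect_equal(names(resB$kept), "FB")
  expect_length(resB$removed, 0L)
})
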