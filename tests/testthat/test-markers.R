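test_that("SSU detection recovers implanted loci at their coordinates", {
  sim <- small_sim()
  reg <- sim$registry
  for (g in c("p1_g1", "p3_g2")) {
    asm <- assembly(g, sim$genomes[[g]])
    loci <- detect_ssu(asm, sim$ssu_family)
    want <- reg[reg$genome_id == g & reg$kind == "SSU", ]
    expect_equal(nrow(loci), nrow(want))
    want <- want[order(want$start), ]
    loci <- loci[order(loci$start), ]
    expect_true(all(abs(loci$start - want$start) <= 10))
    expect_true(all(abs(loci$end - want$end) <= 10))
  }
})

test_that("assemblies without SSU-like regions yield no loci", {
  set.seed(51)
  asm <- assembly("r", c(s = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                                   collapse = "")))
  loci <- detect_ssu(asm, small_sim()$ssu_family)
  expect_equal(nrow(loci), 0)
  sc <- ssu_contamination(loci, small_sim()$tree)
  expect_true(is.na(sc$contamination)) # devoid of SSU: missing value
})

test_that("SSU detection works on the reverse strand", {
  sim <- small_sim()
  reg <- sim$registry
  ssu <- reg[reg$genome_id == "p2_g1" & reg$kind == "SSU", ][1, ]
  s <- sim$genomes[["p2_g1"]][[1]]
  frag <- substr(s, max(1, ssu$start - 1000), ssu$end + 1000)
  asm <- assembly("rc", c(s = revcomp(frag)))
  loci <- detect_ssu(asm, sim$ssu_family)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$strand, "-")
  expect_equal(loci$best_ref, "p2_g1")
})

test_that("ssu_contamination computes the foreign ratio", {
  tree <- toy_tree()
  loci <- data.frame(best_taxon_id = c("a1", "b1"))
  expect_equal(ssu_contamination(loci, tree)$contamination, 50)
  loci3 <- data.frame(best_taxon_id = c("a1", "b1", "b1"))
  expect_equal(ssu_contamination(loci3, tree)$contamination, 100 * 2 / 3)
})

test_that("rprot detection assigns candidates to their true family", {
  sim <- small_sim()
  asm <- assembly("p2_g2", sim$genomes[["p2_g2"]])
  cand <- detect_rprot_orthologues(asm, sim$rprot_families)
  reg <- sim$registry[sim$registry$genome_id == "p2_g2" &
                        sim$registry$kind == "rprot", ]
  expect_equal(nrow(cand), nrow(reg))
  # coordinates pair up family by family
  m <- merge(cand, reg, by = "family_id")
  expect_true(all(m$start.x < m$end.y & m$end.x > m$start.y))
})

test_that("random intergenic sequence yields no rprot candidate", {
  set.seed(52)
  asm <- assembly("r", c(s = paste(sample(c("A", "C", "G", "T"), 15000, TRUE),
                                   collapse = "")))
  cand <- detect_rprot_orthologues(asm, small_sim()$rprot_families)
  expect_true(is.null(cand) || nrow(cand) == 0)
})

test_that("classify_marker follows the top-3 neighbour LCA rule", {
  sim <- small_sim()
  tree <- sim$tree
  fam <- sim$rprot_families[[1]]
  # a focal genome's own marker: neighbours are focal, label FOCAL
  own <- fam$references$sequence[fam$references$genome_id == "p1_g1"]
  r <- classify_marker(own, fam, tree)
  expect_equal(r$label, "FOCAL")
  # only the focal references are close enough to pass the 70% cutoff
  expect_lte(nrow(r$neighbours), 3)
  expect_true(all(label_of(tree, r$neighbours$taxon_id) == "FOCAL"))
  expect_equal(r$neighbours$identity[1], 100)

  # a contaminant genome's marker: nearest references share its phylum
  foreign <- fam$references$sequence[fam$references$genome_id == "p4_g2"]
  expect_equal(classify_marker(foreign, fam, tree)$label, "CONTAMINANT")

  # nothing close enough: unclassified
  set.seed(53)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 150, TRUE),
                collapse = "")
  expect_equal(classify_marker(junk, fam, tree)$label, "UNCLASSIFIED")
})

test_that("marker labels are stable under reference duplication", {
  sim <- small_sim()
  tree <- sim$tree
  fam <- sim$rprot_families[[2]]
  fam_dup <- fam
  dup <- fam$references[1, ]
  dup$ref_id <- paste0(dup$ref_id, "_copy")
  fam_dup$references <- rbind(fam$references, dup)
  for (g in c("p1_g1", "p3_g1", "p5_g2")) {
    pep <- fam$references$sequence[fam$references$genome_id == g]
    expect_equal(classify_marker(pep, fam_dup, tree)$label,
                 classify_marker(pep, fam, tree)$label)
  }
})

test_that("marker estimators recover the registry ratios on a chimera", {
  sim <- small_sim()
  tree <- sim$tree
  chim <- small_chimera()
  mt <- chim$marker_truth
  host <- chim$host_id

  loci <- detect_ssu(chim$assembly, sim$ssu_family)
  sc <- ssu_contamination(loci, tree)
  expect_equal(sc$total_predicted, sum(mt$kind == "SSU"))
  expect_equal(sc$foreign, sum(mt$kind == "SSU" & mt$genome_id != host))

  rp <- rprot_contamination(chim$assembly, sim$rprot_families, tree)
  expect_equal(rp$classified, sum(mt$kind == "rprot"))
  expect_equal(rp$foreign, sum(mt$kind == "rprot" & mt$genome_id != host))
})

test_that("pure assemblies give complete, non-redundant marker panels", {
  sim <- small_sim()
  tree <- sim$tree
  asm <- assembly("p1_g2", sim$genomes[["p1_g2"]])
  rp <- rprot_contamination(asm, sim$rprot_families, tree)
  expect_equal(rp$contamination, 0)
  red <- redundancy_estimate(rp$hits, names(sim$rprot_families))
  expect_equal(red$completeness, 100)
  expect_equal(red$contamination, 0)
})

test_that("redundancy arithmetic matches copy-count bookkeeping", {
  hits1 <- data.frame(family_id = paste0("L", 1:10),
                      scaffold_id = "s", start = (1:10) * 1000)
  r1 <- redundancy_estimate(hits1, paste0("L", 1:10))
  expect_equal(r1$completeness, 100)
  expect_equal(r1$contamination, 0)

  hits3 <- data.frame(family_id = rep(paste0("L", 1:10), 3),
                      scaffold_id = rep(c("a", "b", "c"), each = 10),
                      start = rep((1:10) * 1000, 3))
  r3 <- redundancy_estimate(hits3, paste0("L", 1:10))
  expect_equal(r3$completeness, 100)
  expect_equal(r3$contamination, 200) # the beyond-100% regime

  r5 <- redundancy_estimate(hits1[1:5, ], paste0("L", 1:10))
  expect_equal(r5$completeness, 50)
  expect_equal(r5$contamination, 0)

  expect_error(redundancy_estimate(hits1, character(0)), "empty")
})

test_that("collocation merging collapses nearby marker hits", {
  hits <- data.frame(family_id = c("L1", "L2", "L1"),
                     scaffold_id = "s", start = c(1000, 2000, 40000))
  r <- redundancy_estimate(hits, c("L1", "L2"), collocate = TRUE)
  # the two L1 copies are far apart and stay distinct; L1+L2 at 1-2 kb
  # merge into one unit, so L2 is no longer counted separately
  expect_equal(unname(r$copy_counts["L1"]), 2L)
  expect_equal(unname(r$copy_counts["L2"]), 0L)
})

test_that("marker panel FASTA round trips", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_marker_panel(c(sim$rprot_families[1:2], list(SSU = sim$ssu_family)), d)
  back <- read_marker_panel(d)
  expect_setequal(names(back),
                  c(names(sim$rprot_families[1:2]), "SSU"))
  expect_equal(back[["SSU"]]$kind, "nucleotide")
  expect_equal(back[[names(sim$rprot_families)[1]]]$references,
               sim$rprot_families[[1]]$references,
               ignore_attr = TRUE)
})
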