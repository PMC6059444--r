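test_that("simulated taxonomy has the promised shape and labels", {
  cfg <- sim_config(seed = 1, n_phyla = 2, genomes_per_phylum = 1)
  tree <- simulate_taxonomy(cfg)
  leaves <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
  expect_length(leaves, 2)
  expect_equal(label_of(tree, "p1_g1"), "FOCAL")
  expect_equal(label_of(tree, "p2_g1"), "CONTAMINANT")
  expect_equal(label_of(tree, tree$root_id), "UNKNOWN")
  expect_equal(label_of(tree, "dom"), "UNKNOWN")
})

test_that("simulation is byte-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 5, genome_length = 2e4, n_rprot_families = 2,
                    n_phyla = 2)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$proteome, s2$proteome)
  expect_identical(s1$registry, s2$registry)
})

test_that("realized GC tracks the phylum target within 3 points", {
  sim <- small_sim()
  targets <- rep(seq(35, 65, length.out = 5), each = 2)
  gc <- vapply(sim$genomes, gc_content, numeric(1))
  expect_true(all(abs(gc - targets) <= 3))
})

test_that("within-phylum genomes are compositionally closer than between", {
  sim <- small_sim()
  vec <- function(g) kmer_vectors(c(x = sim$genomes[[g]][[1]]))[1, ]
  d <- function(a, b) sqrt(sum((vec(a) - vec(b))^2))
  within <- c(d("p1_g1", "p1_g2"), d("p3_g1", "p3_g2"), d("p5_g1", "p5_g2"))
  between <- c(d("p1_g1", "p3_g1"), d("p3_g1", "p5_g1"), d("p1_g2", "p5_g2"))
  expect_true(max(within) < min(between))
})

test_that("registry loci are non-overlapping and markers lie where recorded", {
  sim <- small_sim()
  reg <- sim$registry
  for (g in unique(reg$genome_id)) {
    r <- reg[reg$genome_id == g, ]
    r <- r[order(r$start), ]
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    # SSU loci contain the genome's own SSU reference verbatim
    ssu <- r[r$kind == "SSU", ][1, ]
    expect_equal(substr(sim$genomes[[g]][[1]], ssu$start + 1, ssu$end),
                 sim$ssu_family$references$sequence[
                   sim$ssu_family$references$genome_id == g])
  }
})

test_that("chimeras keep exact bookkeeping of the contaminant fraction", {
  sim <- small_sim()
  cfg0 <- sim$config; cfg0$contaminant_fraction <- 0
  pure <- build_chimera(sim, "p1_g1", character(0), config = cfg0, seed = 3)
  expect_equal(pure$true_fraction, 0)
  expect_identical(paste(pure$assembly$seqs, collapse = ""),
                   sim$genomes[["p1_g1"]][[1]])

  chim <- small_chimera()
  truth_bases <- sum((chim$truth$end - chim$truth$start)[
    chim$truth$source_genome != "p1_g1"])
  expect_equal(chim$true_fraction,
               100 * truth_bases / sum(nchar(chim$assembly$seqs)))
  # every truth interval matches the actual assembled sequence origin
  for (i in seq_len(nrow(chim$truth))) {
    tr <- chim$truth[i, ]
    expect_equal(nchar(chim$assembly$seqs[[tr$scaffold_id]]) >= tr$end, TRUE)
  }
})

test_that("chimeric_scaffold_rate = 1 concatenates every block onto a host scaffold", {
  sim <- small_sim()
  cfg1 <- sim$config; cfg1$chimeric_scaffold_rate <- 1
  chim <- suppressWarnings(
    build_chimera(sim, "p1_g2", "p4_g1", config = cfg1, seed = 9))
  cont <- chim$truth[chim$truth$source_genome == "p4_g1", ]
  host_scaffolds <- chim$truth$scaffold_id[chim$truth$source_genome == "p1_g2"]
  expect_true(all(cont$scaffold_id %in% host_scaffolds))
  expect_true(all(cont$start > 0)) # appended, never a scaffold of its own
})

test_that("error-free reads are exact substrings and depth is conserved", {
  sim <- small_sim()
  chim <- small_chimera()
  cfg <- sim$config
  cfg$host_depth <- 4; cfg$contaminant_depth <- 2
  rr <- simulate_reads(chim, cfg, seed = 4)
  idx <- sample(seq_len(nrow(rr$reads)), 50)
  same <- vapply(idx, function(i) {
    r <- rr$reads[i, ]
    substr(chim$assembly$seqs[[r$scaffold_id]], r$start + 1, r$end) ==
      r$sequence
  }, logical(1))
  expect_true(all(same))
  # the exact depth track integrates to reads x read length
  expect_equal(sum((rr$track$end - rr$track$start) * rr$track$depth),
               nrow(rr$reads) * cfg$read_length)
})

test_that("substitution errors appear at roughly the requested rate", {
  sim <- small_sim()
  chim <- small_chimera()
  cfg <- sim$config
  cfg$host_depth <- 1; cfg$contaminant_depth <- 1
  cfg$read_error_rate <- 0.05
  rr <- simulate_reads(chim, cfg, seed = 6)
  r <- rr$reads[1:100, ]
  ref <- substring(chim$assembly$seqs[r$scaffold_id], r$start + 1, r$end)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), r$sequence, ref))
  rate <- mism / sum(nchar(ref))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("write_fastq emits one well-formed record per read", {
  sim <- small_sim()
  chim <- small_chimera()
  cfg <- sim$config; cfg$host_depth <- 0.5; cfg$contaminant_depth <- 0.5
  rr <- simulate_reads(chim, cfg, seed = 8)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rr$reads, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4 * nrow(rr$reads))
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_equal(nchar(lines[seq(2, length(lines), 4)]),
               nchar(lines[seq(4, length(lines), 4)]))
})

test_that("make_reference_db excludes genomes everywhere", {
  sim <- small_sim()
  db <- make_reference_db(sim, exclude = c("p1_g1", "p2_g1"))
  expect_false("p1_g1" %in% names(db$genomes))
  expect_false("p1_g1" %in% db$proteome$genome_id)
  expect_false(any(vapply(db$rprot_families, function(f)
    "p1_g1" %in% f$references$genome_id, logical(1))))
  expect_false("p2_g1" %in% db$ssu_family$references$genome_id)
  expect_error(make_reference_db(sim, exclude = names(sim$genomes)),
               "every genome excluded")
})

test_that("excluding the query genus pushes kmer labels rootward", {
  sim <- small_sim()
  tree <- sim$tree
  asm <- assembly("p2_g1", sim$genomes[["p2_g1"]])
  reads <- make_pseudoreads(asm)[seq(1, 200, by = 4), ]
  full <- build_kmer_index(sim$genomes, sim$taxa, tree)
  isolated <- make_reference_db(sim, exclude = c("p2_g1", "p2_g2"))
  iso_idx <- build_kmer_index(isolated$genomes, isolated$taxa, tree)
  lab_full <- classify_reads_kmer(reads, full, tree)
  lab_iso <- classify_reads_kmer(reads, iso_idx, tree)
  uncl <- function(l) mean(l$label %in% c("UNKNOWN", "UNCLASSIFIED"))
  expect_gt(uncl(lab_iso), uncl(lab_full))
})
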