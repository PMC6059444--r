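# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# small simulated world: 5 phyla x 2 genomes of 60 kb, 5 marker families
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(
      sim_config(seed = 3, genome_length = 6e4, n_rprot_families = 5))
  }
  .fixture_env$sim
}

small_kmer_index <- function() {
  if (is.null(.fixture_env$kidx)) {
    sim <- small_sim()
    .fixture_env$kidx <- build_kmer_index(sim$genomes, sim$taxa, sim$tree)
  }
  .fixture_env$kidx
}

small_protein_db <- function() {
  if (is.null(.fixture_env$pdb)) {
    .fixture_env$pdb <- protein_db(small_sim()$proteome)
  }
  .fixture_env$pdb
}

small_chimera <- function() {
  if (is.null(.fixture_env$chim)) {
    .fixture_env$chim <- suppressWarnings(
      build_chimera(small_sim(), "p1_g1", "p5_g1", seed = 11))
  }
  .fixture_env$chim
}

# hand-built taxonomy:
# root -> dom -> {phyA -> genA -> {a1, a2}, phyB -> genB -> {b1}}
toy_tree <- function() {
  taxonomy(data.frame(
    taxon_id = c("root", "dom", "phyA", "genA", "a1", "a2",
                 "phyB", "genB", "b1"),
    parent_id = c(NA, "root", "dom", "phyA", "genA", "genA",
                  "dom", "phyB", "genB"),
    rank = c("no-rank", "superkingdom", "phylum", "genus", "species",
             "species", "phylum", "genus", "species"),
    name = c("root", "domain", "A", "gA", "a1", "a2", "B", "gB", "b1"),
    stringsAsFactors = FALSE
  ), focal_id = "phyA")
}

# random rooted tree with n nodes (node 1 is the root); returns taxonomy
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
  taxonomy(data.frame(
    taxon_id = paste0("t", seq_len(n)),
    parent_id = ifelse(is.na(parent), NA, paste0("t", parent)),
    rank = "no-rank", name = paste0("node", seq_len(n)),
    stringsAsFactors = FALSE
  ), focal_id = paste0("t", sample.int(n, 1)))
}

# brute-force LCA oracle: intersect root paths, take the deepest member
lca_oracle <- function(tree, taxa) {
  paths <- lapply(taxa, function(t) ancestors(tree, t))
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[common])]
}

# independent naive Smith-Waterman with affine gaps (linear-space-naive,
# O(nm) with explicit three-matrix recursion) for oracle checks
sw_oracle <- function(a, b, mat, gap_open, gap_extend) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  Ix <- matrix(-Inf, n + 1, m + 1) # gap in y (deletion from a)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[x[i - 1], y[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

expect_label <- function(object, label) {
  expect_equal(object$label, label)
}
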