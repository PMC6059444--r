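# helper: index whose entries map given canonical codes to given taxa
manual_index <- function(codes, taxa, k = 21L, source = character(0)) {
  entries <- data.table::data.table(code = codes, taxon_id = taxa)
  data.table::setkeyv(entries, "code")
  structure(list(k = k, entries = entries, source_genomes = source),
            class = "kmer_index")
}

random_read <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# independent oracle for the kmer classifier: exhaustive path enumeration
# over all nodes, then the confidence-promotion loop
kmer_oracle <- function(tree, counts, total, conf) {
  hit <- names(counts)
  score <- vapply(hit, function(t)
    sum(counts[intersect(ancestors(tree, t), hit)]), numeric(1))
  top <- hit[score == max(score)]
  leafmost <- top[!vapply(top, function(t)
    any(vapply(setdiff(top, t), function(o)
      t %in% ancestors(tree, o), logical(1))), logical(1))]
  cand <- if (length(leafmost) > 1) lca(tree, leafmost) else leafmost
  repeat {
    inside <- vapply(hit, function(t) cand %in% ancestors(tree, t), logical(1))
    if (sum(counts[hit[inside]]) / total >= conf) return(cand)
    if (cand == tree$root_id) return(NA_character_)
    cand <- tree$parent[[cand]]
  }
}

test_that("kmer classifier resolves the 60/40 sibling split by path score", {
  tree <- toy_tree()
  read <- random_read(120, seed = 31) # 100 kmers
  codes <- kmer_codes(read, 21)
  expect_false(anyNA(codes))
  expect_equal(length(unique(codes)), 100)
  idx <- manual_index(codes, c(rep("a1", 60), rep("a2", 40)))

  res <- classify_read_kmer(read, idx, tree, kmer_config(confidence = 0.5))
  expect_equal(res$taxon_id, "a1") # path score 60 beats 40
  expect_equal(res$confidence, 0.6)
  expect_equal(res$label, "FOCAL")

  # a higher threshold promotes to the genus, whose clade holds all hits
  res2 <- classify_read_kmer(read, idx, tree, kmer_config(confidence = 0.7))
  expect_equal(res2$taxon_id, "genA")
  expect_equal(res2$confidence, 1.0)
})

test_that("kmer classifier handles no hits, verbatim reads and short input", {
  tree <- toy_tree()
  read <- random_read(120, seed = 32)
  idx_empty <- manual_index(numeric(0), character(0))
  res <- classify_read_kmer(read, idx_empty, tree)
  expect_equal(res$label, "UNCLASSIFIED")
  expect_true(is.na(res$taxon_id))

  # all kmers from one leaf: that leaf at confidence 1
  codes <- kmer_codes(read, 21)
  res2 <- classify_read_kmer(read, manual_index(codes, rep("b1", 100)), tree)
  expect_equal(res2$taxon_id, "b1")
  expect_equal(res2$confidence, 1)
  expect_equal(res2$label, "CONTAMINANT")

  expect_error(classify_read_kmer(substr(read, 1, 10),
                                  manual_index(codes, rep("b1", 100)), tree),
               "shorter than k")
})

test_that("kmer classifier agrees with the exhaustive-path oracle", {
  tree <- toy_tree()
  ids <- tree$nodes$taxon_id
  for (i in 1:25) {
    read <- random_read(141, seed = 400 + i) # 121 kmers
    codes <- unique(kmer_codes(read, 21))
    set.seed(500 + i)
    n_hit <- sample(10:length(codes), 1)
    taxa <- sample(ids, n_hit, TRUE)
    idx <- manual_index(codes[seq_len(n_hit)], taxa)
    conf <- sample(c(0.02, 0.1, 0.3, 0.6), 1)
    got <- classify_read_kmer(read, idx, tree, kmer_config(confidence = conf))
    counts <- table(taxa)
    counts <- setNames(as.numeric(counts), names(counts))
    want <- kmer_oracle(tree, counts, length(codes), conf)
    expect_identical(got$taxon_id, want)
  }
})

test_that("raising the confidence threshold only promotes rootward", {
  tree <- toy_tree()
  ids <- tree$nodes$taxon_id
  for (i in 1:10) {
    read <- random_read(141, seed = 600 + i)
    codes <- unique(kmer_codes(read, 21))
    set.seed(700 + i)
    idx <- manual_index(codes, sample(ids, length(codes), TRUE))
    prev <- NULL
    for (conf in c(0.02, 0.04, 0.06, 0.2, 0.5)) {
      got <- classify_read_kmer(read, idx, tree,
                                kmer_config(confidence = conf))$taxon_id
      if (!is.null(prev)) {
        if (is.na(prev)) {
          expect_true(is.na(got)) # once unclassified, stays unclassified
        } else if (!is.na(got)) {
          expect_true(got %in% ancestors(tree, prev))
        }
      }
      prev <- got
    }
  }
})

make_hit <- function(query = "q1", subject = "s", genome = "g", taxon = "a1",
                     bit = 100) {
  data.frame(query_id = query, subject_id = subject,
             subject_genome_id = genome, subject_taxon_id = taxon,
             identity = 90, aln_len = 50, bit_score = bit, e_value = 1e-10,
             stringsAsFactors = FALSE)
}

test_that("protein LCA applies bit filters, top fraction and self-exclusion", {
  tree <- toy_tree()
  # single strong hit labels its taxon
  r <- classify_read_protein(make_hit(taxon = "b1", bit = 120), tree)
  expect_equal(r$taxon_id, "b1")
  expect_equal(r$label, "CONTAMINANT")

  # 94 < 0.95 * 100: second hit excluded, label follows the first alone
  h <- rbind(make_hit(subject = "s1", taxon = "a1", bit = 100),
             make_hit(subject = "s2", taxon = "b1", bit = 94))
  r2 <- classify_read_protein(h, tree)
  expect_equal(r2$taxon_id, "a1")
  expect_equal(r2$n_hits_used, 1)

  # two siblings within the window collapse to their parent
  h3 <- rbind(make_hit(subject = "s1", taxon = "a1", bit = 100),
              make_hit(subject = "s2", taxon = "a2", bit = 96))
  r3 <- classify_read_protein(h3, tree)
  expect_equal(r3$taxon_id, "genA")
  expect_equal(r3$label, "FOCAL")

  # two phyla collapse to the domain: classified but unknown
  h4 <- rbind(make_hit(subject = "s1", taxon = "a1", bit = 100),
              make_hit(subject = "s2", taxon = "b1", bit = 96))
  expect_equal(classify_read_protein(h4, tree)$label, "UNKNOWN")

  # a lone self-match leaves the read unclassified
  r5 <- classify_read_protein(make_hit(genome = "self", bit = 150), tree,
                              self_genome_id = "self")
  expect_equal(r5$label, "UNCLASSIFIED")

  # hits below min_bit are unusable
  r6 <- classify_read_protein(make_hit(bit = 70), tree)
  expect_equal(r6$label, "UNCLASSIFIED")
})

test_that("raising top_fraction moves protein labels leafward or not at all", {
  tree <- toy_tree()
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(j)
      make_hit(subject = paste0("s", j),
               taxon = sample(tree$nodes$taxon_id, 1),
               bit = stats::runif(1, 80, 120))))
    lo <- classify_read_protein(h, tree, protein_lca_config(top_fraction = 0.9))
    hi <- classify_read_protein(h, tree, protein_lca_config(top_fraction = 0.99))
    expect_true(lo$taxon_id %in% ancestors(tree, hi$taxon_id))
  }
})

test_that("profiles partition reads and break them down by phylum", {
  tree <- toy_tree()
  labels <- data.frame(
    read_id = paste0("r", 1:10),
    taxon_id = c("a1", "a1", "a2", "b1", "dom", NA, NA, "a1", "b1", "phyA"),
    stringsAsFactors = FALSE)
  labels$label <- label_of(tree, labels$taxon_id)
  p <- profile_assembly(labels, tree, "x")
  expect_equal(p$contaminant, 20)
  expect_equal(p$focal, 50)
  expect_equal(p$unknown, 10)
  expect_equal(p$unclassified, 20)
  expect_equal(p$focal + p$contaminant + p$unknown + p$unclassified, 100)
  expect_equal(sum(p$per_phylum), 100)
  expect_equal(unname(p$per_phylum[["A"]]), 50)
  expect_equal(unname(p$per_phylum[["B"]]), 20)
  expect_error(profile_assembly(labels[0, ], tree), "at least one read")
})

test_that("the kmer NA mask flags only index source genomes", {
  idx <- manual_index(numeric(0), character(0), source = c("g1", "g2"))
  expect_true(kraken_na_mask("g1", idx))
  expect_false(kraken_na_mask("g3", idx))
  empty <- manual_index(numeric(0), character(0))
  expect_false(kraken_na_mask("g1", empty))
})

test_that("self-exclusion equals searching a database without the genome", {
  sim <- small_sim()
  tree <- sim$tree
  asm <- assembly("p1_g1", sim$genomes[["p1_g1"]])
  reads <- make_pseudoreads(asm)[1:40, ]
  db_full <- small_protein_db()
  db_without <- protein_db(
    sim$proteome[sim$proteome$genome_id != "p1_g1", ])
  h_full <- search_reads(reads, db_full, min_seeds = 2)
  h_wo <- search_reads(reads, db_without, min_seeds = 2)
  l1 <- classify_reads_protein(h_full, tree, self_genome_id = "p1_g1",
                               read_ids = reads$read_id)
  l2 <- classify_reads_protein(h_wo, tree, self_genome_id = NULL,
                               read_ids = reads$read_id)
  expect_identical(l1$taxon_id, l2$taxon_id)
  expect_identical(l1$label, l2$label)
})
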