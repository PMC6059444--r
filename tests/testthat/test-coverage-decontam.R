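toy_map_fixture <- function() {
  set.seed(81)
  # two scaffolds with distinct GC so ordering is testable
  lowgc <- paste(sample(c("A", "T", "G", "C"), 30000, TRUE,
                        prob = c(0.3, 0.3, 0.2, 0.2)), collapse = "")
  higc <- paste(sample(c("A", "T", "G", "C"), 20000, TRUE,
                       prob = c(0.2, 0.2, 0.3, 0.3)), collapse = "")
  asm <- assembly("t", c(hi = higc, lo = lowgc))
  reads <- make_pseudoreads(asm)
  labels <- data.frame(
    read_id = reads$read_id,
    taxon_id = NA_character_,
    label = ifelse(reads$scaffold_id == "hi", "CONTAMINANT", "FOCAL"),
    stringsAsFactors = FALSE)
  list(asm = asm, reads = reads, labels = labels)
}

test_that("segment_report orders scaffolds by GC and sums fractions to 100", {
  fx <- toy_map_fixture()
  rec <- segment_report(fx$asm, fx$reads, fx$labels)
  expect_equal(unique(rec$scaffold_id), c("lo", "hi")) # ascending GC
  sums <- rec$focal + rec$contaminant + rec$unknown + rec$unclassified
  expect_equal(sums, rep(100, nrow(rec)))
  expect_true(all(rec$contaminant[rec$scaffold_id == "hi"] == 100))
  expect_true(all(rec$focal[rec$scaffold_id == "lo"] == 100))
})

test_that("a read spanning a segment boundary contributes proportionally", {
  asm <- assembly("t", c(s = strrep("ACGT", 5000))) # 20,000 nt
  reads <- data.frame(read_id = "r1", scaffold_id = "s",
                      start = 9900L, end = 10150L,
                      sequence = strrep("A", 250))
  labels <- data.frame(read_id = "r1", taxon_id = NA, label = "CONTAMINANT")
  rec <- segment_report(asm, reads, labels)
  expect_equal(rec$contaminant, c(100, 100)) # only covered bases count
  expect_equal(rec$unclassified, c(0, 0))
})

test_that("scaffold labels follow the classified length majority", {
  rec <- data.frame(scaffold_id = "s", start = 0, end = 10000,
                    focal = 90, contaminant = 5, unknown = 5, unclassified = 0)
  expect_equal(scaffold_label(rec), "FOCAL")
  rec$focal <- 30; rec$contaminant <- 45
  expect_equal(scaffold_label(rec), "CONTAMINANT")
  rec$focal <- 0; rec$contaminant <- 0; rec$unclassified <- 100
  expect_equal(scaffold_label(rec), "UNDETERMINED")
  rec$focal <- 20; rec$contaminant <- 20
  expect_equal(scaffold_label(rec), "UNDETERMINED")
})

test_that("coverage statistics: constant depth, classes and QCD", {
  fx <- toy_map_fixture()
  len <- nchar(fx$asm$seqs)
  trk <- data.frame(scaffold_id = names(len), start = 0L, end = unname(len),
                    depth = 30)
  rec <- segment_report(fx$asm, fx$reads, fx$labels, coverage = trk)
  cs <- coverage_stats(rec)
  expect_equal(cs$per_class$median, rep(30, nrow(cs$per_class)))
  expect_equal(cs$per_class$iqr, rep(0, nrow(cs$per_class)))
  expect_equal(cs$qcd, 0)

  # single segment: median is its own coverage
  asm1 <- assembly("u", c(s = strrep("ACGT", 500)))
  reads1 <- make_pseudoreads(asm1)
  lab1 <- data.frame(read_id = reads1$read_id, taxon_id = NA, label = "FOCAL")
  trk1 <- data.frame(scaffold_id = "s", start = 0L, end = 2000L, depth = 12)
  rec1 <- segment_report(asm1, reads1, lab1, coverage = trk1)
  cs1 <- coverage_stats(rec1)
  expect_equal(cs1$per_class$median, 12)
  expect_equal(cs1$per_class$iqr, 0)

  rec_nocov <- segment_report(fx$asm, fx$reads, fx$labels)
  expect_error(coverage_stats(rec_nocov), "coverage")
})

test_that("bedGraph round trips and rejects malformed input", {
  trk <- data.frame(scaffold_id = c("a", "a", "b"),
                    start = c(0L, 100L, 0L), end = c(100L, 150L, 70L),
                    depth = c(3.5, 1, 0))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, f)
  back <- read_bedgraph(f)
  expect_equal(back$start, trk$start)
  expect_equal(back$depth, trk$depth)

  writeLines(c("a\t0\t100\t3.5", "a\t100\t150"), f)
  expect_error(read_bedgraph(f), "line 2")

  writeLines("a\t0\t5000\t3.5", f)
  asm <- assembly("x", c(a = strrep("ACGT", 100)))
  expect_error(read_bedgraph(f, asm), "beyond scaffold end")
})

test_that("the naive exact mapper recovers uniform depth", {
  set.seed(82)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  asm <- assembly("m", c(s = s))
  starts <- sample(0:(4000 - 100), 300, TRUE)
  reads <- substring(s, starts + 1, starts + 100)
  # mix in reverse-strand reads
  flip <- seq(1, 300, by = 3)
  reads[flip] <- revcomp(reads[flip])
  trk <- coverage_from_reads(asm, reads)
  mean_depth <- sum((trk$end - trk$start) * trk$depth) / 4000
  expect_lt(abs(mean_depth - 300 * 100 / 4000), 0.05 * 300 * 100 / 4000)
})

test_that("mask mode replaces exactly the contaminant intervals with N", {
  asm <- assembly("d", c(s = strrep("ACGT", 250))) # 1000 nt
  reads <- make_pseudoreads(asm)
  labels <- data.frame(read_id = reads$read_id, taxon_id = NA,
                       label = c("FOCAL", "CONTAMINANT", "FOCAL", "UNKNOWN"))
  out <- decontaminate(asm, reads, labels, mode = "mask")
  expect_equal(nchar(out$seqs[["s"]]), 1000)
  expect_equal(substr(out$seqs[["s"]], 251, 500), strrep("N", 250))
  expect_equal(substr(out$seqs[["s"]], 1, 250), substr(asm$seqs[["s"]], 1, 250))
  # UNKNOWN reads are never masked
  expect_equal(substr(out$seqs[["s"]], 751, 1000),
               substr(asm$seqs[["s"]], 751, 1000))

  # no contaminant: identity
  labels$label <- "FOCAL"
  expect_identical(decontaminate(asm, reads, labels, "mask")$seqs, asm$seqs)
})

test_that("drop mode removes scaffolds past the contaminant threshold", {
  asm <- assembly("d", c(bad = strrep("ACGT", 250), ok = strrep("ACGT", 250)))
  reads <- make_pseudoreads(asm)
  labels <- data.frame(
    read_id = reads$read_id, taxon_id = NA,
    label = ifelse(reads$scaffold_id == "bad", "CONTAMINANT", "FOCAL"))
  out <- decontaminate(asm, reads, labels, mode = "drop")
  expect_equal(names(out$seqs), "ok")
  expect_error(decontaminate(assembly("d", c(bad = strrep("ACGT", 250))),
                             reads[reads$scaffold_id == "bad", ],
                             labels, "drop"),
               "every scaffold dropped")
})
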