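test_that("rank_method ranks descending with averaged ties and kept NAs", {
  expect_equal(rank_method(c(10, 5, 5, 0)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_method(c(7, NA, 3)), c(1, NA, 2))
  expect_error(rank_method(c(NA_real_, NA_real_)), "all scores missing")
  # sort-based oracle on random vectors with ties and NAs
  set.seed(71)
  for (i in 1:50) {
    x <- sample(c(round(stats::runif(8), 1), NA, NA))
    if (all(is.na(x))) next
    got <- rank_method(x)
    ok <- !is.na(x)
    oracle <- rank(-x[ok], ties.method = "average")
    expect_equal(got[ok], oracle)
    expect_true(all(is.na(got[!ok])))
  }
})

test_that("consensus_rank averages non-missing ranks and breaks ties by id", {
  ranks <- matrix(c(1, 2, 3, 1, 3, 2), ncol = 2,
                  dimnames = list(c("a", "b", "c"), NULL))
  out <- consensus_rank(ranks)
  expect_equal(out$rank_avg, c(1, 2.5, 2.5))
  expect_equal(out$global_rank, c(1, 2, 3)) # b before c by id

  withna <- matrix(c(1, 2, NA, 1, 3, 2), ncol = 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  out2 <- consensus_rank(withna)
  expect_equal(out2$rank_avg, c(1, 2.5, 2)) # c: mean over one method

  allna <- matrix(c(1, NA, 2, NA), ncol = 2,
                  dimnames = list(c("a", "b"), NULL))
  expect_error(consensus_rank(allna), "b")

  # permuting method columns changes nothing
  expect_equal(consensus_rank(ranks[, 2:1])$rank_avg, out$rank_avg)
})

test_that("consensus is invariant to monotone transforms of one method", {
  set.seed(72)
  scores <- matrix(stats::runif(30, 0, 50), ncol = 3,
                   dimnames = list(paste0("g", 1:10), c("m1", "m2", "m3")))
  r1 <- consensus_rank(apply(scores, 2, rank_method))
  scores2 <- scores
  scores2[, 2] <- exp(scores2[, 2] / 10) # strictly monotone
  r2 <- consensus_rank(apply(scores2, 2, rank_method))
  expect_equal(r1$rank_avg, r2$rank_avg)
  expect_equal(r1$global_rank, r2$global_rank)
})

test_that("an assembly worst everywhere takes global rank 1", {
  set.seed(73)
  scores <- matrix(stats::runif(24, 0, 20), ncol = 3,
                   dimnames = list(paste0("g", 1:8), NULL))
  base <- consensus_rank(apply(scores, 2, rank_method))
  worst <- rbind(scores, zz = c(99, 99, 99))
  out <- consensus_rank(apply(worst, 2, rank_method))
  expect_equal(out$global_rank[out$assembly_id == "zz"], 1)
  rest <- out[out$assembly_id != "zz", ]
  expect_equal(order(rest$global_rank), order(base$global_rank))
})

test_that("spearman matches rank-then-Pearson and handles NAs pairwise", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, x), 1)
  expect_equal(spearman(x, rev(x)), -1)
  expect_equal(spearman(x, x + 100), 1)
  set.seed(74)
  for (i in 1:50) {
    a <- sample(c(round(stats::runif(12), 1), NA))
    b <- sample(c(round(stats::runif(12), 1), NA))
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) next
    expect_equal(spearman(a, b),
                 stats::cor(a[ok], b[ok], method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman(c(1, NA, 3), c(NA, 2, 3)), "3 complete pairs")
})

test_that("categorize applies the published band boundaries", {
  sc <- function(red = 0, rrna = 0, rprot = 0, kmer = 0, prot = 0, bin = 0) {
    c(rRNA = rrna, rprot = rprot, redundancy = red, kmer = kmer,
      protein = prot, binning = bin)
  }
  expect_equal(categorize(sc(red = 104.63))$redundancy_category, "very_high")
  expect_equal(categorize(sc(red = 12))$redundancy_category, "high")
  expect_equal(categorize(sc(red = 7))$redundancy_category, "moderate")
  expect_equal(categorize(sc(red = 5))$redundancy_category, "low")
  expect_equal(categorize(sc(red = 0))$redundancy_category, "none")

  expect_equal(categorize(sc(rrna = 50))$ribosomal_category, 1)
  expect_equal(categorize(sc(rrna = 50, rprot = 10))$ribosomal_category, 2)
  expect_equal(categorize(sc())$flagged_method_count, 0)
  expect_equal(categorize(sc(red = 3, rrna = 1, kmer = 2))$flagged_method_count, 3)
  # genome-wide methods need the 1% floor, marker methods any positive
  expect_equal(categorize(sc(kmer = 0.5, prot = 0.5, bin = 0.5))$flagged_method_count, 0)
  expect_equal(categorize(sc(rprot = 0.5))$flagged_method_count, 1)
})

test_that("consensus_report assembles the ranking table", {
  set.seed(75)
  scores <- matrix(stats::runif(18, 0, 30), ncol = 6,
                   dimnames = list(paste0("g", 1:3),
                                   c("rRNA", "rprot", "redundancy", "kmer",
                                     "protein", "binning")))
  scores["g2", "kmer"] <- NA
  rep <- consensus_report(scores)
  expect_equal(sort(rep$global_rank), 1:3)
  expect_equal(rep$assembly_id[order(rep$rank_avg)], rep$assembly_id)
  expect_true(all(c("redundancy_category", "flagged_method_count")
                  %in% names(rep)))
})
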