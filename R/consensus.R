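# Per-method ranking, NA-aware rank averaging into a global consensus
# ranking, contamination categories and Spearman congruence analysis.

#' Rank one method's contamination scores
#'
#' Rank 1 is the most contaminated assembly; ties receive the average of
#' the positions they cover; missing scores stay missing.
#'
#' @param scores numeric vector (NA allowed).
#' @return Numeric ranks, same length and names.
#' @export
rank_method <- function(scores) {
  if (all(is.na(scores))) stop("rank_method(): all scores missing")
  rank(-scores, ties.method = "average", na.last = "keep")
}

#' Consensus ranking over the per-method rank table
#'
#' Each assembly's consensus score is the arithmetic mean of its
#' non-missing per-method ranks; the global rank orders this average
#' ascending (1 = most contaminated), breaking exact ties
#' lexicographically by assembly id.
#'
#' @param ranks matrix or data.frame, assemblies x methods, of
#'   per-method ranks (from [rank_method()] per column); rownames are
#'   assembly ids.
#' @return data.frame: `assembly_id`, `rank_avg`, `global_rank`.
#' @export
consensus_rank <- function(ranks) {
  ranks <- as.matrix(ranks)
  ids <- rownames(ranks)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ranks)))
  all_na <- rowSums(!is.na(ranks)) == 0
  if (any(all_na)) {
    stop("assembly with no non-missing rank: ", ids[all_na][1])
  }
  rank_avg <- rowMeans(ranks, na.rm = TRUE)
  ord <- order(rank_avg, ids)
  global_rank <- integer(length(ord))
  global_rank[ord] <- seq_along(ord)
  data.frame(assembly_id = ids, rank_avg = rank_avg,
             global_rank = global_rank, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with pairwise-complete observations
#'
#' Pearson correlation of averaged-tie ranks over the indices where both
#' vectors are present.
#'
#' @param x,y numeric vectors of equal length (NA allowed).
#' @return rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("spearman() needs at least 3 complete pairs")
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Pairwise Spearman correlation matrix of a score table
#' @param scores assemblies x methods matrix/data.frame.
#' @return methods x methods correlation matrix.
#' @export
spearman_matrix <- function(scores) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  out <- matrix(NA_real_, m, m, dimnames = list(colnames(scores), colnames(scores)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    out[i, j] <- spearman(scores[, i], scores[, j])
  }
  out
}

#' Contamination categories and flag counts for one assembly
#'
#' The redundancy-based category uses the conventional bands none (=0),
#' low (<=5), moderate (>5-10), high (>10-15), very_high (>15). The
#' ribosomal category counts how many of the two ribosomal-gene methods
#' (SSU rRNA, ribosomal proteins) report any foreign marker. The flagged
#' method count applies a per-method threshold: any positive score for
#' the marker methods, and at least `genomewide_flag` percent for the
#' three genome-wide methods (whose scores are noisy near zero).
#'
#' @param scores named numeric vector with entries `rRNA`, `rprot`,
#'   `redundancy`, `kmer`, `protein`, `binning` (NA allowed).
#' @param genomewide_flag flag threshold for kmer/protein/binning
#'   (default 1.0 percent).
#' @return List: `redundancy_category`, `ribosomal_category`,
#'   `flagged_method_count`.
#' @export
categorize <- function(scores, genomewide_flag = 1.0) {
  red <- scores[["redundancy"]]
  redundancy_category <- if (is.na(red)) NA_character_
    else if (red == 0) "none"
    else if (red <= 5) "low"
    else if (red <= 10) "moderate"
    else if (red <= 15) "high"
    else "very_high"
  rib <- c(scores[["rRNA"]], scores[["rprot"]])
  ribosomal_category <- sum(!is.na(rib) & rib > 0)
  marker_flags <- vapply(c("rRNA", "rprot", "redundancy"),
                         function(m) !is.na(scores[[m]]) && scores[[m]] > 0,
                         logical(1))
  gw_flags <- vapply(c("kmer", "protein", "binning"),
                     function(m) !is.na(scores[[m]]) &&
                       scores[[m]] >= genomewide_flag, logical(1))
  list(redundancy_category = redundancy_category,
       ribosomal_category = ribosomal_category,
       flagged_method_count = sum(marker_flags) + sum(gw_flags))
}

#' Build the consensus report from a method-score matrix
#'
#' @param scores assemblies x methods matrix/data.frame with columns
#'   `rRNA`, `rprot`, `redundancy`, `kmer`, `protein`, `binning`
#'   (rownames = assembly ids, NA allowed).
#' @param stats optional data.frame from [compute_stats()] rows, matched
#'   by `assembly_id`.
#' @param genomewide_flag see [categorize()].
#' @return data.frame sorted by global rank, with the six method
#'   columns, `rank_avg`, `global_rank`, categories and flag counts.
#' @export
consensus_report <- function(scores, stats = NULL, genomewide_flag = 1.0) {
  scores <- as.matrix(scores)
  ranks <- apply(scores, 2, rank_method)
  rownames(ranks) <- rownames(scores)
  cons <- consensus_rank(ranks)
  cats <- lapply(seq_len(nrow(scores)), function(i) {
    categorize(stats::setNames(scores[i, ], colnames(scores)), genomewide_flag)
  })
  out <- cbind(cons["assembly_id"], as.data.frame(scores, row.names = NULL),
               cons[c("rank_avg", "global_rank")])
  out$redundancy_category <- vapply(cats, `[[`, character(1), "redundancy_category")
  out$ribosomal_category <- vapply(cats, `[[`, double(1), "ribosomal_category")
  out$flagged_method_count <- vapply(cats, `[[`, double(1), "flagged_method_count")
  if (!is.null(stats)) {
    i <- match(out$assembly_id, stats$assembly_id)
    out <- cbind(out[1], stats[i, c("n_scaffolds_ge_1000", "total_length_ge_1000")],
                 out[-1])
  }
  out <- out[order(out$global_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
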