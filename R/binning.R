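# Reference-free contamination estimate: short-kmer frequency vectors per
# segment, PCA, Gaussian-mixture clustering with an information-criterion
# sweep over the number of groups, and the largest-group statistic.

canonical_classes <- function(kappa) {
  kmers <- decode_kmer(seq.int(0, 4^kappa - 1), kappa)
  canon <- pmin(kmers, revcomp(kmers))
  list(kmers = kmers, canon = canon, classes = sort(unique(canon)))
}

#' Canonical kmer frequency vectors for segments
#'
#' Counts kmers of size `kappa` with a kmer and its reverse complement
#' collapsed into one canonical class (for `kappa = 4`:
#' `(4^4 + 4^2) / 2 = 136` classes), adds a pseudocount of 1 per class,
#' normalizes to frequencies and applies a natural-log transform. The
#' vector is invariant under reverse complement of the segment.
#'
#' @param segments data.frame from [make_segments()] (needs
#'   `segment_id`, `sequence`), or a character vector of sequences.
#' @param kappa kmer size (default 4).
#' @return Numeric matrix, one row per segment, one column per canonical
#'   kmer class.
#' @export
kmer_vectors <- function(segments, kappa = 4L) {
  stopifnot(kappa >= 2)
  if (is.character(segments)) {
    segments <- data.frame(
      segment_id = if (is.null(names(segments)))
        paste0("seg", seq_along(segments)) else names(segments),
      sequence = unname(segments), stringsAsFactors = FALSE)
  }
  cc <- canonical_classes(kappa)
  raw <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(segments$sequence), width = kappa)
  grp <- factor(cc$canon, levels = cc$classes)
  coll <- t(rowsum(t(raw), group = grp))
  # palindromes were counted once; non-palindromic classes got both
  # orientations summed -- exactly the canonical count either way
  freq <- (coll + 1) / rowSums(coll + 1)
  out <- log(freq)
  rownames(out) <- segments$segment_id
  out
}

#' Binning configuration
#' @param kappa kmer size, 4-6 (default 4).
#' @param max_clusters upper bound on the number of groups (default 400;
#'   the criterion sweep is additionally capped by the number of
#'   segments).
#' @param min_segment minimum segment length (default 1000 nt).
#' @param pca_variance fraction of variance the retained principal
#'   components must explain (default 0.90).
#' @param seed RNG seed for the clustering.
#' @export
binning_config <- function(kappa = 4L, max_clusters = 400L,
                           min_segment = 1000L, pca_variance = 0.90,
                           seed = 1L) {
  stopifnot(kappa >= 2, max_clusters >= 2)
  list(kappa = kappa, max_clusters = max_clusters, min_segment = min_segment,
       pca_variance = pca_variance, seed = seed)
}

#' Cluster segments by kmer composition
#'
#' Center-scales the log-frequency vectors, projects onto the leading
#' principal components explaining at least `pca_variance` of the
#' variance, and fits Gaussian mixtures over an increasing number of
#' components, selecting the model by BIC (components that would be
#' empty are never selected). Segments are hard-assigned to their
#' maximum-responsibility group. Deterministic under a fixed seed.
#'
#' @param vectors matrix from [kmer_vectors()] (rows = segments).
#' @param config a [binning_config()].
#' @param seg_lengths optional segment lengths (nt). Kmer-count noise
#'   scales inversely with segment length, so centered vectors are
#'   rescaled by `sqrt(length / mean length)` to homogenize noise —
#'   without this, mixed 10-20 kb segments cluster by noise level
#'   rather than composition.
#' @param coverage optional numeric vector (one value per segment)
#'   appended to the composition features after scaling; the default,
#'   `NULL`, matches a dummy uniform-coverage track.
#' @return List of class `bin_assignment`: `group` (named integer
#'   vector segment -> group), `n_groups`, `model`.
#' @export
cluster_segments <- function(vectors, config = binning_config(),
                             seg_lengths = NULL, coverage = NULL) {
  n <- nrow(vectors)
  if (is.null(n) || n < 2) stop("cluster_segments() needs at least 2 segments")
  x <- scale(vectors)
  x[, attr(x, "scaled:scale") == 0] <- 0
  if (!is.null(seg_lengths)) {
    stopifnot(length(seg_lengths) == n)
    x <- x * sqrt(seg_lengths / mean(seg_lengths))
  }
  if (all(x == 0)) { # identical segments: one group, nothing to fit
    grp <- stats::setNames(rep(1L, n), rownames(vectors))
    return(structure(list(group = grp, n_groups = 1L, model = NULL),
                     class = "bin_assignment"))
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  d <- which(cum >= config$pca_variance)[1]
  # parallel-analysis screen: at these sample sizes the variance rule
  # alone retains components that are indistinguishable from noise, and
  # the mixture would hallucinate groups in them. Keep only components
  # whose eigenvalue exceeds the largest eigenvalue of column-permuted
  # (signal-destroyed) data, and never more than the sample size supports.
  set.seed(config$seed + 1L)
  null_max <- mean(vapply(1:5, function(i) {
    max(stats::prcomp(apply(x, 2, sample), center = FALSE)$sdev^2)
  }, numeric(1)))
  d_signal <- sum(ev > 1.05 * null_max)
  d <- max(1L, min(d, d_signal, n %/% 4L, 15L))
  proj <- pc$x[, seq_len(d), drop = FALSE]
  if (!is.null(coverage)) {
    stopifnot(length(coverage) == n)
    cov_feat <- log(coverage + 1)
    s <- stats::sd(cov_feat)
    cov_feat <- if (s > 0) (cov_feat - mean(cov_feat)) / s else cov_feat * 0
    # weight the coverage column like the leading composition axis, so
    # neither signal drowns the other
    proj <- cbind(proj, cov = cov_feat * pc$sdev[1])
  }
  gmax <- max(2L, min(config$max_clusters, n %/% 5L, 20L))
  # equal-variance models only: cluster separation must come from the
  # means; variable-variance models latch onto residual heteroscedasticity.
  # Model and component count are selected by ICL rather than BIC: the
  # entropy term merges overlapping components instead of splitting the
  # homogeneous cloud, which is the behaviour a component-emptying
  # mixture would show.
  models <- if (ncol(proj) == 1L) "E" else c("EII", "EEI")
  set.seed(config$seed)
  # the conjugate prior keeps near-zero-variance dimensions (e.g. a
  # two-level coverage track) from collapsing the diagonal models
  icl <- suppressWarnings(
    mclust::mclustICL(proj, G = 1:gmax, modelNames = models,
                      prior = mclust::priorControl(), verbose = FALSE))
  pick <- strsplit(names(summary(icl))[1], ",", fixed = TRUE)[[1]]
  fit <- mclust::Mclust(proj, G = as.integer(pick[2]), modelNames = pick[1],
                        prior = mclust::priorControl(), verbose = FALSE)
  if (is.null(fit)) { # degenerate input (e.g. identical segments)
    grp <- stats::setNames(rep(1L, n), rownames(vectors))
    return(structure(list(group = grp, n_groups = 1L, model = NULL),
                     class = "bin_assignment"))
  }
  grp <- stats::setNames(as.integer(fit$classification), rownames(vectors))
  structure(list(group = grp, n_groups = length(unique(grp)),
                 model = fit$modelName),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("<bin_assignment> ", length(x$group), " segments in ", x$n_groups,
      " groups (model ", x$model, ")\n", sep = "")
  invisible(x)
}

#' Largest-group contamination statistic
#'
#' Treats the biggest composition cluster as the genuine genome:
#' `100 * (1 - n_largest / n_total)`. Ties for the largest group give
#' the same value whichever group is chosen.
#'
#' @param assignment a [cluster_segments()] result (or a vector of group
#'   ids).
#' @return Percentage of segments outside the largest group.
#' @export
largest_group_contamination <- function(assignment) {
  grp <- if (inherits(assignment, "bin_assignment")) assignment$group
         else assignment
  if (!length(grp)) stop("no assigned segments")
  tab <- table(grp)
  100 * (1 - max(tab) / length(grp))
}

#' Whole-assembly composition binning estimate
#'
#' Convenience wrapper: cut, vectorize, cluster, score.
#'
#' @param asm an [assembly()].
#' @param config a [binning_config()].
#' @param seg_len segment length (default 10,000 nt).
#' @return List: `contamination`, `assignment`, `segments`.
#' @export
binning_contamination <- function(asm, config = binning_config(),
                                  seg_len = 10000L) {
  segs <- make_segments(asm, seg_len = seg_len, min_len = config$min_segment)
  if (is.null(segs) || nrow(segs) < 2) {
    return(list(contamination = NA_real_, assignment = NULL, segments = segs))
  }
  vec <- kmer_vectors(segs, config$kappa)
  asg <- cluster_segments(vec, config, seg_lengths = segs$end - segs$start)
  list(contamination = largest_group_contamination(asg),
       assignment = asg, segments = segs)
}
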