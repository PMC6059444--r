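# Marker-based contamination estimators: SSU rRNA best-hit
# classification, ribosomal-protein top-3 LCA classification, and a
# single-copy-marker redundancy estimator of completeness/contamination.

#' Construct a marker family
#'
#' @param family_id family name (e.g. `"L12"`, `"SSU"`).
#' @param kind `"nucleotide"` or `"protein"`.
#' @param references data.frame with `ref_id`, `genome_id`, `taxon_id`,
#'   `sequence`.
#' @return List of class `marker_family`.
#' @export
marker_family <- function(family_id, kind = c("protein", "nucleotide"),
                          references) {
  kind <- match.arg(kind)
  req <- c("ref_id", "genome_id", "taxon_id", "sequence")
  stopifnot(all(req %in% names(references)))
  references <- as.data.frame(references, stringsAsFactors = FALSE)
  if (anyDuplicated(references$ref_id)) stop("duplicate ref_id in ", family_id)
  structure(list(family_id = family_id, kind = kind, references = references),
            class = "marker_family")
}

#' Read / write marker panels as multi-FASTA
#'
#' One FASTA per family with `>ref_id|genome_id|taxon_id` headers.
#'
#' @param families named list of [marker_family()] objects.
#' @param dir directory of `<family_id>.faa` / `.fna` files.
#' @export
write_marker_panel <- function(families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fam in families) {
    ext <- if (fam$kind == "protein") ".faa" else ".fna"
    r <- fam$references
    seqs <- stats::setNames(r$sequence,
                            paste(r$ref_id, r$genome_id, r$taxon_id, sep = "|"))
    write_fasta(seqs, file.path(dir, paste0(fam$family_id, ext)))
  }
  invisible(dir)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(dir) {
  files <- list.files(dir, pattern = "\\.(faa|fna)$", full.names = TRUE)
  fams <- lapply(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    parts <- strsplit(sub("\\s.*$", "", names(ss)), "|", fixed = TRUE)
    marker_family(
      sub("\\.(faa|fna)$", "", basename(f)),
      kind = if (endsWith(f, ".faa")) "protein" else "nucleotide",
      references = data.frame(
        ref_id = vapply(parts, `[`, character(1), 1),
        genome_id = vapply(parts, `[`, character(1), 2),
        taxon_id = vapply(parts, `[`, character(1), 3),
        sequence = as.character(ss), stringsAsFactors = FALSE
      )
    )
  })
  stats::setNames(fams, vapply(fams, `[[`, character(1), "family_id"))
}

nuc_align_params <- function() {
  list(matrix = Biostrings::nucleotideSubstitutionMatrix(
         match = 2, mismatch = -3, baseOnly = FALSE),
       gap_open = 5, gap_extend = 2)
}

#' Detect SSU rRNA-like loci in an assembly
#'
#' Candidate regions are found by exact-word seeding against the SSU
#' references (conserved stretches of real SSU genes make this reliable)
#' and refined by local nucleotide alignment (match +2 / mismatch -3 /
#' gap 5+2) on both strands. Loci with an aligned span of at least
#' `min_len` nt at `min_identity` percent identity or better are
#' reported; overlapping calls on a scaffold are merged keeping the
#' highest-scoring one.
#'
#' @param asm an [assembly()].
#' @param ssu_family a nucleotide-kind [marker_family()].
#' @param min_len minimum aligned span (default 300 nt).
#' @param min_identity minimum percent identity (default 70).
#' @param seed_k exact seed word size (default 16).
#' @return data.frame of loci: `scaffold_id`, `start`, `end`, `strand`,
#'   `best_ref`, `best_taxon_id`, `identity`, `aln_len`, `score`
#'   (0-based half-open coordinates).
#' @export
detect_ssu <- function(asm, ssu_family, min_len = 300L, min_identity = 70,
                       seed_k = 16L) {
  stopifnot(ssu_family$kind == "nucleotide")
  refs <- ssu_family$references
  nref <- nrow(refs)
  ref_code_list <- lapply(refs$sequence, kmer_codes, k = seed_k)
  code_ref <- data.table::data.table(
    code = unlist(ref_code_list, use.names = FALSE),
    ref = rep.int(seq_len(nref), lengths(ref_code_list)))
  code_ref <- unique(code_ref[!is.na(code_ref$code)])
  pars <- nuc_align_params()
  max_ref <- max(nchar(refs$sequence))
  flank <- 400L
  n_align <- 3L # align only the best-seeded references (both strands)
  out <- list()
  for (sid in names(asm$seqs)) {
    s <- asm$seqs[[sid]]
    if (nchar(s) < seed_k) next
    codes <- kmer_codes(s, k = seed_k)
    pos <- which(codes %in% code_ref$code) # 1-based window starts
    if (!length(pos)) next
    # cluster seed positions into candidate windows
    brk <- c(0L, which(diff(pos) > max_ref), length(pos))
    for (ci in seq_len(length(brk) - 1L)) {
      p <- pos[(brk[ci] + 1L):brk[ci + 1L]]
      w0 <- max(1L, min(p) - flank)
      w1 <- min(nchar(s), max(p) + seed_k - 1L + flank)
      win <- substring(s, w0, w1)
      hit_refs <- code_ref[code_ref$code %in% codes[p], ]
      ref_tab <- sort(table(hit_refs$ref), decreasing = TRUE)
      top <- as.integer(names(utils::head(ref_tab, n_align)))
      queries <- Biostrings::DNAStringSet(c(refs$sequence[top],
                                            revcomp(refs$sequence[top])))
      # a window can hold several loci (e.g. tandem copies): after each
      # accepted call its span is masked and the window re-searched
      for (round in 1:8) {
        alns <- Biostrings::pairwiseAlignment(
          queries, Biostrings::DNAString(win),
          type = "local", substitutionMatrix = pars$matrix,
          gapOpening = pars$gap_open, gapExtension = pars$gap_extend
        )
        sc <- Biostrings::score(alns)
        alen <- Biostrings::nchar(alns)
        idy <- 100 * Biostrings::nmatch(alns) / alen
        ok <- which(sc > 0 & alen >= min_len & idy >= min_identity)
        if (!length(ok)) break
        b <- ok[which.max(sc[ok])]
        ri <- top[((b - 1L) %% length(top)) + 1L]
        sub <- Biostrings::subject(alns[b])
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = sid,
          start = w0 - 1L + Biostrings::start(sub) - 1L,
          end = w0 - 1L + Biostrings::end(sub),
          strand = if (b <= length(top)) "+" else "-",
          best_ref = refs$ref_id[ri], best_taxon_id = refs$taxon_id[ri],
          identity = idy[b], aln_len = alen[b], score = sc[b],
          stringsAsFactors = FALSE
        )
        substr(win, Biostrings::start(sub), Biostrings::end(sub)) <-
          strrep("N", Biostrings::end(sub) - Biostrings::start(sub) + 1L)
      }
    }
  }
  loci <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), best_ref = character(0),
               best_taxon_id = character(0), identity = numeric(0),
               aln_len = integer(0), score = numeric(0))
  merge_overlapping_loci(loci)
}

merge_overlapping_loci <- function(loci) {
  if (nrow(loci) < 2) return(loci)
  loci <- loci[order(loci$scaffold_id, loci$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in 2:nrow(loci)) {
    j <- max(which(keep[1:(i - 1)]))
    if (loci$scaffold_id[i] == loci$scaffold_id[j] &&
        loci$start[i] < loci$end[j]) {
      if (loci$score[i] > loci$score[j]) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SSU-based contamination estimate
#'
#' The ratio of SSU loci classified to taxa outside the focal clade over
#' all predicted SSU loci. Each locus is labelled by its best-hit
#' reference taxon. Assemblies with no predicted SSU return `NA`.
#'
#' @param loci data.frame from [detect_ssu()].
#' @param tree a [taxonomy()].
#' @return List: `total_predicted`, `foreign`, `contamination` (percent
#'   or NA), `labels` (per-locus labels).
#' @export
ssu_contamination <- function(loci, tree) {
  labels <- if (nrow(loci)) label_of(tree, loci$best_taxon_id) else character(0)
  total <- nrow(loci)
  foreign <- sum(labels == "CONTAMINANT")
  list(total_predicted = total, foreign = foreign,
       contamination = if (total == 0) NA_real_ else 100 * foreign / total,
       labels = labels)
}

# ORF windows (>= min_aa residues between stops) from the six-frame
# translation of every scaffold, with genomic coordinates.
orf_windows <- function(asm, min_aa = 30L) {
  out <- list()
  peps_all <- six_frame_translate(asm$seqs)
  for (sid in names(asm$seqs)) {
    n <- nchar(asm$seqs[[sid]])
    for (fr in colnames(peps_all)) {
      pep <- peps_all[sid, fr]
      if (!nzchar(pep)) next
      m <- gregexpr("[^*]+", pep)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      keep <- len >= min_aa
      if (!any(keep)) next
      aa_start <- as.integer(m[keep]); aa_len <- len[keep]
      off <- as.integer(substring(fr, 2)) - 1L
      strand <- substring(fr, 1, 1)
      nt_start0 <- off + (aa_start - 1L) * 3L # on the translated strand
      nt_end0 <- nt_start0 + aa_len * 3L
      if (strand == "-") {
        g_start <- n - nt_end0
        g_end <- n - nt_start0
      } else {
        g_start <- nt_start0
        g_end <- nt_end0
      }
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = sid, start = g_start, end = g_end, strand = strand,
        frame = fr, peptide = substring(pep, aa_start, aa_start + aa_len - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# seeded alignment of peptides against a protein_db; best local alignment
# per (peptide, subject)
align_peptides <- function(peptides, db, params = alignment_params(),
                           min_seeds = 1L) {
  seeds <- aa_seeds(peptides, db$seed_k)
  cand <- data.table::data.table(
    seed = unlist(seeds, use.names = FALSE),
    task = rep.int(seq_along(peptides), lengths(seeds))
  )
  task <- prot <- NULL # data.table NSE
  cand <- db$seed_index[cand, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[, list(nseed = .N), by = list(task, prot)]
  cand <- cand[cand$nseed >= min_seeds]
  if (!nrow(cand)) return(NULL)
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(peptides[cand$task]),
    Biostrings::AAStringSet(db$proteins$sequence[cand$prot]),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(alns)
  keep <- which(raw > 0)
  if (!length(keep)) return(NULL)
  st <- aln_stats(alns[keep], raw[keep], params)
  st$task <- cand$task[keep]
  st$subject_id <- db$proteins$protein_id[cand$prot[keep]]
  st$subject_genome_id <- db$proteins$genome_id[cand$prot[keep]]
  st$subject_taxon_id <- db$proteins$taxon_id[cand$prot[keep]]
  st
}

#' Detect ribosomal-protein-like orthologues in an assembly
#'
#' Searches all six-frame ORF windows (at least `min_aa` residues between
#' stops) against the pooled references of all protein marker families. A
#' candidate is assigned to the family holding its single best hit (a
#' mutual-best screen against picking up paralogues from other families);
#' overlapping candidates on a scaffold are deduplicated keeping the best
#' bit score.
#'
#' @param asm an [assembly()].
#' @param families named list of protein-kind [marker_family()] objects.
#' @param params an [alignment_params()].
#' @param min_aa minimum ORF length in residues (default 30).
#' @param min_bit minimum bit score for a candidate (default 50).
#' @return data.frame of candidates: locus columns, `family_id`,
#'   `bit_score`, `identity`, `aln_len`, `peptide`.
#' @export
detect_rprot_orthologues <- function(asm, families, params = alignment_params(),
                                     min_aa = 30L, min_bit = 50) {
  stopifnot(all(vapply(families, `[[`, character(1), "kind") == "protein"))
  pooled <- do.call(rbind, lapply(families, function(fam) {
    r <- fam$references
    data.frame(protein_id = paste(fam$family_id, r$ref_id, sep = "|"),
               family_id = fam$family_id, genome_id = r$genome_id,
               taxon_id = r$taxon_id, sequence = r$sequence,
               stringsAsFactors = FALSE)
  }))
  db <- protein_db(pooled[, c("protein_id", "genome_id", "taxon_id", "sequence")])
  fam_of <- stats::setNames(pooled$family_id, pooled$protein_id)

  orfs <- orf_windows(asm, min_aa = min_aa)
  if (is.null(orfs)) return(NULL)
  hits <- align_peptides(orfs$peptide, db, params)
  if (is.null(hits)) return(NULL)
  hits <- hits[hits$bit_score >= min_bit, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  # best hit per ORF decides its family
  hits <- hits[order(hits$task, -hits$bit_score, hits$subject_id), , drop = FALSE]
  best <- hits[!duplicated(hits$task), , drop = FALSE]
  cand <- cbind(orfs[best$task, c("scaffold_id", "start", "end", "strand", "peptide")],
                data.frame(family_id = unname(fam_of[best$subject_id]),
                           bit_score = best$bit_score, identity = best$identity,
                           aln_len = best$aln_len, stringsAsFactors = FALSE))
  # deduplicate candidates covering the same locus (same scaffold, mutual
  # overlap over half of the shorter window) keeping the best bit score;
  # ORF windows of *adjacent* genes overlap slightly across frames and
  # must not eat each other
  cand <- cand[order(cand$scaffold_id, -cand$bit_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    prev <- which(keep[1:(i - 1)] & cand$scaffold_id[1:(i - 1)] == cand$scaffold_id[i])
    if (!length(prev)) next
    ov <- pmin(cand$end[prev], cand$end[i]) - pmax(cand$start[prev], cand$start[i])
    shorter <- pmin(cand$end[prev] - cand$start[prev], cand$end[i] - cand$start[i])
    if (any(ov > 0.5 * shorter)) keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Classify a marker candidate by top-k LCA over its nearest references
#'
#' The candidate is aligned against every reference of its family; the
#' `n_neighbours` most identity-similar references with identity at
#' least `min_identity` percent and alignment length at least
#' `min_alnlen` residues vote by LCA. Ties in identity break by longer
#' alignment, then by reference id. A candidate with no passing
#' neighbour stays unclassified.
#'
#' @param peptide candidate peptide.
#' @param family a protein-kind [marker_family()].
#' @param tree a [taxonomy()].
#' @param min_identity identity threshold (default 70).
#' @param min_alnlen alignment length threshold (default 30 aa).
#' @param n_neighbours number of nearest references used (default 3).
#' @param params an [alignment_params()].
#' @return List: `label`, `taxon_id`, `neighbours` (data.frame).
#' @export
classify_marker <- function(peptide, family, tree, min_identity = 70,
                            min_alnlen = 30L, n_neighbours = 3L,
                            params = alignment_params()) {
  refs <- family$references
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(peptide, nrow(refs))),
    Biostrings::AAStringSet(refs$sequence),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  alen <- Biostrings::nchar(alns)
  idy <- 100 * Biostrings::nmatch(alns) / alen
  ok <- which(Biostrings::score(alns) > 0 & idy >= min_identity & alen >= min_alnlen)
  if (!length(ok)) {
    return(list(label = "UNCLASSIFIED", taxon_id = NA_character_,
                neighbours = NULL))
  }
  ord <- ok[order(-idy[ok], -alen[ok], refs$ref_id[ok])]
  nb <- utils::head(ord, n_neighbours)
  taxon <- lca(tree, unique(refs$taxon_id[nb]))
  list(label = label_of(tree, taxon), taxon_id = taxon,
       neighbours = data.frame(ref_id = refs$ref_id[nb],
                               taxon_id = refs$taxon_id[nb],
                               identity = idy[nb], aln_len = alen[nb],
                               stringsAsFactors = FALSE))
}

#' Ribosomal-protein contamination estimate
#'
#' Detects marker orthologues, classifies each by the top-3 LCA rule,
#' and pools over all families, ignoring collocation: the estimate is
#' the percentage of classified orthologues labelled `CONTAMINANT`.
#'
#' @param asm an [assembly()].
#' @param families named list of protein-kind [marker_family()] objects.
#' @param tree a [taxonomy()].
#' @param ... passed to [classify_marker()].
#' @return List: `hits` (data.frame with `family_id`, locus, `label`,
#'   `taxon_id`), `classified`, `foreign`, `contamination` (percent or
#'   NA when nothing classified).
#' @export
rprot_contamination <- function(asm, families, tree, ...) {
  cand <- detect_rprot_orthologues(asm, families)
  if (is.null(cand) || !nrow(cand)) {
    return(list(hits = NULL, classified = 0L, foreign = 0L,
                contamination = NA_real_))
  }
  cls <- lapply(seq_len(nrow(cand)), function(i) {
    classify_marker(cand$peptide[i], families[[cand$family_id[i]]], tree, ...)
  })
  cand$label <- vapply(cls, `[[`, character(1), "label")
  cand$taxon_id <- vapply(cls, `[[`, character(1), "taxon_id")
  classified <- sum(cand$label != "UNCLASSIFIED")
  foreign <- sum(cand$label == "CONTAMINANT")
  list(hits = cand, classified = classified, foreign = foreign,
       contamination = if (classified == 0) NA_real_ else
         100 * foreign / classified)
}

#' Single-copy marker redundancy estimator
#'
#' Over a panel of `M` markers expected exactly once per genome, with
#' detected copy counts `c_m`: completeness is the percentage of markers
#' seen at least once, contamination is `100 * sum(max(0, c_m - 1)) / M`
#' — extra copies indicate sequence from additional organisms, and the
#' estimate exceeds 100 when more than one complete contaminant is
#' present. Optional collocation merging collapses hits within
#' `collocate_dist` nt on one scaffold into a single countable unit.
#'
#' @param hits data.frame of detected marker hits (needs `family_id`,
#'   `scaffold_id`, `start`), e.g. from [detect_rprot_orthologues()];
#'   `NULL` counts as zero detections.
#' @param panel character vector of the single-copy family ids.
#' @param collocate merge nearby hits before counting (default FALSE).
#' @param collocate_dist distance for merging (default 5000 nt).
#' @return List: `completeness`, `contamination` (percent), `copy_counts`.
#' @export
redundancy_estimate <- function(hits, panel, collocate = FALSE,
                                collocate_dist = 5000L) {
  if (!length(panel)) stop("empty marker panel")
  counts <- stats::setNames(integer(length(panel)), panel)
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$family_id %in% panel, , drop = FALSE]
    if (collocate && nrow(hits)) {
      # hits within collocate_dist on one scaffold collapse into a single
      # countable unit: collocated genes carry no independent evidence
      hits <- hits[order(hits$scaffold_id, hits$start), , drop = FALSE]
      grp <- cumsum(c(TRUE, hits$scaffold_id[-1] != hits$scaffold_id[-nrow(hits)] |
                        diff(hits$start) > collocate_dist))
      hits <- hits[!duplicated(grp), , drop = FALSE]
    }
    tab <- table(hits$family_id)
    counts[names(tab)] <- as.integer(tab)
  }
  list(completeness = 100 * sum(counts >= 1) / length(panel),
       contamination = 100 * sum(pmax(0L, counts - 1L)) / length(panel),
       copy_counts = counts)
}
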