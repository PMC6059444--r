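# The two genome-wide per-read classifiers: the signature-kmer path
# classifier with confidence promotion, and the MEGAN-like bit-score
# collapsing LCA over translated protein hits with self-match exclusion.

#' Configuration for the signature-kmer classifier
#' @param k kmer size (default 21).
#' @param confidence confidence threshold in \[0,1\] (default 0.04): the
#'   minimum fraction of a read's valid kmers that must fall inside the
#'   clade of the assigned label; labels failing it are promoted rootward.
#' @export
kmer_config <- function(k = 21L, confidence = 0.04) {
  stopifnot(confidence >= 0, confidence <= 1)
  list(k = k, confidence = confidence)
}

#' Configuration for the protein-hit LCA classifier
#' @param min_bit minimum bit score of a usable hit (default 80).
#' @param top_fraction keep hits within this fraction of the best bit
#'   score (default 0.95; 0.99 is a stricter alternative).
#' @param min_hits minimum number of kept hits for classification.
#' @param exclude_self drop hits to the query's own genome.
#' @export
protein_lca_config <- function(min_bit = 80, top_fraction = 0.95,
                               min_hits = 1L, exclude_self = TRUE) {
  stopifnot(top_fraction > 0, top_fraction <= 1, min_hits >= 1)
  list(min_bit = min_bit, top_fraction = top_fraction,
       min_hits = min_hits, exclude_self = exclude_self)
}

#' Classify pseudo-reads with the signature-kmer index
#'
#' For each read: (i) all canonical kmers are looked up, giving per-taxon
#' hit counts; (ii) the candidate label is the leaf-most node maximizing
#' the summed hit count along its root path, ties resolved by the LCA of
#' the tied nodes; (iii) the label's confidence is the fraction of the
#' read's valid (ACGT-only) kmers hitting nodes inside the clade rooted
#' at the label — while it falls below the threshold the label is
#' promoted to its parent, and a read whose root-level confidence still
#' fails is left unclassified.
#'
#' @param reads data.frame from [make_pseudoreads()], or a character
#'   vector of sequences (names become read ids).
#' @param index a [build_kmer_index()].
#' @param tree a [taxonomy()].
#' @param config a [kmer_config()].
#' @return data.frame: `read_id`, `taxon_id` (NA if unclassified),
#'   `label`, `confidence`.
#' @export
classify_reads_kmer <- function(reads, index, tree, config = kmer_config()) {
  if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  k <- index$k
  if (any(nchar(reads$sequence) < k)) {
    stop("read shorter than k=", k, ": ",
         reads$read_id[nchar(reads$sequence) < k][1])
  }
  codes <- lapply(reads$sequence, kmer_codes, k = k)
  nvalid <- vapply(codes, function(x) sum(!is.na(x)), integer(1))
  lut <- data.table::data.table(
    read = rep.int(seq_len(nrow(reads)), lengths(codes)),
    code = unlist(codes, use.names = FALSE)
  )
  lut <- lut[!is.na(lut$code)]
  read <- code <- taxon_id <- NULL # data.table NSE
  hits <- index$entries[lut, on = "code", nomatch = NULL]
  counts <- hits[, list(n = .N), by = list(read, taxon_id)]
  by_read <- split(counts, counts$read)

  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- ancestors(tree, t)
    anc_cache[[t]]
  }

  taxon <- rep(NA_character_, nrow(reads))
  conf <- rep(NA_real_, nrow(reads))
  for (key in names(by_read)) {
    i <- as.integer(key)
    ct <- by_read[[key]]
    hit_taxa <- ct$taxon_id
    n <- stats::setNames(ct$n, hit_taxa)
    paths <- lapply(hit_taxa, get_anc)
    # root-path score of each hit taxon: counts on its ancestors-or-self
    score <- vapply(paths, function(p) sum(n[intersect(p, hit_taxa)]),
                    numeric(1))
    top <- hit_taxa[score == max(score)]
    if (length(top) > 1L) {
      # keep leaf-most among the tied, then collapse remaining ties by LCA
      keep <- vapply(top, function(t) {
        !any(vapply(setdiff(top, t), function(o) {
          t %in% get_anc(o) # t is a strict ancestor of another tied node
        }, logical(1)))
      }, logical(1))
      top <- top[keep]
      cand <- if (length(top) > 1L) lca(tree, top) else top
    } else {
      cand <- top
    }
    # confidence promotion loop
    total <- nvalid[i]
    repeat {
      inside <- vapply(paths, function(p) cand %in% p, logical(1))
      cf <- sum(n[hit_taxa[inside]]) / total
      if (cf >= config$confidence) {
        taxon[i] <- cand
        conf[i] <- cf
        break
      }
      if (cand == tree$root_id) break # root fails: leave unclassified
      cand <- tree$parent[[cand]]
    }
  }
  data.frame(read_id = reads$read_id, taxon_id = taxon,
             label = label_of(tree, taxon), confidence = conf,
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads_kmer
#' @param read a single read sequence (or one-row reads data.frame).
#' @export
classify_read_kmer <- function(read, index, tree, config = kmer_config()) {
  classify_reads_kmer(read, index, tree, config)
}

#' MEGAN-like LCA classification of protein hits
#'
#' For each read: self-matches (hits to the read's own genome) are
#' dropped, hits below `min_bit` are dropped, and of the remainder only
#' hits within `top_fraction` of the best bit score are kept; if at
#' least `min_hits` survive, the read is labelled by the LCA of the kept
#' subject taxa, otherwise it stays unclassified.
#'
#' @param hits hits data.frame (from [search_reads()] or
#'   [read_hits_tsv()]).
#' @param tree a [taxonomy()].
#' @param config a [protein_lca_config()].
#' @param self_genome_id the query assembly's own genome id (for
#'   self-match exclusion), or `NULL`.
#' @param read_ids read ids to report (reads without hits come back
#'   `UNCLASSIFIED`); defaults to the reads present in `hits`.
#' @return data.frame: `read_id`, `taxon_id`, `label`, `n_hits_used`.
#' @export
classify_reads_protein <- function(hits, tree, config = protein_lca_config(),
                                   self_genome_id = NULL, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- unique(hits$query_id)
  if (config$exclude_self && !is.null(self_genome_id)) {
    hits <- hits[hits$subject_genome_id != self_genome_id, , drop = FALSE]
  }
  hits <- hits[hits$bit_score >= config$min_bit, , drop = FALSE]
  taxon <- rep(NA_character_, length(read_ids))
  used <- integer(length(read_ids))
  if (nrow(hits)) {
    grp <- split(hits, hits$query_id)
    for (qid in names(grp)) {
      h <- grp[[qid]]
      best <- max(h$bit_score)
      kept <- h[h$bit_score >= config$top_fraction * best, , drop = FALSE]
      if (nrow(kept) < config$min_hits) next
      i <- match(qid, read_ids)
      if (is.na(i)) next
      taxon[i] <- lca(tree, unique(kept$subject_taxon_id))
      used[i] <- nrow(kept)
    }
  }
  data.frame(read_id = read_ids, taxon_id = taxon,
             label = label_of(tree, taxon), n_hits_used = used,
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads_protein
#' @export
classify_read_protein <- function(hits, tree, config = protein_lca_config(),
                                  self_genome_id = NULL, read_ids = NULL) {
  classify_reads_protein(hits, tree, config, self_genome_id, read_ids)
}

#' Aggregate read labels into an assembly contamination profile
#'
#' The contamination level is the percentage of reads labelled
#' `CONTAMINANT` over *all* reads; `UNKNOWN` (classified but too
#' high-ranking) and `UNCLASSIFIED` reads stay in the denominator but are
#' counted in neither the focal nor the contaminant fraction. The
#' per-phylum breakdown attributes each classified read to the
#' phylum-rank ancestor of its taxon; classified reads with no such
#' ancestor below the unknown boundary are reported under `"unknown"`.
#'
#' @param labels data.frame with `taxon_id` and `label` (one row per
#'   read), as returned by the classifiers.
#' @param tree a [taxonomy()].
#' @param assembly_id identifier carried into the profile.
#' @return List of class `assembly_profile`: `assembly_id`, `n_reads`,
#'   `focal`, `contaminant`, `unknown`, `unclassified` (percentages
#'   summing to 100), and `per_phylum` (named percentages, phylum *names*,
#'   summing to 100).
#' @export
profile_assembly <- function(labels, tree, assembly_id = NA_character_) {
  n <- nrow(labels)
  if (!n) stop("profile_assembly() needs at least one read")
  pct <- function(lbl) 100 * sum(labels$label == lbl) / n
  phyl <- rank_ancestor(tree, labels$taxon_id, "phylum")
  nm <- stats::setNames(tree$nodes$name, tree$nodes$taxon_id)
  grp <- ifelse(labels$label == "UNCLASSIFIED", "unclassified",
         ifelse(labels$label == "UNKNOWN" | is.na(phyl), "unknown",
                unname(nm[phyl])))
  per_phylum <- 100 * table(grp) / n
  per_phylum <- stats::setNames(as.numeric(per_phylum), names(per_phylum))
  structure(list(
    assembly_id = assembly_id, n_reads = n,
    focal = pct("FOCAL"), contaminant = pct("CONTAMINANT"),
    unknown = pct("UNKNOWN"), unclassified = pct("UNCLASSIFIED"),
    per_phylum = per_phylum
  ), class = "assembly_profile")
}

#' @export
print.assembly_profile <- function(x, ...) {
  cat("<assembly_profile> ", x$assembly_id, ": ", x$n_reads, " reads | focal ",
      round(x$focal, 2), "% contaminant ", round(x$contaminant, 2),
      "% unknown ", round(x$unknown, 2), "% unclassified ",
      round(x$unclassified, 2), "%\n", sep = "")
  invisible(x)
}

#' Should the kmer-method score be masked to NA for an assembly?
#'
#' A signature-kmer database contains every kmer of the genomes it was
#' built from, so querying one of those genomes against it is
#' uninformative: its own kmers always match. Such assemblies get a
#' missing kmer-method score in the consensus ranking.
#'
#' @param assembly_id assembly identifier.
#' @param index a [build_kmer_index()].
#' @return `TRUE` if the assembly is among the index source genomes.
#' @export
kraken_na_mask <- function(assembly_id, index) {
  assembly_id %in% index$source_genomes
}
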