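# Translated (blastx-style) search of nucleotide reads against a protein
# reference set. The aligner is standard Smith-Waterman with affine gaps
# (BLOSUM62, 11/1) plus an exact amino-acid word prefilter so whole
# assemblies can be screened; the search engine is replaceable through the
# tabular hit interface, the post-processing downstream is what matters.

#' Local-alignment scoring parameters
#'
#' BLOSUM62 with affine gap penalties 11/1 and the published ungapped
#' Karlin-Altschul constants for bit-score conversion,
#' `bit = (lambda * raw - ln K) / ln 2`. Stop codons (`*`) score -4
#' against everything, so alignments do not extend through a stop.
#'
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul constants.
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = 11, gap_extend = 1,
                             lambda = 0.3176, K = 0.134) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  mat["*", ] <- -4
  mat[, "*"] <- -4
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "alignment_params")
}

#' Six-frame conceptual translation
#'
#' Frames +1, +2, +3 on the forward strand and -1, -2, -3 on the reverse
#' complement, standard genetic code, stops emitted as `*`, trailing
#' partial codons dropped. Codons containing `N` translate to `X`.
#'
#' @param sequence nucleotide string(s); vectorized.
#' @return A character matrix with one row per input sequence and columns
#'   `+1`,`+2`,`+3`,`-1`,`-2`,`-3`.
#' @export
six_frame_translate <- function(sequence) {
  fwd <- Biostrings::DNAStringSet(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  one_frame <- function(ss, off) {
    w <- Biostrings::width(ss)
    keep_w <- pmax(((w - off) %/% 3L) * 3L, 0L)
    trimmed <- Biostrings::subseq(ss, start = off + 1L, width = keep_w)
    suppressWarnings(as.character(
      Biostrings::translate(trimmed, if.fuzzy.codon = "X")
    ))
  }
  out <- cbind(
    `+1` = one_frame(fwd, 0L), `+2` = one_frame(fwd, 1L), `+3` = one_frame(fwd, 2L),
    `-1` = one_frame(rev, 0L), `-2` = one_frame(rev, 1L), `-3` = one_frame(rev, 2L)
  )
  rownames(out) <- names(sequence)
  out
}

#' Smith-Waterman local alignment of two peptides
#'
#' @param query_pep,subject_pep non-empty peptide strings.
#' @param params an [alignment_params()].
#' @return One-row data.frame (`raw_score`, `bit_score`, `identity`,
#'   `aln_len`, `qstart`, `qend`, `sstart`, `send`, `mismatch`,
#'   `gapopen`), or `NULL` when no alignment scores above zero.
#' @export
local_align <- function(query_pep, subject_pep, params = alignment_params()) {
  stopifnot(nzchar(query_pep), nzchar(subject_pep))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_pep), Biostrings::AAString(subject_pep),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = FALSE
  )
  raw <- Biostrings::score(aln)
  if (raw <= 0) return(NULL)
  aln_stats(aln, raw, params)[1, ]
}

# vectorized alignment statistics over a PairwiseAlignments object
aln_stats <- function(alns, raw, params) {
  alen <- Biostrings::nchar(alns)
  nid <- Biostrings::nmatch(alns)
  ind <- Biostrings::nindel(alns)
  ins <- ind@insertion
  del <- ind@deletion
  data.frame(
    raw_score = raw,
    bit_score = (params$lambda * raw - log(params$K)) / log(2),
    identity = 100 * nid / alen,
    aln_len = alen,
    qstart = Biostrings::start(Biostrings::pattern(alns)),
    qend = Biostrings::end(Biostrings::pattern(alns)),
    sstart = Biostrings::start(Biostrings::subject(alns)),
    send = Biostrings::end(Biostrings::subject(alns)),
    mismatch = alen - nid - ins[, 2] - del[, 2],
    gapopen = ins[, 1] + del[, 1]
  )
}

#' Build a searchable protein reference set
#'
#' @param proteins data.frame with columns `protein_id`, `genome_id`,
#'   `taxon_id`, `sequence` (amino acids).
#' @param seed_k exact amino-acid word size used to prefilter candidate
#'   subjects before alignment (default 5).
#' @return Object of class `protein_db`.
#' @export
protein_db <- function(proteins, seed_k = 5L) {
  req <- c("protein_id", "genome_id", "taxon_id", "sequence")
  stopifnot(all(req %in% names(proteins)))
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein_id")
  if (any(!nzchar(proteins$sequence))) stop("empty protein sequence")
  seeds <- aa_seeds(proteins$sequence, seed_k)
  seed_index <- data.table::data.table(
    seed = unlist(seeds, use.names = FALSE),
    prot = rep.int(seq_len(nrow(proteins)), lengths(seeds))
  )
  seed_index <- unique(seed_index)
  data.table::setkeyv(seed_index, "seed")
  structure(list(proteins = proteins, seed_k = seed_k,
                 seed_index = seed_index,
                 total_aa = sum(nchar(proteins$sequence))),
            class = "protein_db")
}

aa_seeds <- function(peptides, k) {
  lapply(peptides, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    w <- substring(p, 1:(n - k + 1), k:n)
    unique(w[!grepl("[*X]", w)])
  })
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", nrow(x$proteins), " proteins, ",
      x$total_aa, " aa, seed_k=", x$seed_k, "\n", sep = "")
  invisible(x)
}

#' Translated search of pseudo-reads against a protein reference set
#'
#' Each read is translated in six frames; candidate subjects sharing at
#' least `min_seeds` exact `seed_k`-mers with a frame are aligned with
#' [local_align()] and the best local alignment per (frame, protein) pair
#' is reported, filtered at `min_bit`. Order is deterministic: bit score
#' descending, then subject id.
#'
#' @param reads data.frame as from [make_pseudoreads()] (columns
#'   `read_id`, `sequence`), or a single read's sequence with
#'   `read_id` as name.
#' @param db a [protein_db()].
#' @param params an [alignment_params()].
#' @param min_bit minimum bit score reported (default 0).
#' @param min_seeds minimum shared seed words to trigger alignment.
#' @param max_candidates cap on aligned subjects per frame, keeping those
#'   sharing most seeds (ties by subject order).
#' @return data.frame of hits: `query_id`, `subject_id`,
#'   `subject_genome_id`, `subject_taxon_id`, `identity`, `aln_len`,
#'   `bit_score`, `e_value`, `frame`, plus alignment coordinates.
#' @export
search_reads <- function(reads, db, params = alignment_params(),
                         min_bit = 0, min_seeds = 1L, max_candidates = 32L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  if (!nrow(reads)) return(empty_hits())
  peps <- six_frame_translate(stats::setNames(reads$sequence, reads$read_id))
  frames <- colnames(peps)
  # one long task list: (query, frame, peptide)
  qidx <- rep(seq_len(nrow(reads)), times = 6L)
  fidx <- rep(frames, each = nrow(reads))
  pep <- as.vector(peps)
  ok <- nchar(gsub("[*X]", "", pep)) >= db$seed_k
  qidx <- qidx[ok]; fidx <- fidx[ok]; pep <- pep[ok]
  if (!length(pep)) return(empty_hits())

  seeds <- aa_seeds(pep, db$seed_k)
  cand <- data.table::data.table(
    seed = unlist(seeds, use.names = FALSE),
    task = rep.int(seq_along(pep), lengths(seeds))
  )
  prot <- task <- nseed <- NULL # data.table NSE
  cand <- db$seed_index[cand, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(cand)) return(empty_hits())
  cand <- cand[, list(nseed = .N), by = list(task, prot)]
  cand <- cand[nseed >= min_seeds]
  if (!nrow(cand)) return(empty_hits())
  data.table::setorder(cand, task, -nseed, prot)
  cand <- cand[, utils::head(.SD, max_candidates), by = task]

  # one elementwise alignment call for every (frame peptide, candidate)
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pep[cand$task]),
    Biostrings::AAStringSet(db$proteins$sequence[cand$prot]),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(alns)
  keep <- which(raw > 0)
  if (!length(keep)) return(empty_hits())
  hits <- aln_stats(alns[keep], raw[keep], params)
  kt <- cand$task[keep]
  hits$query_id <- reads$read_id[qidx[kt]]
  hits$frame <- fidx[kt]
  hits$subject_id <- db$proteins$protein_id[cand$prot[keep]]
  hits$subject_genome_id <- db$proteins$genome_id[cand$prot[keep]]
  hits$subject_taxon_id <- db$proteins$taxon_id[cand$prot[keep]]
  hits$e_value <- nchar(pep[kt]) * db$total_aa * params$K *
    exp(-params$lambda * hits$raw_score)
  hits <- hits[hits$bit_score >= min_bit, , drop = FALSE]
  hits <- hits[order(-hits$bit_score, hits$subject_id, hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "subject_genome_id", "subject_taxon_id",
           "identity", "aln_len", "bit_score", "e_value", "frame",
           "raw_score", "qstart", "qend", "sstart", "send",
           "mismatch", "gapopen")]
}

#' @rdname search_reads
#' @param read one row of a pseudo-read data.frame, or a named length-1
#'   character vector.
#' @export
search_read <- function(read, db, params = alignment_params(), min_bit = 0,
                        min_seeds = 1L, max_candidates = 32L) {
  search_reads(read, db, params, min_bit, min_seeds, max_candidates)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             subject_genome_id = character(0), subject_taxon_id = character(0),
             identity = numeric(0), aln_len = integer(0),
             bit_score = numeric(0), e_value = numeric(0),
             frame = character(0), raw_score = numeric(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), mismatch = integer(0), gapopen = integer(0),
             stringsAsFactors = FALSE)
}

#' Read / write hits in 12-column BLAST tabular dialect plus extensions
#'
#' Columns: `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`, optionally extended with
#' `subject_genome_id` and `subject_taxon_id`. A 12-column file can be
#' completed with a `mapping` data.frame (`subject_id`, `genome_id`,
#' `taxon_id`), so output of an external search tool can be dropped in.
#'
#' @param path file path.
#' @param mapping optional subject-to-genome/taxon mapping for 12-column
#'   input.
#' @return `read_hits_tsv()` a hits data.frame as from [search_reads()]
#'   (alignment columns only as far as the format carries them).
#' @export
read_hits_tsv <- function(path, mapping = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_hits()[, 1:8])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (!all(nf %in% c(12L, 14L))) {
    bad <- which(!nf %in% c(12L, 14L))[1]
    stop("hits TSV line ", bad, " has ", nf[bad], " columns, expected 12 or 14")
  }
  if (length(unique(nf)) != 1L) stop("mixed column counts in ", path)
  m <- do.call(rbind, parts)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (nf[1] == 14L) {
    hits$subject_genome_id <- m[, 13]
    hits$subject_taxon_id <- m[, 14]
  } else if (!is.null(mapping)) {
    i <- match(hits$subject_id, mapping$subject_id)
    hits$subject_genome_id <- mapping$genome_id[i]
    hits$subject_taxon_id <- mapping$taxon_id[i]
  } else {
    hits$subject_genome_id <- NA_character_
    hits$subject_taxon_id <- NA_character_
  }
  hits
}

#' @rdname read_hits_tsv
#' @param hits a hits data.frame.
#' @export
write_hits_tsv <- function(hits, path) {
  fmt <- function(x) formatC(x, format = "fg", digits = 6)
  lines <- paste(
    hits$query_id, hits$subject_id, fmt(hits$identity), hits$aln_len,
    hits$mismatch, hits$gapopen, hits$qstart, hits$qend, hits$sstart,
    hits$send, formatC(hits$e_value, format = "e", digits = 3),
    fmt(hits$bit_score), hits$subject_genome_id, hits$subject_taxon_id,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
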