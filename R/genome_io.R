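#' Construct an assembly
#'
#' An assembly is an ordered set of named scaffolds. Sequences are
#' upper-cased; IUPAC ambiguity codes other than A/C/G/T are collapsed to
#' `N` (all downstream kmer logic is ACGT-only).
#'
#' @param assembly_id identifier.
#' @param seqs named character vector of nucleotide sequences.
#' @return Object of class `assembly`.
#' @export
assembly <- function(assembly_id, seqs) {
  if (!length(seqs)) stop("assembly needs at least one scaffold")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("every scaffold needs a non-empty id")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate scaffold id: ", names(seqs)[duplicated(names(seqs))][1])
  }
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for scaffold: ", names(seqs)[!nzchar(seqs)][1])
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) stop("illegal character in scaffold: ", names(seqs)[bad][1])
  # ambiguity codes -> N
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  structure(list(assembly_id = assembly_id, seqs = seqs), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly> ", x$assembly_id, ": ", length(x$seqs), " scaffolds, ",
      sum(nchar(x$seqs)), " nt\n", sep = "")
  invisible(x)
}

#' Read / write an assembly in FASTA format
#'
#' The header token up to the first whitespace is the scaffold id. Output
#' is wrapped at 60 columns.
#'
#' @param path file path.
#' @param assembly_id id for the loaded assembly; defaults to the file
#'   name without extension.
#' @return `read_fasta()` an [assembly()]; `write_fasta()` the path,
#'   invisibly.
#' @export
read_fasta <- function(path, assembly_id = NULL) {
  if (is.null(assembly_id)) {
    assembly_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), ids)
  assembly(assembly_id, seqs)
}

#' @rdname read_fasta
#' @param x an [assembly()] (or any named character vector of sequences).
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "assembly")) x$seqs else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Assembly summary statistics and size filters
#'
#' Scaffold counts and total length are computed over scaffolds of at
#' least 1000 nt, the convention used for assembly quality tables. An
#' assembly is flagged `too_small` below 500 kbp and `too_large` above
#' 15,000 kbp of such sequence; genome-wide screening is unreliable
#' outside this range.
#'
#' @param asm an [assembly()].
#' @param min_scaffold scaffold length cutoff for the counts (default 1000).
#' @return A one-row data.frame: `assembly_id`, `n_scaffolds_ge_1000`,
#'   `total_length_ge_1000`, `gc_percent`, `n_fraction`, `too_small`,
#'   `too_large`.
#' @export
compute_stats <- function(asm, min_scaffold = 1000L) {
  len <- nchar(asm$seqs)
  keep <- len >= min_scaffold
  total <- sum(len[keep])
  allseq <- paste(asm$seqs, collapse = "")
  nN <- sum(nchar(gsub("[^N]", "", allseq)))
  data.frame(
    assembly_id = asm$assembly_id,
    n_scaffolds_ge_1000 = sum(keep),
    total_length_ge_1000 = total,
    gc_percent = gc_content(allseq),
    n_fraction = 100 * nN / nchar(allseq),
    too_small = total < 5e5,
    too_large = total > 1.5e7,
    stringsAsFactors = FALSE
  )
}

#' GC content of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the
#' denominator. All-N (or empty) input returns `NA`.
#'
#' @param sequence nucleotide string(s); vectorized.
#' @return Numeric percentage(s).
#' @export
gc_content <- function(sequence) {
  sequence <- toupper(sequence)
  gc <- nchar(gsub("[^GC]", "", sequence))
  acgt <- nchar(gsub("[^ACGT]", "", sequence))
  ifelse(acgt == 0, NA_real_, 100 * gc / acgt)
}

#' Split scaffolds into fixed-length pseudo-reads
#'
#' Each scaffold is tiled left-to-right into consecutive windows of
#' `read_len` nt (0-based, half-open coordinates). A trailing partial
#' window is kept only if it is at least `min_keep` nt long — shorter
#' windows contain no classifiable kmer.
#'
#' @param asm an [assembly()].
#' @param read_len window length (default 250).
#' @param min_keep minimum length of a kept trailing window (default 21,
#'   the signature-kmer size).
#' @return data.frame: `read_id`, `scaffold_id`, `start`, `end`,
#'   `sequence`.
#' @export
make_pseudoreads <- function(asm, read_len = 250L, min_keep = 21L) {
  stopifnot(read_len >= min_keep, min_keep >= 1)
  out <- lapply(names(asm$seqs), function(sid) {
    s <- asm$seqs[[sid]]
    n <- nchar(s)
    starts <- seq.int(0L, n - 1L, by = read_len)
    ends <- pmin(starts + read_len, n)
    keep <- (ends - starts) >= min_keep
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(
      read_id = sprintf("%s:%d-%d", sid, starts, ends),
      scaffold_id = sid, start = starts, end = ends,
      sequence = substring(s, starts + 1L, ends),
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cut scaffolds into segments for composition binning
#'
#' Consecutive `seg_len` windows per scaffold; a trailing remainder
#' shorter than `seg_len` is merged into the preceding segment of the
#' same scaffold, so the only segments shorter than `seg_len` come from
#' scaffolds shorter than `seg_len`. Segments below `min_len` are
#' discarded.
#'
#' @param asm an [assembly()].
#' @param seg_len window length (default 10,000).
#' @param min_len minimum segment length retained (default 1000).
#' @return data.frame: `segment_id`, `scaffold_id`, `start`, `end`,
#'   `sequence`.
#' @export
make_segments <- function(asm, seg_len = 10000L, min_len = 1000L) {
  stopifnot(seg_len > min_len)
  out <- lapply(names(asm$seqs), function(sid) {
    s <- asm$seqs[[sid]]
    n <- nchar(s)
    if (n < min_len) return(NULL)
    if (n < 2L * seg_len) {
      starts <- 0L; ends <- n
    } else {
      starts <- seq.int(0L, n - 1L, by = seg_len)
      ends <- starts + seg_len
      # merge the remainder into the last full window
      if (n %% seg_len != 0L) starts <- starts[-length(starts)]
      ends <- c(ends[seq_len(length(starts) - 1L)], n)
    }
    data.frame(
      segment_id = sprintf("%s:%d-%d", sid, starts, ends),
      scaffold_id = sid, start = starts, end = ends,
      sequence = substring(s, starts + 1L, ends),
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reverse complement (character interface)
#' @param sequence nucleotide string(s); vectorized.
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}
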