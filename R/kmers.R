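# Kmers are encoded as base-4 numerics (A=0, C=1, G=2, T=3, big-endian),
# exact in doubles up to k = 26. Lexicographic order on ACGT strings equals
# numeric order on codes, so the canonical form (min of kmer and reverse
# complement) carries over.

nt_digits <- local({
  lut <- rep(NA_real_, 256)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  function(sequence) lut[as.integer(charToRaw(sequence))]
})

#' Encode all kmers of a sequence as numeric codes
#'
#' @param sequence a nucleotide string.
#' @param k kmer size (2..26).
#' @param canonical if TRUE (default) return the canonical code, the
#'   minimum of the kmer and its reverse complement.
#' @return Numeric vector of length `nchar(sequence) - k + 1`; windows
#'   containing characters other than A/C/G/T are `NA`.
#' @export
kmer_codes <- function(sequence, k = 21L, canonical = TRUE) {
  stopifnot(k >= 2, k <= 26)
  d <- nt_digits(sequence)
  n <- length(d)
  if (n < k) return(numeric(0))
  fwd <- as.numeric(stats::filter(d, 4^(seq_len(k) - 1), sides = 1))[k:n]
  if (!canonical) return(fwd)
  rc <- as.numeric(stats::filter(3 - d, 4^(k - seq_len(k)), sides = 1))[k:n]
  pmin(fwd, rc)
}

#' Decode a numeric kmer code back to a string
#' @param code numeric vector of codes.
#' @param k kmer size used at encoding.
#' @return Character vector of kmers.
#' @export
decode_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(code), ncol = k)
  for (j in seq.int(k, 1)) {
    out[, j] <- bases[(code %% 4) + 1]
    code <- code %/% 4
  }
  apply(out, 1, paste, collapse = "")
}

#' Build a signature-kmer index over reference genomes
#'
#' Every canonical kmer occurring in the reference set is stored with the
#' LCA of all taxa whose genomes contain it, mirroring the databases used
#' by signature-kmer read classifiers. Kmers containing `N` are skipped.
#'
#' @param genomes named list of reference genomes (each an [assembly()]
#'   or a character vector of scaffold sequences), names are genome ids.
#' @param taxa named character vector mapping genome id to taxon_id.
#' @param tree a [taxonomy()].
#' @param k kmer size (default 21).
#' @return Object of class `kmer_index`: fields `k`, `entries` (a
#'   data.table `code`,`taxon_id` keyed by code), `source_genomes`.
#' @export
build_kmer_index <- function(genomes, taxa, tree, k = 21L) {
  if (k < 1) stop("k must be >= 1")
  gids <- names(genomes)
  if (is.null(gids) || !all(gids %in% names(taxa))) {
    stop("every genome needs a taxon_id in `taxa`")
  }
  assert_taxa(tree, unname(taxa[gids]))
  per <- lapply(gids, function(g) {
    seqs <- genomes[[g]]
    if (inherits(seqs, "assembly")) seqs <- seqs$seqs
    codes <- unlist(lapply(seqs, kmer_codes, k = k), use.names = FALSE)
    codes <- unique(codes[!is.na(codes)])
    data.table::data.table(code = codes, taxon_id = taxa[[g]])
  })
  dt <- unique(data.table::rbindlist(per))
  code <- taxon_id <- key <- NULL # data.table NSE
  nt <- dt[, list(n = .N), by = code]
  single <- dt[code %in% nt[nt$n == 1L, code]]
  multi <- dt[code %in% nt[nt$n > 1L, code]]
  if (nrow(multi)) {
    grp <- multi[, list(key = paste(sort(taxon_id), collapse = "|")), by = code]
    uk <- unique(grp$key)
    lcas <- vapply(strsplit(uk, "|", fixed = TRUE),
                   function(tt) lca(tree, tt), character(1))
    grp[, taxon_id := lcas[match(key, uk)]]
    entries <- data.table::rbindlist(list(
      single[, list(code, taxon_id)], grp[, list(code, taxon_id)]
    ))
  } else {
    entries <- single[, list(code, taxon_id)]
  }
  data.table::setkeyv(entries, "code")
  structure(list(k = k, entries = entries, source_genomes = gids),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", nrow(x$entries), " kmers from ",
      length(x$source_genomes), " genomes\n", sep = "")
  invisible(x)
}

#' Look up canonical kmer codes in an index
#' @param index a [build_kmer_index()] result.
#' @param codes numeric canonical codes (NA allowed).
#' @return Character vector of taxon ids (`NA` for misses).
#' @export
kmer_lookup <- function(index, codes) {
  idx <- data.table::data.table(code = codes)
  index$entries[idx, on = "code"]$taxon_id
}

#' Serialize a kmer index as TSV (`kmer<TAB>taxon_id`)
#' @param index a `kmer_index`.
#' @param path file path.
#' @export
write_kmer_index <- function(index, path) {
  dt <- data.table::data.table(
    kmer = decode_kmer(index$entries$code, index$k),
    taxon_id = index$entries$taxon_id
  )
  hdr <- paste0("#k=", index$k, " genomes=",
                paste(index$source_genomes, collapse = ","))
  writeLines(c(hdr, paste(dt$kmer, dt$taxon_id, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^#k=", hdr)) stop("missing #k= header in ", path)
  k <- as.integer(sub("^#k=(\\d+).*", "\\1", hdr))
  gids <- strsplit(sub(".*genomes=", "", hdr), ",", fixed = TRUE)[[1]]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  kmers <- vapply(parts, `[`, character(1), 1L)
  taxa <- vapply(parts, `[`, character(1), 2L)
  codes <- vapply(kmers, function(s) kmer_codes(s, k, canonical = FALSE),
                  numeric(1), USE.NAMES = FALSE)
  entries <- data.table::data.table(code = codes, taxon_id = taxa)
  data.table::setkeyv(entries, "code")
  structure(list(k = k, entries = entries, source_genomes = gids),
            class = "kmer_index")
}
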