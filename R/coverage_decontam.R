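# Per-segment genome maps (classification fractions, GC, marker loci,
# coverage), per-class coverage statistics, scaffold labelling, and
# decontaminated FASTA output.

#' Per-segment report for genome maps
#'
#' Cuts the assembly into segments, attributes pseudo-read labels to
#' segments by coordinate overlap (a read spanning a segment boundary
#' contributes proportionally to its overlap), and attaches GC content,
#' mean coverage and overlapping marker hits. Scaffolds are ordered by
#' ascending mean GC, the layout used for contamination genome maps.
#'
#' @param asm an [assembly()].
#' @param reads data.frame from [make_pseudoreads()] (coordinates).
#' @param labels data.frame from a read classifier, aligned with `reads`
#'   by `read_id`.
#' @param marker_hits optional data.frame of marker loci (`scaffold_id`,
#'   `start`, `end`, plus anything else; carried through).
#' @param coverage optional coverage track from [read_bedgraph()].
#' @param seg_len segment length (default 10,000 nt).
#' @return data.frame, one row per segment, ordered for plotting:
#'   `scaffold_id`, `start`, `end`, `gc`, `focal`, `contaminant`,
#'   `unknown`, `unclassified` (percent of the segment's read bases),
#'   `mean_coverage` (NA without a track), `n_markers`.
#' @export
segment_report <- function(asm, reads, labels, marker_hits = NULL,
                           coverage = NULL, seg_len = 10000L) {
  segs <- make_segments(asm, seg_len = seg_len, min_len = 1L)
  lab <- labels$label[match(reads$read_id, labels$read_id)]
  classes <- c("FOCAL", "CONTAMINANT", "UNKNOWN", "UNCLASSIFIED")
  out <- segs[, c("segment_id", "scaffold_id", "start", "end")]
  out$gc <- gc_content(segs$sequence)
  frac <- matrix(0, nrow(segs), 4, dimnames = list(NULL, classes))
  out$mean_coverage <- NA_real_
  out$n_markers <- 0L
  for (i in seq_len(nrow(segs))) {
    sid <- segs$scaffold_id[i]
    s0 <- segs$start[i]; s1 <- segs$end[i]
    r <- reads$scaffold_id == sid & reads$end > s0 & reads$start < s1
    if (any(r)) {
      ov <- pmin(reads$end[r], s1) - pmax(reads$start[r], s0)
      for (cl in classes) {
        frac[i, cl] <- sum(ov[lab[r] == cl])
      }
      frac[i, ] <- 100 * frac[i, ] / sum(ov)
    }
    if (!is.null(marker_hits) && nrow(marker_hits)) {
      out$n_markers[i] <- sum(marker_hits$scaffold_id == sid &
                                marker_hits$end > s0 & marker_hits$start < s1)
    }
    if (!is.null(coverage)) {
      out$mean_coverage[i] <- mean_depth(coverage, sid, s0, s1)
    }
  }
  out$focal <- frac[, "FOCAL"]
  out$contaminant <- frac[, "CONTAMINANT"]
  out$unknown <- frac[, "UNKNOWN"]
  out$unclassified <- frac[, "UNCLASSIFIED"]
  # scaffolds ordered by ascending mean GC; segments in position order
  sc_gc <- tapply(out$gc, out$scaffold_id, mean)
  out$scaffold_order <- match(out$scaffold_id, names(sort(sc_gc)))
  out <- out[order(out$scaffold_order, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label a scaffold from its segment records
#'
#' Among classified (focal + contaminant) length-weighted fractions:
#' `CONTAMINANT` if contaminant outweighs focal, `FOCAL` in the opposite
#' case, `UNDETERMINED` when they tie or nothing is classified.
#'
#' @param records rows of a [segment_report()] for one scaffold.
#' @return One of `"FOCAL"`, `"CONTAMINANT"`, `"UNDETERMINED"`.
#' @export
scaffold_label <- function(records) {
  w <- records$end - records$start
  foc <- sum(w * records$focal)
  con <- sum(w * records$contaminant)
  if (foc + con == 0 || foc == con) return("UNDETERMINED")
  if (con > foc) "CONTAMINANT" else "FOCAL"
}

#' Label every scaffold of a segment report
#' @param records a full [segment_report()].
#' @return Named character vector scaffold_id -> label.
#' @export
scaffold_labels <- function(records) {
  vapply(split(records, records$scaffold_id), scaffold_label, character(1))
}

quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                         type = 7)

#' Coverage statistics per scaffold class
#'
#' Median and IQR of per-segment mean coverage for focal and contaminant
#' scaffolds (classes from [scaffold_labels()]), plus the assembly-wide
#' quartile coefficient of dispersion `QCD = (Q3 - Q1) / (Q3 + Q1)` —
#' small values indicate the uniform sequencing depth expected of a
#' clean, single-organism assembly. Quartiles use linear interpolation
#' between order statistics.
#'
#' @param records a [segment_report()] with coverage.
#' @param labels named vector from [scaffold_labels()]; computed from
#'   `records` if missing.
#' @return List: `per_class` (data.frame class/n/median/iqr), `qcd`.
#' @export
coverage_stats <- function(records, labels = NULL) {
  if (all(is.na(records$mean_coverage))) {
    stop("coverage_stats() needs coverage in the segment report")
  }
  if (is.null(labels)) labels <- scaffold_labels(records)
  cls <- labels[records$scaffold_id]
  cov <- records$mean_coverage
  per_class <- do.call(rbind, lapply(unique(cls), function(cl) {
    x <- cov[cls == cl & !is.na(cov)]
    q <- quartiles(x)
    data.frame(class = cl, n_segments = length(x), median = q[2],
               iqr = q[3] - q[1], stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  q <- quartiles(cov[!is.na(cov)])
  list(per_class = per_class, qcd = (q[3] - q[1]) / (q[3] + q[1]))
}

#' Read / write a coverage track in bedGraph format
#'
#' 4-column bedGraph, 0-based half-open intervals, one depth value per
#' interval. Intervals are validated against scaffold bounds when an
#' assembly is supplied.
#'
#' @param path file path.
#' @param asm optional [assembly()] for bounds validation.
#' @return A data.frame of class `coverage_track`: `scaffold_id`,
#'   `start`, `end`, `depth`, position-sorted.
#' @export
read_bedgraph <- function(path, asm = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    stop("bedGraph line ", which(nf != 4)[1], " has ", nf[nf != 4][1],
         " fields, expected 4")
  }
  m <- do.call(rbind, parts)
  trk <- data.frame(scaffold_id = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), depth = as.numeric(m[, 4]),
                    stringsAsFactors = FALSE)
  if (any(trk$end <= trk$start) || any(trk$depth < 0)) {
    stop("bedGraph has an empty interval or negative depth")
  }
  if (!is.null(asm)) {
    len <- nchar(asm$seqs)
    bad <- trk$end > len[trk$scaffold_id]
    if (any(is.na(bad)) || any(bad)) {
      stop("bedGraph interval beyond scaffold end: ",
           trk$scaffold_id[which(is.na(bad) | bad)][1])
    }
  }
  trk <- trk[order(trk$scaffold_id, trk$start), , drop = FALSE]
  rownames(trk) <- NULL
  class(trk) <- c("coverage_track", "data.frame")
  trk
}

#' @rdname read_bedgraph
#' @param track a coverage track data.frame.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$scaffold_id, track$start, track$end,
                   formatC(track$depth, format = "fg", digits = 8),
                   sep = "\t"), path)
  invisible(path)
}

mean_depth <- function(track, scaffold_id, start, end) {
  t <- track[track$scaffold_id == scaffold_id &
               track$end > start & track$start < end, , drop = FALSE]
  if (!nrow(t)) return(0)
  ov <- pmin(t$end, end) - pmax(t$start, start)
  sum(ov * t$depth) / (end - start)
}

#' Coverage track from error-free reads by exact matching
#'
#' A deliberately naive mapper for synthetic reads: each read is placed
#' at its unique exact match in the assembly (either strand); reads with
#' no match or multiple matches are discarded. Intended for simulated
#' error-free reads, not real data.
#'
#' @param asm an [assembly()].
#' @param reads character vector of read sequences.
#' @return A `coverage_track` data.frame.
#' @export
coverage_from_reads <- function(asm, reads) {
  subject <- Biostrings::DNAStringSet(asm$seqs)
  depth <- lapply(nchar(asm$seqs), function(n) numeric(n))
  names(depth) <- names(asm$seqs)
  for (rd in reads) {
    hits <- NULL
    for (q in c(rd, revcomp(rd))) {
      mm <- Biostrings::startIndex(Biostrings::vmatchPattern(q, subject))
      for (si in seq_along(mm)) {
        st <- mm[[si]]
        if (!is.null(st) && length(st)) {
          hits <- rbind(hits, data.frame(sid = names(asm$seqs)[si],
                                         start = st, w = nchar(q)))
        }
      }
      if (!is.null(hits)) break # forward match found; don't try revcomp
    }
    if (is.null(hits) || nrow(hits) != 1) next # non- or multi-mapper
    i <- hits$start[1]:(hits$start[1] + hits$w[1] - 1)
    depth[[hits$sid[1]]][i] <- depth[[hits$sid[1]]][i] + 1
  }
  depth_to_track(depth)
}

# run-length encode per-base depth vectors into a bedGraph-style track
depth_to_track <- function(depth) {
  out <- lapply(names(depth), function(sid) {
    r <- rle(depth[[sid]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    if (!any(keep)) return(NULL)
    data.frame(scaffold_id = sid, start = starts[keep], end = ends[keep],
               depth = r$values[keep], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  trk <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(scaffold_id = character(0), start = integer(0),
               end = integer(0), depth = numeric(0))
  }
  class(trk) <- c("coverage_track", "data.frame")
  trk
}

#' Remove or mask contaminant regions of an assembly
#'
#' In `mask` mode every pseudo-read interval labelled `CONTAMINANT` is
#' replaced by `N`, conserving scaffold count and lengths. In `drop`
#' mode scaffolds whose classified (focal + contaminant) fraction is at
#' least `scaffold_drop_threshold` contaminant are removed entirely, and
#' masking is applied to the survivors. Reads labelled `UNKNOWN` are
#' never masked: genuinely transferred genes tend to end up in that
#' fraction, and masking them would destroy real signal.
#'
#' @param asm an [assembly()].
#' @param reads data.frame from [make_pseudoreads()].
#' @param labels classifier output aligned by `read_id`.
#' @param mode `"mask"` or `"drop"`.
#' @param scaffold_drop_threshold contaminant fraction (of classified
#'   bases) above which a scaffold is dropped (default 0.5).
#' @return A decontaminated [assembly()].
#' @export
decontaminate <- function(asm, reads, labels, mode = c("mask", "drop"),
                          scaffold_drop_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(scaffold_drop_threshold > 0, scaffold_drop_threshold <= 1)
  lab <- labels$label[match(reads$read_id, labels$read_id)]
  seqs <- asm$seqs
  if (mode == "drop") {
    con <- tapply((reads$end - reads$start) * (lab == "CONTAMINANT"),
                  reads$scaffold_id, sum)
    cls <- tapply((reads$end - reads$start) *
                    (lab %in% c("FOCAL", "CONTAMINANT")),
                  reads$scaffold_id, sum)
    frac <- ifelse(cls > 0, con / cls, 0)
    dropped <- names(frac)[frac >= scaffold_drop_threshold]
    seqs <- seqs[!names(seqs) %in% dropped]
    if (!length(seqs)) stop("decontaminate(): every scaffold dropped")
  }
  bad <- which(lab == "CONTAMINANT" & reads$scaffold_id %in% names(seqs))
  for (i in bad) {
    sid <- reads$scaffold_id[i]
    substr(seqs[[sid]], reads$start[i] + 1L, reads$end[i]) <-
      strrep("N", reads$end[i] - reads$start[i])
  }
  assembly(paste0(asm$assembly_id, "_decontam"), seqs)
}
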