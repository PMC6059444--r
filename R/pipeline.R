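# End-to-end scoring of one assembly by all six methods, and the genome
# map built from segment reports.

#' Score an assembly with all six contamination estimators
#'
#' Runs, against a shared reference database: (1) SSU rRNA best-hit
#' classification, (2) ribosomal-protein top-3 LCA classification,
#' (3) single-copy-marker redundancy, (4) signature-kmer pseudo-read
#' classification, (5) MEGAN-like protein LCA over translated
#' pseudo-read hits, and (6) reference-free composition binning; and
#' returns the six contamination percentages plus the per-read labels
#' the genome-wide methods produced (for maps and decontamination).
#'
#' @param asm an [assembly()].
#' @param tree a [taxonomy()].
#' @param index a [build_kmer_index()] over the reference genomes.
#' @param prot_db a [protein_db()] over the reference proteome.
#' @param rprot_families named list of protein [marker_family()]s.
#' @param ssu_family nucleotide [marker_family()].
#' @param self_genome_id genome id for protein self-match exclusion
#'   (the genome the assembly claims to be), or `NULL`.
#' @param kmer_cfg,prot_cfg,bin_cfg method configurations.
#' @param na_mask_kmer apply the kmer NA mask when the assembly id is
#'   among the index source genomes (default TRUE).
#' @param min_seeds,max_candidates seed-prefilter settings passed to
#'   [search_reads()]; the assembly-scale defaults (2, 16) trade a
#'   negligible amount of marginal-hit sensitivity for a several-fold
#'   smaller alignment workload.
#' @return List of class `method_result`: `scores` (named numeric:
#'   `rRNA`, `rprot`, `redundancy`, `kmer`, `protein`, `binning`),
#'   `reads`, `kmer_labels`, `protein_labels`, `kmer_profile`,
#'   `protein_profile`, `ssu`, `rprot`, `redundancy`, `binning`.
#' @export
score_assembly <- function(asm, tree, index, prot_db, rprot_families,
                           ssu_family, self_genome_id = NULL,
                           kmer_cfg = kmer_config(),
                           prot_cfg = protein_lca_config(),
                           bin_cfg = binning_config(),
                           na_mask_kmer = TRUE,
                           min_seeds = 2L, max_candidates = 16L) {
  reads <- make_pseudoreads(asm)

  ssu_loci <- detect_ssu(asm, ssu_family)
  ssu <- ssu_contamination(ssu_loci, tree)

  rp <- rprot_contamination(asm, rprot_families, tree)
  red <- redundancy_estimate(rp$hits, panel = names(rprot_families))

  kmer_labels <- classify_reads_kmer(reads, index, tree, kmer_cfg)
  kmer_profile <- profile_assembly(kmer_labels, tree, asm$assembly_id)
  kmer_score <- kmer_profile$contaminant
  masked <- na_mask_kmer && kraken_na_mask(strip_query_suffix(asm$assembly_id),
                                           index)

  hits <- search_reads(reads, prot_db, min_bit = 0,
                       min_seeds = min_seeds, max_candidates = max_candidates)
  protein_labels <- classify_reads_protein(
    hits, tree, prot_cfg, self_genome_id = self_genome_id,
    read_ids = reads$read_id)
  protein_profile <- profile_assembly(protein_labels, tree, asm$assembly_id)

  bin <- binning_contamination(asm, bin_cfg)

  res <- list(
    scores = c(rRNA = ssu$contamination, rprot = rp$contamination,
               redundancy = red$contamination,
               kmer = if (masked) NA_real_ else kmer_score,
               protein = protein_profile$contaminant,
               binning = bin$contamination),
    kmer_score_unmasked = kmer_score,
    reads = reads, kmer_labels = kmer_labels,
    protein_labels = protein_labels,
    kmer_profile = kmer_profile, protein_profile = protein_profile,
    ssu = c(ssu, list(loci = ssu_loci)), rprot = rp, redundancy = red,
    binning = bin
  )
  class(res) <- "method_result"
  res
}

# query assemblies derived from genome `x` are named `x_q`; the kmer NA
# mask applies to the source genome id
strip_query_suffix <- function(assembly_id) {
  sub("_q$", "", assembly_id)
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result> scores (%):\n")
  print(round(x$scores, 2))
  invisible(x)
}

#' Assemble a method-score matrix from several scored assemblies
#' @param results named list of [score_assembly()] results (names =
#'   assembly ids).
#' @return Numeric matrix assemblies x methods.
#' @export
method_scores <- function(results) {
  t(vapply(results, function(r) r$scores, numeric(6)))
}

#' Genome map of a segment report
#'
#' One panel row per quantity: the classification band (each segment
#' coloured by focal / contaminant / unknown / unclassified fractions),
#' the GC curve, marker-locus symbols and, when present, the coverage
#' curve. Scaffolds appear in ascending-GC order as produced by
#' [segment_report()].
#'
#' @param records a [segment_report()].
#' @return A ggplot object.
#' @export
plot_genome_map <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_genome_map() needs the ggplot2 package")
  }
  rec <- records
  rec$idx <- seq_len(nrow(rec))
  long <- do.call(rbind, lapply(
    c("focal", "contaminant", "unknown", "unclassified"),
    function(cl) data.frame(idx = rec$idx, class = cl, frac = rec[[cl]])))
  long$class <- factor(long$class,
                       levels = c("focal", "contaminant", "unknown",
                                  "unclassified"))
  sc_breaks <- rec$idx[!duplicated(rec$scaffold_id)] - 0.5
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$idx, y = .data$frac,
                                          fill = .data$class)) +
    ggplot2::geom_col(width = 1, position = "stack") +
    ggplot2::geom_vline(xintercept = sc_breaks, linewidth = 0.2,
                        colour = "grey40") +
    ggplot2::geom_line(
      data = rec, inherit.aes = FALSE,
      ggplot2::aes(x = .data$idx, y = .data$gc), colour = "lightblue3") +
    ggplot2::scale_fill_manual(values = c(
      focal = "#2E8B57", contaminant = "#C23B22", unknown = "grey70",
      unclassified = "white")) +
    ggplot2::labs(x = "segments (scaffolds by ascending GC)",
                  y = "% of segment / GC%", fill = NULL) +
    ggplot2::theme_minimal()
  if (any(rec$n_markers > 0)) {
    p <- p + ggplot2::geom_point(
      data = rec[rec$n_markers > 0, ], inherit.aes = FALSE,
      ggplot2::aes(x = .data$idx, y = 104), shape = 1, size = 1.5)
  }
  if (!all(is.na(rec$mean_coverage))) {
    m <- max(rec$mean_coverage, na.rm = TRUE)
    p <- p + ggplot2::geom_line(
      data = rec, inherit.aes = FALSE, colour = "salmon",
      ggplot2::aes(x = .data$idx, y = 100 * .data$mean_coverage / m))
  }
  p
}

#' Prepare the shared reference structures for scoring
#'
#' Builds the signature-kmer index and the protein database once, so
#' many assemblies can be scored against them. The kmer index may
#' exclude genomes (typically the query hosts: a kmer database
#' containing the query genome is uninformative about it).
#'
#' @param sim a [simulate_dataset()] result or a [make_reference_db()]
#'   list.
#' @param tree a [taxonomy()] (defaults to `sim$tree`).
#' @param exclude_from_kmer genome ids left out of the kmer index.
#' @param k kmer size.
#' @return List: `tree`, `index`, `prot_db`, `rprot_families`,
#'   `ssu_family`.
#' @export
prepare_reference <- function(sim, tree = sim$tree,
                              exclude_from_kmer = character(0), k = 21L) {
  keep <- setdiff(names(sim$genomes), exclude_from_kmer)
  if (!length(keep)) stop("kmer index would be empty")
  list(
    tree = tree,
    index = build_kmer_index(sim$genomes[keep], sim$taxa[keep], tree, k = k),
    prot_db = protein_db(sim$proteome),
    rprot_families = sim$rprot_families,
    ssu_family = sim$ssu_family
  )
}

#' Score a list of query assemblies against a prepared reference
#'
#' @param queries list of [build_chimera()] results (or a
#'   [build_query_set()] element).
#' @param ref a [prepare_reference()] result.
#' @param ... passed to [score_assembly()].
#' @return Named list of [score_assembly()] results.
#' @export
score_queries <- function(queries, ref, ...) {
  out <- lapply(queries, function(q) {
    score_assembly(q$assembly, ref$tree, ref$index, ref$prot_db,
                   ref$rprot_families, ref$ssu_family,
                   self_genome_id = q$host_id, ...)
  })
  stats::setNames(out, names(queries))
}
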