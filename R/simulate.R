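# Synthetic-data generator: taxonomies, reference genomes and proteomes
# with phylum-structured composition, implanted SSU-like and
# ribosomal-protein-like marker genes, chimeric query assemblies, reads
# and exact ground truth. Everything downstream of this module is
# testable without downloading a single public genome.

BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a handful of phyla with distinct base composition spread over
#' a wide GC range, two genomes per phylum, compact 300-kb genomes that
#' keep the full pipeline affordable, a gene-dense architecture (about
#' 85 percent coding, as in real prokaryotes) so translated searches see
#' most of the sequence, a 20-family single-copy ribosomal-protein
#' panel, one to four SSU copies per genome, and a host:contaminant
#' depth ratio of 68:26 as observed for a real contaminated assembly.
#'
#' @param seed master RNG seed.
#' @param n_phyla number of phyla (first one is focal).
#' @param genomes_per_phylum leaf genomes per phylum (one genus each).
#' @param genome_length target genome length in nt.
#' @param gc_range per-phylum GC targets are spread evenly over this
#'   range (fractions).
#' @param coding_density fraction of each genome covered by
#'   protein-coding genes.
#' @param n_rprot_families single-copy protein marker families.
#' @param ssu_copies_range SSU copies per genome drawn uniformly from
#'   this range.
#' @param gene_len_range bulk/marker protein lengths (aa).
#' @param branch_sub_aa per-unit-branch amino-acid substitution
#'   probability scale (see vignette).
#' @param contaminant_fraction true contaminant base fraction f of a
#'   chimera.
#' @param n_contaminants number of contaminant organisms (0-2).
#' @param chimeric_scaffold_rate probability a contaminant block is
#'   concatenated onto a host scaffold instead of forming its own.
#' @param scaffold_meanlog,scaffold_sdlog lognormal scaffold lengths.
#' @param host_depth,contaminant_depth simulated sequencing depths.
#' @param read_length,read_error_rate read simulation parameters.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_phyla = 5L, genomes_per_phylum = 2L,
                       genome_length = 3e5, gc_range = c(0.35, 0.65),
                       coding_density = 0.85, n_rprot_families = 20L,
                       ssu_copies_range = c(1L, 4L),
                       gene_len_range = c(120L, 200L),
                       branch_sub_aa = 1.0,
                       contaminant_fraction = 0.10, n_contaminants = 1L,
                       chimeric_scaffold_rate = 0.2,
                       scaffold_meanlog = log(25000), scaffold_sdlog = 0.6,
                       host_depth = 68, contaminant_depth = 26,
                       read_length = 100L, read_error_rate = 0) {
  stopifnot(n_phyla >= 2, contaminant_fraction >= 0, contaminant_fraction < 1,
            host_depth > 0, contaminant_depth > 0,
            gc_range[1] > 0.2, gc_range[2] < 0.8)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a taxonomy
#'
#' Root, a domain-like intermediate (so that high-ranking LCAs exist and
#' map to `UNKNOWN`), `n_phyla` phyla each with one genus and
#' `genomes_per_phylum` leaf genomes. The first phylum is focal.
#'
#' @param config a [sim_config()].
#' @return A [taxonomy()]; leaf ids double as genome ids
#'   (`"p<i>_g<j>"`).
#' @export
simulate_taxonomy <- function(config = sim_config()) {
  rows <- list(
    data.frame(taxon_id = "root", parent_id = NA, rank = "no-rank",
               name = "cellular organisms"),
    data.frame(taxon_id = "dom", parent_id = "root", rank = "superkingdom",
               name = "Bacteria-like domain")
  )
  for (i in seq_len(config$n_phyla)) {
    pid <- sprintf("phy%02d", i)
    gid <- sprintf("gen%02d", i)
    rows[[length(rows) + 1]] <- data.frame(
      taxon_id = pid, parent_id = "dom", rank = "phylum",
      name = sprintf("Phylum%02d", i))
    rows[[length(rows) + 1]] <- data.frame(
      taxon_id = gid, parent_id = pid, rank = "genus",
      name = sprintf("Genus%02d", i))
    for (j in seq_len(config$genomes_per_phylum)) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = sprintf("p%d_g%d", i, j), parent_id = gid,
        rank = "species", name = sprintf("Species %d-%d", i, j))
    }
  }
  taxonomy(do.call(rbind, rows), focal_id = "phy01")
}

# branch lengths of the simulated tree (expected substitutions scale);
# chosen so within-genus identity ~94% aa and between-phyla ~50-60%
sim_branch_lengths <- function(tree) {
  rk <- stats::setNames(tree$nodes$rank, tree$nodes$taxon_id)
  bl <- c(`no-rank` = 0, superkingdom = 0.05, phylum = 0.22,
          genus = 0.05, species = 0.03)
  stats::setNames(unname(bl[rk]), tree$nodes$taxon_id)
}

# evolve a peptide along every branch of the tree; returns a list
# taxon_id -> sequence (all nodes, leaves included)
evolve_protein <- function(tree, ancestral, rate) {
  bl <- sim_branch_lengths(tree)
  seqs <- list(root = ancestral)
  order_by_depth <- tree$nodes$taxon_id[order(tree$depth[tree$nodes$taxon_id])]
  for (t in order_by_depth[-1]) {
    parent <- tree$parent[[t]]
    p <- seqs[[parent]]
    x <- strsplit(p, "")[[1]]
    hit <- stats::runif(length(x)) < (1 - exp(-rate * bl[[t]]))
    if (any(hit)) {
      x[hit] <- vapply(x[hit], function(a) sample(setdiff(AA20, a), 1),
                       character(1))
    }
    seqs[[t]] <- paste(x, collapse = "")
  }
  seqs
}

# evolve a nucleotide sequence with a mask of invariant (conserved)
# positions, substitution-only
evolve_nucleotide <- function(tree, ancestral, rate, conserved) {
  bl <- sim_branch_lengths(tree)
  seqs <- list(root = ancestral)
  order_by_depth <- tree$nodes$taxon_id[order(tree$depth[tree$nodes$taxon_id])]
  for (t in order_by_depth[-1]) {
    x <- strsplit(seqs[[tree$parent[[t]]]], "")[[1]]
    hit <- stats::runif(length(x)) < (1 - exp(-rate * bl[[t]]))
    hit <- hit & !conserved
    if (any(hit)) {
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1),
                       character(1))
    }
    seqs[[t]] <- paste(x, collapse = "")
  }
  seqs
}

# codon table grouped by amino acid, with per-codon G+C counts
codon_sets <- local({
  gcod <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gcod), unname(gcod))
  by_aa <- by_aa[names(by_aa) != "*"]
  list(codons = by_aa,
       ngc = lapply(by_aa, function(cs) nchar(gsub("[^GC]", "", cs))))
})

# expected coding GC fraction under codon weights r^nGC, uniform AA use
coding_gc_expect <- function(r) {
  per_aa <- vapply(names(codon_sets$codons), function(a) {
    ngc <- codon_sets$ngc[[a]]
    p <- r^ngc / sum(r^ngc)
    sum(p * ngc) / 3
  }, numeric(1))
  mean(per_aa)
}

# solve the codon-bias odds ratio r so that coding GC hits `target`
# (clamped to the achievable range), by bisection on log r
solve_codon_bias <- function(target) {
  lo <- -6; hi <- 6
  emin <- coding_gc_expect(exp(lo)) + 0.005
  emax <- coding_gc_expect(exp(hi)) - 0.005
  target <- min(max(target, emin), emax)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (coding_gc_expect(exp(mid)) < target) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# per-phylum then per-genome order-3 Markov transition matrices (64 x 4)
# for the intergenic background, Dirichlet-perturbed around a GC-target
# base distribution so within-phylum genomes are compositionally closer
# than between-phylum; the intergenic GC compensates for the part of the
# phylum target the coding fraction cannot reach through codon bias alone
markov_params <- function(tree, config) {
  gc <- seq(config$gc_range[1], config$gc_range[2],
            length.out = config$n_phyla)
  rdir <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  phyla <- grep("^phy", tree$nodes$taxon_id, value = TRUE)
  out <- list()
  for (i in seq_along(phyla)) {
    r <- solve_codon_bias(gc[i])
    coding_gc <- coding_gc_expect(r)
    ig <- (gc[i] - config$coding_density * coding_gc) /
      (1 - config$coding_density)
    ig <- min(max(ig, 0.22), 0.78)
    q <- c((1 - ig) / 2, ig / 2, ig / 2, (1 - ig) / 2)
    phy_mat <- t(vapply(1:64, function(ctx) rdir(60 * q), numeric(4)))
    leaves <- tree$nodes$taxon_id[grepl(sprintf("^p%d_g", i),
                                        tree$nodes$taxon_id)]
    for (lf in leaves) {
      out[[lf]] <- list(
        trans = t(apply(phy_mat, 1, function(p) rdir(400 * p))),
        gc = gc[i], codon_r = r
      )
    }
  }
  out
}

# sample `n` nt from an order-3 Markov chain given a 64x4 transition matrix
markov_sample <- function(trans, n) {
  if (n <= 0) return("")
  d <- integer(n + 3L)
  d[1:3] <- sample.int(4L, 3L, replace = TRUE) - 1L
  cum <- t(apply(trans, 1, cumsum))
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    ctx <- 16L * d[i] + 4L * d[i + 1L] + d[i + 2L] + 1L
    d[i + 3L] <- findInterval(u[i], cum[ctx, ]) # 0..3
  }
  paste(BASES[d[4:(n + 3L)] + 1L], collapse = "")
}

# reverse-translate peptides with GC-biased codon usage: codon odds are
# proportional to r^nGC, with r from solve_codon_bias(), emulating host
# codon bias; vectorized over all residues of all peptides at once
reverse_translate <- function(peptides, codon_r) {
  lens <- nchar(peptides)
  x <- strsplit(paste(peptides, collapse = ""), "")[[1]]
  codons <- character(length(x))
  for (a in unique(x)) {
    cs <- codon_sets$codons[[a]]
    idx <- which(x == a)
    if (length(cs) == 1L) {
      codons[idx] <- cs
    } else {
      p <- codon_r^codon_sets$ngc[[a]]
      codons[idx] <- sample(cs, length(idx), replace = TRUE, prob = p)
    }
  }
  vapply(split(codons, rep(seq_along(peptides), lens)),
         paste, character(1), collapse = "")
}

#' Simulate reference genomes and proteomes along a taxonomy
#'
#' Each genome is a mosaic of protein-coding genes (orthologous families
#' evolved along the tree, reverse-translated with a GC-biased codon
#' usage matching the phylum's composition target) separated by
#' intergenic background drawn from an order-3 Markov chain whose
#' transition parameters are inherited phylum -> genome with Dirichlet
#' perturbation. Within-phylum genomes are therefore compositionally
#' closer than between-phylum genomes, and realized GC tracks the
#' phylum target.
#'
#' @param tree a [simulate_taxonomy()] result.
#' @param config a [sim_config()].
#' @return List of class `sim_genomes`: `genomes` (named list of
#'   single-sequence character vectors), `taxa` (genome -> taxon, here
#'   the identity), `proteome` (data.frame `protein_id`, `genome_id`,
#'   `taxon_id`, `sequence`), `genes` (coordinate table), `config`,
#'   `tree`.
#' @export
simulate_genomes <- function(tree, config = sim_config()) {
  set.seed(config$seed)
  leaves <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
  mk <- markov_params(tree, config)

  mean_gene_nt <- 3 * mean(config$gene_len_range)
  n_genes <- max(1L, round(config$genome_length * config$coding_density /
                             mean_gene_nt))
  # orthologous bulk families evolved along the tree
  fams <- sprintf("g%04d", seq_len(n_genes))
  fam_seqs <- lapply(fams, function(f) {
    L <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]), 1)
    evolve_protein(tree, paste(sample(AA20, L, replace = TRUE), collapse = ""),
                   rate = config$branch_sub_aa)
  })
  names(fam_seqs) <- fams

  mean_spacer <- config$genome_length * (1 - config$coding_density) / n_genes
  genomes <- list()
  genes <- list()
  proteome <- list()
  for (lf in leaves) {
    ord <- sample(fams)
    gene_nt <- reverse_translate(
      vapply(ord, function(f) fam_seqs[[f]][[lf]], character(1)),
      mk[[lf]]$codon_r)
    spacer_len <- pmax(10L, round(stats::rexp(n_genes, 1 / mean_spacer)))
    spacers <- vapply(spacer_len, function(sp)
      markov_sample(mk[[lf]]$trans, sp), character(1))
    parts <- as.vector(rbind(spacers, gene_nt))
    cum <- cumsum(nchar(parts))
    gstart <- cum[seq(1, 2 * n_genes, by = 2)]       # end of each spacer
    gend <- cum[seq(2, 2 * n_genes, by = 2)]
    genomes[[lf]] <- stats::setNames(paste(parts, collapse = ""),
                                     paste0(lf, "_chr"))
    genes[[lf]] <- data.frame(
      genome_id = lf, family = ord, start = gstart, end = gend,
      stringsAsFactors = FALSE)
    proteome[[lf]] <- data.frame(
      protein_id = paste(lf, ord, sep = "|"), genome_id = lf,
      taxon_id = lf,
      sequence = vapply(ord, function(f) fam_seqs[[f]][[lf]], character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(
    genomes = genomes,
    taxa = stats::setNames(leaves, leaves),
    proteome = do.call(rbind, c(proteome, list(make.row.names = FALSE))),
    genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
    config = config, tree = tree
  ), class = "sim_genomes")
}

# build an SSU-like ancestral sequence with invariant conserved blocks
# (~60% of positions), mirroring the conserved/variable architecture of
# real SSU genes that makes exact-word seeding work
ssu_architecture <- function(len = 1500L, block = 50L, conserved_frac = 0.6) {
  n_blocks <- ceiling(len / block)
  cons_blocks <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), length.out = n_blocks)
  conserved <- rep(cons_blocks, each = block)[seq_len(len)]
  # trim/extend to hit the requested fraction approximately
  conserved
}

#' Implant marker genes into simulated genomes
#'
#' For each protein marker family an ancestral 120-200 aa sequence is
#' evolved along the tree, reverse-translated with the host's codon
#' bias, and written into a random locus that overlaps neither another
#' marker nor a previously implanted one; an SSU-like 1500-nt
#' nucleotide family with invariant conserved blocks is implanted in
#' 1-4 copies per genome. Bulk genes destroyed by an implant are
#' dropped from the proteome. All implanted loci are recorded in the
#' registry (the ground-truth marker table).
#'
#' @param sim a [simulate_genomes()] result.
#' @return `sim` augmented with `rprot_families` (named list of
#'   [marker_family()]), `ssu_family`, `registry` (data.frame
#'   `genome_id`, `family_id`, `kind`, `scaffold_id`, `start`, `end`,
#'   `strand`), and updated `genomes`/`proteome`.
#' @export
implant_markers <- function(sim) {
  config <- sim$config
  tree <- sim$tree
  set.seed(config$seed + 1L)
  leaves <- names(sim$genomes)

  rfams <- sprintf("L%02d", seq_len(config$n_rprot_families))
  rprot_seqs <- lapply(rfams, function(f) {
    L <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]), 1)
    evolve_protein(tree, paste(sample(AA20, L, replace = TRUE), collapse = ""),
                   rate = config$branch_sub_aa)
  })
  names(rprot_seqs) <- rfams

  ssu_len <- 1500L
  conserved <- ssu_architecture(ssu_len)
  ssu_anc <- paste(sample(BASES, ssu_len, replace = TRUE), collapse = "")
  ssu_seqs <- evolve_nucleotide(tree, ssu_anc, rate = 1.2, conserved = conserved)

  mk <- markov_params_cache(sim)
  registry <- list()
  ssu_copies <- stats::setNames(
    sample(seq(config$ssu_copies_range[1], config$ssu_copies_range[2]),
           length(leaves), replace = TRUE), leaves)

  for (lf in leaves) {
    g <- sim$genomes[[lf]]
    seqname <- names(g)
    s <- g[[1]]
    n <- nchar(s)
    # the ribosomal genes form one collocated cluster (operon-like, as
    # in real prokaryotes): all rprot genes plus the first SSU copy,
    # separated by short intergenic gaps
    rprot_nt <- reverse_translate(
      vapply(rfams, function(f) rprot_seqs[[f]][[lf]], character(1)),
      mk[[lf]]$codon_r)
    members <- c(stats::setNames(as.list(rprot_nt), rfams),
                 list(SSU = ssu_seqs[[lf]]))
    # "TAAATAAATAA" puts a stop in all three forward frames, so the ORFs
    # of adjacent cluster genes never merge
    gaps <- vapply(seq_along(members), function(i)
      paste0("TAAATAAATAA", markov_sample(mk[[lf]]$trans, sample(60:150, 1))),
      character(1))
    cluster_parts <- as.vector(rbind(gaps, unlist(members)))
    cluster <- paste(cluster_parts, collapse = "")
    cum <- cumsum(nchar(cluster_parts))
    mem_start <- cum[seq(1, length(cluster_parts), by = 2)]
    mem_end <- cum[seq(2, length(cluster_parts), by = 2)]

    # implant the cluster, then any additional standalone SSU copies
    implants <- list(list(kind = "cluster", nt = cluster))
    for (ci in seq_len(ssu_copies[[lf]] - 1L)) {
      implants[[length(implants) + 1L]] <- list(kind = "SSU",
                                                nt = ssu_seqs[[lf]])
    }
    taken <- matrix(numeric(0), ncol = 2)
    for (im in implants) {
      w <- nchar(im$nt)
      if (w >= n) stop("implant_markers(): genome too short for implant")
      ok <- FALSE
      for (try in 1:200) {
        st <- sample.int(n - w, 1) # 1-based
        if (!any(st < taken[, 2] & (st + w) > taken[, 1])) { ok <- TRUE; break }
      }
      if (!ok) stop("implant_markers(): no free locus after 200 retries")
      taken <- rbind(taken, c(st, st + w))
      substr(s, st, st + w - 1L) <- im$nt
      if (im$kind == "cluster") {
        registry[[length(registry) + 1]] <- data.frame(
          genome_id = lf, family_id = c(rfams, "SSU"),
          kind = c(rep("rprot", length(rfams)), "SSU"),
          scaffold_id = seqname, start = st - 1L + mem_start,
          end = st - 1L + mem_end, strand = "+", stringsAsFactors = FALSE)
      } else {
        registry[[length(registry) + 1]] <- data.frame(
          genome_id = lf, family_id = "SSU", kind = "SSU",
          scaffold_id = seqname, start = st - 1L, end = st - 1L + w,
          strand = "+", stringsAsFactors = FALSE)
      }
    }
    sim$genomes[[lf]] <- stats::setNames(s, seqname)
    # drop bulk proteins whose gene locus was overwritten
    gt <- sim$genes[sim$genes$genome_id == lf, ]
    hit <- vapply(seq_len(nrow(gt)), function(i) {
      any(gt$start[i] < taken[, 2] - 1 & gt$end[i] > taken[, 1] - 1)
    }, logical(1))
    if (any(hit)) {
      dead <- paste(lf, gt$family[hit], sep = "|")
      sim$proteome <- sim$proteome[!sim$proteome$protein_id %in% dead, ]
      sim$genes <- sim$genes[!(sim$genes$genome_id == lf &
                                 sim$genes$family %in% gt$family[hit]), ]
    }
  }
  registry <- do.call(rbind, c(registry, list(make.row.names = FALSE)))

  sim$rprot_families <- stats::setNames(lapply(rfams, function(f) {
    marker_family(f, "protein", data.frame(
      ref_id = leaves, genome_id = leaves, taxon_id = leaves,
      sequence = vapply(leaves, function(lf) rprot_seqs[[f]][[lf]],
                        character(1)),
      stringsAsFactors = FALSE))
  }), rfams)
  sim$ssu_family <- marker_family("SSU", "nucleotide", data.frame(
    ref_id = leaves, genome_id = leaves, taxon_id = leaves,
    sequence = vapply(leaves, function(lf) ssu_seqs[[lf]], character(1)),
    stringsAsFactors = FALSE))
  # ribosomal proteins are part of the proteome, as in real genomes
  sim$proteome <- rbind(sim$proteome, do.call(rbind, lapply(rfams, function(f) {
    data.frame(protein_id = paste(leaves, f, sep = "|"), genome_id = leaves,
               taxon_id = leaves,
               sequence = vapply(leaves, function(lf) rprot_seqs[[f]][[lf]],
                                 character(1)),
               stringsAsFactors = FALSE)
  })))
  rownames(sim$proteome) <- NULL
  sim$registry <- registry
  sim
}

# markov params are re-derived deterministically from the config seed so
# implant_markers can reuse the per-genome GC for codon bias
markov_params_cache <- function(sim) {
  set.seed(sim$config$seed)
  markov_params(sim$tree, sim$config)
}

#' Generate the full synthetic reference dataset
#'
#' Taxonomy, genomes, proteomes, marker panels and registry in one call.
#'
#' @param config a [sim_config()].
#' @return A `sim_genomes` list with markers implanted.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_taxonomy(config)
  implant_markers(simulate_genomes(tree, config))
}

#' Build a chimeric query assembly with exact ground truth
#'
#' The host genome is fragmented into lognormal-length scaffolds (min
#' 1 kb). Contaminant bases totalling `f / (1 - f)` times the host
#' length are drawn from the contaminant genome(s) as contiguous blocks
#' and either appended as separate scaffolds or, at the chimeric
#' scaffold rate, concatenated onto host scaffolds. When
#' `cover_markers` is `TRUE` (default) the blocks are chosen to include
#' the contaminant's implanted marker loci — emulating a co-sequenced
#' organism whose marker genes made it into the assembly, the situation
#' in which marker-based estimators are informative.
#'
#' @param sim a [simulate_dataset()] result.
#' @param host_id leaf genome id of the host.
#' @param contaminant_ids character vector (possibly empty) of
#'   contaminant genome ids.
#' @param config a [sim_config()] (defaults to the simulation's own).
#' @param seed RNG seed for fragmentation.
#' @param cover_markers draw contaminant blocks over marker loci first.
#' @return List of class `chimera`: `assembly`, `truth` (data.frame
#'   `scaffold_id`, `start`, `end`, `source_genome`, `taxon_id`),
#'   `true_fraction` (percent of contaminant bases, exact),
#'   `marker_truth` (registry rows present in the assembly, remapped to
#'   assembly coordinates), `host_id`, `contaminant_ids`.
#' @export
build_chimera <- function(sim, host_id, contaminant_ids = character(0),
                          config = sim$config, seed = config$seed,
                          cover_markers = TRUE) {
  stopifnot(host_id %in% names(sim$genomes),
            all(contaminant_ids %in% names(sim$genomes)),
            !host_id %in% contaminant_ids)
  set.seed(seed)
  host <- sim$genomes[[host_id]][[1]]
  hlen <- nchar(host)
  f <- config$contaminant_fraction
  asm_id <- paste0(host_id, "_q")

  # fragment the host; breakpoints are moved off marker loci so the
  # marker ground truth stays well-defined (a split marker belongs to
  # no scaffold)
  host_reg <- sim$registry[sim$registry$genome_id == host_id, ]
  cuts <- integer(0)
  pos <- 0L
  while (pos < hlen) {
    w <- max(1000L, round(stats::rlnorm(1, config$scaffold_meanlog,
                                        config$scaffold_sdlog)))
    pos <- min(hlen, pos + w)
    inside <- host_reg$start < pos & pos < host_reg$end
    if (any(inside)) pos <- max(host_reg$end[inside])
    pos <- min(pos, hlen)
    cuts <- c(cuts, pos)
  }
  cuts <- unique(cuts)
  if (hlen - utils::tail(c(0L, utils::head(cuts, -1)), 1) < 1000L &&
      length(cuts) > 1) {
    cuts <- cuts[-(length(cuts) - 1)] # avoid a tiny trailing scaffold
  }
  starts <- c(0L, utils::head(cuts, -1))
  scaffolds <- substring(host, starts + 1L, cuts)
  names(scaffolds) <- sprintf("%s_s%03d", asm_id, seq_along(scaffolds))
  truth <- data.frame(
    scaffold_id = names(scaffolds), start = 0L, end = nchar(scaffolds),
    source_genome = host_id, taxon_id = host_id,
    src_start = starts, stringsAsFactors = FALSE)

  # contaminant blocks
  total_cont <- if (length(contaminant_ids)) round(f / (1 - f) * hlen) else 0L
  blocks <- list()
  if (total_cont > 0) {
    share <- diff(round(seq(0, total_cont, length.out = length(contaminant_ids) + 1)))
    for (ci in seq_along(contaminant_ids)) {
      cid <- contaminant_ids[ci]
      cg <- sim$genomes[[cid]][[1]]
      clen <- nchar(cg)
      if (share[ci] > clen) stop("contaminant fraction too large for ", cid)
      intervals <- matrix(numeric(0), ncol = 2) # chosen [start0, end0)
      if (cover_markers) {
        reg <- sim$registry[sim$registry$genome_id == cid, ]
        reg <- reg[order(reg$start), ]
        if (nrow(reg)) {
          # group marker loci into blocks with 500 nt flanks
          st <- pmax(0L, reg$start - 500L); en <- pmin(clen, reg$end + 500L)
          grp <- cumsum(c(TRUE, st[-1] > cummax(en[-length(en)])))
          intervals <- cbind(tapply(st, grp, min), tapply(en, grp, max))
        }
      }
      used <- sum(intervals[, 2] - intervals[, 1])
      if (used > share[ci]) {
        warning("marker blocks of ", cid, " exceed the contaminant share; ",
                "realized fraction will be higher than requested")
      }
      # fill up with random non-overlapping blocks
      tries <- 0L
      while (used < share[ci] && tries < 500L) {
        tries <- tries + 1L
        w <- min(share[ci] - used,
                 max(1000L, round(stats::rlnorm(1, config$scaffold_meanlog - 0.7,
                                                config$scaffold_sdlog))))
        if (w < 200L) w <- share[ci] - used
        st <- sample.int(clen - w, 1) - 1L
        if (any(st < intervals[, 2] & (st + w) > intervals[, 1])) next
        intervals <- rbind(intervals, c(st, st + w))
        used <- used + w
      }
      for (bi in seq_len(nrow(intervals))) {
        blocks[[length(blocks) + 1]] <- list(
          genome = cid, start = intervals[bi, 1], end = intervals[bi, 2],
          seq = substring(cg, intervals[bi, 1] + 1, intervals[bi, 2]))
      }
    }
  }

  # place blocks: own scaffold, or concatenated onto a host scaffold
  if (length(blocks)) {
    chim <- stats::runif(length(blocks)) < config$chimeric_scaffold_rate
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      w <- b$end - b$start
      if (chim[bi]) {
        tgt <- sample(seq_along(scaffolds), 1)
        sid <- names(scaffolds)[tgt]
        off <- nchar(scaffolds[[tgt]])
        scaffolds[[tgt]] <- paste0(scaffolds[[tgt]], b$seq)
        truth <- rbind(truth, data.frame(
          scaffold_id = sid, start = off, end = off + w,
          source_genome = b$genome, taxon_id = b$genome,
          src_start = b$start, stringsAsFactors = FALSE))
      } else {
        sid <- sprintf("%s_c%03d", asm_id, bi)
        scaffolds[[sid]] <- b$seq
        truth <- rbind(truth, data.frame(
          scaffold_id = sid, start = 0L, end = w,
          source_genome = b$genome, taxon_id = b$genome,
          src_start = b$start, stringsAsFactors = FALSE))
      }
    }
  }

  cont_bases <- sum((truth$end - truth$start)[truth$source_genome != host_id])
  tot_bases <- sum(truth$end - truth$start)

  # remap registry loci fully contained in an assembled interval
  mt <- list()
  for (i in seq_len(nrow(truth))) {
    src <- truth$source_genome[i]
    reg <- sim$registry[sim$registry$genome_id == src, ]
    s0 <- truth$src_start[i]
    s1 <- s0 + (truth$end[i] - truth$start[i])
    inside <- reg$start >= s0 & reg$end <= s1
    if (any(inside)) {
      r <- reg[inside, ]
      r$scaffold_id <- truth$scaffold_id[i]
      r$start <- r$start - s0 + truth$start[i]
      r$end <- r$end - s0 + truth$start[i]
      mt[[length(mt) + 1]] <- r
    }
  }
  marker_truth <- if (length(mt))
    do.call(rbind, c(mt, list(make.row.names = FALSE))) else NULL

  structure(list(
    assembly = assembly(asm_id, scaffolds),
    truth = truth[, c("scaffold_id", "start", "end", "source_genome",
                      "taxon_id")],
    true_fraction = 100 * cont_bases / tot_bases,
    marker_truth = marker_truth,
    host_id = host_id, contaminant_ids = contaminant_ids
  ), class = "chimera")
}

#' Simulate sequencing reads and the true depth track
#'
#' Uniform fragment sampling per source organism at its configured
#' depth (host vs contaminant), substitution errors at the configured
#' rate, and an exact depth track accumulated from the sampled
#' intervals.
#'
#' @param chim a [build_chimera()] result.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param return_sequences materialize read sequences (default TRUE);
#'   with `FALSE` only coordinates and the track are produced.
#' @return List: `reads` (data.frame `read_id`, `scaffold_id`, `start`,
#'   `end`, `source_genome`, and `sequence` if requested), `track` (a
#'   `coverage_track`).
#' @export
simulate_reads <- function(chim, config, seed = config$seed,
                           return_sequences = TRUE) {
  set.seed(seed)
  rl <- config$read_length
  truth <- chim$truth
  seqs <- chim$assembly$seqs
  depth_of <- ifelse(truth$source_genome == chim$host_id,
                     config$host_depth, config$contaminant_depth)
  reads <- list()
  acc <- lapply(nchar(seqs), function(n) numeric(n + 1L))
  for (i in seq_len(nrow(truth))) {
    w <- truth$end[i] - truth$start[i]
    if (w < rl) next
    n_reads <- round(depth_of[i] * w / rl)
    if (n_reads == 0) next
    st <- truth$start[i] + sample.int(w - rl + 1L, n_reads, replace = TRUE) - 1L
    sid <- truth$scaffold_id[i]
    reads[[length(reads) + 1]] <- data.frame(
      scaffold_id = sid, start = st, end = st + rl,
      source_genome = truth$source_genome[i], stringsAsFactors = FALSE)
    # exact interval accumulation: +1 at start, -1 at end
    a <- acc[[sid]]
    tab <- tabulate(st + 1L, nbins = length(a))
    tab2 <- tabulate(st + rl + 1L, nbins = length(a))
    acc[[sid]] <- a + tab - tab2
  }
  track <- depth_to_track(lapply(acc, function(a)
    utils::head(cumsum(a), -1L)))
  if (!length(reads)) {
    return(list(reads = NULL, track = track))
  }
  rd <- do.call(rbind, c(reads, list(make.row.names = FALSE)))
  rd <- rd[sample.int(nrow(rd)), , drop = FALSE] # shuffle, as a sequencer would
  rd$read_id <- sprintf("r%07d", seq_len(nrow(rd)))
  if (return_sequences) {
    rd$sequence <- substring(seqs[rd$scaffold_id], rd$start + 1L, rd$end)
    if (config$read_error_rate > 0) {
      rd$sequence <- add_substitution_errors(rd$sequence,
                                             config$read_error_rate)
    }
  }
  rownames(rd) <- NULL
  list(reads = rd, track = track)
}

add_substitution_errors <- function(sequences, rate) {
  vapply(sequences, function(s) {
    x <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(x)) < rate & x %in% BASES)
    if (length(hit)) {
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1),
                       character(1))
    }
    paste(x, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write reads as FASTQ
#' @param reads data.frame from [simulate_reads()] with sequences.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con)
  invisible(path)
}

#' Derive a reference database, optionally excluding genomes
#'
#' Returns the reference collections (genomes, proteome, marker panels)
#' without the named genomes — e.g. the query's own genome, or its
#' whole genus to emulate an evolutionarily isolated query.
#'
#' @param sim a [simulate_dataset()] result.
#' @param exclude character vector of genome ids to drop.
#' @return List: `genomes`, `taxa`, `proteome`, `rprot_families`,
#'   `ssu_family`, `excluded`.
#' @export
make_reference_db <- function(sim, exclude = character(0)) {
  keep <- setdiff(names(sim$genomes), exclude)
  if (!length(keep)) stop("make_reference_db(): every genome excluded")
  list(
    genomes = sim$genomes[keep],
    taxa = sim$taxa[keep],
    proteome = sim$proteome[sim$proteome$genome_id %in% keep, ],
    rprot_families = lapply(sim$rprot_families, function(fam) {
      fam$references <- fam$references[fam$references$genome_id %in% keep, ]
      fam
    }),
    ssu_family = local({
      fam <- sim$ssu_family
      fam$references <- fam$references[fam$references$genome_id %in% keep, ]
      fam
    }),
    excluded = exclude
  )
}

#' Build a paired set of contaminated and clean query assemblies
#'
#' For benchmarking the estimators: `n` chimeric queries whose hosts
#' cycle through the focal-clade genomes and whose contaminants cycle
#' through genomes at least `min_gc_gap` GC points away (so composition
#' methods have signal), each paired with a clean fragmentation of the
#' same host under a different fragmentation seed.
#'
#' @param sim a [simulate_dataset()] result.
#' @param n number of chimera/clean pairs.
#' @param contaminant_fraction true contaminant fraction of the chimeras.
#' @param min_gc_gap minimum host-contaminant GC distance (points).
#' @param seed base seed; chimera i uses `seed*1000 + i`.
#' @param cover_markers passed to [build_chimera()].
#' @return List: `chimeras`, `cleans` (lists of [build_chimera()]
#'   results, named by assembly id).
#' @export
build_query_set <- function(sim, n = 10, contaminant_fraction = 0.10,
                            min_gc_gap = 15, seed = 1, cover_markers = TRUE) {
  tree <- sim$tree
  leaves <- names(sim$genomes)
  gc <- vapply(sim$genomes, gc_content, numeric(1))
  hosts <- leaves[label_of(tree, leaves) == "FOCAL"]
  chimeras <- list()
  cleans <- list()
  cfg <- sim$config
  cfg$contaminant_fraction <- contaminant_fraction
  cfg0 <- sim$config
  cfg0$contaminant_fraction <- 0
  for (i in seq_len(n)) {
    host <- hosts[(i - 1L) %% length(hosts) + 1L]
    cands <- leaves[label_of(tree, leaves) == "CONTAMINANT" &
                      abs(gc - gc[[host]]) >= min_gc_gap]
    if (!length(cands)) stop("no contaminant ", min_gc_gap,
                             " GC points away from ", host)
    cont <- cands[(i - 1L) %% length(cands) + 1L]
    ch <- build_chimera(sim, host, cont, config = cfg,
                        seed = seed * 1000L + i, cover_markers = cover_markers)
    ch$assembly$assembly_id <- sprintf("%s_chim%02d", host, i)
    names(ch$assembly$seqs) <- sub(paste0("^", host, "_q"),
                                   ch$assembly$assembly_id,
                                   names(ch$assembly$seqs))
    ch$truth$scaffold_id <- sub(paste0("^", host, "_q"),
                                ch$assembly$assembly_id,
                                ch$truth$scaffold_id)
    if (!is.null(ch$marker_truth)) {
      ch$marker_truth$scaffold_id <- sub(paste0("^", host, "_q"),
                                         ch$assembly$assembly_id,
                                         ch$marker_truth$scaffold_id)
    }
    cl <- build_chimera(sim, host, character(0), config = cfg0,
                        seed = seed * 1000L + 500L + i)
    cl$assembly$assembly_id <- sprintf("%s_clean%02d", host, i)
    names(cl$assembly$seqs) <- sub(paste0("^", host, "_q"),
                                   cl$assembly$assembly_id,
                                   names(cl$assembly$seqs))
    cl$truth$scaffold_id <- sub(paste0("^", host, "_q"),
                                cl$assembly$assembly_id,
                                cl$truth$scaffold_id)
    if (!is.null(cl$marker_truth)) {
      cl$marker_truth$scaffold_id <- sub(paste0("^", host, "_q"),
                                         cl$assembly$assembly_id,
                                         cl$marker_truth$scaffold_id)
    }
    chimeras[[ch$assembly$assembly_id]] <- ch
    cleans[[cl$assembly$assembly_id]] <- cl
  }
  list(chimeras = chimeras, cleans = cleans)
}
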