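#!/usr/bin/env Rscript
# Step 1: generate the synthetic study world -- a taxonomy over five
# phyla spanning GC 35-65%, ten 300-kb reference genomes with proteomes
# and implanted ribosomal marker panels, and a paired query set of four
# chimeric assemblies (10% foreign DNA from a distant phylum) and four
# clean fragmentations of the same hosts.
#
# Writes: results/data/ (taxonomy TSV, reference + query FASTA, marker
# panels, ground-truth manifests) and results/state_sim.rds (session
# state reused by the later steps).

library(contamcheck)

seed <- 7L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating reference dataset (seed ", seed, ")")
sim <- simulate_dataset(sim_config(seed = seed))
write_taxonomy(sim$tree, file.path(out, "taxonomy.tsv"))
dir.create(file.path(out, "references"), showWarnings = FALSE)
for (g in names(sim$genomes)) {
  write_fasta(sim$genomes[[g]], file.path(out, "references", paste0(g, ".fna")))
}
write_fasta(stats::setNames(sim$proteome$sequence, sim$proteome$protein_id),
            file.path(out, "references", "proteome.faa"))
write_marker_panel(c(sim$rprot_families, list(SSU = sim$ssu_family)),
                   file.path(out, "markers"))
utils::write.table(sim$registry, file.path(out, "marker_registry.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("building 4 chimeric + 4 clean query assemblies")
qs <- build_query_set(sim, n = 4, seed = seed)
dir.create(file.path(out, "queries"), showWarnings = FALSE)
truth <- list()
for (q in c(qs$chimeras, qs$cleans)) {
  id <- q$assembly$assembly_id
  write_fasta(q$assembly, file.path(out, "queries", paste0(id, ".fna")))
  tr <- q$truth
  tr$assembly_id <- id
  truth[[id]] <- tr
}
utils::write.table(do.call(rbind, truth), file.path(out, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

gc_tab <- data.frame(genome = names(sim$genomes),
                     gc = round(vapply(sim$genomes, gc_content, numeric(1)), 2))
utils::write.table(gc_tab, file.path(out, "reference_gc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

saveRDS(list(sim = sim, qs = qs, seed = seed), "results/state_sim.rds")
message("found: ", length(sim$genomes), " genomes, GC ",
        paste(range(gc_tab$gc), collapse = "-"),
        "; true contaminant fractions ",
        paste(round(vapply(qs$chimeras, `[[`, numeric(1), "true_fraction"), 2),
              collapse = ", "))
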