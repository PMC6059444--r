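#!/usr/bin/env Rscript
# Step 3: the three genome-wide estimators -- signature-kmer pseudo-read
# classification (confidence 0.04), MEGAN-like protein LCA with
# self-match exclusion (bit >= 80, 95% window), and tetranucleotide
# binning with the largest-group statistic. The kmer index excludes the
# query hosts (a database containing the query is uninformative about
# it -- the same reason those assemblies would get NA in a ranking).
#
# Reads results/state_sim.rds; writes results/genomewide_estimates.tsv,
# results/read_classifications.tsv.gz-like TSV and results/state_scores.rds.

library(contamcheck)

st <- readRDS("results/state_sim.rds")
sim <- st$sim
hosts <- unique(vapply(st$qs$chimeras, `[[`, character(1), "host_id"))
message("preparing reference (kmer index excludes ",
        paste(hosts, collapse = ", "), ")")
ref <- prepare_reference(sim, exclude_from_kmer = hosts)

queries <- c(st$qs$chimeras, st$qs$cleans)
results <- score_queries(queries, ref)

tab <- do.call(rbind, lapply(names(results), function(id) {
  r <- results[[id]]
  data.frame(assembly_id = id, n_reads = nrow(r$reads),
             kmer = r$kmer_score_unmasked,
             kmer_unclassified = r$kmer_profile$unclassified,
             protein = r$scores[["protein"]],
             protein_unclassified = r$protein_profile$unclassified,
             protein_unknown = r$protein_profile$unknown,
             binning = r$scores[["binning"]])
}))
utils::write.table(tab, "results/genomewide_estimates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cls <- do.call(rbind, lapply(names(results), function(id) {
  r <- results[[id]]
  data.frame(assembly_id = id, read_id = r$protein_labels$read_id,
             kmer_taxon = r$kmer_labels$taxon_id,
             kmer_label = r$kmer_labels$label,
             protein_taxon = r$protein_labels$taxon_id,
             protein_label = r$protein_labels$label)
}))
utils::write.table(cls, "results/read_classifications.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

saveRDS(results, "results/state_scores.rds")
chim <- grepl("chim", tab$assembly_id)
message("found: genome-wide estimates on chimeras (true 10%): kmer ",
        round(mean(tab$kmer[chim]), 2), "%, protein ",
        round(mean(tab$protein[chim]), 2), "%, binning ",
        round(mean(tab$binning[chim]), 2), "%")
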