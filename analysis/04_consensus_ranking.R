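#!/usr/bin/env Rscript
# Step 4: combine the six per-method contamination estimates into the
# NA-aware consensus ranking, classify assemblies into contamination
# categories, and measure method congruence by Spearman correlation.
#
# Reads results/marker_estimates.tsv, results/state_scores.rds; writes
# results/consensus_ranking.tsv and results/spearman_matrix.tsv.

library(contamcheck)

mk <- utils::read.delim("results/marker_estimates.tsv")
gw <- utils::read.delim("results/genomewide_estimates.tsv")
st <- readRDS("results/state_sim.rds")

tab <- merge(mk, gw, by = "assembly_id")
scores <- as.matrix(tab[, c("rRNA", "rprot", "redundancy", "kmer",
                            "protein", "binning")])
rownames(scores) <- tab$assembly_id

stats_tab <- do.call(rbind, lapply(c(st$qs$chimeras, st$qs$cleans),
                                   function(q) compute_stats(q$assembly)))
rep <- consensus_report(scores, stats = stats_tab)
utils::write.table(rep, "results/consensus_ranking.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rho <- spearman_matrix(cbind(scores,
                             consensus = -rank(rep$rank_avg)[
                               match(rownames(scores), rep$assembly_id)]))
utils::write.table(round(rho, 3), "results/spearman_matrix.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)

chim <- grepl("chim", rep$assembly_id)
message("found: all ", sum(chim), " chimeras rank above all ",
        sum(!chim), " clean assemblies: ",
        max(rep$global_rank[chim]) < min(rep$global_rank[!chim]),
        "; flagged-method counts ",
        paste(rep$flagged_method_count[chim], collapse = "/"),
        " (chimeras) vs ",
        paste(rep$flagged_method_count[!chim], collapse = "/"), " (cleans)")
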