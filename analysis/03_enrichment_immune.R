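#!/usr/bin/env Rscript
# T-cell-inflamed enrichment and immune associations: per-sample enrichment
# scores, the enrichment-by-RSI contingency table, macrophage polarisation,
# and the Spearman association matrix.

suppressPackageStartupMessages(library(radsens))

m <- read_expression("results/cohort/expression.tsv")
fractions <- utils::read.delim("results/cohort/fractions.tsv",
                               check.names = FALSE)
subtypes <- utils::read.delim("results/cohort/subtypes.tsv")
scores <- utils::read.delim("results/rsi_scores.tsv")

enr <- tcia_enrichment(m)
utils::write.table(enr, "results/tcia_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%.1f%% of samples enriched at z > %.2f\n",
            100 * mean(enr$enriched), enr$threshold[1]))

ct <- table(enrichment = ifelse(enr$enriched, "E", "NE"),
            rsi = scores$category)
print(ct)
utils::write.table(as.data.frame(ct), "results/enrichment_by_rsi.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

pol <- m1_m2_log_ratio(fractions)
cat(sprintf("M1/M2 ratio computed for %d samples (%d excluded for zeros)\n",
            nrow(pol$ratios), pol$n_excluded))

assoc <- data.frame(sample_id = scores$sample_id, rsi = scores$rsi,
                    tcia_z = enr$z)
assoc <- merge(assoc, pol$ratios, by = "sample_id", sort = FALSE)
sp <- spearman_matrix(assoc["rsi"], assoc[c("tcia_z", "log2_m1_m2")])
for (cn in colnames(sp$rho))
  cat(sprintf("Spearman rho(RSI, %s) = %.3f (p = %.3g)\n",
              cn, sp$rho["rsi", cn], sp$p["rsi", cn]))

is_c2 <- factor(ifelse(subtypes$subtype == "C2", "C2", "non-C2"))
mw <- group_compare(scores$rsi, is_c2)
cat(sprintf("RSI in C2 vs non-C2: U = %g, p = %.3g\n", mw$U, mw$p))
av <- anova_across_groups(scores$rsi, subtypes$subtype)
cat(sprintf("RSI across C1-C6: F(%d,%d) = %.2f, p = %.3g\n",
            av$df[1], av$df[2], av$F, av$p))
cat("wrote results/tcia_enrichment.tsv, results/enrichment_by_rsi.tsv\n")
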