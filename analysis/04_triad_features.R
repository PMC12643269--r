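#!/usr/bin/env Rscript
# Study 2, step 3: information vs topology vs compressibility.
#
# For every significant triad from the screen: information measures of the
# raw and PCA-rotated point clouds, dimension-2 persistence summaries (void
# count, average and maximum persistence) of a shared 120-frame subsample,
# and the PC1 variance share. Features are then rank-correlated within each
# significance class, and the compressibility distributions of the two
# classes are compared with a two-sample KS test.

library(topoinfo)

dir.create("results", showWarnings = FALSE)
if (!file.exists("results/bold.csv")) stop("run analysis/02_simulate_bold.R first")
sim <- read_bold_csv("results/bold.csv", scan_length = 1100)
scr <- read.table("results/triad_screen.tsv", header = TRUE, sep = "\t")
sig <- scr[scr$label != "neither", ]
cat(sprintf("Computing features for %d significant triads (%d redundant, %d synergistic)\n",
            nrow(sig), sum(sig$label == "redundant"),
            sum(sig$label == "synergistic")))

t0 <- Sys.time()
feats <- compute_triad_features(sim, as.matrix(sig[, c("i", "j", "k")]),
                                k = 4, subsample = 120, seed = 7,
                                labels = sig$label)
cat(sprintf("done in %.1f min\n", as.numeric(Sys.time() - t0, units = "mins")))
write.table(format(feats, digits = 6), "results/triad_features.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

pairs <- list(c("o_norm", "n_voids"), c("o_norm", "avg_persistence"),
              c("o_norm", "pc1_variance"), c("tc", "avg_persistence"),
              c("tc", "n_voids"), c("dtc", "avg_persistence"),
              c("dtc", "n_voids"), c("pc1_variance", "avg_persistence"))
rep_tab <- correlate_features(feats, pairs)
print(rep_tab, digits = 3)
write.table(format(rep_tab, digits = 4), "results/correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# headline relationships pooled across all classified triads (triads with an
# undefined normalized O are dropped)
rho_voids <- cor(feats$o_norm, feats$n_voids, method = "spearman",
                 use = "complete.obs")
rho_pc1 <- cor(feats$o_norm, feats$pc1_variance, method = "spearman",
               use = "complete.obs")
cat(sprintf("\nPooled Spearman(o_norm, n_voids) = %.3f (expected < 0)\n",
            rho_voids))
cat(sprintf("Pooled Spearman(o_norm, pc1_variance) = %.3f (expected > 0)\n",
            rho_pc1))

ks <- ks_compare(feats$pc1_variance[feats$label == "redundant"],
                 feats$pc1_variance[feats$label == "synergistic"])
cat(sprintf("KS(pc1 share | redundant vs synergistic) = %.3f, p = %.2g\n",
            ks$statistic, ks$p))
cat("Wrote results/triad_features.tsv and results/correlations.tsv\n")
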