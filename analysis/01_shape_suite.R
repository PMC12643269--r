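#!/usr/bin/env Rscript
# Study 1: higher-order information of point clouds with known topology.
#
# Eight benchmark clouds (line, embedded plane, sphere, ball, hollow and
# filled torus, trefoil and 5,3-knot; 10,000 points each) are scored with the
# nearest-neighbor O-information estimator (k = 4, Chebyshev) before and
# after PCA rotation. The table distinguishes contextual structure (line,
# plane: collapses to ~0 after PCA) from intrinsic structure (sphere and
# hollow torus stay synergy-dominated; knots stay redundancy-dominated).

library(topoinfo)

seed <- 1
dir.create("results", showWarnings = FALSE)

cat("Running shape suite (n = 10,000 per shape, k = 4, Chebyshev)...\n")
t0 <- Sys.time()
suite <- run_shape_suite(n = 10000, k = 4, seed = seed)
cat(sprintf("done in %.1f s\n\n", as.numeric(Sys.time() - t0, units = "secs")))

print(suite, digits = 4)

write.table(format(suite, digits = 6), "results/shape_suite.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nWrote results/shape_suite.tsv\n")

cat("\nReadings:\n")
cat(sprintf(" - line: O = %.3f nat raw, %.3f after PCA (contextual redundancy)\n",
            suite$o_raw[1], suite$o_pca[1]))
cat(sprintf(" - sphere: O = %.3f nat raw vs %.3f after PCA (intrinsic synergy)\n",
            suite$o_raw[3], suite$o_pca[3]))
cat(sprintf(" - hollow torus %.3f vs filled torus %.3f: the cavity drives synergy\n",
            suite$o_raw[5], suite$o_raw[6]))
cat(sprintf(" - trefoil: O = %.3f nat, still %.3f after PCA (intrinsic redundancy)\n",
            suite$o_raw[7], suite$o_pca[7]))
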