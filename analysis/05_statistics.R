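#!/usr/bin/env Rscript
# Step 5: psycholinguistic characterisation of the LVC.
#
# Compares words inside the LVC with words outside it on every attribute
# (medians; means for the heavy-tailed frequency and polysemy, frequency on
# a log10 scale), with Monte Carlo sample-size correction and optionally
# multidegree matching of the out-group. Also reports the Kendall rank
# correlations of each attribute with age of acquisition, cumulative
# attribute curves, and the core-periphery link densities of the LVC
# partition.

suppressPackageStartupMessages(library(lexiviable))

data_dir <- "results/data"
layers <- c("free_association", "synonymy", "taxonomic", "phonological")
M <- read_multiplex(stats::setNames(
  file.path(data_dir, paste0("layer_", layers, ".tsv")), layers))
at <- read_attributes(file.path(data_dir, "attributes.tsv"))
mem <- utils::read.table("results/lvc_membership.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
lvc_in <- mem$word[mem$in_lvc == 1]
lvc_out <- mem$word[mem$in_lvc == 0]

cmp <- compare_groups(at, lvc_in, lvc_out, repetitions = 500, seed = 5)
message("LVC-in vs LVC-out (sample-size corrected):")
print(cmp, row.names = FALSE)
utils::write.table(format(cmp, digits = 4), "results/lvc_group_comparison.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cmp_dc <- compare_groups(at, lvc_in, lvc_out, repetitions = 500, seed = 6,
                         degree_corrected = TRUE, M = M)
utils::write.table(format(cmp_dc, digits = 4),
                   "results/lvc_group_comparison_degree_corrected.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## paired direction of the differences across attributes (sign test)
diffs <- cmp$in_value - cmp$out_value
st <- sign_test(diffs)
message(sprintf("sign test over attribute differences: p = %.4f (%d of %d positive)",
                st$p_value, st$n_positive, st$n_nonzero))

deg <- multidegree(M)
taus <- data.frame(
  attribute = c("frequency", "multidegree", "polysemy", "length",
                "concreteness", "reaction_time"),
  tau_vs_aoa = round(c(
    kendall_tau(at$frequency, at$aoa_mean),
    kendall_tau(unname(deg[at$word]), at$aoa_mean),
    kendall_tau(at$polysemy, at$aoa_mean),
    kendall_tau(at$length, at$aoa_mean),
    kendall_tau(at$concreteness, at$aoa_mean),
    kendall_tau(at$reaction_time, at$aoa_mean)), 3))
print(taus, row.names = FALSE)
utils::write.table(taus, "results/kendall_tau.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## cumulative curves for LVC-in vs LVC-out (concreteness on a 0-1 scale)
thresholds <- seq(0, 1, by = 0.05)
cc <- rbind(
  cbind(group = "lvc_in",
        cumulative_curve(at, "concreteness", lvc_in, thresholds)),
  cbind(group = "lvc_out",
        cumulative_curve(at, "concreteness", lvc_out, thresholds)))
utils::write.table(cc, "results/cumulative_concreteness.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cp <- core_periphery_densities(M, lvc_in)
message("core-periphery link densities (normalised by the global maximum):")
print(round(cp$normalised, 4))
utils::write.table(cbind(layer = rownames(cp$normalised),
                         as.data.frame(cp$normalised)),
                   "results/core_periphery_densities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote group comparison, tau, cumulative and density tables under results/")
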