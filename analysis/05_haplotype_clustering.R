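#!/usr/bin/env Rscript

# Stage 5: haplotype clustering. Simulates a modern + ancient-sample pair
# of populations over several independent loci, runs haplotype PCA,
# chooses k by the WSS elbow rule, and tests whether the ancient
# haplotypes are confined to a single modern cluster.

suppressPackageStartupMessages(library(sdpopgen))
dir.create("results", showWarnings = FALSE)

model <- two_group_model(n_modern = 30, n_archaic = 8,
                         ne_modern = 10000, ne_archaic = 2000,
                         t_split = 60000, t_archaic = 2000,
                         mutation_rate = 1e-8)

reps <- lapply(1:8, function(i) simulate_coalescent(model, 5000,
                                                    seed = 500 + i))
ent <- do.call(cbind, lapply(reps, function(r) r$haplotypes$entries))
x <- hap_matrix(ent, positions = seq_len(ncol(ent)),
                populations = reps[[1]]$haplotypes$populations)
x <- maf_filter(x, 0.05)
cat(sprintf("%d haplotypes x %d sites after MAF filter\n",
            n_haplotypes(x), n_sites(x)))

p <- haplotype_pca(x)
print(p)
cm <- choose_k(p$scores[, seq_len(p$n_informative), drop = FALSE],
               k_max = 8, seed = 51)
print(cm)

assign_tab <- data.frame(haplotype = seq_len(n_haplotypes(x)),
                         population = x$populations,
                         cluster = cm$assignment)
write.table(assign_tab, "results/cluster_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

het <- haplotype_heterozygosity(cm$assignment)
cat(sprintf("haplotype heterozygosity: %.3f\n", het))

modern <- cm$assignment[x$populations == "modern"]
archaic <- cm$assignment[x$populations == "archaic"]
if (length(unique(archaic)) == 1) {
  hom <- homogeneity_permutation(modern, m = length(archaic),
                                 n_perm = 9999, seed = 52)
  cat(sprintf("archaic haplotypes all in cluster %s; homogeneity p = %.3g\n",
              unique(archaic), hom$p))
} else {
  cat(sprintf("archaic haplotypes span %d clusters\n",
              length(unique(archaic))))
}
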