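#!/usr/bin/env Rscript
# Stage 5: community structure. Manhattan-distance hierarchical
# clustering of the unmixed compositions with a principal-component check
# of the clustering tendency, plus the pigment-based mean size index.

library(sestonmix)

comp <- read_table("results/composition_percent.tsv")
m <- as.matrix(comp[, -1])
rownames(m) <- comp$sample_id

k <- 4
res <- hca_cut(manhattan_distance_matrix(m), k = k, linkage = "average")
pv <- pca_validation(m, res$labels)

write_table(data.frame(sample_id = comp$sample_id, cluster = res$labels),
            "results/cluster_labels.tsv")
write_table(data.frame(sample_id = comp$sample_id,
                       pv$scores[, 1:2, drop = FALSE]),
            "results/pca_scores.tsv")

cat(sprintf("Cut at k = %d: cluster sizes %s\n", k,
            paste(table(res$labels), collapse = ", ")))
cat(sprintf("PC1+PC2 explain %.1f%% of the variance\n",
            100 * sum(pv$variance_fraction[1:2])))
cat("Centroid separation / within-cluster spread per cluster pair:\n")
print(pv$separation, digits = 3)

pig <- read_pigment_table("results/synthetic/pigments.tsv")
msi <- mean_size_index(pig$pigments)
write_table(cbind(sample_id = rownames(pig$pigments), msi),
            "results/size_index.tsv")
cat(sprintf("\nMean size index across samples: %.2f (1 = pico ... 3 = micro)\n",
            mean(msi$size_index, na.rm = TRUE)))
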