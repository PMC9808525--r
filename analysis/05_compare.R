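#!/usr/bin/env Rscript
# Stage 5: sample-level multivariate comparisons.
# Hierarchical clustering of top-clone log abundances (heat-map row order +
# newick dendrogram), PCA of CPM profiles, pairwise Pearson correlations.

source("analysis/00_config.R")

sheet <- load_sample_sheet(file.path(RESULTS_DIR, "sample_sheet.tsv"))
frac <- read_abundance(file.path(RESULTS_DIR, "fraction.tsv"))
cpm <- read_abundance(file.path(RESULTS_DIR, "cpm.tsv"))
logf <- read_abundance(file.path(RESULTS_DIR, "log_fraction.tsv"))

tc <- top_clones(frac, n = 10)
cl <- cluster_rows(unclass(logf)[tc$union, , drop = FALSE])
write_dendrogram_newick(cl, file.path(RESULTS_DIR, "dendrogram.newick"))
ordered <- unclass(logf)[cl$order, , drop = FALSE]
write.table(data.frame(barcode = rownames(ordered), ordered,
                       check.names = FALSE),
            file.path(RESULTS_DIR, "heatmap_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pca <- pca_project(cpm, n_components = 2)
write.table(data.frame(sample_id = rownames(pca$coords), pca$coords,
                       check.names = FALSE),
            file.path(RESULTS_DIR, "pca_coords.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("PCA variance explained: PC1 %.1f%%, PC2 %.1f%%",
                100 * pca$var_explained[1], 100 * pca$var_explained[2]))

r <- pearson_pairwise(frac)
write.table(data.frame(sample_id = rownames(r), r, check.names = FALSE),
            file.path(RESULTS_DIR, "correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
grp <- paste(sheet$tissue, sheet$population)[match(colnames(r),
                                                   sheet$sample_id)]
same <- outer(grp, grp, `==`) & upper.tri(r)
diff_g <- outer(grp, grp, `!=`) & upper.tri(r)
message(sprintf("mean Pearson r within location %.3f vs between %.3f",
                mean(r[same], na.rm = TRUE), mean(r[diff_g], na.rm = TRUE)))
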