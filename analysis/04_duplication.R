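#!/usr/bin/env Rscript
# Gene-duplication view of the pipeline output: tandem clusters and
# paralog pairs, including silent (synonymous-only) duplicates, plus the
# published malpisin cluster layout recomputed from the catalog.

library(fdlpminer)

cl <- utils::read.delim("results/pipeline/clusters.tsv")
pairs <- utils::read.delim("results/pipeline/pairs.tsv")
cat(sprintf("%d tandem cluster(s) among recovered genes\n",
            length(unique(cl$cluster))))
silent <- pairs[!is.na(pairs$n_synonymous) & pairs$identity == 1, ]
if (nrow(silent)) {
  cat("identical-protein paralog pair(s):\n")
  print(silent[, c("a", "b", "n_synonymous", "n_nonsynonymous")])
}

# the published malpisin arrangement, from catalog coordinates
cat69 <- load_catalog()
m <- cat69[!is.na(cat69$range_start), ]
genes <- data.frame(gene_id = m$name,
                    contig = paste(m$accession, m$contig),
                    start = m$range_start, end = m$range_end)
mcl <- find_clusters(genes, max_gap = 30000)
cat(sprintf("malpisin catalog: %d clusters on %d contigs\n",
            length(unique(mcl$cluster)), length(unique(mcl$contig))))
print(mcl[, c("cluster", "gene_id")])
utils::write.table(mcl, "results/malpisin_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
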