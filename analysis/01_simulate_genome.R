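#!/usr/bin/env Rscript
# Build the synthetic study genome: 50 defensin genes spanning every
# precursor architecture (with and without propeptides, two-domain
# precursors, C-terminal amidation), intron layouts from intronless to
# the dermatophyte two-intron pattern, two tandem clusters, two
# pseudogenes, and one identical-protein paralog pair with four
# synonymous substitutions.

library(fdlpminer)

spec <- random_plant_spec(n_genes = 50, seed = 1)
genome <- plant_genes(spec)
write_synthetic(genome, "results/synthetic")

truth <- genome$truth
cat(sprintf("planted %d genes on %d contigs (%d bp total)\n",
            nrow(truth), length(genome$contigs),
            sum(nchar(genome$contigs))))
cat(sprintf("architectures: %s\n",
            paste(names(table(truth$architecture)),
                  table(truth$architecture), collapse = ", ")))
cat(sprintf("introns per gene: %s\n",
            paste(names(table(truth$n_introns)), table(truth$n_introns),
                  collapse = ", ")))
cat(sprintf("%d pseudogene(s), %d amidated gene(s), clusters: %s\n",
            sum(truth$pseudogene), sum(truth$amidation),
            paste(unique(na.omit(truth$cluster)), collapse = ", ")))
cat("outputs: results/synthetic/{contigs.fna,genes.gff3,truth.tsv}\n")
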