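test_that("generated matures keep the six-cysteine framework and size range", {
  for (fam in family_templates()) {
    for (seed in c(1, 99, 1234)) {
      p <- generate_mature(seed, fam)
      expect_equal(sum(strsplit(p, "")[[1]] == "C"), 6L)
      expect_gte(nchar(p), 33L)
      expect_lte(nchar(p), 60L)
    }
  }
  expect_identical(generate_mature(7, "fDEF2"), generate_mature(7, "fDEF2"))
  expect_error(generate_mature(1, "fDEF7"), "unknown family")
})

test_that("planted genes are internally consistent", {
  g <- small_genome()
  truth <- g$truth
  expect_true(all(!duplicated(truth$gene_id)))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    gm <- g$models[[tr$gene_id]]
    expect_lte(tr$gene_end, nchar(g$contigs[[tr$contig]]))
    if (tr$pseudogene) next
    # spliced CDS translates exactly to the recorded precursor
    cds <- cds_sequence(gm, g$contigs[[tr$contig]])
    expect_identical(cds, tr$cds)
    prot <- sub("\\*$", "", fdlpminer:::translate_cds(cds))
    expect_identical(prot, tr$precursor)
    # all introns begin GT and end AG on the coding strand
    intr <- model_introns(gm)
    for (k in seq_len(nrow(intr))) {
      s <- substr(g$contigs[[tr$contig]], intr$start[k], intr$end[k])
      if (tr$strand == "-") s <- fdlpminer:::revcomp(s)
      expect_identical(substr(s, 1, 2), "GT")
      expect_identical(substr(s, nchar(s) - 1, nchar(s)), "AG")
    }
    # complete genes: exon lengths sum to a codon multiple
    expect_equal(sum(gm$exons$end - gm$exons$start + 1) %% 3, 0)
  }
})

test_that("regeneration with the same spec is byte-identical", {
  spec <- random_plant_spec(n_genes = 10, seed = 5)
  expect_identical(plant_genes(spec), plant_genes(spec))
})

test_that("an intronless plant sits in an uninterrupted ORF", {
  plan <- data.frame(
    id = "solo", family = "fDEF1", family_c = NA, architecture = "no_pro",
    introns = "", amidation = FALSE, pseudogene = FALSE, strand = "+",
    contig = "c1", syn_pair_of = NA, syn_count = 0L,
    stringsAsFactors = FALSE)
  g <- plant_genes(plant_spec(plan, seed = 9))
  tr <- g$truth[1, ]
  expect_equal(tr$n_introns, 0L)
  orf <- substr(g$contigs[["c1"]], tr$gene_start + 12, tr$gene_end)
  prot <- fdlpminer:::translate_cds(orf)
  expect_false(grepl("\\*", sub("\\*$", "", prot)))
  expect_true(grepl(tr$mature_n, prot, fixed = TRUE))
})

test_that("a planned phase plan lands in the truth table verbatim", {
  plan <- data.frame(
    id = "twointron", family = "fDEF2", family_c = NA,
    architecture = "pro_mature", introns = "alpha_helix:0,c_loop:2",
    amidation = FALSE, pseudogene = FALSE, strand = "+", contig = "c1",
    syn_pair_of = NA, syn_count = 0L, stringsAsFactors = FALSE)
  g <- plant_genes(plant_spec(plan, seed = 3))
  expect_equal(g$truth$intron_phases, "0,2")
  expect_equal(g$truth$intron_regions, "alpha_helix,c_loop")
})

test_that("synonymous paralog pairs differ only silently, by the planned count", {
  g <- small_genome()
  truth <- g$truth
  # locate the planted pair via identical precursors
  pre <- split(truth$gene_id[!truth$pseudogene],
               truth$precursor[!truth$pseudogene])
  pair <- pre[lengths(pre) == 2][[1]]
  cds_a <- truth$cds[truth$gene_id == pair[1]]
  cds_b <- truth$cds[truth$gene_id == pair[2]]
  cnt <- count_synonymous(cds_a, cds_b)
  expect_equal(cnt$n_synonymous, 4L)
  expect_equal(cnt$n_nonsynonymous, 0L)
  expect_identical(fdlpminer:::translate_cds(cds_a),
                   fdlpminer:::translate_cds(cds_b))
})

test_that("an infeasible intron plan is rejected", {
  plan <- data.frame(
    id = "bad", family = "fDEF1", family_c = NA, architecture = "no_pro",
    introns = "nucleus:0", amidation = FALSE, pseudogene = FALSE,
    strand = "+", contig = "c1", syn_pair_of = NA, syn_count = 0L,
    stringsAsFactors = FALSE)
  expect_error(plant_spec(plan), "unsupported intron region")
})
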