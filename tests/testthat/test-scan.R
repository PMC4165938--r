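make_single_gene <- function(id = "solo", introns = "", strand = "+",
                             seed = 13, architecture = "pro_mature",
                             pseudogene = FALSE) {
  plan <- data.frame(
    id = id, family = "fDEF1", family_c = NA, architecture = architecture,
    introns = introns, amidation = FALSE, pseudogene = pseudogene,
    strand = strand, contig = "c1", syn_pair_of = NA, syn_count = 0L,
    stringsAsFactors = FALSE)
  plant_genes(plant_spec(plan, seed = seed))
}

test_that("a planted intronless gene yields exactly one overlapping locus", {
  g <- make_single_gene()
  prof <- seed_profile()
  loci <- scan_six_frames(g$contigs[["c1"]], prof, contig_id = "c1")
  tr <- g$truth[1, ]
  ov <- loci[loci$strand == tr$strand & loci$start <= tr$gene_end &
             loci$end >= tr$gene_start, ]
  expect_equal(nrow(ov), 1L)
})

test_that("scanning the reverse complement flips the locus strand", {
  g <- make_single_gene()
  prof <- seed_profile()
  ctg <- g$contigs[["c1"]]
  fwd <- scan_six_frames(ctg, prof, contig_id = "c1")
  rev <- scan_six_frames(fdlpminer:::revcomp(ctg), prof, contig_id = "c1")
  L <- nchar(ctg)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(rev$strand, chartr("+-", "-+", fwd$strand))
  expect_setequal(L - rev$end + 1, fwd$start)
})

test_that("default thresholds stay quiet on random GC-matched contigs", {
  set.seed(81)
  prof <- seed_profile()
  clean <- 0
  n_trials <- 100
  for (k in seq_len(n_trials)) {
    ctg <- random_contig(10000, gc = 0.48)
    loci <- scan_six_frames(ctg, prof, contig_id = "rnd")
    if (nrow(loci) == 0) clean <- clean + 1
  }
  expect_gte(clean / n_trials, 0.95)
})

test_that("spliced completion recovers planted exon structures", {
  prof <- seed_profile()
  # two-intron gene: exact exon recovery
  g <- make_single_gene(introns = "alpha_helix:0,c_loop:2", seed = 14)
  tr <- g$truth[1, ]
  loci <- scan_six_frames(g$contigs[["c1"]], prof, contig_id = "c1")
  ov <- loci[loci$strand == tr$strand & loci$start <= tr$gene_end &
             loci$end >= tr$gene_start, ]
  gm <- complete_spliced_model(g$contigs[["c1"]], ov[1, ], prof,
                               contig_id = "c1")
  expect_false(is.null(gm))
  expect_equal(paste(gm$exons$start, collapse = ","), tr$exon_starts)
  expect_equal(paste(gm$exons$end, collapse = ","), tr$exon_ends)

  # intronless gene: model with a single exon
  g0 <- make_single_gene(seed = 15)
  tr0 <- g0$truth[1, ]
  loci0 <- scan_six_frames(g0$contigs[["c1"]], prof, contig_id = "c1")
  gm0 <- complete_spliced_model(g0$contigs[["c1"]], loci0[1, ], prof,
                                contig_id = "c1")
  expect_equal(nrow(gm0$exons), 1L)
  expect_equal(gm0$exons$start, as.integer(tr0$exon_starts))

  # recovered introns never undercut the configured minimum length
  intr <- model_introns(gm)
  expect_true(all(intr$end - intr$start + 1 >= prof$intron_len[1]))
})

test_that("an exon-1-only pseudogene fails completion and is flagged", {
  g <- make_single_gene(introns = "alpha_helix:0", seed = 16,
                        pseudogene = TRUE)
  prof <- seed_profile()
  tr <- g$truth[1, ]
  loci <- scan_six_frames(g$contigs[["c1"]], prof, contig_id = "c1")
  ov <- loci[loci$strand == tr$strand & loci$start <= tr$gene_end &
             loci$end >= tr$gene_start, ]
  expect_gte(nrow(ov), 1L)
  gm <- complete_spliced_model(g$contigs[["c1"]], ov[1, ], prof,
                               contig_id = "c1")
  expect_null(gm)
  fl <- flag_pseudogene(list(model = gm))
  expect_true(fl$pseudogene)
  expect_equal(fl$reason, "truncated_exons")
})

test_that("per-contig scans do not depend on companion contigs", {
  g <- small_genome()
  prof <- seed_profile()
  ids <- names(g$contigs)[1:2]
  solo <- lapply(ids, function(ctg)
    scan_six_frames(g$contigs[[ctg]], prof, contig_id = ctg))
  together <- lapply(rev(ids), function(ctg)
    scan_six_frames(g$contigs[[ctg]], prof, contig_id = ctg))
  expect_equal(solo[[1]], together[[2]])
  expect_equal(solo[[2]], together[[1]])
})
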