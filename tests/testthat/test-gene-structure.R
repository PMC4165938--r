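test_that("intron phase is upstream coding length mod 3", {
  gm <- gene_model("g", "c", "+",
                   data.frame(start = c(1, 100), end = c(9, 200)))
  expect_equal(intron_phase(gm, 1), 0L)
  gm <- gene_model("g", "c", "+",
                   data.frame(start = c(1, 100), end = c(10, 200)))
  expect_equal(intron_phase(gm, 1), 1L)
  expect_error(intron_phase(gm, 2), "out of range")
})

test_that("phases are invariant under coordinate translation", {
  gm <- gene_model("g", "c", "+",
                   data.frame(start = c(11, 150), end = c(27, 260)))
  shifted <- gene_model("g", "c", "+",
                        data.frame(start = c(11, 150) + 1000,
                                   end = c(27, 260) + 1000))
  expect_equal(intron_phase(gm, 1), intron_phase(shifted, 1))
})

test_that("all planted intron phases are recovered from the gene models", {
  n_checked <- 0
  for (seed in c(101, 102)) {
    g <- plant_genes(random_plant_spec(n_genes = 25, seed = seed,
                                       n_pseudo = 0, n_syn_pairs = 0))
    truth <- g$truth
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      if (tr$n_introns == 0) next
      gm <- g$models[[tr$gene_id]]
      ph <- vapply(seq_len(tr$n_introns), function(k) intron_phase(gm, k),
                   integer(1))
      expect_identical(paste(ph, collapse = ","), tr$intron_phases)
      n_checked <- n_checked + tr$n_introns
    }
  }
  expect_gte(n_checked, 20)
})

test_that("introns localise to their planted precursor regions", {
  g <- small_genome()
  truth <- g$truth[!g$truth$pseudogene & g$truth$n_introns > 0, ]
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    gm <- g$models[[tr$gene_id]]
    anno <- annotate_precursor(tr$precursor)
    regions <- vapply(seq_len(tr$n_introns),
                      function(k) localize_intron(gm, anno, k), character(1))
    expect_identical(paste(regions, collapse = ","), tr$intron_regions)
  }
})

test_that("the c-loop window lies strictly between C4 and C5", {
  # single-domain precursor with known cysteine positions
  mat <- generate_mature(12, "fDEF1")
  sig <- "MKLLFILLFILLPHAHA"
  prec <- paste0(sig, mat)
  anno <- annotate_precursor(prec)
  cys <- which(strsplit(prec, "")[[1]] == "C")
  # build a model whose single intron interrupts a codon between C4 and C5
  pos <- cys[5] - 1L
  exon1_len <- 3L * (pos - 1L)
  gm <- gene_model("g", "c", "+",
                   data.frame(start = c(1, exon1_len + 101),
                              end = c(exon1_len, exon1_len + 100 + 3 *
                                        (nchar(prec) + 1) - exon1_len)))
  expect_equal(localize_intron(gm, anno, 1), "c_loop")
})

test_that("pseudogene flags carry their reason", {
  r <- flag_pseudogene(list(model = NULL))
  expect_true(r$pseudogene)
  expect_equal(r$reason, "truncated_exons")

  gm <- gene_model("g", "c", "+", data.frame(start = 1, end = 120))
  r <- flag_pseudogene(list(model = gm, protein = "MAAC*AAC"))
  expect_true(r$pseudogene)
  expect_equal(r$reason, "premature_stop")

  r <- flag_pseudogene(list(model = gm, protein = "MAACAACAA"))
  expect_true(r$pseudogene)
  expect_equal(r$reason, "missing_cysteines")

  complete <- paste0("MKLLFILLFILL", generate_mature(3, "fDEF2"))
  r <- flag_pseudogene(list(model = gm, protein = complete))
  expect_false(r$pseudogene)
})
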