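test_that("signal prediction needs a hydrophobic core", {
  expect_null(predict_signal("MDEDNSKEDDESNKEDDESNKEDDESNK"))
  expect_null(predict_signal("KLLLLLLLLLLAQA"))  # no initial M
  sig <- "MKLLFILLFILLPHAHA"  # core 3-13, first valid site at 17
  p <- predict_signal(paste0(sig, "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY"))
  expect_equal(p, c(1L, 17L))
})

test_that("planted signal boundaries are recovered", {
  set.seed(51)
  n <- 200
  hits <- 0
  exact <- 0
  for (k in seq_len(n)) {
    sig <- fdlpminer:::make_signal_peptide()
    mat <- generate_mature(k, sample(family_templates(), 1))
    prec <- paste0(sig, mat)
    p <- predict_signal(prec)
    if (!is.null(p)) {
      if (abs(p[2] - nchar(sig)) <= 2) hits <- hits + 1
      if (p[2] == nchar(sig)) exact <- exact + 1
    }
  }
  expect_gte(hits / n, 0.90)
  expect_gte(exact / n, 0.90)
})

test_that("the acidic propeptide rule follows charge and basic terminus", {
  r <- detect_propeptide("EEDDAASLEKR")
  expect_true(r$is_propeptide)
  expect_equal(r$cleave_after, 11L)
  expect_false(detect_propeptide("GGSSGG")$is_propeptide)
  expect_true(detect_propeptide("DDK")$is_propeptide)
  # basic terminus but net positive charge: not a propeptide
  expect_false(detect_propeptide("KKKKR")$is_propeptide)
  # case-invariance
  expect_identical(detect_propeptide("eeddaaslekr"),
                   detect_propeptide("EEDDAASLEKR"))
})

test_that("amidation signals are detected and trimmed, glycine retained", {
  r <- detect_amidation("KCYGR")
  expect_true(r$amidated)
  expect_equal(r$trimmed, "KCYG")
  r <- detect_amidation("KCYGRR")
  expect_true(r$amidated)
  expect_equal(r$trimmed, "KCYG")
  expect_false(detect_amidation("KCY")$amidated)
})

test_that("segmentation tiles the precursor and recovers architectures", {
  g <- small_genome()
  truth <- g$truth[!g$truth$pseudogene, ]
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    anno <- annotate_precursor(tr$precursor)
    expect_equal(architecture_class(anno), tr$architecture)
    # segments tile the precursor without gaps or overlap
    ivs <- c(list(anno$signal), anno$propeptides, unname(anno$domains))
    ivs <- ivs[order(vapply(ivs, `[`, integer(1), 1))]
    expect_equal(ivs[[1]][1], 1L)
    expect_equal(ivs[[length(ivs)]][2], nchar(tr$precursor))
    for (k in seq_len(length(ivs) - 1)) {
      expect_equal(ivs[[k + 1]][1], ivs[[k]][2] + 1L)
    }
    # processed matures equal the planted ones
    want <- c(tr$mature_n, if (!is.na(tr$mature_c)) tr$mature_c)
    expect_equal(unname(anno$matures), want)
  }
})

test_that("architecture class is recovered for at least 95% of 200 plants", {
  spec <- random_plant_spec(n_genes = 50, seed = 77, n_pseudo = 0,
                            n_syn_pairs = 0)
  spec2 <- random_plant_spec(n_genes = 50, seed = 78, n_pseudo = 0,
                             n_syn_pairs = 0)
  spec3 <- random_plant_spec(n_genes = 50, seed = 79, n_pseudo = 0,
                             n_syn_pairs = 0)
  spec4 <- random_plant_spec(n_genes = 50, seed = 80, n_pseudo = 0,
                             n_syn_pairs = 0)
  ok <- 0; n <- 0
  for (sp in list(spec, spec2, spec3, spec4)) {
    g <- plant_genes(sp)
    truth <- g$truth[!g$truth$pseudogene, ]
    n <- n + nrow(truth)
    for (i in seq_len(nrow(truth))) {
      anno <- annotate_precursor(truth$precursor[i])
      if (architecture_class(anno) == truth$architecture[i]) ok <- ok + 1
    }
  }
  expect_gte(n, 200)
  expect_gte(ok / n, 0.95)
})

test_that("two-domain precursors split into N and C domains", {
  g <- small_genome()
  td <- g$truth[g$truth$architecture == "two_domain" & !g$truth$pseudogene, ]
  skip_if(nrow(td) == 0, "no two-domain gene in the shared genome")
  anno <- annotate_precursor(td$precursor[1])
  doms <- split_domains(anno)
  expect_equal(names(doms), c("N", "C"))
  expect_lt(doms$N[2], doms$C[1])
})

test_that("more than two frameworks is an unsupported architecture", {
  one <- generate_mature(1, "fDEF1")
  sig <- "MKLLFILLFILLPHAHA"
  tri <- paste0(sig, one, "EEDDSSLKR", one, "EEDDSSLKR", one)
  expect_error(annotate_precursor(tri), "unsupported architecture")
})
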