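test_that("the published malpisin coordinates form one tandem cluster", {
  cat69 <- load_catalog()
  m <- cat69[cat69$name %in% paste0("Malpisin1-", 1:4), ]
  genes <- data.frame(gene_id = m$name, contig = m$contig,
                      start = m$range_start, end = m$range_end)
  cl <- find_clusters(genes, max_gap = 30000)
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(nrow(cl), 4L)
  expect_equal(cl$gene_id, paste0("Malpisin1-", 1:4))  # genomic order
})

test_that("distant genes do not cluster and order does not matter", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "c",
                      start = c(1000, 150000), end = c(1500, 150500))
  expect_equal(nrow(find_clusters(genes, max_gap = 30000)), 0L)

  g3 <- data.frame(gene_id = c("b", "a", "c"), contig = "c",
                   start = c(5000, 1000, 9000), end = c(5400, 1400, 9400))
  cl1 <- find_clusters(g3)
  cl2 <- find_clusters(g3[c(3, 1, 2), ])
  expect_equal(cl1$gene_id, c("a", "b", "c"))
  expect_equal(cl1, cl2)
})

test_that("synonymous counting matches the codon table", {
  expect_equal(count_synonymous("CTT", "CTC"),
               list(n_total = 1L, n_synonymous = 1L, n_nonsynonymous = 0L))
  expect_equal(count_synonymous("ATGGCT", "ATGGCT"),
               list(n_total = 0L, n_synonymous = 0L, n_nonsynonymous = 0L))
  # CTT (Leu) vs ATT (Ile): one nonsynonymous difference
  expect_equal(count_synonymous("CTT", "ATT")$n_nonsynonymous, 1L)
  expect_error(count_synonymous("ATG", "ATGC"), "mismatch")
  expect_error(count_synonymous("ATGC", "ATGC"), "divisible")
})

test_that("difference counts are consistent under random codon mutation", {
  set.seed(71)
  codons <- names(fdlpminer:::codon_table())
  for (k in 1:25) {
    n_cod <- sample(5:30, 1)
    a <- paste0(sample(codons, n_cod, replace = TRUE), collapse = "")
    b <- a
    n_mut <- sample(1:5, 1)
    pos <- sample(nchar(a), n_mut)
    for (p in pos) {
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(a, p, p)), 1)
    }
    cnt <- count_synonymous(a, b)
    expect_equal(cnt$n_total, cnt$n_synonymous + cnt$n_nonsynonymous)
    expect_equal(cnt$n_total, n_mut)
  }
})

test_that("paralog pairs respect the identity threshold", {
  two <- c(p1 = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY",
           p2 = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY")
  pr <- paralog_pairs(two)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$identity, 1)

  fam <- setNames(vapply(1:6, function(k) generate_mature(500 + k, "fDEF3"),
                         character(1)), paste0("m", 1:6))
  expect_equal(nrow(paralog_pairs(fam, identity_min = 0)), 15L)  # 6 choose 2

  set.seed(72)
  div <- c(fam[1:3], lone = random_peptide(40))
  pr <- paralog_pairs(div, identity_min = 0.70)
  expect_false(any(pr$a == "lone" | pr$b == "lone"))
})
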