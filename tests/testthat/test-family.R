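test_that("three taxa resolve with closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-8)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-8)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-8)
})

test_that("an additive four-taxon matrix yields the generating topology", {
  # tree ((a,b),(c,d)) with internal branch 0.4
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 0.1, b = 0.2, c = 0.15, d = 0.25)
  for (i in 1:3) for (j in (i + 1):4) {
    extra <- if ((i <= 2) == (j <= 2)) 0 else 0.4
    d[i, j] <- d[j, i] <- bl[i] + bl[j] + extra
  }
  tr <- neighbor_joining(d)
  ref <- ape::read.tree(text = "((a:0.1,b:0.2):0.4,(c:0.15,d:0.25):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ref)), 0)
})

test_that("path lengths on an additive 5-taxon matrix reproduce the input", {
  set.seed(61)
  ref <- ape::rtree(5)
  d <- ape::cophenetic.phylo(ref)
  d <- d[order(rownames(d)), order(colnames(d))]
  tr <- neighbor_joining(d)
  d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(d2, d, tolerance = 1e-8)
})

test_that("NJ agrees with the ape reference on random matrices", {
  set.seed(62)
  for (k in 1:10) {
    n <- sample(5:10, 1)
    x <- matrix(runif(n * n, 0.05, 1), n, n)
    d <- (x + t(x)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("non-symmetric input is rejected and branch lengths stay non-negative", {
  d <- matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "symmetric")
  set.seed(63)
  for (k in 1:5) {
    n <- 6
    x <- matrix(runif(n * n, 0, 1), n, n)
    d <- (x + t(x)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(all(neighbor_joining(d)$edge.length >= 0))
  }
})

test_that("bootstrap gives full support to clean splits and is seed-stable", {
  peps <- c(a1 = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY",
            a2 = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCF",
            b1 = "ATYCHSDPWGNNLACFGHCRTFGGVGLGYCSNHFTCNCKA",
            b2 = "ATYCHSDPWGNNLACFGHCRTFGGVGLGYCSNHFTCNCKG")
  am <- align_star(peps)
  bs1 <- bootstrap_support(am, n_reps = 100, seed = 4)
  bs2 <- bootstrap_support(am, n_reps = 100, seed = 4)
  expect_identical(bs1$support, bs2$support)
  # the single internal edge separates {a1,a2} from {b1,b2}
  expect_gte(max(bs1$support, na.rm = TRUE), 99)
  expect_error(bootstrap_support(am, n_reps = 0), "n_reps")
})

test_that("a planted two-family split earns high support", {
  set.seed(64)
  peps <- c(
    setNames(vapply(1:5, function(k) generate_mature(200 + k, "fDEF1"),
                    character(1)), paste0("fam1_", 1:5)),
    setNames(vapply(1:5, function(k) generate_mature(300 + k, "fDEF6"),
                    character(1)), paste0("fam6_", 1:5)))
  am <- align_star(peps)
  bs <- bootstrap_support(am, n_reps = 100, seed = 9)
  # find the edge bipartitioning the two families
  tr <- bs$tree
  ntip <- length(tr$tip.label)
  found <- FALSE
  for (node in (ntip + 2):(ntip + tr$Nnode)) {
    tips <- ape::extract.clade(tr, node)$tip.label
    if (setequal(tips, paste0("fam1_", 1:5)) ||
        setequal(tips, paste0("fam6_", 1:5))) {
      found <- TRUE
      expect_gte(bs$support[node - ntip], 90)
    }
  }
  expect_true(found)
})

test_that("family assignment follows anchors, identity and support", {
  seeds <- seed_anchor_set()
  anchors <- setNames(seeds$family, seeds$name)
  # a query identical to plectasin
  peps <- c(setNames(seeds$seq, seeds$name),
            query = seeds$seq[seeds$name == "plectasin"])
  am <- align_star(peps)
  bs <- bootstrap_support(am, n_reps = 100, seed = 2)
  ids <- setNames(vapply(seeds$seq, function(s)
    pairwise_identity(peps[["query"]], s), numeric(1)), seeds$name)
  fam <- assign_family(bs$tree, anchors, "query", support = bs$support,
                       identity = ids)
  expect_equal(fam, "fDEF1")
  expect_error(assign_family(bs$tree, anchors, "absent"), "not in tree")
})

test_that("a divergent clade away from all anchors is called new", {
  seeds <- seed_anchor_set()
  anchors <- setNames(seeds$family, seeds$name)
  # random-loop peptides unrelated to any template, forming their own clade
  set.seed(65)
  novel <- vapply(1:5, function(k) {
    paste0("W", random_peptide(3), "C", random_peptide(12), "C",
           random_peptide(3), "C", random_peptide(9), "C",
           random_peptide(6), "C", random_peptide(1), "CW")
  }, character(1))
  names(novel) <- paste0("nov", 1:5)
  peps <- c(setNames(seeds$seq, seeds$name), novel)
  am <- align_star(peps)
  bs <- bootstrap_support(am, n_reps = 100, seed = 3)
  ids <- setNames(vapply(seeds$seq, function(s)
    pairwise_identity(novel[[1]], s), numeric(1)), seeds$name)
  skip_if(max(ids) >= 0.30, "random novel family too close to an anchor")
  fam <- assign_family(bs$tree, anchors, "nov1", support = bs$support,
                       identity = ids)
  expect_equal(fam, "new")
})
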