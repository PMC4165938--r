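test_that("average molecular weight matches hand values and is additive", {
  expect_equal(average_mw("G"), 75.07, tolerance = 0.01)
  expect_equal(average_mw("GG"), 132.12, tolerance = 0.01)
  set.seed(31)
  for (k in 1:10) {
    a <- random_peptide(sample(3:20, 1))
    b <- random_peptide(sample(3:20, 1))
    expect_equal(average_mw(paste0(a, b)),
                 average_mw(a) + average_mw(b) - 18.0153,
                 tolerance = 1e-9)
  }
  expect_error(average_mw("GXZ"), "X")
})

test_that("net charge matches an independent Henderson-Hasselbalch sum", {
  expect_lt(abs(net_charge("GGGGG", 7.0)), 0.1)
  set.seed(32)
  for (k in 1:100) {
    p <- random_peptide(sample(5:60, 1))
    pH <- runif(1, 2, 12)
    expect_equal(net_charge(p, pH), ref_net_charge(p, pH), tolerance = 1e-9)
  }
})

test_that("net charge is non-increasing in pH", {
  set.seed(33)
  for (k in 1:20) {
    p <- random_peptide(sample(5:40, 1))
    phs <- sort(runif(5, 1, 13))
    z <- vapply(phs, function(x) net_charge(p, x), numeric(1))
    expect_true(all(diff(z) <= 1e-12))
  }
})

test_that("concatenation charge obeys the closed form", {
  pka <- default_pka_table()
  set.seed(34)
  for (k in 1:10) {
    a <- random_peptide(sample(4:25, 1))
    b <- random_peptide(sample(4:25, 1))
    lost_cterm <- -1 / (1 + 10^(pka$acidic[["Cterm"]] - 7))
    lost_nterm <- 1 / (1 + 10^(7 - pka$basic[["Nterm"]]))
    expect_equal(net_charge(paste0(a, b)),
                 net_charge(a) + net_charge(b) - lost_cterm - lost_nterm,
                 tolerance = 1e-9)
  }
})

test_that("disulfide-engaged cysteines can be excluded from titration", {
  p <- "ACCACCA"
  full <- net_charge(p, 7, n_disulfides = 0)
  ox <- net_charge(p, 7, n_disulfides = 2)
  expect_gt(ox, full)  # removing acidic thiols raises the charge
  expect_error(net_charge(p, 7, n_disulfides = 3), "cysteines")
})
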