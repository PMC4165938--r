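# Independent reference implementations used as oracles. These share no
# code with the package: plain-R dynamic programming for alignment and a
# direct Henderson-Hasselbalch sum for net charge.

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap alignment by exhaustive dynamic programming.
# A gap of length L costs open + L * extend (first gap base open+extend).
ref_align_score <- function(a, b, type = "local", open = 10, extend = 1,
                            mat = blosum62_matrix) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  local <- type == "local"
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
    for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      best_prev <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      M[i, j] <- s + best_prev
      if (local) M[i, j] <- max(0, M[i, j])
      Ix[i, j] <- max(M[i - 1, j] - (open + extend), Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - (open + extend), Iy[i, j - 1] - extend)
    }
  }
  if (local) {
    max(M)
  } else {
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  }
}

# Independent Henderson-Hasselbalch net charge with the package's default
# constants written out explicitly.
ref_net_charge <- function(peptide, pH = 7.0) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  pos <- c(Nterm = 8.0, K = 10.0, R = 12.0, H = 6.5)
  neg <- c(Cterm = 3.1, D = 4.4, E = 4.4, C = 8.5, Y = 10.0)
  z <- 1 / (1 + 10^(pH - pos["Nterm"])) - 1 / (1 + 10^(neg["Cterm"] - pH))
  for (r in c("K", "R", "H")) {
    z <- z + sum(aa == r) / (1 + 10^(pH - pos[r]))
  }
  for (r in c("D", "E", "C", "Y")) {
    z <- z - sum(aa == r) / (1 + 10^(neg[r] - pH))
  }
  unname(z)
}

random_peptide <- function(n) {
  paste0(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                n, replace = TRUE), collapse = "")
}

random_contig <- function(n, gc = 0.48) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# small shared synthetic genome, built once per test run
small_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- random_plant_spec(n_genes = 12, seed = 421, n_pseudo = 1,
                                n_syn_pairs = 1, syn_count = 4)
      cache <<- plant_genes(spec)
    }
    cache
  }
})
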