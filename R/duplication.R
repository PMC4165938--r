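# Gene duplication analysis: tandem clusters on contigs, synonymous
# substitution counts between paralogous CDSs, paralog pair detection.

#' Find tandem gene clusters on contigs
#'
#' Single-linkage chaining of genes sharing a contig with inter-gene gap
#' at most `max_gap`; singletons are not reported.
#'
#' @param genes Data frame with columns `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive), optionally `strand`.
#' @param max_gap Maximum gap (bp) between consecutive cluster members
#'   (default 30 kb, which reproduces the published malpisin contig
#'   groupings).
#' @return Data frame: `cluster`, `contig`, `gene_id`, `start`, `end`,
#'   `strand`, ordered by genomic coordinate within cluster.
#' @export
find_clusters <- function(genes, max_gap = 30000L) {
  stopifnot(all(c("gene_id", "contig", "start", "end") %in% names(genes)))
  if (!"strand" %in% names(genes)) genes$strand <- NA_character_
  out <- list()
  k <- 0L
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) next
    gap <- g$start[-1] - g$end[-nrow(g)]
    brk <- c(0L, cumsum(gap > max_gap))
    for (b in unique(brk)) {
      members <- g[brk == b, , drop = FALSE]
      if (nrow(members) < 2L) next
      k <- k + 1L
      out[[k]] <- data.frame(cluster = sprintf("cluster%02d", k),
                             contig = ctg, gene_id = members$gene_id,
                             start = members$start, end = members$end,
                             strand = members$strand,
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = character(), contig = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count synonymous and nonsynonymous differences between two CDSs
#'
#' Codon-by-codon comparison of equal-length in-frame CDSs: nucleotide
#' differences inside a codon pair translating to the same amino acid are
#' synonymous, otherwise nonsynonymous.
#'
#' @param cds_a,cds_b CDS strings of equal length divisible by 3.
#' @return List with `n_total`, `n_synonymous`, `n_nonsynonymous`.
#' @examples
#' count_synonymous("CTT", "CTC")  # one synonymous difference (both Leu)
#' @export
count_synonymous <- function(cds_a, cds_b) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stop_fmt("CDS length mismatch (%d vs %d)",
                                     nchar(a), nchar(b))
  if (nchar(a) %% 3L != 0L) stop_fmt("CDS length not divisible by 3")
  n <- nchar(a)
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- codon_table()
  n_syn <- 0L; n_non <- 0L
  for (i in which(ca != cb)) {
    diffs <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    if (identical(tab[[ca[i]]], tab[[cb[i]]])) {
      n_syn <- n_syn + diffs
    } else {
      n_non <- n_non + diffs
    }
  }
  list(n_total = n_syn + n_non, n_synonymous = n_syn,
       n_nonsynonymous = n_non)
}

#' Detect paralog pairs among peptides of one assembly
#'
#' All peptide pairs with global-alignment identity at least
#' `identity_min`, annotated by whether the two genes share a contig.
#'
#' @param peptides Named character vector of mature peptides.
#' @param identity_min Minimum identity (default 0.70).
#' @param contigs Optional named character vector: contig per peptide.
#' @return Data frame: `a`, `b`, `identity`, `same_contig`.
#' @export
paralog_pairs <- function(peptides, identity_min = 0.70, contigs = NULL) {
  n <- length(peptides)
  if (n < 2L) {
    return(data.frame(a = character(), b = character(),
                      identity = numeric(), same_contig = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  nm <- names(peptides)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      id <- pairwise_identity(peptides[[i]], peptides[[j]])
      if (id >= identity_min) {
        same <- if (is.null(contigs)) NA else
          unname(contigs[nm[i]] == contigs[nm[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          a = nm[i], b = nm[j], identity = id, same_contig = same,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(), b = character(),
                      identity = numeric(), same_contig = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
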