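#' Construct a spliced gene model
#'
#' A gene model is the exon structure of one defensin coding sequence on a
#' contig. Coordinates are 1-based inclusive genomic positions; exons are
#' stored in ascending genomic order regardless of strand.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (nrow(exons) < 1L) stop_fmt("gene model '%s' has no exons", gene_id)
  if (any(exons$end < exons$start)) {
    stop_fmt("gene model '%s': exon end < start", gene_id)
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop_fmt("gene model '%s': overlapping exons", gene_id)
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d exon(s)\n",
              x$gene_id, x$contig, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons)))
  invisible(x)
}

# exons in transcription (5'->3') order
exons_tx_order <- function(gm) {
  if (gm$strand == "+") gm$exons else gm$exons[rev(seq_len(nrow(gm$exons))), ]
}

#' Genomic intervals of a model's introns
#' @param gm A `gene_model`.
#' @return Data frame `start`, `end` (1-based inclusive), ascending; zero
#'   rows for single-exon models.
#' @export
model_introns <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Spliced coding sequence of a gene model
#' @param gm A `gene_model`.
#' @param contig_seq Nucleotide sequence of the model's contig (character).
#' @return The spliced CDS, 5' to 3' on the coding strand.
#' @export
cds_sequence <- function(gm, contig_seq) {
  parts <- substring(contig_seq, gm$exons$start, gm$exons$end)
  cds <- paste0(parts, collapse = "")
  if (gm$strand == "-") cds <- revcomp(cds)
  cds
}

# GFF3 CDS phase column per exon in transcription order:
# bases to skip to reach the next codon start.
gff3_phases <- function(gm) {
  ex <- exons_tx_order(gm)
  lens <- ex$end - ex$start + 1L
  cum <- c(0L, cumsum(lens))[seq_len(nrow(ex))]
  (3L - cum %% 3L) %% 3L
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with 1-based inclusive
#' coordinates and a populated CDS phase column.
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(models, function(gm) {
    ex <- gm$exons
    span <- c(min(ex$start), max(ex$end))
    n <- nrow(ex)
    phase_tx <- gff3_phases(gm)
    # map phases back to ascending genomic order
    phase_gen <- if (gm$strand == "+") phase_tx else rev(phase_tx)
    data.frame(
      seqid = gm$contig,
      start = c(span[1], span[1], ex$start, ex$start),
      end = c(span[2], span[2], ex$end, ex$end),
      strand = gm$strand,
      type = c("gene", "mRNA", rep("exon", n), rep("CDS", n)),
      phase = c(NA, NA, rep(NA, n), phase_gen),
      ID = c(gm$gene_id, paste0(gm$gene_id, ".t1"),
             paste0(gm$gene_id, ".exon", seq_len(n)),
             rep(paste0(gm$gene_id, ".cds"), n)),
      Parent = c(NA, gm$gene_id, rep(paste0(gm$gene_id, ".t1"), 2L * n)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- as.integer(tab$phase)
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- tab$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Rebuilds `gene_model` objects from the CDS features of a GFF3 file (the
#' inverse of [write_gff3()] for the fields the pipeline uses).
#'
#' @param path GFF3 path.
#' @return List of `gene_model` objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  parent <- as.character(unlist(S4Vectors::mcols(cds)$Parent))
  gene_ids <- sub("\\.t1$", "", parent)
  out <- lapply(split(seq_along(cds), gene_ids), function(idx) {
    sub <- cds[idx]
    gene_model(
      gene_id = sub("\\.t1$", "", as.character(unlist(S4Vectors::mcols(sub)$Parent))[1]),
      contig = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(BiocGenerics::strand(sub))[1],
      exons = data.frame(start = BiocGenerics::start(sub),
                         end = BiocGenerics::end(sub))
    )
  })
  unname(out[unique(gene_ids)])
}
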