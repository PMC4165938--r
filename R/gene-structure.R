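# Intron-phase annotation, localization of introns onto precursor
# regions, and pseudogene flagging.

#' Phase of an intron in a gene model
#'
#' Phase is the number of coding nucleotides upstream of the intron modulo
#' 3: phase 0 introns fall between codons, phase 1 after the first base of
#' a codon, phase 2 after the second.
#'
#' @param gm A [gene_model()].
#' @param intron_ordinal Intron index in transcription order.
#' @return 0, 1 or 2.
#' @export
intron_phase <- function(gm, intron_ordinal) {
  ex <- exons_tx_order(gm)
  n_intr <- nrow(ex) - 1L
  if (intron_ordinal < 1L || intron_ordinal > n_intr) {
    stop_fmt("gene '%s' has %d intron(s); ordinal %d out of range",
             gm$gene_id, n_intr, intron_ordinal)
  }
  lens <- ex$end - ex$start + 1L
  sum(lens[seq_len(intron_ordinal)]) %% 3L
}

#' Precursor region interrupted by an intron
#'
#' Maps an intron's codon position onto the segmented precursor. Signal
#' and propeptide regions come from the segmentation; within a mature
#' domain the windows are keyed off the framework cysteines: alpha-helix
#' `[C2-2, C3]`, c-loop `(C4, C5)`, n-loop `(C1, C2-3)`; anything after C6
#' is c-terminal. The windows follow the canonical CSab topology and are
#' heuristic: no per-family structural coordinates exist.
#'
#' @param gm A [gene_model()].
#' @param anno A `defensin_precursor` from [annotate_precursor()] for the
#'   model's translated CDS.
#' @param intron_ordinal Intron index in transcription order.
#' @return One of `"signal"`, `"propeptide"`, `"n_loop"`, `"alpha_helix"`,
#'   `"c_loop"`, `"c_terminal"`, `"unknown"`.
#' @export
localize_intron <- function(gm, anno, intron_ordinal) {
  ex <- exons_tx_order(gm)
  lens <- ex$end - ex$start + 1L
  upstream <- sum(lens[seq_len(intron_ordinal)])
  pos <- upstream %/% 3L + 1L  # codon (aa) index the intron interrupts
  if (is.null(anno$signal) || length(anno$domains) == 0L) return("unknown")
  if (pos <= anno$signal[2]) return("signal")
  for (p in anno$propeptides) {
    if (pos >= p[1] && pos <= p[2]) return("propeptide")
  }
  aa <- strsplit(anno$full, "", fixed = TRUE)[[1]]
  for (d in anno$domains) {
    if (pos < d[1] || pos > d[2]) next
    cys <- which(aa == "C")
    cys <- cys[cys >= d[1] & cys <= d[2]][1:6]
    if (any(is.na(cys))) return("unknown")
    if (pos >= cys[2] - 2L && pos <= cys[3]) return("alpha_helix")
    if (pos > cys[4] && pos < cys[5]) return("c_loop")
    if (pos > cys[1] && pos <= cys[2] - 3L) return("n_loop")
    return("c_terminal")
  }
  "c_terminal"
}

#' Flag a candidate locus as a pseudogene
#'
#' A locus is a pseudogene when spliced completion failed (lost exons), or
#' when its best model still translates with a premature stop, or when the
#' resulting peptide lacks the six framework cysteines.
#'
#' @param locus_result List with elements `model` (a [gene_model()] or
#'   `NULL`) and optionally `protein` (translated precursor of the best
#'   completion).
#' @return List with `pseudogene` (logical) and `reason` (one of
#'   `"truncated_exons"`, `"premature_stop"`, `"missing_cysteines"`, or
#'   `NA`).
#' @export
flag_pseudogene <- function(locus_result) {
  if (is.null(locus_result$model)) {
    return(list(pseudogene = TRUE, reason = "truncated_exons"))
  }
  prot <- locus_result$protein
  if (!is.null(prot)) {
    body <- sub("\\*$", "", prot)
    if (grepl("\\*", body)) {
      return(list(pseudogene = TRUE, reason = "premature_stop"))
    }
    if (sum(strsplit(body, "")[[1]] == "C") < 6L) {
      return(list(pseudogene = TRUE, reason = "missing_cysteines"))
    }
  }
  list(pseudogene = FALSE, reason = NA_character_)
}
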