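#' Read a FASTA file into a sequence record table
#'
#' Parses nucleotide or peptide FASTA into a data frame with one row per
#' record. Sequences are uppercased and alignment gaps (`-`, `.`) stripped;
#' the molecule type is inferred from the residue alphabet.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"auto"` (default), `"dna"` or `"protein"`. With `"auto"`
#'   a sequence consisting only of `A/C/G/T/N` is called DNA.
#' @return A `data.frame` with columns `id`, `desc`, `seq`, `moltype`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">pep1 a defensin", "GFGCNGPWDEDD"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, moltype = c("auto", "dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_fmt("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  headers <- names(set)
  seqs <- toupper(gsub("[-.]", "", as.character(set)))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop_fmt("malformed FASTA: record %d has an empty header",
             which(ids == "")[1])
  }
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop_fmt("malformed FASTA: record '%s' has an empty sequence", ids[empty[1]])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_fmt("duplicate FASTA id: '%s'", dup[1])
  mt <- if (moltype == "auto") {
    ifelse(grepl("^[ACGTN]+$", seqs), "dna", "protein")
  } else rep(moltype, length(seqs))
  data.frame(id = ids, desc = desc, seq = seqs, moltype = mt,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Writes 60-column wrapped FASTA. `write_fasta(read_fasta(f), g)` is
#' byte-identical to `f` for files already in this normal form.
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`,
#'   or a named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), desc = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    d <- if ("desc" %in% names(records)) records$desc[i] else ""
    if (!is.na(d) && nzchar(d)) hdr <- paste(hdr, d)
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
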