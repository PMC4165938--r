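#' Load the packaged fDLP catalog
#'
#' The package ships a TSV transcription of the published catalog of newly
#' discovered fungal defensin-like peptides: 45 non-*Mortierella* entries
#' plus 24 malpisins from two *Mortierella alpina* isolates. Numeric columns
#' keep the printed typography (typographic minus signs, en-dash coordinate
#' ranges); [load_catalog()] normalises them.
#'
#' @param path Path to a catalog TSV. Defaults to the packaged fixture.
#' @return A `data.frame` with one row per mature peptide and columns
#'   `name`, `accession`, `evidence`, `family`, `organism`, `phylum`,
#'   `contig`, `range_start`, `range_end`, `size` (aa), `mw` (Da),
#'   `nc` (net charge at pH 7.0).
#' @examples
#' cat69 <- load_catalog()
#' nrow(cat69)  # 69 peptides
#' @export
load_catalog <- function(path = fdlp_catalog_path()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("name", "accession", "evidence", "family", "organism",
            "contig", "range", "size", "mw", "nc")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_fmt("catalog TSV lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(empty_catalog())

  num <- function(x, col) {
    y <- normalize_minus(trimws(x))
    v <- suppressWarnings(as.numeric(y))
    bad <- which(is.na(v) & nzchar(y))
    if (length(bad)) {
      stop_fmt("catalog row '%s': cannot parse %s value '%s'",
               raw$name[bad[1]], col, x[bad[1]])
    }
    v
  }
  rng <- strsplit(normalize_minus(raw$range), "-", fixed = TRUE)
  range_start <- vapply(rng, function(r)
    if (length(r) == 2L) as.numeric(r[1]) else NA_real_, numeric(1))
  range_end <- vapply(rng, function(r)
    if (length(r) == 2L) as.numeric(r[2]) else NA_real_, numeric(1))

  phylum <- sub("^.*\\(([^:)]+).*$", "\\1", raw$organism)
  phylum <- trimws(phylum)

  out <- data.frame(
    name = raw$name,
    accession = raw$accession,
    evidence = raw$evidence,
    family = raw$family,
    organism = trimws(sub("\\s*\\(.*\\)", "", raw$organism)),
    phylum = phylum,
    contig = raw$contig,
    range_start = range_start,
    range_end = range_end,
    size = as.integer(num(raw$size, "size")),
    mw = num(raw$mw, "mw"),
    nc = num(raw$nc, "nc"),
    stringsAsFactors = FALSE
  )
  fam_ok <- c("fDEF1", "fDEF2", "fDEF3", "fDEF4", "fDEF6", "fDEF8", "unassigned")
  bad_fam <- setdiff(unique(out$family), fam_ok)
  if (length(bad_fam)) stop_fmt("unknown family label: %s", bad_fam[1])
  if (any(out$size < 1L)) stop_fmt("catalog row '%s': size < 1",
                                   out$name[which(out$size < 1L)[1]])
  out
}

#' Path of the packaged catalog fixture
#' @return File path of the TSV shipped in `inst/extdata`.
#' @export
fdlp_catalog_path <- function() {
  system.file("extdata", "fdlp_catalog.tsv", package = "fdlpminer",
              mustWork = TRUE)
}

# Typographic minus (U+2212), figure dash (U+2012), en dash (U+2013) -> "-"
normalize_minus <- function(x) {
  gsub("−|‒|–", "-", x)
}

empty_catalog <- function() {
  data.frame(name = character(), accession = character(),
             evidence = character(), family = character(),
             organism = character(), phylum = character(),
             contig = character(), range_start = numeric(),
             range_end = numeric(), size = integer(), mw = numeric(),
             nc = numeric(), stringsAsFactors = FALSE)
}
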