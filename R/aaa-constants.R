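# Shared low-level helpers: codon translation, reverse complement,
# hydropathy scale, residue alphabets.

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# Kyte-Doolittle hydropathy index
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' @keywords internal
codon_table <- function() {
  Biostrings::GENETIC_CODE
}

# Vectorised codon-string translation; '*' for stop. Trailing partial codon
# is dropped. Much lighter than constructing a DNAString per call inside the
# spliced-model search loops.
translate_cds <- function(dna) {
  n <- nchar(dna)
  n <- n - n %% 3L
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# positions (1-based) of a character within a string
char_positions <- function(s, ch) {
  which(strsplit(s, "", fixed = TRUE)[[1]] == ch)
}

# sample helper immune to the length-1 x behaviour of base::sample
sample_one <- function(x) x[sample.int(length(x), 1L)]

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
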