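# Precursor segmentation: signal peptide, propeptide(s), one or two mature
# CSab-defensin domains, C-terminal amidation and terminal-extension flags.

# Relaxed inter-cysteine gap bounds (residues between consecutive framework
# cysteines) accepted when locating six-cysteine frameworks in a precursor.
DEFAULT_CYS_ENVELOPE <- cbind(min = c(5L, 1L, 6L, 2L, 1L),
                              max = c(16L, 6L, 14L, 9L, 3L))

#' Predict the signal peptide of a defensin precursor
#'
#' Transparent hydropathy heuristic: within residues 1-40 the precursor
#' must contain a hydrophobic core (six consecutive residues of mean
#' Kyte-Doolittle hydropathy >= 1.5); cleavage is placed after the first
#' position >= 15 whose -1 and -3 residues are small
#' (A/G/S/C/T/V, the signal-peptidase preference). User-supplied cleavage
#' sites can override the heuristic in [annotate_precursor()].
#'
#' @param precursor Precursor peptide, starting with M.
#' @param min_len,max_len Cleavage-site search range.
#' @return `c(1, cleavage_position)` or `NULL` when no core or no
#'   acceptable site is found.
#' @export
predict_signal <- function(precursor, min_len = 15L, max_len = 40L) {
  aa <- strsplit(toupper(precursor), "", fixed = TRUE)[[1]]
  if (length(aa) < min_len || aa[1] != "M") return(NULL)
  upto <- min(max_len, length(aa))
  kd <- unname(KD_SCALE[aa[seq_len(upto)]])
  kd[is.na(kd)] <- 0
  has_core <- FALSE
  if (upto >= 6L) {
    run_means <- vapply(seq_len(upto - 5L),
                        function(i) mean(kd[i:(i + 5L)]), numeric(1))
    has_core <- any(run_means >= 1.5)
  }
  if (!has_core) return(NULL)
  for (p in seq.int(min_len, min(upto, length(aa) - 1L))) {
    if (aa[p] %in% SMALL_CLEAVAGE_SET && aa[p - 2L] %in% SMALL_CLEAVAGE_SET) {
      return(c(1L, p))
    }
  }
  NULL
}

#' Test a segment for the acidic propeptide rule
#'
#' A propeptide is called when the segment has negative net charge at
#' pH 7.0 and terminates in one or two basic residues
#' (K, R, KR or RR) marking a proprotein-convertase cleavage site.
#'
#' @param segment Peptide segment between signal end and the first
#'   framework cysteine region (case-insensitive).
#' @return List with `is_propeptide` and `cleave_after` (position of the
#'   last basic residue within the segment, `NA` if not a propeptide).
#' @examples
#' detect_propeptide("EEDDAASLEKR")  # TRUE, cleave after 11
#' detect_propeptide("GGSSGG")       # FALSE
#' @export
detect_propeptide <- function(segment) {
  seg <- toupper(segment)
  if (!nzchar(seg)) return(list(is_propeptide = FALSE, cleave_after = NA_integer_))
  last <- substr(seg, nchar(seg), nchar(seg))
  ends_basic <- last %in% c("K", "R")
  acidic <- ends_basic && net_charge(seg, 7.0) < 0
  list(is_propeptide = acidic,
       cleave_after = if (acidic) nchar(seg) else NA_integer_)
}

#' Detect a C-terminal amidation signal
#'
#' A domain at the precursor C-terminus ending in Gly-Arg or Gly-Arg-Arg
#' is flagged as amidated; the arginine(s) are trimmed and the glycine is
#' retained as the amide donor.
#'
#' @param domain_with_tail Peptide of the terminal domain.
#' @return List with `amidated` and `trimmed` (sequence).
#' @examples
#' detect_amidation("KCYGR")  # amidated, trimmed "KCYG"
#' @export
detect_amidation <- function(domain_with_tail) {
  s <- toupper(domain_with_tail)
  if (grepl("GRR$", s)) {
    list(amidated = TRUE, trimmed = substr(s, 1L, nchar(s) - 2L))
  } else if (grepl("GR$", s)) {
    list(amidated = TRUE, trimmed = substr(s, 1L, nchar(s) - 1L))
  } else {
    list(amidated = FALSE, trimmed = s)
  }
}

# positions of six-cysteine frameworks among cysteine positions `cys`
find_frameworks <- function(cys, envelope = DEFAULT_CYS_ENVELOPE) {
  frameworks <- list()
  i <- 1L
  while (i + 5L <= length(cys)) {
    gaps <- diff(cys[i:(i + 5L)]) - 1L
    if (all(gaps >= envelope[, "min"] & gaps <= envelope[, "max"])) {
      frameworks[[length(frameworks) + 1L]] <- cys[i:(i + 5L)]
      i <- i + 6L
    } else {
      i <- i + 1L
    }
  }
  frameworks
}

#' Segment a defensin precursor
#'
#' Full segmentation: signal peptide ([predict_signal()] or a supplied
#' cleavage position), optional acidic propeptide, one or two mature
#' domains (two when two six-cysteine frameworks are separated by a spacer
#' satisfying [detect_propeptide()]), amidation, and N-/C-terminal
#' extension flags (a >= 15-residue segment before C1 that is not a
#' propeptide; a >= 8-residue tail after C6 with >= 40% R/P/G).
#'
#' @param precursor Precursor peptide string.
#' @param signal_end Optional known signal cleavage position overriding
#'   the heuristic.
#' @param envelope Inter-cysteine gap bounds used to locate frameworks.
#' @return Object of class `defensin_precursor`: `full`, `signal`,
#'   `propeptides`, `domains` (intervals with N/C tags), `matures` (named
#'   character: processed sequences, amidation-trimmed), `amidated`,
#'   `n_extension`, `c_extension`.
#' @export
annotate_precursor <- function(precursor, signal_end = NULL,
                               envelope = DEFAULT_CYS_ENVELOPE) {
  full <- toupper(precursor)
  aa <- strsplit(full, "", fixed = TRUE)[[1]]
  if (is.null(signal_end)) {
    sig <- predict_signal(full)
    if (is.null(sig)) {
      return(structure(list(full = full, signal = NULL, propeptides = list(),
                            domains = list(), matures = character(),
                            amidated = logical(), n_extension = NULL,
                            c_extension = NULL),
                       class = "defensin_precursor"))
    }
    signal_end <- sig[2]
  }
  cys <- which(aa == "C" & seq_along(aa) > signal_end)
  fw <- find_frameworks(cys, envelope)
  if (length(fw) > 2L) {
    stop_fmt("unsupported architecture: %d cysteine frameworks", length(fw))
  }
  propeptides <- list()
  domains <- list()
  matures <- character()
  amidated <- logical()
  n_extension <- NULL
  c_extension <- NULL

  if (length(fw) >= 1L) {
    c1 <- fw[[1]][1]
    # propeptide: longest prefix of the pre-C1 segment ending at its
    # rightmost basic residue and passing the acidic rule
    seg_end <- c1 - 1L
    dom_start <- signal_end + 1L
    if (seg_end > signal_end) {
      basics <- which(aa %in% c("K", "R") &
                      seq_along(aa) > signal_end & seq_along(aa) <= seg_end)
      if (length(basics)) {
        p <- max(basics)
        seg <- substr(full, signal_end + 1L, p)
        if (detect_propeptide(seg)$is_propeptide) {
          propeptides <- c(propeptides, list(c(signal_end + 1L, p)))
          dom_start <- p + 1L
        }
      }
      if (dom_start == signal_end + 1L && (c1 - 1L - signal_end) >= 15L) {
        n_extension <- c(signal_end + 1L, c1 - 1L)
      }
    }

    two_dom <- FALSE
    if (length(fw) == 2L) {
      gap_start <- fw[[1]][6] + 1L
      gap_end <- fw[[2]][1] - 1L
      basics <- which(aa %in% c("K", "R") &
                      seq_along(aa) >= gap_start & seq_along(aa) <= gap_end)
      if (length(basics)) {
        p2 <- max(basics)
        spacer <- substr(full, gap_start, p2)
        if (detect_propeptide(spacer)$is_propeptide) {
          two_dom <- TRUE
          domains <- list(N = c(dom_start, fw[[1]][6]),
                          C = c(p2 + 1L, length(aa)))
          propeptides <- c(propeptides, list(c(gap_start, p2)))
          am <- detect_amidation(substr(full, p2 + 1L, length(aa)))
          matures <- c(N = substr(full, dom_start, fw[[1]][6]),
                       C = am$trimmed)
          amidated <- c(N = FALSE, C = am$amidated)
        }
      }
    }
    if (!two_dom) {
      domains <- list(N = c(dom_start, length(aa)))
      am <- detect_amidation(substr(full, dom_start, length(aa)))
      matures <- c(N = am$trimmed)
      amidated <- c(N = am$amidated)
      c6 <- fw[[1]][6]
      tail_len <- nchar(matures[["N"]]) - (c6 - dom_start + 1L)
      if (tail_len >= 8L) {
        tail_seq <- substr(matures[["N"]], c6 - dom_start + 2L,
                           nchar(matures[["N"]]))
        rpg <- sum(strsplit(tail_seq, "")[[1]] %in% c("R", "P", "G"))
        if (rpg / nchar(tail_seq) >= 0.4) {
          c_extension <- c(c6 + 1L, length(aa))
        }
      }
    }
  }
  structure(list(full = full, signal = c(1L, signal_end),
                 propeptides = propeptides, domains = domains,
                 matures = matures, amidated = amidated,
                 n_extension = n_extension, c_extension = c_extension),
            class = "defensin_precursor")
}

#' Architecture class of a segmented precursor
#' @param anno A `defensin_precursor` from [annotate_precursor()].
#' @return `"two_domain"`, `"pro_mature"`, `"no_pro"` or `"unsegmented"`.
#' @export
architecture_class <- function(anno) {
  if (is.null(anno$signal) || length(anno$domains) == 0L) return("unsegmented")
  if (length(anno$domains) == 2L) return("two_domain")
  if (length(anno$propeptides) >= 1L) return("pro_mature")
  "no_pro"
}

#' Mature-domain split of a segmented precursor
#'
#' Convenience accessor mirroring the two-domain release rule: returns the
#' mature intervals tagged N (and C for two-domain precursors).
#'
#' @param anno A `defensin_precursor`.
#' @return Named list of `c(start, end)` intervals.
#' @export
split_domains <- function(anno) {
  stopifnot(inherits(anno, "defensin_precursor"))
  anno$domains
}

#' @export
print.defensin_precursor <- function(x, ...) {
  cat(sprintf("defensin_precursor (%d aa, %s)\n", nchar(x$full),
              architecture_class(x)))
  if (!is.null(x$signal)) {
    cat(sprintf("  signal 1-%d\n", x$signal[2]))
  }
  for (p in x$propeptides) cat(sprintf("  propeptide %d-%d\n", p[1], p[2]))
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    cat(sprintf("  domain %s %d-%d%s\n", names(x$domains)[i], d[1], d[2],
                if (x$amidated[i]) " (amidated)" else ""))
  }
  invisible(x)
}
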