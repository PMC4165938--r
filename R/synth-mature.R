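# Synthetic mature-peptide generation. Each family template fixes the
# six-cysteine CSab framework spacing; sampled peptides mutate loop
# positions only, so every generated mature keeps exactly six framework
# cysteines and its family's inter-cysteine spacing.

# Segments: pre (N-terminus before C1), g1..g5 (inter-cysteine loops),
# tail (after C6). Pre-C1 and tail composition is constrained so that
# precursor segmentation on synthetic genes is unambiguous: no K/R before
# C1 (no spurious propeptide cleavage) and no terminal R on unamidated
# matures (no spurious Gly-Arg amidation call).
FAMILY_TEMPLATES <- list(
  fDEF1 = list(pre = "GFG", g1 = "NGPWDEDDMQ", g2 = "HNH",
               g3 = "KSIKGYKGGY", g4 = "AKGGFV", g5 = "K", tail = "Y"),
  fDEF2 = list(pre = "ATY", g1 = "HSDPWGNNLA", g2 = "EGH",
               g3 = "RTFGGYGGGQ", g4 = "SNHFT", g5 = "N", tail = "GA"),
  fDEF3 = list(pre = "QV", g1 = "WGSNDAAQ", g2 = "AAH",
               g3 = "YTSGGYRGGY", g4 = "NQHYM", g5 = "T", tail = "NG"),
  fDEF4 = list(pre = "SFHA", g1 = "LSGGIDNDHS", g2 = "TWH",
               g3 = "ASPFNGGHAQ", g4 = "GFLHG", g5 = "E", tail = "WS"),
  fDEF6 = list(pre = "GH", g1 = "IKGWRNDALS", g2 = "KRH",
               g3 = "GKSYKGRYGG", g4 = "KRGFK", g5 = "K", tail = "GK"),
  fDEF8 = list(pre = "AQ", g1 = "FHGWDNEHLA", g2 = "NGH",
               g3 = "YSPIKGYAGG", g4 = "QWNFG", g5 = "S", tail = "GRPG")
)

# mutation pools; never C (framework must stay at exactly six cysteines)
POOL_LOOP <- setdiff(AA_STANDARD, "C")
POOL_PRE <- setdiff(AA_STANDARD, c("C", "K", "R"))
POOL_TAIL_LAST <- setdiff(AA_STANDARD, c("C", "R"))

#' Family names of the synthetic mature-peptide templates
#' @return Character vector of template names.
#' @export
family_templates <- function() names(FAMILY_TEMPLATES)

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mutate_segment <- function(seg, pool, rate, last_pool = NULL) {
  ch <- strsplit(seg, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return("")
  hit <- stats::runif(length(ch)) < rate
  for (i in which(hit)) {
    p <- if (!is.null(last_pool) && i == length(ch)) last_pool else pool
    ch[i] <- sample_one(setdiff(p, ch[i]))
  }
  paste0(ch, collapse = "")
}

#' Generate a synthetic mature defensin
#'
#' Samples a mature peptide from a family template: the six framework
#' cysteines and their spacing are fixed, loop residues are mutated at
#' `mut_rate`. Output length lies in the catalog size range (33-60 aa) and
#' is identical for identical seeds.
#'
#' @param seed Integer seed; same seed, same peptide.
#' @param family_template One of [family_templates()].
#' @param mut_rate Per-position substitution probability in loops.
#' @return Mature peptide string with exactly six cysteines.
#' @export
generate_mature <- function(seed, family_template = "fDEF1",
                            mut_rate = 0.25) {
  if (!family_template %in% names(FAMILY_TEMPLATES)) {
    stop_fmt("unknown family template '%s'", family_template)
  }
  tpl <- FAMILY_TEMPLATES[[family_template]]
  with_seed(seed, {
    paste0(
      mutate_segment(tpl$pre, POOL_PRE, mut_rate), "C",
      mutate_segment(tpl$g1, POOL_LOOP, mut_rate), "C",
      mutate_segment(tpl$g2, POOL_LOOP, mut_rate), "C",
      mutate_segment(tpl$g3, POOL_LOOP, mut_rate), "C",
      mutate_segment(tpl$g4, POOL_LOOP, mut_rate), "C",
      mutate_segment(tpl$g5, POOL_LOOP, mut_rate), "C",
      mutate_segment(tpl$tail, POOL_LOOP, mut_rate, last_pool = POOL_TAIL_LAST)
    )
  })
}

#' Seed set of mature defensins used by the genome scan
#'
#' Reads the packaged seed FASTA: the published mature sequence of
#' plectasin plus one synthetic anchor per family template (generated by
#' [generate_mature()]; synthetic stand-ins, not published sequences).
#'
#' @param path Seed FASTA path; defaults to the packaged set.
#' @return Data frame with `name`, `family`, `seq`.
#' @export
seed_anchor_set <- function(path = system.file("extdata",
                                               "seed_anchors_synthetic.faa",
                                               package = "fdlpminer",
                                               mustWork = TRUE)) {
  rec <- read_fasta(path, moltype = "protein")
  data.frame(name = rec$id,
             family = sub("^family=", "", rec$desc),
             seq = rec$seq, stringsAsFactors = FALSE)
}
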