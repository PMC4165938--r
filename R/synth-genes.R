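# Synthetic genome generation: plants defensin genes with known precursor
# architectures, GT-AG introns at planned regions/phases, tandem clusters,
# pseudogenes and synonymous paralog pairs into random-background contigs,
# and records a machine-readable truth table.

SMALL_CLEAVAGE_SET <- c("A", "G", "S", "C", "T", "V")

# 5' leader with stop codons in all three frames (and, being its own
# reverse complement, on both strands): terminates any reading frame
# running into a planted gene from the flanking background, so the
# planted ATG is the unambiguous ORF start.
ORF_GUARD <- "TTAATTAATTAA"

#' Build a validated gene-planting specification
#'
#' @param genes Data frame of per-gene plans with columns `id`, `family`
#'   (template for the single/N-terminal domain), `family_c` (C-terminal
#'   domain template, `NA` unless two-domain), `architecture`
#'   (`no_pro`/`pro_mature`/`two_domain`), `introns` (plan string like
#'   `"alpha_helix:0,c_loop:2"`, `""` for none; regions `signal`,
#'   `alpha_helix`, `c_loop`), `amidation`, `pseudogene` (logicals),
#'   `strand` (`+`/`-`), `contig` (placement label; shared label = tandem
#'   cluster), `syn_pair_of` (id of an earlier gene to copy with synonymous
#'   changes only, else `NA`), `syn_count` (number of synonymous
#'   substitutions for such copies).
#' @param gc Intergenic/intron GC fraction.
#' @param seed Integer seed; generation is byte-identical per seed.
#' @param intergenic_len Length range (bp) of intergenic spacers.
#' @param intron_len Length range (bp) of planted introns.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(genes, gc = 0.48, seed = 1,
                       intergenic_len = c(500L, 5000L),
                       intron_len = c(60L, 300L)) {
  stopifnot(gc >= 0, gc <= 1, is.data.frame(genes), nrow(genes) >= 1)
  need <- c("id", "family", "family_c", "architecture", "introns",
            "amidation", "pseudogene", "strand", "contig",
            "syn_pair_of", "syn_count")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop_fmt("gene plan lacks column(s): %s",
                             paste(miss, collapse = ", "))
  bad <- setdiff(genes$architecture, c("no_pro", "pro_mature", "two_domain"))
  if (length(bad)) stop_fmt("unknown architecture '%s'", bad[1])
  for (pl in genes$introns) {
    for (iv in parse_intron_plan(pl)) {
      if (!iv$region %in% c("signal", "alpha_helix", "c_loop")) {
        stop_fmt("unsupported intron region '%s'", iv$region)
      }
      if (!iv$phase %in% 0:2) stop_fmt("intron phase must be 0, 1 or 2")
    }
  }
  structure(list(genes = genes, gc = gc, seed = as.integer(seed),
                 intergenic_len = as.integer(intergenic_len),
                 intron_len = as.integer(intron_len)),
            class = "plant_spec")
}

parse_intron_plan <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    list(region = kv[1], phase = as.integer(kv[2]))
  })
}

#' Randomised planting specification spanning all architectures
#'
#' Builds a standard study mix: ~40% intronless genes, one- and two-intron
#' genes in the alpha-helix/c-loop regions (the two-intron genes use the
#' dermatophyte phase-0/phase-2 pattern), a few signal-peptide introns,
#' `no_pro`/`pro_mature`/`two_domain` precursors, C-terminally amidated
#' genes, tandem clusters of 4 and 7 genes, `n_pseudo` exon-1-only
#' pseudogenes and `n_syn_pairs` identical-protein paralog pairs with
#' `syn_count` synonymous substitutions.
#'
#' @param n_genes Total genes planted (pseudogenes and paralog copies
#'   included).
#' @param seed Integer seed.
#' @param n_pseudo Number of pseudogenes.
#' @param n_syn_pairs Number of synonymous paralog pairs.
#' @param syn_count Synonymous substitutions per paralog pair.
#' @param gc Background GC fraction.
#' @return A `plant_spec`.
#' @export
random_plant_spec <- function(n_genes = 50, seed = 1, n_pseudo = 2,
                              n_syn_pairs = 1, syn_count = 4, gc = 0.48) {
  stopifnot(n_genes >= n_pseudo + 2 * n_syn_pairs + 5)
  with_seed(seed + 77L, {
    n_coding <- n_genes - n_pseudo
    n_base <- n_coding - n_syn_pairs  # paralog copies mirror their partner
    fams <- sample(family_templates(), n_base, replace = TRUE)
    arch <- sample(c("no_pro", "pro_mature", "two_domain"), n_base,
                   replace = TRUE, prob = c(0.30, 0.55, 0.15))
    intron_choices <- c("", "alpha_helix:0", "c_loop:0", "c_loop:2",
                        "alpha_helix:0,c_loop:2", "signal:0", "signal:1")
    intr <- sample(intron_choices, n_base, replace = TRUE,
                   prob = c(0.38, 0.12, 0.06, 0.08, 0.26, 0.05, 0.05))
    amid <- stats::runif(n_base) < 0.2
    ids <- sprintf("synfdlp%02d", seq_len(n_base))
    genes <- data.frame(
      id = ids, family = fams,
      family_c = ifelse(arch == "two_domain",
                        sample(family_templates(), n_base, replace = TRUE),
                        NA_character_),
      architecture = arch, introns = intr, amidation = amid,
      pseudogene = FALSE, strand = sample(c("+", "-"), n_base, replace = TRUE),
      contig = NA_character_, syn_pair_of = NA_character_,
      syn_count = 0L, stringsAsFactors = FALSE
    )
    if (n_syn_pairs > 0) {
      partners <- sample(which(!genes$pseudogene), n_syn_pairs)
      copies <- genes[partners, , drop = FALSE]
      copies$id <- sprintf("synfdlp%02d", n_base + seq_len(n_syn_pairs))
      copies$syn_pair_of <- genes$id[partners]
      copies$syn_count <- as.integer(syn_count)
      genes <- rbind(genes, copies)
    }
    if (n_pseudo > 0) {
      # pseudogenes are findable only through first-exon similarity, so
      # they are planted in the plectasin/micasin-like families whose
      # exon 1 retains the longest recognisable fragment
      pse <- data.frame(
        id = sprintf("synpseudo%02d", seq_len(n_pseudo)),
        family = sample(c("fDEF1", "fDEF2", "fDEF4"), n_pseudo,
                        replace = TRUE),
        family_c = NA_character_, architecture = "pro_mature",
        introns = "alpha_helix:0", amidation = FALSE, pseudogene = TRUE,
        strand = sample(c("+", "-"), n_pseudo, replace = TRUE),
        contig = NA_character_, syn_pair_of = NA_character_,
        syn_count = 0L, stringsAsFactors = FALSE
      )
      genes <- rbind(genes, pse)
    }
    # tandem clusters of 4 and 7 (malpisin-style layouts), rest singletons
    n <- nrow(genes)
    ord <- sample(n)
    genes <- genes[ord, , drop = FALSE]
    contig <- sprintf("ctg%03d", seq_len(n))
    take <- seq_len(min(4, n)); contig[take] <- "ctg_cluster_a"
    if (n >= 11) contig[5:11] <- "ctg_cluster_b"
    genes$contig <- contig
    genes <- genes[order(genes$contig, method = "radix"), , drop = FALSE]
    rownames(genes) <- NULL
    plant_spec(genes, gc = gc, seed = seed)
  })
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

make_signal_peptide <- function() {
  n <- sample(16:22, 1L)
  mid_pool <- c("L", "P", "H", "Q", "W", "M")
  ch <- character(n)
  ch[1] <- "M"
  ch[2] <- sample_one(c("K", "R", "N"))
  ch[3:13] <- sample(c("L", "I", "F"), 11L, replace = TRUE)
  if (n - 3L >= 14L) {
    ch[14:(n - 3L)] <- sample(mid_pool, n - 16L, replace = TRUE)
  }
  ch[n - 2L] <- "A"
  ch[n - 1L] <- sample_one(mid_pool)
  ch[n] <- sample_one(c("A", "G", "S"))
  paste0(ch, collapse = "")
}

# acidic segment ending in K/R/KR/RR; interior free of basic residues so
# the proprotein-convertase site is the unique rightmost basic position
make_propeptide_seg <- function() {
  len_body <- sample(6:12, 1L)
  term <- sample_one(c("K", "R", "KR", "RR"))
  n_acid <- min(nchar(term) + 2L + sample(0:2, 1L), len_body)
  ch <- sample(c("A", "S", "L", "Q", "G", "T", "N"), len_body, replace = TRUE)
  ch[sample.int(len_body, n_acid)] <- sample(c("D", "E"), n_acid,
                                             replace = TRUE)
  paste0(paste0(ch, collapse = ""), term)
}

# uniform random synonymous back-translation (standard nuclear code)
back_translate <- function(aa) {
  tab <- codon_table()
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(a) {
    sample_one(names(tab)[tab == a])
  }, character(1))
  paste0(codons, collapse = "")
}

synonymous_variants_1nt <- function(codon) {
  tab <- codon_table()
  aa <- tab[[codon]]
  nts <- c("A", "C", "G", "T")
  out <- character()
  for (i in 1:3) {
    for (b in setdiff(nts, substr(codon, i, i))) {
      v <- codon
      substr(v, i, i) <- b
      if (tab[[v]] == aa) out <- c(out, v)
    }
  }
  out
}

# Construct one gene: precursor, segmentation, CDS, intron placement and
# the sense-strand genomic cassette with local exon coordinates.
build_gene <- function(plan, spec) {
  arch <- plan$architecture
  signal <- make_signal_peptide()
  sig_end <- nchar(signal)

  pro_seg <- NULL
  if (arch == "pro_mature") pro_seg <- make_propeptide_seg()

  # pseudogenes are planted as recent, minimally-diverged duplicates:
  # only the retained first exon makes them findable, and that requires
  # the high similarity to a known defensin reported for such loci
  dom1_rate <- if (isTRUE(plan$pseudogene)) 0.05 else 0.25
  dom1 <- generate_mature(sample.int(.Machine$integer.max, 1L), plan$family,
                          mut_rate = dom1_rate)
  dom2 <- NULL
  spacer <- NULL
  if (arch == "two_domain") {
    # N-terminal domain is trimmed at its final framework cysteine
    c6 <- char_positions(dom1, "C")[6]
    dom1 <- substr(dom1, 1L, c6)
    spacer <- make_propeptide_seg()
    dom2 <- generate_mature(sample.int(.Machine$integer.max, 1L),
                            plan$family_c)
  }
  terminal_dom <- if (arch == "two_domain") dom2 else dom1
  amid_tail <- ""
  if (isTRUE(plan$amidation)) {
    terminal_dom <- paste0(terminal_dom, "G")
    amid_tail <- sample_one(c("R", "RR"))
  }
  if (arch == "two_domain") dom2 <- terminal_dom else dom1 <- terminal_dom

  parts <- c(signal, pro_seg,
             dom1,
             if (arch == "two_domain") c(spacer, dom2))
  precursor <- paste0(parts, collapse = "")

  # precursor-coordinate segmentation
  cur <- sig_end
  propeptides <- list()
  if (!is.null(pro_seg)) {
    propeptides <- c(propeptides, list(c(cur + 1L, cur + nchar(pro_seg))))
    cur <- cur + nchar(pro_seg)
  }
  d1 <- c(cur + 1L, cur + nchar(dom1))
  cur <- d1[2]
  d2 <- NULL
  if (arch == "two_domain") {
    propeptides <- c(propeptides, list(c(cur + 1L, cur + nchar(spacer))))
    cur <- cur + nchar(spacer)
    d2 <- c(cur + 1L, cur + nchar(dom2))
    cur <- d2[2]
  }

  # intron placement windows keyed off the first domain's cysteines
  cys1 <- d1[1] - 1L + char_positions(dom1, "C")
  plan_introns <- parse_intron_plan(plan$introns)
  offsets <- integer(0)
  phases <- integer(0)
  regions <- character(0)
  for (iv in plan_introns) {
    window <- switch(iv$region,
      signal = seq.int(2L, sig_end - 1L),
      alpha_helix = if (isTRUE(plan$pseudogene)) {
        # keep C1..C2 and most of the helix in exon 1: a pseudogene is
        # only discoverable through its retained first-exon similarity
        seq.int(cys1[3] - 1L, cys1[3])
      } else seq.int(cys1[2] - 2L, cys1[3]),
      c_loop = seq.int(cys1[4] + 1L, cys1[5] - 1L)
    )
    if (length(window) == 0L) {
      stop_fmt("infeasible intron plan for gene '%s': empty %s window",
               plan$id, iv$region)
    }
    k <- sample_one(window)
    offsets <- c(offsets, 3L * (k - 1L) + iv$phase)
    phases <- c(phases, iv$phase)
    regions <- c(regions, iv$region)
  }
  ord <- order(offsets)
  offsets <- offsets[ord]; phases <- phases[ord]; regions <- regions[ord]
  if (any(diff(offsets) < 9L)) {
    stop_fmt("infeasible intron plan for gene '%s': introns too close",
             plan$id)
  }

  cds <- paste0(back_translate(precursor),
                sample_one(c("TAA", "TAG", "TGA")))

  list(id = plan$id, precursor = precursor, cds = cds,
       sig_end = sig_end, propeptides = propeptides,
       domains = if (is.null(d2)) list(d1) else list(d1, d2),
       matures = if (is.null(dom2)) c(N = dom1) else c(N = dom1, C = dom2),
       amidation = isTRUE(plan$amidation),
       intron_offsets = offsets, intron_phases = phases,
       intron_regions = regions, architecture = arch,
       pseudogene = isTRUE(plan$pseudogene))
}

# turn CDS + intron offsets into a sense-strand cassette and local exons
assemble_cassette <- function(gene, spec) {
  cds <- gene$cds
  offs <- gene$intron_offsets
  n_ex <- length(offs) + 1L
  bounds <- c(0L, offs, nchar(cds))
  exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- character(0)
  if (length(offs)) {
    lens <- sample(seq.int(spec$intron_len[1], spec$intron_len[2]),
                   length(offs), replace = TRUE)
    # guard blocks (stops in every frame, no internal GT/AG) flank the
    # intron interior so that mis-spliced variants reading into the
    # intron always hit a stop: the planted junctions are the only ones
    # yielding a stop-free ORF
    introns <- vapply(lens, function(L) {
      paste0("GT", ORF_GUARD, random_dna(L - 4L - 2L * nchar(ORF_GUARD),
                                         spec$gc), ORF_GUARD, "AG")
    }, character(1))
  }
  guard <- nchar(ORF_GUARD)
  if (gene$pseudogene) {
    # exon 1 and a decaying intron only: the downstream exons are lost
    cassette <- paste0(ORF_GUARD, exon_seqs[1], "GT",
                       random_dna(180L, spec$gc))
    local <- data.frame(start = guard + 1L,
                        end = guard + nchar(exon_seqs[1]))
    return(list(cassette = cassette, exons_local = local))
  }
  pieces <- ORF_GUARD
  local <- data.frame(start = integer(n_ex), end = integer(n_ex))
  pos <- guard
  for (i in seq_len(n_ex)) {
    local$start[i] <- pos + 1L
    pos <- pos + nchar(exon_seqs[i])
    local$end[i] <- pos
    pieces <- c(pieces, exon_seqs[i])
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(cassette = paste0(pieces, collapse = ""), exons_local = local)
}

apply_synonymous_copy <- function(gene, partner, n_sub) {
  cds <- partner$cds
  offs <- partner$intron_offsets
  # mature-region codons (first domain) not split by an intron
  d1 <- partner$domains[[1]]
  cand <- seq.int(d1[1], d1[2])
  cand <- cand[vapply(cand, function(j) {
    !any(offs %in% c(3L * j - 2L, 3L * j - 1L))
  }, logical(1))]
  cand <- cand[vapply(cand, function(j) {
    length(synonymous_variants_1nt(substr(cds, 3L * j - 2L, 3L * j))) > 0
  }, logical(1))]
  if (length(cand) < n_sub) {
    stop_fmt("cannot place %d synonymous substitutions in gene '%s'",
             n_sub, gene$id)
  }
  picks <- sample(cand, n_sub)
  for (j in picks) {
    codon <- substr(cds, 3L * j - 2L, 3L * j)
    substr(cds, 3L * j - 2L, 3L * j) <-
      sample_one(synonymous_variants_1nt(codon))
  }
  out <- partner
  out$id <- gene$id
  out$cds <- cds
  out
}

#' Plant defensin genes into synthetic contigs
#'
#' Generates every gene of a [plant_spec()], assembles contigs with
#' random intergenic background at the requested GC, and returns the
#' contigs plus a truth table recording, per planted gene: coordinates,
#' strand, exon structure, intron phases and regions, precursor
#' segmentation, mature peptide sequence(s), amidation, cluster and
#' pseudogene status. Regeneration with the same spec is byte-identical.
#'
#' @param spec A `plant_spec`.
#' @return List with `contigs` (named character vector of DNA sequences),
#'   `truth` (data frame, one row per gene) and `models` (list of
#'   [gene_model()] objects for non-pseudogene genes; pseudogenes carry
#'   their exon-1 model).
#' @export
plant_genes <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    plans <- spec$genes
    built <- list()
    build_order <- order(!is.na(plans$syn_pair_of))  # partners first
    for (i in build_order) {
      plan <- as.list(plans[i, ])
      if (!is.na(plan$syn_pair_of)) {
        partner <- built[[plan$syn_pair_of]]
        if (is.null(partner)) {
          stop_fmt("syn_pair_of '%s' does not name a planted gene",
                   plan$syn_pair_of)
        }
        built[[plan$id]] <- apply_synonymous_copy(plan, partner,
                                                  plan$syn_count)
      } else {
        built[[plan$id]] <- build_gene(plan, spec)
      }
    }
    contigs <- character(0)
    truth_rows <- list()
    models <- list()
    for (ctg in unique(plans$contig)) {
      idx <- which(plans$contig == ctg)
      parts <- character(0)
      pos <- 0L
      for (i in idx) {
        gene <- built[[plans$id[i]]]
        cass <- assemble_cassette(gene, spec)
        gap <- sample(seq.int(spec$intergenic_len[1],
                              spec$intergenic_len[2]), 1L)
        parts <- c(parts, random_dna(gap, spec$gc))
        pos <- pos + gap
        strand <- plans$strand[i]
        L <- nchar(cass$cassette)
        gene_start <- pos + 1L
        seq_out <- if (strand == "+") cass$cassette else revcomp(cass$cassette)
        parts <- c(parts, seq_out)
        pos <- pos + L
        loc <- cass$exons_local
        if (strand == "+") {
          ex <- data.frame(start = gene_start - 1L + loc$start,
                           end = gene_start - 1L + loc$end)
        } else {
          ex <- data.frame(start = gene_start + (L - loc$end),
                           end = gene_start + (L - loc$start))
          ex <- ex[order(ex$start), , drop = FALSE]
        }
        gm <- gene_model(gene$id, ctg, strand, ex)
        models[[gene$id]] <- gm
        n_clustered <- length(idx)
        truth_rows[[gene$id]] <- data.frame(
          gene_id = gene$id, contig = ctg, strand = strand,
          gene_start = gene_start, gene_end = gene_start + L - 1L,
          exon_starts = paste(gm$exons$start, collapse = ","),
          exon_ends = paste(gm$exons$end, collapse = ","),
          n_introns = length(gene$intron_offsets),
          intron_phases = paste(gene$intron_phases, collapse = ","),
          intron_regions = paste(gene$intron_regions, collapse = ","),
          architecture = gene$architecture,
          signal_len = gene$sig_end,
          mature_n = unname(gene$matures["N"]),
          mature_c = if ("C" %in% names(gene$matures))
            unname(gene$matures["C"]) else NA_character_,
          amidation = gene$amidation,
          cluster = if (n_clustered > 1L) ctg else NA_character_,
          pseudogene = gene$pseudogene,
          precursor = gene$precursor,
          cds = gene$cds,
          stringsAsFactors = FALSE
        )
      }
      parts <- c(parts, random_dna(sample(seq.int(spec$intergenic_len[1],
                                                  spec$intergenic_len[2]),
                                          1L), spec$gc))
      contigs[[ctg]] <- paste0(parts, collapse = "")
    }
    truth <- do.call(rbind, truth_rows[plans$id])
    rownames(truth) <- NULL
    list(contigs = contigs, truth = truth, models = models[plans$id])
  })
}

#' Write a synthetic genome to disk
#'
#' Emits contig FASTA, gene-model GFF3 and the truth table TSV.
#'
#' @param genome Result of [plant_genes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$contigs, file.path(dir, "contigs.fna"))
  write_gff3(genome$models, file.path(dir, "genes.gff3"))
  utils::write.table(genome$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
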