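# End-to-end orchestration: scan -> spliced completion -> precursor
# annotation -> physicochemistry -> family classification -> duplication
# analysis, plus catalog tallies.

#' Run the full fDLP discovery pipeline
#'
#' Scans contigs for candidate defensin loci, completes spliced gene
#' models, segments precursors, computes mature-peptide size/MW/net
#' charge, classifies peptides against the seed anchors with a
#' bootstrapped NJ tree, and reports tandem clusters and paralog pairs.
#' Deterministic given `seed`.
#'
#' @param contigs Named character vector of contig DNA sequences, or a
#'   path to a nucleotide FASTA.
#' @param profile A [seed_profile()].
#' @param seed Integer seed (bootstrap resampling).
#' @param pH pH for net-charge estimation.
#' @param max_gap Tandem-cluster gap limit (bp).
#' @param bootstrap_reps Bootstrap replicates for the family tree.
#' @param out_dir Optional directory; when given, writes `peptides.tsv`,
#'   `genes.gff3`, `tree.nwk`, `clusters.tsv`, `pairs.tsv`,
#'   `pseudogenes.tsv` and `summary.tsv`.
#' @return List with `loci`, `genes`, `models`, `peptides`,
#'   `pseudogenes`, `tree`, `support`, `clusters`, `pairs`, `summary`.
#' @export
run_pipeline <- function(contigs, profile = seed_profile(), seed = 1L,
                         pH = 7.0, max_gap = 30000L, bootstrap_reps = 200L,
                         out_dir = NULL) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    rec <- read_fasta(contigs, moltype = "dna")
    contigs <- stats::setNames(rec$seq, rec$id)
  }
  stopifnot(!is.null(names(contigs)))

  loci <- do.call(rbind, lapply(names(contigs), function(ctg) {
    scan_six_frames(contigs[[ctg]], profile, contig_id = ctg)
  }))
  message(sprintf("scan: %d candidate locus/loci on %d contig(s)",
                  if (is.null(loci)) 0L else nrow(loci), length(contigs)))
  if (is.null(loci) || nrow(loci) == 0L) {
    return(empty_pipeline_result())
  }

  models <- list()
  gene_rows <- list()
  pep_rows <- list()
  pseudo_rows <- list()
  matures <- character()
  cds_by_gene <- character()
  contig_by_pep <- character()

  seen_models <- character(0)
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    gid <- sprintf("fdlp_%s_%07d", locus$contig, locus$start)
    gm <- complete_spliced_model(contigs[[locus$contig]], locus, profile,
                                 contig_id = locus$contig, gene_id = gid)
    if (!is.null(gm)) {
      key <- paste(gm$contig, gm$strand,
                   paste(gm$exons$start, gm$exons$end, collapse = ";"))
      if (key %in% seen_models) next
      seen_models <- c(seen_models, key)
      gid <- sprintf("fdlp_%s_%07d", gm$contig, min(gm$exons$start))
      gm$gene_id <- gid
    }
    if (is.null(gm)) {
      # only loci with strong evidence are reported as possible
      # pseudogenes; failed weak-pair loci are dropped
      if (locus$motif || locus$score >= profile$score_min) {
        fl <- flag_pseudogene(list(model = NULL))
        pseudo_rows[[gid]] <- data.frame(
          gene_id = gid, contig = locus$contig, strand = locus$strand,
          start = locus$start, end = locus$end, reason = fl$reason,
          stringsAsFactors = FALSE)
      }
      next
    }
    cds <- cds_sequence(gm, contigs[[locus$contig]])
    prot <- sub("\\*$", "", translate_cds(cds))
    fl <- flag_pseudogene(list(model = gm, protein = prot))
    if (fl$pseudogene) {
      pseudo_rows[[gid]] <- data.frame(
        gene_id = gid, contig = locus$contig, strand = locus$strand,
        start = min(gm$exons$start), end = max(gm$exons$end),
        reason = fl$reason, stringsAsFactors = FALSE)
      next
    }
    anno <- annotate_precursor(prot)
    if (length(anno$matures) == 0L) {
      pseudo_rows[[gid]] <- data.frame(
        gene_id = gid, contig = locus$contig, strand = locus$strand,
        start = min(gm$exons$start), end = max(gm$exons$end),
        reason = "missing_cysteines", stringsAsFactors = FALSE)
      next
    }
    models[[gid]] <- gm
    n_intr <- nrow(gm$exons) - 1L
    phases <- if (n_intr > 0L) {
      vapply(seq_len(n_intr), function(k) intron_phase(gm, k), integer(1))
    } else integer(0)
    regions <- if (n_intr > 0L) {
      vapply(seq_len(n_intr), function(k) localize_intron(gm, anno, k),
             character(1))
    } else character(0)
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, contig = locus$contig, strand = gm$strand,
      start = min(gm$exons$start), end = max(gm$exons$end),
      n_exons = nrow(gm$exons),
      intron_phases = paste(phases, collapse = ","),
      intron_regions = paste(regions, collapse = ","),
      architecture = architecture_class(anno),
      stringsAsFactors = FALSE)
    two_dom <- length(anno$matures) == 2L
    for (tag in names(anno$matures)) {
      pname <- if (two_dom) paste0(gid, tag) else gid
      matures[[pname]] <- unname(anno$matures[[tag]])
      contig_by_pep[[pname]] <- locus$contig
      pep_rows[[pname]] <- data.frame(
        name = pname, gene_id = gid, domain = tag,
        sequence = unname(anno$matures[[tag]]),
        size = nchar(anno$matures[[tag]]),
        mw = round(average_mw(anno$matures[[tag]]), 0),
        nc = round(net_charge(anno$matures[[tag]], pH = pH), 1),
        amidated = unname(anno$amidated[[tag]]),
        stringsAsFactors = FALSE)
    }
    cds_by_gene[[gid]] <- cds
  }
  genes <- do.call(rbind, gene_rows)
  peptides <- do.call(rbind, pep_rows)
  pseudogenes <- do.call(rbind, pseudo_rows)
  message(sprintf("models: %d gene(s), %d mature peptide(s), %d pseudogene(s)",
                  length(models), length(matures),
                  if (is.null(pseudogenes)) 0L else nrow(pseudogenes)))

  # family classification against the seed anchors
  tree <- NULL; support <- NULL
  if (length(matures) >= 1L) {
    anchors <- stats::setNames(profile$seeds$family, profile$seeds$name)
    allpep <- c(stats::setNames(profile$seeds$seq, profile$seeds$name),
                matures)
    am <- align_star(allpep)
    bs <- bootstrap_support(am, n_reps = bootstrap_reps, seed = seed)
    tree <- bs$tree; support <- bs$support
    fam <- vapply(names(matures), function(q) {
      ids <- vapply(profile$seeds$seq, function(s)
        pairwise_identity(matures[[q]], s), numeric(1))
      names(ids) <- profile$seeds$name
      assign_family(tree, anchors, q, support = support, identity = ids)
    }, character(1))
    peptides$family <- unname(fam[peptides$name])
    message(sprintf("classify: %d peptide(s) over %d bootstrap replicates",
                    length(matures), bootstrap_reps))
  }

  clusters <- if (!is.null(genes)) find_clusters(genes, max_gap) else NULL
  pairs <- if (length(matures) >= 2L) {
    paralog_pairs(matures, contigs = unlist(contig_by_pep))
  } else NULL
  if (!is.null(pairs) && nrow(pairs)) {
    pairs$n_synonymous <- NA_integer_
    pairs$n_nonsynonymous <- NA_integer_
    for (r in seq_len(nrow(pairs))) {
      ga <- peptides$gene_id[peptides$name == pairs$a[r]]
      gb <- peptides$gene_id[peptides$name == pairs$b[r]]
      ca <- cds_by_gene[[ga]]; cb <- cds_by_gene[[gb]]
      if (!is.null(ca) && !is.null(cb) && nchar(ca) == nchar(cb)) {
        cnt <- count_synonymous(ca, cb)
        pairs$n_synonymous[r] <- cnt$n_synonymous
        pairs$n_nonsynonymous[r] <- cnt$n_nonsynonymous
      }
    }
  }

  summary <- data.frame(
    n_loci = nrow(loci),
    n_genes = length(models),
    n_peptides = length(matures),
    n_two_domain_genes = if (is.null(genes)) 0L else
      sum(genes$architecture == "two_domain"),
    n_pseudogenes = if (is.null(pseudogenes)) 0L else nrow(pseudogenes),
    n_clusters = if (is.null(clusters)) 0L else
      length(unique(clusters$cluster)),
    stringsAsFactors = FALSE)

  res <- list(loci = loci, genes = genes, models = models,
              peptides = peptides, pseudogenes = pseudogenes,
              tree = tree, support = support, clusters = clusters,
              pairs = pairs, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

empty_pipeline_result <- function() {
  list(loci = NULL, genes = NULL, models = list(), peptides = NULL,
       pseudogenes = NULL, tree = NULL, support = NULL, clusters = NULL,
       pairs = NULL,
       summary = data.frame(n_loci = 0L, n_genes = 0L, n_peptides = 0L,
                            n_two_domain_genes = 0L, n_pseudogenes = 0L,
                            n_clusters = 0L))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    if (is.null(x)) x <- data.frame()
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(res$peptides, "peptides.tsv")
  wt(res$genes, "genes.tsv")
  wt(res$pseudogenes, "pseudogenes.tsv")
  wt(res$clusters, "clusters.tsv")
  wt(res$pairs, "pairs.tsv")
  wt(res$summary, "summary.tsv")
  if (length(res$models)) {
    write_gff3(unname(res$models), file.path(out_dir, "genes.gff3"))
  }
  if (!is.null(res$tree)) {
    tr <- res$tree
    sup <- res$support
    lab <- ifelse(!is.na(sup) & sup >= 50, sprintf("%.0f", sup), "")
    tr$node.label <- lab
    ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
  }
  invisible(out_dir)
}

#' Tally a catalog of mature defensin peptides
#'
#' Computes the headline counts of a peptide catalog: peptides, genes
#' (N/C domain pairs sharing a base name and accession collapse to one
#' two-domain gene), per-phylum, per-family and per-organism counts.
#'
#' @param records Catalog data frame from [load_catalog()].
#' @return List of class `catalog_summary`: `n_peptides`, `n_genes`,
#'   `n_two_domain_genes`, `per_phylum`, `per_family`, `per_organism`,
#'   `n_pseudogenes`.
#' @export
tally_catalog <- function(records) {
  if (nrow(records) == 0L) {
    return(structure(list(n_peptides = 0L, n_genes = 0L,
                          n_two_domain_genes = 0L,
                          per_phylum = table(character()),
                          per_family = table(character()),
                          per_organism = table(character()),
                          n_pseudogenes = 0L),
                     class = "catalog_summary"))
  }
  nc <- grepl("[NC]$", records$name)
  base <- ifelse(nc, sub("[NC]$", "", records$name), records$name)
  tag <- ifelse(nc, substring(records$name, nchar(records$name)), "")
  key <- paste(base, records$accession)
  n_pairs <- 0L
  for (k in unique(key[nc])) {
    tags <- tag[key == k & nc]
    if (all(c("N", "C") %in% tags)) {
      n_pairs <- n_pairs + 1L
    } else {
      warning(sprintf("domain '%s' of '%s' lacks its partner; counted as its own gene",
                      tags[1], k), call. = FALSE)
    }
  }
  structure(list(
    n_peptides = nrow(records),
    n_genes = nrow(records) - n_pairs,
    n_two_domain_genes = n_pairs,
    per_phylum = table(records$phylum),
    per_family = table(records$family),
    per_organism = table(records$organism),
    n_pseudogenes = 0L
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("catalog: %d peptides encoded by %d genes (%d two-domain)\n",
              x$n_peptides, x$n_genes, x$n_two_domain_genes))
  cat("per phylum:\n"); print(x$per_phylum)
  cat("per family:\n"); print(x$per_family)
  invisible(x)
}
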