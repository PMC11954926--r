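#' Controlled vocabulary of per-transcript consequence terms
#'
#' VEP-style consequence terms recognised by the feature aggregation, plus the
#' NMD-escape flag. Unknown terms are either rejected or pooled into an
#' `"other"` bucket depending on the aggregation's `unknown` argument.
#'
#' @return Character vector of consequence terms.
#' @export
consequence_vocabulary <- function() {
  c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
    "splice_donor_variant", "splice_region_variant", "start_lost",
    "stop_lost", "inframe_deletion", "inframe_insertion", "missense_variant",
    "intron_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
    "upstream_gene_variant", "downstream_gene_variant", "synonymous_variant",
    "transcript_ablation", "NMD_escaping")
}

#' Filter variants down to rare, high-quality calls
#'
#' SNVs and short indels are kept when the population minor allele frequency
#' is at most `max_af`, the variant is carried by at most
#' `max_cohort_carriers` cohort individuals, the genotype quality exceeds 30
#' (`genotype_quality >= min_gq` with the default `min_gq = 31`, i.e. GQ > 30)
#' and the call is supported by at least `min_depth` reads. Structural
#' variants (`is_structural == TRUE`) are only filtered on the cohort carrier
#' count; their genotype-quality fields are ignored. A missing population
#' frequency is treated as 0 (not observed, hence rare). Rows with missing
#' quality fields on small variants are dropped with a warning.
#'
#' @param variants Table with columns `population_af`,
#'   `cohort_carrier_count`, `genotype_quality`, `read_depth`,
#'   `is_structural` (plus any id columns, carried through).
#' @param max_af Population allele-frequency ceiling (default 0.001).
#' @param max_cohort_carriers Cohort carrier ceiling (default 2).
#' @param min_gq Minimal genotype quality kept (default 31, i.e. GQ > 30).
#' @param min_depth Minimal supporting read depth (default 10).
#' @return Filtered `data.table`.
#' @export
filter_rare_variants <- function(variants, max_af = 0.001,
                                 max_cohort_carriers = 2,
                                 min_gq = 31, min_depth = 10) {
  dt <- as.data.table(variants)
  if (nrow(dt) == 0L) return(dt)
  if (!"is_structural" %in% names(dt)) dt[, is_structural := FALSE]
  dt <- copy(dt)
  dt[is.na(population_af), population_af := 0]
  small <- dt[is_structural == FALSE]
  malformed <- !complete.cases(small[, .(genotype_quality, read_depth,
                                         cohort_carrier_count)])
  if (any(malformed)) {
    warning(sum(malformed), " small variant(s) with malformed genotype fields dropped")
    small <- small[!malformed]
  }
  small <- small[population_af <= max_af &
                 cohort_carrier_count <= max_cohort_carriers &
                 genotype_quality >= min_gq &
                 read_depth >= min_depth]
  svs <- dt[is_structural == TRUE][cohort_carrier_count <= max_cohort_carriers]
  rbind(small, svs)
}

#' Pair variants with nearby genes
#'
#' SNVs/indels are paired with every gene whose transcript span, extended by
#' `snv_window` bp on both sides, contains the variant position. Structural
#' variants are additionally paired with genes whose strand-aware 5' upstream
#' window `[TSS - sv_upstream_window, TSS]` (reversed on the minus strand)
#' overlaps the SV interval `[pos, end]`. Coordinates are 1-based closed
#' (GTF/VCF convention). Pairs are deduplicated; variants on contigs absent
#' from the gene models are skipped with a warning.
#'
#' @param variants Table with `variant_key`, `chrom`, `pos`, optional `end`
#'   (SVs), `is_structural`, `individual_id`.
#' @param transcripts Table with `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param snv_window Window around the gene for small variants (default 5000).
#' @param sv_upstream_window 5' window for structural variants (default 1e6).
#' @return `data.table` of (variant_key, individual_id, gene_id) pairs.
#' @export
assign_variants_to_genes <- function(variants, transcripts,
                                     snv_window = 5000,
                                     sv_upstream_window = 1e6) {
  v <- as.data.table(variants)
  tx <- as.data.table(transcripts)
  if (!"is_structural" %in% names(v)) v[, is_structural := FALSE]
  if (!"end" %in% names(v)) v[, end := pos]
  v <- copy(v)
  v[is.na(end), end := pos]
  genes <- tx[, .(start = min(start), end = max(end),
                  strand = strand[1], chrom = chrom[1]), by = gene_id]
  missing_contig <- setdiff(unique(v$chrom), unique(genes$chrom))
  if (length(missing_contig)) {
    warning("variants on contig(s) absent from gene models skipped: ",
            paste(missing_contig, collapse = ", "))
    v <- v[!chrom %in% missing_contig]
  }
  if (nrow(v) == 0L || nrow(genes) == 0L)
    return(data.table(variant_key = character(0),
                      individual_id = character(0), gene_id = character(0)))

  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - snv_window), genes$end + snv_window))
  pos_gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::findOverlaps(pos_gr, gene_gr)
  pairs <- data.table(variant_key = v$variant_key[S4Vectors::queryHits(hits)],
                      individual_id = v$individual_id[S4Vectors::queryHits(hits)],
                      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])

  sv <- v[is_structural == TRUE]
  if (nrow(sv)) {
    tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    up_start <- ifelse(genes$strand == "-", tss, pmax(1, tss - sv_upstream_window))
    up_end <- ifelse(genes$strand == "-", tss + sv_upstream_window, tss)
    up_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(up_start, up_end))
    sv_gr <- GenomicRanges::GRanges(sv$chrom, IRanges::IRanges(sv$pos, sv$end))
    h2 <- GenomicRanges::findOverlaps(sv_gr, up_gr)
    pairs <- rbind(pairs, data.table(
      variant_key = sv$variant_key[S4Vectors::queryHits(h2)],
      individual_id = sv$individual_id[S4Vectors::queryHits(h2)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(h2)]))
  }
  unique(pairs)[order(variant_key, individual_id, gene_id)]
}

#' Tissue-specific isoform proportions from transcript-level TPM
#'
#' For every transcript and tissue, the proportion is the median across
#' individuals of the transcript's share of its gene's total TPM. Individuals
#' in which the gene has zero total TPM in that tissue are excluded from the
#' median. Because a median of ratios need not sum to one across isoforms,
#' per-(gene, tissue) proportions are renormalised to sum to 1; the
#' pre-normalisation sum is kept in column `raw_sum`. Genes with zero TPM in
#' all individuals of a tissue are emitted with `NA` proportions.
#'
#' @param tpm Long table with columns `gene_id`, `transcript_id`, `tissue`,
#'   `individual_id`, `tpm`.
#' @return `data.table` with `gene_id`, `transcript_id`, `tissue`,
#'   `proportion`, `raw_sum`.
#' @export
compute_isoform_proportions <- function(tpm) {
  dt <- as.data.table(tpm)
  if (any(dt$tpm < 0)) stop("TPM values must be non-negative")
  dt <- copy(dt)
  dt[, gene_total := sum(tpm), by = .(gene_id, tissue, individual_id)]
  shares <- dt[gene_total > 0,
               .(med = median(tpm / gene_total)),
               by = .(gene_id, transcript_id, tissue)]
  shares[, raw_sum := sum(med), by = .(gene_id, tissue)]
  shares[, proportion := ifelse(raw_sum > 0, med / raw_sum, NA_real_)]
  # genes never expressed in a tissue: emit NA rows
  all_keys <- unique(dt[, .(gene_id, transcript_id, tissue)])
  out <- shares[all_keys, on = c("gene_id", "transcript_id", "tissue")]
  out[, med := NULL]
  setorder(out, gene_id, transcript_id, tissue)
  out[]
}

#' Total isoform proportion affected by a variant
#'
#' The weight of a variant on a gene in a tissue is the summed proportion of
#' the gene's isoforms it affects: `w = sum_i proportion(i, t) * affects(v, i)`.
#' A variant affecting all isoforms gets weight 1; one affecting none, 0.
#'
#' @param affected_isoforms Character vector of affected transcript ids.
#' @param gene_id,tissue Scalar keys.
#' @param proportions Table from [compute_isoform_proportions()].
#' @return Weight in \[0, 1\].
#' @export
isoform_weight <- function(affected_isoforms, gene_id, tissue, proportions) {
  pr <- as.data.table(proportions)
  g <- gene_id; t <- tissue
  sub <- pr[gene_id == g & tissue == t]
  if (nrow(sub) == 0L || all(is.na(sub$proportion)))
    stop("no isoform proportions for gene ", g, " in tissue ", t,
         "; fall back to canonical mode")
  sum(sub[transcript_id %in% affected_isoforms, proportion], na.rm = TRUE)
}

#' Derive transcript-ablation annotations from structural deletions
#'
#' Emits a `transcript_ablation` annotation row for every (DEL structural
#' variant, transcript) where the deletion fully covers the transcript span.
#'
#' @param variants Variant table (needs `variant_key`, `chrom`, `pos`, `end`,
#'   `is_structural`, `sv_type`).
#' @param transcripts Transcript-model table.
#' @return `data.table` with `variant_key`, `transcript_id`, `consequence`,
#'   `loftee`, `cadd` columns matching the annotation contract.
#' @export
annotate_sv_ablation <- function(variants, transcripts) {
  v <- as.data.table(variants)
  tx <- as.data.table(transcripts)
  sv <- v[is_structural == TRUE & sv_type == "DEL"]
  if (nrow(sv) == 0L || nrow(tx) == 0L)
    return(data.table(variant_key = character(0), transcript_id = character(0),
                      consequence = character(0), loftee = character(0),
                      cadd = numeric(0)))
  # deletion covers transcript: sv.pos <= tx.start and tx.end <= sv.end
  out <- sv[tx, on = .(chrom), allow.cartesian = TRUE, nomatch = NULL][
    pos <= start & i.end <= end, .(variant_key, transcript_id)]
  unique(out)[, `:=`(consequence = "transcript_ablation",
                     loftee = "", cadd = NA_real_)][]
}

.expand_annotations <- function(annotations, unknown = c("error", "other")) {
  unknown <- match.arg(unknown)
  ann <- as.data.table(annotations)
  long <- ann[, .(term = trimws(unlist(strsplit(consequence, ",", fixed = TRUE)))),
              by = .(variant_key, transcript_id)]
  long <- long[term != ""]
  bad <- setdiff(unique(long$term), consequence_vocabulary())
  if (length(bad)) {
    if (unknown == "error")
      stop("unknown consequence term(s): ", paste(bad, collapse = ", "))
    long[term %in% bad, term := "other"]
  }
  lof <- ann[!is.na(loftee) & loftee %in% c("HC", "LC"),
             .(variant_key, transcript_id, term = paste0("LOFTEE_", loftee))]
  unique(rbind(long, lof))
}

#' Aggregate variant annotations into gene x individual x tissue features
#'
#' Two aggregation modes are supported. In `canonical` mode a per-consequence
#' (and per-LOFTEE-class) feature is 1 iff any of the individual's rare
#' variants carries that annotation on the gene's canonical transcript; the
#' result is identical across tissues. In `weighted` mode each variant's
#' annotation is first weighted by the total tissue-specific proportion of
#' isoforms it affects ([isoform_weight()]), then max-aggregated across
#' variants per (gene, individual, tissue). CADD is max-aggregated per gene
#' across variants (tissue-independent); AbSplice keeps the signed value of
#' maximum absolute score per gene and tissue. The gene-tissue biological
#' coefficient of variation is joined when a `bcv_table` is given. A zero
#' (or NA for bcv) row is emitted for every requested (gene, individual,
#' tissue) with no rare variant.
#'
#' @param pairs (variant_key, individual_id, gene_id) pairs from
#'   [assign_variants_to_genes()], already restricted to rare variants.
#' @param annotations Table with `variant_key`, `transcript_id`,
#'   `consequence` (comma-separated terms), `loftee` (`"HC"`, `"LC"` or
#'   `""`), optional `cadd`.
#' @param transcripts Transcript models (for the canonical flag and
#'   gene-transcript mapping).
#' @param mode `"weighted"` or `"canonical"`.
#' @param proportions Isoform-proportion table (required in weighted mode).
#' @param tissues Tissues to emit (default: tissues present in
#'   `proportions`, or `"all"` single pseudo-tissue in canonical mode without
#'   proportions).
#' @param individuals Individuals to emit rows for (default: those in
#'   `pairs`).
#' @param genes Genes to emit rows for (default: those in `transcripts`).
#' @param bcv_table Optional (gene_id, tissue, bcv) table.
#' @param absplice Optional (variant_key, tissue, absplice) table.
#' @param unknown How to treat consequence terms outside the vocabulary.
#' @return `data.table`, one row per (gene, individual, tissue), feature
#'   columns `feat_<term>`, `feat_LOFTEE_HC`, `feat_LOFTEE_LC`, `cadd_max`,
#'   `absplice_max_abs`, `bcv`.
#' @export
aggregate_gene_features <- function(pairs, annotations, transcripts,
                                    mode = c("weighted", "canonical"),
                                    proportions = NULL, tissues = NULL,
                                    individuals = NULL, genes = NULL,
                                    bcv_table = NULL, absplice = NULL,
                                    unknown = c("error", "other")) {
  mode <- match.arg(mode)
  unknown <- match.arg(unknown)
  pairs <- as.data.table(pairs)
  tx <- as.data.table(transcripts)
  if (mode == "weighted" && is.null(proportions))
    stop("weighted mode requires an isoform-proportion table")
  if (is.null(tissues))
    tissues <- if (!is.null(proportions)) unique(as.data.table(proportions)$tissue)
               else "all"
  if (is.null(individuals)) individuals <- unique(pairs$individual_id)
  if (is.null(genes)) genes <- unique(tx$gene_id)

  terms <- c(consequence_vocabulary(), "LOFTEE_HC", "LOFTEE_LC")
  if (unknown == "other") terms <- c(terms, "other")
  grid <- CJ(gene_id = genes, individual_id = individuals, tissue = tissues,
             unique = TRUE)

  long <- .expand_annotations(annotations, unknown = unknown)
  # restrict annotation transcripts to the paired gene
  long <- merge(long, tx[, .(transcript_id, gene_id)], by = "transcript_id",
                allow.cartesian = TRUE)
  hits <- unique(merge(pairs, long, by = c("variant_key", "gene_id"),
                       allow.cartesian = TRUE))

  if (mode == "canonical") {
    canon <- tx[is_canonical == TRUE, .(gene_id, transcript_id)]
    hc <- merge(hits, canon, by = c("gene_id", "transcript_id"))
    feat <- unique(hc[, .(gene_id, individual_id, term)])
    feat[, w := 1]
    feat <- feat[, .(w = max(w)), by = .(gene_id, individual_id, term)]
    feat[, .dummy := 1L]
    feat <- merge(feat, data.table(tissue = tissues, .dummy = 1L),
                  by = ".dummy", allow.cartesian = TRUE)[, .dummy := NULL]
  } else {
    pr <- as.data.table(proportions)[!is.na(proportion),
                                     .(gene_id, transcript_id, tissue, proportion)]
    wv <- merge(hits, pr, by = c("gene_id", "transcript_id"),
                allow.cartesian = TRUE)
    # per variant/term/tissue: total affected proportion, then max over variants
    wv <- wv[, .(w = sum(proportion)),
             by = .(gene_id, individual_id, tissue, variant_key, term)]
    feat <- wv[, .(w = max(w)), by = .(gene_id, individual_id, tissue, term)]
  }

  wide <- dcast(feat, gene_id + individual_id + tissue ~ term,
                value.var = "w", fill = 0)
  for (tt in setdiff(terms, names(wide))) wide[, (tt) := 0]
  setnames(wide, terms, paste0("feat_", terms))
  out <- merge(grid, wide, by = c("gene_id", "individual_id", "tissue"),
               all.x = TRUE)
  featcols <- paste0("feat_", terms)
  for (cc in featcols) out[is.na(get(cc)), (cc) := 0]

  ann <- as.data.table(annotations)
  if ("cadd" %in% names(ann)) {
    cadd_v <- ann[!is.na(cadd), .(cadd = max(cadd)), by = variant_key]
    cg <- merge(pairs, cadd_v, by = "variant_key")[,
      .(cadd_max = max(cadd)), by = .(gene_id, individual_id)]
    out <- merge(out, cg, by = c("gene_id", "individual_id"), all.x = TRUE)
  }
  if (!"cadd_max" %in% names(out)) out[, cadd_max := NA_real_]
  out[is.na(cadd_max), cadd_max := 0]

  if (!is.null(absplice)) {
    ab <- merge(pairs, as.data.table(absplice), by = "variant_key",
                allow.cartesian = TRUE)
    abg <- ab[, .(absplice_max_abs = absplice[which.max(abs(absplice))]),
              by = .(gene_id, individual_id, tissue)]
    out <- merge(out, abg, by = c("gene_id", "individual_id", "tissue"),
                 all.x = TRUE)
  }
  if (!"absplice_max_abs" %in% names(out)) out[, absplice_max_abs := NA_real_]
  out[is.na(absplice_max_abs), absplice_max_abs := 0]

  if (!is.null(bcv_table)) {
    out <- merge(out, as.data.table(bcv_table)[, .(gene_id, tissue, bcv)],
                 by = c("gene_id", "tissue"), all.x = TRUE)
  } else out[, bcv := NA_real_]

  setorder(out, gene_id, individual_id, tissue)
  out[]
}

#' Names of the model feature columns in a feature table
#'
#' @param features Table from [aggregate_gene_features()].
#' @return Character vector of numeric feature column names.
#' @export
feature_columns <- function(features) {
  nm <- names(features)
  c(grep("^feat_", nm, value = TRUE),
    intersect(c("cadd_max", "absplice_max_abs", "bcv", "enformer_score"), nm))
}
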