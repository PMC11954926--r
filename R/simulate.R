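#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale cohort with the statistical structure the
#' predictor assumes: negative-binomial expression counts with gene- and
#' tissue-specific mean and dispersion, rare planted variants whose effect on
#' the log2 fold-change follows a consequence hierarchy (NMD-like strongest,
#' synonymous none), tissue-specific isoform proportions that modulate the
#' effect via the affected-isoform weight, and fold-change attenuation for
#' genes with low expression variability (BCV). The targeted outlier
#' prevalence is about 1e-4, matching the extreme class imbalance of real
#' cohort benchmarks.
#'
#' @param n_individuals,n_genes,n_tissues Cohort dimensions (defaults 200,
#'   500, 5).
#' @param max_isoforms Isoforms per gene are drawn uniformly from
#'   1..`max_isoforms` (default 3).
#' @param variants_per_individual Mean (Poisson) number of rare candidate
#'   variants per individual (default 10).
#' @param consequence_probs Named sampling probabilities over consequence
#'   categories.
#' @param effect_sizes Named full-weight effect sizes on -log2FC per
#'   category (NMD-like strongest).
#' @param sv_per_individual Expected number of gene-ablating structural
#'   deletions per individual (default 0.02; set 0 for none).
#' @param bcv_meanlog,bcv_sdlog Log-normal BCV distribution parameters
#'   (median ~0.2).
#' @param bcv_ref Attenuation reference: planted fold-changes are scaled by
#'   `min(1, bcv / bcv_ref)` so low-variability genes show smaller
#'   fold-changes (default 0.3).
#' @param mu_meanlog,mu_sdlog Log-normal distribution of expected fragment
#'   counts.
#' @param fdr_cutoff FDR used for the simulator's ground-truth labels
#'   (default 0.05).
#' @param prevalence_target Intended underexpression-outlier prevalence
#'   (default 1e-4); must lie in (0, 0.01).
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `abexp_sim_config`.
#' @export
sim_config <- function(n_individuals = 200, n_genes = 500, n_tissues = 5,
                       max_isoforms = 3, variants_per_individual = 10,
                       consequence_probs = c(synonymous = 0.25, intron = 0.25,
                                             upstream = 0.16, utr = 0.14,
                                             missense = 0.17, nmd = 0.012,
                                             splice = 0.018),
                       effect_sizes = c(nmd = 2.4, splice = 1.8,
                                        missense = 0.25, utr = 0.2,
                                        upstream = 0.15, intron = 0.1,
                                        synonymous = 0),
                       sv_per_individual = 0.02,
                       bcv_meanlog = log(0.2), bcv_sdlog = 0.5,
                       bcv_ref = 0.3,
                       mu_meanlog = log(900), mu_sdlog = 0.8,
                       fdr_cutoff = 0.05, prevalence_target = 1e-4,
                       seed = 1L) {
  if (prevalence_target <= 0 || prevalence_target >= 0.01)
    stop("prevalence target must lie in (0, 0.01)")
  es <- effect_sizes
  stopifnot(es[["nmd"]] >= es[["splice"]], es[["splice"]] > es[["missense"]],
            es[["synonymous"]] == 0)
  structure(as.list(environment()), class = "abexp_sim_config")
}

.category_terms <- list(
  nmd = c("stop_gained", "frameshift_variant"),
  splice = c("splice_acceptor_variant", "splice_donor_variant",
             "splice_region_variant"),
  missense = "missense_variant",
  utr = c("5_prime_UTR_variant", "3_prime_UTR_variant"),
  upstream = "upstream_gene_variant",
  intron = "intron_variant",
  synonymous = "synonymous_variant")

.cadd_params <- c(nmd = 35, splice = 25, missense = 22, utr = 6,
                  upstream = 5, intron = 4, synonymous = 3)

#' Simulate a self-contained synthetic cohort
#'
#' Generates, deterministically given the config seed, every input the
#' pipeline consumes: transcript models, a rare-variant table with quality
#' fields (plus a handful of variants failing the quality/frequency filters
#' and a few structural deletions), per-transcript annotations with
#' consequence terms, LOFTEE class and CADD, a transcript-level TPM table,
#' an outlier-caller-style result table (observed/expected counts,
#' dispersion, FDR from two-sided NB tail probabilities with
#' Benjamini-Yekutieli adjustment per sample), and the ground truth of
#' planted effects. The simulator's FDR stands in for a real outlier
#' caller's: no confounder fitting is emulated.
#'
#' @param config [sim_config()] object.
#' @return List with `transcripts`, `variants`, `annotations`, `tpm`,
#'   `outrider`, `truth`, `gene_params`, `proportions_true`, and the config.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  individuals <- sprintf("IND%04d", seq_len(cfg$n_individuals))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  tissues <- sprintf("tissue_%d", seq_len(cfg$n_tissues))

  ## transcript models: genes spaced along one contig, isoforms share the span
  n_iso <- sample.int(cfg$max_isoforms, cfg$n_genes, replace = TRUE)
  gene_start <- seq(1e5, by = 2e6, length.out = cfg$n_genes)
  gene_len <- round(runif(cfg$n_genes, 1e4, 1e5))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  transcripts <- data.table(
    gene_id = rep(genes, n_iso),
    transcript_id = unlist(lapply(seq_len(cfg$n_genes), function(g)
      sprintf("%s.T%d", genes[g], seq_len(n_iso[g])))),
    chrom = "chr1",
    start = rep(gene_start, n_iso),
    end = rep(gene_start + gene_len, n_iso),
    strand = rep(strand, n_iso))
  transcripts[, is_canonical := seq_len(.N) == 1L, by = gene_id]

  ## per gene-tissue NB parameters and true isoform proportions
  gene_params <- CJ(gene_id = genes, tissue = tissues)
  gene_params[, mu := exp(rnorm(.N, cfg$mu_meanlog, cfg$mu_sdlog))]
  gene_params[, bcv := exp(rnorm(.N, cfg$bcv_meanlog, cfg$bcv_sdlog))]
  gene_params[, theta := 1 / bcv^2]
  prop_true <- rbindlist(lapply(seq_len(cfg$n_genes), function(g) {
    k <- n_iso[g]
    props <- vapply(tissues, function(tt) {
      a <- rgamma(k, shape = 1)
      a / sum(a)
    }, numeric(k))
    data.table(gene_id = genes[g],
               transcript_id = sprintf("%s.T%d", genes[g], seq_len(k)),
               tissue = rep(tissues, each = k),
               proportion = as.vector(props))
  }))

  ## TPM table consistent with the true proportions
  gene_tpm <- CJ(gene_id = genes, tissue = tissues)
  gene_tpm[, gene_level := exp(rnorm(.N, log(20), 1))]
  tpm <- merge(prop_true, gene_tpm, by = c("gene_id", "tissue"))
  tpm <- tpm[rep(seq_len(.N), each = cfg$n_individuals)]
  tpm[, individual_id := rep(individuals, length.out = .N)]
  tpm[, tpm := gene_level * proportion * exp(rnorm(.N, 0, 0.2))]
  tpm <- tpm[, .(gene_id, transcript_id, tissue, individual_id, tpm)]

  ## rare candidate variants
  nv <- rpois(cfg$n_individuals, cfg$variants_per_individual)
  variants <- data.table(
    individual_id = rep(individuals, nv),
    gene_idx = sample.int(cfg$n_genes, sum(nv), replace = TRUE),
    category = sample(names(cfg$consequence_probs), sum(nv), replace = TRUE,
                      prob = cfg$consequence_probs))
  variants[, gene_id := genes[gene_idx]]
  variants[, pos := gene_start[gene_idx] +
             round(runif(.N) * gene_len[gene_idx])]
  variants[, `:=`(chrom = "chr1",
                  ref = sample(c("A", "C", "G", "T"), .N, replace = TRUE))]
  variants[, alt := vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))]
  variants[, variant_key := sprintf("chr1:%d:%s>%s:%s", pos, ref, alt,
                                    individual_id)]
  variants[, genotype_quality := sample(31:99, .N, replace = TRUE)]
  variants[, read_depth := sample(10:60, .N, replace = TRUE)]
  variants[, population_af := ifelse(runif(.N) < 0.5, 0,
                                     runif(.N, 0, 0.001))]
  variants[, cohort_carrier_count := sample(1:2, .N, replace = TRUE,
                                            prob = c(0.85, 0.15))]
  variants[, `:=`(is_structural = FALSE, sv_type = NA_character_)]
  ## ~8% of candidates fail a filter (no planted effect for those)
  n_all <- nrow(variants)
  fail <- sample.int(n_all, round(0.08 * n_all))
  fail_mode <- sample(1:3, length(fail), replace = TRUE)
  variants[fail[fail_mode == 1], genotype_quality := sample(5:30, .N, replace = TRUE)]
  variants[fail[fail_mode == 2], read_depth := sample(1:9, .N, replace = TRUE)]
  variants[fail[fail_mode == 3], population_af := runif(.N, 0.002, 0.2)]
  variants[, passes := genotype_quality >= 31 & read_depth >= 10 &
             population_af <= 0.001 & cohort_carrier_count <= 2]

  ## a few structural deletions fully covering their gene (transcript ablation)
  n_sv <- round(cfg$n_individuals * cfg$sv_per_individual)
  variants[, end := pos]
  if (n_sv > 0) {
  sv_gene <- sample.int(cfg$n_genes, n_sv, replace = TRUE)
  svs <- data.table(
    individual_id = sample(individuals, n_sv),
    gene_idx = sv_gene, category = "sv_del",
    gene_id = genes[sv_gene],
    pos = gene_start[sv_gene] - 100L,
    chrom = "chr1", ref = "N", alt = "<DEL>",
    genotype_quality = NA_integer_, read_depth = NA_integer_,
    population_af = 0,
    cohort_carrier_count = sample(1:2, n_sv, replace = TRUE),
    is_structural = TRUE, sv_type = "DEL", passes = TRUE)
  svs[, variant_key := sprintf("chr1:%d:DEL:%s", pos, individual_id)]
  svs[, end := gene_start[gene_idx] + gene_len[gene_idx] + 100L]
  variants <- rbind(variants, svs, fill = TRUE)
  }

  ## annotations: affected isoforms per variant (all isoforms w.p. 1/2,
  ## else one random isoform), one term per category
  ann_list <- vector("list", nrow(variants))
  eff_w <- matrix(0, nrow(variants), cfg$n_tissues,
                  dimnames = list(NULL, tissues))
  prop_w <- dcast(prop_true, gene_id + transcript_id ~ tissue,
                  value.var = "proportion")
  setkey(prop_w, gene_id, transcript_id)
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene_id[i]
    iso <- sprintf("%s.T%d", g, seq_len(n_iso[variants$gene_idx[i]]))
    cat_i <- variants$category[i]
    if (cat_i == "sv_del") {
      affected <- iso
      term <- "transcript_ablation"
      loftee <- ""
      cadd <- NA_real_
    } else {
      affected <- if (runif(1) < 0.5 || length(iso) == 1L) iso
                  else sample(iso, 1)
      term <- sample(.category_terms[[cat_i]], 1)
      loftee <- if (cat_i == "nmd" && runif(1) < 0.8) "HC"
                else if (cat_i %in% c("nmd", "splice") && runif(1) < 0.3) "LC"
                else ""
      cadd <- max(0, rnorm(1, .cadd_params[[cat_i]], 5))
    }
    ann_list[[i]] <- data.table(variant_key = variants$variant_key[i],
                                transcript_id = affected,
                                consequence = term, loftee = loftee,
                                cadd = cadd)
    w <- prop_w[.(g, affected), as.matrix(.SD), .SDcols = tissues]
    eff_w[i, ] <- colSums(w, na.rm = TRUE)
  }
  annotations <- rbindlist(ann_list)

  ## planted effects on log2FC: -effect_size * isoform_weight * attenuation(bcv)
  sizes <- c(cfg$effect_sizes, sv_del = unname(cfg$effect_sizes[["nmd"]]) + 0.6)
  eff <- data.table(variants[, .(variant_key, individual_id, gene_id,
                                 category, passes)],
                    eff_w)
  eff <- melt(eff, measure.vars = tissues, variable.name = "tissue",
              value.name = "w", variable.factor = FALSE)
  eff[, size := sizes[category]]
  eff <- merge(eff, gene_params[, .(gene_id, tissue, bcv)],
               by = c("gene_id", "tissue"))
  eff[, atten := pmin(1, bcv / cfg$bcv_ref)]
  eff[, l2fc := ifelse(passes, -size * w * atten, 0)]
  planted <- eff[l2fc != 0]
  planted <- if (nrow(planted))
    planted[, .(l2fc = min(l2fc)), by = .(individual_id, gene_id, tissue)]
  else planted[, .(individual_id, gene_id, tissue, l2fc)]

  ## counts and outlier-caller-style table
  outr <- CJ(individual_id = individuals, gene_id = genes, tissue = tissues)
  outr <- merge(outr, gene_params, by = c("gene_id", "tissue"))
  outr <- merge(outr, planted, by = c("individual_id", "gene_id", "tissue"),
                all.x = TRUE)
  outr[is.na(l2fc), l2fc := 0]
  outr[, x := rnbinom(.N, size = theta, mu = mu * 2^l2fc)]
  lo <- pnbinom(outr$x, size = outr$theta, mu = outr$mu)
  hi <- 1 - pnbinom(outr$x - 1, size = outr$theta, mu = outr$mu)
  outr[, p := pmin(1, 2 * pmin(lo, hi))]
  outr[, sample_id := paste(individual_id, tissue, sep = ":")]
  outr[, fdr := p.adjust(p, method = "BY"), by = sample_id]
  truth <- outr[, .(sample_id, individual_id, gene_id, tissue,
                    planted_l2fc = l2fc,
                    planted = l2fc != 0,
                    true_outlier = fdr < cfg$fdr_cutoff & x < mu)]
  outrider <- outr[, .(sample_id, individual_id, gene_id, tissue,
                       x, mu, theta, fdr)]
  setorder(outrider, sample_id, gene_id, tissue)
  setorder(truth, sample_id, gene_id, tissue)

  list(config = cfg, transcripts = transcripts,
       variants = variants[, .(variant_key, individual_id, chrom, pos, end,
                               ref, alt, gene_id, category,
                               genotype_quality, read_depth, population_af,
                               cohort_carrier_count, is_structural, sv_type)],
       annotations = annotations, tpm = tpm,
       gene_params = gene_params, proportions_true = prop_true,
       outrider = outrider, truth = truth)
}

#' Plant a tissue-specific outlier driven by isoform proportions
#'
#' A minimal two-tissue scenario: one gene with two isoforms whose canonical
#' share differs strongly between tissues (default 0.48 vs 0.04), and a
#' frameshift confined to the canonical isoform in one carrier. The planted
#' expression drop is proportional to the affected-isoform weight, so the
#' outlier materialises only in the high-proportion tissue.
#'
#' @param n_individuals Cohort size (default 100).
#' @param shares Canonical-isoform proportion in the two tissues (default
#'   `c(0.48, 0.04)`).
#' @param effect_size Full-weight effect on -log2FC (default 2.4).
#' @param mu,theta NB parameters of the gene in both tissues.
#' @param seed Seed.
#' @return List with the same component types as [simulate_cohort()]
#'   (restricted to the mini-scenario) plus `carrier`.
#' @export
plant_tissue_specific_case <- function(n_individuals = 100,
                                       shares = c(0.48, 0.04),
                                       effect_size = 2.4,
                                       mu = 1500, theta = 30, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  individuals <- sprintf("IND%04d", seq_len(n_individuals))
  tissues <- c("tissue_hi", "tissue_lo")
  gene <- "GENE0001"
  transcripts <- data.table(
    gene_id = gene, transcript_id = c("GENE0001.T1", "GENE0001.T2"),
    chrom = "chr1", start = 1e5, end = 2e5, strand = "+",
    is_canonical = c(TRUE, FALSE))
  prop_true <- data.table(
    gene_id = gene,
    transcript_id = rep(c("GENE0001.T1", "GENE0001.T2"), 2),
    tissue = rep(tissues, each = 2),
    proportion = c(shares[1], 1 - shares[1], shares[2], 1 - shares[2]))
  carrier <- individuals[1]
  variants <- data.table(
    variant_key = "chr1:150000:C>CA", individual_id = carrier,
    chrom = "chr1", pos = 150000L, end = 150000L, ref = "C", alt = "CA",
    gene_id = gene, category = "nmd",
    genotype_quality = 60L, read_depth = 30L, population_af = 0,
    cohort_carrier_count = 1L, is_structural = FALSE, sv_type = NA_character_)
  annotations <- data.table(
    variant_key = "chr1:150000:C>CA", transcript_id = "GENE0001.T1",
    consequence = "frameshift_variant", loftee = "HC", cadd = 35)
  grid <- CJ(individual_id = individuals, tissue = tissues)
  grid[, `:=`(gene_id = gene, mu = mu, theta = theta)]
  grid[, l2fc := 0]
  grid[individual_id == carrier & tissue == "tissue_hi",
       l2fc := -effect_size * shares[1]]
  grid[individual_id == carrier & tissue == "tissue_lo",
       l2fc := -effect_size * shares[2]]
  grid[, x := rnbinom(.N, size = theta, mu = mu * 2^l2fc)]
  lo_p <- pnbinom(grid$x, size = grid$theta, mu = grid$mu)
  hi_p <- 1 - pnbinom(grid$x - 1, size = grid$theta, mu = grid$mu)
  grid[, p := pmin(1, 2 * pmin(lo_p, hi_p))]
  grid[, sample_id := paste(individual_id, tissue, sep = ":")]
  grid[, fdr := p.adjust(p, method = "BY"), by = sample_id]
  outrider <- grid[, .(sample_id, individual_id, gene_id, tissue,
                       x, mu, theta, fdr)]
  tpm_rows <- prop_true[rep(seq_len(.N), each = n_individuals)]
  tpm_rows[, individual_id := rep(individuals, length.out = .N)]
  tpm_rows[, tpm := 20 * proportion * exp(rnorm(.N, 0, 0.1))]
  list(transcripts = transcripts, proportions_true = prop_true,
       variants = variants, annotations = annotations,
       tpm = tpm_rows[, .(gene_id, transcript_id, tissue, individual_id, tpm)],
       outrider = outrider, carrier = carrier,
       truth = grid[, .(sample_id, individual_id, gene_id, tissue,
                        planted_l2fc = l2fc, planted = l2fc != 0,
                        true_outlier = fdr < 0.05 & x < mu)])
}
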