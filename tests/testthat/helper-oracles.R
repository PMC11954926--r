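library(data.table)

# ---- shared expensive fixtures (computed once per test run) ----------------

.fixtures <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_cohort(sim_config(seed = 1))
  .fixtures$sim
}

default_pipeline <- function() {
  if (is.null(.fixtures$pipe))
    .fixtures$pipe <- run_cohort_pipeline(default_sim())
  .fixtures$pipe
}

# ---- independent brute-force oracles ---------------------------------------

# NB CDF by direct pmf summation, then normal quantile
oracle_nb_z <- function(x, mu, theta, clamp_eps = 1e-16) {
  p <- sum(dnbinom(0:x, size = theta, mu = mu))
  qnorm(min(max(p, clamp_eps), 1 - clamp_eps))
}

# average precision by explicit confusion-matrix sweep over distinct scores
oracle_ap <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  pts <- list()
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp <- sum(pred & labels == 1L)
    p <- tp / sum(pred)
    r <- tp / sum(labels == 1L)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
    pts[[i]] <- c(precision = p, recall = r)
  }
  list(ap = ap, points = do.call(rbind, pts))
}

# benchmark filter rules re-derived with plain loops
oracle_benchmark <- function(records, min_mu = 450, fdr_cutoff = 0.05,
                             max_outliers = 20) {
  df <- as.data.frame(records)
  df$z <- mapply(function(x, mu, th) oracle_nb_z(x, mu, th),
                 df$x, df$mu, df$theta)
  df$label <- "non_outlier"
  for (i in seq_len(nrow(df))) {
    if (df$fdr[i] < fdr_cutoff && df$z[i] < 0)
      df$label[i] <- "underexpression_outlier"
    if (df$fdr[i] < fdr_cutoff && df$z[i] > 0)
      df$label[i] <- "overexpression_outlier"
  }
  df <- df[df$mu >= min_mu, ]
  keep <- rep(TRUE, nrow(df))
  for (s in unique(df$sample_id)) for (t in unique(df$tissue)) {
    idx <- df$sample_id == s & df$tissue == t
    if (sum(df$label[idx] != "non_outlier") > max_outliers) keep[idx] <- FALSE
  }
  df[keep, ]
}

# two-sided Fisher exact p by hypergeometric enumeration of a 2x2 table
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- signs %*% r
  v_obs <- sum(r[d > 0])
  p_le <- mean(vdist <= v_obs)
  p_ge <- mean(vdist >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# gene-feature aggregation with nested loops and no indexing
oracle_aggregate <- function(pairs, annotations, transcripts, proportions,
                             mode, tissues, individuals, genes) {
  ann <- as.data.frame(annotations)
  tx <- as.data.frame(transcripts)
  pr <- as.data.frame(proportions)
  pairs <- as.data.frame(pairs)
  vocab <- c(consequence_vocabulary(), "LOFTEE_HC", "LOFTEE_LC")
  rows <- list()
  for (g in genes) for (ind in individuals) for (tt in tissues) {
    vks <- unique(pairs$variant_key[pairs$gene_id == g &
                                    pairs$individual_id == ind])
    feats <- setNames(rep(0, length(vocab)), vocab)
    for (vk in vks) {
      sub <- ann[ann$variant_key == vk, ]
      for (j in seq_len(nrow(sub))) {
        tid <- sub$transcript_id[j]
        if (!tid %in% tx$transcript_id[tx$gene_id == g]) next
        terms <- trimws(strsplit(sub$consequence[j], ",")[[1]])
        if (!is.na(sub$loftee[j]) && sub$loftee[j] %in% c("HC", "LC"))
          terms <- c(terms, paste0("LOFTEE_", sub$loftee[j]))
        for (tm in unique(terms)) {
          if (mode == "canonical") {
            canon <- tx$is_canonical[tx$transcript_id == tid]
            if (isTRUE(canon)) feats[tm] <- 1
          } else {
            # weight of THIS variant for term tm: sum over all affected
            # transcripts of the gene
            aff <- unique(sub$transcript_id[
              vapply(seq_len(nrow(sub)), function(r) {
                tr <- trimws(strsplit(sub$consequence[r], ",")[[1]])
                if (!is.na(sub$loftee[r]) && sub$loftee[r] %in% c("HC", "LC"))
                  tr <- c(tr, paste0("LOFTEE_", sub$loftee[r]))
                tm %in% tr
              }, logical(1))])
            aff <- aff[aff %in% tx$transcript_id[tx$gene_id == g]]
            w <- 0
            for (a in aff) {
              p <- pr$proportion[pr$gene_id == g & pr$transcript_id == a &
                                 pr$tissue == tt]
              if (length(p) && !is.na(p)) w <- w + p
            }
            feats[tm] <- max(feats[tm], w)
          }
        }
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = g, individual_id = ind, tissue = tt,
                 t(feats), check.names = FALSE)
  }
  do.call(rbind, rows)
}

# OLS Gaussian log-likelihood computed explicitly from residuals
oracle_lrt_stat <- function(y, X0, X1) {
  ll <- function(X) {
    X <- cbind(1, X)
    b <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% b)^2)
    n <- length(y)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  2 * (ll(X1) - ll(X0))
}

# toy OUTRIDER-style table builder
toy_outrider <- function(n = 10, mu = 1000, theta = 25, fdr = 0.5,
                         tissue = "t1", sample_prefix = "S") {
  data.table(sample_id = paste0(sample_prefix, seq_len(n)),
             individual_id = paste0("I", seq_len(n)),
             gene_id = "G1", tissue = tissue,
             x = rep(round(mu), n), mu = mu, theta = theta, fdr = fdr)
}
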