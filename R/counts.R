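## Count-level RNA-seq computations: pseudoreference (median-of-ratios)
## normalization, log2(x+1) transform, per-region log2 fold changes, a
## bootstrap-calibrated two-sample t-test, and the 95th-percentile
## fluorescence comparison used for induction experiments.

#' Pseudoreference (median-of-ratios) normalization
#'
#' For each gene the geometric mean of its counts across all samples is the
#' pseudoreference; each sample's size factor is the median, over genes with
#' a positive geometric mean, of the ratio count/pseudoreference. Normalized
#' counts are raw counts divided by the sample's size factor.
#'
#' @param counts Non-negative numeric matrix, genes x samples (>= 2
#'   samples), with dimnames.
#' @return A list of class `normalized_counts`: `size_factors`,
#'   `normalized`, `log2` (the `log2(x+1)` transform of the normalized
#'   counts), `n_reference_genes`.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' pseudoreference_normalize(m)$size_factors  # (sqrt(2)/2, sqrt(2))
#' @export
pseudoreference_normalize <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot("counts must be non-negative" = all(counts >= 0),
            "need >= 2 samples" = ncol(counts) >= 2)
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)  # genes with nonzero count in every sample
  if (!any(ref)) stop("no gene with nonzero counts in every sample")
  geo <- exp(log_geo[ref])
  sf <- apply(counts[ref, , drop = FALSE], 2, function(s) median(s / geo))
  normalized <- sweep(counts, 2, sf, "/")
  structure(list(size_factors = sf, normalized = normalized,
                 log2 = log2p1(normalized), n_reference_genes = sum(ref)),
            class = "normalized_counts")
}

#' log2(x + 1) transform
#'
#' @param values Non-negative numeric vector or matrix.
#' @return `log2(values + 1)`.
#' @export
log2p1 <- function(values) {
  if (any(values < 0)) stop("log2p1 requires non-negative values")
  log2(values + 1)
}

#' Per-gene and per-region log2 fold changes
#'
#' Computes, for each gene, the log2 ratio of mean normalized counts between
#' two sample groups, and aggregates genes into regions by their mean. Genes
#' with a zero denominator mean fall back to the difference of group means
#' in `log2(x+1)` space and are flagged. Both the ratio-of-means and the
#' log-space variants are returned.
#'
#' @param norm A `normalized_counts` object (or a normalized matrix).
#' @param group_a,group_b Column names (or indices) of the two groups;
#'   fold change is A over B.
#' @param regions Optional named character vector or two-column data frame
#'   (`gene`, `region`) mapping genes to regions; unmapped genes form their
#'   own region.
#' @return A list of class `region_log2fc`: `genes` (data frame `gene`,
#'   `region`, `log2fc`, `log2fc_logspace`, `flagged`), `regions` (data
#'   frame `region`, `log2fc`, `log2fc_logspace`, `n_genes`).
#' @export
region_log2fc <- function(norm, group_a, group_b, regions = NULL) {
  mat <- if (inherits(norm, "normalized_counts")) norm$normalized else norm
  stopifnot("both groups must be non-empty" =
              length(group_a) > 0 && length(group_b) > 0)
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  log_a <- rowMeans(log2p1(a)); log_b <- rowMeans(log2p1(b))
  flagged <- mean_b == 0 | mean_a == 0
  lfc <- ifelse(flagged, log_a - log_b, log2(mean_a / mean_b))
  genes <- rownames(mat)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(mat)))
  region_of <- genes
  if (!is.null(regions)) {
    if (is.data.frame(regions)) {
      regions <- setNames(as.character(regions[[2]]),
                          as.character(regions[[1]]))
    }
    hit <- genes %in% names(regions)
    region_of[hit] <- regions[genes[hit]]
  }
  gene_df <- data.frame(gene = genes, region = region_of, log2fc = lfc,
                        log2fc_logspace = log_a - log_b, flagged = flagged,
                        stringsAsFactors = FALSE)
  reg_df <- do.call(rbind, lapply(split(gene_df, gene_df$region), function(d)
    data.frame(region = d$region[1], log2fc = mean(d$log2fc),
               log2fc_logspace = mean(d$log2fc_logspace),
               n_genes = nrow(d), stringsAsFactors = FALSE)))
  rownames(reg_df) <- NULL
  structure(list(genes = gene_df, regions = reg_df),
            class = "region_log2fc")
}

two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Bootstrap-calibrated two-sample t-test per gene
#'
#' For each gene, computes the pooled-variance two-sample t statistic
#' between the groups and calibrates it against a null distribution built by
#' centering each group at zero mean, pooling the centered values, and
#' resampling the two groups with replacement `n_boot` times. The p-value is
#' `(1 + #(|t*| >= |t|)) / (n_boot + 1)`. Genes with degenerate (zero
#' pooled) variance fall back to a label-permutation test and are flagged.
#'
#' @param mat_a,mat_b Matrices (genes x samples) for the two groups, same
#'   genes in the same order; >= 2 samples per group.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return Data frame `gene`, `t`, `p_value`, `flagged`.
#' @export
bootstrap_ttest <- function(mat_a, mat_b, n_boot = 1000, seed = NULL) {
  mat_a <- as.matrix(mat_a); mat_b <- as.matrix(mat_b)
  stopifnot("same genes in both groups" = nrow(mat_a) == nrow(mat_b),
            ">= 2 samples per group" = ncol(mat_a) >= 2 && ncol(mat_b) >= 2)
  if (!is.null(seed)) set.seed(seed)
  na <- ncol(mat_a); nb <- ncol(mat_b); n <- na + nb
  g <- nrow(mat_a)
  t_obs <- p <- rep(NA_real_, g)
  flagged <- logical(g)
  for (i in seq_len(g)) {
    a <- mat_a[i, ]; b <- mat_b[i, ]
    t_i <- two_sample_t(a, b)
    if (is.na(t_i)) {  # degenerate variance: permute labels, use mean diff
      flagged[i] <- TRUE
      pool <- c(a, b)
      d_obs <- mean(a) - mean(b)
      d_null <- vapply(seq_len(n_boot), function(k) {
        idx <- sample.int(n, na)
        mean(pool[idx]) - mean(pool[-idx])
      }, 0)
      t_obs[i] <- 0
      p[i] <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_boot + 1)
      next
    }
    pool <- c(a - mean(a), b - mean(b))
    ia <- matrix(sample.int(n, na * n_boot, replace = TRUE), na)
    ib <- matrix(sample.int(n, nb * n_boot, replace = TRUE), nb)
    ra <- matrix(pool[ia], na); rb <- matrix(pool[ib], nb)
    ma <- colMeans(ra); mb <- colMeans(rb)
    va <- (colSums(ra^2) - na * ma^2) / (na - 1)
    vb <- (colSums(rb^2) - nb * mb^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    t_null <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    t_null[!is.finite(t_null)] <- 0
    t_obs[i] <- t_i
    p[i] <- (1 + sum(abs(t_null) >= abs(t_i))) / (n_boot + 1)
  }
  genes <- rownames(mat_a)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(g))
  data.frame(gene = genes, t = t_obs, p_value = p, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' 95th-percentile fluorescence comparison across paired replicates
#'
#' For strongly tailed fluorescence distributions, compares induced versus
#' control strains by the 95th percentile of background-subtracted per-cell
#' fluorescence in each replicate, followed by a paired one-sided t-test
#' (H1: induced exceeds control).
#'
#' @param induced,control Lists of per-replicate numeric vectors of raw
#'   per-cell fluorescence; the lists are paired by position (>= 2
#'   replicates; matched lengths required).
#' @param background_induced,background_control Per-replicate image
#'   background scalars (recycled if length 1).
#' @return A list of class `p95_compare`: `p95_induced`, `p95_control`
#'   (per-replicate 95th percentiles of F - I), `mean_difference`, `t`,
#'   `p_value`, `degenerate`.
#' @export
percentile95_compare <- function(induced, control,
                                 background_induced = 0,
                                 background_control = 0) {
  stopifnot("replicates must be paired" = length(induced) == length(control),
            "need >= 2 paired replicates" = length(induced) >= 2)
  bi <- rep_len(background_induced, length(induced))
  bc <- rep_len(background_control, length(control))
  p95_i <- mapply(function(v, b) quantile(v - b, 0.95, names = FALSE),
                  induced, bi)
  p95_c <- mapply(function(v, b) quantile(v - b, 0.95, names = FALSE),
                  control, bc)
  tt <- paired_main_vs_sub_test(p95_c, p95_i)  # H1: induced > control
  structure(list(p95_induced = p95_i, p95_control = p95_c,
                 mean_difference = mean(p95_i - p95_c), t = tt$t,
                 p_value = tt$p_value, degenerate = tt$degenerate),
            class = "p95_compare")
}
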