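## Replicate-level statistics: conjugative transfer frequencies, one-way
## ANOVA with Tukey compact letter display, Bartlett's test, and the
## Table-1-style subpopulation summary.

#' Conjugative transfer frequency from mating plate counts
#'
#' Transfer frequency is exconjugant colony-forming units per donor CFU in
#' the same assay, with plate counts scaled by their dilution factors and
#' background-corrected by subtracting the spontaneous-growth control. When
#' the corrected exconjugant count is not positive the assay is below the
#' detection limit, reported as one exconjugant colony at the plated
#' dilution per donor CFU.
#'
#' @param exconjugant_cfu Colonies on the selective (exconjugant) plate.
#' @param donor_cfu Colonies on the donor plate (> 0).
#' @param exconjugant_dilution,donor_dilution Dilution factors (a count of
#'   100 colonies at dilution 1e2 means 1e4 CFU); default 1.
#' @param background_cfu Colonies on the spontaneous-growth control plate at
#'   the exconjugant dilution; default 0.
#' @return A data frame `frequency`, `below_detection`, `detection_limit`
#'   (one row per assay; vectorized over inputs).
#' @examples
#' transfer_frequency(100, 1e7, exconjugant_dilution = 1e2,
#'                    donor_dilution = 1e3)  # 1e-6
#' @export
transfer_frequency <- function(exconjugant_cfu, donor_cfu,
                               exconjugant_dilution = 1, donor_dilution = 1,
                               background_cfu = 0) {
  stopifnot("donor CFU must be > 0" = all(donor_cfu > 0),
            "CFU must be >= 0" =
              all(exconjugant_cfu >= 0) && all(background_cfu >= 0),
            "dilutions must be > 0" =
              all(exconjugant_dilution > 0) && all(donor_dilution > 0))
  corrected <- pmax(exconjugant_cfu - background_cfu, 0)
  donor_total <- donor_cfu * donor_dilution
  freq <- corrected * exconjugant_dilution / donor_total
  below <- corrected <= 0
  data.frame(frequency = ifelse(below, NA_real_, freq),
             below_detection = below,
             detection_limit = exconjugant_dilution / donor_total)
}

#' Bartlett's test of homogeneity of variances
#'
#' Thin wrapper around [stats::bartlett.test()] that flags the degenerate
#' all-constant case instead of failing.
#'
#' @param values Numeric measurements.
#' @param group Group label per measurement (>= 2 groups, each n >= 2).
#' @return A list `statistic`, `df`, `p_value`, `degenerate`.
#' @export
bartlett_groups <- function(values, group) {
  group <- as.factor(group)
  stopifnot(">= 2 groups required" = nlevels(group) >= 2,
            "each group needs n >= 2" = all(table(group) >= 2))
  vars <- tapply(values, group, var)
  if (all(vars == 0)) {
    return(list(statistic = 0, df = nlevels(group) - 1, p_value = NA_real_,
                degenerate = TRUE))
  }
  bt <- bartlett.test(values, group)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = bt$p.value, degenerate = FALSE)
}

## Compact letter display by insert-and-absorb over the pairwise
## non-significance graph. Groups are processed in decreasing mean order; a
## group joins every existing letter whose members it is not significantly
## different from, otherwise it opens a new letter which then absorbs all
## compatible earlier groups. Redundant (subset) letters are dropped.
cld_insert_absorb <- function(groups, nonsig) {
  letters_sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (k in seq_along(letters_sets)) {
      if (all(nonsig[g, letters_sets[[k]]])) {
        letters_sets[[k]] <- c(letters_sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      set <- g
      for (h in groups[seq_len(match(g, groups) - 1)]) {
        if (all(nonsig[h, set])) set <- c(set, h)
      }
      letters_sets[[length(letters_sets) + 1]] <- set
    }
  }
  keep <- rep(TRUE, length(letters_sets))
  for (i in seq_along(letters_sets)) {
    for (j in seq_along(letters_sets)) {
      if (i != j && keep[j] &&
          all(letters_sets[[i]] %in% letters_sets[[j]]) &&
          (length(letters_sets[[i]]) < length(letters_sets[[j]]) ||
           (length(letters_sets[[i]]) == length(letters_sets[[j]]) &&
            i > j))) {
        keep[i] <- FALSE
      }
    }
  }
  letters_sets <- letters_sets[keep]
  ## name letters by the first group (in factor-level order) each set holds,
  ## so the display does not depend on which set was opened first
  lv <- attr(nonsig, "dimnames")[[1]]
  first_lv <- vapply(letters_sets, function(s) min(match(s, lv)), 0)
  letters_sets <- letters_sets[order(first_lv)]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(letters_sets)) {
    for (g in letters_sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         "")
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-factor analysis of variance, computes Tukey multiple
#' comparisons of means at the requested family-wise confidence level, and
#' assigns compact letters: groups sharing a letter are not significantly
#' different. Letters are assigned deterministically in decreasing order of
#' group mean, so the brightest (or most frequent) group is lettered first.
#'
#' @param values Numeric measurements.
#' @param group Group label per measurement (>= 2 groups, each n >= 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list of class `anova_letters`: `anova_F`, `anova_p`, `tukey`
#'   (pairwise data frame `comparison`, `diff`, `p_adj`), `letters` (named
#'   character vector per group), `means`, `alpha`.
#' @export
anova_tukey_letters <- function(values, group, alpha = 0.05) {
  group <- as.factor(group)
  stopifnot(">= 2 groups required" = nlevels(group) >= 2,
            "each group needs n >= 2" = all(table(group) >= 2))
  fit <- aov(values ~ group, data = data.frame(values = values,
                                               group = group))
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  lv <- levels(group)
  nonsig <- matrix(TRUE, nlevels(group), nlevels(group),
                   dimnames = list(lv, lv))
  for (cmp in rownames(tk)) {
    pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    sig <- tk[cmp, "p adj"] < alpha
    nonsig[pair[1], pair[2]] <- nonsig[pair[2], pair[1]] <- !sig
  }
  means <- tapply(values, group, mean)
  ordered_groups <- names(sort(means, decreasing = TRUE))
  lets <- cld_insert_absorb(ordered_groups, nonsig)[lv]
  structure(list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"],
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL),
                 letters = lets, means = means, alpha = alpha),
            class = "anova_letters")
}

#' Table-style summary of subpopulation percentages across clones
#'
#' Aggregates per-clone subpopulation fractions into a mean +/- sd table by
#' promoter (and any further grouping such as sampling time).
#'
#' @param data Data frame with a `fraction` column (proportion in `[0,1]`)
#'   and grouping columns.
#' @param by Names of the grouping columns (default `"promoter"`).
#' @return Data frame with the grouping columns, `mean_percent`,
#'   `sd_percent` (`NA` for a single clone), `n`, and a formatted `label`
#'   like `"9.10 +/- 0.87"`.
#' @export
summarize_subpops <- function(data, by = "promoter") {
  if (nrow(data) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(by)))
    names(out) <- by
    out$mean_percent <- numeric(0); out$sd_percent <- numeric(0)
    out$n <- integer(0); out$label <- character(0)
    return(out)
  }
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(data, key), function(d) {
    pct <- 100 * d$fraction
    r <- d[1, by, drop = FALSE]
    r$mean_percent <- mean(pct)
    r$sd_percent <- if (nrow(d) > 1) sd(pct) else NA_real_
    r$n <- nrow(d)
    r$label <- if (is.na(r$sd_percent)) sprintf("%.2f", r$mean_percent)
               else sprintf("%.2f ± %.2f", r$mean_percent, r$sd_percent)
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
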