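# Factorial statistics: three-way ANOVA per feature, Tukey HSD post-hoc
# contrasts, the per-animal repertoire variance statistic with LS-means
# comparison, usage-vector regression, and the fold-change marker screen.

ANOVA_TERMS <- c("AOS", "TT", "CpG", "AOSxTT", "AOSxCpG", "TTxCpG",
                 "AOSxTTxCpG")

prep_response <- function(values, design) {
  if (is.data.frame(values)) {
    stopifnot(all(c("animal_id", "value") %in% names(values)))
    v <- stats::setNames(values$value, values$animal_id)
  } else {
    v <- values
  }
  if (is.null(names(v))) stop("values must be named by animal_id")
  missing <- setdiff(design$animal_id, names(v))
  if (length(missing) > 0) {
    stop("values missing for animal(s): ", paste(missing, collapse = ", "))
  }
  data.frame(
    y = as.numeric(v[design$animal_id]),
    aos = factor(ifelse(design$aos, "+", "-"), levels = c("-", "+")),
    tt = factor(ifelse(design$tt, "+", "-"), levels = c("-", "+")),
    cpg = factor(ifelse(design$cpg, "+", "-"), levels = c("-", "+")),
    cell = treatment_cell(design)
  )
}

check_cells <- function(df, min_n = 2) {
  counts <- table(df$cell)
  bad <- names(counts)[counts < min_n]
  empty <- setdiff(CELL_LEVELS, names(counts)[counts > 0])
  if (length(empty) > 0) {
    stop("empty treatment cell(s): ", paste(empty, collapse = ", "))
  }
  if (length(bad) > 0) {
    stop("treatment cell(s) with fewer than ", min_n, " animals: ",
         paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Three-way factorial ANOVA on one response
#'
#' Fits the full-factorial linear model `y ~ AOS * TT * CpG` and returns
#' the sequential ANOVA table (on balanced designs the sequential sums of
#' squares coincide with the marginal ones, so term order does not
#' matter). A zero-variance response is flagged degenerate and reported
#' with p = 1 for every term.
#'
#' @param values per-animal measurements: named numeric vector or tibble
#'   (`animal_id`, `value`).
#' @param design design tibble covering all 8 cells with >= 2 animals.
#' @param alpha significance threshold for the `significant` column.
#' @return tibble `term`, `df`, `sumsq`, `statistic`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
threeway_anova <- function(values, design, alpha = 0.05) {
  df <- check_cells(prep_response(values, design))
  if (stats::var(df$y) == 0 || !all(is.finite(df$y))) {
    return(tibble::tibble(
      term = ANOVA_TERMS, df = 1L, sumsq = 0, statistic = NA_real_,
      p_value = 1, significant = FALSE, degenerate = TRUE
    ))
  }
  fit <- stats::lm(y ~ aos * tt * cpg, data = df)
  at <- stats::anova(fit)
  terms <- rownames(at)
  keep <- terms != "Residuals"
  label <- gsub("aos", "AOS", gsub("tt", "TT", gsub("cpg", "CpG",
                gsub(":", "x", terms[keep]))))
  tibble::tibble(
    term = label,
    df = at$Df[keep],
    sumsq = at$`Sum Sq`[keep],
    statistic = at$`F value`[keep],
    p_value = at$`Pr(>F)`[keep],
    significant = at$`Pr(>F)`[keep] < alpha,
    degenerate = FALSE
  )
}

#' Per-feature three-way ANOVA over a usage table
#'
#' Runs [threeway_anova()] on each feature's percent-of-repertoire column.
#' No correction across features is applied by default, matching per-
#' segment reporting at P < 0.05; `adjust = "BH"` adds a
#' Benjamini-Hochberg adjusted column per term.
#'
#' @param usage usage table.
#' @param design design tibble.
#' @param adjust `"none"` or `"BH"`.
#' @param alpha significance threshold.
#' @return tibble with one row per feature x term.
#' @export
usage_anova <- function(usage, design, adjust = c("none", "BH"),
                        alpha = 0.05) {
  adjust <- match.arg(adjust)
  feats <- sort(unique(usage$feature))
  out <- purrr::map_dfr(feats, function(f) {
    sub <- usage[usage$feature == f, , drop = FALSE]
    res <- threeway_anova(
      stats::setNames(sub$percent, sub$animal_id), design, alpha = alpha
    )
    res$feature <- f
    res
  })
  out <- out[, c("feature", setdiff(names(out), "feature"))]
  if (adjust == "BH") {
    out <- dplyr::group_by(out, .data$term)
    out <- dplyr::mutate(out,
                         p_adjusted = stats::p.adjust(.data$p_value, "BH"))
    out <- dplyr::ungroup(out)
  }
  out
}

#' Tukey HSD post-hoc contrasts between treatment cells
#'
#' Fits a cell-means model on the (optionally subsetted) treatment groups
#' and returns all pairwise mean differences with studentized-range
#' adjusted p-values.
#'
#' @param values per-animal measurements (named vector or tibble).
#' @param design design tibble.
#' @param groups treatment-cell labels to compare (default all 8).
#' @return tibble `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(values, design, groups = NULL) {
  df <- prep_response(values, design)
  if (!is.null(groups)) {
    df <- df[df$cell %in% groups, , drop = FALSE]
  }
  df$cell <- droplevels(df$cell)
  if (nlevels(df$cell) < 2) stop("tukey_posthoc: need >= 2 groups")
  tukey_cells(df)
}

# Tukey HSD over treatment cells. Cell labels contain "+"/"-", which would
# make TukeyHSD's "levelA-levelB" rownames ambiguous, so the model runs on
# safe labels and contrasts are reconstructed as "cellA vs cellB".
tukey_cells <- function(df) {
  lev <- levels(df$cell)
  df$gcell <- factor(paste0("G", match(df$cell, lev)),
                     levels = paste0("G", seq_along(lev)))
  fit <- stats::aov(y ~ gcell, data = df)
  tk <- stats::TukeyHSD(fit)$gcell
  idx <- stringi::stri_match_first_regex(rownames(tk), "^G(\\d+)-G(\\d+)$")
  tibble::tibble(
    contrast = paste(lev[as.integer(idx[, 2])], "vs",
                     lev[as.integer(idx[, 3])]),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
}

#' Per-animal repertoire variance statistic
#'
#' For every feature, the squared deviation of the animal's percent of
#' repertoire from the across-animal mean percent; the whole-animal
#' variation is the sum of those squared deviations over all features.
#'
#' @param usage usage table.
#' @param by_feature return the per-feature squared deviations instead of
#'   the per-animal totals.
#' @return tibble `animal_id`, `variation` (or `animal_id`, `feature`,
#'   `sq_dev` when `by_feature`).
#' @export
animal_variance <- function(usage, by_feature = FALSE) {
  if (length(unique(usage$animal_id)) < 2) {
    stop("animal_variance: need >= 2 animals")
  }
  dev <- dplyr::group_by(usage, .data$feature)
  dev <- dplyr::mutate(dev, sq_dev = (.data$percent - mean(.data$percent))^2)
  dev <- dplyr::ungroup(dev)
  if (by_feature) {
    return(dev[, c("animal_id", "feature", "sq_dev")])
  }
  dplyr::summarise(dplyr::group_by(dev, .data$animal_id),
                   variation = sum(.data$sq_dev), .groups = "drop")
}

#' Compare per-animal variance across treatment cells
#'
#' Least-squares means analysis of the whole-animal variation: a
#' cell-means linear model gives the marginal (LS) group means, the global
#' F test, and all pairwise contrasts with Tukey-adjusted p-values.
#'
#' @param var_stats tibble `animal_id`, `variation` from
#'   [animal_variance()].
#' @param design design tibble.
#' @return list with `global` (one-row tibble `statistic`, `df1`, `df2`,
#'   `p_value`), `means` (tibble `group`, `lsmean`, `se`) and `contrasts`
#'   (Tukey pairwise tibble).
#' @export
compare_variance <- function(var_stats, design) {
  df <- prep_response(
    stats::setNames(var_stats$variation, var_stats$animal_id), design
  )
  check_cells(df)
  df$cell <- droplevels(df$cell)
  fit <- stats::aov(y ~ cell, data = df)
  an <- stats::anova(fit)
  global <- tibble::tibble(
    statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1]
  )
  mse <- an$`Mean Sq`[2]
  cell_n <- table(df$cell)
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cell = as.character(df$cell), y = df$y),
                    .data$cell),
    lsmean = mean(.data$y), .groups = "drop"
  )
  means$se <- sqrt(mse / as.numeric(cell_n[means$cell]))
  names(means)[1] <- "group"
  contrasts <- tukey_cells(df)
  list(global = global, means = means, contrasts = contrasts)
}

#' Regression of one group-mean usage vector on another
#'
#' Ordinary least squares of `y` on `x` over the shared feature universe;
#' reports the coefficient of determination and the slope p-value.
#'
#' @param x,y named numeric vectors (same features, >= 3 of them).
#' @return one-row tibble `r_squared`, `slope`, `p_value`, `n_features`.
#' @export
usage_regression <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    if (length(common) < length(x) || length(common) < length(y)) {
      x <- x[common]
      y <- y[common]
    } else {
      y <- y[names(x)]
    }
  }
  if (length(x) < 3) stop("usage_regression: need >= 3 features")
  if (stats::var(x) == 0) stop("usage_regression: zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    r_squared = sm$r.squared,
    slope = stats::coef(fit)[["x"]],
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    n_features = length(x)
  )
}

#' Fold-change marker screen on a TPM table
#'
#' Per gene, compares the mean TPM of the factor's `+` animals against the
#' `-` animals. The signed fold change follows the larger-over-smaller
#' convention: `m+/m-` when the `+` mean is at least the `-` mean, else
#' `-(m-/m+)`, so |FC| >= 1 by construction. The p-value comes from a
#' Welch two-sample test on log2(TPM + 1). A gene is flagged exactly when
#' |FC| > 2 and p < 0.05.
#'
#' @param tpm tibble with a `gene` column and one numeric column per
#'   animal.
#' @param design design tibble.
#' @param factor `"AOS"`, `"TT"` or `"CpG"`.
#' @return tibble `gene`, `mean_pos`, `mean_neg`, `fold_change`,
#'   `p_value`, `flagged` (genes with a zero mean get NA fold change and
#'   are never flagged).
#' @export
marker_screen <- function(tpm, design, factor = c("AOS", "TT", "CpG")) {
  factor <- match.arg(factor)
  col <- switch(factor, AOS = "aos", TT = "tt", CpG = "cpg")
  pos <- design$animal_id[design[[col]]]
  neg <- design$animal_id[!design[[col]]]
  if (length(pos) < 2 || length(neg) < 2) {
    stop("marker_screen: need >= 2 animals per factor level")
  }
  missing <- setdiff(c(pos, neg), names(tpm))
  if (length(missing) > 0) {
    stop("marker_screen: TPM table missing animal(s): ",
         paste(missing, collapse = ", "))
  }
  mp <- as.matrix(tpm[, pos])
  mn <- as.matrix(tpm[, neg])
  mean_pos <- rowMeans(mp)
  mean_neg <- rowMeans(mn)
  fc <- ifelse(mean_pos >= mean_neg, mean_pos / mean_neg,
               -(mean_neg / mean_pos))
  fc[mean_pos == 0 | mean_neg == 0] <- NA_real_
  p <- vapply(seq_len(nrow(tpm)), function(i) {
    a <- log2(mp[i, ] + 1)
    b <- log2(mn[i, ] + 1)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  tibble::tibble(
    gene = tpm$gene,
    mean_pos = mean_pos,
    mean_neg = mean_neg,
    fold_change = fc,
    p_value = p,
    flagged = !is.na(fc) & abs(fc) > 2 & p < 0.05
  )
}
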