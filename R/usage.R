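# Fractional gene-segment abundance and percent-of-repertoire tables.
#
# Usage tables are long tibbles (animal_id, feature, count, percent) with
# an "axis" attribute; each animal's percentages sum to 100 over the
# features included for that axis (including "U" where applicable).

#' Fractional gene-segment abundance for one animal
#'
#' Implements the ambiguity-weighted counting rule: a record whose call
#' list names exactly one gene contributes 1.0 to that gene; a record with
#' two candidate genes contributes 0.5 to each; records with three or more
#' candidates (or none) are excluded from the axis entirely.
#'
#' @param records records tibble from a single animal and single locus.
#' @param axis `"V"`, `"D"` or `"J"`.
#' @return named numeric vector of summed weights per gene (sorted by
#'   name).
#' @export
assign_abundance <- function(records, axis = c("V", "D", "J")) {
  axis <- match.arg(axis)
  if (length(unique(records$locus)) > 1) {
    stop("assign_abundance: records span multiple loci; filter to one locus first")
  }
  calls <- records[[paste0(tolower(axis), "_call")]]
  n <- n_calls(calls)
  counts <- numeric(0)
  single <- calls[n == 1L]
  if (length(single) > 0) {
    t1 <- table(single)
    counts <- stats::setNames(as.numeric(t1), names(t1))
  }
  dbl <- calls[n == 2L]
  if (length(dbl) > 0) {
    genes2 <- unlist(stringi::stri_split_fixed(dbl, ","), use.names = FALSE)
    t2 <- table(genes2)
    add <- stats::setNames(as.numeric(t2) * 0.5, names(t2))
    all_genes <- union(names(counts), names(add))
    merged <- stats::setNames(numeric(length(all_genes)), all_genes)
    merged[names(counts)] <- counts
    merged[names(add)] <- merged[names(add)] + add
    counts <- merged
  }
  counts[order(names(counts))]
}

# Undetermined-segment mask per the pairing rules: segment not reported,
# multiple candidate genes, or (D only) alignment under `d_min_nt`
# nucleotides.
undetermined_mask <- function(records, segment = c("d", "j"), d_min_nt = 6) {
  segment <- match.arg(segment)
  calls <- records[[paste0(segment, "_call")]]
  n <- n_calls(calls)
  mask <- n == 0L | n > 1L
  if (segment == "d") {
    mask <- mask | records$d_alignment_length < d_min_nt
  }
  mask
}

#' Convert per-animal fractional counts to percent of repertoire
#'
#' @param counts long tibble with columns `animal_id`, `feature`, `count`.
#' @param features optional feature universe; absent features are reported
#'   as 0 for every animal.
#' @return usage table: long tibble `animal_id`, `feature`, `count`,
#'   `percent`; animals with zero total weight are dropped with a warning.
#' @export
usage_percent <- function(counts, features = NULL) {
  stopifnot(all(c("animal_id", "feature", "count") %in% names(counts)))
  totals <- tapply(counts$count, counts$animal_id, sum)
  zero <- names(totals)[totals <= 0 | is.na(totals)]
  if (length(zero) > 0) {
    warning("usage_percent: dropping animal(s) with zero assigned weight: ",
            paste(zero, collapse = ", "))
    counts <- counts[!counts$animal_id %in% zero, , drop = FALSE]
  }
  if (is.null(features)) features <- sort(unique(counts$feature))
  out <- tidyr::complete(
    counts,
    animal_id = unique(counts$animal_id),
    feature = features,
    fill = list(count = 0)
  )
  out <- dplyr::group_by(out, .data$animal_id)
  out <- dplyr::mutate(out, percent = 100 * .data$count / sum(.data$count))
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$animal_id, .data$feature)
  out
}

#' Per-animal usage table along a chosen axis
#'
#' Computes percent-of-repertoire per animal for gene segments, isotypes or
#' CDR3 amino-acid lengths. By default productive and unknown-functionality
#' records enter gene-segment usage (mirroring total assessed reads);
#' `functionality = "productive"` restricts to productive only. The D and J
#' axes carry an explicit `"U"` (undetermined) feature fed by the pairing
#' rules; on the V axis records without a usable call are simply excluded.
#' The isotype axis uses records with an identifiable constant region and
#' aggregates IgG subclasses; the CDR3-length axis uses productive,
#' motif-valid records with length = junction length - 2 anchors.
#'
#' @param records records tibble (any number of animals).
#' @param axis `"V"`, `"D"`, `"J"`, `"isotype"` or `"cdr3_length"`.
#' @param locus locus analyzed (lambda is excluded from analyses; pass
#'   records of one locus).
#' @param functionality functionality classes included on gene axes.
#' @param undetermined include the `"U"` feature (default TRUE on D/J).
#' @param d_min_nt minimum D alignment length in nucleotides.
#' @return usage table (see [usage_percent()]) with attribute `axis`.
#' @export
usage_table <- function(records, axis = c("V", "D", "J", "isotype",
                                          "cdr3_length"),
                        locus = "IGH",
                        functionality = c("productive", "unknown"),
                        undetermined = NULL, d_min_nt = 6) {
  axis <- match.arg(axis)
  if (axis == "isotype") {
    out <- constant_usage(records[records$locus == locus, , drop = FALSE])
  } else if (axis == "cdr3_length") {
    out <- cdr3_length_distribution(records, locus = locus)$distribution
  } else {
    if (is.null(undetermined)) undetermined <- axis %in% c("D", "J")
    loc <- records$locus == locus
    func <- classify_functionality_vec(
      records$vj_in_frame[loc], records$stop_codon[loc],
      records$junction_aa[loc]
    )
    sel <- func %in% functionality
    animal <- records$animal_id[loc][sel]
    calls <- records[[paste0(tolower(axis), "_call")]][loc][sel]
    n <- n_calls(calls)
    if (undetermined) {
      und <- n == 0L | n > 1L
      if (axis == "D") {
        und <- und | records$d_alignment_length[loc][sel] < d_min_nt
      }
      feature <- calls
      feature[und] <- "U"
      weight <- rep(1, length(calls))
      keep <- rep(TRUE, length(calls))
      multi <- rep(FALSE, length(calls))
    } else {
      feature <- calls
      weight <- c(0, 1, 0.5)[pmin(n, 2L) + 1L]
      keep <- n == 1L | n == 2L
      multi <- n == 2L
    }
    animal <- animal[keep]
    feature <- feature[keep]
    weight <- weight[keep]
    multi <- multi[keep]
    # split two-gene calls into half-weight contributions
    if (any(multi)) {
      genes <- stringi::stri_split_fixed(feature[multi], ",")
      animal <- c(animal[!multi], rep(animal[multi], lengths(genes)))
      weight <- c(weight[!multi], rep(weight[multi], lengths(genes)))
      feature <- c(feature[!multi], unlist(genes, use.names = FALSE))
    }
    key <- stringi::stri_c(animal, "\r", feature)
    sums <- rowsum(weight, key)
    parts <- stringi::stri_split_fixed(rownames(sums), "\r")
    agg <- tibble::tibble(
      animal_id = vapply(parts, `[`, character(1), 1),
      feature = vapply(parts, `[`, character(1), 2),
      count = as.numeric(sums[, 1])
    )
    out <- usage_percent(agg)
  }
  attr(out, "axis") <- axis
  attr(out, "locus") <- locus
  out
}

#' Constant-region (isotype) usage
#'
#' Percent per isotype among heavy-chain records with an identifiable
#' constant region, IgG subclasses aggregated into `"IgG"`.
#'
#' @param records heavy-chain records tibble.
#' @return usage table over isotypes (empty, with a warning, if no record
#'   carries an identifiable constant region).
#' @export
constant_usage <- function(records) {
  records <- records[records$locus == "IGH", , drop = FALSE]
  known <- records[records$c_call %in% ISOTYPES, , drop = FALSE]
  if (nrow(known) == 0) {
    warning("constant_usage: no records with identifiable constant region")
    out <- tibble::tibble(animal_id = character(0), feature = character(0),
                          count = numeric(0), percent = numeric(0))
    attr(out, "axis") <- "isotype"
    return(out)
  }
  iso <- ifelse(known$c_call %in% c("IgG1", "IgG2b", "IgG2c", "IgG3"),
                "IgG", known$c_call)
  agg <- dplyr::count(
    tibble::tibble(animal_id = known$animal_id, feature = iso),
    .data$animal_id, .data$feature, name = "count"
  )
  agg$count <- as.numeric(agg$count)
  out <- usage_percent(agg)
  attr(out, "axis") <- "isotype"
  out
}

#' Group-mean usage
#'
#' Mean percent per feature over the animals of each group (treatment cell
#' or single-factor level).
#'
#' @param usage usage table.
#' @param design design tibble.
#' @param by `"cell"` for the 8 treatment cells, or `"AOS"`, `"TT"`,
#'   `"CpG"` for the two pooled levels of one factor.
#' @return tibble `group`, `feature`, `mean_percent`.
#' @export
group_mean_usage <- function(usage, design, by = "cell") {
  grp <- group_labels(design, by)
  merged <- dplyr::inner_join(usage, grp, by = "animal_id")
  dplyr::summarise(dplyr::group_by(merged, .data$group, .data$feature),
                   mean_percent = mean(.data$percent), .groups = "drop")
}

group_labels <- function(design, by = "cell") {
  if (by == "cell") {
    out <- tibble::tibble(animal_id = design$animal_id,
                          group = as.character(treatment_cell(design)))
    attr(out, "levels") <- CELL_LEVELS
  } else {
    col <- switch(by, AOS = "aos", TT = "tt", CpG = "cpg",
                  stop("unknown grouping: ", by))
    out <- tibble::tibble(animal_id = design$animal_id,
                          group = paste0(by, ifelse(design[[col]], "+", "-")))
    attr(out, "levels") <- paste0(by, c("-", "+"))
  }
  out
}

#' High-frequency segments
#'
#' Features whose group-mean percent strictly exceeds the threshold in at
#' least one of the named treatment groups ("over five percent" is read
#' strictly; a feature at exactly the threshold is excluded).
#'
#' @param usage usage table.
#' @param design design tibble.
#' @param groups treatment-cell labels to scan (default the saline, TT+CpG
#'   and AOS+TT+CpG groups).
#' @param threshold percent threshold.
#' @return character vector of feature names (sorted).
#' @export
high_frequency_segments <- function(usage, design,
                                    groups = c("---", "-++", "+++"),
                                    threshold = 5) {
  if (nrow(usage) == 0) return(character(0))
  unknown <- setdiff(groups, CELL_LEVELS)
  if (length(unknown) > 0) {
    stop("high_frequency_segments: unknown group(s): ",
         paste(unknown, collapse = ", "))
  }
  gm <- group_mean_usage(usage, design, by = "cell")
  gm <- gm[gm$group %in% groups, , drop = FALSE]
  if (nrow(gm) == 0) return(character(0))
  hit <- dplyr::summarise(dplyr::group_by(gm, .data$feature),
                          top = max(.data$mean_percent), .groups = "drop")
  sort(hit$feature[hit$top > threshold])
}
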