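# V/(D)/J combination analysis: per-record resolution under the
# undetermined rules, frequency tables, top-k rankings, the low-frequency
# pair filter, and Circos link-file export.

#' Resolve V(D)J combinations per record
#'
#' A record is resolvable only when it is productive, its junction passes
#' the CDR3 motif rules, and exactly one V gene was identified. The D
#' component is `"U"` (undetermined) when no D was reported, multiple
#' candidate D genes were reported, or the D alignment spans fewer than
#' `d_min_nt` nucleotides; the J component is `"U"` when no J or multiple
#' J candidates were reported (the length rule targets the short random D
#' matches and is applied to D only — no J alignment length is carried).
#' Light-chain combinations have no D component (`NA`).
#'
#' @param records records tibble.
#' @param d_min_nt minimum D alignment length (nucleotides).
#' @return tibble of resolved combinations: `animal_id`, `locus`, `v`,
#'   `d`, `j` (unresolvable records are dropped).
#' @export
resolve_vdj <- function(records, d_min_nt = 6) {
  func <- classify_functionality(records)
  eligible <- func == "productive" & n_calls(records$v_call) == 1L
  cand <- records[eligible, , drop = FALSE]
  if (nrow(cand) > 0) {
    cand <- cand[cdr3_is_valid(cand), , drop = FALSE]
  }
  heavy <- cand$locus == "IGH"
  d <- rep(NA_character_, nrow(cand))
  if (any(heavy)) {
    und_d <- undetermined_mask(cand[heavy, , drop = FALSE], "d",
                               d_min_nt = d_min_nt)
    d[heavy] <- ifelse(und_d, "U", cand$d_call[heavy])
  }
  und_j <- undetermined_mask(cand, "j")
  tibble::tibble(
    animal_id = cand$animal_id,
    locus = cand$locus,
    v = cand$v_call,
    d = d,
    j = ifelse(und_j, "U", cand$j_call)
  )
}

combo_label <- function(resolved) {
  v <- short_gene_label(resolved$v)
  j <- short_gene_label(ifelse(resolved$j == "U", "U", resolved$j))
  if (all(is.na(resolved$d))) {
    paste(v, j, sep = "/")
  } else {
    d <- short_gene_label(ifelse(resolved$d == "U", "U", resolved$d))
    paste(v, d, j, sep = "/")
  }
}

#' Per-animal V(D)J pairing frequency table
#'
#' Percentages are of each animal's resolved records, so they sum to 100
#' per animal over all combinations including those containing `"U"`.
#' `mode = "VJ"` marginalizes the D component.
#'
#' @param records records tibble.
#' @param mode `"VDJ"` (heavy chain) or `"VJ"`.
#' @param locus locus analyzed.
#' @param d_min_nt minimum D alignment length.
#' @return long tibble `animal_id`, `v`, `d` (VDJ mode), `j`, `combo`,
#'   `count`, `percent`; animals without resolvable records are excluded
#'   with a warning.
#' @export
pairing_table <- function(records, mode = c("VDJ", "VJ"), locus = "IGH",
                          d_min_nt = 6) {
  mode <- match.arg(mode)
  if (locus != "IGH" && mode == "VDJ") {
    stop("pairing_table: VDJ mode applies to the heavy chain only")
  }
  res <- resolve_vdj(records[records$locus == locus, , drop = FALSE],
                     d_min_nt = d_min_nt)
  animals_in <- unique(records$animal_id[records$locus == locus])
  missing <- setdiff(animals_in, unique(res$animal_id))
  if (length(missing) > 0) {
    warning("pairing_table: no resolvable records for animal(s): ",
            paste(missing, collapse = ", "))
  }
  keys <- c("animal_id", "v", "j")
  if (mode == "VDJ") keys <- c("animal_id", "v", "d", "j")
  agg <- dplyr::count(res, dplyr::across(dplyr::all_of(keys)),
                      name = "count")
  agg <- dplyr::group_by(agg, .data$animal_id)
  agg <- dplyr::mutate(agg, percent = 100 * .data$count / sum(.data$count))
  agg <- dplyr::ungroup(agg)
  if (mode == "VJ") agg$d <- NA_character_
  agg$combo <- combo_label(agg)
  cols <- c("animal_id", "v", "d", "j", "combo", "count", "percent")
  if (mode == "VJ") cols <- setdiff(cols, "d")
  out <- agg[, cols]
  attr(out, "mode") <- mode
  attr(out, "locus") <- locus
  out
}

#' Group-mean pairing frequencies
#'
#' Mean percent per combination over the animals of each group; animals
#' lacking a combination contribute 0 for it.
#'
#' @param pt pairing table from [pairing_table()].
#' @param design design tibble.
#' @param by `"cell"` or a factor name (`"AOS"`, `"TT"`, `"CpG"`).
#' @return tibble `group`, `v`, (`d`,) `j`, `combo`, `mean_percent`.
#' @export
group_mean_pairing <- function(pt, design, by = "cell") {
  grp <- group_labels(design, by)
  grp <- grp[grp$animal_id %in% unique(pt$animal_id), , drop = FALSE]
  key_cols <- intersect(c("v", "d", "j", "combo"), names(pt))
  combos <- dplyr::distinct(pt[, key_cols])
  full <- tidyr::crossing(grp, combos)
  merged <- dplyr::left_join(
    full, pt[, c("animal_id", key_cols, "percent")],
    by = c("animal_id", key_cols)
  )
  merged$percent[is.na(merged$percent)] <- 0
  out <- dplyr::summarise(
    dplyr::group_by(merged, .data$group,
                    dplyr::across(dplyr::all_of(key_cols))),
    mean_percent = mean(.data$percent), .groups = "drop"
  )
  attr(out, "mode") <- attr(pt, "mode")
  attr(out, "locus") <- attr(pt, "locus")
  out
}

#' Rank the top-k combinations per group
#'
#' Takes the union of each named group's top-k combinations by group-mean
#' percent and reports every union member's rank within each group. Ties
#' are broken lexicographically by (v, d, j) and flagged.
#'
#' @param means group-mean pairing table from [group_mean_pairing()].
#' @param groups group labels to rank (default all groups present).
#' @param k ranks retained per group.
#' @return tibble `combo`, `group`, `rank`, `mean_percent`, `tied`.
#' @export
rank_top_combinations <- function(means, groups = NULL, k = 5) {
  stopifnot(k >= 1)
  if (is.null(groups)) groups <- sort(unique(means$group))
  means <- means[means$group %in% groups, , drop = FALSE]
  key_cols <- intersect(c("v", "d", "j"), names(means))
  ranked <- dplyr::group_by(means, .data$group)
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$mean_percent),
                           !!!rlang::syms(key_cols), .by_group = TRUE)
  ranked <- dplyr::mutate(
    ranked,
    rank = dplyr::row_number(),
    tied = duplicated(.data$mean_percent) |
      duplicated(.data$mean_percent, fromLast = TRUE)
  )
  ranked <- dplyr::ungroup(ranked)
  top <- unique(ranked$combo[ranked$rank <= k])
  out <- ranked[ranked$combo %in% top,
                c("combo", "group", "rank", "mean_percent", "tied")]
  dplyr::arrange(out, .data$combo, .data$group)
}

#' Drop pairs that are rare in every compared level
#'
#' A combination is retained when at least one compared group's mean
#' percent reaches the threshold; it is excluded only when *all* compared
#' levels sit below it (pairs "both detected at less than 0.1%" in a
#' two-level comparison).
#'
#' @param means group-mean pairing table restricted to the compared levels.
#' @param threshold percent threshold.
#' @return filtered group-mean table.
#' @export
filter_low_frequency_pairs <- function(means, threshold = 0.1) {
  if (nrow(means) == 0) return(means)
  keep <- dplyr::summarise(dplyr::group_by(means, .data$combo),
                           top = max(.data$mean_percent), .groups = "drop")
  out <- means[means$combo %in% keep$combo[keep$top >= threshold], ,
               drop = FALSE]
  attr(out, "mode") <- attr(means, "mode")
  attr(out, "locus") <- attr(means, "locus")
  out
}

#' Export a Circos link file of V/J pairings
#'
#' One whitespace-delimited line per V/J pair — `segmentV segmentJ count` —
#' with group-total resolved counts, suitable for chord-diagram renderers.
#' Undetermined segments are emitted as their own `"U"` segment.
#'
#' @param pt VJ-mode pairing table.
#' @param design design tibble.
#' @param group treatment-cell label whose animals are pooled.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_circos_links <- function(pt, design, group, path) {
  if (!identical(attr(pt, "mode"), "VJ")) {
    stop("export_circos_links: requires a VJ-mode pairing table")
  }
  grp <- group_labels(design, "cell")
  animals <- grp$animal_id[grp$group == group]
  sub <- pt[pt$animal_id %in% animals, , drop = FALSE]
  agg <- dplyr::summarise(dplyr::group_by(sub, .data$v, .data$j),
                          count = sum(.data$count), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$v, .data$j)
  lines <- sprintf("%s %s %d", short_gene_label(agg$v),
                   short_gene_label(agg$j), as.integer(agg$count))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a Circos link file back into a count table
#'
#' @param path link file written by [export_circos_links()].
#' @return tibble `v`, `j`, `count` (short gene labels).
#' @export
read_circos_links <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(v = character(0), j = character(0),
                          count = integer(0)))
  }
  parts <- stringi::stri_split_regex(lines, "\\s+")
  tibble::tibble(
    v = vapply(parts, `[`, character(1), 1),
    j = vapply(parts, `[`, character(1), 2),
    count = as.integer(vapply(parts, `[`, character(1), 3))
  )
}
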