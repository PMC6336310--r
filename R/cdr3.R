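# CDR3 length distributions, unique-CDR3 set construction, shared-by-k
# tables and pairwise overlap percentages.
#
# The stored clonotype string is the full junction (anchors included);
# length reporting subtracts the two anchor residues. Uniqueness is per
# amino-acid string within a locus; heavy and kappa chains are never
# paired (bulk RNA-seq carries no pairing information).

#' CDR3 amino-acid length distribution
#'
#' Per-animal percent per CDR3 length among productive, motif-valid
#' records, where CDR3 length = junction length - 2 (the conserved C and
#' W/F anchors are excluded), plus each animal's mean length.
#'
#' @param records records tibble.
#' @param locus locus analyzed.
#' @return list with `distribution` (usage table over lengths, features as
#'   character integers) and `mean_length` (tibble `animal_id`,
#'   `mean_length`).
#' @export
cdr3_length_distribution <- function(records, locus = "IGH") {
  records <- records[records$locus == locus, , drop = FALSE]
  func <- classify_functionality(records)
  records <- records[func == "productive", , drop = FALSE]
  if (nrow(records) > 0) {
    records <- records[cdr3_is_valid(records), , drop = FALSE]
  }
  len <- stringi::stri_length(records$junction_aa) - 2L
  agg <- dplyr::count(
    tibble::tibble(animal_id = records$animal_id,
                   feature = sprintf("%02d", len)),
    .data$animal_id, .data$feature, name = "count"
  )
  agg$count <- as.numeric(agg$count)
  dist <- usage_percent(agg)
  attr(dist, "axis") <- "cdr3_length"
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(animal_id = records$animal_id, len = len),
                    .data$animal_id),
    mean_length = mean(.data$len), .groups = "drop"
  )
  list(distribution = dist, mean_length = means)
}

#' Build unique-CDR3 sets per group
#'
#' Pools the animals of each group and deduplicates junction strings from
#' productive, motif-valid records (optionally restricted to class-switched
#' records). Pooling precedes deduplication, so a CDR3 seen in several
#' animals of one group counts once for that group.
#'
#' @param records records tibble.
#' @param design design tibble covering every animal present.
#' @param grouping `"cell"` for the 8 treatment cells; `"AOS"`, `"TT"` or
#'   `"CpG"` for the two pooled levels of one factor; or a custom tibble
#'   (`animal_id`, `group`) assigning each animal to exactly one group.
#' @param locus locus analyzed.
#' @param class_switched_only restrict to class-switched records.
#' @return named list of character vectors (unique junctions), with
#'   attribute `locus`.
#' @export
build_cdr3_sets <- function(records, design, grouping = "cell",
                            locus = "IGH", class_switched_only = FALSE) {
  records <- records[records$locus == locus, , drop = FALSE]
  if (is.data.frame(grouping)) {
    if (anyDuplicated(grouping$animal_id)) {
      stop("build_cdr3_sets: grouping assigns an animal to several groups")
    }
    grp <- grouping
  } else {
    grp <- group_labels(design, grouping)
  }
  uncovered <- setdiff(unique(records$animal_id), grp$animal_id)
  if (length(uncovered) > 0) {
    stop("build_cdr3_sets: grouping does not cover animal(s): ",
         paste(uncovered, collapse = ", "))
  }
  func <- classify_functionality(records)
  records <- records[func == "productive", , drop = FALSE]
  if (nrow(records) > 0) {
    records <- records[cdr3_is_valid(records), , drop = FALSE]
  }
  if (class_switched_only) records <- subset_class_switched(records)
  merged <- dplyr::inner_join(
    tibble::tibble(animal_id = records$animal_id,
                   junction = records$junction_aa),
    grp, by = "animal_id"
  )
  lv <- attr(grp, "levels")
  groups <- if (is.null(lv)) sort(unique(grp$group)) else
    lv[lv %in% unique(grp$group)]
  sets <- lapply(groups, function(g) {
    sort(unique(merged$junction[merged$group == g]))
  })
  names(sets) <- groups
  attr(sets, "locus") <- locus
  sets
}

#' Shared-by-k table of unique CDR3s
#'
#' For every CDR3 in the union of the group sets, counts the number of
#' groups containing it and tallies by k = 1..G; the percent column is of
#' the union, rounded half-up to 2 decimals.
#'
#' @param sets named list of >= 2 character vectors (one per group).
#' @return tibble `k`, `count`, `percent`.
#' @export
sharing_table <- function(sets) {
  if (length(sets) < 2) stop("sharing_table: need >= 2 sets")
  members <- unlist(lapply(sets, unique), use.names = FALSE)
  if (length(members) == 0) {
    return(tibble::tibble(k = seq_along(sets), count = 0L, percent = NaN))
  }
  k_per_cdr3 <- table(members)
  tally <- tabulate(as.integer(k_per_cdr3), nbins = length(sets))
  tibble::tibble(
    k = seq_along(sets),
    count = tally,
    percent = percent_from_counts(tally)
  )
}

#' Percentages from a count column, rounded half-up to 2 decimals
#'
#' @param counts nonnegative integer counts with positive sum.
#' @return numeric percentages (100 * count / sum), half-up rounding.
#' @export
percent_from_counts <- function(counts) {
  if (any(counts < 0)) stop("percent_from_counts: counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop("percent_from_counts: counts sum to zero")
  round_half_up(100 * counts / total, 2)
}

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Pairwise overlap of two CDR3 sets
#'
#' Reports the intersection size and the per-side shares: the percent of
#' set A found in B and the percent of B found in A (the two sides are
#' reported separately, as repertoire overlaps usually are).
#'
#' @param a,b character vectors of unique CDR3s (same locus).
#' @return one-row tibble `n_a`, `n_b`, `n_shared`, `pct_a`, `pct_b`.
#' @export
variable_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  shared <- length(intersect(a, b))
  pct <- function(n, d) {
    if (d == 0) {
      warning("variable_overlap: empty set; percent reported as 0")
      return(0)
    }
    100 * n / d
  }
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_shared = shared,
    pct_a = pct(shared, length(a)), pct_b = pct(shared, length(b))
  )
}
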