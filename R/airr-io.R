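# AIRR Rearrangement TSV dialect used throughout the package.
#
# Records are held as a plain tibble, one row per rearrangement, with gene
# calls stored as comma-joined gene-level names (alleles collapsed at parse
# time). Tri-state evidence fields (vj_in_frame, stop_codon) are logicals
# with NA meaning "unknown". A repertoire is simply a records tibble carrying
# an animal_id column; a multi-animal dataset is the row-bound tibble.

#' Column order of the AIRR Rearrangement dialect written by this package
#' @export
AIRR_COLUMNS <- c(
  "sequence_id", "locus", "v_call", "d_call", "j_call", "c_call",
  "junction_aa", "d_alignment_length", "vj_in_frame", "stop_codon"
)

MANDATORY_COLUMNS <- c("sequence_id", "locus", "v_call", "d_call", "j_call",
                       "junction_aa")

#' Isotype alphabet
#'
#' Heavy-chain constant-region labels recognized by the package.
#' `SWITCHED_ISOTYPES` are the class-switched subset (everything except
#' IgM and IgD); records without an identifiable constant region carry
#' `"unknown"`.
#' @export
ISOTYPES <- c("IgM", "IgD", "IgG1", "IgG2b", "IgG2c", "IgG3", "IgA", "IgE")

#' @rdname ISOTYPES
#' @export
SWITCHED_ISOTYPES <- c("IgG1", "IgG2b", "IgG2c", "IgG3", "IgA", "IgE")

JUNCTION_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY*"

#' Collapse allele-level gene calls to unique gene-level calls
#'
#' Strips the IMGT allele suffix (text after `*`) from each name in a
#' comma-separated call string and removes duplicates, so
#' `"IGHV1-26*01,IGHV1-26*02"` collapses to `"IGHV1-26"`. Empty or NA input
#' yields `""`.
#'
#' @param x character vector of comma-separated gene calls.
#' @return character vector of comma-joined unique gene-level names.
#' @export
collapse_gene_calls <- function(x) {
  x[is.na(x)] <- ""
  out <- x
  todo <- nzchar(x)
  if (!any(todo)) return(out)
  parts <- stringi::stri_split_fixed(x[todo], ",")
  out[todo] <- vapply(parts, function(p) {
    p <- stringi::stri_trim_both(p)
    p <- sub("\\*.*$", "", p)
    p <- unique(p[nzchar(p)])
    paste(p, collapse = ",")
  }, character(1))
  out
}

#' Number of genes in a comma-joined call string
#'
#' @param x character vector of comma-joined calls (`""` means no call).
#' @return integer vector of call-list lengths.
#' @export
n_calls <- function(x) {
  n <- stringi::stri_count_fixed(x, ",") + 1L
  n[!nzchar(x) | is.na(x)] <- 0L
  n
}

tristate_to_chr <- function(x) {
  out <- rep("", length(x))
  out[isTRUE_v(x)] <- "T"
  out[isFALSE_v(x)] <- "F"
  out
}

isTRUE_v <- function(x) !is.na(x) & x
isFALSE_v <- function(x) !is.na(x) & !x

chr_to_tristate <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("T", "TRUE", "true")] <- TRUE
  out[x %in% c("F", "FALSE", "false")] <- FALSE
  out
}

#' Read an AIRR Rearrangement TSV for one animal
#'
#' Reads a tab-separated Rearrangement file, collapses allele-level calls to
#' unique gene-level calls, and normalizes optional columns. Boolean cells
#' use `"T"`/`"F"` with empty meaning unknown. Rows whose junction contains
#' characters outside the amino-acid alphabet (plus `*`) are skipped with a
#' message giving the count.
#'
#' @param path path to the TSV file.
#' @param animal_id animal identifier attached to every record (defaults to
#'   the file name without extension).
#' @return tibble of records with columns `animal_id` plus
#'   [AIRR_COLUMNS], gene calls comma-joined at gene level.
#' @export
read_airr <- function(path, animal_id = NULL) {
  if (!file.exists(path)) stop("AIRR file not found: ", path)
  if (is.null(animal_id)) {
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("AIRR file ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  opt_chr <- c("c_call", "junction_aa")
  for (col in opt_chr) if (!col %in% names(raw)) raw[[col]] <- ""
  if (!"d_alignment_length" %in% names(raw)) raw[["d_alignment_length"]] <- "0"
  for (col in c("vj_in_frame", "stop_codon")) {
    if (!col %in% names(raw)) raw[[col]] <- ""
  }

  junction <- ifelse(is.na(raw$junction_aa), "", raw$junction_aa)
  bad <- nzchar(junction) &
    stringi::stri_detect_regex(junction, paste0("[^", gsub("\\*", "\\\\*", JUNCTION_ALPHABET), "]"))
  if (any(bad)) {
    message("read_airr: skipped ", sum(bad), " row(s) with malformed junction in ", basename(path))
  }

  dal <- suppressWarnings(as.integer(raw$d_alignment_length))
  dal[is.na(dal)] <- 0L

  c_call <- ifelse(is.na(raw$c_call) | !nzchar(raw$c_call), "unknown", raw$c_call)

  rec <- tibble::tibble(
    animal_id = animal_id,
    sequence_id = raw$sequence_id,
    locus = raw$locus,
    v_call = collapse_gene_calls(raw$v_call),
    d_call = collapse_gene_calls(raw$d_call),
    j_call = collapse_gene_calls(raw$j_call),
    c_call = c_call,
    junction_aa = junction,
    d_alignment_length = dal,
    vj_in_frame = chr_to_tristate(raw$vj_in_frame),
    stop_codon = chr_to_tristate(raw$stop_codon)
  )
  # light chains carry no D segment
  light <- rec$locus %in% c("IGK", "IGL")
  rec$d_call[light] <- ""
  rec$d_alignment_length[light] <- 0L
  rec[!bad, , drop = FALSE]
}

#' Write records to an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: gene-level comma-joined calls, `"T"`/`"F"`
#' tri-states with empty for unknown, unknown constant region written as an
#' empty cell. Writing then reading reproduces all typed fields.
#'
#' @param records records tibble (one animal).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  out <- tibble::tibble(
    sequence_id = records$sequence_id,
    locus = records$locus,
    v_call = records$v_call,
    d_call = records$d_call,
    j_call = records$j_call,
    c_call = ifelse(records$c_call == "unknown", "", records$c_call),
    junction_aa = records$junction_aa,
    d_alignment_length = records$d_alignment_length,
    vj_in_frame = tristate_to_chr(records$vj_in_frame),
    stop_codon = tristate_to_chr(records$stop_codon)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write the animal-to-treatment design table
#'
#' The design maps each animal to the 2x2x2 factorial cell: columns
#' `animal_id`, `aos`, `tt`, `cpg` (logical) and `trial` (integer replicate
#' label). `read_design` validates uniqueness of animal ids.
#'
#' @param path TSV path.
#' @return tibble design.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = "c", aos = "l", tt = "l", cpg = "l", trial = "i"
  ), progress = FALSE)
  validate_design(d)
  d
}

#' @rdname read_design
#' @param design design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

validate_design <- function(design, require_full = FALSE) {
  need <- c("animal_id", "aos", "tt", "cpg")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$animal_id)) stop("design has duplicated animal_id")
  if (require_full) {
    cells <- table(treatment_cell(design))
    if (any(cells == 0)) {
      stop("design does not cover all 8 treatment cells; missing: ",
           paste(names(cells)[cells == 0], collapse = ", "))
    }
  }
  invisible(design)
}

#' Treatment-cell labels
#'
#' Cells are labelled by the presence/absence convention `(AOS, TT, CpG)`,
#' e.g. `"---"` for saline controls, `"-++"` for TT+CpG, `"+++"` for
#' AOS+TT+CpG.
#' @export
CELL_LEVELS <- c("---", "--+", "-+-", "-++", "+--", "+-+", "++-", "+++")

#' @rdname CELL_LEVELS
#' @param design design tibble (or any tibble with aos/tt/cpg logicals).
#' @return factor of cell labels with levels [CELL_LEVELS].
#' @export
treatment_cell <- function(design) {
  lab <- paste0(ifelse(design$aos, "+", "-"),
                ifelse(design$tt, "+", "-"),
                ifelse(design$cpg, "+", "-"))
  factor(lab, levels = CELL_LEVELS)
}

#' Shorten IMGT gene names for reporting
#'
#' Drops the locus prefix so `"IGHV1-26"` prints as `"V1-26"`, matching the
#' labels used in repertoire figures. `"U"` (undetermined) passes through.
#'
#' @param x character vector of gene names.
#' @export
short_gene_label <- function(x) {
  sub("^IG[HKL]", "", x)
}
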