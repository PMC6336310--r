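# Record-level classification rules: functionality, CDR3 junction motif
# validity, class-switch status. All functions are vectorized over a
# records tibble.

#' Classify rearrangement functionality
#'
#' A sequence is *productive* when it is in frame, free of stop codons, and
#' carries a junction; *unknown* when the evidence is incomplete (either
#' frame or stop status unknown, or no junction was resolved — typically
#' short sequences); *unproductive* otherwise. The three classes partition
#' any set of records.
#'
#' @param records records tibble (see [read_airr()]).
#' @return character vector in `{"productive","unknown","unproductive"}`.
#' @export
classify_functionality <- function(records) {
  classify_functionality_vec(records$vj_in_frame, records$stop_codon,
                             records$junction_aa)
}

classify_functionality_vec <- function(in_frame, has_stop, junction) {
  has_junction <- nzchar(junction)
  out <- rep("unproductive", length(junction))
  unknown <- is.na(in_frame) | is.na(has_stop) | !has_junction
  out[unknown] <- "unknown"
  out[!unknown & in_frame & !has_stop] <- "productive"
  out
}

#' Is a record class-switched?
#'
#' TRUE only for heavy-chain records whose identifiable constant region is a
#' switched isotype (IgG subclasses, IgA or IgE). IgM, IgD, unidentified
#' constant regions, and all light chains are FALSE.
#'
#' @param records records tibble.
#' @return logical vector.
#' @export
is_class_switched <- function(records) {
  records$locus == "IGH" & records$c_call %in% SWITCHED_ISOTYPES
}

#' CDR3 junction motif validity
#'
#' Heavy-chain junctions must show the canonical C-xx-W anchor motif
#' (leading cysteine, trailing tryptophan) *or* the record must be
#' class-switched — switching to an identifiable downstream constant region
#' is accepted as functional evidence in place of the W anchor. Kappa (and
#' lambda) junctions must show C-xx-F. The length between anchors is
#' unconstrained.
#'
#' @param records records tibble; every junction must be nonempty.
#' @return logical vector.
#' @export
cdr3_is_valid <- function(records) {
  junction <- records$junction_aa
  if (any(!nzchar(junction))) {
    stop("cdr3_is_valid: junction_aa must be nonempty for all records")
  }
  first <- stringi::stri_sub(junction, 1, 1)
  last <- stringi::stri_sub(junction, -1, -1)
  heavy <- records$locus == "IGH"
  out <- logical(nrow(records))
  out[heavy] <- (first[heavy] == "C" & last[heavy] == "W") |
    is_class_switched(records)[heavy]
  out[!heavy] <- first[!heavy] == "C" & last[!heavy] == "F"
  out
}

#' Retain only class-switched records
#'
#' Restricts a repertoire to heavy-chain records with a switched,
#' identifiable constant region — the subset most likely to be
#' antigen-experienced. Idempotent; downstream analyses accept the subset
#' unchanged.
#'
#' @param records records tibble.
#' @return filtered records tibble.
#' @export
subset_class_switched <- function(records) {
  records[is_class_switched(records), , drop = FALSE]
}
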