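# Toy germline gene sets for the simulator. Gene names follow mouse IMGT
# nomenclature at the gene level (alleles are never generated).

#' Construct a germline gene set
#'
#' Lists of V, D and J gene names per locus. IGK and IGL carry no D
#' segments. The defaults name 20 IGHV, 4 IGHD, 4 IGHJ, 20 IGKV and 4 IGKJ
#' genes (mouse kappa expresses J1, J2, J4 and J5), plus a small lambda set
#' that is parsed but excluded from analyses.
#'
#' @param igh,igk,igl per-locus lists with elements `v`, `d` (heavy only),
#'   `j`.
#' @param isotypes heavy-chain isotype alphabet.
#' @return object of class `germline_set`.
#' @export
germline_set <- function(igh, igk, igl = NULL, isotypes = ISOTYPES) {
  stopifnot(!anyDuplicated(igh$v), !anyDuplicated(igh$d), !anyDuplicated(igh$j),
            !anyDuplicated(igk$v), !anyDuplicated(igk$j))
  if (!is.null(igk$d) && length(igk$d) > 0) stop("IGK has no D segments")
  structure(list(IGH = igh, IGK = igk, IGL = igl, isotypes = isotypes),
            class = "germline_set")
}

#' @rdname germline_set
#' @export
default_germline <- function() {
  germline_set(
    igh = list(
      v = paste0("IGHV", c("1-26", "9-3", "8-8", "1-53", "3-6", "6-3",
                           "8-12", "1-80", "1-63", "1-76", "1-78", "1-31",
                           "1-69", "1-74", "1-85", "5-16", "1-36", "10-3",
                           "1-18", "2-3")),
      d = paste0("IGHD", c("1-1", "2-3", "3-1", "5-5")),
      j = paste0("IGHJ", 1:4)
    ),
    igk = list(
      v = paste0("IGKV", c("5-39", "3-4", "4-55", "6-23", "8-30", "10-96",
                           "4-71", "5-48", "1-132", "4-86", "4-70", "12-46",
                           "8-19", "4-57", "4-62", "6-14", "4-58", "4-63",
                           "4-91", "14-111")),
      j = paste0("IGKJ", c(1, 2, 4, 5))
    ),
    igl = list(
      v = paste0("IGLV", 1:3),
      j = paste0("IGLJ", 1:3)
    )
  )
}

# Rank-based power-law baseline so a handful of genes exceed 5% of the
# repertoire, as observed in real spleens.
power_law_weights <- function(genes, exponent = 1) {
  w <- (seq_along(genes))^(-exponent)
  stats::setNames(w / sum(w), genes)
}
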