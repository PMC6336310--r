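# Seeded generator of per-animal repertoires under the 2x2x2 factorial.
#
# Every record is sampled i.i.d. within an animal: V/D/J indices from
# baseline weights times the animal's applicable effect multipliers,
# isotype likewise, junctions built as C + core + anchor with cores drawn
# from a finite shared ("public") pool with configured probability or
# freshly generated ("private") otherwise. Configured fractions of records
# receive ambiguous V calls, missing/short/ambiguous D, missing/ambiguous
# J, stop codons, or unknown functionality. Fully reproducible from the
# seed in the config.

#' Simulation configuration
#'
#' Defaults state the simulated world: four animals per treatment cell
#' (matching the sequenced cohort), desk-scale read depth, an IgM-dominated
#' isotype distribution, a large undetermined-D fraction, roughly half of
#' reads with unknown functionality, and mostly-private CDR3 pools (heavy
#' chains far more private than kappa).
#'
#' @param n_per_group animals per treatment cell (>= 2 for ANOVA).
#' @param reads_per_animal heavy-chain records per animal.
#' @param kappa_fraction kappa records generated per heavy record.
#' @param lambda_fraction fraction of light-chain records on the lambda
#'   locus (parsed downstream but excluded from analyses).
#' @param ambig_v2_rate,ambig_v3_rate fractions of records reported with 2
#'   or >= 3 candidate V genes.
#' @param d_missing_rate,d_short_rate,ambig_d_rate fractions of heavy
#'   records with no reported D, a D alignment under 6 nt, or 2 candidate
#'   D genes.
#' @param j_missing_rate,ambig_j_rate same for J segments.
#' @param unknown_rate,unproductive_rate fractions of records with
#'   insufficient evidence (no junction, unknown frame) or a
#'   frameshift/stop.
#' @param isotype_probs named probabilities over [ISOTYPES] plus
#'   `"unknown"` for heavy records.
#' @param mean_cdr3_igh,mean_cdr3_igk Poisson mean of the CDR3 length
#'   (junction length minus the two anchors).
#' @param public_pool_size,p_public per-locus shared-pool size and
#'   probability that a junction core is drawn from it (named `IGH`/`IGK`).
#' @param motif_fail_rate fraction of heavy junctions whose trailing W is
#'   corrupted, so they only stay analyzable through class switching.
#' @param v_weights,d_weights,j_weights optional named baseline weights per
#'   locus (lists with elements `IGH`/`IGK`); default rank power-law.
#' @param seed integer seed; identical config implies byte-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 4,
                       reads_per_animal = 10000,
                       kappa_fraction = 0.8,
                       lambda_fraction = 0.05,
                       ambig_v2_rate = 0.10,
                       ambig_v3_rate = 0.03,
                       d_missing_rate = 0.25,
                       d_short_rate = 0.10,
                       ambig_d_rate = 0.05,
                       j_missing_rate = 0.02,
                       ambig_j_rate = 0.02,
                       unknown_rate = 0.45,
                       unproductive_rate = 0.05,
                       isotype_probs = c(IgM = 0.55, IgD = 0.03, IgG1 = 0.08,
                                         IgG2b = 0.06, IgG2c = 0.06,
                                         IgG3 = 0.05, IgA = 0.08, IgE = 0.01,
                                         unknown = 0.08),
                       mean_cdr3_igh = 12,
                       mean_cdr3_igk = 9,
                       public_pool_size = c(IGH = 1000, IGK = 300),
                       p_public = c(IGH = 0.05, IGK = 0.30),
                       motif_fail_rate = 0.02,
                       v_weights = NULL,
                       d_weights = NULL,
                       j_weights = NULL,
                       seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, reads_per_animal = reads_per_animal,
    kappa_fraction = kappa_fraction, lambda_fraction = lambda_fraction,
    ambig_v2_rate = ambig_v2_rate, ambig_v3_rate = ambig_v3_rate,
    d_missing_rate = d_missing_rate, d_short_rate = d_short_rate,
    ambig_d_rate = ambig_d_rate, j_missing_rate = j_missing_rate,
    ambig_j_rate = ambig_j_rate, unknown_rate = unknown_rate,
    unproductive_rate = unproductive_rate, isotype_probs = isotype_probs,
    mean_cdr3_igh = mean_cdr3_igh, mean_cdr3_igk = mean_cdr3_igk,
    public_pool_size = public_pool_size, p_public = p_public,
    motif_fail_rate = motif_fail_rate,
    v_weights = v_weights, d_weights = d_weights, j_weights = j_weights,
    seed = as.integer(seed)
  )
  rates <- cfg[c("kappa_fraction", "lambda_fraction", "ambig_v2_rate",
                 "ambig_v3_rate", "d_missing_rate", "d_short_rate",
                 "ambig_d_rate", "j_missing_rate", "ambig_j_rate",
                 "unknown_rate", "unproductive_rate", "motif_fail_rate")]
  bad <- vapply(rates, function(r) any(r < 0 | r > 1), logical(1))
  if (any(bad)) stop("sim_config: rates must lie in [0,1]: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (cfg$unknown_rate + cfg$unproductive_rate > 1) {
    stop("sim_config: unknown_rate + unproductive_rate must not exceed 1")
  }
  if (n_per_group < 2) {
    stop("sim_config: n_per_group must be >= 2 for ANOVA estimability")
  }
  if (any(isotype_probs < 0) || sum(isotype_probs) <= 0) {
    stop("sim_config: isotype_probs must be nonnegative and sum > 0")
  }
  structure(cfg, class = "sim_config")
}

#' Declare a factorial usage effect
#'
#' A multiplier applied to the baseline sampling weight of one target when
#' the named factor is `+` for an animal. Targets may be gene names
#' (V, D or J), isotype labels, or `"public_pool"` (scales the public-core
#' probability). Multiplier 1 encodes no effect.
#'
#' @param factor one of `"AOS"`, `"TT"`, `"CpG"`.
#' @param target gene name, isotype, or `"public_pool"`.
#' @param multiplier positive real.
#' @export
effect_spec <- function(factor, target, multiplier) {
  factor <- match.arg(factor, c("AOS", "TT", "CpG"))
  if (!is.numeric(multiplier) || multiplier <= 0) {
    stop("effect_spec: multiplier must be > 0")
  }
  structure(list(factor = factor, target = target, multiplier = multiplier),
            class = "effect_spec")
}

#' Build a full-factorial design table
#'
#' @param n_per_group animals per treatment cell.
#' @return design tibble with `n_per_group * 8` animals; trial alternates
#'   within each cell, mirroring two independent suspension trials.
#' @export
sim_design <- function(n_per_group = 4) {
  cells <- expand.grid(cpg = c(FALSE, TRUE), tt = c(FALSE, TRUE),
                       aos = c(FALSE, TRUE))
  cells <- cells[, c("aos", "tt", "cpg")]
  d <- cells[rep(seq_len(8), each = n_per_group), ]
  tibble::tibble(
    animal_id = sprintf("m%02d", seq_len(nrow(d))),
    aos = d$aos, tt = d$tt, cpg = d$cpg,
    trial = rep_len(c(1L, 2L), nrow(d))
  )
}

# Multiply baseline weights by the effect multipliers applicable to one
# animal, then renormalize.
apply_effects <- function(weights, effects, animal) {
  for (e in effects) {
    on <- switch(e$factor, AOS = animal$aos, TT = animal$tt, CpG = animal$cpg)
    if (on && e$target %in% names(weights)) {
      weights[e$target] <- weights[e$target] * e$multiplier
    }
  }
  if (sum(weights) <= 0) stop("simulate_repertoires: all sampling weights are zero")
  weights / sum(weights)
}

# Vectorized weighted index sampling (inverse-CDF; much faster than
# sample.int with prob for large n).
weighted_index <- function(n, w) {
  cw <- cumsum(w) / sum(w)
  findInterval(stats::runif(n), cw) + 1L
}

# Pick `k` extra distinct gene indices per row, never equal to `idx`.
extra_gene_idx <- function(idx, n_genes, k = 1) {
  off <- sample.int(n_genes - 1L, length(idx), replace = TRUE)
  first <- (idx + off - 1L) %% n_genes + 1L
  if (k == 1) return(matrix(first, ncol = 1))
  # second offset distinct from both 0 and the first offset
  off2 <- sample.int(n_genes - 2L, length(idx), replace = TRUE)
  off2 <- off2 + (off2 >= pmin(off, n_genes - 1L))  # skip nothing below
  off2[off2 == off] <- ((off[off2 == off]) %% (n_genes - 1L)) + 1L
  second <- (idx + off2 - 1L) %% n_genes + 1L
  clash <- second == first | second == idx
  while (any(clash)) {
    repl <- sample.int(n_genes, sum(clash), replace = TRUE)
    second[clash] <- repl
    clash <- second == first | second == idx
  }
  cbind(first, second)
}

# Random junction cores via substrings of one long random string; cheap and
# effectively unique at the scales used here.
random_cores <- function(n, mean_len) {
  if (n == 0) return(character(0))
  lens <- pmax(2L, stats::rpois(n, mean_len))
  span <- max(2000L, 50L * as.integer(sqrt(n))) + max(lens)
  big <- stringi::stri_rand_strings(1, span, pattern = "[ACDEFGHIKLMNPQRSTVWY]")
  starts <- sample.int(span - max(lens), n, replace = TRUE)
  stringi::stri_sub(big, starts, length = lens)
}

simulate_locus <- function(n, locus, genes_v, genes_d, genes_j, w_v, w_d, w_j,
                           isotype_probs, cfg, pool, p_public, mean_len,
                           animal_ids, seq_within) {
  anchor <- if (locus == "IGH") "W" else "F"
  v_idx <- weighted_index(n, w_v)
  v_call <- genes_v[v_idx]
  # ambiguous V calls: 2 genes, or >= 3 genes
  u <- stats::runif(n)
  amb2 <- u < cfg$ambig_v2_rate
  amb3 <- !amb2 & u < cfg$ambig_v2_rate + cfg$ambig_v3_rate
  if (any(amb2)) {
    ex <- extra_gene_idx(v_idx[amb2], length(genes_v), 1)
    v_call[amb2] <- paste(v_call[amb2], genes_v[ex[, 1]], sep = ",")
  }
  if (any(amb3)) {
    ex <- extra_gene_idx(v_idx[amb3], length(genes_v), 2)
    v_call[amb3] <- paste(v_call[amb3], genes_v[ex[, 1]], genes_v[ex[, 2]],
                          sep = ",")
  }

  if (locus == "IGH") {
    d_idx <- weighted_index(n, w_d)
    d_call <- genes_d[d_idx]
    d_len <- sample(6:16, n, replace = TRUE)
    ud <- stats::runif(n)
    d_miss <- ud < cfg$d_missing_rate
    d_short <- !d_miss & ud < cfg$d_missing_rate + cfg$d_short_rate
    d_amb <- !d_miss & !d_short &
      ud < cfg$d_missing_rate + cfg$d_short_rate + cfg$ambig_d_rate
    d_call[d_miss] <- ""
    d_len[d_miss] <- 0L
    d_len[d_short] <- sample(2:5, sum(d_short), replace = TRUE)
    if (any(d_amb)) {
      ex <- extra_gene_idx(d_idx[d_amb], length(genes_d), 1)
      d_call[d_amb] <- paste(d_call[d_amb], genes_d[ex[, 1]], sep = ",")
    }
  } else {
    d_call <- rep("", n)
    d_len <- rep(0L, n)
  }

  j_idx <- weighted_index(n, w_j)
  j_call <- genes_j[j_idx]
  uj <- stats::runif(n)
  j_miss <- uj < cfg$j_missing_rate
  j_amb <- !j_miss & uj < cfg$j_missing_rate + cfg$ambig_j_rate
  j_call[j_miss] <- ""
  if (any(j_amb)) {
    ex <- extra_gene_idx(j_idx[j_amb], length(genes_j), 1)
    j_call[j_amb] <- paste(j_call[j_amb], genes_j[ex[, 1]], sep = ",")
  }

  if (locus == "IGH") {
    iso <- names(isotype_probs)[weighted_index(n, isotype_probs)]
  } else {
    iso <- rep("unknown", n)
  }

  # functionality classes
  uf <- stats::runif(n)
  unknown <- uf < cfg$unknown_rate
  unprod <- !unknown & uf < cfg$unknown_rate + cfg$unproductive_rate
  prod <- !unknown & !unprod

  junction <- character(n)
  with_junc <- which(!unknown)
  nj <- length(with_junc)
  if (nj > 0) {
    cores <- character(nj)
    pub <- stats::runif(nj) < p_public
    if (any(pub)) cores[pub] <- pool[sample.int(length(pool), sum(pub),
                                                replace = TRUE)]
    cores[!pub] <- random_cores(sum(!pub), mean_len)
    junction[with_junc] <- paste0("C", cores, anchor)
  }
  # heavy-chain motif corruption: trailing W lost to mutation/truncation
  if (locus == "IGH" && cfg$motif_fail_rate > 0 && nj > 0) {
    fail <- which(!unknown & stats::runif(n) < cfg$motif_fail_rate)
    if (length(fail) > 0) stringi::stri_sub(junction[fail], -1, -1) <- "F"
  }

  in_frame <- rep(NA, n)
  has_stop <- rep(NA, n)
  in_frame[prod] <- TRUE
  has_stop[prod] <- FALSE
  # unproductive: half frameshifts, half stop codons (with * in junction)
  if (any(unprod)) {
    kind <- stats::runif(sum(unprod)) < 0.5
    idx_up <- which(unprod)
    fs <- idx_up[kind]
    st <- idx_up[!kind]
    in_frame[fs] <- FALSE
    has_stop[fs] <- FALSE
    in_frame[st] <- TRUE
    has_stop[st] <- TRUE
    if (length(st) > 0) {
      mid <- pmax(2L, stringi::stri_length(junction[st]) %/% 2L)
      stringi::stri_sub(junction[st], mid, length = 1L) <- "*"
    }
  }
  junction[unknown] <- ""

  tibble::new_tibble(list(
    animal_id = animal_ids,
    sequence_id = stringi::stri_c(animal_ids, "_", locus, "_", seq_within),
    locus = rep(locus, n),
    v_call = v_call,
    d_call = d_call,
    j_call = j_call,
    c_call = iso,
    junction_aa = junction,
    d_alignment_length = d_len,
    vj_in_frame = in_frame,
    stop_codon = has_stop
  ), nrow = n)
}

#' Simulate annotated repertoires for a full factorial design
#'
#' One call generates the whole cohort: per animal, heavy-chain records plus
#' (optionally) kappa and lambda light-chain records, with factorial usage
#' effects injected through multiplicative reweighting of the baseline
#' sampling distributions.
#'
#' @param design design tibble covering all 8 cells (see [sim_design()]).
#' @param cfg a [sim_config()].
#' @param effects list of [effect_spec()] objects.
#' @param germline a [germline_set()].
#' @return records tibble for all animals (split by `animal_id` to recover
#'   per-animal repertoires).
#' @export
simulate_repertoires <- function(design, cfg = sim_config(),
                                 effects = list(),
                                 germline = default_germline()) {
  validate_design(design, require_full = TRUE)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  set.seed(cfg$seed)

  w_v_igh <- cfg$v_weights$IGH %||% power_law_weights(germline$IGH$v)
  w_d_igh <- cfg$d_weights$IGH %||%
    stats::setNames(c(1.5, 0.8, 0.8, 0.6)[seq_along(germline$IGH$d)],
                    germline$IGH$d)
  w_j_igh <- cfg$j_weights$IGH %||%
    stats::setNames(c(1, 0.9, 0.8, 0.7)[seq_along(germline$IGH$j)],
                    germline$IGH$j)
  w_v_igk <- cfg$v_weights$IGK %||% power_law_weights(germline$IGK$v)
  w_j_igk <- cfg$j_weights$IGK %||%
    stats::setNames(c(1, 1, 0.4, 1)[seq_along(germline$IGK$j)],
                    germline$IGK$j)

  # shared public pools, one per locus, common to all animals
  pool_igh <- random_cores(cfg$public_pool_size[["IGH"]], cfg$mean_cdr3_igh)
  pool_igk <- random_cores(cfg$public_pool_size[["IGK"]], cfg$mean_cdr3_igk)

  n_heavy <- cfg$reads_per_animal
  n_light <- round(cfg$reads_per_animal * cfg$kappa_fraction)
  n_lambda <- round(n_light * cfg$lambda_fraction)
  n_kappa <- n_light - n_lambda

  p_pub_eff <- function(p, animal) {
    for (e in effects) {
      on <- switch(e$factor, AOS = animal$aos, TT = animal$tt,
                   CpG = animal$cpg)
      if (on && identical(e$target, "public_pool")) p <- p * e$multiplier
    }
    min(max(p, 0), 1)
  }

  # animals within a treatment cell share the same effect-adjusted weights,
  # so each cell is generated as one vectorized batch
  cell <- as.character(treatment_cell(design))
  out <- vector("list", 0)
  for (cl in unique(cell)) {
    animals <- design[cell == cl, , drop = FALSE]
    rep_cell <- animals[1, ]
    n_anim <- nrow(animals)
    chunk_ids <- function(n_per) {
      list(ids = rep(animals$animal_id, each = n_per),
           seq = rep(seq_len(n_per), times = n_anim))
    }
    if (n_heavy > 0) {
      ch <- chunk_ids(n_heavy)
      out[[paste0(cl, "_igh")]] <- simulate_locus(
        n_heavy * n_anim, "IGH", germline$IGH$v, germline$IGH$d,
        germline$IGH$j,
        apply_effects(w_v_igh, effects, rep_cell),
        apply_effects(w_d_igh, effects, rep_cell),
        apply_effects(w_j_igh, effects, rep_cell),
        apply_effects(cfg$isotype_probs, effects, rep_cell),
        cfg, pool_igh, p_pub_eff(cfg$p_public[["IGH"]], rep_cell),
        cfg$mean_cdr3_igh, ch$ids, ch$seq)
    }
    if (n_kappa > 0) {
      ch <- chunk_ids(n_kappa)
      out[[paste0(cl, "_igk")]] <- simulate_locus(
        n_kappa * n_anim, "IGK", germline$IGK$v, NULL, germline$IGK$j,
        apply_effects(w_v_igk, effects, rep_cell), NULL,
        apply_effects(w_j_igk, effects, rep_cell),
        NULL, cfg, pool_igk, p_pub_eff(cfg$p_public[["IGK"]], rep_cell),
        cfg$mean_cdr3_igk, ch$ids, ch$seq)
    }
    if (n_lambda > 0 && !is.null(germline$IGL)) {
      ch <- chunk_ids(n_lambda)
      out[[paste0(cl, "_igl")]] <- simulate_locus(
        n_lambda * n_anim, "IGL", germline$IGL$v, NULL, germline$IGL$j,
        power_law_weights(germline$IGL$v), NULL,
        power_law_weights(germline$IGL$j),
        NULL, cfg, pool_igk, cfg$p_public[["IGK"]], cfg$mean_cdr3_igk,
        ch$ids, ch$seq)
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a gene x animal TPM table for the marker screen
#'
#' Log-normal TPM per gene; an [effect_spec()] whose target matches a gene
#' multiplies the expected TPM of `+` animals of that factor.
#'
#' @param genes character vector of marker gene names.
#' @param design design tibble.
#' @param effects list of [effect_spec()].
#' @param seed integer seed.
#' @param base_mean expected TPM for every gene at baseline.
#' @param sdlog log-scale standard deviation (biological variability).
#' @return tibble with a `gene` column and one numeric column per animal.
#' @export
simulate_tpm <- function(genes, design, effects = list(), seed = 1L,
                         base_mean = 200, sdlog = 0.4) {
  validate_design(design)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  cells <- table(treatment_cell(design))
  if (any(cells < 2)) stop("simulate_tpm: need >= 2 animals per cell")
  set.seed(as.integer(seed))
  mat <- matrix(0, nrow = length(genes), ncol = nrow(design),
                dimnames = list(genes, design$animal_id))
  for (i in seq_len(nrow(design))) {
    animal <- design[i, ]
    mu <- stats::setNames(rep(base_mean, length(genes)), genes)
    for (e in effects) {
      on <- switch(e$factor, AOS = animal$aos, TT = animal$tt,
                   CpG = animal$cpg)
      if (on && e$target %in% genes) mu[e$target] <- mu[e$target] * e$multiplier
    }
    mat[, i] <- stats::rlnorm(length(genes), meanlog = log(mu) - sdlog^2 / 2,
                              sdlog = sdlog)
  }
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
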