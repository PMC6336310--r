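# Pipeline orchestration: simulate -> analyze -> report, driven by one
# structured config (YAML or JSON), with a manifest recording the config
# hash and every file written. All outputs are deterministic for a fixed
# config and seed (no timestamps).

#' Read a pipeline configuration file
#'
#' YAML or JSON by extension. Recognized blocks: `seed` (integer),
#' `simulate` (arguments of [sim_config()] plus an optional `effects`
#' list of `{factor, target, multiplier}` entries and `tpm_genes`),
#' `analyze` (switches: `productive_only`, `d_min_nt`,
#' `high_frequency_threshold`, `pair_exclusion_threshold`).
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(sub("^.*\\.", "", path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("read_pipeline_config: unsupported config format: .", ext)
  }
  cfg
}

config_effects <- function(block) {
  effs <- block$effects
  if (is.null(effs) || length(effs) == 0) return(list())
  if (is.data.frame(effs)) effs <- split(effs, seq_len(nrow(effs)))
  lapply(effs, function(e) {
    effect_spec(e$factor, e$target, as.numeric(e$multiplier))
  })
}

config_sim <- function(config) {
  block <- config$simulate %||% list()
  block$effects <- NULL
  block$tpm_genes <- NULL
  args <- block[names(block) %in% names(formals(sim_config))]
  if (!is.null(config$seed) && is.null(args$seed)) {
    args$seed <- as.integer(config$seed)
  }
  do.call(sim_config, args)
}

write_manifest <- function(out_dir, config, files, stage) {
  manifest <- list(
    stage = stage,
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA_integer_,
    package_version = as.character(utils::packageVersion("igfactorial")),
    files = sort(files)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate a full dataset to disk
#'
#' Writes one AIRR TSV per animal (`airr/<animal_id>.tsv`), the design
#' table, a marker TPM table, and a manifest. Deterministic for a fixed
#' config.
#'
#' @param config pipeline config list (see [read_pipeline_config()]).
#' @param out_dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  scfg <- config_sim(config)
  effects <- config_effects(config$simulate %||% list())
  design <- sim_design(scfg$n_per_group)
  records <- simulate_repertoires(design, scfg, effects)
  airr_dir <- file.path(out_dir, "airr")
  dir.create(airr_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (animal in design$animal_id) {
    p <- file.path(airr_dir, paste0(animal, ".tsv"))
    write_airr(records[records$animal_id == animal, , drop = FALSE], p)
    files <- c(files, file.path("airr", paste0(animal, ".tsv")))
  }
  write_design(design, file.path(out_dir, "design.tsv"))
  files <- c(files, "design.tsv")
  genes <- config$simulate$tpm_genes %||%
    c("B220", "CD62L", "CD44", "CD27", "CD19", "CD138", "CD80")
  tpm <- simulate_tpm(genes, design, effects,
                      seed = (scfg$seed + 1L) %% .Machine$integer.max)
  readr::write_tsv(tpm, file.path(out_dir, "tpm.tsv"), progress = FALSE)
  files <- c(files, "tpm.tsv")
  invisible(write_manifest(out_dir, config, files, "simulate"))
}

analyze_switches <- function(config) {
  block <- config$analyze %||% list()
  list(
    productive_only = isTRUE(block$productive_only),
    d_min_nt = block$d_min_nt %||% 6,
    hf_threshold = block$high_frequency_threshold %||% 5,
    pair_threshold = block$pair_exclusion_threshold %||% 0.1,
    top_k = block$top_k %||% 5,
    focus_groups = block$focus_groups %||% c("---", "-++", "+++")
  )
}

tsv_out <- function(x, out_dir, name, files) {
  readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  c(files, name)
}

#' Run the full analysis over an AIRR dataset
#'
#' Executes the analysis sequence on a directory of per-animal AIRR files
#' plus a design table: usage tables (V/D/J, isotype, CDR3 length; whole
#' and class-switched), per-feature three-way ANOVAs, per-animal variance
#' with LS-means comparison, group-mean regressions, V(D)J pairing tables
#' with top-k rankings and the low-frequency pair filter, Circos link
#' exports, CDR3 sharing and overlap tables, read accounting, and (when a
#' TPM table is present) the marker screen.
#'
#' @param config pipeline config list.
#' @param airr_dir directory of `<animal_id>.tsv` AIRR files.
#' @param design_path design TSV path.
#' @param out_dir output directory.
#' @param tpm_path optional TPM TSV path.
#' @return the manifest path, invisibly.
#' @export
run_analyze <- function(config, airr_dir, design_path, out_dir,
                        tpm_path = NULL) {
  sw <- analyze_switches(config)
  design <- read_design(design_path)
  files_found <- file.path(airr_dir, paste0(design$animal_id, ".tsv"))
  missing <- design$animal_id[!file.exists(files_found)]
  if (length(missing) > 0) {
    stop("run_analyze: no AIRR file for animal(s): ",
         paste(missing, collapse = ", "))
  }
  records <- purrr::map2_dfr(files_found, design$animal_id, read_airr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  func_classes <- if (sw$productive_only) "productive" else
    c("productive", "unknown")

  # read accounting (Table-1 style)
  func <- classify_functionality(records)
  acct <- dplyr::count(
    tibble::tibble(animal_id = records$animal_id, locus = records$locus,
                   functionality = func),
    .data$animal_id, .data$locus, .data$functionality, name = "reads"
  )
  files <- tsv_out(acct, out_dir, "read_counts.tsv", files)

  analyses <- list(
    list(axis = "V", locus = "IGH"), list(axis = "D", locus = "IGH"),
    list(axis = "J", locus = "IGH"), list(axis = "isotype", locus = "IGH"),
    list(axis = "cdr3_length", locus = "IGH"),
    list(axis = "V", locus = "IGK"), list(axis = "J", locus = "IGK"),
    list(axis = "cdr3_length", locus = "IGK")
  )
  usage_store <- list()
  for (a in analyses) {
    u <- usage_table(records, axis = a$axis, locus = a$locus,
                     functionality = func_classes, d_min_nt = sw$d_min_nt)
    key <- paste0(a$axis, "_", a$locus)
    usage_store[[key]] <- u
    files <- tsv_out(u, out_dir, paste0("usage_", key, ".tsv"), files)
    gm <- group_mean_usage(u, design, by = "cell")
    files <- tsv_out(gm, out_dir, paste0("group_means_", key, ".tsv"), files)
    an <- usage_anova(u, design)
    files <- tsv_out(an, out_dir, paste0("anova_", key, ".tsv"), files)
  }
  # class-switched heavy-chain V usage
  switched <- subset_class_switched(records)
  if (nrow(switched) > 0) {
    u_sw <- usage_table(switched, axis = "V", locus = "IGH",
                        functionality = func_classes)
    usage_store[["V_IGH_switched"]] <- u_sw
    files <- tsv_out(u_sw, out_dir, "usage_V_IGH_switched.tsv", files)
    files <- tsv_out(usage_anova(u_sw, design), out_dir,
                     "anova_V_IGH_switched.tsv", files)
  }

  # high-frequency segments, per-animal variance, regressions
  hf <- purrr::map_dfr(c("V_IGH", "V_IGK", "V_IGH_switched"), function(key) {
    u <- usage_store[[key]]
    if (is.null(u)) return(NULL)
    tibble::tibble(table = key,
                   feature = high_frequency_segments(
                     u, design, groups = sw$focus_groups,
                     threshold = sw$hf_threshold))
  })
  files <- tsv_out(hf, out_dir, "high_frequency.tsv", files)

  var_rows <- purrr::map_dfr(c("V_IGH", "D_IGH", "J_IGH", "V_IGK", "J_IGK"),
                             function(key) {
    av <- animal_variance(usage_store[[key]])
    av$table <- key
    av
  })
  files <- tsv_out(var_rows, out_dir, "animal_variance.tsv", files)
  var_cmp <- purrr::map_dfr(unique(var_rows$table), function(key) {
    vs <- var_rows[var_rows$table == key, , drop = FALSE]
    res <- compare_variance(vs, design)
    out <- res$global
    out$table <- key
    out
  })
  files <- tsv_out(var_cmp, out_dir, "variance_comparison.tsv", files)

  reg <- purrr::map_dfr(c("V_IGH", "V_IGK"), function(key) {
    gm <- group_mean_usage(usage_store[[key]], design, by = "cell")
    pairs <- utils::combn(sw$focus_groups, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      a <- gm[gm$group == p[1], ]
      b <- gm[gm$group == p[2], ]
      va <- stats::setNames(a$mean_percent, a$feature)
      vb <- stats::setNames(b$mean_percent, b$feature)
      res <- usage_regression(va, vb)
      dplyr::bind_cols(tibble::tibble(table = key, group_a = p[1],
                                      group_b = p[2]), res)
    })
  })
  files <- tsv_out(reg, out_dir, "regressions.tsv", files)

  # pairing
  pt_vdj <- pairing_table(records, mode = "VDJ", locus = "IGH",
                          d_min_nt = sw$d_min_nt)
  pt_vj_h <- pairing_table(records, mode = "VJ", locus = "IGH",
                           d_min_nt = sw$d_min_nt)
  pt_vj_k <- pairing_table(records, mode = "VJ", locus = "IGK")
  files <- tsv_out(pt_vdj, out_dir, "pairing_VDJ_IGH.tsv", files)
  files <- tsv_out(pt_vj_h, out_dir, "pairing_VJ_IGH.tsv", files)
  files <- tsv_out(pt_vj_k, out_dir, "pairing_VJ_IGK.tsv", files)
  gm_vdj <- group_mean_pairing(pt_vdj, design, by = "cell")
  gm_vj_k <- group_mean_pairing(pt_vj_k, design, by = "cell")
  files <- tsv_out(
    rank_top_combinations(gm_vdj, groups = sw$focus_groups, k = sw$top_k),
    out_dir, "ranking_VDJ_IGH.tsv", files)
  files <- tsv_out(
    rank_top_combinations(gm_vj_k, groups = sw$focus_groups, k = sw$top_k),
    out_dir, "ranking_VJ_IGK.tsv", files)
  for (fct in c("AOS", "TT", "CpG")) {
    for (nm in c("IGH", "IGK")) {
      pt <- if (nm == "IGH") pt_vj_h else pt_vj_k
      gm <- group_mean_pairing(pt, design, by = fct)
      kept <- filter_low_frequency_pairs(gm, threshold = sw$pair_threshold)
      files <- tsv_out(kept, out_dir,
                       sprintf("vj_filtered_%s_%s.tsv", fct, nm), files)
    }
  }
  for (g in sw$focus_groups) {
    for (nm in c("IGH", "IGK")) {
      pt <- if (nm == "IGH") pt_vj_h else pt_vj_k
      safe <- gsub("\\+", "p", gsub("-", "m", g))
      fn <- sprintf("circos_%s_%s.txt", safe, nm)
      export_circos_links(pt, design, g, file.path(out_dir, fn))
      files <- c(files, fn)
    }
  }

  # CDR3 sharing and overlaps
  for (nm in c("IGH", "IGK")) {
    sets_cell <- build_cdr3_sets(records, design, "cell", locus = nm)
    files <- tsv_out(sharing_table(sets_cell), out_dir,
                     sprintf("sharing_cell_%s.tsv", nm), files)
    ov <- purrr::map_dfr(c("AOS", "TT", "CpG"), function(fct) {
      s <- build_cdr3_sets(records, design, fct, locus = nm)
      dplyr::bind_cols(
        tibble::tibble(factor = fct, group_a = names(s)[1],
                       group_b = names(s)[2]),
        variable_overlap(s[[1]], s[[2]])
      )
    })
    files <- tsv_out(ov, out_dir, sprintf("overlap_%s.tsv", nm), files)
    ml <- cdr3_length_distribution(records, locus = nm)$mean_length
    files <- tsv_out(ml, out_dir, sprintf("cdr3_mean_length_%s.tsv", nm),
                     files)
  }
  sets_sw <- build_cdr3_sets(records, design, "cell", locus = "IGH",
                             class_switched_only = TRUE)
  if (any(lengths(sets_sw) > 0)) {
    files <- tsv_out(sharing_table(sets_sw), out_dir,
                     "sharing_cell_IGH_switched.tsv", files)
    ov_sw <- purrr::map_dfr(c("AOS", "TT", "CpG"), function(fct) {
      s <- build_cdr3_sets(records, design, fct, locus = "IGH",
                           class_switched_only = TRUE)
      dplyr::bind_cols(
        tibble::tibble(factor = fct, group_a = names(s)[1],
                       group_b = names(s)[2]),
        variable_overlap(s[[1]], s[[2]])
      )
    })
    files <- tsv_out(ov_sw, out_dir, "overlap_IGH_switched.tsv", files)
  }

  # marker screen
  if (!is.null(tpm_path) && file.exists(tpm_path)) {
    tpm <- readr::read_tsv(tpm_path, col_types = readr::cols(gene = "c",
                                                             .default = "d"),
                           progress = FALSE)
    screen <- purrr::map_dfr(c("AOS", "TT", "CpG"), function(fct) {
      res <- marker_screen(tpm, design, fct)
      res$factor <- fct
      res
    })
    files <- tsv_out(screen, out_dir, "marker_screen.tsv", files)
  }

  invisible(write_manifest(out_dir, config, files, "analyze"))
}

#' Summarize an analysis bundle
#'
#' Builds a machine-readable JSON plus a markdown digest from a completed
#' analysis directory: per-group read accounting, shared-CDR3 tables,
#' overlap summaries, high-frequency segments, top combinations and the
#' significant ANOVA features. Missing sections are listed as warnings in
#' the report rather than failing.
#'
#' @param out_dir analysis output directory (report is written here).
#' @return path of the JSON report, invisibly.
#' @export
run_report <- function(out_dir) {
  read_if <- function(name, col_types = NULL) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, col_types = col_types %||% readr::cols(),
                    progress = FALSE)
  }
  report <- list()
  missing <- character(0)

  acct <- read_if("read_counts.tsv")
  design <- if (file.exists(file.path(out_dir, "..", "design.tsv"))) {
    read_design(file.path(out_dir, "..", "design.tsv"))
  } else NULL
  if (!is.null(acct)) {
    wide <- tidyr::pivot_wider(acct, names_from = "functionality",
                               values_from = "reads", values_fill = 0)
    for (cls in c("productive", "unknown", "unproductive")) {
      if (!cls %in% names(wide)) wide[[cls]] <- 0
    }
    wide$total_assessed <- wide$productive + wide$unknown
    if (!is.null(design)) {
      wide <- dplyr::inner_join(wide, group_labels(design, "cell"),
                                by = "animal_id")
      grp <- dplyr::summarise(
        dplyr::group_by(wide, .data$group, .data$locus),
        mean_productive = mean(.data$productive),
        mean_unknown = mean(.data$unknown),
        mean_total_assessed = mean(.data$total_assessed),
        .groups = "drop"
      )
      report$read_accounting <- grp
    } else {
      report$read_accounting <- wide
    }
  } else missing <- c(missing, "read_counts")

  for (nm in c("IGH", "IGK", "IGH_switched")) {
    sh <- read_if(sprintf("sharing_cell_%s.tsv", nm))
    if (!is.null(sh)) report[[paste0("sharing_", nm)]] <- sh
    ov <- read_if(sprintf("overlap_%s.tsv", nm))
    if (!is.null(ov)) report[[paste0("overlap_", nm)]] <- ov
  }
  if (is.null(report$sharing_IGH)) missing <- c(missing, "sharing")

  hf <- read_if("high_frequency.tsv")
  if (!is.null(hf)) report$high_frequency <- hf else
    missing <- c(missing, "high_frequency")

  for (nm in c("ranking_VDJ_IGH", "ranking_VJ_IGK")) {
    rk <- read_if(paste0(nm, ".tsv"))
    if (!is.null(rk)) report[[nm]] <- rk
  }

  sig <- list()
  for (f in list.files(out_dir, pattern = "^anova_.*\\.tsv$")) {
    an <- read_if(f)
    key <- sub("^anova_(.*)\\.tsv$", "\\1", f)
    sig[[key]] <- an[an$significant & !an$degenerate,
                     c("feature", "term", "p_value")]
  }
  if (length(sig) > 0) report$significant_features <- sig

  screen <- read_if("marker_screen.tsv")
  if (!is.null(screen)) {
    report$marker_screen <- screen[screen$flagged, , drop = FALSE]
  }
  report$missing_sections <- missing

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 6, dataframe = "rows")

  md <- c("# Repertoire analysis report", "")
  if (length(missing) > 0) {
    md <- c(md, paste("**Warning: missing sections:**",
                      paste(missing, collapse = ", ")), "")
  }
  fmt_tbl <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(empty)")
    hdr <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1, function(r) paste(trimws(format(r)), collapse = " | "))
    c(hdr, sep, rows)
  }
  if (!is.null(report$read_accounting)) {
    md <- c(md, "## Read accounting (group means)", "",
            fmt_tbl(report$read_accounting), "")
  }
  for (nm in c("IGH", "IGK")) {
    sh <- report[[paste0("sharing_", nm)]]
    if (!is.null(sh)) {
      md <- c(md, sprintf("## Shared unique CDR3s (%s)", nm), "",
              fmt_tbl(sh), "")
    }
    ov <- report[[paste0("overlap_", nm)]]
    if (!is.null(ov)) {
      md <- c(md, sprintf("## CDR3 overlap by factor (%s)", nm), "",
              fmt_tbl(ov), "")
    }
  }
  if (!is.null(report$high_frequency)) {
    md <- c(md, "## High-frequency segments", "",
            fmt_tbl(report$high_frequency), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(json_path)
}
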