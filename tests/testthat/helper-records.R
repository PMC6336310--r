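# Fixture builders used across the suite.

# One record per call, with analysis-friendly defaults: a productive heavy
# chain with a canonical C...W junction and a single call per segment.
make_record <- function(sequence_id = "s1", animal_id = "m01",
                        locus = "IGH", v_call = "IGHV1-26",
                        d_call = if (locus == "IGH") "IGHD1-1" else "",
                        j_call = if (locus == "IGH") "IGHJ1" else "IGKJ1",
                        c_call = if (locus == "IGH") "IgM" else "unknown",
                        junction_aa = if (locus == "IGH") "CARDYW" else
                          "CQQYNSF",
                        d_alignment_length = if (nzchar(d_call)) 8L else 0L,
                        vj_in_frame = TRUE, stop_codon = FALSE) {
  tibble::tibble(
    animal_id = animal_id, sequence_id = sequence_id, locus = locus,
    v_call = v_call, d_call = d_call, j_call = j_call, c_call = c_call,
    junction_aa = junction_aa,
    d_alignment_length = as.integer(d_alignment_length),
    vj_in_frame = vj_in_frame, stop_codon = stop_codon
  )
}

make_records <- function(...) {
  dplyr::bind_rows(...)
}

# A small factorial design (2 animals per cell keeps ANOVA estimable).
tiny_design <- function(n_per_group = 2) {
  sim_design(n_per_group)
}

# A fast simulated cohort for integration-style tests.
small_cohort <- function(seed = 42, reads = 400, n_per_group = 2, ...) {
  design <- sim_design(n_per_group)
  cfg <- sim_config(n_per_group = n_per_group, reads_per_animal = reads,
                    seed = seed, ...)
  list(design = design,
       records = simulate_repertoires(design, cfg),
       cfg = cfg)
}

# Random usage table for oracle tests.
random_usage <- function(n_animals, n_features, seed) {
  set.seed(seed)
  tidyr::crossing(animal_id = sprintf("a%02d", seq_len(n_animals)),
                  feature = sprintf("f%02d", seq_len(n_features))) |>
    dplyr::mutate(count = stats::runif(dplyr::n(), 0, 50)) |>
    usage_percent()
}
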