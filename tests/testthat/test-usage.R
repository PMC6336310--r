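test_that("fractional abundance: 1.0 single, 0.5 split, >2 matches excluded", {
  rec <- make_records(
    make_record("s1", v_call = "IGHV1-26"),
    make_record("s2", v_call = "IGHV1-63,IGHV1-76"),
    make_record("s3", v_call = "IGHV1-26,IGHV1-63,IGHV1-76"),
    make_record("s4", v_call = "")
  )
  w <- assign_abundance(rec, "V")
  expect_equal(w, c(`IGHV1-26` = 1.0, `IGHV1-63` = 0.5, `IGHV1-76` = 0.5))
  expect_error(
    assign_abundance(make_records(make_record("a"),
                                  make_record("b", locus = "IGK")), "V"),
    "loci")
})

test_that("weight conservation: total weight counts 1- and 2-call records once", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    k <- sample(0:4, n, replace = TRUE)
    genes <- paste0("IGHV1-", 1:30)
    calls <- vapply(k, function(m) paste(sample(genes, m), collapse = ","),
                    character(1))
    rec <- make_record(sprintf("s%d", 1:n), v_call = calls)
    w <- assign_abundance(rec, "V")
    expect_equal(sum(w), sum(k == 1) + sum(k == 2))
  }
})

test_that("usage_percent normalizes rows to 100 and fills absent features", {
  counts <- tibble::tibble(
    animal_id = c("a", "a", "b"),
    feature = c("A", "B", "B"),
    count = c(0.5, 1.5, 2)
  )
  u <- usage_percent(counts)
  expect_equal(u$percent[u$animal_id == "a"], c(25, 75))
  expect_equal(u$percent[u$animal_id == "b"], c(0, 100))
  sums <- tapply(u$percent, u$animal_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_warning(
    usage_percent(tibble::tibble(animal_id = c("a", "z"),
                                 feature = "A", count = c(1, 0))),
    "zero")
})

test_that("usage_table rows sum to 100 on every axis, with U on D/J", {
  co <- small_cohort(seed = 9, reads = 600)
  for (spec in list(list("V", "IGH"), list("D", "IGH"), list("J", "IGH"),
                    list("V", "IGK"), list("isotype", "IGH"),
                    list("cdr3_length", "IGH"))) {
    u <- usage_table(co$records, axis = spec[[1]], locus = spec[[2]])
    sums <- tapply(u$percent, u$animal_id, sum)
    expect_true(all(abs(sums - 100) < 1e-6), label = spec[[1]])
  }
  ud <- usage_table(co$records, axis = "D", locus = "IGH")
  expect_true("U" %in% ud$feature)
  uv <- usage_table(co$records, axis = "V", locus = "IGH")
  expect_false("U" %in% uv$feature)
})

test_that("constant usage aggregates IgG subclasses and drops unknowns", {
  rec <- make_records(
    make_record("s1", c_call = "IgM"), make_record("s2", c_call = "IgM"),
    make_record("s3", c_call = "IgM"), make_record("s4", c_call = "IgG1"),
    make_record("s5", c_call = "unknown")
  )
  u <- constant_usage(rec)
  expect_equal(sort(unique(u$feature)), c("IgG", "IgM"))
  expect_equal(u$percent[u$feature == "IgM"], 75)
  expect_equal(u$percent[u$feature == "IgG"], 25)
  expect_warning(constant_usage(make_record(c_call = "unknown")),
                 "constant region")
})

test_that("class-switched subset shows zero IgM usage", {
  rec <- make_records(
    make_record("s1", c_call = "IgM"), make_record("s2", c_call = "IgG1"),
    make_record("s3", c_call = "IgA")
  )
  u <- constant_usage(subset_class_switched(rec))
  expect_false("IgM" %in% u$feature[u$percent > 0])
})

test_that("high-frequency detection uses strict group-mean threshold", {
  design <- tiny_design(2)
  cells <- igfactorial:::group_labels(design, "cell")
  grp_of <- stats::setNames(cells$group, cells$animal_id)
  # feature A at 6% in saline only; B at exactly 5% everywhere; C the rest
  counts <- purrr::map_dfr(design$animal_id, function(a) {
    pa <- if (grp_of[[a]] == "---") 6 else 1
    tibble::tibble(animal_id = a, feature = c("A", "B", "C"),
                   count = c(pa, 5, 100 - pa - 5))
  })
  u <- usage_percent(counts)
  hf <- high_frequency_segments(u, design, groups = c("---", "-++", "+++"))
  expect_true("A" %in% hf)   # 6% in one group suffices
  expect_false("B" %in% hf)  # exactly 5% is not "over five percent"
  expect_error(high_frequency_segments(u, design, groups = "?+?"), "unknown")
  empty <- u[0, ]
  expect_equal(high_frequency_segments(empty, design), character(0))
})

test_that("realized V usage converges to effect-adjusted weights", {
  # one-cell convergence check at high depth: observed single-call usage
  # approaches the sampling weights within 1 percentage point
  design <- sim_design(2)
  cfg <- sim_config(reads_per_animal = 100000, kappa_fraction = 0,
                    lambda_fraction = 0, ambig_v2_rate = 0,
                    ambig_v3_rate = 0, seed = 77)
  rec <- simulate_repertoires(design[, ], cfg)
  one <- rec[rec$animal_id == "m01", ]
  u <- usage_table(one, axis = "V", locus = "IGH")
  w <- igfactorial:::power_law_weights(default_germline()$IGH$v)
  obs <- stats::setNames(u$percent, u$feature)[names(w)]
  expect_true(all(abs(obs - 100 * w) < 1))
})
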