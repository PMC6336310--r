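test_that("resolve_vdj applies eligibility and undetermined rules", {
  rec <- make_records(
    make_record("s1", d_call = "IGHD1-1", d_alignment_length = 7),
    make_record("s2", d_call = "IGHD1-1", d_alignment_length = 5),
    make_record("s3", v_call = "IGHV1-26,IGHV1-63"),
    make_record("s4", vj_in_frame = FALSE),
    make_record("s5", d_call = ""),
    make_record("s6", d_call = "IGHD1-1,IGHD2-3", d_alignment_length = 10),
    make_record("s7", j_call = "IGHJ1,IGHJ2"),
    make_record("s8", locus = "IGK")
  )
  res <- resolve_vdj(rec)
  # multi-V and unproductive records resolve to nothing
  expect_equal(nrow(res), 6)
  expect_equal(res$d[1], "IGHD1-1")   # D alignment >= 6 nt keeps the gene
  expect_equal(res$d[2], "U")         # < 6 nt -> undetermined
  expect_equal(res$d[3], "U")         # not reported -> undetermined
  expect_equal(res$d[4], "U")         # multiple candidates -> undetermined
  expect_equal(res$j[5], "U")         # multiple J candidates
  expect_true(is.na(res$d[6]))        # kappa has no D component
})

test_that("resolve_vdj returns nothing for non-productive records", {
  co <- small_cohort(seed = 3, reads = 300)
  rec <- co$records
  res <- resolve_vdj(rec)
  func <- classify_functionality(rec)
  expect_lte(nrow(res), sum(func == "productive"))
  # no resolvable record may come from a non-productive source: rerun on
  # the productive subset and expect identical output
  res2 <- resolve_vdj(rec[func == "productive", ])
  expect_equal(res, res2)
})

test_that("pairing percentages sum to 100 per animal; VJ marginalizes VDJ", {
  co <- small_cohort(seed = 13, reads = 400)
  pt <- pairing_table(co$records, mode = "VDJ", locus = "IGH")
  sums <- tapply(pt$percent, pt$animal_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  vj <- pairing_table(co$records, mode = "VJ", locus = "IGH")
  marg <- dplyr::summarise(dplyr::group_by(pt, animal_id, v, j),
                           count = sum(count), .groups = "drop")
  merged <- dplyr::full_join(marg, vj[, c("animal_id", "v", "j", "count")],
                             by = c("animal_id", "v", "j"))
  expect_false(any(is.na(merged$count.x)))
  expect_equal(merged$count.x, merged$count.y)
})

test_that("pairing table matches a brute-force per-record tally", {
  co <- small_cohort(seed = 21, reads = 300)
  pt <- pairing_table(co$records, mode = "VDJ", locus = "IGH")
  res <- resolve_vdj(co$records[co$records$locus == "IGH", ])
  for (a in unique(pt$animal_id)) {
    sub <- res[res$animal_id == a, ]
    key <- paste(sub$v, sub$d, sub$j)
    tally <- table(key)
    pta <- pt[pt$animal_id == a, ]
    expect_equal(nrow(pta), length(tally))
    expect_equal(
      stats::setNames(pta$count, paste(pta$v, pta$d, pta$j))[names(tally)],
      stats::setNames(as.numeric(tally), names(tally))
    )
  }
})

test_that("top-k ranking unions groups and breaks ties deterministically", {
  means <- tibble::tibble(
    group = rep(c("g1", "g2", "g3"), each = 3),
    v = rep(c("V1", "V2", "V3"), 3),
    d = "D1", j = "J1",
    combo = rep(c("V1/D1/J1", "V2/D1/J1", "V3/D1/J1"), 3),
    mean_percent = c(50, 30, 20, 50, 30, 20, 50, 30, 20)
  )
  rk <- rank_top_combinations(means, k = 5)
  expect_equal(length(unique(rk$combo)), 3)  # shared top combos union to 3
  expect_equal(rk$rank[rk$combo == "V1/D1/J1"], rep(1L, 3))
  # disjoint tops union to k * groups
  means2 <- means
  means2$combo <- paste0(means2$group, "_", means2$combo)
  rk2 <- rank_top_combinations(means2, k = 5)
  expect_equal(length(unique(rk2$combo)), 9)
  # k larger than the table returns everything
  rk3 <- rank_top_combinations(means, k = 99)
  expect_equal(sort(unique(rk3$combo)), sort(unique(means$combo)))
  # ties flagged and ordered lexicographically
  tie <- tibble::tibble(group = "g1", v = c("V2", "V1"), d = "D1", j = "J1",
                        combo = c("V2/D1/J1", "V1/D1/J1"),
                        mean_percent = c(10, 10))
  rkt <- rank_top_combinations(tie, k = 2)
  expect_true(all(rkt$tied))
  expect_equal(rkt$rank[rkt$combo == "V1/D1/J1"], 1L)
})

test_that("low-frequency pair filter drops only pairs rare in all levels", {
  means <- tibble::tibble(
    group = rep(c("AOS-", "AOS+"), 3),
    combo = rep(c("p1", "p2", "p3"), each = 2),
    mean_percent = c(0.05, 0.05, 0.5, 0.01, 0.1, 0.02)
  )
  kept <- filter_low_frequency_pairs(means, threshold = 0.1)
  expect_equal(sort(unique(kept$combo)), c("p2", "p3"))
  expect_equal(nrow(filter_low_frequency_pairs(means[0, ])), 0)
  # never removes a pair whose max group mean reaches the threshold
  for (seed in 1:10) {
    set.seed(seed)
    m <- tibble::tibble(group = rep(c("a", "b"), 20),
                        combo = rep(sprintf("c%02d", 1:20), each = 2),
                        mean_percent = stats::runif(40, 0, 0.3))
    kept <- filter_low_frequency_pairs(m, threshold = 0.1)
    top <- tapply(m$mean_percent, m$combo, max)
    expect_setequal(unique(kept$combo), names(top)[top >= 0.1])
  }
})

test_that("circos link files round-trip group-total counts", {
  co <- small_cohort(seed = 8, reads = 300)
  pt <- pairing_table(co$records, mode = "VJ", locus = "IGH")
  path <- withr::local_tempfile(fileext = ".txt")
  export_circos_links(pt, co$design, "---", path)
  back <- read_circos_links(path)
  grp <- igfactorial:::group_labels(co$design, "cell")
  animals <- grp$animal_id[grp$group == "---"]
  sub <- pt[pt$animal_id %in% animals, ]
  agg <- dplyr::summarise(dplyr::group_by(sub, v, j),
                          count = sum(count), .groups = "drop")
  expect_equal(sum(back$count), sum(agg$count))
  expect_equal(nrow(back), nrow(agg))
  expect_true("U" %in% c(back$j, back$v) ||
                !any(agg$j == "U" | agg$v == "U"))
  expect_error(export_circos_links(pt_vdj <- pairing_table(
    co$records, mode = "VDJ"), co$design, "---", path), "VJ")
})
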