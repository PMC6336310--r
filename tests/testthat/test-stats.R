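test_that("three-way ANOVA recovers a constructed main effect", {
  design <- tiny_design(2)
  set.seed(2)
  y <- stats::rnorm(nrow(design), sd = 0.01) + ifelse(design$aos, 10, 0)
  res <- threeway_anova(stats::setNames(y, design$animal_id), design)
  expect_equal(res$term, c("AOS", "TT", "CpG", "AOSxTT", "AOSxCpG",
                           "TTxCpG", "AOSxTTxCpG"))
  expect_lt(res$p_value[res$term == "AOS"], 1e-10)
  expect_true(all(res$p_value[res$term != "AOS"] > 0.05))
})

test_that("degenerate responses report p = 1 and are flagged", {
  design <- tiny_design(2)
  res <- threeway_anova(stats::setNames(rep(3, nrow(design)),
                                        design$animal_id), design)
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))
  expect_error(threeway_anova(stats::setNames(1:8, sim_design(2)$animal_id[1:8]),
                              design), "missing")
})

test_that("ANOVA p-values are invariant to factor ordering on balanced designs", {
  design <- tiny_design(2)
  set.seed(11)
  y <- stats::rnorm(nrow(design))
  res <- threeway_anova(stats::setNames(y, design$animal_id), design)
  flipped <- design
  names(flipped)[2:4] <- c("cpg", "tt", "aos")  # permute factor roles
  res2 <- threeway_anova(stats::setNames(y, flipped$animal_id), flipped)
  expect_equal(sort(res$p_value), sort(res2$p_value))
  relabel <- c(AOS = "CpG", TT = "TT", CpG = "AOS")
  expect_equal(res2$p_value[match(c("CpG", "TT", "AOS"), res2$term)],
               res$p_value[match(c("AOS", "TT", "CpG"), res$term)])
})

test_that("Tukey post-hoc flags only the shifted group", {
  design <- tiny_design(3)
  set.seed(7)
  y <- stats::rnorm(nrow(design), sd = 1)
  y[treatment_cell(design) == "+++"] <- y[treatment_cell(design) == "+++"] + 10
  tk <- tukey_posthoc(stats::setNames(y, design$animal_id), design,
                      groups = c("---", "-++", "+++"))
  hit <- grepl("\\+\\+\\+", tk$contrast)
  expect_true(all(tk$p_adj[hit] < 0.01))
  expect_true(all(tk$p_adj[!hit] > 0.05))
  # identical within-cell patterns: group means equal, adjusted p = 1
  y2 <- 5 + rep(c(-0.1, 0, 0.1), 8)  # design rows are cell blocks of 3
  tk2 <- tukey_posthoc(stats::setNames(y2, design$animal_id), design,
                       groups = c("---", "-++"))
  expect_gt(min(tk2$p_adj), 0.99)
  expect_error(tukey_posthoc(stats::setNames(y, design$animal_id), design,
                             groups = "---"), ">= 2")
})

test_that("animal variance equals the printed squared-deviation formula", {
  u <- usage_percent(tibble::tibble(
    animal_id = c("a", "a", "b", "b"),
    feature = c("f1", "f2", "f1", "f2"),
    count = c(10, 90, 20, 80)
  ))
  av <- animal_variance(u)
  # f1: 10% vs 20% about mean 15 -> 25 each; f2 symmetric -> total 50
  expect_equal(av$variation, c(50, 50))
  same <- usage_percent(tibble::tibble(
    animal_id = rep(c("a", "b", "c"), each = 2),
    feature = rep(c("f1", "f2"), 3), count = rep(c(1, 3), 3)
  ))
  expect_equal(animal_variance(same)$variation, rep(0, 3))
  expect_error(animal_variance(u[u$animal_id == "a", ]), ">= 2")
})

test_that("variance comparison detects an inflated group", {
  design <- tiny_design(3)
  set.seed(2)
  v <- abs(stats::rnorm(nrow(design), mean = 2, sd = 0.2))
  v[treatment_cell(design) == "+--"] <- v[treatment_cell(design) == "+--"] * 100
  res <- compare_variance(
    tibble::tibble(animal_id = design$animal_id, variation = v), design)
  expect_lt(res$global$p_value, 0.001)
  hit <- grepl("\\+--", res$contrasts$contrast)
  expect_true(all(res$contrasts$p_adj[hit] < 0.05))
  expect_true(all(res$contrasts$p_adj[!hit] > 0.5))
  expect_equal(nrow(res$means), 8)
  # equal group means (identical within-cell pattern): nothing significant
  flat <- compare_variance(
    tibble::tibble(animal_id = design$animal_id,
                   variation = 1 + rep(c(-0.05, 0, 0.05), 8)), design)
  expect_true(all(flat$contrasts$p_adj > 0.99))
  expect_equal(flat$global$p_value, 1)
})

test_that("usage regression returns R^2 with affine invariance", {
  x <- stats::setNames(c(10, 20, 30, 40), paste0("g", 1:4))
  suppressWarnings({  # lm warns on exact fits
    expect_equal(usage_regression(x, x)$r_squared, 1)
    expect_equal(usage_regression(x, 2 * x + 7)$r_squared, 1)
  })
  set.seed(3)
  a <- stats::setNames(stats::runif(200), paste0("g", 1:200))
  b <- stats::setNames(stats::runif(200), paste0("g", 1:200))
  expect_lt(usage_regression(a, b)$r_squared, 0.1)
  expect_error(usage_regression(x[1:2], x[1:2]), ">= 3")
  expect_error(usage_regression(stats::setNames(rep(1, 4), names(x)), x),
               "zero-variance")
})

test_that("marker screen sign convention and flag rule", {
  design <- tiny_design(2)
  pos <- design$animal_id[design$aos]
  neg <- design$animal_id[!design$aos]
  mk_tpm <- function(vals_pos, vals_neg, gene = "CD138") {
    tpm <- tibble::tibble(gene = gene)
    for (a in pos) tpm[[a]] <- vals_pos
    for (a in neg) tpm[[a]] <- vals_neg
    tpm
  }
  # m+ = 10, m- = 21.5 -> fold change -2.15 (larger-over-smaller, signed)
  res <- marker_screen(mk_tpm(10, 21.5), design, "AOS")
  expect_equal(res$fold_change, -2.15)
  expect_true(res$flagged)  # identical replicates -> p ~ 0
  # identical means -> FC +1, never flagged
  res1 <- marker_screen(mk_tpm(15, 15), design, "AOS")
  expect_equal(res1$fold_change, 1)
  expect_false(res1$flagged)
  # zero mean -> undefined FC, excluded from flagging
  res0 <- marker_screen(mk_tpm(0, 10), design, "AOS")
  expect_true(is.na(res0$fold_change))
  expect_false(res0$flagged)
})

test_that("flagging is exactly |FC| > 2 and p < 0.05", {
  design <- tiny_design(2)
  set.seed(6)
  genes <- sprintf("g%03d", 1:150)
  tpm <- simulate_tpm(genes, design, seed = 606)
  res <- marker_screen(tpm, design, "TT")
  expect_equal(res$flagged,
               !is.na(res$fold_change) & abs(res$fold_change) > 2 &
                 res$p_value < 0.05)
  # a sub-threshold fold change is never flagged however small its p-value
  small_fc <- abs(res$fold_change) <= 2
  expect_false(any(res$flagged[small_fc]))
})

test_that("marker screen recovers an injected suppression", {
  design <- tiny_design(4)
  tpm <- simulate_tpm(c("CD138", "B220"), design,
                      effects = list(effect_spec("AOS", "CD138", 0.4)),
                      seed = 17)
  res <- marker_screen(tpm, design, "AOS")
  cd138 <- res[res$gene == "CD138", ]
  expect_lt(cd138$fold_change, -2)
  expect_true(cd138$flagged)
  expect_false(res$flagged[res$gene == "B220"])
})
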