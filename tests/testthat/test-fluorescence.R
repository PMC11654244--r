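test_that("cell summaries trim outliers and use the geometric mean", {
  # constant population
  s <- summarize_cells(rep(250, 30))
  expect_equal(s$geo_mean, 250)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 30L)

  # geometric mean of {100, 400} is 200
  expect_equal(summarize_cells(c(100, 400))$geo_mean, 200)

  # a gross outlier among 50 uniform cells is trimmed
  x <- c(rep(100, 50), 10000)
  s2 <- summarize_cells(x)
  expect_equal(s2$n, 50L)
  expect_equal(s2$geo_mean, 100)
  # matches the brute-force trim oracle
  o <- oracle_trim_summary(x)
  expect_equal(s2$geo_mean, o$geo_mean)
  expect_equal(s2$n, o$n)

  expect_error(summarize_cells(numeric()), "non-empty")
  expect_error(summarize_cells(c(1, -1)), "positive")
})

test_that("trimmed summary matches the brute-force oracle on random draws", {
  set.seed(41)
  for (i in 1:25) {
    x <- rlnorm(sample(5:50, 1), log(200), runif(1, 0.1, 1))
    got <- summarize_cells(x)
    want <- oracle_trim_summary(x)
    expect_equal(got$geo_mean, want$geo_mean)
    expect_equal(got$n, want$n)
  }
})

test_that("geometric mean summary is scale-equivariant", {
  set.seed(43)
  x <- rlnorm(200, log(300), 0.4)
  for (c in c(0.5, 3, 10)) {
    expect_equal(summarize_cells(c * x)$geo_mean,
                 c * summarize_cells(x)$geo_mean, tolerance = 1e-10)
  }
})

test_that("autofluorescence band is mean +/- 2 SD of control geo-means", {
  b <- autofluorescence_band(c(90, 100, 110))
  expect_equal(b$mean, 100)
  expect_equal(b$upper, 100 + 2 * sd(c(90, 100, 110)))
  expect_equal(b$lower, 100 - 2 * sd(c(90, 100, 110)))
  expect_equal(b$brightest_control, 110)

  # degenerate controls: zero-width band
  b2 <- autofluorescence_band(c(50, 50))
  expect_equal(b2$lower, b2$upper)
  expect_error(autofluorescence_band(100), "2 control")
})

test_that("band covers ~95% of normal control geo-means", {
  set.seed(47)
  cover <- vapply(1:500, function(i) {
    gms <- rnorm(50, 100, 8)
    b <- autofluorescence_band(gms)
    mean(gms >= b$lower & gms <= b$upper)
  }, numeric(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("classification follows the screen decision tree", {
  band <- tiny_band()
  pops <- tiny_populations(depletion = 0.1, n_cells = 300)

  # dim strain: not visible regardless of the after population
  dim_pop <- sim_cell_population(100, log_mean = log(0.5), log_sd = 0,
                                 seed = 3)
  call <- classify_strain(dim_pop, pops$after, band)
  expect_equal(as.character(call$status), "not_visible")
  expect_false(call$fluorescent)

  # same distribution before and after: irresponsive
  a <- sim_cell_population(400, induced = FALSE, seed = 5)
  b <- sim_cell_population(400, induced = TRUE, depletion_factor = 1,
                           seed = 6)
  call2 <- classify_strain(a, b, band)
  expect_equal(as.character(call2$status), "irresponsive")

  # strong depletion with many cells: responsive, and the t statistic
  # agrees with a direct computation on the same trimmed samples
  call3 <- classify_strain(pops$before, pops$after, band)
  expect_equal(as.character(call3$status), "responsive")
  expect_lt(call3$effect, 0.75)
  direct <- t.test(log(pops$after$mean_intensity),
                   log(pops$before$mean_intensity),
                   alternative = "less", var.equal = FALSE)$p.value
  expect_equal(call3$p_value, direct)

  # death call: after-induction cell count collapse
  few <- pops$after[1:20, ]
  call4 <- classify_strain(pops$before, few, band)
  expect_equal(as.character(call4$status), "dead")

  expect_error(classify_strain(pops$before, pops$after, band = NULL),
               "af_band")
})

test_that("classification is invariant to cell order", {
  band <- tiny_band()
  pops <- tiny_populations()
  set.seed(51)
  shuffled <- lapply(pops, function(p) p[sample(nrow(p)), ])
  c1 <- classify_strain(pops$before, pops$after, band)
  c2 <- classify_strain(shuffled$before, shuffled$after, band)
  expect_equal(c1$p_value, c2$p_value)
  expect_equal(c1$effect, c2$effect)
  expect_equal(c1$status, c2$status)
})

test_that("panel adjustment applies BH and re-resolves calls", {
  band <- tiny_band()
  calls <- dplyr::bind_rows(lapply(1:10, function(i) {
    pops <- list(
      before = sim_cell_population(120, induced = FALSE, seed = 100 + i,
                                   strain_id = sprintf("S%04d", i)),
      after = sim_cell_population(120, induced = TRUE,
                                  depletion_factor = ifelse(i <= 5, 0.3, 1),
                                  seed = 200 + i,
                                  strain_id = sprintf("S%04d", i))
    )
    classify_strain(pops$before, pops$after, band)
  }))
  adj <- adjust_strain_calls(calls)
  testable <- !is.na(calls$p_value)
  expect_equal(adj$p_adj[testable],
               p.adjust(calls$p_value[testable], "BH"))
  expect_true(all(adj$p_adj[testable] >= calls$p_value[testable]))
  # the five depleted strains stay responsive after adjustment
  expect_true(all(adj$status[1:5] == "responsive"))
})

test_that("library summary uses the documented denominators", {
  calls <- tibble::tibble(
    strain_id = sprintf("S%02d", 1:10),
    fluorescent = c(rep(TRUE, 8), FALSE, FALSE),
    status = factor(c(rep("responsive", 5), "irresponsive", "dead", "dead",
                      "not_visible", "not_visible"),
                    levels = c("not_visible", "responsive", "irresponsive",
                               "dead", "manual_review")),
    effect = NA_real_, p_value = NA_real_, p_adj = NA_real_,
    geo_before = NA_real_, geo_after = NA_real_,
    n_before = NA_integer_, n_after = NA_integer_
  )
  s <- library_summary(calls)
  expect_equal(s$pct_fluorescent, 80)
  # 5 responsive of 6 live fluorescent
  expect_equal(s$pct_responsive_of_fluorescent, 100 * 5 / 6)
  # dead counted as responding over all fluorescent
  expect_equal(s$pct_responsive_incl_dead, 100 * 7 / 8)

  all_dark <- dplyr::mutate(calls, fluorescent = FALSE,
                            status = factor("not_visible",
                                            levels = levels(calls$status)))
  expect_equal(library_summary(all_dark)$pct_fluorescent, 0)
})
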