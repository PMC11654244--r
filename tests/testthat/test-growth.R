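test_that("relative growth is mean(induced)/mean(uninduced) per strain", {
  # hand-computed: 2 induced replicates (80, 120) vs 2 uninduced (200, 200)
  plates <- tibble::tibble(
    plate_id = "P1", media = "rich",
    induced = rep(c(TRUE, FALSE), each = 2),
    replicate = c(1, 2, 1, 2),
    row = 1, col = 1, strain_id = "s1",
    size = c(80, 120, 200, 200)
  )
  out <- score_relative_growth(plates)
  expect_equal(out$raw_ratio, 0.5)

  # noise-free screen: every scorable ratio is 1
  sim <- sim_plate_pair(96, c(8, 12), lethal_fraction = 0, noise_cv = 0,
                        edge_boost = 1.3, seed = 1)
  sc <- score_relative_growth(sim$plates)
  expect_true(all(sc$raw_ratio == 1))

  # planted lethal with effect 0 scores exactly 0
  sim2 <- sim_plate_pair(100, c(10, 10), lethal_fraction = 0.1,
                         effect_size = 0, noise_cv = 0, seed = 2)
  sc2 <- score_relative_growth(sim2$plates)
  lethal <- sim2$truth$strain_id[sim2$truth$lethal]
  expect_true(all(sc2$raw_ratio[sc2$strain_id %in% lethal] == 0))
})

test_that("absent strains are flagged, not divided", {
  plates <- tibble::tibble(
    plate_id = "P1", media = "rich",
    induced = rep(c(TRUE, FALSE), each = 2),
    replicate = rep(1, 4),
    row = c(1, 2, 1, 2), col = 1,
    strain_id = rep(c("grew", "empty"), 2),
    size = c(100, 0, 200, 0)
  )
  out <- score_relative_growth(plates)
  expect_true(out$absent[out$strain_id == "empty"])
  expect_true(is.na(out$raw_ratio[out$strain_id == "empty"]))
  expect_false(out$absent[out$strain_id == "grew"])
})

test_that("mismatched strain maps between conditions are an error", {
  plates <- tibble::tibble(
    plate_id = "P1", media = "rich",
    induced = c(TRUE, FALSE),
    replicate = 1, row = 1, col = 1,
    strain_id = c("a", "b"), size = c(100, 100)
  )
  expect_error(score_relative_growth(plates), "strain map")
})

test_that("plate-median normalization sets the robust group median to 1", {
  # all raw ratios equal c -> all normalized scores 1
  sc <- tibble::tibble(strain_id = letters[1:5], media = "rich",
                       plate_id = "P1", raw_ratio = 0.8,
                       n_induced = 2L, n_uninduced = 2L, absent = FALSE)
  out <- normalize_scores(sc)
  expect_true(all(out$normalized_score == 1))

  # lethal zero is excluded by the robust trim, stays 0 after division
  sc2 <- tibble::tibble(strain_id = letters[1:10], media = "rich",
                        plate_id = "P1",
                        raw_ratio = c(rep(1, 9), 0),
                        n_induced = 2L, n_uninduced = 2L, absent = FALSE)
  out2 <- normalize_scores(sc2)
  # brute-force oracle: median after trimming outside median +/- 2*1.4826*MAD
  x <- sc2$raw_ratio
  med <- median(x); s <- mad(x)
  trimmed <- if (s == 0) x else x[abs(x - med) <= 2 * s]
  expect_equal(unique(out2$norm_factor), median(trimmed))
  expect_equal(out2$normalized_score[10], 0)
  expect_equal(out2$normalized_score[1], 1)

  # two plates offset by 2x align after normalization
  set.seed(31)
  base <- rlnorm(200, 0, 0.1)
  sc3 <- tibble::tibble(
    strain_id = rep(sprintf("s%03d", 1:200), 2),
    media = "rich",
    plate_id = rep(c("P1", "P2"), each = 200),
    raw_ratio = c(base, 2 * rlnorm(200, 0, 0.1)),
    n_induced = 2L, n_uninduced = 2L, absent = FALSE
  )
  out3 <- normalize_scores(sc3)
  ks <- suppressWarnings(stats::ks.test(
    out3$normalized_score[out3$plate_id == "P1"],
    out3$normalized_score[out3$plate_id == "P2"]))
  expect_gt(ks$p.value, 0.01)

  # under-populated groups are skipped with a warning
  sc4 <- sc[1:2, ]
  expect_warning(normalize_scores(sc4), "unnormalized")
})

test_that("essentiality classes follow strict thresholds", {
  df <- tibble::tibble(
    strain_id = c("a", "b", "c", "d", "e"), media = "rich",
    normalized_score = c(0.45, 0.05, 1.0, 0.5, NA)
  )
  out <- classify_essentiality(df)
  expect_equal(as.character(out$class),
               c("severe", "stringent_severe", "none", "none", "absent"))
  # stringent_severe implies severe
  expect_true(all(out$severe[out$stringent_severe]))
  # boundary is strict: exactly 0.1 is severe but not stringent
  b <- classify_essentiality(tibble::tibble(
    strain_id = "x", media = "rich", normalized_score = 0.1))
  expect_equal(as.character(b$class), "severe")
  expect_false(b$stringent_severe)
})

test_that("lowering the threshold never adds strains to the severe set", {
  set.seed(17)
  df <- tibble::tibble(strain_id = sprintf("s%03d", 1:300), media = "rich",
                       normalized_score = runif(300, 0, 1.5))
  thresholds <- c(0.6, 0.5, 0.3, 0.1)
  sets <- lapply(thresholds, function(th) {
    out <- classify_essentiality(df, permissive = th, stringent = th / 10)
    out$strain_id[out$severe]
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("media partition yields exhaustive disjoint regions", {
  part <- media_partition(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
  m <- part$membership
  expect_equal(m$region[m$strain_id == "y"], "A&B&C")
  expect_equal(m$region[m$strain_id == "x"], "A")
  expect_equal(m$region[m$strain_id == "z"], "B")
  expect_equal(sum(part$regions$n), 3)

  # identical sets: everything in the triple intersection
  p2 <- media_partition(list(A = c("a", "b"), B = c("a", "b"),
                             C = c("a", "b")))
  expect_equal(p2$regions$region, "A&B&C")
  expect_equal(p2$regions$n, 2)

  # disjoint sets: all strains exclusive
  p3 <- media_partition(list(A = "a", B = "b", C = "c"))
  expect_true(all(p3$membership$exclusive))
  expect_equal(lengths(p3$exclusive), c(A = 1L, B = 1L, C = 1L))
})

test_that("region sizes always sum to the union cardinality", {
  set.seed(23)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) {
      sample(sprintf("s%02d", 1:30), sample(0:20, 1))
    })
    names(sets) <- c("A", "B", "C")
    if (all(lengths(sets) == 0)) next
    part <- media_partition(sets)
    expect_equal(sum(part$regions$n),
                 length(unique(unlist(sets))))
    # cross-check every region label against the brute-force membership oracle
    oracle <- oracle_venn(sets)
    expect_equal(part$membership$region[
      match(names(oracle), part$membership$strain_id)],
      unname(oracle))
  }
})

test_that("colony presence uses a strict 'over threshold' rule", {
  out <- colony_presence(c(50, 51, 0, 400))
  expect_equal(out$present, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(colony_presence(rep(0, 10))$survival_rate, 0)
  expect_equal(colony_presence(c(rep(100, 92), rep(0, 8)))$survival_rate,
               0.92)
})

test_that("induced/uninduced ratio cancels shared positional effects", {
  sim <- sim_plate_pair(n_strains = 384, layout = c(16, 24),
                        lethal_fraction = 0, noise_cv = 0.1,
                        edge_boost = 1.4, seed = 29)
  sc <- normalize_scores(score_relative_growth(sim$plates))
  p <- sim$plates[sim$plates$replicate == 1 & !sim$plates$induced, ]
  edge_ids <- p$strain_id[p$row == 1 | p$row == 16 | p$col == 1 | p$col == 24]
  m_edge <- mean(sc$normalized_score[sc$strain_id %in% edge_ids])
  m_center <- mean(sc$normalized_score[!sc$strain_id %in% edge_ids])
  # edge and center strains score the same despite the 1.4x edge boost
  expect_lt(abs(m_edge - m_center), 0.03)
})
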