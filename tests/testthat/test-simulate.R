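test_that("plate pair generator honors its noise-free contracts", {
  # no noise, no edge effect, no lethals: induced identical to uninduced
  sim <- sim_plate_pair(n_strains = 96, layout = c(8, 12),
                        lethal_fraction = 0, noise_cv = 0, edge_boost = 1,
                        seed = 1)
  ind <- sim$plates[sim$plates$induced & sim$plates$replicate == 1, ]
  unind <- sim$plates[!sim$plates$induced & sim$plates$replicate == 1, ]
  expect_identical(ind$size, unind$size)

  # effect_size = 0: lethal strains have induced size exactly 0
  sim2 <- sim_plate_pair(n_strains = 100, layout = c(10, 10),
                         lethal_fraction = 0.1, effect_size = 0, seed = 2)
  expect_identical(sum(sim2$truth$lethal), 10L)
  lethal_ids <- sim2$truth$strain_id[sim2$truth$lethal]
  ind2 <- sim2$plates[sim2$plates$induced &
                        sim2$plates$strain_id %in% lethal_ids, ]
  expect_true(all(ind2$size == 0))

  # determinism: same seed, bit-identical grids
  expect_identical(tiny_screen(seed = 5), tiny_screen(seed = 5))

  # capacity overflow
  expect_error(sim_plate_pair(n_strains = 97, layout = c(8, 12)),
               "capacity")
})

test_that("edge boost multiplies only the outermost ring, both conditions", {
  sim <- sim_plate_pair(n_strains = 96, layout = c(8, 12),
                        lethal_fraction = 0, noise_cv = 0,
                        edge_boost = 1.5, baseline = 100, seed = 3)
  p <- sim$plates[sim$plates$replicate == 1, ]
  edge <- p$row == 1 | p$row == 8 | p$col == 1 | p$col == 12
  expect_true(all(p$size[edge] == 150))
  expect_true(all(p$size[!edge] == 100))
})

test_that("cell population generator matches its distributional contracts", {
  # degenerate: all draws identical, geometric mean equals the constant
  pop <- sim_cell_population(20, log_mean = log(500), log_sd = 0,
                             af_mean = 100, af_sd = 0, seed = 1)
  expect_equal(pop$mean_intensity, rep(600, 20))
  expect_equal(summarize_cells(pop$mean_intensity)$geo_mean, 600)

  # depletion_factor = 1: induced and uninduced share one distribution
  a <- sim_cell_population(50, induced = FALSE, seed = 4)
  b <- sim_cell_population(50, induced = TRUE, depletion_factor = 1,
                           seed = 4)
  expect_equal(a$mean_intensity, b$mean_intensity)

  # strictly positive always
  p2 <- sim_cell_population(2000, af_mean = 1, af_sd = 5,
                            depletion_factor = 0, induced = TRUE, seed = 5)
  expect_true(all(p2$mean_intensity > 0))
})

test_that("depleted population geometric-mean ratio tracks the closed form", {
  # signal-plus-background ratio expected from the generating parameters
  log_mean <- log(1000); log_sd <- 0.3; af <- 100; depl <- 0.1
  n <- 500
  before <- sim_cell_population(n, log_mean, log_sd, af, 10,
                                induced = FALSE, seed = 11)
  after <- sim_cell_population(n, log_mean, log_sd, af, 10,
                               depletion_factor = depl, induced = TRUE,
                               seed = 12)
  # Monte-Carlo expectation of the geo-mean ratio at large n
  set.seed(1)
  sig <- rlnorm(2e5, log_mean, log_sd)
  bg <- rnorm(2e5, af, 10)
  expected <- exp(mean(log(bg + depl * sig))) / exp(mean(log(bg + sig)))
  observed <- geo_mean(after$mean_intensity) / geo_mean(before$mean_intensity)
  expect_lt(abs(observed - expected) / expected, 0.10)
})

test_that("time-course generator reproduces the decay law exactly at cv 0", {
  tc <- sim_timecourse(t50 = 30, plateau = 0, noise_cv = 0, n_rep = 1,
                       timepoints = c(0, 30, 60))
  expect_equal(tc$signal, c(1, 0.5, 0.25))
  # plateau asymptote
  tc2 <- sim_timecourse(t50 = 30, plateau = 0.2, noise_cv = 0, n_rep = 1,
                        timepoints = c(0, 1e6))
  expect_equal(tc2$signal[2], 0.2, tolerance = 1e-6)
  expect_error(sim_timecourse(t50 = -1), "t50")
  expect_error(sim_timecourse(t50 = 30, timepoints = c(10, 20, 30)),
               "include 0")
})

test_that("annotation generator plants exact term sizes", {
  ann <- sim_annotation_table(6000, c(`GO:A` = 151, `GO:B` = 30), seed = 8)
  expect_identical(sum(ann$term_id == "GO:A"), 151L)
  expect_identical(sum(ann$term_id == "GO:B"), 30L)
  # full-universe term annotates every gene
  ann2 <- sim_annotation_table(40, c(`GO:C` = 40), seed = 8)
  expect_setequal(ann2$gene_id, sprintf("G%04d", 1:40))
  # determinism and size validation
  expect_identical(sim_annotation_table(100, c(`GO:D` = 10), seed = 3),
                   sim_annotation_table(100, c(`GO:D` = 10), seed = 3))
  expect_error(sim_annotation_table(100, c(`GO:E` = 101)), "term size")
})

test_that("cell image generator places disks with recoverable centroids", {
  blank <- sim_cell_image(0, image_size = 64)
  expect_identical(nrow(blank$centroids), 0L)
  expect_true(all(blank$image == blank$image[1, 1]))

  img <- sim_cell_image(5, image_size = 256, cell_radius = 6,
                        intensity = 5000, background = 100, seed = 9)
  expect_identical(nrow(img$centroids), 5L)
  # the centroid pixel carries the disk intensity
  for (i in 1:5) {
    expect_equal(img$image[img$centroids$row[i], img$centroids$col[i]], 5000)
  }
  # non-overlap: pairwise centroid distance above 2r
  d <- as.matrix(dist(img$centroids[, c("row", "col")]))
  expect_true(all(d[upper.tri(d)] > 12))
  # determinism
  img2 <- sim_cell_image(5, image_size = 256, cell_radius = 6,
                         intensity = 5000, background = 100, seed = 9)
  expect_identical(img$image, img2$image)
  # impossible packing errors out
  expect_error(sim_cell_image(50, image_size = 40, cell_radius = 8,
                              max_tries = 20, seed = 1), "overlap|radius")
})

test_that("signal geometric mean converges to exp(log_mean) at large n", {
  n <- 1e5
  set.seed(13)
  sig <- rlnorm(n, meanlog = log(800), sdlog = 0.4)
  expect_lt(abs(exp(mean(log(sig))) - 800) / 800, 0.01)
})
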