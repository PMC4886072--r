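test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_config(seed = 42)
  a <- generate_tissue_image(cfg)
  b <- generate_tissue_image(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$centers, b$truth$centers)

  da <- generate_crop_dataset(cfg, n_per_class = 3)
  db <- generate_crop_dataset(cfg, n_per_class = 3)
  expect_identical(da$crops[[1]]$snsci, db$crops[[1]]$snsci)

  ta <- generate_feature_table(20, separation = 2, seed = 9)
  tb <- generate_feature_table(20, separation = 2, seed = 9)
  expect_identical(ta$x, tb$x)
  expect_false(identical(ta$x, generate_feature_table(20, 2, seed = 10)$x))
})

test_that("n_cells = 0 yields a background-only image with empty truth", {
  sim <- generate_tissue_image(synthetic_config(n_cells = 0, seed = 1))
  expect_equal(nrow(sim$truth$centers), 0)
  expect_length(sim$truth$masks, 0)
  expect_true(all(sim$image >= 0 & sim$image <= 255))
  # no dark nuclei: everything stays near the background level
  expect_gt(min(sim$image), 150)
})

test_that("round ground-truth masks are disjoint and pass the circularity filter", {
  cfg <- synthetic_config(n_cells = 20, class_mix = 0, normal_radius_px = 17,
                          seed = 7)
  sim <- generate_tissue_image(cfg)
  expect_length(sim$truth$masks, 20)
  overlap <- Reduce(`+`, lapply(sim$truth$masks, function(m) m * 1))
  expect_lte(max(overlap), 1)
  circ <- vapply(sim$truth$masks, function(m) {
    regs <- connected_regions(m)
    expect_length(regs, 1)
    region_circularity(regs[[1]])
  }, numeric(1))
  expect_true(all(circ >= 0.85))
})

test_that("cell placement honors the minimum spacing or errors out", {
  cfg <- synthetic_config(n_cells = 12, seed = 3)
  sim <- generate_tissue_image(cfg)
  d <- as.matrix(dist(sim$truth$centers))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_cell_spacing)
  too_many <- synthetic_config(n_cells = 500, image_size = c(128L, 128L),
                               min_cell_spacing = 40, seed = 1)
  expect_error(generate_tissue_image(too_many), "could not place")
})

test_that("crop datasets respect the size contract and class intensities", {
  cfg <- synthetic_config(seed = 5)
  ds <- generate_crop_dataset(cfg, n_per_class = 10)
  expect_length(ds$crops, 20)
  expect_identical(as.integer(table(ds$labels)), c(10L, 10L))
  for (cr in ds$crops) {
    expect_identical(dim(cr$sbci), c(51L, 51L))
    expect_identical(dim(cr$snsci), c(51L, 51L))
    px <- which(cr$sbci, arr.ind = TRUE)
    expect_identical(dim(cr$smerci),
                     c(diff(range(px[, 1])) + 1L, diff(range(px[, 2])) + 1L))
  }
  # all-normal, roughness 0: SBCI is a centered disk
  ds0 <- generate_crop_dataset(synthetic_config(class_mix = 0, seed = 2),
                               n_per_class = 3)
  for (cr in ds0$crops[ds0$labels == "normal"]) {
    expect_true(cr$sbci[26, 26])
    expect_gte(region_circularity(connected_regions(cr$sbci)[[1]]), 0.9)
  }
  # crop too small for the requested radius
  expect_error(generate_crop_dataset(cfg, 2, crop_size = 21), "cannot contain")
})

test_that("class intensity means separate as configured", {
  cfg <- synthetic_config(normal_mean_intensity = 180, hcc_mean_intensity = 120,
                          intensity_noise_sd = 5, hcc_noise_factor = 1,
                          seed = 8)
  ds <- generate_crop_dataset(cfg, n_per_class = 50)
  gm <- vapply(ds$crops, function(cr) mean(cr$snsci[cr$sbci]), numeric(1))
  expect_gt(mean(gm[ds$labels == "normal"]) - mean(gm[ds$labels == "HCC"]), 50)
})

test_that("feature tables are separable exactly when separation is large", {
  # separation 10: nearest-centroid classification is perfect
  tab <- generate_feature_table(100, separation = 10, seed = 1)
  mu_n <- colMeans(tab$x[tab$labels == "normal", ])
  mu_h <- colMeans(tab$x[tab$labels == "HCC", ])
  d_n <- rowSums(sweep(tab$x, 2, mu_n)^2)
  d_h <- rowSums(sweep(tab$x, 2, mu_h)^2)
  pred <- ifelse(d_h < d_n, "HCC", "normal")
  expect_equal(mean(pred == tab$labels), 1.0)

  # separation 0: held-out nearest-centroid accuracy is at chance level
  tr <- generate_feature_table(100, separation = 0, seed = 2)
  te <- generate_feature_table(100, separation = 0, seed = 3)
  mu_n <- colMeans(tr$x[tr$labels == "normal", ])
  mu_h <- colMeans(tr$x[tr$labels == "HCC", ])
  d_n <- rowSums(sweep(te$x, 2, mu_n)^2)
  d_h <- rowSums(sweep(te$x, 2, mu_h)^2)
  acc0 <- mean(ifelse(d_h < d_n, "HCC", "normal") == te$labels)
  expect_lt(abs(acc0 - 0.5), 0.15)
})

test_that("generated classes differ in the directions the features assume", {
  ds <- generate_crop_dataset(synthetic_config(seed = 21), n_per_class = 100)
  hcc <- ds$labels == "HCC"
  gm <- vapply(ds$crops, function(cr) gray_mean_std(cr$snsci)[["gray_mean"]], numeric(1))
  gs <- vapply(ds$crops, function(cr) gray_mean_std(cr$snsci)[["gray_sd"]], numeric(1))
  circ <- vapply(ds$crops, function(cr)
    region_circularity(connected_regions(cr$sbci)[[1]]), numeric(1))
  expect_lt(wilcox.test(gm[hcc], gm[!hcc], alternative = "less")$p.value, 0.01)
  expect_lt(wilcox.test(gs[hcc], gs[!hcc], alternative = "greater")$p.value, 0.01)
  expect_lt(wilcox.test(circ[hcc], circ[!hcc], alternative = "less")$p.value, 0.01)
})
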