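test_that("auxiliary circularity follows its closed form", {
  # large circular region: A = pi r^2, L = 2 pi r, correction -> 0.625
  r <- 1e6
  expect_equal(auxiliary_circularity(pi * r^2, 2 * pi * r), 1 / 0.625,
               tolerance = 1e-6)
  # at A = 6.8 / 0.375 the correction factor is exactly 1
  a0 <- 6.8 / 0.375
  expect_equal(auxiliary_circularity(a0, 40), 4 * pi * a0 / 40^2,
               tolerance = 1e-12)
  # measured disk values agree with a direct evaluation of the formula
  reg <- connected_regions(make_disk(51, 20))[[1]]
  expect_equal(auxiliary_circularity(reg$area, reg$perimeter),
               4 * pi * reg$area / ((6.8 / reg$area + 0.625) * reg$perimeter^2))
  # alternative reading multiplies instead of divides
  expect_equal(auxiliary_circularity(100, 40, form = "multiply"),
               (6.8 / 100 + 0.625) * 4 * pi * 100 / 40^2)
  expect_error(auxiliary_circularity(0, 10), "area")
})

test_that("amendment circularity matches its closed forms", {
  expect_equal(amendment_circularity(100, 10, 10), 2 / pi)
  # continuum disk of radius r in its 2r x 2r box -> 0.5
  r <- 37.3
  expect_equal(amendment_circularity(pi * r^2, 2 * r, 2 * r), 0.5)
  # digital disk: within 0.03 of 0.5
  px <- which(make_disk(51, 20), arr.ind = TRUE)
  a <- nrow(px)
  w <- diff(range(px[, 2])) + 1; h <- diff(range(px[, 1])) + 1
  expect_lt(abs(amendment_circularity(a, w, h) - 0.5), 0.03)
  expect_error(amendment_circularity(10, 0, 5), "width")
})

test_that("quadrant split follows the documented center convention", {
  m <- matrix(0, 51, 51)
  qs <- quadrant_split(m)
  expect_identical(dim(qs$a), c(26L, 26L))
  expect_identical(dim(qs$b), c(26L, 25L))
  expect_identical(dim(qs$c), c(25L, 26L))
  expect_identical(dim(qs$d), c(25L, 25L))

  edge <- canny_edges(make_disk(51, 15))
  qs2 <- quadrant_split(edge)
  # a circle's left and right halves mirror each other up to the center column
  expect_equal(sum(qs2$a), sum(qs2$b[, ncol(qs2$b):1]), tolerance = 2)

  qs0 <- quadrant_split(matrix(FALSE, 10, 10))
  expect_true(all(!unlist(qs0)))
})

test_that("cell symmetry sums adjacent quadrant differences", {
  expect_equal(cell_symmetry(c(1.2, 1.2, 1.2, 1.2)), 0)
  expect_equal(cell_symmetry(c(1.0, 1.1, 1.2, 1.3)), 0.6)
  # invariant under horizontal mirror (a<->b, c<->d) and vertical (a<->c, b<->d)
  set.seed(1)
  for (i in 1:20) {
    fd <- runif(4, 0, 2)
    expect_equal(cell_symmetry(fd), cell_symmetry(fd[c(2, 1, 4, 3)]))
    expect_equal(cell_symmetry(fd), cell_symmetry(fd[c(3, 4, 1, 2)]))
  }
  expect_error(cell_symmetry(c(1, 2, 3)), "four")
})

test_that("shape features match closed forms on squares, bars and disks", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  s <- shape_features(sq)
  expect_equal(s[["shape_area"]], 100)
  expect_equal(s[["shape_rectangularity"]], 1.0)

  rect <- matrix(FALSE, 30, 40); rect[10:14, 10:29] <- TRUE  # 5 x 20
  expect_equal(shape_features(rect)[["shape_elongation"]], 4.0, tolerance = 0.1)

  d <- shape_features(make_disk(51, 20))
  expect_gte(d[["shape_roundness"]], 0.85)
  expect_lte(d[["shape_elongation"]], 1.1)

  expect_error(shape_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("box-counting dimension matches analytic cases and brute counts", {
  sq <- matrix(TRUE, 512, 512)
  dsq <- box_counting_dimension(sq)
  expect_gte(dsq, 1.95); expect_lte(dsq, 2.0)

  ln <- matrix(FALSE, 512, 512); ln[200, ] <- TRUE
  dln <- box_counting_dimension(ln)
  expect_gte(dln, 0.95); expect_lte(dln, 1.05)

  px1 <- matrix(FALSE, 512, 512); px1[30, 40] <- TRUE
  expect_equal(box_counting_dimension(px1), 0, tolerance = 0.05)

  expect_error(box_counting_dimension(matrix(FALSE, 64, 64)), "empty")

  # the internal grid counts agree with a brute-force scan
  set.seed(2)
  blob <- random_blob()
  for (eps in c(12, 5, 2)) {
    fg <- which(blob, arr.ind = TRUE)
    expect_equal(length(vrrf:::box_measure(fg, eps)), brute_box_count(blob, eps))
  }
})

test_that("multifractal dimensions behave like a uniform measure on plain sets", {
  sq <- matrix(TRUE, 512, 512)
  mfd <- multifractal_dimensions(sq)
  expect_true(all(abs(mfd[1:5] - 2) < 0.1))
  expect_lt(mfd[["mfd_dalpha"]], 0.05)

  px1 <- matrix(FALSE, 256, 256); px1[100, 100] <- TRUE
  expect_true(all(abs(multifractal_dimensions(px1)) < 0.05))

  set.seed(3)
  for (i in 1:10) {
    blob <- random_blob()
    expect_lt(abs(multifractal_dimensions(blob)[["mfd_q0"]] -
                  box_counting_dimension(blob)), 0.05)
  }
})

test_that("gray statistics and entropy match hand values", {
  expect_equal(unname(gray_mean_std(matrix(100, 7, 7))), c(100, 0))
  two <- matrix(c(0, 200), 10, 10)
  expect_equal(unname(gray_mean_std(two)), c(100, 100))

  expect_equal(gray_entropy(matrix(42, 9, 9)), 0)
  expect_equal(gray_entropy(matrix(c(10, 20), 8, 8)), 1.0)
  expect_equal(gray_entropy(matrix(rep(0:255, 4), 32, 32)), 8.0)
})

test_that("LBP histogram equals the brute-force recomputation", {
  expect_error(lbp_histogram(matrix(1, 2, 5)), "3x3")
  h0 <- lbp_histogram(matrix(55, 10, 10))
  expect_equal(unname(h0[1]), 1)       # all mass on code 0
  set.seed(4)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    h <- lbp_histogram(img)
    expect_equal(sum(h), 1)
    expect_equal(unname(h), brute_lbp_histogram(img))
  }
  # additive gray shift leaves the codes unchanged
  img <- matrix(runif(400, 0, 200), 20, 20)
  expect_equal(lbp_histogram(img), lbp_histogram(img + 10))
})

test_that("GLCM features match constant-image and checkerboard oracles", {
  const <- matrix(80, 15, 15)
  for (d in c(1L, 2L)) for (o in list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
    q <- floor(const / 16)
    p <- vrrf:::glcm_matrix(q, o[1] * d, o[2] * d)
    st <- vrrf:::glcm_stats(p)
    expect_equal(sum(p), 1)
    expect_equal(st[["asm"]], 1)
    expect_equal(st[["ent"]], 0)
    expect_equal(st[["con"]], 0)
  }

  # checkerboard: horizontal/vertical neighbors at d = 1 differ by 15 bins
  ch <- outer(1:16, 1:16, function(i, j) ifelse((i + j) %% 2 == 0, 0, 255))
  q <- floor(ch / 16)
  st_h <- vrrf:::glcm_stats(vrrf:::glcm_matrix(q, 0, 1))
  expect_equal(st_h[["con"]], brute_glcm_contrast(ch, 0, 1))
  expect_equal(st_h[["con"]], 15^2)
  # diagonal neighbors are equal
  st_d <- vrrf:::glcm_stats(vrrf:::glcm_matrix(q, -1, 1))
  expect_equal(st_d[["con"]], 0)

  v <- glcm_features(ch)
  expect_length(v, 16)
  expect_equal(v[["glcm_con_d1_mean"]], (15^2 + 0 + 15^2 + 0) / 4)

  set.seed(5)
  img <- matrix(runif(900, 0, 255), 30, 30)
  expect_equal(glcm_features(img)[["glcm_con_d2_mean"]],
               mean(c(brute_glcm_contrast(img, 0, 2),
                      brute_glcm_contrast(img, -2, 2),
                      brute_glcm_contrast(img, -2, 0),
                      brute_glcm_contrast(img, -2, -2))))
})

test_that("Tamura features order textures as perception suggests", {
  expect_equal(tamura_features(matrix(50, 32, 32))[["tamura_contrast"]], 0)

  stripes <- function(period, n = 64)
    matrix(ifelse((seq_len(n) - 1) %/% (period / 2) %% 2 == 0, 0, 255),
           n, n, byrow = TRUE)
  t2 <- tamura_features(stripes(2))
  t16 <- tamura_features(stripes(16))
  expect_gt(t16[["tamura_coarseness"]], t2[["tamura_coarseness"]])

  set.seed(6)
  noise <- matrix(runif(64^2, 0, 255), 64, 64)
  tn <- tamura_features(noise)
  tv <- tamura_features(stripes(8))
  expect_gt(tv[["tamura_directionality"]], tn[["tamura_directionality"]])
  expect_equal(tv[["tamura_roughness"]],
               tv[["tamura_coarseness"]] + tv[["tamura_contrast"]])
  expect_error(tamura_features(matrix(1, 4, 4)), "small")
})

test_that("feature vectors have the documented layout and invariances", {
  ds <- generate_crop_dataset(synthetic_config(seed = 13), n_per_class = 2)
  v <- extract_feature_vector(ds$crops[[1]])
  expect_length(v, 296)
  expect_identical(names(v)[1:3], c("cf", "cw", "sym"))
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_feature_vector(ds$crops[[1]]))

  # constant intensity shift: LBP block unchanged, gray mean shifted
  cr <- ds$crops[[1]]
  cr2 <- cr; cr2$snsci <- cr$snsci + 10
  v2 <- extract_feature_vector(cr2)
  lbp_cols <- grep("^lbp_", names(v))
  expect_equal(v[lbp_cols], v2[lbp_cols])
  expect_equal(v2[["gray_mean"]], v[["gray_mean"]] + 10)

  # entropy and gray moments are pixel-permutation invariant; LBP is not
  set.seed(7)
  img <- matrix(sample(0:255, 51 * 51, replace = TRUE), 51, 51)
  perm <- matrix(sample(img), 51, 51)
  expect_equal(gray_entropy(img), gray_entropy(perm))
  expect_equal(gray_mean_std(img), gray_mean_std(perm))
  expect_false(isTRUE(all.equal(lbp_histogram(img), lbp_histogram(perm))))

  # SMERCI gray block doubles the gray features when enabled
  v3 <- extract_feature_vector(cr, feature_config(include_smerci = TRUE))
  expect_length(v3, 296 + 280)
  expect_true(any(grepl("^smerci_", names(v3))))

  df <- extract_features(ds$crops, labels = ds$labels)
  expect_identical(dim(df), c(4L, 298L))
  expect_identical(colnames(df)[1:2], c("id", "label"))
})
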