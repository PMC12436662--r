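# Bouton ROI extraction, actin enrichment, ring autocorrelation, cluster
# density and the shared two-group statistics.

test_that("ROI count matches the planted puncta", {
  sc <- make_bouton_scene(15, 0.5, seed = 3, noise_sd = 0.01)
  r <- bouton_rois(sc$image[, , "marker"])
  expect_equal(nrow(r$rois), 15)
  expect_true(all(r$rois$circularity > 0 & r$rois$circularity <= 1))
})

test_that("rescue mode with an empty GFP channel yields no ROIs", {
  sc <- make_bouton_scene(10, 1, seed = 4)
  r <- bouton_rois(sc$image[, , "marker"],
                   gfp_channel = matrix(0, 256, 256))
  expect_equal(nrow(r$rois), 0)
})

test_that("low-circularity fused puncta are re-split", {
  m <- matrix(0, 96, 96)
  m[(row(m) - 48)^2 + (col(m) - 40)^2 <= 9^2] <- 1
  m[(row(m) - 48)^2 + (col(m) - 55)^2 <= 9^2] <- 1
  base <- bouton_rois(m, smooth_sigma = 0)
  expect_equal(nrow(base$rois), 1)
  split <- bouton_rois(m, smooth_sigma = 0, split_by_circularity = TRUE,
                       circularity_threshold = base$rois$circularity + 0.01)
  expect_equal(nrow(split$rois), 2)
})

test_that("actin enrichment is normalized and scale invariant", {
  sc <- make_bouton_scene(10, 1, seed = 5, noise_sd = 0.01)
  r <- bouton_rois(sc$image[, , "marker"])
  act <- sc$image[, , "actin"]
  ae <- actin_enrichment(r, act)
  expect_true(all(ae$per_roi$max_actin_norm > 0 &
                  ae$per_roi$max_actin_norm <= 1))
  # the global actin max sits inside an enriched punctum here
  expect_equal(max(ae$per_roi$max_actin_norm), 1)
  ae2 <- actin_enrichment(r, act * 37)
  expect_equal(ae$per_roi$max_actin_norm, ae2$per_roi$max_actin_norm,
               tolerance = 1e-12)
  # single-ROI image: the median is that ROI's value
  one <- bouton_rois(make_bouton_scene(1, 1, seed = 6)$image[, , "marker"])
  ae3 <- actin_enrichment(one, make_bouton_scene(1, 1, seed = 6)$image[, , "actin"])
  expect_equal(ae3$image_median, ae3$per_roi$max_actin_norm)
})

test_that("planted enrichment separates enriched from background ROIs", {
  seps <- vapply(1:30, function(s) {
    sc <- make_bouton_scene(12, 0.5, seed = s, noise_sd = 0.02)
    r <- bouton_rois(sc$image[, , "marker"])
    ae <- actin_enrichment(r, sc$image[, , "actin"])
    ctrs <- sc$truth$punctum_centers
    lab <- r$labels[cbind(round(ctrs[, 1]), round(ctrs[, 2]))]
    vals <- ae$per_roi$max_actin_norm[match(lab, ae$per_roi$roi_id)]
    median(vals[sc$truth$enriched], na.rm = TRUE) >
      median(vals[!sc$truth$enriched], na.rm = TRUE)
  }, logical(1))
  expect_true(all(seps))
})

test_that("ring autocorrelation finds the planted period", {
  rp <- make_ring_profile(0.19, 0.02, 10, noise_sd = 0, seed = 1)
  ac <- ring_autocorrelation(rp$profile, 0.02)
  expect_equal(ac$acf[1], 1)
  expect_gte(ac$period_um, 0.18)
  expect_lte(ac$period_um, 0.20)
  expect_true(ac$significant)
  expect_error(ring_autocorrelation(rep(2, 100), 0.02), "constant")
  # featureless profile: no significant period
  set.seed(9)
  ac0 <- ring_autocorrelation(rnorm(500), 0.02)
  expect_false(ac0$significant)
})

test_that("cluster density equals the pixel-scan oracle and its algebra", {
  for (s in 1:5) {
    sc <- make_cluster_scene(3, 2, 1, seed = s)
    dr <- cluster_density(sc$image, sc$truth$axon_mask)
    expect_equal(dr$n_objects,
                 pixel_scan_density_oracle(sc$image, sc$truth$axon_mask,
                                           4000, 10))
    expect_equal(dr$n_objects, sc$truth$n_pass)
  }
  sc <- make_cluster_scene(3, 0, 0, seed = 7)
  # threshold above the image maximum: nothing passes
  hi <- cluster_density(sc$image, sc$truth$axon_mask,
                        theta_intensity = max(sc$image) + 1)
  expect_equal(hi$n_objects, 0)
  # enlarging the axon area with the same objects rescales the density
  narrow <- sc$truth$axon_mask
  wide <- matrix(TRUE, nrow(sc$image), ncol(sc$image))
  d1 <- cluster_density(sc$image, narrow)
  d2 <- cluster_density(sc$image, wide)
  expect_equal(d2$n_objects, d1$n_objects)
  expect_equal(d2$density, d1$density * sum(narrow) / sum(wide))
  expect_error(cluster_density(sc$image, matrix(FALSE, 10, 10)), "empty")
})

test_that("identical samples compare as indistinguishable", {
  set.seed(2)
  x <- rexp(20)                      # skewed: routed to Mann-Whitney
  cg <- compare_groups(x, x, outlier_method = "none")
  expect_equal(cg$test, "mann-whitney")
  expect_equal(cg$p_value, 1)
})

test_that("normality gate routes to the right test", {
  set.seed(3)
  norm_ab <- compare_groups(rnorm(40), rnorm(40), outlier_method = "none")
  expect_equal(norm_ab$test, "welch-t")
  skew <- compare_groups(rexp(40), rexp(40), outlier_method = "none")
  expect_equal(skew$test, "mann-whitney")
})

test_that("grubbs removal strips a planted outlier before testing", {
  set.seed(4)
  a <- c(rnorm(30), 50)
  b <- rnorm(30)
  cg <- compare_groups(a, b, outlier_method = "grubbs")
  expect_equal(cg$removed$a, 50)
  expect_equal(cg$n[["a"]], 30)
})

test_that("a unit mean shift is essentially always detected at n = 50", {
  set.seed(6)
  rej <- vapply(1:1000, function(i)
    compare_groups(rnorm(50), rnorm(50, 1),
                   outlier_method = "none")$p_value < 0.05, logical(1))
  expect_gt(mean(rej), 0.99)
})
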