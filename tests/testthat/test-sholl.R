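# Sholl intersection profiling and the between-condition comparison.

test_that("a single radial ray yields count 1 inside its reach, 0 beyond", {
  sc <- make_aster_scene(1, 1, 40, seed = 2)
  g <- reconstruct_network(sc$image[, , "actin"], 0.1)
  ctr <- sc$truth$condensate_centers[1, ]
  pr <- sholl_profile(g, ctr, step_um = 0.5, r_max_um = 6)
  reach_um <- 40 * 0.1
  inside <- pr$radii_um > 0.7 & pr$radii_um < reach_um - 0.5
  expect_true(all(pr$counts[inside] == 1))
  expect_true(all(pr$counts[pr$radii_um > reach_um] == 0))
})

test_that("six planted rays give count 6 between rim and reach", {
  sc <- make_aster_scene(1, 6, 40, seed = 7)
  g <- reconstruct_network(sc$image[, , "actin"], 0.1)
  ctr <- sc$truth$condensate_centers[1, ]
  pr <- sholl_profile(g, ctr, step_um = 0.5, r_max_um = 6)
  band <- pr$radii_um >= 1 & pr$radii_um <= 3.5
  expect_true(all(pr$counts[band] == 6))
  # the geometric oracle agrees on the planted layout
  for (r_um in pr$radii_um[band]) {
    expect_equal(ray_circle_crossings(sc$truth$filament_segments, ctr,
                                      r_um / 0.1), 6)
  }
})

test_that("a circular edge between shells crosses nothing", {
  m <- matrix(FALSE, 96, 96)
  ctr <- c(48, 48)
  rho_px <- 22                      # 2.2 um at 0.1 um pixels: between shells
  theta <- seq(0, 2 * pi, length.out = 600)
  ys <- round(ctr[1] + rho_px * sin(theta))
  xs <- round(ctr[2] + rho_px * cos(theta))
  m[cbind(ys, xs)] <- TRUE
  g <- skeletonize_and_trace(m, pixel_size_um = 0.1)
  pr <- sholl_profile(g, ctr, step_um = 0.5, r_max_um = 4)
  expect_true(all(pr$counts == 0))
})

test_that("profile counts equal the brute-force crossing oracle", {
  set.seed(31)
  for (i in 1:5) {
    sc <- make_aster_scene(1, sample(3:8, 1), sample(25:40, 1),
                           seed = 100 + i)
    g <- reconstruct_network(sc$image[, , "actin"], 0.1)
    ctr <- sc$truth$condensate_centers[1, ]
    pr <- sholl_profile(g, ctr, step_um = 0.5, r_max_um = 6)
    expect_identical(pr$counts,
                     brute_sholl_oracle(g, ctr, pr$radii_um))
  }
})

test_that("profiles are invariant under joint translation", {
  sc <- make_aster_scene(1, 5, 30, seed = 41)
  mask <- rasterize_segments(sc$truth$filament_segments, c(128, 128))
  ctr <- sc$truth$condensate_centers[1, ]
  g1 <- skeletonize_and_trace(mask, 0.1)
  p1 <- sholl_profile(g1, ctr, r_max_um = 5)
  # shift everything by (6, -9)
  big <- matrix(FALSE, 128, 128)
  src <- which(mask, arr.ind = TRUE)
  shifted <- src + matrix(rep(c(6, -9), each = nrow(src)), ncol = 2)
  big[shifted] <- TRUE
  g2 <- skeletonize_and_trace(big, 0.1)
  p2 <- sholl_profile(g2, ctr + c(6, -9), r_max_um = 5)
  expect_identical(p1$counts, p2$counts)
})

test_that("adding a filament never decreases any shell count", {
  sc <- make_aster_scene(1, 4, 30, seed = 51)
  segs <- sc$truth$filament_segments
  ctr <- sc$truth$condensate_centers[1, ]
  mask1 <- rasterize_segments(segs, c(128, 128))
  extra <- matrix(c(ctr, ctr + c(28, 12)), 2, 2, byrow = TRUE)
  mask2 <- rasterize_segments(c(segs, list(extra)), c(128, 128))
  p1 <- sholl_profile(skeletonize_and_trace(mask1, 0.1), ctr, r_max_um = 5)
  p2 <- sholl_profile(skeletonize_and_trace(mask2, 0.1), ctr, r_max_um = 5)
  expect_true(all(p2$counts >= p1$counts))
})

test_that("center outside the image is rejected", {
  sc <- make_aster_scene(1, 3, 25, seed = 61)
  g <- reconstruct_network(sc$image[, , "actin"], 0.1)
  expect_error(sholl_profile(g, c(-4, 10)), "outside")
})

# --- between-condition comparison ---------------------------------------

mk_count_profile <- function(mult, id, cond, seed) {
  set.seed(seed)
  radii <- seq(0.5, 5, 0.5)
  mu <- mult * pmax(6 - radii, 0.2)
  structure(list(radii_um = radii, counts = rpois(length(radii), mu),
                 center = c(1, 1), step_um = 0.5, condensate_id = id,
                 condition = cond), class = "sholl_profile")
}

test_that("identically generated conditions are rarely called different", {
  ps <- vapply(1:100, function(rep) {
    pr <- c(lapply(1:5, function(i) mk_count_profile(1, i, "A",
                                                     rep * 1000 + i)),
            lapply(1:5, function(i) mk_count_profile(1, i, "B",
                                                     rep * 1000 + 500 + i)))
    suppressWarnings(compare_sholl_lmm(pr))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("a doubled filament load is detected with 10 profiles per arm", {
  profs <- c(lapply(1:10, function(i) mk_count_profile(1, i, "A", i)),
             lapply(1:10, function(i) mk_count_profile(2, i, "B", 100 + i)))
  r <- suppressWarnings(compare_sholl_lmm(profs))
  expect_lt(r$p_value, 0.05)
})

test_that("a profile duplicated into both conditions shows no effect", {
  p1 <- mk_count_profile(1, 1, "A", 1)
  p2 <- p1; p2$condition <- "B"
  r <- suppressWarnings(compare_sholl_lmm(list(p1, p2)))
  expect_equal(r$estimate, 0, tolerance = 1e-8)
  expect_gte(r$p_value, 0.99)
})

test_that("permutation fallback is available explicitly", {
  profs <- c(lapply(1:4, function(i) mk_count_profile(1, i, "A", i)),
             lapply(1:4, function(i) mk_count_profile(3, i, "B", 50 + i)))
  r <- suppressWarnings(compare_sholl_lmm(profs, method = "permutation",
                                          n_perm = 499))
  expect_equal(r$method, "permutation")
  expect_lt(r$p_value, 0.05)
})
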