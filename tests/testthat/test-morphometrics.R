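# Node extraction, property correlations, clustering and PCA.

test_that("watershed splits touching disks and conserves pixels", {
  m <- matrix(FALSE, 96, 96)
  m[(row(m) - 40)^2 + (col(m) - 40)^2 <= 15^2] <- TRUE
  m[(row(m) - 40)^2 + (col(m) - 62)^2 <= 15^2] <- TRUE  # 1.47 radii apart
  nt <- extract_nodes(m, matrix(1, 96, 96), min_size_px = 50)
  expect_equal(nrow(nt), 2)
  expect_equal(sum(nt$area_px), sum(m))
})

test_that("pixel conservation holds on random blob fields", {
  for (sd in 1:5) {
    set.seed(sd)
    m <- matrix(FALSE, 128, 128)
    for (i in 1:8) {
      cy <- runif(1, 15, 113); cx <- runif(1, 15, 113)
      r <- runif(1, 4, 12)
      m <- m | ((row(m) - cy)^2 + (col(m) - cx)^2 <= r^2)
    }
    nt <- extract_nodes(m, matrix(1, 128, 128), min_size_px = 1)
    expect_equal(sum(nt$area_px), sum(m))
  }
})

test_that("small components are removed and empty masks allowed", {
  m <- matrix(FALSE, 64, 64)
  m[(row(m) - 32)^2 + (col(m) - 32)^2 <= 5^2] <- TRUE   # ~80 px
  nt <- extract_nodes(m, matrix(1, 64, 64), min_size_px = 100)
  expect_equal(nrow(nt), 0)
  nt0 <- extract_nodes(matrix(FALSE, 32, 32), matrix(0, 32, 32))
  expect_equal(nrow(nt0), 0)
})

test_that("extraction is deterministic and geometry matches a circle", {
  m <- matrix(FALSE, 96, 96)
  m[(row(m) - 48)^2 + (col(m) - 48)^2 <= 20^2] <- TRUE
  set.seed(8)
  inten <- matrix(runif(96 * 96) + 1, 96, 96)
  nt1 <- extract_nodes(m, inten, min_size_px = 50, pixel_size_um = 0.2)
  nt2 <- extract_nodes(m, inten, min_size_px = 50, pixel_size_um = 0.2)
  expect_identical(nt1, nt2)
  expect_equal(nt1$diameter, 40 * 0.2, tolerance = 0.05)
  expect_equal(nt1$axis_main, nt1$axis_second, tolerance = 0.05)
  expect_gte(nt1$axis_main, nt1$axis_second)
  expect_lte(nt1$int_min, nt1$int_mean)
  expect_lte(nt1$int_mean, nt1$int_max)
  expect_equal(nt1$volume, sum(m) * 0.2^2)
})

test_that("volume and surface correlate strongly across disk sizes", {
  m <- matrix(FALSE, 256, 256)
  centers <- cbind(rep(c(40, 100, 160, 220), each = 4),
                   rep(c(40, 100, 160, 220), times = 4))
  radii <- seq(5, 18, length.out = 16)
  for (i in 1:16)
    m <- m | ((row(m) - centers[i, 1])^2 +
              (col(m) - centers[i, 2])^2 <= radii[i]^2)
  set.seed(2)
  nt <- extract_nodes(m, matrix(runif(256^2) + 1, 256, 256),
                      min_size_px = 20)
  expect_equal(nrow(nt), 16)
  cm <- property_correlation(nt)
  expect_equal(dim(cm), c(10, 10))
  expect_gt(cm["volume", "surface"], 0.95)
  expect_equal(unname(diag(cm)[c("volume", "surface", "diameter")]),
               rep(1, 3))
  expect_true(isSymmetric(cm))
  # third axis is constant zero in 2D: correlations undefined, not 0
  expect_true(all(is.na(cm["axis_third", setdiff(colnames(cm),
                                                 "axis_third")])))
})

test_that("independent property columns show near-zero correlation", {
  set.seed(12)
  n <- 1000
  rcol <- function() rnorm(n) + 10
  tab <- data.frame(node_id = 1:n, dataset_id = 1L,
                    volume = rcol(), surface = rcol(),
                    diameter = rcol(), axis_main = rcol(),
                    axis_second = rcol(), axis_third = rcol(),
                    int_mean = rcol(), int_max = rcol(),
                    int_min = rcol(), median_dist = rcol())
  class(tab) <- c("node_table", "data.frame")
  cm <- property_correlation(tab)
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 0.1)
})

test_that("three planted property clusters are recovered exactly", {
  tab <- make_planted_cluster_table(n_per = 30, seed = 3)
  cl <- suppressMessages(cluster_nodes(tab, seed = 5))
  expect_equal(cl$chosen_k, 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, attr(tab, "planted")),
               1.0)
  # determinism under the recorded seed
  cl2 <- suppressMessages(cluster_nodes(tab, seed = 5))
  expect_identical(cl$labels, cl2$labels)
})

test_that("degenerate tables report no clustering structure", {
  tab <- make_planted_cluster_table(n_per = 10, seed = 1)
  tab[] <- lapply(tab, function(col) if (is.numeric(col)) col * 0 + 1 else col)
  tab$node_id <- seq_len(nrow(tab)); tab$dataset_id <- 1L
  expect_warning(cl <- suppressMessages(cluster_nodes(tab, k_range = 2:4)),
                 "no clustering")
  expect_true(is.na(cl$chosen_k))
})

test_that("PCA behaves on rank-1 and isotropic inputs", {
  # points on a line in log-property space
  set.seed(21)
  t <- runif(60, 1, 3)
  tab <- data.frame(node_id = 1:60, dataset_id = 1L,
                    volume = 10^t, surface = 10^(2 * t),
                    diameter = 10^(0.5 * t), axis_main = 10^t,
                    axis_second = 10^(1.5 * t), axis_third = 0,
                    int_mean = 10^t, int_max = 10^(1.2 * t),
                    int_min = 10^(0.8 * t), median_dist = 10^t)
  class(tab) <- c("node_table", "data.frame")
  pc <- suppressMessages(pca_nodes(tab))
  expect_gt(pc$explained_variance[1], 0.999)
  # scores are uncorrelated
  cv <- cov(pc$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # isotropic cloud: variance spread nearly uniform
  n <- 2000
  iso <- as.data.frame(matrix(exp(rnorm(n * 10, sd = 0.3)), n, 10))
  names(iso) <- c("volume", "surface", "diameter", "axis_main",
                  "axis_second", "axis_third", "int_mean", "int_max",
                  "int_min", "median_dist")
  iso$node_id <- 1:n; iso$dataset_id <- 1L
  class(iso) <- c("node_table", "data.frame")
  pc2 <- suppressMessages(pca_nodes(iso))
  expect_lt(max(pc2$explained_variance), 0.15)
  expect_gt(min(pc2$explained_variance), 0.05)
})

test_that("large nodes carry wider intensity ranges and sit closer together", {
  # three large bright blobs in a tight triangle, five small dim ones far out
  img <- matrix(0, 256, 256)
  mask <- matrix(FALSE, 256, 256)
  put <- function(cy, cx, r, amp) {
    d2 <- (row(img) - cy)^2 + (col(img) - cx)^2
    mask <<- mask | (d2 <= r^2)
    img <<- img + amp * exp(-d2 / (2 * (r / 1.5)^2))
  }
  put(110, 110, 16, 10); put(110, 150, 16, 10); put(145, 130, 16, 10)
  small <- cbind(c(30, 30, 226, 226, 128), c(30, 226, 30, 226, 20))
  for (i in 1:5) put(small[i, 1], small[i, 2], 6, 2)
  nt <- extract_nodes(mask, img, min_size_px = 30)
  big <- nt$area_px > 400
  expect_equal(sum(big), 3)
  rng <- nt$int_max - nt$int_min
  expect_gt(min(rng[big]), max(rng[!big]))
  expect_lt(median(nt$median_dist[big]), median(nt$median_dist[!big]))
})
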