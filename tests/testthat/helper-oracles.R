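# Independent oracles used to check the pipelines. Deliberately naive:
# plain loops, no shared code with the implementation under test.

# Brute-force Sholl crossing count: for every edge path and every shell,
# walk consecutive pixel pairs and count straddles (inner pixel strictly
# inside, the other at or beyond the shell).
brute_sholl_oracle <- function(graph, center, radii_um) {
  px <- graph$pixel_size_um
  counts <- integer(length(radii_um))
  for (p in graph$paths) {
    if (nrow(p) < 2) next
    d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2) * px
    for (k in seq_along(radii_um)) {
      r <- radii_um[k]
      for (i in seq_len(nrow(p) - 1)) {
        a <- d[i]; b <- d[i + 1]
        if ((a < r && b >= r) || (b < r && a >= r))
          counts[k] <- counts[k] + 1L
      }
    }
  }
  counts
}

# Geometric ray/circle crossings: how many planted segments cross a circle
# of radius r_px around the center (both endpoints assumed on opposite
# sides or the segment spanning the radius).
ray_circle_crossings <- function(segments, center, r_px) {
  n <- 0L
  for (s in segments) {
    d0 <- sqrt(sum((s[1, ] - center)^2))
    d1 <- sqrt(sum((s[2, ] - center)^2))
    if (min(d0, d1) < r_px && max(d0, d1) >= r_px) n <- n + 1L
  }
  n
}

# Pixel-scan density oracle: threshold, hand-rolled 8-connected flood
# fill, area filter. Independent of label_components/EBImage.
pixel_scan_density_oracle <- function(img, axon_mask, theta_i, theta_a) {
  fg <- (img > theta_i) & axon_mask
  visited <- matrix(FALSE, nrow(fg), ncol(fg))
  ny <- nrow(fg); nx <- ncol(fg)
  n_obj <- 0L
  for (start in which(fg & !visited)) {
    if (visited[start]) next
    stack <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      cy <- ((cur - 1) %% ny) + 1; cx <- ((cur - 1) %/% ny) + 1
      for (dy in -1:1) for (dx in -1:1) {
        yy <- cy + dy; xx <- cx + dx
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
          id <- (xx - 1) * ny + yy
          if (fg[id] && !visited[id]) {
            visited[id] <- TRUE
            stack <- c(stack, id)
          }
        }
      }
    }
    if (size > theta_a) n_obj <- n_obj + 1L
  }
  n_obj
}

# Naive dense 2D convolution with a Gaussian kernel (truncated at 4 sigma),
# zero-padded borders; used to cross-check the difference-of-Gaussians.
naive_gaussian_convolve <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  ax <- (-r):r
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (dy in ax) for (dx in ax) {
      yy <- y + dy; xx <- x + dx
      v <- if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) img[yy, xx] else 0
      acc <- acc + v * k[dy + r + 1, dx + r + 1]
    }
    out[y, x] <- acc
  }
  out
}

# Property table with three planted clusters a decade apart on every
# property (log-normal scatter), for clustering/PCA checks.
make_planted_cluster_table <- function(n_per = 30, seed = 1, sdlog = 0.05) {
  set.seed(seed)
  mk <- function(decade, n) {
    base <- 10^decade
    data.frame(
      node_id = seq_len(n), dataset_id = 1L,
      volume = base * exp(rnorm(n, 0, sdlog)),
      surface = base * exp(rnorm(n, 0, sdlog)),
      diameter = base * exp(rnorm(n, 0, sdlog)),
      axis_main = base * exp(rnorm(n, 0, sdlog)),
      axis_second = 0.8 * base * exp(rnorm(n, 0, sdlog)),
      axis_third = 0,
      int_mean = base * exp(rnorm(n, 0, sdlog)),
      int_max = 1.5 * base * exp(rnorm(n, 0, sdlog)),
      int_min = 0.5 * base * exp(rnorm(n, 0, sdlog)),
      median_dist = base * exp(rnorm(n, 0, sdlog)))
  }
  tab <- rbind(mk(1, n_per), mk(2, n_per), mk(3, n_per))
  tab$node_id <- seq_len(nrow(tab))
  class(tab) <- c("node_table", "data.frame")
  attr(tab, "planted") <- rep(1:3, each = n_per)
  tab
}

# Rasterize truth filament segments into a mask (2 px wide), bypassing the
# intensity rendering; used for graph-level Sholl checks.
rasterize_segments <- function(segments, dim, half_width = 1) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (s in segments) {
    n <- ceiling(2 * sqrt(sum((s[2, ] - s[1, ])^2)))
    t <- seq(0, 1, length.out = max(n, 2))
    ys <- round(s[1, 1] + t * (s[2, 1] - s[1, 1]))
    xs <- round(s[1, 2] + t * (s[2, 2] - s[1, 2]))
    ok <- ys >= 1 & ys <= dim[1] & xs >= 1 & xs <= dim[2]
    m[cbind(ys[ok], xs[ok])] <- TRUE
  }
  m
}
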