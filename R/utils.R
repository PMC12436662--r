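# Internal helpers shared across the pipelines. Images are numeric matrices
# [y, x]; coordinates are 1-based pixel centers.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_matrix <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix [y, x]", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

as_binary <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (0/1 or logical)", call. = FALSE)
  mask > 0
}

# Logical disk: pixel centers within radius r of (cy, cx).
raster_disk <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Additive intensity footprint of a straight segment with Gaussian
# cross-section (amplitude 1 on the segment axis). Only the bounding box
# (+4 sigma margin) is touched.
add_gaussian_segment <- function(img, y0, x0, y1, x1, sigma = 0.8,
                                 amplitude = 1) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- ceiling(4 * sigma)
  ylo <- max(1L, floor(min(y0, y1)) - pad); yhi <- min(ny, ceiling(max(y0, y1)) + pad)
  xlo <- max(1L, floor(min(x0, x1)) - pad); xhi <- min(nx, ceiling(max(x0, x1)) + pad)
  if (ylo > yhi || xlo > xhi) return(img)
  yy <- matrix(ylo:yhi, yhi - ylo + 1L, xhi - xlo + 1L)
  xx <- matrix(xlo:xhi, yhi - ylo + 1L, xhi - xlo + 1L, byrow = TRUE)
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  if (len2 == 0) {
    d2 <- (yy - y0)^2 + (xx - x0)^2
  } else {
    t <- ((yy - y0) * vy + (xx - x0) * vx) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (yy - (y0 + t * vy))^2 + (xx - (x0 + t * vx))^2
  }
  img[ylo:yhi, xlo:xhi] <- img[ylo:yhi, xlo:xhi] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components <- function(mask) {
  mask <- as_binary(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ny <- nrow(lab); nx <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-ny, -nx]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nx]), as.vector(lab[-ny, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0] <- relab[out[out > 0]]
  out
}

# Per-region properties from a label image and matching intensity image.
region_props <- function(labels, intensity = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(data.frame(region_id = integer(0), y = numeric(0), x = numeric(0),
                      area_px2 = numeric(0), mean_intensity = numeric(0),
                      max_intensity = numeric(0), min_intensity = numeric(0)))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  ys <- ((idx - 1L) %% nrow(labels)) + 1L
  xs <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- as.numeric(tabulate(lab, nbins = max(ids))[ids])
  cy <- as.numeric(tapply(ys, lab, mean)[as.character(ids)])
  cx <- as.numeric(tapply(xs, lab, mean)[as.character(ids)])
  if (is.null(intensity)) {
    mi <- ma <- mn <- rep(NA_real_, length(ids))
  } else {
    vals <- intensity[idx]
    mi <- as.numeric(tapply(vals, lab, mean)[as.character(ids)])
    ma <- as.numeric(tapply(vals, lab, max)[as.character(ids)])
    mn <- as.numeric(tapply(vals, lab, min)[as.character(ids)])
  }
  data.frame(region_id = ids, y = cy, x = cx, area_px2 = area,
             mean_intensity = mi, max_intensity = ma, min_intensity = mn)
}

# Strip EBImage attributes so images stay plain numeric matrices.
as_plain_matrix <- function(x) {
  m <- as.matrix(x)
  attributes(m) <- list(dim = dim(m))
  m
}

# Otsu threshold with an informative error on constant input.
otsu_threshold <- function(img) {
  stop_if_not_matrix(img)
  rng <- range(img)
  if (diff(rng) == 0)
    stop("no threshold separable: image is constant", call. = FALSE)
  EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
}

# Maximum Feret diameter (px) of a set of pixel coordinates, via the convex
# hull of the pixel corner cloud so single pixels have diameter ~sqrt(2).
feret_diameter <- function(ys, xs) {
  if (length(ys) == 0) return(NA_real_)
  py <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  px <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  h <- chull(px, py)
  hy <- py[h]; hx <- px[h]
  max(sqrt(outer(hy, hy, "-")^2 + outer(hx, hx, "-")^2))
}

# Translate an image by (dy, dx); positive dy moves content downward.
# Non-integer shifts use bilinear interpolation; uncovered pixels take `fill`.
shift_image <- function(img, dy, dx, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, ny, nx)
    dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- img[ys[oky], xs[okx]]
    return(out)
  }
  yy <- matrix(seq_len(ny), ny, nx) - dy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - dx
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  val <- function(iy, ix) {
    ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
    v <- matrix(0, ny, nx)
    v[ok] <- img[cbind(iy[ok], ix[ok])]
    list(v = v, ok = ok)
  }
  a <- val(y0, x0); b <- val(y0, x0 + 1); cc <- val(y0 + 1, x0); d <- val(y0 + 1, x0 + 1)
  out <- (1 - fy) * (1 - fx) * a$v + (1 - fy) * fx * b$v +
    fy * (1 - fx) * cc$v + fy * fx * d$v
  out[!(a$ok & b$ok & cc$ok & d$ok)] <- fill
  out
}

# Gas constant in kcal mol^-1 K^-1 (and the literal value as printed in
# typical partitioning pipelines, which is in cal mol^-1 K^-1).
R_KCAL <- 1.9872e-3
R_PRINTED <- 1.9872
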