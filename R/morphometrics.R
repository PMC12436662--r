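# Node-level morphometrics of condensate:actin assemblies: watershed
# splitting, 10-property extraction, correlation structure, k-means with
# silhouette, and PCA.

#' Extract nodes and their ten morphometric properties
#'
#' Connected components of the mask are treated as candidate nodes;
#' touching blobs are split by the watershed transform of the distance map
#' with h-maxima suppression (`h_px`), so small unimodal nodes are never
#' split. Components below `min_size_px` pixels are removed. For each
#' surviving node ten properties are computed (2D mode): (1) volume (the
#' node area, um^2), (2) surface area (perimeter length, um), (3) diameter
#' (maximum Feret diameter, um), (4-6) main/second/third axis lengths from
#' the intensity-weighted inertia tensor (third axis is 0 in 2D, kept as a
#' placeholder column), (7-9) mean/max/min intensity, and (10) the median
#' Euclidean centroid distance to all other nodes (um).
#'
#' @param mask binary matrix (or a label matrix; any positive pixel is
#'   foreground).
#' @param intensity intensity image, same shape.
#' @param min_size_px minimum node size, pixels.
#' @param pixel_size_um physical pixel size.
#' @param h_px h-maxima depth for watershed seeding, in distance-map units
#'   (px); larger values split less.
#' @param split apply watershed splitting (`TRUE`) or keep plain connected
#'   components.
#' @param dataset_id label recorded per row, used by
#'   [property_correlation()] for per-dataset intensity rescaling.
#' @return object of class `node_table`: a data.frame with `node_id`,
#'   `dataset_id`, the ten properties (`volume`, `surface`, `diameter`,
#'   `axis_main`, `axis_second`, `axis_third`, `int_mean`, `int_max`,
#'   `int_min`, `median_dist`), centroid `y`/`x` and `area_px`; the label
#'   image is attached as attribute `"labels"`.
#' @export
extract_nodes <- function(mask, intensity, min_size_px = 100,
                          pixel_size_um = 1, h_px = 2, split = TRUE,
                          dataset_id = 1L) {
  mask <- mask > 0
  if (!all(dim(mask) == dim(intensity)))
    stop("mask and intensity shapes differ", call. = FALSE)
  empty <- data.frame(node_id = integer(0), dataset_id = integer(0),
                      volume = numeric(0), surface = numeric(0),
                      diameter = numeric(0), axis_main = numeric(0),
                      axis_second = numeric(0), axis_third = numeric(0),
                      int_mean = numeric(0), int_max = numeric(0),
                      int_min = numeric(0), median_dist = numeric(0),
                      y = numeric(0), x = numeric(0), area_px = numeric(0))
  class(empty) <- c("node_table", "data.frame")
  if (!any(mask)) return(empty)
  if (split) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    labels <- EBImage::watershed(dm, tolerance = h_px, ext = 1)
    labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  } else {
    labels <- label_components(mask)
  }
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_size_px)
  labels[!(labels %in% keep)] <- 0L
  if (!any(labels > 0)) return(empty)
  labels[labels > 0] <- match(labels[labels > 0], sort(keep))
  ids <- sort(unique(labels[labels > 0]))
  px <- pixel_size_um
  shp <- EBImage::computeFeatures.shape(labels)
  props <- region_props(labels, intensity)
  feret <- vapply(ids, function(id) {
    w <- which(labels == id)
    ys <- ((w - 1L) %% nrow(labels)) + 1L
    xs <- ((w - 1L) %/% nrow(labels)) + 1L
    feret_diameter(ys, xs)
  }, numeric(1))
  axes <- t(vapply(ids, function(id) {
    w <- which(labels == id)
    ys <- ((w - 1L) %% nrow(labels)) + 1L
    xs <- ((w - 1L) %/% nrow(labels)) + 1L
    wt <- intensity[w]
    wt <- wt - min(wt) + 1e-12   # weights must be non-negative
    wt <- wt / sum(wt)
    my <- sum(wt * ys); mx <- sum(wt * xs)
    cyy <- sum(wt * (ys - my)^2); cxx <- sum(wt * (xs - mx)^2)
    cyx <- sum(wt * (ys - my) * (xs - mx))
    ev <- eigen(matrix(c(cyy, cyx, cyx, cxx), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    # full axis length of the equivalent uniform ellipse: 4 * sqrt(lambda)
    4 * sqrt(pmax(ev, 0))
  }, numeric(2)))
  cy <- props$y; cx <- props$x
  med_dist <- vapply(seq_along(ids), function(i) {
    if (length(ids) < 2) return(NA_real_)
    d <- sqrt((cy - cy[i])^2 + (cx - cx[i])^2) * px
    median(d[-i])
  }, numeric(1))
  out <- data.frame(
    node_id = ids,
    dataset_id = dataset_id,
    volume = props$area_px2 * px^2,
    surface = shp[, "s.perimeter"] * px,
    diameter = feret * px,
    axis_main = axes[, 1] * px,
    axis_second = axes[, 2] * px,
    axis_third = 0,
    int_mean = props$mean_intensity,
    int_max = props$max_intensity,
    int_min = props$min_intensity,
    median_dist = med_dist,
    y = cy, x = cx, area_px = props$area_px2)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  class(out) <- c("node_table", "data.frame")
  out
}

node_property_names <- c("volume", "surface", "diameter", "axis_main",
                         "axis_second", "axis_third", "int_mean",
                         "int_max", "int_min", "median_dist")

# Property matrix with per-dataset min-max rescaling of intensity columns,
# enabling concatenation of datasets acquired at different gains.
node_property_matrix <- function(table, rescale_intensity = TRUE) {
  m <- as.matrix(table[, node_property_names])
  if (rescale_intensity && length(unique(table$dataset_id)) >= 1) {
    for (col in c("int_mean", "int_max", "int_min")) {
      for (ds in unique(table$dataset_id)) {
        i <- table$dataset_id == ds
        v <- m[i, col]
        rng <- range(v)
        m[i, col] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
      }
    }
  }
  m
}

# log10(x + eps) with eps = 1e-6 of each column's smallest positive value;
# constant columns are dropped (with a message) since they carry no signal.
log_transform_properties <- function(m) {
  for (j in seq_len(ncol(m))) {
    pos <- m[, j][m[, j] > 0]
    eps <- if (length(pos)) 1e-6 * min(pos) else 1e-12
    m[, j] <- log10(m[, j] + eps)
  }
  keep <- apply(m, 2, function(col) diff(range(col)) > 0)
  if (!all(keep))
    message("dropping constant properties: ",
            paste(colnames(m)[!keep], collapse = ", "))
  m[, keep, drop = FALSE]
}

# Shared transform for clustering and PCA: log10 of the raw properties
# (scale differences), then per-dataset min-max of the log-intensity
# columns (gain comparability; applied after the log so values near zero
# are not blown up).
cluster_input_matrix <- function(table) {
  m <- node_property_matrix(table, rescale_intensity = FALSE)
  lt <- log_transform_properties(m)
  for (col in intersect(c("int_mean", "int_max", "int_min"), colnames(lt))) {
    for (ds in unique(table$dataset_id)) {
      i <- table$dataset_id == ds
      v <- lt[i, col]
      rng <- range(v)
      lt[i, col] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
    }
  }
  lt
}

#' Pearson correlation matrix of node properties
#'
#' Intensity columns are min-max rescaled per dataset before concatenation
#' so that datasets acquired at different gains are comparable; the ten
#' properties are then correlated pairwise (Pearson). Zero-variance
#' columns yield `NA` rows/columns rather than silent zeros.
#'
#' @param table a `node_table` (>= 3 nodes).
#' @return 10x10 symmetric correlation matrix with unit diagonal (where
#'   defined).
#' @export
property_correlation <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 nodes", call. = FALSE)
  m <- node_property_matrix(table)
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}

#' k-means clustering of nodes with silhouette model selection
#'
#' Properties are log10-transformed (small positive offset) and
#' standardized; k-means is run for every `k` in `k_range` with `nstart`
#' restarts under a fixed seed, and the mean silhouette width selects the
#' number of clusters.
#'
#' @param table a `node_table` with at least `max(k_range) + 1` nodes.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed (recorded in the output).
#' @param nstart k-means restarts per k.
#' @return list with `labels` (for the chosen k), `chosen_k`, `silhouette`
#'   (data.frame `k`, `mean_silhouette`), `seed`, `centers`. When the data
#'   admit no clustering (all rows identical) `chosen_k` is `NA`.
#' @export
cluster_nodes <- function(table, k_range = 2:8, seed = 1L, nstart = 10) {
  if (nrow(table) < max(k_range) + 1)
    stop("need more nodes than the largest candidate k", call. = FALSE)
  lt <- cluster_input_matrix(table)
  if (ncol(lt) == 0 || nrow(unique(lt)) == 1) {
    warning("no clustering structure: all nodes identical")
    return(list(labels = rep(1L, nrow(table)), chosen_k = NA_integer_,
                silhouette = data.frame(k = integer(0),
                                        mean_silhouette = numeric(0)),
                seed = seed, centers = NULL))
  }
  X <- scale(lt)
  X <- X[, apply(X, 2, function(c) all(is.finite(c))), drop = FALSE]
  d <- dist(X)
  n_distinct <- nrow(unique(X))
  sil <- data.frame(k = integer(0), mean_silhouette = numeric(0))
  fits <- list()
  for (k in k_range) {
    if (n_distinct < k) {
      warning(sprintf("skipping k = %d: only %d distinct points", k,
                      n_distinct))
      next
    }
    fit <- with_local_seed(seed + k, kmeans(X, centers = k, nstart = nstart,
                                            iter.max = 100))
    sw <- cluster::silhouette(fit$cluster, d)
    sil <- rbind(sil, data.frame(k = k, mean_silhouette = mean(sw[, 3])))
    fits[[as.character(k)]] <- fit
  }
  if (!nrow(sil)) stop("no k in k_range could be fitted", call. = FALSE)
  chosen <- sil$k[which.max(sil$mean_silhouette)]
  best <- fits[[as.character(chosen)]]
  list(labels = best$cluster, chosen_k = chosen, silhouette = sil,
       seed = seed, centers = best$centers)
}

#' PCA of node properties
#'
#' Principal component analysis of the log10-transformed, column-
#' standardized property matrix (the same transform as [cluster_nodes()]).
#'
#' @param table a `node_table` (>= 3 nodes).
#' @return list with `scores` (nodes x components), `loadings`,
#'   `explained_variance` (proportions, all components; zero beyond the
#'   matrix rank), `sdev`.
#' @export
pca_nodes <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 nodes", call. = FALSE)
  lt <- cluster_input_matrix(table)
  pc <- prcomp(lt, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = ev / sum(ev), sdev = pc$sdev)
}
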