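# Actin network reconstruction: fibril enhancement, despeckling,
# skeletonization and graph tracing.

#' Difference-of-Gaussians fibril enhancement
#'
#' Band-pass filters the actin channel as `G(sigma_narrow)*img -
#' G(sigma_wide)*img` (narrow minus wide, so thin bright fibrils respond
#' positively), clipped at zero. Defaults (1.0 and 2.0 px) favour 2-4 px
#' wide structures.
#'
#' @param img numeric matrix.
#' @param sigma_narrow,sigma_wide Gaussian sigmas, px
#'   (`sigma_narrow < sigma_wide`).
#' @return enhanced image, same size, non-negative.
#' @export
enhance_fibrils <- function(img, sigma_narrow = 1, sigma_wide = 2) {
  stop_if_not_matrix(img)
  stopifnot(sigma_narrow < sigma_wide)
  narrow <- as_plain_matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_narrow))
  wide <- as_plain_matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_wide))
  pmax(narrow - wide, 0)
}

#' Restore fibril-condensate connections
#'
#' The difference-of-Gaussians step suppresses large condensate bodies and
#' can sever fibrils from the condensates they emerge from. This operation
#' ORs the enhanced binary mask with the Otsu-thresholded original image,
#' restoring those connections.
#'
#' @param enhanced_mask binary matrix from the enhanced image.
#' @param original the unenhanced intensity image (same shape).
#' @return logical mask.
#' @export
restore_connections <- function(enhanced_mask, original) {
  if (!all(dim(enhanced_mask) == dim(original)))
    stop("mask and image shapes differ", call. = FALSE)
  em <- as_binary(enhanced_mask)
  if (diff(range(original)) == 0) return(em)
  thr <- otsu_threshold(original)
  em | (original > thr)
}

#' Iterative median despeckling
#'
#' Median filter with a circular structuring element, applied repeatedly
#' (defaults: two iterations, radius 2 px) to remove salt-and-pepper noise
#' while preserving fibrils wider than the kernel. Binary inputs use an
#' exact majority vote; grayscale inputs use a true neighborhood median.
#'
#' @param x binary or grayscale matrix.
#' @param iterations number of passes (>= 0).
#' @param radius_px structuring-element radius, px.
#' @return filtered matrix (logical in, logical out).
#' @export
despeckle <- function(x, iterations = 2, radius_px = 2) {
  stopifnot(iterations >= 0, radius_px > 0)
  was_logical <- is.logical(x)
  binary <- was_logical || all(x %in% c(0, 1))
  r <- radius_px
  offs <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  m <- if (was_logical) x * 1 else x
  for (it in seq_len(iterations)) {
    stack <- vapply(seq_len(nrow(offs)), function(k) {
      # replicate borders so edges are not eroded
      s <- shift_image(m, offs$dy[k], offs$dx[k], fill = NA_real_)
      s[is.na(s)] <- m[is.na(s)]
      s
    }, m)
    dim(stack) <- c(length(m), nrow(offs))
    if (binary) {
      cnt <- rowSums(stack)
      m <- matrix(as.numeric(cnt > nrow(offs) / 2), nrow(m), ncol(m))
    } else {
      m <- matrix(apply(stack, 1, median), nrow(m), ncol(m))
    }
  }
  if (was_logical) m > 0 else m
}

# Zhang-Suen topological thinning to a 1-px, 8-connected skeleton.
skeletonize_mask <- function(mask) {
  m <- as_binary(mask) * 1L
  shift0 <- function(a, dy, dx) {
    out <- matrix(0L, nrow(a), ncol(a))
    ny <- nrow(a); nx <- ncol(a)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- a[ys[oky], xs[okx]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift0(m, -1, 0);  p3 <- shift0(m, -1, 1)
      p4 <- shift0(m, 0, 1);   p5 <- shift0(m, 1, 1)
      p6 <- shift0(m, 1, 0);   p7 <- shift0(m, 1, -1)
      p8 <- shift0(m, 0, -1);  p9 <- shift0(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

# Build the pixel-adjacency graph of a skeleton, dropping diagonal edges
# that are redundant with an existing 4-connected path (skan-style), so the
# traced paths are single-pixel wide.
skeleton_pixel_graph <- function(skel) {
  idx <- which(skel)
  ny <- nrow(skel)
  vid <- integer(length(skel)); vid[idx] <- seq_along(idx)
  ys <- ((idx - 1L) %% ny) + 1L
  xs <- ((idx - 1L) %/% ny) + 1L
  at <- function(y, x) {
    ok <- y >= 1 & y <= ny & x >= 1 & x <= ncol(skel)
    v <- integer(length(y))
    v[ok] <- vid[(x[ok] - 1L) * ny + y[ok]]
    v
  }
  edges <- list()
  # 4-connected
  for (d in list(c(0, 1), c(1, 0))) {
    nb <- at(ys + d[1], xs + d[2])
    sel <- nb > 0
    edges[[length(edges) + 1L]] <- cbind(seq_along(idx)[sel], nb[sel])
  }
  # diagonals, unless short-circuited by a shared 4-neighbor
  for (d in list(c(1, 1), c(-1, 1))) {
    nb <- at(ys + d[1], xs + d[2])
    c1 <- at(ys + d[1], xs)
    c2 <- at(ys, xs + d[2])
    sel <- nb > 0 & c1 == 0 & c2 == 0
    edges[[length(edges) + 1L]] <- cbind(seq_along(idx)[sel], nb[sel])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  list(g = igraph::simplify(g), ys = ys, xs = xs)
}

#' Skeletonize a binary mask and trace it into a graph
#'
#' Topologically thins the mask to a 1-px skeleton (Zhang-Suen), then
#' extracts a graph whose nodes are endpoints and junctions (adjacent
#' junction pixels are merged into one node) and whose edges are the pixel
#' paths between them. Edges shorter than `min_segment_px` that hang from a
#' free end (and short isolated fragments) are pruned iteratively, with the
#' graph re-simplified after every pass.
#'
#' @param mask binary matrix.
#' @param pixel_size_um physical pixel size, micrometers.
#' @param min_segment_px minimum retained segment length, px.
#' @return object of class `skeleton_graph`: list with `nodes` (data.frame
#'   `node_id`, `y`, `x`, `degree`, `kind`), `edges` (data.frame `edge_id`,
#'   `node_a`, `node_b`, `length_px`, `length_um`), `paths` (list of n x 2
#'   pixel-coordinate matrices, one per edge, 8-connected), `skeleton`
#'   (logical matrix) and `pixel_size_um`. An empty mask gives an empty
#'   graph.
#' @export
skeletonize_and_trace <- function(mask, pixel_size_um = 1,
                                  min_segment_px = 3) {
  mask <- as_binary(mask)
  skel <- if (any(mask)) skeletonize_mask(mask) else mask
  repeat {
    gr <- trace_skeleton(skel, pixel_size_um)
    if (!nrow(gr$edges)) break
    spur <- prunable_edges(gr, min_segment_px)
    if (!length(spur)) break
    # drop the spur edges' non-junction pixels and re-trace
    drop <- matrix(numeric(0), 0, 2)
    for (e in spur) {
      p <- gr$paths[[e]]
      deg_a <- gr$nodes$degree[gr$edges$node_a[e]]
      deg_b <- gr$nodes$degree[gr$edges$node_b[e]]
      keep_first <- deg_a > 1
      keep_last <- deg_b > 1
      rows <- seq_len(nrow(p))
      if (keep_first) rows <- rows[-1]
      if (keep_last && length(rows)) rows <- rows[-length(rows)]
      drop <- rbind(drop, p[rows, , drop = FALSE])
    }
    if (!nrow(drop)) break
    skel[cbind(drop[, 1], drop[, 2])] <- FALSE
    skel <- skeletonize_mask(skel)  # re-thin in case pruning left nubs
  }
  gr
}

# Edges eligible for pruning: every traced segment shorter than the
# cutoff is discarded (spurs, short bridges and tiny loops alike); the
# graph is re-traced afterwards, so affected junctions re-simplify.
prunable_edges <- function(gr, min_segment_px) {
  if (!nrow(gr$edges)) return(integer(0))
  which(gr$edges$length_px < min_segment_px)
}

# Trace a thinned skeleton into nodes, edges and pixel paths.
trace_skeleton <- function(skel, pixel_size_um) {
  empty <- function() {
    structure(list(
      nodes = data.frame(node_id = integer(0), y = numeric(0), x = numeric(0),
                         degree = integer(0), kind = character(0)),
      edges = data.frame(edge_id = integer(0), node_a = integer(0),
                         node_b = integer(0), length_px = numeric(0),
                         length_um = numeric(0)),
      paths = list(), skeleton = skel, pixel_size_um = pixel_size_um),
      class = "skeleton_graph")
  }
  if (!any(skel)) return(empty())
  pg <- skeleton_pixel_graph(skel)
  g <- pg$g; ys <- pg$ys; xs <- pg$xs
  deg <- igraph::degree(g)
  node_v <- which(deg != 2)
  # pure cycles: components with no irregular vertex get one artificial node
  comp <- igraph::components(g)$membership
  for (cm in setdiff(unique(comp), unique(comp[node_v])))
    node_v <- c(node_v, which(comp == cm)[1])
  node_v <- sort(node_v)
  is_node <- logical(length(deg)); is_node[node_v] <- TRUE
  # merge adjacent node vertices into node groups
  sub_nodes <- igraph::induced_subgraph(g, node_v)
  grp_local <- igraph::components(sub_nodes)$membership
  node_group <- integer(length(deg))
  node_group[node_v] <- grp_local
  n_groups <- max(grp_local)
  # chains: components among non-node vertices
  chain_v <- which(!is_node)
  edges_out <- list(); paths_out <- list()
  add_edge <- function(ga, gb, path_v) {
    py <- ys[path_v]; px <- xs[path_v]
    steps <- sqrt(diff(py)^2 + diff(px)^2)
    edges_out[[length(edges_out) + 1L]] <<-
      c(ga, gb, sum(steps))
    paths_out[[length(paths_out) + 1L]] <<-
      cbind(y = py, x = px)
  }
  if (length(chain_v)) {
    sub_chain <- igraph::induced_subgraph(g, chain_v)
    cmem <- igraph::components(sub_chain)$membership
    for (ci in seq_len(max(cmem))) {
      verts <- chain_v[cmem == ci]
      # order the chain by walking from a terminal vertex
      sub <- igraph::induced_subgraph(g, verts)
      dloc <- igraph::degree(sub)
      start_loc <- if (any(dloc <= 1)) which(dloc <= 1)[1] else 1L
      ord_loc <- as.integer(igraph::dfs(sub, root = start_loc)$order)
      ordered <- verts[ord_loc]
      # attached node vertices at each end
      ends <- c(ordered[1], ordered[length(ordered)])
      att <- lapply(ends, function(v) {
        nb <- as.integer(igraph::neighbors(g, v))
        nb[is_node[nb]]
      })
      a_att <- att[[1]]; b_att <- att[[2]]
      if (length(ordered) == 1) {
        # single chain pixel: may touch up to two node vertices
        nb <- a_att
        if (length(nb) >= 2) {
          add_edge(node_group[nb[1]], node_group[nb[2]],
                   c(nb[1], ordered, nb[2]))
        } else if (length(nb) == 1) {
          add_edge(node_group[nb[1]], node_group[nb[1]], c(nb[1], ordered))
        }
        next
      }
      pa <- if (length(a_att)) a_att[1] else NA_integer_
      pb <- if (length(b_att)) b_att[1] else NA_integer_
      path_v <- ordered
      ga <- gb <- NA_integer_
      if (!is.na(pa)) { path_v <- c(pa, path_v); ga <- node_group[pa] }
      if (!is.na(pb)) { path_v <- c(path_v, pb); gb <- node_group[pb] }
      if (is.na(ga) && is.na(gb)) next      # unreachable: isolated chain
      if (is.na(ga)) ga <- gb
      if (is.na(gb)) gb <- ga
      add_edge(ga, gb, path_v)
    }
  }
  # direct adjacencies between vertices of two *different* node groups
  # cannot occur (adjacent node vertices share a group by construction)
  nodes <- data.frame(
    node_id = seq_len(n_groups),
    y = as.numeric(tapply(ys[node_v], grp_local, mean)),
    x = as.numeric(tapply(xs[node_v], grp_local, mean)))
  if (length(edges_out)) {
    em <- do.call(rbind, edges_out)
    edges <- data.frame(edge_id = seq_len(nrow(em)),
                        node_a = as.integer(em[, 1]),
                        node_b = as.integer(em[, 2]),
                        length_px = em[, 3],
                        length_um = em[, 3] * pixel_size_um)
  } else {
    edges <- data.frame(edge_id = integer(0), node_a = integer(0),
                        node_b = integer(0), length_px = numeric(0),
                        length_um = numeric(0))
  }
  degree <- integer(n_groups)
  for (i in seq_len(nrow(edges))) {
    degree[edges$node_a[i]] <- degree[edges$node_a[i]] + 1L
    degree[edges$node_b[i]] <- degree[edges$node_b[i]] + 1L
  }
  nodes$degree <- degree
  nodes$kind <- ifelse(degree <= 1, "endpoint", "junction")
  # drop isolated zero-degree nodes (single-pixel or tiny-blob debris)
  keep <- nodes$degree > 0
  if (!all(keep)) {
    remap <- cumsum(keep)
    nodes <- nodes[keep, , drop = FALSE]
    nodes$node_id <- seq_len(nrow(nodes))
    if (nrow(edges)) {
      edges$node_a <- remap[edges$node_a]
      edges$node_b <- remap[edges$node_b]
    }
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, paths = paths_out,
                 skeleton = skel, pixel_size_um = pixel_size_um),
            class = "skeleton_graph")
}

#' @exportS3Method
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, total length",
      signif(sum(x$edges$length_um), 4), "um\n")
  invisible(x)
}

#' Full actin-network reconstruction from an intensity image
#'
#' Convenience pipeline chaining [enhance_fibrils()], Otsu thresholding,
#' [restore_connections()], [despeckle()] and [skeletonize_and_trace()].
#'
#' @param img actin-channel intensity image.
#' @param pixel_size_um physical pixel size.
#' @param min_segment_px minimum retained segment length.
#' @param despeckle_iterations,despeckle_radius_px median-filter settings.
#' @return a `skeleton_graph`.
#' @export
reconstruct_network <- function(img, pixel_size_um = 1, min_segment_px = 3,
                                despeckle_iterations = 2,
                                despeckle_radius_px = 2) {
  enh <- enhance_fibrils(img)
  if (diff(range(enh)) == 0) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
  } else {
    mask <- enh > otsu_threshold(enh)
  }
  mask <- despeckle(mask, iterations = despeckle_iterations,
                    radius_px = despeckle_radius_px)
  # restore after despeckling so thin fibrils and fibril-condensate
  # connections recovered from the original are not re-eroded
  mask <- restore_connections(mask, img)
  skeletonize_and_trace(mask, pixel_size_um = pixel_size_um,
                        min_segment_px = min_segment_px)
}
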