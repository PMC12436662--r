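# TIFF image I/O, ground-truth JSON sidecars, and the reproducible
# pipeline runner.

#' Read a grayscale TIFF into a normalized image stack
#'
#' Pages are read in file order and arranged according to `axes`
#' (`"YX"`, `"CYX"`, `"TYX"`, or `"TCYX"`); missing axes become
#' singletons, so the result is always a 5D array `[T, C, Z, Y, X]`.
#' Intensity scaling written by [write_image()] is undone using the JSON
#' sidecar when present. RGB TIFFs are rejected: pipelines expect
#' grayscale channels.
#'
#' @param path TIFF file.
#' @param axes axis order of the pages.
#' @param pixel_size_um pixel size recorded on the result (attribute);
#'   a config-supplied value wins over any file metadata.
#' @return numeric 5D array with attributes `axes = "TCZYX"` and
#'   `pixel_size_um`.
#' @export
read_image <- function(path, axes = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("unreadable TIFF ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3)
      stop("RGB TIFF rejected (page ", i,
           "): grayscale channels expected", call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  scale <- 1; offset <- 0; side <- NULL
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(side$scale)) scale <- side$scale
    if (!is.null(side$offset)) offset <- side$offset
    if (is.null(axes) && !is.null(side$axes)) axes <- side$axes
    if (is.null(pixel_size_um) && !is.null(side$pixel_size_um))
      pixel_size_um <- side$pixel_size_um
  }
  if (is.null(axes)) axes <- if (length(pages) == 1) "YX" else "TYX"
  np <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  nt <- nc <- nz <- 1L
  if (axes == "YX") {
    if (np != 1) stop("axes 'YX' but file has ", np, " pages", call. = FALSE)
  } else if (axes == "CYX") {
    nc <- np
  } else if (axes == "TYX") {
    nt <- np
  } else if (axes == "TCYX") {
    if (is.null(side$n_channels))
      stop("axes 'TCYX' needs n_channels in the sidecar", call. = FALSE)
    nc <- as.integer(side$n_channels)
    nt <- np %/% nc
    if (nt * nc != np) stop("page count not divisible by channels",
                            call. = FALSE)
  } else stop("unsupported axes: ", axes, call. = FALSE)
  out <- array(0, dim = c(nt, nc, nz, ny, nx))
  p <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    out[t, ch, 1, , ] <- pages[[p]] * scale + offset
    p <- p + 1L
  }
  attr(out, "axes") <- "TCZYX"
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Write an image stack as multi-page grayscale TIFF
#'
#' Data are linearly mapped into `[0, 1]` for storage (32-bit float
#' pages); the mapping, the axis order and the pixel size are recorded in
#' a JSON sidecar (`<path>.json`) so [read_image()] restores the original
#' values.
#'
#' @param x matrix `[y, x]`, 3D array (`[y, x, c]` or `[y, x, t]`
#'   according to `axes`), or a `synth_scene`.
#' @param path output TIFF path.
#' @param axes `"YX"`, `"CYX"`, `"TYX"` (3D input uses the last axis as C
#'   or T).
#' @param pixel_size_um recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, axes = NULL, pixel_size_um = NULL) {
  if (inherits(x, "synth_scene")) x <- x$image
  if (is.matrix(x)) {
    pages <- list(x)
    if (is.null(axes)) axes <- "YX"
  } else if (length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    if (is.null(axes)) axes <- if (!is.null(dimnames(x)[[3]])) "CYX" else "TYX"
  } else stop("unsupported input dimensionality", call. = FALSE)
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  span <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(p) (p - lo) / span)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = span, offset = lo, axes = axes,
         pixel_size_um = pixel_size_um,
         n_pages = length(pages)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic scene with its ground truth
#'
#' The image goes to `<prefix>.tif` (with sidecar) and the truth to
#' `<prefix>_truth.json`.
#'
#' @param scene a `synth_scene`.
#' @param prefix output path prefix.
#' @param axes page-axis order passed to [write_image()].
#' @return prefix, invisibly.
#' @export
write_scene <- function(scene, prefix, axes = NULL) {
  stopifnot(inherits(scene, "synth_scene"))
  write_image(scene$image, paste0(prefix, ".tif"), axes = axes,
              pixel_size_um = scene$truth$pixel_size_um)
  truth <- scene$truth
  # large matrix-valued truth fields (e.g. masks) get their own TIFF and
  # are referenced by file name instead of being inlined in the JSON
  for (nm in names(truth)) {
    if (is.matrix(truth[[nm]]) && length(truth[[nm]]) > 1024) {
      f <- paste0(prefix, "_", nm, ".tif")
      write_image(truth[[nm]] * 1, f)
      truth[[nm]] <- list(file = basename(f))
    }
  }
  truth$filament_segments <- lapply(truth$filament_segments,
                                    function(m) as.data.frame(m))
  jsonlite::write_json(list(seed = scene$seed, params = scene$params,
                            truth = truth),
                       paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(prefix)
}

#' Build a run configuration with documented defaults
#'
#' Unspecified fields resolve to the package defaults (never silent
#' zeros); the returned object carries a provenance block (package
#' version, config hash) that output writers embed.
#'
#' @param ... overrides for any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    pixel_size_um = 0.1,
    temperature_K = 298.15,
    gaussian_sigma_px = 2,
    min_area_px = 20,
    min_segment_px = 3,
    sholl_step_um = 0.5,
    theta_intensity = 4000,
    theta_area_px = 10,
    seed = 1L,
    out_dir = "condactin-run"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  js <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                         digits = NA)
  tf <- tempfile(); writeLines(js, tf)
  cfg$provenance <- list(
    package_version = as.character(utils::packageVersion("condactin")),
    config_hash = unname(tools::md5sum(tf)),
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tf)
  class(cfg) <- "run_config"
  cfg
}

#' Run an ordered subset of pipeline stages
#'
#' Executes stages in order over a synthetic condensate-field scene,
#' writing per-stage CSV/JSON outputs plus a machine-readable run report
#' embedding the config hash. Identical config implies identical outputs.
#' Stage dependencies are checked before anything runs, and existing
#' outputs are not overwritten unless `force = TRUE`.
#'
#' Available stages: `synth` (generate the scene), `segment`, `partition`,
#' `network`, `sholl`.
#'
#' @param config a `run_config`.
#' @param stages character vector, ordered subset of the available stages.
#' @param force overwrite existing outputs.
#' @return list with per-stage results and the report path, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("synth", "segment", "partition"),
                         force = FALSE) {
  valid <- c("synth", "segment", "partition", "network", "sholl")
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("unknown stage(s) ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(valid, collapse = ", "), call. = FALSE)
  deps <- list(synth = character(0), segment = "synth",
               partition = c("synth", "segment"),
               network = "synth", sholl = c("synth", "network"))
  for (s in stages) {
    missing <- setdiff(deps[[s]], stages[seq_len(match(s, stages))])
    if (length(missing))
      stop("stage '", s, "' requires ", paste(missing, collapse = ", "),
           " earlier in the run", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(config$out_dir, "run_report.json")
  if (file.exists(report_path) && !force)
    stop("outputs already exist in ", config$out_dir,
         "; use force = TRUE to overwrite", call. = FALSE)
  res <- list()
  for (s in stages) {
    res[[s]] <- switch(s,
      synth = {
        scene <- make_condensate_field(n = 5, seed = config$seed,
                                       pixel_size_um = config$pixel_size_um)
        write_scene(scene, file.path(config$out_dir, "scene"))
        scene
      },
      segment = {
        seg <- segment_condensates(res$synth$image,
                                   gaussian_sigma_px = config$gaussian_sigma_px,
                                   min_area_px = config$min_area_px)
        write.csv(seg$regions, file.path(config$out_dir, "regions.csv"),
                  row.names = FALSE)
        seg
      },
      partition = {
        pk <- partition_coefficient(res$synth$image, res$segment,
                                    temperature_K = config$temperature_K)
        write.csv(pk, file.path(config$out_dir, "partition.csv"),
                  row.names = FALSE)
        pk
      },
      network = {
        aster <- make_aster_scene(seed = config$seed,
                                  pixel_size_um = config$pixel_size_um)
        gr <- reconstruct_network(aster$image[, , "actin"],
                                  pixel_size_um = config$pixel_size_um,
                                  min_segment_px = config$min_segment_px)
        write.csv(gr$edges, file.path(config$out_dir, "edges.csv"),
                  row.names = FALSE)
        list(scene = aster, graph = gr)
      },
      sholl = {
        ctr <- res$network$scene$truth$condensate_centers[1, ]
        pr <- sholl_profile(res$network$graph, ctr,
                            step_um = config$sholl_step_um)
        write.csv(sholl_long(list(pr)),
                  file.path(config$out_dir, "sholl.csv"), row.names = FALSE)
        pr
      })
  }
  jsonlite::write_json(
    list(stages = stages, config_hash = config$provenance$config_hash,
         package_version = config$provenance$package_version,
         seed = config$seed),
    report_path, auto_unbox = TRUE)
  invisible(c(res, list(report = report_path)))
}

#' Export a skeleton graph as SWC
#'
#' One tree per connected component (breadth-first from an arbitrary
#' root, parent -1 for roots), nodes written as type code 0 with their
#' centroid coordinates in pixels; readable by standard neuroanatomy
#' viewers. Cycle-closing edges cannot be represented in SWC's tree
#' format and are dropped with a warning.
#'
#' @param graph a `skeleton_graph`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_swc <- function(graph, path) {
  stopifnot(inherits(graph, "skeleton_graph"))
  n <- nrow(graph$nodes)
  parent <- rep(-1L, n)
  if (nrow(graph$edges)) {
    g <- igraph::graph_from_edgelist(
      cbind(graph$edges$node_a, graph$edges$node_b), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::ecount(igraph::simplify(g)) <
        igraph::ecount(g))
      warning("multi-edges/cycles dropped in SWC tree export")
    comp <- igraph::components(g)$membership
    for (cm in unique(comp)) {
      verts <- which(comp == cm)
      bfs <- igraph::bfs(g, root = verts[1], father = TRUE,
                         unreachable = FALSE)
      fa <- suppressWarnings(as.integer(bfs$father))
      parent[verts] <- ifelse(is.na(fa[verts]), -1L, fa[verts])
    }
  }
  df <- data.frame(id = graph$nodes$node_id, type = 0L,
                   x = graph$nodes$x, y = graph$nodes$y, z = 0,
                   radius = 1, parent = parent)
  lines <- c("# SWC export: traced filament graph, coordinates in pixels",
             apply(df, 1, function(r) paste(format(r, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC file
#'
#' @param path SWC file.
#' @return data.frame with `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(id = integer(0), type = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), radius = numeric(0),
                      parent = integer(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  setNames(as.data.frame(m),
           c("id", "type", "x", "y", "z", "radius", "parent"))
}
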