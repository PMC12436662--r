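# Sholl intersection profiling of traced networks around condensate
# centers, and the between-condition mixed-model comparison.

#' Sholl intersection profile of a skeleton graph
#'
#' Counts, for each concentric circle of radius `r` around `center`
#' (arithmetic radii, default step 0.5 um), the number of times edge pixel
#' paths cross the circle. A crossing is a consecutive pixel pair on one
#' edge path straddling the radius; a pixel exactly at distance `r` counts
#' as outside (half-open shells), so a tangent path does not cross.
#' Tortuous edges crossing a shell several times count each crossing.
#'
#' @param graph a `skeleton_graph`.
#' @param center numeric `(y, x)` in pixels; must lie inside the image.
#' @param step_um shell spacing, micrometers.
#' @param r_max_um largest shell radius; defaults to the image diagonal.
#' @param condensate_id,condition optional labels carried into the profile.
#' @return object of class `sholl_profile`: list with `radii_um`, `counts`
#'   (integer, same length), `center`, `condensate_id`, `condition`.
#' @export
sholl_profile <- function(graph, center, step_um = 0.5, r_max_um = NULL,
                          condensate_id = NA, condition = NA) {
  if (!inherits(graph, "skeleton_graph"))
    stop("`graph` must be a skeleton_graph", call. = FALSE)
  dims <- dim(graph$skeleton)
  if (center[1] < 1 || center[1] > dims[1] ||
      center[2] < 1 || center[2] > dims[2])
    stop("center lies outside the image bounds", call. = FALSE)
  px <- graph$pixel_size_um
  if (is.null(r_max_um)) r_max_um <- sqrt(sum(dims^2)) * px
  radii <- seq(step_um, r_max_um, by = step_um)
  counts <- integer(length(radii))
  for (p in graph$paths) {
    if (nrow(p) < 2) next
    d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2) * px
    lo <- pmin(head(d, -1), tail(d, -1))
    hi <- pmax(head(d, -1), tail(d, -1))
    # each pair crosses every shell radius r with lo < r <= hi
    k_lo <- findInterval(lo, radii)        # last shell with r <= lo
    k_hi <- findInterval(hi, radii)        # last shell with r <= hi
    inc <- k_hi > k_lo
    if (any(inc)) {
      delta <- integer(length(radii) + 1L)
      for (i in which(inc)) {
        delta[k_lo[i] + 1L] <- delta[k_lo[i] + 1L] + 1L
        delta[k_hi[i] + 1L] <- delta[k_hi[i] + 1L] - 1L
      }
      counts <- counts + cumsum(delta[seq_along(radii)])
    }
  }
  structure(list(radii_um = radii, counts = counts, center = center,
                 step_um = step_um, condensate_id = condensate_id,
                 condition = condition),
            class = "sholl_profile")
}

#' @exportS3Method
print.sholl_profile <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat("<sholl_profile> ", length(x$radii_um), " shells (step ",
      x$step_um, " um), max count ", if (length(nz)) max(x$counts) else 0,
      "\n", sep = "")
  invisible(x)
}

#' Long-format table from Sholl profiles
#'
#' @param profiles list of `sholl_profile` objects.
#' @param trim drop trailing all-zero shells (largest radius with a nonzero
#'   count across profiles is kept).
#' @return data.frame with `condensate_id`, `condition`, `radius_um`,
#'   `intersections`.
#' @export
sholl_long <- function(profiles, trim = TRUE) {
  stopifnot(length(profiles) > 0)
  out <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    id <- if (is.na(p$condensate_id)) i else p$condensate_id
    data.frame(condensate_id = id, condition = p$condition,
               radius_um = p$radii_um, intersections = p$counts)
  }))
  if (trim && any(out$intersections > 0)) {
    rmax <- max(out$radius_um[out$intersections > 0])
    out <- out[out$radius_um <= rmax, ]
  }
  rownames(out) <- NULL
  out
}

#' Compare Sholl profiles between conditions
#'
#' Fits a linear mixed model `intersections ~ condition * radius + (1 |
#' condensate)` (random intercept per profile) and reports the condition
#' main effect (Satterthwaite approximation). When the fit is singular or
#' fails, or when `method = "permutation"`, a permutation test on the
#' per-profile area under the Sholl curve (condition labels shuffled across
#' profiles) is used instead.
#'
#' @param profiles list of `sholl_profile`s with `condition` set, or an
#'   equivalent long data.frame (see [sholl_long()]).
#' @param method `"auto"` (mixed model with permutation fallback),
#'   `"lmm"`, or `"permutation"`.
#' @param n_perm permutations for the fallback test.
#' @param seed RNG seed for the permutation test.
#' @return list with `method`, `estimate` (condition effect on the mean
#'   intersection count), `p_value`, `n_profiles`, and for the mixed model
#'   the `fixed_effects` table.
#' @export
compare_sholl_lmm <- function(profiles, method = c("auto", "lmm",
                                                   "permutation"),
                              n_perm = 1999, seed = 1L) {
  method <- match.arg(method)
  df <- if (is.data.frame(profiles)) profiles else sholl_long(profiles)
  df$condition <- factor(df$condition)
  df$condensate_id <- factor(paste(df$condition, df$condensate_id))
  if (nlevels(df$condition) < 2)
    stop("need at least two conditions", call. = FALSE)
  n_per <- table(tapply(df$condition, df$condensate_id, function(z) z[1]))
  if (any(n_per < 3))
    warning("fewer than 3 profiles in some condition; estimates are fragile")
  auc <- tapply(df$intersections, df$condensate_id, sum) *
    (df$radius_um[2] - df$radius_um[1])
  cond_of <- tapply(as.character(df$condition), df$condensate_id,
                    function(z) z[1])
  run_perm <- function() {
    grp <- factor(cond_of)
    obs_means <- tapply(auc, grp, mean)
    obs <- max(obs_means) - min(obs_means)
    stat <- numeric(n_perm)
    with_local_seed(seed, {
      for (i in seq_len(n_perm)) {
        pg <- sample(grp)
        m <- tapply(auc, pg, mean)
        stat[i] <- max(m) - min(m)
      }
    })
    list(method = "permutation",
         estimate = unname(obs_means[length(obs_means)] - obs_means[1]) /
           diff(range(df$radius_um)),
         p_value = (1 + sum(stat >= obs)) / (n_perm + 1),
         n_profiles = as.integer(table(grp)))
  }
  if (method == "permutation") return(run_perm())
  fit <- tryCatch(
    lmerTest::lmer(intersections ~ condition * radius_um +
                     (1 | condensate_id), data = df,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
  if (method == "auto" && singular) {
    if (!is.null(fit)) warning("singular mixed-model fit; using permutation test")
    return(run_perm())
  }
  if (is.null(fit)) stop("mixed model failed to fit", call. = FALSE)
  an <- suppressMessages(anova(fit, type = 3))
  p <- an["condition", "Pr(>F)"]
  fe <- summary(fit)$coefficients
  est <- fe[grep("^condition", rownames(fe))[1], "Estimate"]
  if (!length(est)) est <- 0
  list(method = "lmm", estimate = unname(est), p_value = p,
       n_profiles = as.integer(table(cond_of)),
       fixed_effects = fe)
}
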