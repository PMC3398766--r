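# Group statistics on 3-D effect maps: factorial contrast vectors,
# unequal-variance t maps, cluster formation at a height threshold,
# direction-based voxel categorisation, and effect sampling at named foci.

CONDITION_ORDER <- c("mful_a", "mful_t", "mless_a", "mless_t", "silence")

#' Factorial contrast vectors
#'
#' Exact integer contrast weights over the fixed condition order
#' `(mful_a, mful_t, mless_a, mless_t, silence)`:
#' * `all_sound_vs_silence`: (1, 1, 1, 1, -4) -- all sound over baseline.
#' * `meaningless_vs_silence`: (0, 0, 1, 1, -2) -- perceptual processing of
#'   spectrotemporally complex but meaningless sound.
#' * `meaningful_vs_meaningless`: (1, 1, -1, -1, 0) -- semantic processing.
#' * `semantic_animal`: (1, 0, -1, 0, 0); `semantic_tool`: (0, 1, 0, -1, 0).
#' * `category_animal`: (1, -1, -1, 1, 0) -- category-specific semantic
#'   processing favouring animal sounds; `category_tool` is its negation.
#'
#' @param name One of the seven contrast names above.
#' @return Named integer vector over the condition order.
#' @export
contrast_vector <- function(name) {
  tab <- list(
    all_sound_vs_silence      = c(1, 1, 1, 1, -4),
    meaningless_vs_silence    = c(0, 0, 1, 1, -2),
    meaningful_vs_meaningless = c(1, 1, -1, -1, 0),
    semantic_animal           = c(1, 0, -1, 0, 0),
    semantic_tool             = c(0, 1, 0, -1, 0),
    category_animal           = c(1, -1, -1, 1, 0),
    category_tool             = c(-1, 1, 1, -1, 0))
  if (!name %in% names(tab))
    stop("unknown contrast name: ", name, " (known: ",
         paste(names(tab), collapse = ", "), ")")
  stats::setNames(as.integer(tab[[name]]), CONDITION_ORDER)
}

#' Expand a contrast vector to a full design width
#'
#' Duplicates condition weights across runs and inserts zeros for the
#' per-run motion regressors, matching a design matrix laid out as
#' `[conditions, motion] x n_runs`.
#'
#' @param weights Contrast weights over the condition order (length 5).
#' @param n_runs Number of runs (default 2).
#' @param n_motion Motion regressors per run (default 6).
#' @return Numeric vector of length `n_runs * (length(weights) + n_motion)`.
#' @export
expand_contrast <- function(weights, n_runs = 2L, n_motion = 6L) {
  rep(c(weights, numeric(n_motion)), n_runs)
}

#' 3-D statistic / effect map
#'
#' @param values 3-D numeric array of finite voxel values.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices),
#'   defaulting to 2 mm isotropic voxels centred on the origin.
#' @param kind `"effect"` or `"t"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, affine = NULL, kind = c("effect", "t")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (!all(is.finite(values))) stop("map values must be finite")
  if (is.null(affine)) affine <- default_affine(dim(values))
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(values = values, affine = affine, kind = kind),
            class = "stat_map")
}

default_affine <- function(dims, spacing = 2) {
  A <- diag(c(rep(spacing, 3), 1))
  A[1:3, 4] <- -(dims - 1) / 2 * spacing
  A
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map (%s): %s voxels, range [%.3g, %.3g]>\n", x$kind,
              paste(dim(x$values), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write statistic maps as NIfTI-1
#'
#' @param path NIfTI file path.
#' @param kind Map kind for [stat_map()].
#' @return `read_stat_map` returns a `stat_map`; `write_stat_map` returns
#'   `path` invisibly.
#' @export
read_stat_map <- function(path, kind = "effect") {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = c(4L, 4L))
  stat_map(array(as.numeric(img), dim = dim(img)), affine = aff,
           kind = kind)
}

#' @rdname read_stat_map
#' @param map A `stat_map`.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel-wise two-sample t map with unequal group variances
#'
#' Welch two-sample t statistic `(meanA - meanB) / sqrt(vA/nA + vB/nB)` at
#' every voxel, with the Welch-Satterthwaite degrees of freedom map.
#' Group variances are not pooled, so patient and control groups may
#' differ in variance. Voxels where both groups are constant and equal
#' yield t = 0.
#'
#' @param groupA,groupB Lists (>= 2 each) of aligned effect `stat_map`s.
#' @return A list with `t` (a `stat_map` of kind `"t"`), `df` (numeric
#'   array of voxel-wise degrees of freedom) and `diff` (meanA - meanB
#'   effect `stat_map`).
#' @export
welch_group_t_map <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop("need at least 2 maps per group")
  dims <- dim(groupA[[1]]$values)
  all_maps <- c(groupA, groupB)
  if (!all(vapply(all_maps, function(m)
    identical(dim(m$values), dims), logical(1))))
    stop("all maps must share the same grid")
  A <- vapply(groupA, function(m) m$values, array(0, dims))
  B <- vapply(groupB, function(m) m$values, array(0, dims))
  dim(A) <- c(prod(dims), nA); dim(B) <- c(prod(dims), nB)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  tval <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               nA + nB - 2)
  aff <- groupA[[1]]$affine
  list(t = stat_map(array(tval, dims), aff, "t"),
       df = array(df, dims),
       diff = stat_map(array(mA - mB, dims), aff, "effect"))
}

# Neighbour offsets for 6/18/26 3-D connectivity.
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  off[keep, , drop = FALSE]
}

#' Form clusters of supra-threshold voxels
#'
#' Connected components of `values > height_threshold` under the chosen
#' 3-D connectivity; analogous to cluster formation at an uncorrected
#' height threshold before extent-level assessment. The threshold is a
#' statistic value; use [p_to_t_threshold()] to convert a p-value given
#' the degrees-of-freedom map.
#'
#' @param map A `stat_map`.
#' @param height_threshold Scalar threshold, or an array matched to the
#'   map (e.g. a voxel-wise t threshold from varying df).
#' @param connectivity 6, 18 (default; face or edge neighbours) or 26.
#' @return A list of clusters sorted by decreasing extent, each with
#'   `voxels` (n x 3 index matrix), `extent_k`, `peak_ijk`, `peak_mm` and
#'   `peak_value`.
#' @export
form_clusters <- function(map, height_threshold, connectivity = 18L) {
  stopifnot(inherits(map, "stat_map"))
  off <- connectivity_offsets(as.integer(connectivity))
  dims <- dim(map$values)
  supra <- map$values > height_threshold
  labels <- array(0L, dims)
  nxt <- 0L
  idx_all <- which(supra)
  if (length(idx_all) == 0L) return(list())
  coords_all <- arrayInd(idx_all, dims)
  lin <- function(ijk) (ijk[, 3] - 1L) * dims[1] * dims[2] +
    (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    labels[start] <- nxt
    frontier <- matrix(arrayInd(start, dims), ncol = 3)
    while (nrow(frontier) > 0L) {
      cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        sweep(frontier, 2, off[k, ], "+")))
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      li <- lin(cand)
      new <- !duplicated(li) & supra[li] & labels[li] == 0L
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand) == 0L) break
      labels[lin(cand)] <- nxt
      frontier <- cand
    }
  }
  clusters <- lapply(seq_len(nxt), function(lb) {
    vox <- coords_all[labels[idx_all] == lb, , drop = FALSE]
    vals <- map$values[vox]
    pk <- vox[which.max(vals), ]
    mm <- (map$affine %*% c(pk - 1, 1))[1:3]
    list(voxels = vox, extent_k = nrow(vox),
         peak_ijk = pk, peak_mm = as.numeric(mm),
         peak_value = max(vals))
  })
  clusters[order(vapply(clusters, `[[`, 0L, "extent_k"),
                 decreasing = TRUE)]
}

#' Convert a height p-value to voxel-wise t thresholds
#'
#' @param p Upper-tail height threshold (e.g. 0.001).
#' @param df Degrees-of-freedom array (e.g. from [welch_group_t_map()]).
#' @return Array of t thresholds matched to `df`.
#' @export
p_to_t_threshold <- function(p, df) {
  stopifnot(p > 0, p < 1)
  array(stats::qt(1 - p, df), dim = if (is.null(dim(df))) length(df)
        else dim(df))
}

#' Categorise interaction voxels by control-group direction
#'
#' Colour-codes voxels within a significant group-interaction mask by the
#' sign of the control group's effect in the forward contrast: `cyan`
#' where controls activate in the forward direction (the interaction is
#' plausibly driven by stronger patient activation in the forward
#' contrast), `magenta` where the control effect is negative (controls
#' alone activate the reverse contrast more), `indeterminate` at exactly
#' zero.
#'
#' @param interaction_mask Binary `stat_map` (or logical/0-1 array) of
#'   significant interaction voxels.
#' @param control_forward_effect `stat_map` of the control group's mean
#'   effect in the forward contrast, on the same grid.
#' @return A list of class `label_map`: integer array `labels`
#'   (0 = outside mask, 1 = cyan, 2 = magenta, 3 = indeterminate) plus a
#'   `legend`.
#' @export
categorise_interaction_voxels <- function(interaction_mask,
                                          control_forward_effect) {
  mask <- if (inherits(interaction_mask, "stat_map"))
    interaction_mask$values else interaction_mask
  ctrl <- control_forward_effect$values
  if (!identical(dim(mask), dim(ctrl))) stop("grids do not match")
  if (!all(mask %in% c(0, 1))) stop("interaction mask must be binary")
  labels <- array(0L, dim(mask))
  inside <- mask == 1
  labels[inside & ctrl > 0] <- 1L
  labels[inside & ctrl < 0] <- 2L
  labels[inside & ctrl == 0] <- 3L
  structure(list(labels = labels,
                 legend = c(outside = 0L, cyan = 1L, magenta = 2L,
                            indeterminate = 3L)),
            class = "label_map")
}

#' Named coordinate foci
#'
#' @param labels Character labels (e.g. `mSTG_L`, `pLaS_R`, `pMTG_L`).
#' @param coords n x 3 matrix of mm (MNI) coordinates.
#' @return A data frame of class `focus_set`.
#' @export
focus_set <- function(labels, coords) {
  coords <- matrix(coords, ncol = 3)
  if (length(labels) != nrow(coords)) stop("one label per coordinate row")
  structure(data.frame(label = labels, x = coords[, 1], y = coords[, 2],
                       z = coords[, 3], stringsAsFactors = FALSE),
            class = c("focus_set", "data.frame"))
}

#' Read a focus configuration from JSON
#'
#' Expects `[{"label": ..., "mni": [x, y, z]}, ...]`. Focus coordinates
#' are supplied by configuration (they originate from prior published
#' work), never hard-coded.
#'
#' @param path JSON file path.
#' @return A [focus_set()].
#' @export
read_focus_set <- function(path) {
  js <- jsonlite::read_json(path)
  focus_set(vapply(js, `[[`, "", "label"),
            t(vapply(js, function(f) as.numeric(unlist(f$mni)),
                     numeric(3))))
}

#' Sample per-subject effect sizes at named foci
#'
#' Looks up, for every subject map, the value at the voxel nearest each
#' mm coordinate (via the map affine), and summarises each focus with the
#' group mean and a t-based 95% confidence interval.
#'
#' @param effect_maps List of per-subject effect `stat_map`s on a common
#'   grid.
#' @param foci A [focus_set()].
#' @param level Confidence level for the group summary (default 0.95).
#' @return A list with `values` (subjects x foci matrix) and `summary`
#'   (data frame with `label`, `mean`, `ci_low`, `ci_high`, `n`).
#' @export
sample_foci <- function(effect_maps, foci, level = 0.95) {
  stopifnot(inherits(foci, "focus_set"), length(effect_maps) >= 1)
  aff <- effect_maps[[1]]$affine
  dims <- dim(effect_maps[[1]]$values)
  inv <- solve(aff)
  vox <- t(apply(foci[, c("x", "y", "z")], 1, function(mm) {
    ijk0 <- round((inv %*% c(as.numeric(mm), 1))[1:3])
    ijk0 + 1  # to 1-based indices
  }))
  if (any(vox < 1) || any(sweep(vox, 2, dims, ">")))
    stop("focus outside the map field of view")
  vals <- t(vapply(effect_maps, function(m)
    m$values[vox], numeric(nrow(vox))))
  if (nrow(foci) == 1L) vals <- matrix(vals, ncol = 1L)
  colnames(vals) <- foci$label
  n <- nrow(vals)
  summ <- do.call(rbind, lapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    m <- mean(v)
    half <- if (n > 1) stats::qt(1 - (1 - level) / 2, n - 1) *
      stats::sd(v) / sqrt(n) else NA_real_
    data.frame(label = foci$label[j], mean = m,
               ci_low = m - half, ci_high = m + half, n = n,
               stringsAsFactors = FALSE)
  }))
  list(values = vals, summary = summ)
}

#' Simulate subject-level effect maps for two groups
#'
#' Fixture generator standing in for subject-level contrast images:
#' independent Gaussian noise maps, with additive effects inside named
#' spherical regions. Each region's effect is `effect_size * region$effect`
#' and is applied to group A only (so `effect_size = 0` makes the groups
#' exchangeable).
#'
#' @param n_per_group Subjects per group (single value or length-2 vector
#'   `c(nA, nB)`).
#' @param dims Grid dimensions (default `c(24, 24, 24)`).
#' @param effect_regions List of regions, each
#'   `list(center = c(x, y, z) mm, radius = mm, effect = multiplier)`.
#' @param effect_size Scalar scale applied to all region effects.
#' @param noise_sd Standard deviation of the voxel noise.
#' @param spacing Voxel size in mm (default 2).
#' @param seed Integer seed; maps are deterministic per seed.
#' @return A list with `groupA` and `groupB` lists of effect `stat_map`s.
#' @export
simulate_group_maps <- function(n_per_group, dims = c(24L, 24L, 24L),
                                effect_regions = list(), effect_size = 1,
                                noise_sd = 1, spacing = 2, seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2)
  aff <- default_affine(dims, spacing)
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                k = seq_len(dims[3])))
  mm <- sweep(sweep(grid - 1, 2, diag(aff)[1:3], "*"), 2, aff[1:3, 4], "+")
  signal <- numeric(prod(dims))
  for (reg in effect_regions) {
    d2 <- rowSums(sweep(mm, 2, reg$center, "-")^2)
    inside <- d2 <= reg$radius^2
    if (!any(inside)) stop("effect region lies outside the grid")
    signal[inside] <- signal[inside] + effect_size * reg$effect
  }
  with_seed(seed, {
    mk <- function(add_signal) {
      v <- stats::rnorm(prod(dims), sd = noise_sd)
      if (add_signal) v <- v + signal
      stat_map(array(v, dims), aff, "effect")
    }
    list(groupA = replicate(n_per_group[1], mk(TRUE), simplify = FALSE),
         groupB = replicate(n_per_group[2], mk(FALSE), simplify = FALSE))
  })
}

#' Permutation null for maximum cluster extent
#'
#' Optional cluster-extent calibration for synthetic experiments:
#' relabels subjects across groups, recomputes the unequal-variance t map
#' and records the maximum supra-threshold cluster extent per relabelling.
#'
#' @param groupA,groupB Lists of effect `stat_map`s.
#' @param height_p Height threshold as an upper-tail p-value.
#' @param connectivity Cluster connectivity (default 18).
#' @param n_perm Number of relabellings (default 100).
#' @param seed Integer seed.
#' @return Numeric vector of maximum extents (voxels), one per
#'   relabelling.
#' @export
cluster_extent_null <- function(groupA, groupB, height_p = 0.001,
                                connectivity = 18L, n_perm = 100L,
                                seed = 1L) {
  all_maps <- c(groupA, groupB)
  nA <- length(groupA)
  n <- length(all_maps)
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pick <- sample(n, nA)
    res <- welch_group_t_map(all_maps[pick], all_maps[-pick])
    thr <- p_to_t_threshold(height_p, res$df)
    cl <- form_clusters(res$t, thr, connectivity)
    if (length(cl) == 0L) 0 else max(vapply(cl, `[[`, 0L, "extent_k"))
  }, numeric(1)))
}
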