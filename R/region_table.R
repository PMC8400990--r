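#' Feature names of the regional feature vector
#'
#' Fixed order of the five per-region features: the four aggregated
#' curvature descriptors followed by the enclosed region volume.
#' @return Character vector of length 5.
#' @export
region_feature_names <- function() {
  c("gaussian", "mean", "sharpness", "curvedness", "volume")
}

# 1-voxel nearest-nonzero dilation of a label array: background voxels with
# at least one labelled 26-neighbour take the most frequent neighbouring
# label (ties broken toward the smallest label id). Isosurface vertices sit
# between tissue and background voxels; without this, roughly half of them
# would look up background.
dilate_labels <- function(lab) {
  dims <- dim(lab)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  shifted_one <- function(off) {
    out <- array(0L, dims)
    sx <- max(1, 1 + off[1]):min(dims[1], dims[1] + off[1])
    sy <- max(1, 1 + off[2]):min(dims[2], dims[2] + off[2])
    sz <- max(1, 1 + off[3]):min(dims[3], dims[3] + off[3])
    out[sx - off[1], sy - off[2], sz - off[3]] <- lab[sx, sy, sz]
    out
  }
  nmax <- array(0L, dims)
  for (s in seq_len(nrow(offs))) nmax <- pmax(nmax, shifted_one(offs[s, ]))
  cand <- which(lab == 0L & nmax > 0L)
  if (!length(cand)) return(lab)
  neigh <- matrix(0L, length(cand), nrow(offs))
  ijk <- arrayInd(cand, dims)
  for (s in seq_len(nrow(offs))) {
    pos <- sweep(ijk, 2L, offs[s, ], "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
      pos[, 2] >= 1 & pos[, 2] <= dims[2] &
      pos[, 3] >= 1 & pos[, 3] <= dims[3]
    neigh[ok, s] <- lab[pos[ok, , drop = FALSE]]
  }
  mode1 <- function(x) {
    x <- x[x > 0L]
    if (!length(x)) return(0L)
    ux <- sort(unique(x))
    ux[which.max(tabulate(match(x, ux)))]
  }
  lab[cand] <- apply(neigh, 1L, mode1)
  lab
}

#' Label mesh vertices with atlas regions
#'
#' Each vertex receives the label of the atlas voxel containing its world
#' coordinate (inverse-affine mapping, nearest voxel centre). Because
#' surface vertices lie between tissue and background voxels, the lookup is
#' performed on a 1-voxel nearest-nonzero dilation of the atlas by default.
#' Vertices outside the atlas field of view get label 0; their count is
#' reported via `message()`.
#'
#' @param mesh A [trimesh()] in the atlas world space.
#' @param atlas A [label_volume()].
#' @param dilate Apply the 1-voxel dilation rule (default TRUE).
#' @return Integer vector of region ids per vertex (0 = background).
#' @export
label_vertices <- function(mesh, atlas, dilate = TRUE) {
  stopifnot(inherits(mesh, "trimesh"), inherits(atlas, "label_volume"))
  lab <- if (dilate) dilate_labels(atlas$labels) else atlas$labels
  dims <- dim(lab)
  inv <- solve(atlas$affine)
  v <- cbind(mesh$vertices, 1) %*% t(inv)
  idx <- floor(v[, 1:3, drop = FALSE] + 0.5) + 1  # 1-based array index
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  out <- integer(nrow(idx))
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE]
    storage.mode(ii) <- "integer"
    out[inside] <- lab[ii]
  }
  n_out <- sum(!inside)
  if (n_out > 0L)
    message(n_out, " vertex(ices) outside the atlas field of view -> label 0")
  out
}

#' Enclosed surface volume of one atlas region
#'
#' Masks the intensity volume to the region's voxels, reconstructs the
#' region's isosurface (after zero-padding by one voxel so the surface is
#' closed even at the volume boundary) and returns the divergence-theorem
#' volume summed over all closed components.
#'
#' @param vol A [volume_grid()] of intensities.
#' @param atlas A [label_volume()] on the same grid.
#' @param region Region label id.
#' @param alpha Isovalue.
#' @return Volume in mm^3, or `NA_real_` (flagged missing) when the region
#'   is empty or contains no above-threshold voxels.
#' @export
region_surface_volume <- function(vol, atlas, region, alpha) {
  stopifnot(inherits(vol, "volume_grid"), inherits(atlas, "label_volume"))
  if (!identical(dim(vol$data), dim(atlas$labels)))
    stop("volume and atlas grids differ")
  sel <- atlas$labels == region
  if (!any(sel)) return(NA_real_)
  sub <- vol$data * sel
  if (max(sub) <= alpha) return(NA_real_)
  dims <- dim(sub)
  padded <- array(0, dims + 2L)
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- sub
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% c(1, 1, 1)
  mesh <- marching_cubes(volume_grid(padded, aff), alpha)
  mesh_signed_volume(mesh)
}

#' Aggregate per-vertex descriptors into one subject's regional features
#'
#' Per region: the mean (or median) over its labelled vertices of each of
#' the four curvature descriptors, plus the region's enclosed volume.
#' Regions with fewer than `min_vertices` labelled vertices are flagged
#' missing (NA), never silently zeroed.
#'
#' @param vertex_shapes data.frame from [mesh_shape_features()].
#' @param vertex_labels Integer region ids per vertex
#'   (from [label_vertices()]).
#' @param region_volumes Named numeric vector of region volumes (mm^3),
#'   names = region ids.
#' @param regions Integer vector of region ids defining row order.
#' @param min_vertices Minimum labelled vertices per region (default 10).
#' @param statistic "mean" (default) or "median".
#' @return `length(regions)` x 5 matrix (rownames = region ids, colnames =
#'   [region_feature_names()]); missing cells are NA.
#' @export
aggregate_region_features <- function(vertex_shapes, vertex_labels,
                                      region_volumes, regions,
                                      min_vertices = 10L,
                                      statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stat <- if (statistic == "mean") mean else stats::median
  if (nrow(vertex_shapes) != length(vertex_labels))
    stop("labels and shapes are not aligned by vertex")
  if (all(vertex_labels == 0L))
    stop("no labelled vertices")
  out <- matrix(NA_real_, length(regions), 5L,
                dimnames = list(as.character(regions),
                                region_feature_names()))
  for (i in seq_along(regions)) {
    r <- regions[i]
    idx <- which(vertex_labels == r)
    if (length(idx) < min_vertices) next
    out[i, 1:4] <- c(stat(vertex_shapes$gaussian[idx]),
                     stat(vertex_shapes$mean[idx]),
                     stat(vertex_shapes$sharpness[idx]),
                     stat(vertex_shapes$curvedness[idx]))
    vol <- region_volumes[as.character(r)]
    out[i, 5] <- if (length(vol)) unname(vol) else NA_real_
  }
  out
}

#' Construct a regional feature table
#'
#' The subjects x regions x 5 container carried through normalization,
#' fusion and diagnosis. Units are mixed (curvature units + mm^3) before
#' normalization and dimensionless in [0, 1] after; missing cells are NA.
#'
#' @param features 3D array `[subjects, regions, 5]`, or a list of
#'   per-subject `regions x 5` matrices.
#' @param subjects Character subject ids.
#' @param regions Integer region ids.
#' @param normalized Whether values are already min-max normalized.
#' @param norm_stats Normalization statistics (see [normalize_features()]).
#' @return Object of class `region_feature_table`.
#' @export
region_feature_table <- function(features, subjects = NULL, regions = NULL,
                                 normalized = FALSE, norm_stats = NULL) {
  if (is.list(features) && !is.array(features)) {
    if (is.null(regions)) regions <- as.integer(rownames(features[[1]]))
    arr <- array(NA_real_, c(length(features), length(regions), 5L))
    for (s in seq_along(features)) arr[s, , ] <- features[[s]]
    features <- arr
  }
  stopifnot(length(dim(features)) == 3L, dim(features)[3] == 5L)
  if (is.null(subjects))
    subjects <- sprintf("S%03d", seq_len(dim(features)[1]))
  if (is.null(regions)) regions <- seq_len(dim(features)[2])
  dimnames(features) <- list(subjects, as.character(regions),
                             region_feature_names())
  structure(list(features = features, subjects = subjects,
                 regions = as.integer(regions),
                 feature_names = region_feature_names(),
                 normalized = normalized, norm_stats = norm_stats),
            class = "region_feature_table")
}

#' @export
print.region_feature_table <- function(x, ...) {
  cat("<region_feature_table> ", length(x$subjects), " subjects x ",
      length(x$regions), " regions x 5 features (",
      if (x$normalized) "normalized" else "raw", "); ",
      sum(is.na(x$features)), " missing cells\n", sep = "")
  invisible(x)
}

#' Min-max normalize a feature table
#'
#' Per (region, feature) column over the (training) subjects:
#' `(x - min) / (max - min)`, so every finite entry lies in [0, 1]. Constant
#' columns carry no information and are set to 0.5 with a warning. The
#' (min, max) pairs are stored in the result so they can be re-applied
#' verbatim to held-out subjects with [apply_normalization()]; statistics are
#' never recomputed on test data.
#'
#' @param table A raw [region_feature_table()] with >= 2 subjects.
#' @return A normalized [region_feature_table()] with `norm_stats`
#'   (`min`, `max`: regions x 5 matrices; `col_means`: training column
#'   means on the normalized scale, used for imputation).
#' @export
normalize_features <- function(table) {
  stopifnot(inherits(table, "region_feature_table"))
  if (table$normalized) stop("table is already normalized")
  if (length(table$subjects) < 2L) stop("need at least 2 subjects")
  arr <- table$features
  mins <- apply(arr, c(2, 3), function(v) suppressWarnings(min(v, na.rm = TRUE)))
  maxs <- apply(arr, c(2, 3), function(v) suppressWarnings(max(v, na.rm = TRUE)))
  mins[!is.finite(mins)] <- NA_real_
  maxs[!is.finite(maxs)] <- NA_real_
  const <- !is.na(mins) & !is.na(maxs) & maxs == mins
  if (any(const))
    warning(sum(const), " constant feature column(s) set to 0.5")
  out <- arr
  for (r in seq_len(dim(arr)[2])) for (k in 1:5) {
    v <- arr[, r, k]
    if (is.na(mins[r, k])) next
    out[, r, k] <- if (const[r, k]) ifelse(is.na(v), NA_real_, 0.5)
      else pmin(1, pmax(0, (v - mins[r, k]) / (maxs[r, k] - mins[r, k])))
  }
  cm <- apply(out, c(2, 3), function(v) mean(v, na.rm = TRUE))
  cm[!is.finite(cm)] <- 0.5
  region_feature_table(out, table$subjects, table$regions,
                       normalized = TRUE,
                       norm_stats = list(min = mins, max = maxs,
                                         constant = const, col_means = cm))
}

#' Apply frozen normalization statistics to held-out subjects
#'
#' @param table A raw [region_feature_table()].
#' @param stats `norm_stats` from a table normalized on training subjects.
#' @return A normalized [region_feature_table()]; values are clipped to
#'   [0, 1], so a test value below the training minimum maps to 0.
#' @export
apply_normalization <- function(table, stats) {
  stopifnot(inherits(table, "region_feature_table"), !table$normalized)
  arr <- table$features
  out <- arr
  for (r in seq_len(dim(arr)[2])) for (k in 1:5) {
    v <- arr[, r, k]
    if (is.na(stats$min[r, k])) { out[, r, k] <- NA_real_; next }
    out[, r, k] <- if (stats$constant[r, k]) ifelse(is.na(v), NA_real_, 0.5)
      else pmin(1, pmax(0, (v - stats$min[r, k]) /
                          (stats$max[r, k] - stats$min[r, k])))
  }
  region_feature_table(out, table$subjects, table$regions,
                       normalized = TRUE, norm_stats = stats)
}

#' Impute missing cells with training column means
#'
#' Missing regions at classification time are filled with the training-set
#' column mean (on the normalized scale); the number of imputed cells is
#' reported via `message()`.
#'
#' @param table A normalized [region_feature_table()].
#' @param col_means regions x 5 matrix of training column means (defaults to
#'   the table's own `norm_stats$col_means`).
#' @return The table with NA cells filled.
#' @export
impute_missing <- function(table, col_means = table$norm_stats$col_means) {
  arr <- table$features
  n_imputed <- 0L
  for (r in seq_len(dim(arr)[2])) for (k in 1:5) {
    miss <- is.na(arr[, r, k])
    if (any(miss)) {
      arr[miss, r, k] <- col_means[r, k]
      n_imputed <- n_imputed + sum(miss)
    }
  }
  if (n_imputed > 0L) message(n_imputed, " missing cell(s) imputed")
  table$features <- arr
  table
}

#' Extract one subject's regional features from a labelled volume
#'
#' The full per-subject feature extraction: mask the scan, select the
#' isovalue, reconstruct the cortical surface, estimate per-vertex
#' curvature descriptors, label vertices with the atlas, reconstruct each
#' region separately for its enclosed volume, and aggregate to the
#' regions x 5 feature matrix.
#'
#' @param scan A [volume_grid()] (already MNI-registered, skull-stripped).
#' @param mask Optional brain-mask [volume_grid()].
#' @param atlas A [label_volume()].
#' @param alpha Isovalue; chosen by [select_isovalue()] when NULL.
#' @param rings Curvature neighbourhood radius (default 5).
#' @param min_vertices Minimum labelled vertices per region (default 10).
#' @return List: `features` (regions x 5 matrix), `mesh`, `vertex_shapes`,
#'   `vertex_labels`, `alpha`.
#' @export
extract_subject_features <- function(scan, mask = NULL, atlas,
                                     alpha = NULL, rings = 5L,
                                     min_vertices = 10L) {
  vol <- if (is.null(mask)) scan else apply_brain_mask(scan, mask)
  if (is.null(alpha)) alpha <- select_isovalue(vol)
  mesh <- marching_cubes(vol, alpha)
  shapes <- mesh_shape_features(mesh, rings = rings)
  vlab <- label_vertices(mesh, atlas)
  regions <- sort(atlas$region_table$label_id)
  vols <- vapply(regions, function(r)
    region_surface_volume(vol, atlas, r, alpha), numeric(1))
  names(vols) <- regions
  feats <- aggregate_region_features(shapes, vlab, vols, regions,
                                     min_vertices = min_vertices)
  list(features = feats, mesh = mesh, vertex_shapes = shapes,
       vertex_labels = vlab, alpha = alpha)
}

#' Write a feature table as tidy or wide CSV
#'
#' @param table A [region_feature_table()].
#' @param path Output CSV path.
#' @param format "tidy" (subject_id, region_id, feature_name, value) or
#'   "wide" (one column per region x feature).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  arr <- table$features
  if (format == "tidy") {
    df <- expand.grid(subject_id = table$subjects,
                      region_id = table$regions,
                      feature_name = table$feature_names,
                      stringsAsFactors = FALSE)
    df$value <- as.vector(arr)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    wide <- matrix(arr, nrow = length(table$subjects))
    colnames(wide) <- as.vector(outer(table$regions, table$feature_names,
                                      function(r, f) paste0(f, "_", r)))
    utils::write.csv(data.frame(subject_id = table$subjects, wide,
                                check.names = FALSE),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a tidy feature-table CSV written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A raw [region_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  subjects <- unique(df$subject_id)
  regions <- sort(unique(df$region_id))
  arr <- array(NA_real_, c(length(subjects), length(regions), 5L))
  si <- match(df$subject_id, subjects)
  ri <- match(df$region_id, regions)
  fi <- match(df$feature_name, region_feature_names())
  arr[cbind(si, ri, fi)] <- df$value
  region_feature_table(arr, subjects, regions)
}
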