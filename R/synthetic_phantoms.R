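#' Generate a voxelized geometric phantom
#'
#' Voxelized stand-ins for preprocessed sMRI inputs, with analytic volume
#' and surface curvature attached so downstream tests never rely on numbers
#' computed by the pipeline under test. Shapes: `ball`, `ellipsoid`, `cube`
#' (axis-aligned box), `slab`, `two_blob` (two disjoint balls, labelled 1
#' and 2). Boundary voxels are partial-volume antialiased by default
#' (fractional occupancy from the signed distance), which makes curvature
#' estimation on the reconstructed surface markedly better behaved than
#' hard binarization; both modes are supported. Gaussian noise (default sd
#' = 2% of the tissue intensity) is added reproducibly from `seed`.
#'
#' @param shape One of `"ball"`, `"ellipsoid"`, `"cube"`, `"slab"`,
#'   `"two_blob"`.
#' @param size Shape parameters in mm: ball radius (scalar); ellipsoid
#'   semi-axes (length 3); cube half-widths (scalar or length 3); slab
#'   half-thickness (scalar, slab normal along z); two_blob radii
#'   (length 2).
#' @param grid_shape Voxel grid dimensions (default c(64, 64, 64)).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param intensity Background and tissue intensity levels
#'   (default c(0, 100)).
#' @param noise_sd Gaussian noise sd (default 2% of tissue intensity).
#' @param antialias Partial-volume antialiasing (default TRUE).
#' @param seed Integer seed for the noise (default 1).
#' @param centers Optional shape centre(s) in mm world coordinates;
#'   defaults to the grid centre (for `two_blob`, two centres separated
#'   along x).
#' @return List: `vol` ([volume_grid()]), `atlas` ([label_volume()] with a
#'   synthetic region table), `analytic` (volume(s) in mm^3, principal
#'   curvatures where constant over the surface or at named points),
#'   `spec` (the generating parameters).
#' @export
make_phantom <- function(shape = c("ball", "ellipsoid", "cube", "slab",
                                   "two_blob"),
                         size = 10, grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         intensity = c(background = 0, tissue = 100),
                         noise_sd = 0.02 * intensity[[2]],
                         antialias = TRUE, seed = 1L, centers = NULL) {
  shape <- match.arg(shape)
  grid_shape <- as.integer(grid_shape)
  affine <- diag(c(spacing, 1))
  # world coordinates of voxel centres (0-based indices)
  xs <- (seq_len(grid_shape[1]) - 1) * spacing[1]
  ys <- (seq_len(grid_shape[2]) - 1) * spacing[2]
  zs <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  ctr <- c(mean(range(xs)), mean(range(ys)), mean(range(zs)))
  extent <- c(diff(range(xs)), diff(range(ys)), diff(range(zs)))
  margin <- 2 * max(spacing)

  dist3 <- function(center) {
    dx <- xs - center[1]; dy <- ys - center[2]; dz <- zs - center[3]
    sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
  }

  sd_field <- NULL; labels_of <- NULL; analytic <- list()
  if (shape == "ball") {
    r <- size[[1]]
    if (2 * r + 2 * margin > min(extent))
      stop("shape exceeds grid (needs a 2-voxel margin)")
    if (is.null(centers)) centers <- ctr
    sd_field <- r - dist3(centers)
    labels_of <- function(occ) array(as.integer(occ > 0.5), grid_shape)
    analytic <- list(volume = 4 / 3 * pi * r^3,
                     lambda1 = 1 / r, lambda2 = 1 / r,
                     mean_curvature = 1 / r, gaussian_curvature = 1 / r^2)
  } else if (shape == "ellipsoid") {
    ax <- size
    stopifnot(length(ax) == 3L)
    if (any(2 * ax + 2 * margin > extent))
      stop("shape exceeds grid (needs a 2-voxel margin)")
    if (is.null(centers)) centers <- ctr
    dx <- (xs - centers[1]); dy <- (ys - centers[2]); dz <- (zs - centers[3])
    rho <- sqrt(outer(outer((dx / ax[1])^2, (dy / ax[2])^2, "+"),
                      (dz / ax[3])^2, "+"))
    # approximate signed distance: (1 - rho) / |grad rho|
    grad <- sqrt(outer(outer((dx / ax[1]^2)^2, (dy / ax[2]^2)^2, "+"),
                       (dz / ax[3]^2)^2, "+")) / pmax(rho, 1e-9)
    sd_field <- (1 - rho) / pmax(grad, 1e-9)
    labels_of <- function(occ) array(as.integer(occ > 0.5), grid_shape)
    analytic <- list(volume = 4 / 3 * pi * prod(ax),
                     pole_x = c(lambda1 = ax[1] / ax[2]^2,
                                lambda2 = ax[1] / ax[3]^2))
  } else if (shape == "cube") {
    h <- if (length(size) == 1L) rep(size, 3L) else size
    if (any(2 * h + 2 * margin > extent))
      stop("shape exceeds grid (needs a 2-voxel margin)")
    if (is.null(centers)) centers <- ctr
    ax1 <- h[1] - abs(xs - centers[1])
    ax2 <- h[2] - abs(ys - centers[2])
    ax3 <- h[3] - abs(zs - centers[3])
    sd_field <- outer(outer(ax1, ax2, pmin), ax3, pmin)
    labels_of <- function(occ) array(as.integer(occ > 0.5), grid_shape)
    analytic <- list(volume = prod(2 * h),
                     face_lambda1 = 0, face_lambda2 = 0)
  } else if (shape == "slab") {
    h <- size[[1]]
    if (2 * h + 2 * margin > extent[3])
      stop("shape exceeds grid (needs a 2-voxel margin)")
    if (is.null(centers)) centers <- ctr
    # finite slab: thick along z, extending to a margin in x and y
    hx <- extent[1] / 2 - margin; hy <- extent[2] / 2 - margin
    ax1 <- hx - abs(xs - centers[1])
    ax2 <- hy - abs(ys - centers[2])
    ax3 <- h - abs(zs - centers[3])
    sd_field <- outer(outer(ax1, ax2, pmin), ax3, pmin)
    labels_of <- function(occ) array(as.integer(occ > 0.5), grid_shape)
    analytic <- list(volume = (2 * hx) * (2 * hy) * (2 * h),
                     face_lambda1 = 0, face_lambda2 = 0)
  } else { # two_blob
    r <- if (length(size) == 1L) rep(size, 2L) else size[1:2]
    if (is.null(centers)) {
      gap <- max(r) # surface-to-surface separation
      centers <- rbind(ctr - c(r[1] + gap / 2, 0, 0),
                       ctr + c(r[2] + gap / 2, 0, 0))
    }
    d1 <- r[1] - dist3(centers[1, ])
    d2 <- r[2] - dist3(centers[2, ])
    if (2 * sum(r) + max(r) + 2 * margin > extent[1])
      stop("shape exceeds grid (needs a 2-voxel margin)")
    sd_field <- pmax(d1, d2)
    labels_of <- function(occ) {
      lab <- array(0L, grid_shape)
      lab[occ > 0.5 & d1 >= d2] <- 1L
      lab[occ > 0.5 & d2 > d1] <- 2L
      lab
    }
    analytic <- list(volume = 4 / 3 * pi * r^3,
                     lambda1 = 1 / r, lambda2 = 1 / r)
  }

  h_eff <- mean(spacing)
  occ <- if (antialias) pmin(1, pmax(0, 0.5 + sd_field / h_eff))
    else (sd_field > 0) * 1
  data <- intensity[[1]] + (intensity[[2]] - intensity[[1]]) * occ
  # noise only within tissue (occupancy > 0): the pipeline consumes
  # brain-masked scans whose background is exactly the background level
  if (noise_sd > 0)
    data <- data + (occ > 0) *
      withr::with_seed(as.integer(seed),
                       array(stats::rnorm(prod(grid_shape), sd = noise_sd),
                             grid_shape))
  lab <- labels_of(occ)
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) stop("phantom produced no tissue voxels")
  region_table <- data.frame(label_id = ids,
                             region_name = paste0("synthetic_region_", ids))
  list(vol = volume_grid(array(data, grid_shape), affine),
       atlas = label_volume(lab, region_table, affine),
       analytic = analytic,
       spec = list(shape = shape, size = size, grid_shape = grid_shape,
                   spacing = spacing, intensity = intensity,
                   noise_sd = noise_sd, antialias = antialias,
                   seed = as.integer(seed), centers = centers))
}

#' Generate a two-group synthetic cohort of regional feature tables
#'
#' Emulates the study's two-group design (60 NC / 86 MCI at baseline):
#' for every subject and region the five regional features are drawn from a
#' common-factor Gaussian model, `x_f = mu_f + sigma_f (loading * g +
#' noise_sd * eps_f)` with one latent factor `g` per subject x region, so
#' the five features of a region are positively correlated as they are in
#' real cortical data. In the MCI group, every feature of each affected
#' region is shifted by `effect_size` pooled standard deviations
#' (downward — emulating atrophy-driven loss of curvature and volume).
#' Feature baselines are on realistic scales (curvatures in 1/mm and
#' 1/mm^2, volume in mm^3) so the min-max normalization step is exercised
#' on mixed units.
#'
#' @param n_per_group Named counts `c(nc = 60, mci = 86)` (the study's
#'   baseline cohort).
#' @param n_regions Number of cortical regions (default 76; region ids are
#'   taken from the packaged AAL table when `n_regions == 76`).
#' @param affected_regions Indices (1..n_regions) of regions carrying the
#'   planted effect; default the first 5.
#' @param effect_size Shift in pooled-sd units (default 3).
#' @param loading Common-factor loading in (0, 1) (default 0.5).
#' @param noise_sd Residual scale; default `sqrt(1 - loading^2)` so each
#'   standardized feature has unit variance.
#' @param seed Integer seed; generation is reproducible.
#' @return List: `table` (raw [region_feature_table()]), `labels` (factor
#'   NC/MCI), `ground_truth` (affected region ids, parameters, per-feature
#'   baselines).
#' @export
make_cohort <- function(n_per_group = c(nc = 60L, mci = 86L),
                        n_regions = 76L,
                        affected_regions = seq_len(5L),
                        effect_size = 3,
                        loading = 0.5,
                        noise_sd = sqrt(1 - loading^2),
                        seed = 1L) {
  stopifnot(effect_size >= 0, all(n_per_group >= 2L),
            all(affected_regions >= 1L),
            all(affected_regions <= n_regions))
  n_nc <- as.integer(n_per_group[[1]]); n_mci <- as.integer(n_per_group[[2]])
  n <- n_nc + n_mci
  labels <- factor(rep(c("NC", "MCI"), c(n_nc, n_mci)),
                   levels = c("NC", "MCI"))
  region_ids <- if (n_regions == 76L) aal_region_table()$label_id
    else seq_len(n_regions)
  # realistic baseline scales for (gaussian 1/mm^2, mean 1/mm,
  # sharpness 1/mm^2, curvedness 1/mm, volume mm^3)
  mu <- c(0.012, 0.11, 0.02, 0.13, 9000)
  sigma <- c(0.004, 0.02, 0.006, 0.02, 1500)
  pooled_sd <- sqrt(loading^2 + noise_sd^2)

  arr <- withr::with_seed(as.integer(seed), {
    g <- array(stats::rnorm(n * n_regions), c(n, n_regions))
    eps <- array(stats::rnorm(n * n_regions * 5L), c(n, n_regions, 5L))
    std <- loading * array(rep(g, 5L), c(n, n_regions, 5L)) + noise_sd * eps
    for (r in affected_regions)
      std[labels == "MCI", r, ] <- std[labels == "MCI", r, ] -
        effect_size * pooled_sd
    out <- std
    for (k in 1:5) out[, , k] <- mu[k] + sigma[k] * std[, , k]
    out
  })
  tab <- region_feature_table(arr,
                              subjects = sprintf("S%03d", seq_len(n)),
                              regions = region_ids)
  list(table = tab, labels = labels,
       ground_truth = list(affected_regions = region_ids[affected_regions],
                           affected_index = affected_regions,
                           effect_size = effect_size, loading = loading,
                           noise_sd = noise_sd, pooled_sd = pooled_sd,
                           mu = mu, sigma = sigma,
                           n_per_group = c(nc = n_nc, mci = n_mci),
                           seed = as.integer(seed)))
}
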