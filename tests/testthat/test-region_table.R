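test_that("vertex labelling looks up the containing atlas voxel", {
  lab <- array(0L, c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 4L
  atlas <- label_volume(lab, data.frame(label_id = 4L, region_name = "r4"))
  # a vertex exactly at the centre of a labelled voxel (0-based index 3,3,3)
  mesh <- trimesh(rbind(c(3, 3, 3), c(100, 100, 100), c(3.2, 3.1, 2.9)),
                  rbind(c(1, 2, 3)))
  expect_message(labs <- label_vertices(mesh, atlas), "outside")
  expect_identical(labs, c(4L, 0L, 4L))
})

test_that("every vertex receives exactly one label; blobs never swap labels", {
  ph <- make_phantom("two_blob", size = c(5, 4), grid_shape = c(48L, 24L, 24L),
                     seed = 2L)
  mesh <- marching_cubes(ph$vol, select_isovalue(ph$vol))
  labs <- label_vertices(mesh, ph$atlas)
  expect_identical(length(labs), nrow(mesh$vertices))
  comp <- mesh_components(mesh)
  # each connected component maps to one blob label (0 allowed at fringes)
  for (cp in unique(comp)) {
    got <- setdiff(unique(labs[comp == cp]), 0L)
    expect_identical(length(got), 1L)
  }
  expect_setequal(setdiff(unique(labs), 0L), c(1L, 2L))
})

test_that("regional surface volumes match voxel-count and additivity oracles", {
  # 10x10x10-voxel cubic region at unit spacing
  arr <- array(0, c(20, 20, 20))
  arr[6:15, 6:15, 6:15] <- 100
  lab <- array(0L, c(20, 20, 20))
  lab[6:15, 6:15, 6:15] <- 1L
  vg <- volume_grid(arr)
  atlas <- label_volume(lab, data.frame(label_id = 1L, region_name = "c"))
  expect_rel_error(region_surface_volume(vg, atlas, 1L, 50), 1000, 0.08)
  # empty region is flagged missing, not zero
  atlas2 <- label_volume(lab, data.frame(label_id = c(1L, 2L),
                                         region_name = c("c", "empty")))
  expect_true(is.na(region_surface_volume(vg, atlas2, 2L, 50)))

  # two regions partitioning a ball: volumes add up to the whole-ball mesh
  fix <- ball_fixture()
  ph <- fix$phantom
  lab2 <- ph$atlas$labels
  half <- slice.index(lab2, 1) <= dim(lab2)[1] / 2
  lab2[lab2 == 1L & !half] <- 2L
  atlas3 <- label_volume(lab2, data.frame(label_id = 1:2,
                                          region_name = c("a", "b")),
                         ph$vol$affine)
  v1 <- region_surface_volume(ph$vol, atlas3, 1L, fix$alpha)
  v2 <- region_surface_volume(ph$vol, atlas3, 2L, fix$alpha)
  expect_rel_error(v1 + v2, mesh_signed_volume(fix$mesh), 0.05)
})

test_that("aggregation means per-vertex descriptors and flags thin regions", {
  shapes <- data.frame(gaussian = rep(0.01, 30), mean = rep(0.1, 30),
                       sharpness = rep(0, 30), curvedness = rep(0.1, 30))
  labs <- c(rep(1L, 25), rep(2L, 3), rep(0L, 2))
  vols <- c(`1` = 500, `2` = 40)
  row <- aggregate_region_features(shapes, labs, vols, regions = c(1L, 2L))
  expect_equal(unname(row["1", ]), c(0.01, 0.1, 0, 0.1, 500))
  expect_true(all(is.na(row["2", ])))  # < 10 vertices -> flagged missing
  expect_error(aggregate_region_features(shapes, rep(0L, 30), vols, 1L),
               "no labelled")

  # ball phantom, single region: aggregated mean curvature ~ 1/R
  fix <- ball_fixture()
  labs2 <- label_vertices(fix$mesh, fix$phantom$atlas)
  vol <- c(`1` = mesh_signed_volume(fix$mesh))
  row2 <- aggregate_region_features(fix$shapes, labs2, vol, regions = 1L)
  expect_rel_error(row2["1", "mean"], 1 / 10, 0.15)
})

test_that("min-max normalization follows the closed form with frozen stats", {
  arr <- array(NA_real_, c(3, 1, 5))
  arr[, 1, ] <- cbind(c(2, 4, 6), c(7, 7, 7), c(0, 1, 2), c(1, 2, 3),
                      c(100, 300, 200))
  tab <- region_feature_table(arr, regions = 1L)
  expect_warning(norm <- normalize_features(tab), "constant")
  expect_equal(norm$features[, 1, 1], c(0, 0.5, 1),
               ignore_attr = TRUE)
  expect_equal(norm$features[, 1, 2], c(0.5, 0.5, 0.5),
               ignore_attr = TRUE)
  expect_true(all(norm$features >= 0 & norm$features <= 1))

  # frozen stats on held-out data, clipped to [0, 1]
  arr2 <- arr
  arr2[1, 1, 1] <- -100   # below training min -> 0
  arr2[2, 1, 1] <- 1000   # above training max -> 1
  test_tab <- region_feature_table(arr2, regions = 1L)
  out <- apply_normalization(test_tab, norm$norm_stats)
  expect_equal(out$features[1, 1, 1], 0)
  expect_equal(out$features[2, 1, 1], 1)

  # renormalizing normalized values with their own min-max is the identity
  renorm <- suppressWarnings(
    normalize_features(region_feature_table(norm$features, regions = 1L)))
  expect_equal(renorm$features, norm$features, tolerance = 1e-12)

  expect_error(normalize_features(
    region_feature_table(arr[1, , , drop = FALSE], regions = 1L)),
    "2 subjects")
})

test_that("missing cells are imputed with training column means", {
  co <- small_cohort()
  norm <- normalize_features(co$table)
  arr <- norm$features
  arr[1, 2, 3] <- NA_real_
  tab <- region_feature_table(arr, co$table$subjects, co$table$regions,
                              normalized = TRUE, norm_stats = norm$norm_stats)
  expect_message(imp <- impute_missing(tab), "1 missing")
  expect_equal(imp$features[1, 2, 3], norm$norm_stats$col_means[2, 3])
})

test_that("feature tables round-trip through tidy CSV", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(co$table, path)
  back <- read_feature_table(path)
  expect_equal(back$features, co$table$features, tolerance = 1e-12)
  expect_identical(back$regions, co$table$regions)
  # wide format writes one column per region x feature
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(co$table, path2, format = "wide")
  hdr <- names(utils::read.csv(path2, nrows = 1, check.names = FALSE))
  expect_identical(length(hdr), 1L + 12L * 5L)
})
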