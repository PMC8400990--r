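#' Vertex adjacency list of a mesh
#'
#' @param mesh A [trimesh()].
#' @return List of integer vectors: sorted neighbour indices per vertex.
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  lapply(split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices)))),
         sort)
}

#' Vertices within a ring neighbourhood
#'
#' All vertices within `rings` edge hops of vertex `v`, excluding `v`
#' itself, in ascending index order.
#'
#' @param mesh A [trimesh()].
#' @param v Vertex index.
#' @param rings Number of edge hops (>= 1).
#' @param adj Optional precomputed [vertex_adjacency()] list.
#' @return Integer vector of vertex indices.
#' @export
vertex_neighborhood <- function(mesh, v, rings = 2L, adj = NULL) {
  stopifnot(rings >= 1L)
  if (is.null(adj)) adj <- vertex_adjacency(mesh)
  frontier <- adj[[v]]
  if (length(frontier) == 0L)
    stop("vertex ", v, " is isolated (no incident faces)")
  seen <- c(v, frontier)
  if (rings > 1L) {
    for (r in 2:rings) {
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                          seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
  }
  sort(setdiff(seen, v))
}

#' Rotate points into the tangent frame of a vertex
#'
#' Rigid map taking `origin` to (0, 0, 0) and `normal` to the local height
#' axis (third coordinate), so the surface patch around the vertex is
#' described as a height field over the tangent (x, y) plane. The two
#' tangent axes complete a right-handed orthonormal frame; which tangent
#' directions are chosen is immaterial for the curvatures derived from the
#' fitted patch.
#'
#' @param points N x 3 matrix of world coordinates.
#' @param origin Length-3 vertex coordinate.
#' @param normal Length-3 unit vector.
#' @return N x 3 matrix of local (x, y, height) coordinates; the 3 x 3 frame
#'   (rows: tangent1, tangent2, normal) is attached as attribute `"basis"`.
#' @export
rotate_to_normal_frame <- function(points, origin, normal) {
  nlen <- sqrt(sum(normal^2))
  if (nlen < 1e-12) stop("zero normal")
  if (abs(nlen - 1) > 1e-6) stop("normal must have unit length")
  n <- normal / nlen
  seed <- diag(3)[, which.min(abs(n))]
  t1 <- seed - sum(seed * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  basis <- rbind(t1, t2, n)
  dimnames(basis) <- NULL
  pts <- sweep(rbind(points), 2L, origin)
  local <- pts %*% t(basis)
  dimnames(local) <- NULL
  attr(local, "basis") <- basis
  local
}

#' Least-squares quadric patch fit
#'
#' Fits `f(x, y) = a x^2 + b y^2 + c x y + d x + e y + f` to local
#' (x, y, height) samples in the least-squares sense; exact when the points
#' lie on a quadric.
#'
#' @param local_points N x 3 matrix of (x, y, height) triples, N >= 6.
#' @return Named numeric vector `(a, b, c, d, e, f)`.
#' @export
fit_quadric_patch <- function(local_points) {
  local_points <- rbind(local_points)
  if (nrow(local_points) < 6L)
    stop("need at least 6 points; increase rings")
  x <- local_points[, 1]; y <- local_points[, 2]; h <- local_points[, 3]
  X <- cbind(x^2, y^2, x * y, x, y, 1)
  qr_x <- qr(X)
  if (qr_x$rank < 6L)
    stop("rank-deficient neighbourhood; increase rings")
  coef <- qr.coef(qr_x, h)
  stats::setNames(as.vector(coef), c("a", "b", "c", "d", "e", "f"))
}

#' Principal curvatures from quadric coefficients
#'
#' With the patch anchored at the vertex in its tangent frame the linear
#' terms d, e are near zero and the shape operator reduces to the Hessian
#' form `[[2a, c], [c, 2b]]`, whose eigenvalues are the principal
#' curvatures. When the fitted tangent plane is appreciably tilted
#' (sqrt(d^2 + e^2) > 0.05) the full first-fundamental-form correction is
#' applied:
#' the shape operator becomes `I^-1 II` with `I = [[1+d^2, de], [de, 1+e^2]]`
#' and `II = [[2a, c], [c, 2b]] / sqrt(1 + d^2 + e^2)`.
#'
#' @param coeffs Named vector `(a, b, c, d, e, f)` from
#'   [fit_quadric_patch()]; `d`, `e`, `f` may be omitted (treated as 0).
#' @return List with `lambda1 >= lambda2` (1/distance units) and `dir1`,
#'   `dir2`, unit principal directions in the local tangent (x, y) plane.
#' @export
principal_curvatures <- function(coeffs) {
  a <- coeffs[["a"]]; b <- coeffs[["b"]]; cc <- coeffs[["c"]]
  d <- if ("d" %in% names(coeffs)) coeffs[["d"]] else 0
  e <- if ("e" %in% names(coeffs)) coeffs[["e"]] else 0
  H <- matrix(c(2 * a, cc, cc, 2 * b), 2L)
  # rotation-invariant tilt criterion (L2 norm of the fitted gradient)
  if (sqrt(d^2 + e^2) > 0.05) {
    w <- sqrt(1 + d^2 + e^2)
    I1 <- matrix(c(1 + d^2, d * e, d * e, 1 + e^2), 2L)
    S <- solve(I1, H / w)
    ev <- eigen(S)
  } else {
    ev <- eigen(H, symmetric = TRUE)
  }
  ord <- order(Re(ev$values), decreasing = TRUE)
  vals <- Re(ev$values)[ord]
  vecs <- Re(ev$vectors)[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
  list(lambda1 = vals[1], lambda2 = vals[2],
       dir1 = vecs[, 1], dir2 = vecs[, 2])
}

#' Curvature shape descriptors
#'
#' The four rotation-invariant descriptors evaluated from the principal
#' curvatures: Gaussian curvature `lambda1 * lambda2`, mean curvature
#' `(lambda1 + lambda2) / 2`, sharpness `(lambda1 - lambda2)^2` and
#' curvedness `sqrt((lambda1^2 + lambda2^2) / 2)`.
#'
#' @param lambda1,lambda2 Principal curvatures, `lambda1 >= lambda2`.
#' @return Named numeric vector `(gaussian, mean, sharpness, curvedness)`.
#' @export
shape_descriptors <- function(lambda1, lambda2) {
  c(gaussian = lambda1 * lambda2,
    mean = (lambda1 + lambda2) / 2,
    sharpness = (lambda1 - lambda2)^2,
    curvedness = sqrt((lambda1^2 + lambda2^2) / 2))
}

#' Per-vertex curvature descriptors of a mesh
#'
#' For each vertex, collects its ring neighbourhood, rotates it into the
#' tangent frame (heights measured along the inward normal, so convex tissue
#' has positive principal curvatures: a ball of radius R gets mean curvature
#' +1/R), fits the least-squares quadric and evaluates the principal
#' curvatures and the four shape descriptors. Rank-deficient or too-small
#' neighbourhoods escalate the ring count up to `max_rings` before failing.
#'
#' @param mesh A [trimesh()] with outward normals.
#' @param rings Neighbourhood radius in edge hops (default 5).
#' @param max_rings Escalation cap for degenerate fits (default 7).
#' @return data.frame with one row per vertex: `vertex_id`, `x`, `y`, `z`,
#'   `lambda1`, `lambda2`, `gaussian`, `mean`, `sharpness`, `curvedness`,
#'   plus `dir1_*`, `dir2_*` world-coordinate principal directions.
#' @export
mesh_shape_features <- function(mesh, rings = 5L, max_rings = 7L) {
  n <- nrow(mesh$vertices)
  adj <- vertex_adjacency(mesh)
  out <- matrix(NA_real_, n, 12L)
  nrm <- mesh$normals
  for (v in seq_len(n)) {
    r <- rings
    repeat {
      nb <- vertex_neighborhood(mesh, v, rings = r, adj = adj)
      pts <- mesh$vertices[c(v, nb), , drop = FALSE]
      local <- rotate_to_normal_frame(pts, mesh$vertices[v, ], -nrm[v, ])
      fit <- try(fit_quadric_patch(local), silent = TRUE)
      if (!inherits(fit, "try-error")) break
      r <- r + 1L
      if (r > max_rings)
        stop("degenerate neighbourhood at vertex ", v,
             " even with rings = ", max_rings)
    }
    pc <- principal_curvatures(fit)
    basis <- attr(local, "basis")
    d1 <- pc$dir1[1] * basis[1, ] + pc$dir1[2] * basis[2, ]
    d2 <- pc$dir2[1] * basis[1, ] + pc$dir2[2] * basis[2, ]
    out[v, ] <- c(pc$lambda1, pc$lambda2,
                  shape_descriptors(pc$lambda1, pc$lambda2), d1, d2)
  }
  data.frame(vertex_id = seq_len(n),
             x = mesh$vertices[, 1], y = mesh$vertices[, 2],
             z = mesh$vertices[, 3],
             lambda1 = out[, 1], lambda2 = out[, 2],
             gaussian = out[, 3], mean = out[, 4],
             sharpness = out[, 5], curvedness = out[, 6],
             dir1_x = out[, 7], dir1_y = out[, 8], dir1_z = out[, 9],
             dir2_x = out[, 10], dir2_y = out[, 11], dir2_z = out[, 12])
}

#' Write per-vertex shape features as CSV
#'
#' @param features data.frame from [mesh_shape_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_features <- function(features, path) {
  utils::write.csv(features[, c("vertex_id", "x", "y", "z", "lambda1",
                                "lambda2", "gaussian", "mean", "sharpness",
                                "curvedness")],
                   path, row.names = FALSE)
  invisible(path)
}
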