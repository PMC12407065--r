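#' Minimal convex hull of a 3-D point set
#'
#' Randomised-incremental (beneath-beyond) convex hull. Facets are maintained
#' with outward-consistent orientation; volume is the sum of signed tetrahedra
#' spanned by the facets and an interior reference point, and the centroid is
#' the volume-weighted mean of those tetrahedra's centroids.
#'
#' @param pts n x 3 numeric matrix of points (n >= 4, not all coplanar).
#' @param tol degeneracy tolerance on simplex volume, relative to the cube of
#'   the point cloud's bounding-box diagonal. Inputs whose best initial
#'   tetrahedron falls below it are rejected as coplanar/collinear.
#' @return A list of class `"hull3d"` with elements `vertices` (m x 3 matrix of
#'   hull vertex coordinates), `faces` (f x 3 index matrix into `vertices`,
#'   outward oriented), `normals` (f x 3 unit outward normals), `offsets`
#'   (plane offsets so a point `p` is inside iff `normals %*% p <= offsets`),
#'   `volume` and `centroid`.
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
#' h <- convex_hull_3d(cube)
#' h$volume    # 1
#' h$centroid  # (0.5, 0.5, 0.5)
convex_hull_3d <- function(pts, tol = 1e-12) {
  pts <- .as_vertex_matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points for a 3-D hull", call. = FALSE)

  rng <- apply(pts, 2L, range)
  diam <- sqrt(sum((rng[2L, ] - rng[1L, ])^2))
  if (diam <= 0) stop("degenerate input: all points coincide", call. = FALSE)
  vol_tol <- tol * diam^3
  # visibility threshold: distance from facet plane, relative to cloud size
  dist_tol <- 1e-10 * diam

  init <- .initial_simplex(pts, vol_tol, diam)
  if (is.null(init)) {
    stop("degenerate input: points are collinear or coplanar", call. = FALSE)
  }

  # face store (grown geometrically); each face is a vertex-index triple with
  # precomputed unit outward normal and plane offset
  cap <- 256L
  fv <- matrix(NA_integer_, cap, 3L)
  fn <- matrix(NA_real_, cap, 3L)
  fo <- rep(NA_real_, cap)
  alive <- logical(cap)
  nf <- 0L

  interior <- colMeans(pts[init, , drop = FALSE])

  add_face <- function(i, j, k) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    len <- sqrt(sum(nrm^2))
    if (len < .Machine$double.eps) return(invisible(NULL))
    nrm <- nrm / len
    # orient outward w.r.t. the interior point
    if (sum(nrm * (interior - a)) > 0) {
      tmp <- j; j <- k; k <- tmp
      nrm <- -nrm
    }
    nf <<- nf + 1L
    if (nf > nrow(fv)) {
      grow <- nrow(fv)
      fv <<- rbind(fv, matrix(NA_integer_, grow, 3L))
      fn <<- rbind(fn, matrix(NA_real_, grow, 3L))
      fo <<- c(fo, rep(NA_real_, grow))
      alive <<- c(alive, logical(grow))
    }
    fv[nf, ] <<- c(i, j, k)
    fn[nf, ] <<- nrm
    fo[nf] <<- sum(nrm * a)
    alive[nf] <<- TRUE
    invisible(NULL)
  }

  cmb <- utils::combn(4L, 3L)
  for (c_i in seq_len(ncol(cmb))) {
    tri <- init[cmb[, c_i]]
    add_face(tri[1L], tri[2L], tri[3L])
  }

  order_rest <- setdiff(seq_len(n), init)
  for (p_i in order_rest) {
    p <- pts[p_i, ]
    live <- which(alive[seq_len(nf)])
    d <- fn[live, , drop = FALSE] %*% p - fo[live]
    vis <- live[d > dist_tol]
    if (length(vis) == 0L) next  # interior (or on-surface) point

    # horizon: directed edges of visible faces whose reverse edge is not visible
    tris <- fv[vis, , drop = FALSE]
    e_from <- c(tris[, 1L], tris[, 2L], tris[, 3L])
    e_to   <- c(tris[, 2L], tris[, 3L], tris[, 1L])
    keys <- paste(e_from, e_to)
    rev_keys <- paste(e_to, e_from)
    horizon <- !(rev_keys %in% keys)
    alive[vis] <- FALSE
    hf <- e_from[horizon]; ht <- e_to[horizon]
    for (e_i in seq_along(hf)) add_face(hf[e_i], ht[e_i], p_i)
  }

  live <- which(alive[seq_len(nf)])
  faces_raw <- fv[live, , drop = FALSE]
  used <- sort(unique(as.vector(faces_raw)))
  remap <- integer(n); remap[used] <- seq_along(used)
  verts <- pts[used, , drop = FALSE]
  faces <- matrix(remap[faces_raw], ncol = 3L)

  # signed-tetrahedra volume and centroid against an interior reference point
  o <- colMeans(verts)
  a <- verts[faces[, 1L], , drop = FALSE]
  b <- verts[faces[, 2L], , drop = FALSE]
  c3 <- verts[faces[, 3L], , drop = FALSE]
  a <- sweep(a, 2L, o); b <- sweep(b, 2L, o); c3 <- sweep(c3, 2L, o)
  v6 <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
        a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
        a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  vol <- sum(v6) / 6
  if (vol <= vol_tol) stop("degenerate input: hull volume not positive", call. = FALSE)
  tet_cent <- (a + b + c3) / 4  # relative to o
  centroid <- o + colSums(tet_cent * v6) / sum(v6)

  structure(list(vertices = verts,
                 faces = faces,
                 normals = fn[live, , drop = FALSE],
                 offsets = fo[live],
                 volume = vol,
                 centroid = centroid),
            class = "hull3d")
}

# best-conditioned initial tetrahedron, or NULL if all points are coplanar
.initial_simplex <- function(pts, vol_tol, diam) {
  n <- nrow(pts)
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) { i1 <- 1L; i2 <- which.max(rowSums(sweep(pts, 2L, pts[1L, ])^2)) }
  if (i1 == i2) return(NULL)
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  crossn2 <- (rel[, 2L] * ab[3L] - rel[, 3L] * ab[2L])^2 +
             (rel[, 3L] * ab[1L] - rel[, 1L] * ab[3L])^2 +
             (rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L])^2
  i3 <- which.max(crossn2)
  if (crossn2[i3] <= (1e-12 * diam^2)^2) return(NULL)
  nvec <- c(rel[i3, 2L] * ab[3L] - rel[i3, 3L] * ab[2L],
            rel[i3, 3L] * ab[1L] - rel[i3, 1L] * ab[3L],
            rel[i3, 1L] * ab[2L] - rel[i3, 2L] * ab[1L])
  # nvec = ac x ab; |rel . nvec| / 6 is tetra volume against triangle (i1,i2,i3)
  h <- abs(rel %*% nvec) / 6
  i4 <- which.max(h)
  if (h[i4] <= vol_tol) return(NULL)
  c(i1, i2, i3, i4)
}

#' Test whether points lie inside (or on) a convex hull
#'
#' @param hull a `"hull3d"` object.
#' @param pts n x 3 matrix of query points.
#' @param tol slack on the facet-plane inequalities, in absolute distance.
#' @return logical vector of length n.
#' @export
in_hull <- function(hull, pts, tol = 1e-9) {
  stopifnot(inherits(hull, "hull3d"))
  pts <- .as_vertex_matrix(pts, "query points")
  d <- hull$normals %*% t(pts) - hull$offsets
  apply(d <= tol, 2L, all)
}

#' @export
print.hull3d <- function(x, ...) {
  cat("3-D convex hull:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "facets\n  volume:", format(x$volume), "m^3\n  centroid:",
      paste(format(x$centroid, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Convex hull of one skeletal segment
#'
#' Wraps [convex_hull_3d()] with segment metadata. The hull centroid doubles as
#' the segment's centre of mass under the uniform within-segment density
#' assumption; the later expansion step scales volume but keeps this centroid
#' fixed.
#'
#' @param segment a `segment_mesh` (see [segment_mesh()]).
#' @param tol degeneracy tolerance, see [convex_hull_3d()].
#' @return A list of class `"segment_hull"`: segment metadata plus `hull`
#'   (the `hull3d`), `volume` (m^3) and `centroid` (m, body frame).
#' @export
compute_hull <- function(segment, tol = 1e-12) {
  stopifnot(inherits(segment, "segment_mesh"))
  h <- tryCatch(convex_hull_3d(segment$vertices, tol = tol),
                error = function(e) {
                  stop("segment '", segment$id, "': ", conditionMessage(e),
                       call. = FALSE)
                })
  structure(list(id = segment$id,
                 segment_class = segment$segment_class,
                 side = segment$side,
                 subdivision = segment$subdivision,
                 hull = h,
                 volume = h$volume,
                 centroid = h$centroid),
            class = "segment_hull")
}

#' Hull every segment of a skeleton
#'
#' @param manifest a `skeleton_manifest` from [load_skeleton()] or
#'   [skeleton_manifest()].
#' @param tol degeneracy tolerance, see [convex_hull_3d()].
#' @return A list of class `"segment_hull_set"` of `segment_hull` objects,
#'   named by segment id. `as.data.frame()` gives the summary table
#'   (id, class, side, subdivision, volume, centroid coordinates).
#' @export
hull_all <- function(manifest, tol = 1e-12) {
  stopifnot(inherits(manifest, "skeleton_manifest"))
  hulls <- lapply(manifest$segments, compute_hull, tol = tol)
  names(hulls) <- vapply(hulls, `[[`, "", "id")
  structure(hulls, class = "segment_hull_set", taxon = manifest$taxon)
}

#' @export
as.data.frame.segment_hull_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(h) {
    data.frame(id = h$id, class = h$segment_class, side = h$side,
               subdivision = h$subdivision, volume = h$volume,
               centroid_x = h$centroid[1L], centroid_y = h$centroid[2L],
               centroid_z = h$centroid[3L], stringsAsFactors = FALSE)
  }))
}

#' @export
print.segment_hull_set <- function(x, ...) {
  cat("Segment hulls for", attr(x, "taxon"), "(", length(x), "segments )\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Export a hull as a Wavefront OBJ mesh for inspection
#'
#' @param hull a `hull3d` or `segment_hull`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hull_obj <- function(hull, path) {
  if (inherits(hull, "segment_hull")) hull <- hull$hull
  stopifnot(inherits(hull, "hull3d"))
  write_obj_mesh(hull$vertices, path, faces = hull$faces)
}
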