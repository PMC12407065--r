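# Shared fixtures and independent oracles.

unit_cube_pts <- function(origin = c(0, 0, 0), edge = 1) {
  sweep(as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge))),
        2L, origin, `+`)
}

# regular tetrahedron, unit edge; volume 1/(6*sqrt(2))
regular_tet_pts <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
        c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

# Monte-Carlo volume/centroid oracle: uniform samples in the hull's bounding
# box, membership by facet-plane inequalities. Independent of the
# signed-tetrahedra computation under test.
mc_hull_oracle <- function(hull, n = 1e6, seed = 42, chunk = 1e5) {
  set.seed(seed)
  bb <- apply(hull$vertices, 2L, range)
  vbox <- prod(bb[2L, ] - bb[1L, ])
  n_in <- 0; csum <- c(0, 0, 0)
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    s <- cbind(runif(m, bb[1L, 1L], bb[2L, 1L]),
               runif(m, bb[1L, 2L], bb[2L, 2L]),
               runif(m, bb[1L, 3L], bb[2L, 3L]))
    inside <- in_hull(hull, s)
    n_in <- n_in + sum(inside)
    csum <- csum + colSums(s[inside, , drop = FALSE])
    done <- done + m
  }
  p <- n_in / n
  list(volume = p * vbox,
       volume_se = vbox * sqrt(p * (1 - p) / n),
       centroid = csum / n_in,
       # SE of a mean of uniforms within the box, conservative per axis
       centroid_se = (bb[2L, ] - bb[1L, ]) / sqrt(12 * n_in))
}

# Explicit GLS / weighted-Laplacian oracle for Brownian ancestral states:
# ML states minimise sum over edges of (x_child - x_parent)^2 / length,
# i.e. solve a linear system with tips clamped. Independent of fastAnc.
anc_gls_oracle <- function(tree, tip_values) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  x <- tip_values[tree$tip.label]
  A <- matrix(0, nnode, nnode)
  b <- rep(0, nnode)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    w <- 1 / tree$edge.length[e]
    iu <- u - ntip
    A[iu, iu] <- A[iu, iu] + w
    if (v > ntip) {
      iv <- v - ntip
      A[iv, iv] <- A[iv, iv] + w
      A[iu, iv] <- A[iu, iv] - w
      A[iv, iu] <- A[iv, iu] - w
    } else {
      b[iu] <- b[iu] + w * x[v]
    }
  }
  stats::setNames(drop(solve(A, b)), ntip + seq_len(nnode))
}

# Whitened-OLS oracle for Brownian PGLS coefficients.
pgls_oracle <- function(tree, y, x, taxa) {
  C <- ape::vcv(tree)[taxa, taxa]
  L <- t(chol(C))           # C = L %*% t(L)
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, cbind(1, x))
  qr.solve(Xw, yw)          # (intercept, slope)
}

# small two-box skeleton for mass/COM hand computations; boxes of given
# centres/sizes and classes, glenoid anterodorsal of the acetabulum
box_skeleton <- function(specs, acetabulum = c(0, 0, 0),
                         glenoid = c(1, 0, 0.5), taxon = "toy",
                         posture = "quadruped") {
  segs <- lapply(specs, function(s) {
    half <- s$size / 2
    corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    segment_mesh(sweep(corners %*% diag(half), 2L, s$center, `+`),
                 class = s$class,
                 side = if (is.null(s$side)) "midline" else s$side,
                 subdivision = if (is.null(s$subdivision)) 1L else s$subdivision)
  })
  skeleton_manifest(taxon, segs, acetabulum, glenoid, posture = posture)
}

# uniform isometric scaling table (k for every class, both sources)
flat_scaling_table <- function(k = 1, mppe = 0, k_bird = k) {
  cls <- setdiff(segment_classes()$class, c("ornament", "osteoderm", "sail"))
  structure(c(
    lapply(cls, function(cl) scaling_model(cl, "NAS", "isometric",
                                           k = k, mppe = mppe)),
    lapply(setdiff(cls, "tail"),
           function(cl) scaling_model(cl, "bird", "isometric",
                                      k = k_bird, mppe = mppe))
  ), class = "scaling_table")
}
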