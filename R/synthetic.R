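#' Body-plan template for synthetic skeletons
#'
#' A template lists geometric primitives (one per segment) whose convex-hull
#' volumes and centroids are analytically known, plus landmarks and posture.
#' Supported shapes:
#'
#' * `box` — fields `center`, `size` (edge lengths); emitted as its 8 corners.
#'   Hull volume and centroid are exact.
#' * `frustum` — fields `base`, `axis` (unit direction), `h`, `r1`, `r2`,
#'   `n_theta`; emitted as two aligned `n_theta`-gon rings. The hull is a
#'   polygonal frustum with exact volume
#'   `(n/2) sin(2 pi/n) (r1^2 + r1 r2 + r2^2) h / 3` and exact centroid on the
#'   axis, converging to the circular frustum as `n_theta` grows.
#' * `ellipsoid` — fields `center`, `semi` (semi-axes), `n`; emitted as `n`
#'   pseudo-random surface points. The hull volume has no closed form but is
#'   bounded above by the solid volume `4/3 pi a b c`, which it approaches as
#'   `n` grows (curved solids are emitted as dense clouds because hulls are
#'   polytopes).
#'
#' @param segments list of shape specs; each also carries `class`, `side`
#'   (default `"midline"`) and `subdivision` (default 1).
#' @param acetabulum,glenoid landmark points (must be distinct).
#' @param posture `"biped"` or `"quadruped"`.
#' @param tail_in_torso bird-convention flag.
#' @param name template label.
#' @return object of class `"body_plan_template"`.
#' @export
body_plan_template <- function(segments, acetabulum, glenoid,
                               posture = "quadruped", tail_in_torso = FALSE,
                               name = "custom") {
  acetabulum <- .as_point3(acetabulum, "acetabulum")
  glenoid <- .as_point3(glenoid, "glenoid")
  if (all(acetabulum == glenoid)) {
    stop("overlapping landmark definitions: acetabulum equals glenoid",
         call. = FALSE)
  }
  stopifnot(length(segments) >= 1L)
  for (s in segments) {
    if (!s$shape %in% c("box", "frustum", "ellipsoid")) {
      stop("unknown primitive shape: ", s$shape, call. = FALSE)
    }
    .check_segment_class(s$class)
  }
  structure(list(name = name, segments = segments, acetabulum = acetabulum,
                 glenoid = glenoid, posture = posture,
                 tail_in_torso = isTRUE(tail_in_torso)),
            class = "body_plan_template")
}

# ---- primitive emitters: points + exact truth -------------------------------

.emit_box <- function(s) {
  half <- s$size / 2
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  pts <- sweep(corners %*% diag(half), 2L, s$center, `+`)
  list(pts = pts, volume_exact = prod(s$size), centroid_exact = s$center,
       volume_solid = prod(s$size))
}

.frustum_frame <- function(axis) {
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  list(u = u, v = v, w = w)
}

.emit_frustum <- function(s) {
  n <- if (is.null(s$n_theta)) 64L else as.integer(s$n_theta)
  fr <- .frustum_frame(s$axis)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ring <- function(center, r) {
    t(vapply(th, function(a) center + r * (cos(a) * fr$v + sin(a) * fr$w),
             numeric(3)))
  }
  top_center <- s$base + s$h * fr$u
  pts <- rbind(ring(s$base, s$r1), ring(top_center, s$r2))
  cpoly <- n / 2 * sin(2 * pi / n)  # polygon area = cpoly * r^2
  q <- s$r1^2 + s$r1 * s$r2 + s$r2^2
  vol <- cpoly * q * s$h / 3
  zbar <- s$h * (s$r1^2 + 2 * s$r1 * s$r2 + 3 * s$r2^2) / (4 * q)
  list(pts = pts, volume_exact = vol, centroid_exact = s$base + zbar * fr$u,
       volume_solid = pi * q * s$h / 3)
}

.emit_ellipsoid <- function(s) {
  n <- if (is.null(s$n)) 500L else as.integer(s$n)
  dirs <- matrix(stats::rnorm(3L * n), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs %*% diag(s$semi), 2L, s$center, `+`)
  list(pts = pts, volume_exact = NA_real_, centroid_exact = s$center,
       volume_solid = 4 / 3 * pi * prod(s$semi))
}

#' Generate a synthetic skeleton with analytic hull truths
#'
#' Instantiates a [body_plan_template()] as an in-memory
#' [skeleton_manifest()] plus a truth table of exact per-segment hull volumes
#' and centroids (exact for boxes and frusta; for ellipsoid clouds the solid
#' volume is an upper bound approached with increasing point count).
#' Optionally writes OBJ meshes + a YAML manifest to disk in the same formats
#' the loader consumes. Regeneration with the same seed is identical
#' (R's default Mersenne-Twister generator).
#'
#' @param template a `body_plan_template`.
#' @param seed integer seed for the pseudo-random primitives.
#' @param dir optional output directory; when given, meshes, manifest and a
#'   `truth.csv` are written there.
#' @return list with `manifest` (a `skeleton_manifest`) and `truth` (data
#'   frame: `id`, `class`, `volume_exact`, `volume_solid`, `centroid_x/y/z`;
#'   truth coordinates are in the body frame, origin at the acetabulum).
#' @export
generate_skeleton <- function(template, seed = 1L, dir = NULL) {
  stopifnot(inherits(template, "body_plan_template"))
  set.seed(seed)
  seg_meshes <- list()
  truth <- list()
  for (s in template$segments) {
    em <- switch(s$shape,
                 box = .emit_box(s),
                 frustum = .emit_frustum(s),
                 ellipsoid = .emit_ellipsoid(s))
    side <- if (is.null(s$side)) "midline" else s$side
    sub <- if (is.null(s$subdivision)) 1L else s$subdivision
    sm <- segment_mesh(em$pts, class = s$class, side = side,
                       subdivision = sub, pivot = s$pivot)
    seg_meshes[[length(seg_meshes) + 1L]] <- sm
    truth[[length(truth) + 1L]] <- data.frame(
      id = sm$id, class = s$class, shape = s$shape,
      volume_exact = em$volume_exact, volume_solid = em$volume_solid,
      centroid_x = em$centroid_exact[1L] - template$acetabulum[1L],
      centroid_y = em$centroid_exact[2L] - template$acetabulum[2L],
      centroid_z = em$centroid_exact[3L] - template$acetabulum[3L],
      stringsAsFactors = FALSE)
  }
  manifest <- skeleton_manifest(
    taxon = template$name, segments = seg_meshes,
    acetabulum = template$acetabulum, glenoid = template$glenoid,
    posture = template$posture, tail_in_torso = template$tail_in_torso,
    notes = sprintf("synthetic skeleton, seed %d", seed))
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    write_skeleton(manifest, dir, name = template$name)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(manifest = manifest, truth = truth)
}

#' A generic quadrupedal body-plan template
#'
#' Abstract volumetric stand-in for a quadrupedal archosaur in the reference
#' pose (axial skeleton extended, limbs ventral): box torso, two-piece
#' frustum neck with joint pivots, ellipsoid head, two-piece frustum tail,
#' and paired box limb segments; optionally two dorsal midline osteoderm
#' plates. The acetabulum sits at the hip, the glenoid anterodorsally. All
#' dimensions scale linearly with `scale` (1 = roughly rhino-sized).
#'
#' @param scale linear scale factor.
#' @param armoured add two osteoderm plates.
#' @return a [body_plan_template()].
#' @export
template_quadruped <- function(scale = 1, armoured = FALSE) {
  s <- scale
  box <- function(class, center, size, side = "midline", subdivision = 1L) {
    list(shape = "box", class = class, center = center * s, size = size * s,
         side = side, subdivision = subdivision)
  }
  fru <- function(class, base, axis, h, r1, r2, subdivision = 1L,
                  pivot = NULL) {
    list(shape = "frustum", class = class, base = base * s, axis = axis,
         h = h * s, r1 = r1 * s, r2 = r2 * s, n_theta = 64L,
         subdivision = subdivision, pivot = if (!is.null(pivot)) pivot * s)
  }
  neck_dir <- c(1, 0, 0.25) / sqrt(1 + 0.25^2)
  limb_pair <- function(class, x, z, size) {
    list(box(class, c(x, 0.30, z), size, side = "left"),
         box(class, c(x, -0.30, z), size, side = "right"))
  }
  segs <- c(
    list(
      box("torso", center = c(0.65, 0, 0.25), size = c(1.5, 0.62, 0.75)),
      fru("neck", base = c(1.40, 0, 0.45), axis = neck_dir, h = 0.45,
          r1 = 0.22, r2 = 0.17, subdivision = 1L, pivot = c(1.40, 0, 0.45)),
      fru("neck", base = c(1.40, 0, 0.45) + 0.45 * neck_dir, axis = neck_dir,
          h = 0.45, r1 = 0.17, r2 = 0.12, subdivision = 2L,
          pivot = c(1.40, 0, 0.45)),
      list(shape = "ellipsoid", class = "head", side = "midline",
           subdivision = 1L, center = (c(1.40, 0, 0.45) + 0.9 * neck_dir +
                                         c(0.22, 0, 0)) * s,
           semi = c(0.28, 0.11, 0.12) * s, n = 400L,
           pivot = (c(1.40, 0, 0.45)) * s),
      fru("tail", base = c(-0.10, 0, 0.25), axis = c(-1, 0, 0.02), h = 0.9,
          r1 = 0.24, r2 = 0.12, subdivision = 1L),
      fru("tail", base = c(-0.10, 0, 0.25) + 0.9 * c(-1, 0, 0.02), h = 0.9,
          axis = c(-1, 0, 0.02), r1 = 0.12, r2 = 0.03, subdivision = 2L)
    ),
    limb_pair("thigh", x = 0.00, z = -0.35, size = c(0.26, 0.17, 0.55)),
    limb_pair("shank", x = 0.02, z = -0.85, size = c(0.20, 0.14, 0.45)),
    limb_pair("metatarsus", x = 0.04, z = -1.18, size = c(0.14, 0.11, 0.22)),
    limb_pair("pes", x = 0.10, z = -1.34, size = c(0.32, 0.14, 0.10)),
    limb_pair("brachium", x = 1.20, z = -0.25, size = c(0.22, 0.15, 0.50)),
    limb_pair("antebrachium", x = 1.22, z = -0.70, size = c(0.17, 0.12, 0.40)),
    limb_pair("manus", x = 1.26, z = -0.97, size = c(0.24, 0.13, 0.14))
  )
  if (armoured) {
    segs <- c(segs, list(
      box("osteoderm", center = c(0.95, 0, 0.72), size = c(0.42, 0.05, 0.30),
          subdivision = 1L),
      box("osteoderm", center = c(0.35, 0, 0.72), size = c(0.42, 0.05, 0.30),
          subdivision = 2L)))
  }
  body_plan_template(segs, acetabulum = c(0, 0, 0) * s,
                     glenoid = c(1.20, 0, 0.12) * s,
                     posture = "quadruped",
                     name = if (armoured) "synthetic_quadruped_armoured"
                            else "synthetic_quadruped")
}

#' Simulate a continuous trait under Brownian motion on a tree
#'
#' Draws independent normal increments along every branch (variance
#' `sigma2 * branch length`) and accumulates them from the root, which is
#' distributionally identical to a multivariate normal with mean `root_value`
#' and covariance `sigma2 * C`, `C` the shared-path-length matrix.
#'
#' @param tree an `ape::phylo` rooted tree with branch lengths.
#' @param sigma2 Brownian rate (>= 0).
#' @param root_value trait value at the root.
#' @param seed optional integer seed (R default Mersenne-Twister).
#' @return named numeric vector of tip values.
#' @export
simulate_brownian <- function(tree, sigma2, root_value = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  # preorder = reverse postorder: parents before children
  ord <- rev(ape::postorder(tree))
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  val <- rep(NA_real_, nnode)
  val[ntip + 1L] <- root_value
  for (e in ord) {
    val[tree$edge[e, 2L]] <- val[tree$edge[e, 1L]] + inc[e]
  }
  stats::setNames(val[seq_len(ntip)], tree$tip.label)
}

#' Generate a synthetic taxon cohort with known allometric truth
#'
#' Simulates a pure-birth ultrametric tree (depth rescaled to 1), evolves
#' log10 body mass under Brownian motion (affinely rescaled to span
#' `mass_range` exactly), and builds log10 segment dimensions as
#' `intercept + slope * log10(mass) + Brownian deviation` with rate `sigma2`.
#' The recorded truth supports parameter-recovery tests; per-taxon skeleton
#' meshes scaled by mass can be materialised with [cohort_skeleton()].
#'
#' @param n_taxa number of tips (>= 8). Default 53 with masses spanning
#'   0.2 kg to 60 tonnes, mimicking the scale of a broad dinosaur cohort.
#' @param true_slope,true_intercept allometric truth for the simulated log10
#'   segment dimension.
#' @param sigma2 Brownian rate of the residual deviation (per unit tree
#'   depth); 0 gives an exact line.
#' @param seed integer seed.
#' @param mass_range range of body masses (kg) spanned by the cohort.
#' @return object of class `"synthetic_cohort"`: `tree`, `data` (data frame
#'   `taxon`, `log10_mass`, `log10_dim`), and the generating truth.
#' @export
generate_cohort <- function(n_taxa = 53L, true_slope = 1 / 3,
                            true_intercept = -1, sigma2 = 0.01, seed = 1L,
                            mass_range = c(0.2, 6e4)) {
  if (n_taxa < 8L) stop("n_taxa must be >= 8", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  x_raw <- simulate_brownian(tree, sigma2 = 1, root_value = 0)
  lo <- log10(mass_range[1L]); hi <- log10(mass_range[2L])
  x <- lo + (x_raw - min(x_raw)) / diff(range(x_raw)) * (hi - lo)
  e <- simulate_brownian(tree, sigma2 = sigma2, root_value = 0)
  y <- true_intercept + true_slope * x + e
  structure(list(tree = tree,
                 data = data.frame(taxon = tree$tip.label,
                                   log10_mass = unname(x),
                                   log10_dim = unname(y),
                                   stringsAsFactors = FALSE),
                 true_slope = true_slope, true_intercept = true_intercept,
                 sigma2 = sigma2, seed = seed, mass_range = mass_range),
            class = "synthetic_cohort")
}

#' Materialise one cohort taxon as a scaled synthetic skeleton
#'
#' Scales a body-plan template isometrically so that linear dimensions go as
#' body mass to the one-third power (reference: scale 1 at 1000 kg), then
#' generates the skeleton with a taxon-specific seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param taxon tip label.
#' @param template a `body_plan_template` factory taking a `scale` argument;
#'   defaults to [template_quadruped()].
#' @return as [generate_skeleton()].
#' @export
cohort_skeleton <- function(cohort, taxon, template = template_quadruped) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  i <- match(taxon, cohort$data$taxon)
  if (is.na(i)) stop("taxon not in cohort: ", taxon, call. = FALSE)
  mass <- 10^cohort$data$log10_mass[i]
  tpl <- template(scale = (mass / 1000)^(1 / 3))
  tpl$name <- taxon
  generate_skeleton(tpl, seed = cohort$seed + i)
}
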