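#' Segment density schemes
#'
#' Named presets for the per-class densities (kg/m^3) used when converting
#' estimated soft-tissue volumes to masses:
#'
#' * `"primary"` — the heterogeneous scheme: head, tail and all limb segments
#'   1000; neck 800 and torso 850 (respiratory structures); ornament and
#'   osteoderm 2000 (compact bone); sail 1000.
#' * `"homogeneous_min"` / `"homogeneous_max"` — uniform 731 / 1169
#'   (minimal and maximal plucked-bird whole-body densities).
#' * `"sauropod_low_neck"` — primary with neck lowered to 500 (extensive
#'   cervical pneumatic diverticula).
#' * `"ornament_light"` — primary with ornament lowered to 1000 (hollow
#'   horn cores, fenestrated frills).
#' * `"sail_compact"` — primary with sail raised to 2000 (robust neural
#'   spines modelled as compact bone).
#'
#' @param name preset name, or `"custom"` with `class_density` supplied.
#' @param class_density named numeric vector of densities by segment class
#'   (only for `"custom"`; may be built by modifying
#'   `density_scheme("primary")$class_density`).
#' @param homogeneous_value optional single density overriding all classes.
#' @return object of class `"density_scheme"`.
#' @export
density_scheme <- function(name = c("primary", "homogeneous_min",
                                    "homogeneous_max", "sauropod_low_neck",
                                    "ornament_light", "sail_compact",
                                    "custom"),
                           class_density = NULL, homogeneous_value = NULL) {
  name <- match.arg(name)
  primary <- c(head = 1000, neck = 800, torso = 850, tail = 1000,
               stats::setNames(rep(1000, length(.limb_classes)), .limb_classes),
               ornament = 2000, osteoderm = 2000, sail = 1000)
  cd <- switch(name,
               primary = primary,
               homogeneous_min = ,
               homogeneous_max = primary,  # overridden below
               sauropod_low_neck = { p <- primary; p["neck"] <- 500; p },
               ornament_light = { p <- primary; p["ornament"] <- 1000; p },
               sail_compact = { p <- primary; p["sail"] <- 2000; p },
               custom = {
                 if (is.null(class_density) && is.null(homogeneous_value)) {
                   stop("custom scheme needs class_density or homogeneous_value",
                        call. = FALSE)
                 }
                 class_density
               })
  hv <- switch(name, homogeneous_min = 731, homogeneous_max = 1169,
               homogeneous_value)
  if (!is.null(cd)) {
    .check_segment_class(names(cd))
    if (any(!is.finite(cd) | cd <= 0)) stop("densities must be > 0", call. = FALSE)
  }
  if (!is.null(hv) && (!is.finite(hv) || hv <= 0)) {
    stop("homogeneous density must be > 0", call. = FALSE)
  }
  structure(list(name = name, class_density = cd, homogeneous_value = hv),
            class = "density_scheme")
}

.density_of <- function(scheme, segment_class) {
  if (!is.null(scheme$homogeneous_value)) return(scheme$homogeneous_value)
  d <- scheme$class_density[segment_class]
  if (is.na(d)) {
    stop("segment class '", segment_class, "' missing from density scheme '",
         scheme$name, "'", call. = FALSE)
  }
  unname(d)
}

#' Mass properties of one expanded segment
#'
#' `mass = density(class) * point_volume`; bounds use the lower/upper volumes
#' at the same density; the centre of mass is the hull centroid (kept constant
#' across expansion iterations).
#'
#' @param vol an [expand_segment()] result.
#' @param centroid segment centre of mass (defaults to the hull centroid
#'   carried by `vol`).
#' @param scheme a [density_scheme()].
#' @return list of class `"segment_mass_props"`.
#' @export
segment_mass <- function(vol, centroid = vol$centroid,
                         scheme = density_scheme("primary")) {
  stopifnot(inherits(vol, "expanded_segment_volume"),
            inherits(scheme, "density_scheme"))
  rho <- .density_of(scheme, vol$segment_class)
  structure(list(id = vol$id, segment_class = vol$segment_class,
                 side = vol$side, subdivision = vol$subdivision,
                 density = rho,
                 point_volume = vol$point_volume,
                 lower_volume = vol$lower_volume,
                 upper_volume = vol$upper_volume,
                 mass = rho * vol$point_volume,
                 mass_lower = rho * vol$lower_volume,
                 mass_upper = rho * vol$upper_volume,
                 com = .as_point3(centroid, "centroid")),
            class = "segment_mass_props")
}

#' Assemble whole-body mass properties
#'
#' Total mass is the sum of segment masses; the whole-body centre of mass is
#' the mass-weighted mean of segment centres (each segment's Cartesian COM
#' times its mass, summed, divided by total mass), expressed as displacement
#' from the acetabulum. Whole-body bounds take every segment simultaneously at
#' its lower (or upper) volume — a conservative envelope. The mediolateral COM
#' is reported but expected to be at or negligibly displaced from the sagittal
#' plane.
#'
#' @param segments list of [segment_mass()] results.
#' @param manifest the source `skeleton_manifest` (landmarks, taxon).
#' @param model_set_name label recorded in the output.
#' @param scheme the [density_scheme()] used (recorded in the output).
#' @return object of class `"body_mass_props"` with `total_mass`,
#'   `total_mass_lower/upper` (kg), `com` (m, body frame), `per_segment`
#'   (data frame incl. per-segment masses, volumes, COMs) and
#'   `segment_fraction` (percent of total mass by class).
#' @export
assemble_body <- function(segments, manifest, model_set_name = "unspecified",
                          scheme = NULL) {
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, inherits, TRUE, "segment_mass_props")))
  m <- vapply(segments, `[[`, 0, "mass")
  if (sum(m) <= 0) stop("zero total body mass", call. = FALSE)
  coms <- t(vapply(segments, `[[`, numeric(3), "com"))
  total <- sum(m)
  com <- colSums(coms * m) / total
  per <- do.call(rbind, lapply(segments, function(s) {
    data.frame(id = s$id, class = s$segment_class, side = s$side,
               subdivision = s$subdivision, density = s$density,
               point_volume = s$point_volume,
               lower_volume = s$lower_volume, upper_volume = s$upper_volume,
               mass = s$mass, mass_lower = s$mass_lower,
               mass_upper = s$mass_upper,
               com_x = s$com[1L], com_y = s$com[2L], com_z = s$com[3L],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  frac <- tapply(per$mass, per$class, sum) / total * 100
  structure(list(taxon = manifest$taxon,
                 model_set_name = model_set_name,
                 density_scheme = if (is.null(scheme)) NA_character_ else scheme$name,
                 total_mass = total,
                 total_mass_lower = sum(per$mass_lower),
                 total_mass_upper = sum(per$mass_upper),
                 com = com,
                 per_segment = per,
                 segment_fraction = frac[order(names(frac))],
                 glenoid = manifest$glenoid,
                 posture = manifest$posture),
            class = "body_mass_props")
}

#' Full pipeline: manifest to body mass properties
#'
#' Convenience wrapper chaining [hull_all()], [build_model_set()],
#' [segment_mass()] and [assemble_body()].
#'
#' @param manifest a `skeleton_manifest`.
#' @param policy an [expansion_policy()].
#' @param factor_table a scaling table, see [read_scaling_table()].
#' @param scheme a [density_scheme()].
#' @return a `"body_mass_props"`.
#' @export
body_mass_props <- function(manifest, policy = expansion_policy(),
                            factor_table = default_scaling_table(),
                            scheme = density_scheme("primary")) {
  hulls <- hull_all(manifest)
  vols <- build_model_set(hulls, policy, factor_table, taxon = manifest$taxon)
  masses <- lapply(vols, segment_mass, scheme = scheme)
  assemble_body(masses, manifest, model_set_name = policy$model_set,
                scheme = scheme)
}

# rebuild a body from its per_segment table (used by variants)
.reassemble <- function(body, per) {
  if (nrow(per) == 0L) stop("zero total body mass", call. = FALSE)
  total <- sum(per$mass)
  if (total <= 0) stop("zero total body mass", call. = FALSE)
  com <- c(sum(per$com_x * per$mass), sum(per$com_y * per$mass),
           sum(per$com_z * per$mass)) / total
  frac <- tapply(per$mass, per$class, sum) / total * 100
  body$total_mass <- total
  body$total_mass_lower <- sum(per$mass_lower)
  body$total_mass_upper <- sum(per$mass_upper)
  body$com <- com
  body$per_segment <- per
  body$segment_fraction <- frac[order(names(frac))]
  body
}

#' Recompute mass properties without osteoderm segments
#'
#' Sensitivity variant for armoured taxa: drops all `osteoderm`-class segments
#' and recomputes totals and the whole-body centre of mass. A body without
#' osteoderms is returned unchanged.
#'
#' @param body a `"body_mass_props"`.
#' @return a `"body_mass_props"`.
#' @export
variant_exclude_osteoderms <- function(body) {
  stopifnot(inherits(body, "body_mass_props"))
  per <- body$per_segment
  keep <- per$class != "osteoderm"
  if (all(keep)) return(body)
  out <- .reassemble(body, per[keep, , drop = FALSE])
  out$model_set_name <- paste0(body$model_set_name, "+no_osteoderms")
  out
}

#' Recompute mass properties under an alternative density scheme
#'
#' Volumes and centroids are untouched; only densities change. Used for the
#' homogeneous-density, low-neck-density, ornament-light and compact-sail
#' sensitivity variants.
#'
#' @param body a `"body_mass_props"`.
#' @param scheme2 the alternative [density_scheme()].
#' @return a `"body_mass_props"`.
#' @export
variant_redensify <- function(body, scheme2) {
  stopifnot(inherits(body, "body_mass_props"),
            inherits(scheme2, "density_scheme"))
  per <- body$per_segment
  rho <- vapply(per$class, function(cl) .density_of(scheme2, cl), 0)
  per$density <- rho
  per$mass <- rho * per$point_volume
  per$mass_lower <- rho * per$lower_volume
  per$mass_upper <- rho * per$upper_volume
  out <- .reassemble(body, per)
  out$density_scheme <- scheme2$name
  out
}

#' @export
print.body_mass_props <- function(x, ...) {
  cat("Body mass properties:", x$taxon, "\n",
      " model set:", x$model_set_name, "| densities:", x$density_scheme, "\n",
      sprintf("  total mass: %.4g kg  [%.4g, %.4g]\n",
              x$total_mass, x$total_mass_lower, x$total_mass_upper),
      sprintf("  COM (m, rel. acetabulum): x=%.4g y=%.4g z=%.4g\n",
              x$com[1L], x$com[2L], x$com[3L]),
      " segments:", nrow(x$per_segment), "\n")
  invisible(x)
}
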