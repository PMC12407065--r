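#' One segmented skeletal mesh
#'
#' Constructor used both by the manifest loader and by the synthetic-skeleton
#' generator. Coordinates must be in the body frame and in metres: origin at
#' the mid-acetabular point, +x anterior, +z dorsal, y mediolateral, with the
#' skeleton in the standardised reference pose (axial skeleton
#' anteroposteriorly extended, limbs ventral).
#'
#' @param vertices n x 3 matrix (n >= 4, not all coplanar), metres.
#' @param class segment class, see [segment_classes()].
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param subdivision optional ordinal for serial sub-segments (necks/tails).
#' @param faces optional triangle index matrix (kept for provenance only).
#' @param pivot optional 3-D joint pivot point used by [repose()].
#' @return object of class `"segment_mesh"`.
#' @export
segment_mesh <- function(vertices, class, side = "midline", subdivision = 1L,
                         faces = NULL, pivot = NULL) {
  .check_segment_class(class)
  side <- match.arg(side, c("left", "right", "midline"))
  vertices <- .as_vertex_matrix(vertices)
  if (nrow(vertices) < 4L) {
    stop("segment '", class, "': needs at least 4 vertices", call. = FALSE)
  }
  if (!is.null(pivot)) pivot <- .as_point3(pivot, "pivot")
  structure(list(id = .segment_id(class, side, subdivision),
                 segment_class = class, side = side,
                 subdivision = as.integer(subdivision),
                 vertices = vertices, faces = faces,
                 is_ornament = class %in% .dermal_classes,
                 pivot = pivot),
            class = "segment_mesh")
}

#' Assemble a skeleton manifest in memory
#'
#' @param taxon taxon name.
#' @param segments list of [segment_mesh()] objects, body frame, metres.
#' @param acetabulum mid-acetabular point; the body frame origin. After
#'   construction it is always `c(0,0,0)` (the whole skeleton is translated).
#' @param glenoid mid-glenoid point (same frame as `acetabulum`).
#' @param posture `"biped"` or `"quadruped"`.
#' @param tail_in_torso bird convention flag: tail is contained in the torso
#'   hull and no separate tail segments may be present.
#' @param notes free-text posture/articulation provenance.
#' @return object of class `"skeleton_manifest"`.
#' @export
skeleton_manifest <- function(taxon, segments, acetabulum, glenoid,
                              posture = c("quadruped", "biped"),
                              tail_in_torso = FALSE, notes = NULL) {
  posture <- match.arg(posture)
  acetabulum <- .as_point3(acetabulum, "acetabulum")
  glenoid <- .as_point3(glenoid, "glenoid")
  if (isTRUE(all.equal(acetabulum, glenoid, tolerance = 0))) {
    stop("acetabulum and glenoid landmarks coincide", call. = FALSE)
  }
  if (!length(segments)) stop("manifest has no segments", call. = FALSE)
  stopifnot(all(vapply(segments, inherits, TRUE, "segment_mesh")))
  # re-origin the body frame at the acetabulum
  segments <- lapply(segments, function(s) {
    s$vertices <- sweep(s$vertices, 2L, acetabulum)
    if (!is.null(s$pivot)) s$pivot <- s$pivot - acetabulum
    s
  })
  glenoid <- glenoid - acetabulum
  m <- structure(list(taxon = taxon, segments = segments,
                      acetabulum = c(0, 0, 0), glenoid = glenoid,
                      posture = posture, tail_in_torso = isTRUE(tail_in_torso),
                      notes = notes),
                 class = "skeleton_manifest")
  names(m$segments) <- vapply(segments, `[[`, "", "id")
  .validate_manifest(m)
  m
}

.validate_manifest <- function(m) {
  ids <- names(m$segments)
  if (anyDuplicated(ids)) {
    stop("duplicate segment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  # sub-segment indices unique and contiguous from 1 within class x side
  key <- vapply(m$segments, function(s) paste(s$segment_class, s$side), "")
  for (k in unique(key)) {
    subs <- sort(unname(vapply(m$segments[key == k], `[[`, 1L, "subdivision")))
    if (!identical(subs, seq_along(subs))) {
      stop("sub-segment indices for ", k,
           " are not contiguous from 1: ", paste(subs, collapse = ","),
           call. = FALSE)
    }
  }
  if (m$tail_in_torso &&
      any(vapply(m$segments, `[[`, "", "segment_class") == "tail")) {
    stop("tail_in_torso is TRUE but separate tail segments are present",
         call. = FALSE)
  }
  # non-coplanarity per segment (hard error, mirrors the hulling requirement)
  for (s in m$segments) {
    ctr <- sweep(s$vertices, 2L, colMeans(s$vertices))
    sv <- svd(ctr, nu = 0L, nv = 0L)$d
    if (length(sv) < 3L || sv[3L] < 1e-12 * max(sv[1L], 1)) {
      stop("segment '", s$id, "' is degenerate (coplanar or collinear)",
           call. = FALSE)
    }
  }
  invisible(m)
}

#' Load a segmented skeleton from a manifest file
#'
#' The manifest (YAML or JSON by extension) declares the taxon, measurement
#' unit, landmarks, posture, and one entry per segment mesh file (OBJ/PLY/STL,
#' paths relative to the manifest). All coordinates are rescaled to metres and
#' translated so the mid-acetabular point is the origin.
#'
#' Expected fields: `taxon`, `unit` (`m`, `cm` or `mm`), `posture`,
#' `tail_in_torso` (optional), `landmarks: {acetabulum: [x,y,z], glenoid:
#' [x,y,z]}`, `segments: [{file, class, side, subdivision, pivot}]`, `notes`.
#'
#' @param manifest_path path to the YAML/JSON manifest.
#' @return a [skeleton_manifest()].
#' @export
load_skeleton <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(manifest_path))
  raw <- switch(ext,
                yml = , yaml = yaml::read_yaml(manifest_path),
                json = jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                stop("manifest must be .yaml/.yml/.json: ", manifest_path,
                     call. = FALSE))
  dir <- dirname(manifest_path)
  unit <- if (is.null(raw$unit)) "m" else raw$unit
  scale <- switch(unit, m = 1, cm = 0.01, mm = 0.001,
                  stop("unknown unit '", unit, "' (use m, cm or mm)",
                       call. = FALSE))
  lm <- raw$landmarks
  if (is.null(lm$acetabulum)) stop("manifest lacks acetabulum landmark", call. = FALSE)
  if (is.null(lm$glenoid)) stop("manifest lacks glenoid landmark", call. = FALSE)

  seg_list <- raw$segments
  if (is.data.frame(seg_list)) seg_list <- split(seg_list, seq_len(nrow(seg_list)))
  segments <- lapply(seg_list, function(s) {
    s <- as.list(s)
    f <- file.path(dir, s$file)
    if (!file.exists(f)) {
      stop("segment '", s$class, "': mesh file missing: ", s$file, call. = FALSE)
    }
    mesh <- read_mesh(f)
    segment_mesh(mesh$vertices * scale, class = s$class,
                 side = if (is.null(s$side)) "midline" else s$side,
                 subdivision = if (is.null(s$subdivision)) 1L else s$subdivision,
                 faces = mesh$faces,
                 pivot = if (is.null(s$pivot)) NULL else unlist(s$pivot) * scale)
  })
  skeleton_manifest(taxon = raw$taxon, segments = segments,
                    acetabulum = unlist(lm$acetabulum) * scale,
                    glenoid = unlist(lm$glenoid) * scale,
                    posture = if (is.null(raw$posture)) "quadruped" else raw$posture,
                    tail_in_torso = isTRUE(raw$tail_in_torso),
                    notes = raw$notes)
}

#' Write a skeleton manifest and its meshes to disk
#'
#' Emits one OBJ per segment plus a YAML manifest (units metres), such that
#' [load_skeleton()] round-trips the skeleton.
#'
#' @param manifest a `skeleton_manifest`.
#' @param dir output directory (created if missing).
#' @param name basename for the manifest file.
#' @return path to the written manifest, invisibly.
#' @export
write_skeleton <- function(manifest, dir, name = "skeleton") {
  stopifnot(inherits(manifest, "skeleton_manifest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_entries <- lapply(manifest$segments, function(s) {
    f <- paste0(s$id, ".obj")
    write_obj_mesh(s$vertices, file.path(dir, f), faces = s$faces)
    e <- list(file = f, class = s$segment_class, side = s$side,
              subdivision = s$subdivision)
    if (!is.null(s$pivot)) e$pivot <- as.numeric(s$pivot)
    e
  })
  names(seg_entries) <- NULL
  y <- list(taxon = manifest$taxon, unit = "m", posture = manifest$posture,
            tail_in_torso = manifest$tail_in_torso,
            landmarks = list(acetabulum = as.numeric(manifest$acetabulum),
                             glenoid = as.numeric(manifest$glenoid)),
            segments = seg_entries)
  if (!is.null(manifest$notes)) y$notes <- manifest$notes
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(y, path, precision = 17L)
  invisible(path)
}

#' Glenoacetabular distances
#'
#' Anteroposterior and dorsoventral distances between the mid-glenoid and
#' mid-acetabular landmarks, measured in the reference pose. These are the
#' denominators of the GA-normalised centre-of-mass coordinates (0 =
#' acetabulum, 1 = glenoid).
#'
#' @param manifest a `skeleton_manifest`.
#' @param dv_epsilon threshold (m) below which the dorsoventral spacing is
#'   flagged degenerate for downstream normalisation.
#' @return named numeric `c(ap=, dv=)` with attribute `dv_degenerate`.
#' @export
glenoacetabular_distances <- function(manifest, dv_epsilon = 1e-6) {
  stopifnot(inherits(manifest, "skeleton_manifest"))
  d <- abs(manifest$glenoid - manifest$acetabulum)
  out <- c(ap = d[1L], dv = d[3L])
  degen <- out["dv"] < dv_epsilon
  if (degen) {
    warning("dorsoventral glenoacetabular distance below epsilon; ",
            "DV-normalised centre of mass will be flagged missing",
            call. = FALSE)
  }
  attr(out, "dv_degenerate") <- unname(degen)
  out
}

#' @export
print.skeleton_manifest <- function(x, ...) {
  cat("Skeleton manifest:", x$taxon, "(", x$posture, ")\n",
      " segments:", length(x$segments), "\n",
      " glenoid (m, rel. acetabulum):",
      paste(format(x$glenoid, digits = 6), collapse = ", "), "\n")
  invisible(x)
}
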