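#' Specification of a rigid repose of a segment chain
#'
#' Describes a rigid rotation of an ordered chain of segments (e.g. the neck
#' sub-segments plus the head) about a joint pivot. The default axis is the
#' mediolateral axis oriented as `(0, -1, 0)` so that, under the right-hand
#' rule in the body frame (+x anterior, +z dorsal, +y left), positive angles
#' pitch anterior points dorsally.
#'
#' @param chain character vector of segment ids (as in
#'   `body$per_segment$id`, e.g. `"neck_midline_1"`).
#' @param pivot 3-D pivot point (m, body frame), e.g. the base of the neck.
#' @param angle_deg rotation angle in degrees; positive = dorsal pitch with
#'   the default axis.
#' @param axis rotation axis (normalised internally; must be nonzero).
#' @return object of class `"repose_spec"`.
#' @export
repose_spec <- function(chain, pivot, angle_deg, axis = c(0, -1, 0)) {
  pivot <- .as_point3(pivot, "pivot")
  axis <- .as_point3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("axis must be nonzero", call. = FALSE)
  stopifnot(is.finite(angle_deg), length(chain) >= 1L)
  structure(list(chain = chain, pivot = pivot, angle_deg = angle_deg,
                 axis = axis / n),
            class = "repose_spec")
}

#' Rigidly repose a segment chain and recompute the whole-body COM
#'
#' Operates on segment centres of mass as point masses: each chain segment's
#' COM is rotated rigidly about the pivot; masses and volumes are unchanged
#' (hulls are measured in the reference pose only). The whole-body centre of
#' mass is then recomputed.
#'
#' @param body a `"body_mass_props"`.
#' @param spec a [repose_spec()].
#' @return a `"body_mass_props"` with rotated chain COMs.
#' @export
repose <- function(body, spec) {
  stopifnot(inherits(body, "body_mass_props"), inherits(spec, "repose_spec"))
  per <- body$per_segment
  idx <- match(spec$chain, per$id)
  if (anyNA(idx)) {
    stop("unknown segment id(s): ",
         paste(spec$chain[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  R <- rotation_matrix(spec$axis, spec$angle_deg)
  pts <- as.matrix(per[idx, c("com_x", "com_y", "com_z")])
  rotated <- sweep(sweep(pts, 2L, spec$pivot) %*% t(R), 2L, spec$pivot, `+`)
  per[idx, c("com_x", "com_y", "com_z")] <- rotated
  out <- .reassemble(body, per)
  out$model_set_name <- paste0(body$model_set_name,
                               sprintf("+repose%+g", spec$angle_deg))
  out
}

#' Centre-of-mass shift between a base and a reposed body
#'
#' Expresses the whole-body COM shift as percentages of the anteroposterior
#' and dorsoventral glenoacetabular distances (positive = anterior / dorsal
#' shift).
#'
#' @param base,pitched `"body_mass_props"` for the same taxon and model set.
#' @param manifest the source `skeleton_manifest` (for the GA distances).
#' @return one-row data frame with `taxon`, `delta_mass_kg`,
#'   `dcom_ap_pct_ga`, `dcom_dv_pct_ga` (the latter `NA` when the
#'   dorsoventral GA spacing is degenerate).
#' @export
neck_pitch_report <- function(base, pitched, manifest) {
  stopifnot(inherits(base, "body_mass_props"),
            inherits(pitched, "body_mass_props"))
  if (!identical(base$taxon, pitched$taxon)) {
    stop("base and pitched bodies are for different taxa", call. = FALSE)
  }
  ga <- suppressWarnings(glenoacetabular_distances(manifest))
  d <- pitched$com - base$com
  data.frame(taxon = base$taxon,
             delta_mass_kg = pitched$total_mass - base$total_mass,
             dcom_ap_pct_ga = 100 * d[1L] / ga["ap"],
             dcom_dv_pct_ga = if (attr(ga, "dv_degenerate")) NA_real_ else
               100 * d[3L] / ga["dv"],
             row.names = NULL)
}
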