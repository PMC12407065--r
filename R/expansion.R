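#' A hull-to-soft-tissue scaling model for one segment class
#'
#' Expansion factors map a segment's minimal skeletal hull volume to its
#' estimated soft-tissue volume, calibrated on extant sauropsids. Two sources
#' (`"NAS"` = non-avian sauropsid, `"bird"`) and two modes are supported:
#' allometric, a power law on log10 volumes
#' (`V_soft = 10^(a + b * log10(V_hull))`), and isometric, a constant
#' multiplier (`V_soft = k * V_hull`). `mppe` is the equation's mean absolute
#' percentage prediction error, used as a symmetric relative error bar.
#'
#' @param segment_class segment class, see [segment_classes()].
#' @param source `"NAS"` or `"bird"`.
#' @param mode `"allometric"` or `"isometric"`.
#' @param a,b allometric intercept (log10 m^3) and exponent.
#' @param k isometric multiplicative factor (> 0).
#' @param mppe mean absolute percentage prediction error, as a fraction >= 0.
#' @return object of class `"scaling_model"`.
#' @export
scaling_model <- function(segment_class, source = c("NAS", "bird"),
                          mode = c("allometric", "isometric"),
                          a = NA_real_, b = NA_real_, k = NA_real_,
                          mppe = 0) {
  .check_segment_class(segment_class)
  source <- match.arg(source)
  mode <- match.arg(mode)
  if (mode == "allometric") {
    if (!is.finite(a) || !is.finite(b)) {
      stop("allometric model needs finite a and b", call. = FALSE)
    }
    k <- NA_real_
  } else {
    if (!is.finite(k) || k <= 0) stop("isometric model needs k > 0", call. = FALSE)
    a <- b <- NA_real_
  }
  if (!is.finite(mppe) || mppe < 0) stop("mppe must be >= 0", call. = FALSE)
  structure(list(segment_class = segment_class, source = source, mode = mode,
                 a = a, b = b, k = k, mppe = mppe),
            class = "scaling_model")
}

#' Read a scaling-factor table
#'
#' CSV with columns `segment_class, source, mode, a, b, k, mppe` (one row per
#' class x source x mode combination).
#'
#' @param path CSV path.
#' @return list of [scaling_model()] objects, class `"scaling_table"`.
#' @export
read_scaling_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_class", "source", "mode", "a", "b", "k", "mppe")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scaling table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  models <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    scaling_model(r$segment_class, r$source, r$mode,
                  a = r$a, b = r$b, k = r$k, mppe = r$mppe)
  })
  structure(models, class = "scaling_table")
}

#' Synthetic default scaling-factor table
#'
#' The calibrated hull-expansion coefficients this pipeline was designed for
#' are published separately and are not bundled; this table is a synthetic
#' placeholder so the pipeline runs end to end. Its isometric factors are
#' plausible (soft-tissue volumes 1.2-2.5 x hull volume, necks larger under
#' NAS than bird, per the qualitative pattern in extant sauropsids), its
#' allometric rows reduce to near-isometry (b close to 1), and its mPPE values
#' use the three published figures (tail 0.52; torso 0.10 NAS / 0.14 bird)
#' with a generic 0.20 elsewhere. Replace it with real coefficients via
#' [read_scaling_table()] for any substantive application.
#'
#' @return a `"scaling_table"`.
#' @export
default_scaling_table <- function() {
  read_scaling_table(system.file("extdata", "scaling_factors_synthetic.csv",
                                 package = "hullmass", mustWork = TRUE))
}

.find_model <- function(table, segment_class, source, mode) {
  for (m in table) {
    if (m$segment_class == segment_class && m$source == source &&
        m$mode == mode) return(m)
  }
  NULL
}

#' Expansion policy: which scaling models apply where
#'
#' @param model_set one of `"NAS_allometric"`, `"NAS_isometric"`,
#'   `"bird_allometric"`, `"bird_isometric"`, `"preferred_allometric"`,
#'   `"preferred_isometric"`, `"sellers21"`. The two `preferred_*` sets take
#'   their default source from the corresponding NAS set and are driven by
#'   per-taxon `overrides`; `"sellers21"` applies one uniform 1.21 factor to
#'   all non-exempt segments.
#' @param overrides data frame with columns `taxon, segment_class, source,
#'   mode` selecting a different factor for specific taxon/segment pairs
#'   (the "preferred" mechanism).
#' @param floor_classes classes whose hulls adhere tightly to the skeleton, so
#'   the hull volume is a minimum threshold for the estimated segment volume.
#' @param exempt_classes classes never expanded (dermal structures whose
#'   envelopes wrap tightly): point volume = hull volume, mppe = 0.
#' @param sellers21_factor the uniform expansion factor for the `"sellers21"`
#'   set (minimal hulls underestimate body mass by ~21%).
#' @return object of class `"expansion_policy"`.
#' @export
expansion_policy <- function(model_set = c("NAS_allometric", "NAS_isometric",
                                           "bird_allometric", "bird_isometric",
                                           "preferred_allometric",
                                           "preferred_isometric", "sellers21"),
                             overrides = NULL,
                             floor_classes = c("neck", "metatarsus"),
                             exempt_classes = c("ornament", "osteoderm", "sail"),
                             sellers21_factor = 1.21) {
  model_set <- match.arg(model_set)
  .check_segment_class(floor_classes)
  .check_segment_class(exempt_classes)
  if (!is.null(overrides)) {
    need <- c("taxon", "segment_class", "source", "mode")
    if (!all(need %in% names(overrides))) {
      stop("overrides need columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    .check_segment_class(overrides$segment_class)
  }
  structure(list(model_set = model_set, overrides = overrides,
                 floor_classes = floor_classes,
                 exempt_classes = exempt_classes,
                 sellers21_factor = sellers21_factor),
            class = "expansion_policy")
}

# source/mode implied by a uniform model-set name
.set_source_mode <- function(model_set) {
  switch(model_set,
         NAS_allometric = c("NAS", "allometric"),
         NAS_isometric = c("NAS", "isometric"),
         bird_allometric = c("bird", "allometric"),
         bird_isometric = c("bird", "isometric"),
         preferred_allometric = c("NAS", "allometric"),
         preferred_isometric = c("NAS", "isometric"),
         sellers21 = c(NA, "sellers21"))
}

#' Expand one segment hull to an estimated soft-tissue volume
#'
#' Applies the scaling model, then the policy's floor rule (for floor classes
#' the hull volume is a minimum threshold) and mPPE error bounds
#' (`point * (1 -/+ mppe)`, each bound also floored). Exempt classes pass
#' through unexpanded with zero mppe.
#'
#' @param hull a [compute_hull()] result.
#' @param model a [scaling_model()] matching the hull's class (ignored for
#'   exempt classes and for the sellers21 set).
#' @param policy an [expansion_policy()].
#' @return list of class `"expanded_segment_volume"` with `point_volume`,
#'   `lower_volume`, `upper_volume` (m^3), `floored` flag, and the hull's
#'   centroid (kept fixed across expansion).
#' @export
expand_segment <- function(hull, model = NULL, policy = expansion_policy()) {
  stopifnot(inherits(hull, "segment_hull"))
  v <- hull$volume
  cls <- hull$segment_class
  exempt <- cls %in% policy$exempt_classes

  if (exempt) {
    point <- v; mppe <- 0; mode_used <- "exempt"
  } else if (policy$model_set == "sellers21") {
    point <- policy$sellers21_factor * v; mppe <- 0; mode_used <- "sellers21"
  } else {
    if (is.null(model)) stop("segment '", hull$id, "': no scaling model supplied",
                             call. = FALSE)
    stopifnot(inherits(model, "scaling_model"))
    if (model$segment_class != cls) {
      stop("scaling model class '", model$segment_class,
           "' does not match segment '", hull$id, "'", call. = FALSE)
    }
    point <- if (model$mode == "allometric") {
      10^(model$a + model$b * log10(v))
    } else {
      model$k * v
    }
    mppe <- model$mppe
    mode_used <- paste(model$source, model$mode, sep = "_")
  }
  if (!is.finite(point) || point <= 0) {
    stop("segment '", hull$id, "': non-positive predicted volume ",
         "(pathological scaling coefficients)", call. = FALSE)
  }
  floored <- FALSE
  apply_floor <- function(x) {
    if (cls %in% policy$floor_classes && x < v) { floored <<- TRUE; v } else x
  }
  point <- apply_floor(point)
  lower <- apply_floor(point * (1 - mppe))
  upper <- apply_floor(point * (1 + mppe))
  structure(list(id = hull$id, segment_class = cls, side = hull$side,
                 subdivision = hull$subdivision,
                 hull_volume = v, point_volume = point,
                 lower_volume = lower, upper_volume = upper,
                 floored = floored, mppe = mppe, model = mode_used,
                 centroid = hull$centroid),
            class = "expanded_segment_volume")
}

#' Build a full model set of expanded segment volumes
#'
#' Applies one model set to every segment of a skeleton. Source/mode come from
#' the set name; for bird-source sets tail segments automatically fall back to
#' the NAS tail factors (birds' reduced tails are contained within the torso
#' hull in the calibration data, so no bird tail factor exists); per-taxon
#' overrides then replace individual segment choices.
#'
#' @param hulls a [hull_all()] result.
#' @param policy an [expansion_policy()].
#' @param factor_table a `"scaling_table"`; defaults to the bundled synthetic
#'   placeholder table.
#' @param taxon taxon name used to match `policy$overrides`.
#' @return list of class `"expanded_volume_set"` of `expanded_segment_volume`s.
#' @export
build_model_set <- function(hulls, policy = expansion_policy(),
                            factor_table = default_scaling_table(),
                            taxon = attr(hulls, "taxon")) {
  stopifnot(inherits(hulls, "segment_hull_set"))
  sm <- .set_source_mode(policy$model_set)
  out <- lapply(hulls, function(h) {
    cls <- h$segment_class
    if (cls %in% policy$exempt_classes || policy$model_set == "sellers21") {
      return(expand_segment(h, NULL, policy))
    }
    source <- sm[1L]; mode <- sm[2L]
    if (source == "bird" && cls == "tail") source <- "NAS"
    ov <- policy$overrides
    if (!is.null(ov)) {
      hit <- which(ov$taxon == taxon & ov$segment_class == cls)
      if (length(hit) > 0L) {
        source <- ov$source[hit[1L]]
        mode <- ov$mode[hit[1L]]
        if (source == "bird" && cls == "tail") source <- "NAS"
      }
    }
    model <- .find_model(factor_table, cls, source, mode)
    if (is.null(model)) {
      stop("no ", source, " ", mode, " scaling factor for segment class '",
           cls, "' in factor table", call. = FALSE)
    }
    expand_segment(h, model, policy)
  })
  structure(out, class = "expanded_volume_set", taxon = taxon,
            model_set = policy$model_set)
}

#' @export
as.data.frame.expanded_volume_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(e) {
    data.frame(id = e$id, class = e$segment_class, side = e$side,
               hull_volume = e$hull_volume, point_volume = e$point_volume,
               lower_volume = e$lower_volume, upper_volume = e$upper_volume,
               floored = e$floored, model = e$model, stringsAsFactors = FALSE)
  }))
}
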