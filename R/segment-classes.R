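#' Recognised body segment classes
#'
#' The pipeline divides a skeleton into functional segments. Each segment in a
#' manifest must map to exactly one of these classes; necks, tails and similar
#' serial regions may additionally carry a `subdivision` ordinal (unique and
#' contiguous from 1 within a class).
#'
#' @return A data frame with columns `class` and `axial_or_limb`
#'   (`"axial"`, `"limb"` or `"dermal"`).
#' @export
#' @examples
#' segment_classes()
segment_classes <- function() {
  data.frame(
    class = c("head", "neck", "torso", "tail",
              "brachium", "antebrachium", "manus",
              "thigh", "shank", "metatarsus", "pes",
              "ornament", "osteoderm", "sail"),
    axial_or_limb = c(rep("axial", 4), rep("limb", 7), rep("dermal", 3)),
    stringsAsFactors = FALSE
  )
}

# limb classes, used when assigning the default density scheme
.limb_classes <- c("brachium", "antebrachium", "manus",
                   "thigh", "shank", "metatarsus", "pes")

.dermal_classes <- c("ornament", "osteoderm", "sail")

.check_segment_class <- function(class) {
  known <- segment_classes()$class
  bad <- setdiff(class, known)
  if (length(bad) > 0L) {
    stop("unknown segment class(es): ", paste(bad, collapse = ", "),
         " (see segment_classes())", call. = FALSE)
  }
  invisible(class)
}

# canonical per-segment identifier, e.g. "neck_midline_2", "thigh_left_1"
.segment_id <- function(class, side, subdivision) {
  sub <- ifelse(is.na(subdivision), 1L, as.integer(subdivision))
  paste(class, side, sub, sep = "_")
}
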