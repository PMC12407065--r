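#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula, right-hand rule about `axis`.
#'
#' @param axis numeric length-3 axis (need not be unit length; must be nonzero).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3L, all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) stop("rotation axis must be nonzero", call. = FALSE)
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(what, " must be a finite length-3 numeric vector", call. = FALSE)
  }
  x
}

.as_vertex_matrix <- function(v, what = "vertices") {
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  if (any(!is.finite(v))) stop(what, " contain non-finite coordinates", call. = FALSE)
  dimnames(v) <- NULL
  v
}
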