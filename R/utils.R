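# Internal helpers shared across modules.

DEG2RAD <- pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
rot_x <- function(alpha) {
  a <- alpha * DEG2RAD
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @noRd
rot_y <- function(beta) {
  b <- beta * DEG2RAD
  matrix(c(cos(b), 0, -sin(b),
           0, 1, 0,
           sin(b), 0, cos(b)), 3, 3)
}

#' @noRd
rot_z <- function(gamma) {
  g <- gamma * DEG2RAD
  matrix(c(cos(g), sin(g), 0,
           -sin(g), cos(g), 0,
           0, 0, 1), 3, 3)
}

#' Axis-angle (Rodrigues) rotation matrix
#'
#' Builds the 3x3 matrix rotating points by `theta` degrees about the unit
#' axis `v` (right-hand rule), via the Rodrigues formula
#' R = I + sin(t) K + (1 - cos(t)) K^2 with K the cross-product matrix of v.
#'
#' @param v numeric length-3 axis; must have nonzero norm (normalized
#'   internally).
#' @param theta rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(v, theta) {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-12) stop("rotation axis has zero norm")
  v <- v / nv
  t <- theta * DEG2RAD
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Evaluate `expr` under `seed` if non-NULL (restoring the caller's RNG
# state), otherwise draw from the ambient RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a per-item child seed from a base seed, kept within 32-bit range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + i) %% 2147483629L)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower) stop(sprintf("`%s` must be >= %g", name, lower))
  invisible(x)
}

check_range <- function(range, name, positive = FALSE) {
  if (!is.numeric(range) || length(range) != 2L || any(!is.finite(range))) {
    stop(sprintf("`%s` must be a numeric (a, b) pair", name))
  }
  if (range[1] > range[2]) stop(sprintf("`%s` must satisfy a <= b", name))
  if (positive && range[1] <= 0) {
    stop(sprintf("`%s` lower bound must be > 0", name))
  }
  invisible(range)
}

.datatable.aware <- TRUE
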