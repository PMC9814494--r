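# Small shared helpers.

# Evaluate expr with a local, seeded RNG stream; the caller's RNG state is
# untouched.  seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Fixed-format numbers for CSV output: 6 significant digits, so identical
# runs give byte-identical files.
fmt_num <- function(x) {
  out <- formatC(x, digits = 6L, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

# unit vector
.unit <- function(v) v / sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# rotation matrix sending unit vector a to unit vector b
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross(a, b); s <- sqrt(sum(v * v)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .unit(.cross(a, p))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# rotation about the z axis by angle (radians)
.rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}
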