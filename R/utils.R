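# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                   allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid domain", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# Angle at vertex `b` formed by points a-b-c, in degrees.
# atan2 of the cross/dot pair keeps full precision near 0 and 180 degrees,
# where acos of the normalized dot product loses ~half the significant digits.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("undefined angle: coincident atoms at the angle vertex", call. = FALSE)
  }
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

# Uniform random rotation matrix (det +1) from a QR decomposition of a
# Gaussian matrix, sign-corrected so R has positive diagonal.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
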