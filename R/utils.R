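#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' random state, so package functions never perturb the global RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exponential waiting time for a per-minute event rate; Inf for rate 0
.expWait <- function(ratePerMin) {
  if (ratePerMin <= 0) return(Inf)
  stats::rexp(1, rate = ratePerMin / 60)
}

.sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

# angle (degrees, in [0,180]) between two planar vectors
.vecAngle <- function(ux, uy, vx, vy) {
  dot <- ux * vx + uy * vy
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  ca <- pmin(1, pmax(-1, dot / (nu * nv)))
  acos(ca) * 180 / pi
}
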