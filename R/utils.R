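## internal numerics shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow; the workhorse for all
#' evidence arithmetic, which is done entirely in log space.
#'
#' @param x numeric vector of log values; may contain `-Inf`.
#' @return a single numeric; `-Inf` for an empty vector.
#' @export
#' @examples
#' logsumexp(c(-1000, -1001))  # log(exp(-1000) + exp(-1001))
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf, or an Inf dominates
  m + log(sum(exp(x - m)))
}

## run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards so seeded helpers do not perturb it
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) ||
      x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

check_number <- function(x, name, min = 0, strict = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) ||
      (if (strict) x <= min else x < min))
    stop(sprintf("'%s' must be a single number %s %g", name,
                 if (strict) ">" else ">=", min), call. = FALSE)
  as.numeric(x)
}

## uniform random unit vector in R^3
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

## Rodrigues rotation matrix about unit axis by angle (radians)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
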