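`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' generators do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# TRUE when `time` is a strictly increasing uniform grid (relative tol on step)
is_uniform_grid <- function(time, tol = 1e-6) {
  if (length(time) < 2L) return(FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) return(FALSE)
  max(abs(dt - dt[1L])) <= tol * abs(dt[1L])
}

# Centered moving average with edge replication; w coerced to odd >= 1
moving_average <- function(y, w) {
  w <- as.integer(w)
  if (w <= 1L) return(y)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(y)
  h <- (w - 1L) %/% 2L
  ypad <- c(rep(y[1L], h), y, rep(y[n], h))
  cs <- c(0, cumsum(ypad))
  (cs[(w + 1L):(n + w)] - cs[1:n]) / w
}

# Trapezoidal integral; exact for piecewise-linear samples
trapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n])) / 2
}

# Largest-remainder apportionment of n among proportions p; ties broken by
# position order. Guarantees sum(counts) == n.
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  target <- n * p
  base <- floor(target)
  extra <- n - sum(base)
  if (extra > 0L) {
    ord <- order(-(target - base), seq_along(p))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Normal draws truncated to be strictly positive (rejection; means here are
# many SDs above zero so this rarely loops)
truncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- mean * 1e-3
  x
}
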