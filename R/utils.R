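# Internal helpers shared across modules.

#' Signal an invalid-argument error
#'
#' @param ... message parts passed to [sprintf()]-style paste.
#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = "invalid_argument"))
}

#' Signal an undefined-value warning (the value itself becomes NA)
#' @noRd
warn_undefined <- function(...) {
  warning(warningCondition(paste0(...), class = "undefined_value"))
}

#' Signal an undefined-value error (degenerate denominator etc.)
#' @noRd
stop_undefined <- function(...) {
  stop(errorCondition(paste0(...), class = "undefined_value"))
}

#' Evaluate code under a fixed seed, restoring RNG state afterwards
#'
#' Keeps user-visible RNG state untouched so generators are deterministic
#' without side effects on the session.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (!had) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Separable Gaussian blur of a matrix (replicate-padded edges)
#' @noRd
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], h), v, rep(v[n], h))
    as.numeric(stats::filter(vp, k, sides = 2))[(h + 1L):(h + n)]
  }
  m2 <- apply(mat, 2L, smooth1)
  t(apply(m2, 1L, smooth1))
}

#' Largest-remainder integer allocation of `total` across weights
#'
#' Exact conservation: the returned integer vector sums to `total`.
#' Ties in the fractional remainders are broken by position (first wins).
#' @noRd
largest_remainder <- function(weights, total) {
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_invalid("allocation weights must be non-negative with positive sum")
  }
  if (total < 0 || abs(total - round(total)) > 1e-8) {
    stop_invalid("`total` must be a non-negative integer count")
  }
  total <- round(total)
  ideal <- total * weights / sum(weights)
  base <- floor(ideal)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  base
}

#' All permutations of a vector (n! rows); n is tiny here (4! = 24)
#' @noRd
permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- permutations(x[-i])
    out[[i]] <- cbind(x[i], sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Centered moving mean with shrinking (partial) windows at the ends
#' @noRd
roll_mean_partial <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Check a data frame has the named columns
#' @noRd
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_invalid(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
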