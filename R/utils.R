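# Small internal helpers.

# Evaluate expr with a local, restorable RNG state so simulation functions
# are deterministic given `seed` without clobbering the caller's stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# trapezoidal integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Gaussian kernel smoothing on a regular grid; sd in grid units
.gauss_smooth <- function(y, sd) {
  if (sd <= 0) return(y)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  out <- numeric(n)
  for (j in seq_along(k)) out <- out + k[j] * ypad[j:(j + n - 1L)]
  out
}

# indices of local maxima (first index of plateau tops; which.max fallback)
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(which.max(y))
  i <- 2:(n - 1L)
  idx <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  if (length(idx) == 0L) which.max(y) else idx
}

.safe_cor <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Pearson correlation matrix of the rows of M without input checking;
# zero-variance rows yield NA entries
.row_cor <- function(M) {
  Mc <- M - rowMeans(M)
  CC <- tcrossprod(Mc)
  d <- sqrt(diag(CC))
  d[d == 0] <- NA_real_
  CC / (d %o% d)
}

# Pearson r of each row of M against y (vectorized); zero variance -> NA
.rows_vs_vector_cor <- function(M, y) {
  m <- ncol(M)
  Sx <- rowSums(M)
  Sxx <- rowSums(M * M)
  varx <- Sxx - Sx^2 / m
  Sy <- sum(y)
  vary <- sum(y * y) - Sy^2 / m
  Sxy <- as.numeric(M %*% y)
  num <- Sxy - Sx * Sy / m
  den <- sqrt(varx * vary)
  out <- rep(NA_real_, nrow(M))
  ok <- is.finite(den) & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}
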