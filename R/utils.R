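#' @useDynLib untca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Internal mutable state: node id counter and instrumentation counters.
.untcaState <- new.env(parent = emptyenv())
.untcaState$nodeId <- 0
.untcaState$gateMults <- 0L

#' Reset the elementwise-gate multiplication counter
#'
#' The recursive gate of gnConv increments an internal counter once per
#' elementwise multiplication; tests use it to verify that exactly `n`
#' gating steps occur per forward pass.
#' @return Invisibly, the reset (zero) count.
#' @export
resetGateMultCount <- function() {
  .untcaState$gateMults <- 0L
  invisible(0L)
}

#' Read the elementwise-gate multiplication counter
#' @return Integer count of gate multiplications since the last reset.
#' @export
gateMultCount <- function() .untcaState$gateMults

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls do not perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated normal draws (|z| <= 2 sd), the standard transformer/ConvNeXt
# weight initialisation. Vectorised rejection sampling.
rtruncnorm02 <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

initArray <- function(dims, sd = 0.02) array(rtruncnorm02(prod(dims), sd), dim = dims)

# Bilinear interpolation matrix mapping a length-`from` axis to `to` samples
# (half-pixel-centre convention). Returns a `to x from` matrix; applying it
# to a signal resamples that axis linearly.
bilinearMatrix <- function(from, to) {
  M <- matrix(0, to, from)
  if (from == 1L) { M[, 1] <- 1; return(M) }
  src <- (seq_len(to) - 0.5) * from / to - 0.5
  src <- pmin(pmax(src, 0), from - 1)
  lo <- floor(src); hi <- pmin(lo + 1, from - 1); fr <- src - lo
  for (i in seq_len(to)) {
    M[i, lo[i] + 1] <- M[i, lo[i] + 1] + (1 - fr[i])
    M[i, hi[i] + 1] <- M[i, hi[i] + 1] + fr[i]
  }
  M
}

# Apply matrix M (m x d_k) to dimension `dim` of array x.
tensordotDim <- function(x, M, dim) {
  d <- dim(x); nd <- length(d)
  perm <- c(dim, seq_len(nd)[-dim])
  xp <- aperm(x, perm)
  xm <- matrix(xp, nrow = d[dim])
  ym <- M %*% xm
  yd <- c(nrow(M), d[-dim])
  y <- array(ym, dim = yd)
  aperm(y, order(perm))
}

stopShape <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
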