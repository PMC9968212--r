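#' Derive a child seed from a master seed and index path
#'
#' Counter-based seed splitting: every source of randomness in the package
#' draws its seed from a master seed plus a path of integer indices
#' (pose, replicate, window, ...), so replicates are independent but the
#' whole experiment is reproducible from one integer.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the consumer (e.g. pose, replicate).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  # multiplier kept small so products stay exact in double precision
  s <- (abs(as.double(master)) + 1) %% 2147483647
  for (k in c(idx, 0xBEEF)) {
    s <- (s * 4093 + as.double(k) * 127 + 1) %% 2147483647
    s <- (s * 3467 + 17) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr with a local RNG stream; global .Random.seed is restored.
with_seed <- function(seed, expr) {
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

# Squared / plain Euclidean distance matrix between rows of A (n x 3) and B (m x 3)
pair_dist <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Angle at vertex `h` between segments h->a and h->b, in degrees
angle_at <- function(h, a, b) {
  u <- a - h; v <- b - h
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Plane fit of ring coordinates: centroid + unit normal (least-squares)
ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  sv <- svd(cen)
  n <- sv$v[, 3]
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn < 1e-8) stop("ring with non-finite normal (collinear atoms)")
  list(centroid = ctr, normal = n / nn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
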