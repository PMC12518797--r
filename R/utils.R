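# Internal helpers shared across modules.

# Lower-triangle vector of a square matrix, column-major (pair order i<j).
lower_tri <- function(m) m[lower.tri(m)]

# All permutations of 1..n as an (n! x n) matrix. Only used for small n
# (exact Mantel / Hommola enumeration), so the recursive construction is fine.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    blk <- nrow(sub)
    out[row:(row + blk - 1L), 1L] <- k
    out[row:(row + blk - 1L), -1L] <- matrix(rest[sub], nrow = blk)
    row <- row + blk
  }
  out
}

# Validate a square symmetric dissimilarity matrix with labels; returns the
# matrix with dimnames enforced.
check_dm <- function(dm, arg = "dm", require_labels = TRUE) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop(sprintf("'%s' must be a square matrix", arg))
  if (any(is.na(dm)))
    stop(sprintf("'%s' contains missing entries", arg))
  if (max(abs(dm - t(dm))) > 1e-8)
    stop(sprintf("'%s' must be symmetric", arg))
  if (require_labels) {
    if (is.null(rownames(dm)))
      stop(sprintf("'%s' must carry row/column labels", arg))
    colnames(dm) <- rownames(dm)
  }
  dm
}

# Derive a per-unit RNG seed from a master seed, kept within 32-bit range so
# set.seed() never overflows.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 999983 * as.double(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
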