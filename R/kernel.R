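# Tanimoto and MMP kernels over sparse identifier sets. Working on sets
# rather than fixed-length vectors means a test fingerprint may carry
# features never seen in training: they enlarge its self-similarity term but
# can never contribute overlap, which is exactly the union-universe vector
# formula without rebuilding any vectors.

.CORE_OFFSET <- 2^34  # tags core ids when an MMP fingerprint is flattened

#' Tanimoto kernel between two sparse feature sets
#'
#' \eqn{K(u,v) = |u \cap v| / (|u| + |v| - |u \cap v|)}. By convention the
#' similarity is 0 when either set is empty: absence of features is not
#' taken as evidence of similarity.
#'
#' @param u,v numeric vectors of feature identifiers (treated as sets).
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto_kernel(c(1, 3), c(1, 2, 3))  # 2/3
#' @export
tanimoto_kernel <- function(u, v) {
  u <- unique(u); v <- unique(v)
  if (length(u) == 0L || length(v) == 0L) return(0)
  o <- sum(u %in% v)
  o / (length(u) + length(v) - o)
}

#' MMP kernel between two MMP fingerprints
#'
#' The product of the core-wise and substituent-wise Tanimoto kernels. Two
#' MMPs are similar only when both their cores and their substituent
#' transformations are.
#'
#' @param x,z objects of class `mmp_fp`.
#' @return similarity in `[0, 1]`.
#' @export
mmp_kernel <- function(x, z) {
  tanimoto_kernel(x$core, z$core) * tanimoto_kernel(x$sub, z$sub)
}

# Flatten an mmp_fp to one identifier set (plain-Tanimoto mode); the core
# segment is offset so it cannot collide with substituent identifiers.
flatten_fp <- function(fp) c(fp$core + .CORE_OFFSET, fp$sub)

#' Gram matrix of the MMP (or flattened Tanimoto) kernel
#'
#' @param fps list of `mmp_fp` (rows).
#' @param fps2 optional second list (columns); defaults to `fps`.
#' @param kernel `"mmp"` for the product kernel, `"tanimoto"` for the plain
#'   Tanimoto kernel on the flattened core+substituent set.
#' @return numeric matrix `length(fps)` x `length(fps2)`.
#' @export
mmp_gram <- function(fps, fps2 = fps, kernel = c("mmp", "tanimoto")) {
  kernel <- match.arg(kernel)
  n <- length(fps); m <- length(fps2)
  K <- matrix(0, n, m)
  if (kernel == "mmp") {
    for (i in seq_len(n)) for (j in seq_len(m))
      K[i, j] <- mmp_kernel(fps[[i]], fps2[[j]])
  } else {
    sets <- lapply(fps, flatten_fp); sets2 <- lapply(fps2, flatten_fp)
    for (i in seq_len(n)) for (j in seq_len(m))
      K[i, j] <- tanimoto_kernel(sets[[i]], sets2[[j]])
  }
  K
}
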