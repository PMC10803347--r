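#' Truncated path signature of a piecewise-linear path
#'
#' Computes all iterated-integral coefficients of order 1..`depth` of the
#' piecewise-linear interpolation of `path`. The signature of a single
#' linear segment with increment `dx` has level-k term `dx^(k tensor)/k!`;
#' segment signatures are combined with Chen's identity (the truncated
#' tensor-algebra product), which is exact for piecewise-linear paths.
#'
#' Level-k coefficients are returned flattened in row-major index order:
#' the coefficient for the word (i1, ..., ik) sits at position
#' `((i1-1) d + (i2-1)) d + ... + ik` of level k, and the levels are
#' concatenated, giving `d + d^2 + ... + d^depth` values named
#' `s_i1`, `s_i1.i2`, ...
#'
#' @param path Numeric matrix, one row per point, `d` columns (a numeric
#'   vector is treated as a 1-dimensional path).
#' @param depth Truncation depth (integer >= 1).
#' @return Named numeric vector of signature coefficients.
#' @examples
#' # 1-d linear path from 0 to 2: level-1 = 2, level-2 = 2^2/2
#' signature_transform(cbind(c(0, 2)), depth = 2)
#' @export
signature_transform <- function(path, depth = 2) {
  if (is.null(dim(path))) path <- matrix(path, ncol = 1)
  path <- as.matrix(path)
  if (!is.numeric(depth) || depth < 1 || depth != floor(depth))
    stopf("depth must be a positive integer")
  if (nrow(path) < 2L) stopf("degenerate path: need at least 2 points")
  d <- ncol(path)
  incs <- diff(path)
  sig <- segment_signature(incs[1, ], depth)
  if (nrow(incs) > 1L) {
    for (r in 2:nrow(incs))
      sig <- chen_product(sig, segment_signature(incs[r, ], depth), d)
  }
  flatten_signature(sig, d)
}

# signature of one linear segment: level k = dx^{\otimes k} / k!
segment_signature <- function(dx, depth) {
  levels <- vector("list", depth)
  cur <- dx
  levels[[1]] <- cur
  if (depth >= 2) for (k in 2:depth) {
    cur <- kronecker(cur, dx) / k
    levels[[k]] <- cur
  }
  levels
}

#' Chen (truncated tensor-algebra) product of two signatures
#'
#' The signature of a concatenated path is the tensor product of the two
#' segment signatures: level k of the product is
#' `sum_{i+j=k} A_i (x) B_j` (with the empty level-0 term equal to 1).
#' Signatures are lists of flattened levels as produced internally by
#' [signature_transform()]; the flattening uses the first factor as the
#' slower-varying index, matching `kronecker()`.
#'
#' @param a,b Lists of per-level coefficient vectors (level k has length
#'   `d^k`).
#' @param d Path dimension.
#' @return A list of per-level coefficient vectors of the same depth.
#' @export
chen_product <- function(a, b, d) {
  depth <- length(a)
  out <- vector("list", depth)
  for (k in seq_len(depth)) {
    acc <- a[[k]] + b[[k]]        # i = k, j = 0 and i = 0, j = k
    if (k >= 2) for (i in 1:(k - 1))
      acc <- acc + kronecker(a[[i]], b[[k - i]])
    out[[k]] <- acc
  }
  out
}

flatten_signature <- function(sig, d) {
  depth <- length(sig)
  names_k <- function(k) {
    idx <- do.call(expand.grid, rev(replicate(k, seq_len(d), simplify = FALSE)))
    idx <- idx[, rev(seq_len(k)), drop = FALSE]  # first index slowest
    apply(idx, 1, function(w) paste0("s_", paste(w, collapse = ".")))
  }
  out <- unlist(sig, use.names = FALSE)
  names(out) <- unlist(lapply(seq_len(depth), names_k))
  out
}

# split a flat signature back into per-level vectors
unflatten_signature <- function(flat, d, depth) {
  lens <- d^seq_len(depth)
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_len(depth), function(k) unname(flat[starts[k]:ends[k]]))
}

#' Level-2 signature matrix
#'
#' Reshapes the level-2 block of a flat signature into the d x d matrix
#' `S[i, j]` = coefficient of the word (i, j). Satisfies the shuffle
#' identity `S + t(S) = dx %o% dx` where `dx` is the total increment.
#'
#' @param flat Output of [signature_transform()] with depth >= 2.
#' @param d Path dimension.
#' @return A `d` x `d` numeric matrix.
#' @export
signature_level2_matrix <- function(flat, d) {
  lv2 <- flat[(d + 1):(d + d^2)]
  matrix(lv2, nrow = d, ncol = d, byrow = TRUE)
}
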