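#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class feature matrix by appending synthetic minority
#' rows. Each synthetic row interpolates between a minority row `m` and
#' one of its `k` nearest minority neighbours `nn` (Euclidean
#' distance): `m + u * (nn - m)` with `u ~ Uniform(0, 1)`, so every
#' synthetic point lies on a segment between two real minority points.
#' Original rows are left unchanged and the output has equal class
#' counts.
#'
#' @param X Numeric feature matrix (rows = subjects).
#' @param y Logical labels, one per row.
#' @param k_neighbors Number of nearest minority neighbours to draw
#'   from (reduced with a warning if the minority class is too small).
#' @param seed Optional integer seed.
#' @return List with the augmented `X`, `y`, and `synthetic` (logical
#'   marker of appended rows).
#' @export
smote_balance <- function(X, y, k_neighbors = 5L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y), !anyNA(y), k_neighbors >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == n_neg)
    return(list(X = X, y = y, synthetic = rep(FALSE, length(y))))
  minority <- if (n_pos < n_neg) y else !y
  n_min <- sum(minority)
  if (n_min < 2L)
    stop("minority class has a single member; no neighbor exists",
         call. = FALSE)
  if (n_min < k_neighbors + 1L) {
    k_neighbors <- n_min - 1L
    warning("minority class too small; k_neighbors reduced to ", k_neighbors,
            call. = FALSE)
  }
  M <- X[minority, , drop = FALSE]
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  # k nearest minority neighbours of each minority row (n_min x k)
  nn_idx <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  n_new <- abs(n_neg - n_pos)
  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- nn_idx[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- runif(n_new)
  synth <- M[base, , drop = FALSE] + u * (M[pick, , drop = FALSE] -
                                            M[base, , drop = FALSE])
  rownames(synth) <- NULL
  list(X = rbind(X, synth),
       y = c(y, rep(n_pos < n_neg, n_new)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new)))
}
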