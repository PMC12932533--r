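#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Like softmax, sparsemax maps a real score vector to a probability
#' distribution, but as the exact Euclidean projection onto the simplex it
#' can assign exact zeros -- the property that makes attention masks sparse
#' and the entropy penalty meaningful. Computed by the sorted-threshold
#' rule: with `z` sorted decreasingly, the support size is the largest `k`
#' with `1 + k*z_(k) > sum_{j<=k} z_(j)`; the threshold is
#' `tau = (sum_{j<=k} z_(j) - 1)/k` and the output is `pmax(z - tau, 0)`.
#'
#' @param z Numeric vector (or matrix; rows are projected independently).
#' @return A vector (or matrix) on the probability simplex, same shape as `z`.
#' @examples
#' sparsemax(c(0, 0))    # 0.5 0.5
#' sparsemax(c(10, 0))   # 1 0
#' @export
sparsemax <- function(z) {
  if (is.matrix(z)) return(sparsemax_rows(z))
  if (any(!is.finite(z))) stop("sparsemax requires finite input", call. = FALSE)
  zs <- sort(z, decreasing = TRUE)
  cs <- cumsum(zs)
  k <- max(which(1 + seq_along(zs) * zs > cs))
  tau <- (cs[k] - 1) / k
  pmax(z - tau, 0)
}

#' Row-wise sparsemax for a matrix of scores
#' @noRd
sparsemax_rows <- function(Z) {
  if (any(!is.finite(Z))) stop("sparsemax requires finite input", call. = FALSE)
  n <- nrow(Z); d <- ncol(Z)
  if (d == 1L) return(matrix(1, n, 1L))
  Zs <- matrix(0, n, d)
  for (b in seq_len(n)) Zs[b, ] <- sort.int(Z[b, ], decreasing = TRUE,
                                            method = "quick")
  CS <- t(apply(Zs, 1L, cumsum))
  ok <- 1 + rep(seq_len(d), each = n) * Zs > CS
  k <- d + 1L - max.col(ok[, d:1, drop = FALSE], ties.method = "first")
  tau <- (CS[cbind(seq_len(n), k)] - 1) / k
  pmax(Z - tau, 0)
}

#' Backward pass of row-wise sparsemax
#'
#' The Jacobian on the active support S is `diag(1_S) - 1_S 1_S' / |S|`
#' and zero off-support, so the pulled-back gradient is the support-centered
#' upstream gradient.
#'
#' @param M Output of `sparsemax_rows` (n x D).
#' @param dM Upstream gradient, same shape.
#' @return Gradient with respect to the input scores.
#' @noRd
sparsemax_backward <- function(M, dM) {
  S <- M > 0
  dMs <- dM * S
  mean_s <- rowSums(dMs) / pmax(rowSums(S), 1L)
  (dMs - mean_s * S)
}

#' Brute-force simplex projection (quadratic-programming oracle)
#'
#' Direct search over all candidate supports: for each support size the
#' candidate threshold is checked for feasibility and the feasible projection
#' minimizing the Euclidean distance is returned. Exponential-free but
#' deliberately naive; used to validate [sparsemax()].
#'
#' @param z Numeric vector.
#' @return The projection of `z` onto the simplex.
#' @export
simplex_project_bruteforce <- function(z) {
  d <- length(z)
  best <- NULL
  best_dist <- Inf
  ord <- order(z, decreasing = TRUE)
  for (k in seq_len(d)) {
    supp <- ord[seq_len(k)]
    tau <- (sum(z[supp]) - 1) / k
    p <- rep(0, d)
    p[supp] <- z[supp] - tau
    if (all(p >= -1e-12)) {
      p <- pmax(p, 0)
      p <- p / sum(p)
      dist <- sum((p - z)^2)
      if (dist < best_dist - 1e-15) {
        best_dist <- dist
        best <- p
      }
    }
  }
  best
}
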