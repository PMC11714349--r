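# Independent oracles used to freeze expected values. These deliberately use
# naive, loop-based textbook formulations and share no code with the package
# internals they check.

# Textbook two-block NIPALS PLS2 (regression mode), iterated to a tight
# tolerance. Sign convention matched to the package: largest-magnitude
# x-weight entry positive.
nipals_pls2_oracle <- function(X, Y, k, tol = 1e-13, max_iter = 50000L) {
  E <- X
  F_ <- Y
  W <- P <- Tm <- Q <- NULL
  for (h in seq_len(k)) {
    u <- F_[, 1]
    for (it in seq_len(max_iter)) {
      w <- t(E) %*% u
      w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- t(F_) %*% t_ / sum(t_^2)
      u_new <- F_ %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    w <- t(E) %*% u
    w <- w / sqrt(sum(w^2))
    t_ <- E %*% w
    if (w[which.max(abs(w))] < 0) {
      w <- -w
      t_ <- -t_
    }
    p_ <- t(E) %*% t_ / sum(t_^2)
    q <- t(F_) %*% t_ / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p_); Q <- cbind(Q, q); Tm <- cbind(Tm, t_)
  }
  R <- W %*% solve(t(P) %*% W)
  list(W = W, P = P, Q = Q, T = Tm, R = R)
}

# Single-source Dijkstra over an explicit edge list (no igraph), O(V^2).
dijkstra_oracle <- function(coords, edges, source) {
  nv <- nrow(coords)
  wts <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                         coords[edges[, 2], , drop = FALSE])^2))
  dist <- rep(Inf, nv)
  dist[source] <- 0
  done <- logical(nv)
  for (step in seq_len(nv)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (r in which(edges[, 1] == u | edges[, 2] == u)) {
      v <- if (edges[r, 1] == u) edges[r, 2] else edges[r, 1]
      if (dist[u] + wts[r] < dist[v]) dist[v] <- dist[u] + wts[r]
    }
  }
  dist
}

# Exhaustive two-alternative 1-NN pairwise decoding: loop over every ordered
# pair (target, reference).
decoding_accuracy_oracle <- function(R) {
  n <- nrow(R)
  correct <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      total <- total + 1L
      if (R[i, i] > R[i, j]) correct <- correct + 1L
    }
  }
  correct / total
}

# Largest principal angle (degrees) between the column spans of B and A.
max_principal_angle <- function(B, A) {
  sv <- svd(crossprod(qr.Q(qr(B)), qr.Q(qr(A))))$d
  max(acos(pmin(1, sv)) * 180 / pi)
}
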