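# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: reachability is computed by repeated squaring of
# boolean adjacency matrices, and OLS by explicit normal equations.

# Transitive closure (including self-reachability) of a directed edge set.
reach_closure <- function(from, to, n) {
  R <- diag(TRUE, n)
  for (k in seq_along(from)) R[from[k], to[k]] <- TRUE
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) return(R2)
    R <- R2
  }
}

# Largest weakly connected component by undirected all-pairs reachability.
oracle_lcc <- function(from, to, n) {
  R <- reach_closure(c(from, to), c(to, from), n)
  max(table(apply(R, 1L, function(r) min(which(r)))))
}

# Largest strongly connected component from R & t(R).
oracle_lsc <- function(from, to, n) {
  R <- reach_closure(from, to, n)
  M <- R & t(R)
  max(table(apply(M, 1L, function(r) min(which(r)))))
}

# Random directed multigraph as a speech_graph object (self-loops and
# parallel edges allowed; isolated nodes possible).
random_multigraph <- function(max_nodes = 12L) {
  n <- sample.int(max_nodes, 1L)
  n_edges <- sample.int(3L * n + 1L, 1L) - 1L
  nodes <- paste0("n", seq_len(n))
  from <- sample.int(n, n_edges, replace = TRUE)
  to <- sample.int(n, n_edges, replace = TRUE)
  g <- structure(
    list(nodes = nodes,
         edges = data.frame(from = nodes[from], to = nodes[to],
                            stringsAsFactors = FALSE),
         n_tokens = NA_integer_),
    class = "speech_graph")
  list(g = g, from = from, to = to, n = n)
}

# OLS by explicit normal equations: estimates, SEs, R^2, F.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  mss <- sum((X %*% beta - mean(y))^2)
  r2 <- mss / (mss + sum(resid^2))
  list(beta = drop(beta), se = se, r2 = r2,
       f = (r2 / (p - 1)) / ((1 - r2) / (n - p)))
}

# A transcript whose tokens are all distinct, as one utterance.
distinct_transcript <- function(n) {
  transcript(list(sprintf("t%03d", seq_len(n))), "distinct")
}
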