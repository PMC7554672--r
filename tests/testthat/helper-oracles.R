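## Single-threaded BLAS: the likelihood inner loops multiply many small
## matrices, where thread spawn-up costs more than it saves.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

## Independent oracles used to check the package's dynamic-programming and
## clustering machinery.  These deliberately use brute force (state
## enumeration, power series, breadth-first search, normal equations) so
## they share no code path with the implementation they verify.

## Enumerate the states of EVERY node (tips weighted by their partials) and
## accumulate likelihoods and marginal posteriors site by site.
enum_ctmc <- function(tree, P, tipp, root_prior) {
  ti <- ancstate:::ctmc_index(tree)
  k <- length(root_prior)
  s <- ncol(tipp[[1L]])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), ti$n_node)))
  lik <- numeric(s)
  marg <- array(0, c(ti$n_node, k, s))
  joint <- vector("list", ti$n_node)       # per child node, k x k x s
  for (ch in ti$edge[, 2L]) joint[[ch]] <- array(0, c(k, k, s))
  for (site in seq_len(s)) {
    w <- root_prior[grid[, ti$root]]
    for (i in seq_len(nrow(ti$edge))) {
      p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
      w <- w * P[[ch]][cbind(grid[, p], grid[, ch])]
    }
    for (tip in seq_len(ti$n_tip)) w <- w * tipp[[tip]][grid[, tip], site]
    tot <- sum(w)
    lik[site] <- tot
    for (v in seq_len(ti$n_node)) for (x in seq_len(k)) {
      marg[v, x, site] <- sum(w[grid[, v] == x]) / tot
    }
    for (i in seq_len(nrow(ti$edge))) {
      p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
      for (x in seq_len(k)) for (y in seq_len(k)) {
        joint[[ch]][x, y, site] <-
          sum(w[grid[, p] == x & grid[, ch] == y]) / tot
      }
    }
  }
  list(loglik = sum(log(lik)), marg = marg, joint = joint)
}

## Truncated power series for expm(Q t).
series_expm <- function(Q, t, terms = 50L) {
  k <- nrow(Q)
  acc <- diag(k)
  term <- diag(k)
  for (n in seq_len(terms)) {
    term <- term %*% (Q * t) / n
    acc <- acc + term
  }
  acc
}

## Connected components by breadth-first search over an adjacency list.
bfs_components <- function(universe, edges) {
  adj <- stats::setNames(vector("list", length(universe)), universe)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(universe)), universe)
  cid <- 0L
  for (v in universe) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  comp
}

## Canonical form of a partition for equality checks.
partition_signature <- function(membership) {
  groups <- split(names(membership), membership)
  sig <- vapply(groups, function(g) paste(sort(g), collapse = "|"), character(1))
  sort(unname(sig))
}

## OLS slope/intercept via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

## Small random tree with positive branch lengths and fixed seed.
random_tree <- function(n_tips, seed) {
  simulate_tree(n_tips, seed = seed, scale = stats::runif(1, 0.3, 1.2))
}
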