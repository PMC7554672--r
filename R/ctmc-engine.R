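## Generic discrete-state CTMC machinery on a rooted tree: Felsenstein
## pruning, inside-outside (up-down) marginal posteriors, exact joint
## parent-child posteriors and joint ancestral sampling.  Shared by the
## nucleotide (thermometer) and copy-number (gene content) tracks; the state
## space is whatever the per-branch transition matrices are defined over.
##
## Conventions: nodes use the phylo integer numbering (tips 1..n, root n+1).
## P is a list indexed by CHILD node, P[[child]][parent_state, child_state].
## Tip partials are k x s matrices (states x sites); missing data = all-ones.

ctmc_index <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    children[[p]] <- c(children[[p]], po$edge[i, 2L])
  }
  parent <- integer(n_node)
  parent[po$edge[, 2L]] <- po$edge[, 1L]
  list(
    edge = po$edge, edge.length = po$edge.length,
    n_tip = n_tip, n_node = n_node, root = n_tip + 1L,
    children = children, parent = parent,
    internal_postorder = unique(po$edge[, 1L])
  )
}

## Upward (inside) pass.  Returns per-node partial likelihood matrices
## (column-rescaled, log scale factors accumulated) plus per-child messages
## msg[[c]] = P[[c]] %*% inside[[c]].
ctmc_inside <- function(ti, P, tip_partials, root_prior) {
  k <- length(root_prior)
  inside <- vector("list", ti$n_node)
  msg <- vector("list", ti$n_node)
  logscale <- vector("list", ti$n_node)
  s <- ncol(tip_partials[[1L]])
  for (tip in seq_len(ti$n_tip)) {
    inside[[tip]] <- tip_partials[[tip]]
    logscale[[tip]] <- numeric(s)
  }
  for (v in ti$internal_postorder) {
    part <- NULL
    ls <- numeric(s)
    for (ch in ti$children[[v]]) {
      msg[[ch]] <- P[[ch]] %*% inside[[ch]]
      part <- if (is.null(part)) msg[[ch]] else part * msg[[ch]]
      ls <- ls + logscale[[ch]]
    }
    # column-rescale (cheap row-wise pmax; impossible sites keep their zeros)
    cmax <- part[1L, ]
    for (i in 2:k) cmax <- pmax(cmax, part[i, ])
    cmax[cmax <= 0] <- 1
    inside[[v]] <- part * rep(1 / cmax, each = k)
    logscale[[v]] <- ls + log(cmax)
  }
  site_lik <- as.vector(crossprod(root_prior, inside[[ti$root]]))
  site_loglik <- ifelse(site_lik > 0,
                        log(site_lik) + logscale[[ti$root]], -Inf)
  list(inside = inside, msg = msg, logscale = logscale,
       site_loglik = site_loglik, loglik = sum(site_loglik))
}

## Downward (outside) pass.  outside[[v]][x, site] is proportional to the
## likelihood of all data outside v's subtree jointly with state x at v;
## columns are renormalized (marginals/joints renormalize anyway).
ctmc_outside <- function(ti, P, ins, keep_above = FALSE) {
  k <- nrow(ins$inside[[ti$root]])
  s <- ncol(ins$inside[[ti$root]])
  outside <- vector("list", ti$n_node)
  above_list <- if (keep_above) vector("list", ti$n_node) else NULL
  outside[[ti$root]] <- matrix(attr(ins, "root_prior"), k, s)
  for (v in rev(ti$internal_postorder)) {
    kids <- ti$children[[v]]
    for (ch in kids) {
      above <- outside[[v]]
      for (sib in kids) if (sib != ch) above <- above * ins$msg[[sib]]
      if (keep_above) above_list[[ch]] <- above
      out <- crossprod(P[[ch]], above)      # t(P) %*% above
      norm <- out[1L, ]
      for (i in 2:k) norm <- pmax(norm, out[i, ])
      norm[norm <= 0] <- 1
      outside[[ch]] <- out * rep(1 / norm, each = k)
    }
  }
  if (keep_above) list(outside = outside, above = above_list) else outside
}

## Marginal posterior state distributions at every node (k x s per node,
## columns summing to 1).
ctmc_marginals <- function(ti, P, tip_partials, root_prior) {
  ins <- ctmc_inside(ti, P, tip_partials, root_prior)
  attr(ins, "root_prior") <- root_prior
  outs <- ctmc_outside(ti, P, ins)
  lapply(seq_len(ti$n_node), function(v) {
    m <- ins$inside[[v]] * outs[[v]]
    tot <- colSums(m)
    tot[tot <= 0] <- 1
    sweep(m, 2L, tot, "/")
  })
}

## Exact joint parent-child posterior for one branch and one site:
## J[x, y] = P(parent = x, child = y | data).
ctmc_joint_branch <- function(ti, P, ins, outs, child, site = 1L) {
  v <- ti$parent[child]
  above <- outs[[v]][, site]
  for (sib in ti$children[[v]]) {
    if (sib != child) above <- above * ins$msg[[sib]][, site]
  }
  J <- (above * P[[child]]) *
    rep(ins$inside[[child]][, site], each = length(above))
  tot <- sum(J)
  if (tot <= 0) stop("joint posterior has zero mass (impossible data?)")
  J / tot
}

## Joint posterior samples of ancestral states at every internal node:
## root from its marginal posterior, children conditionally on the sampled
## parent, independently across sites and replicates.  Returns an
## (n_node x s*R) integer matrix of state indices, replicates laid out as R
## consecutive blocks of s sites.  Ties in the categorical draws resolve by
## cumulative order of the state indexing.
ctmc_sample_joint <- function(ti, P, ins, root_prior, R = 1L) {
  k <- length(root_prior)
  s <- ncol(ins$inside[[ti$root]])
  m <- s * R
  rep_cols <- rep.int(seq_len(s), R)
  states <- matrix(NA_integer_, ti$n_node, m)
  draw <- function(w) {            # w: k x m nonneg weights, one draw per col
    cw <- w
    for (i in 2:k) cw[i, ] <- cw[i, ] + cw[i - 1L, ]
    tot <- cw[k, ]
    tot[tot <= 0] <- NA
    u <- stats::runif(m) * tot
    1L + colSums(cw < rep(u, each = k))
  }
  states[ti$root, ] <- draw(root_prior *
                              ins$inside[[ti$root]][, rep_cols, drop = FALSE])
  for (v in rev(ti$internal_postorder)) {
    for (ch in ti$children[[v]]) {
      w <- t(P[[ch]][states[v, ], , drop = FALSE]) *
        ins$inside[[ch]][, rep_cols, drop = FALSE]
      states[ch, ] <- draw(w)
    }
  }
  states
}
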