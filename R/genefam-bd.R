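## Phylogenetic birth-and-death (gain-loss-duplication) reconstruction of
## ancestral gene-family content.  Copy number per family evolves along the
## tree as a continuous-time Markov chain: innovation 0 -> 1 at rate g,
## per-copy duplication at rate lam, per-copy loss at rate mu, truncated at
## a copy-number cap C_max.  Rates are estimated independently per family;
## posterior copy-number distributions and per-branch event probabilities
## are exact (inside-outside), and events/presence are called where the
## posterior probability exceeds a fixed threshold tau (default 0.5,
## strictly).

#' Gain-loss-duplication rate matrix
#'
#' Generator on copy-number states `0..cmax`: `q(n, n+1) = g + n*lam`,
#' `q(n, n-1) = n*mu`, no up-transition out of the cap.
#'
#' @param g innovation (gain) rate, per unit branch length.
#' @param lam per-copy duplication rate.
#' @param mu per-copy loss rate.
#' @param cmax truncation cap (>= 2).
#' @return `(cmax+1) x (cmax+1)` generator, states named "0".."cmax".
#' @export
bd_generator <- function(g, lam, mu, cmax = 10L) {
  stopifnot(g >= 0, lam >= 0, mu >= 0, cmax >= 2L)
  k <- cmax + 1L
  Q <- matrix(0, k, k, dimnames = list(0:cmax, 0:cmax))
  n <- 0:(cmax - 1L)
  Q[cbind(n + 1L, n + 2L)] <- g + n * lam
  n <- 1:cmax
  Q[cbind(n + 1L, n)] <- n * mu
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the truncated gain-loss-duplication chain
#'
#' Detailed-balance solution `w(n+1)/w(n) = (g + n*lam) / ((n+1)*mu)`.
#' Degenerate corners: `g = 0` gives a point mass at 0 (state 0 absorbing);
#' `mu = 0` with `g > 0` gives a point mass at the cap.
#'
#' @inheritParams bd_generator
#' @return probability vector over `0..cmax`.
#' @export
bd_stationary <- function(g, lam, mu, cmax = 10L) {
  k <- cmax + 1L
  if (g == 0) return(stats::setNames(c(1, numeric(cmax)), 0:cmax))
  if (mu == 0) return(stats::setNames(c(numeric(cmax), 1), 0:cmax))
  w <- numeric(k)
  w[1L] <- 1
  for (n in 0:(cmax - 1L)) {
    w[n + 2L] <- w[n + 1L] * (g + n * lam) / ((n + 1L) * mu)
  }
  stats::setNames(w / sum(w), 0:cmax)
}

## Per-edge transition matrices for one family, via a single
## eigendecomposition of the generator (transition_matrix() as fallback).
bd_P_list <- function(tree, g, lam, mu, cmax) {
  Q <- bd_generator(g, lam, mu, cmax)
  n_node <- length(tree$tip.label) + tree$Nnode
  P <- vector("list", n_node)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(eg$vectors %*% (eg$values * Vinv))
      ok <- max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q)))
    }
  }
  for (i in seq_len(nrow(tree$edge))) {
    t <- tree$edge.length[i]
    if (ok) {
      M <- Re(eg$vectors %*% (exp(eg$values * t) * Vinv))
      M[M < 0] <- 0
      M <- M / rowSums(M)
    } else {
      M <- transition_matrix(Q, t)
    }
    P[[tree$edge[i, 2L]]] <- M
  }
  P
}

## Tip partial likelihoods for one family: point mass at the observed count,
## truncated at cmax; NA counts are missing data.
bd_tip_partials <- function(tree, counts, cmax) {
  missing <- setdiff(tree$tip.label, names(counts))
  if (length(missing)) {
    stop("counts lack tree leaves: ", paste(missing, collapse = ", "))
  }
  k <- cmax + 1L
  lapply(tree$tip.label, function(lab) {
    p <- matrix(0, k, 1L)
    n <- counts[[lab]]
    if (is.na(n)) { p[] <- 1 } else { p[min(n, cmax) + 1L, 1L] <- 1 }
    p
  })
}

bd_root_prior <- function(root_prior, g, lam, mu, cmax) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == cmax + 1L, abs(sum(root_prior) - 1) < 1e-9)
    return(root_prior)
  }
  if (identical(root_prior, "stationary")) {
    return(bd_stationary(g, lam, mu, cmax))
  }
  if (is.list(root_prior) && identical(root_prior$type, "poisson")) {
    w <- stats::dpois(0:cmax, root_prior$mean)
    return(w / sum(w))
  }
  stop("unknown root prior specification")
}

#' Log-likelihood of one family's leaf counts under the birth-death model
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param counts named integer vector of copy numbers at the leaves
#'   (values above `cmax` are truncated).
#' @param g,lam,mu gain-loss-duplication rates.
#' @param cmax truncation cap.
#' @param root_prior `"stationary"` (default), a probability vector over
#'   `0..cmax`, or `list(type = "poisson", mean = m)`.
#' @return log-likelihood (scalar).
#' @export
family_loglik <- function(tree, counts, g, lam, mu, cmax = 10L,
                          root_prior = "stationary") {
  tree <- validate_tree(tree)
  ti <- ctmc_index(tree)
  tipp <- bd_tip_partials(tree, counts, cmax)
  P <- bd_P_list(tree, g, lam, mu, cmax)
  pr <- bd_root_prior(root_prior, g, lam, mu, cmax)
  ctmc_inside(ti, P, tipp, pr)$loglik
}

#' Fit gain-loss-duplication rates per family by maximum likelihood
#'
#' Bounded quasi-Newton optimization of [family_loglik()] on the log-rate
#' scale, independently for every column of the occurrence matrix. Families
#' observed in no genome are rejected; optimizer failures are flagged and
#' the remaining families still processed.
#'
#' @param tree rooted `phylo`; leaves must match the matrix rows.
#' @param mat occurrence matrix (genomes x families).
#' @param config list of options: `cmax` (default 10), `root_prior`
#'   (default `"stationary"`), `bounds` (default `c(1e-4, 100)`), `maxit`
#'   (default 100), `init` (optional `c(g, lam, mu)`), `model` (`"gld"`,
#'   the default, fits all three rates; `"gl"` fixes the duplication rate
#'   at 0 and fits gain and loss only).
#' @return data.frame (one row per family): `family`, `g`, `lam`, `mu`,
#'   `logLik`, `init_logLik`, `converged`; attribute `"config"`.
#' @export
fit_rates <- function(tree, mat, config = list()) {
  cfg <- utils::modifyList(list(
    cmax = 10L, root_prior = "stationary", bounds = c(1e-4, 100),
    maxit = 100L, init = NULL, model = "gld"
  ), config)
  stopifnot(cfg$model %in% c("gld", "gl"))
  tree <- validate_tree(tree)
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing)) {
    stop("occurrence matrix lacks tree leaves: ", paste(missing, collapse = ", "))
  }
  if (any(colSums(mat) == 0)) {
    stop("family observed in zero genomes: ",
         paste(colnames(mat)[colSums(mat) == 0], collapse = ", "))
  }
  ti <- ctmc_index(tree)
  lb <- log(cfg$bounds[1L]); ub <- log(cfg$bounds[2L])
  ## families with identical (truncated) leaf-count patterns share one ML
  ## fit; compute unique patterns once and map back afterwards
  trunc_mat <- pmin(mat[tree$tip.label, , drop = FALSE], cfg$cmax)
  pattern_key <- apply(trunc_mat, 2L, paste, collapse = ",")
  uniq_idx <- which(!duplicated(pattern_key))
  res <- vector("list", length(uniq_idx))
  names(res) <- pattern_key[uniq_idx]
  for (jj in seq_along(uniq_idx)) {
    j <- uniq_idx[jj]
    counts <- stats::setNames(mat[tree$tip.label, j], tree$tip.label)
    if (any(counts > cfg$cmax)) {
      warning("family ", colnames(mat)[j], ": counts above cmax truncated")
    }
    tipp <- bd_tip_partials(tree, counts, cfg$cmax)
    gl_only <- cfg$model == "gl"
    expand <- function(lpar) {
      r <- exp(lpar)
      if (gl_only) c(r[1L], 0, r[2L]) else r
    }
    nll <- function(lpar) {
      r <- expand(lpar)
      P <- bd_P_list(tree, r[1L], r[2L], r[3L], cfg$cmax)
      pr <- bd_root_prior(cfg$root_prior, r[1L], r[2L], r[3L], cfg$cmax)
      ll <- ctmc_inside(ti, P, tipp, pr)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    p_occ <- mean(counts > 0, na.rm = TRUE)
    init <- if (!is.null(cfg$init)) cfg$init else {
      c(max(-log(1 - min(p_occ, 0.95)), 0.02), 0.05, 1)
    }
    if (gl_only) init <- init[c(1L, 3L)]
    lpar0 <- pmin(pmax(log(init), lb), ub)
    fit <- tryCatch(
      stats::optim(lpar0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = cfg$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) {
      res[[jj]] <- data.frame(g = NA, lam = NA, mu = NA, logLik = NA,
                              init_logLik = -nll(lpar0), converged = FALSE)
    } else {
      r <- expand(fit$par)
      res[[jj]] <- data.frame(g = r[1L], lam = r[2L], mu = r[3L],
                              logLik = -fit$value, init_logLik = -nll(lpar0),
                              converged = fit$convergence == 0L)
    }
  }
  out <- do.call(rbind, res[match(pattern_key, names(res))])
  out <- cbind(data.frame(family = colnames(mat), stringsAsFactors = FALSE),
               out)
  rownames(out) <- out$family
  attr(out, "config") <- cfg
  out
}

#' Fit shared gain-loss-duplication rates pooled over all families
#'
#' Maximizes the summed log-likelihood of every family under one common
#' rate triple. Identical leaf-count patterns are collapsed with weights,
#' so the cost is driven by the number of distinct patterns, not families.
#' Optionally conditions each family's likelihood on being observed in at
#' least one genome (ascertainment correction for unobservable families).
#'
#' @inheritParams fit_rates
#' @param config as in [fit_rates()], plus `condition_on_observed`
#'   (default `FALSE`).
#' @return one-row data.frame `g`, `lam`, `mu`, `logLik`, `converged`;
#'   attribute `"config"`.
#' @export
fit_rates_pooled <- function(tree, mat, config = list()) {
  cfg <- utils::modifyList(list(
    cmax = 10L, root_prior = "stationary", bounds = c(1e-4, 100),
    maxit = 200L, model = "gld", condition_on_observed = FALSE
  ), config)
  stopifnot(cfg$model %in% c("gld", "gl"))
  tree <- validate_tree(tree)
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing)) {
    stop("occurrence matrix lacks tree leaves: ", paste(missing, collapse = ", "))
  }
  ti <- ctmc_index(tree)
  k <- cfg$cmax + 1L
  m <- pmin(mat[tree$tip.label, , drop = FALSE], cfg$cmax)
  key <- apply(m, 2L, paste, collapse = ",")
  uniq <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[uniq])))
  mu_pat <- m[, uniq, drop = FALSE]
  s <- ncol(mu_pat)
  tipp <- lapply(seq_len(ti$n_tip), function(i) {
    p <- matrix(0, k, s)
    p[cbind(mu_pat[i, ] + 1L, seq_len(s))] <- 1
    p
  })
  zero_tipp <- lapply(seq_len(ti$n_tip), function(i) {
    p <- matrix(0, k, 1L); p[1L, 1L] <- 1; p
  })
  gl_only <- cfg$model == "gl"
  expand <- function(lpar) {
    r <- exp(lpar)
    if (gl_only) c(r[1L], 0, r[2L]) else r
  }
  nll <- function(lpar) {
    r <- expand(lpar)
    P <- bd_P_list(tree, r[1L], r[2L], r[3L], cfg$cmax)
    pr <- bd_root_prior(cfg$root_prior, r[1L], r[2L], r[3L], cfg$cmax)
    ll <- sum(w * ctmc_inside(ti, P, tipp, pr)$site_loglik)
    if (cfg$condition_on_observed) {
      l0 <- ctmc_inside(ti, P, zero_tipp, pr)$loglik
      ll <- ll - sum(w) * log1p(-exp(l0))
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  p_occ <- mean(m > 0)
  init <- c(max(-log(1 - min(p_occ, 0.95)), 0.02), 0.05, 1)
  if (gl_only) init <- init[c(1L, 3L)]
  lb <- log(cfg$bounds[1L]); ub <- log(cfg$bounds[2L])
  fit <- stats::optim(pmin(pmax(log(init), lb), ub), nll,
                      method = "L-BFGS-B", lower = lb, upper = ub,
                      control = list(maxit = cfg$maxit))
  r <- expand(fit$par)
  out <- data.frame(g = r[1L], lam = r[2L], mu = r[3L],
                    logLik = -fit$value, converged = fit$convergence == 0L)
  attr(out, "config") <- cfg
  out
}

## Shared inside/outside computation for one family.
bd_updown <- function(tree, ti, counts, g, lam, mu, cmax, root_prior) {
  tipp <- bd_tip_partials(tree, counts, cmax)
  P <- bd_P_list(tree, g, lam, mu, cmax)
  pr <- bd_root_prior(root_prior, g, lam, mu, cmax)
  ins <- ctmc_inside(ti, P, tipp, pr)
  attr(ins, "root_prior") <- pr
  outs <- ctmc_outside(ti, P, ins)
  list(P = P, ins = ins, outs = outs, prior = pr)
}

#' Posterior copy-number distributions at every node, per family
#'
#' Exact marginal posteriors from the inside-outside algorithm, given the
#' fitted per-family rates. Leaf posteriors are point masses at the observed
#' (truncated) counts.
#'
#' @param tree rooted `phylo`.
#' @param mat occurrence matrix (genomes x families).
#' @param rates data.frame from [fit_rates()] (columns `family`, `g`,
#'   `lam`, `mu`).
#' @param cmax truncation cap (default from the rates attribute, else 10).
#' @param root_prior see [family_loglik()].
#' @return object of class `node_posterior`: list `posteriors` (family ->
#'   nodes x (cmax+1) matrix, rows named by node label), `nodes`, `cmax`.
#' @export
node_posteriors <- function(tree, mat, rates, cmax = NULL,
                            root_prior = "stationary") {
  tree <- validate_tree(tree)
  cfg <- attr(rates, "config")
  if (is.null(cmax)) cmax <- if (!is.null(cfg)) cfg$cmax else 10L
  ti <- ctmc_index(tree)
  labs <- node_labels(tree)
  fams <- intersect(colnames(mat), rates$family)
  post <- vector("list", length(fams))
  names(post) <- fams
  for (f in fams) {
    r <- rates[rates$family == f, ]
    counts <- stats::setNames(mat[tree$tip.label, f], tree$tip.label)
    ud <- bd_updown(tree, ti, counts, r$g, r$lam, r$mu, cmax, root_prior)
    m <- vapply(seq_len(ti$n_node), function(v) {
      p <- ud$ins$inside[[v]][, 1L] * ud$outs[[v]][, 1L]
      p / sum(p)
    }, numeric(cmax + 1L))
    m <- t(m)
    dimnames(m) <- list(labs, 0:cmax)
    post[[f]] <- m
  }
  structure(list(posteriors = post, nodes = labs, cmax = cmax,
                 n_tip = ti$n_tip),
            class = "node_posterior")
}

#' Per-branch event probabilities and calls
#'
#' For every family and branch, the exact joint parent-child posterior over
#' copy numbers is aggregated into the four event classes: gain
#' (parent 0, child >= 1), loss (parent >= 1, child 0), expansion
#' (child > parent >= 1) and contraction (parent > child >= 1). An event is
#' called when its probability is strictly greater than `tau`.
#'
#' @inheritParams node_posteriors
#' @param tau posterior call threshold in (0, 1), default 0.5.
#' @return data.frame with one row per (family, branch): `family`,
#'   `parent`, `child`, `p_gain`, `p_loss`, `p_expand`, `p_contract` and
#'   the corresponding logical `call_*` columns.
#' @export
call_events <- function(tree, mat, rates, tau = 0.5, cmax = NULL,
                        root_prior = "stationary") {
  stopifnot(tau > 0, tau < 1)
  tree <- validate_tree(tree)
  cfg <- attr(rates, "config")
  if (is.null(cmax)) cmax <- if (!is.null(cfg)) cfg$cmax else 10L
  ti <- ctmc_index(tree)
  labs <- node_labels(tree)
  k <- cmax + 1L
  par_idx <- matrix(rep(0:cmax, k), k, k)        # parent state by row
  chi_idx <- t(par_idx)
  m_gain <- par_idx == 0 & chi_idx >= 1
  m_loss <- par_idx >= 1 & chi_idx == 0
  m_exp <- chi_idx > par_idx & par_idx >= 1
  m_con <- par_idx > chi_idx & chi_idx >= 1
  fams <- intersect(colnames(mat), rates$family)
  rows <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    f <- fams[fi]
    r <- rates[rates$family == f, ]
    counts <- stats::setNames(mat[tree$tip.label, f], tree$tip.label)
    ud <- bd_updown(tree, ti, counts, r$g, r$lam, r$mu, cmax, root_prior)
    children <- ti$edge[, 2L]
    pg <- pl <- pe <- pc <- numeric(length(children))
    for (i in seq_along(children)) {
      J <- ctmc_joint_branch(ti, ud$P, ud$ins, ud$outs, children[i])
      pg[i] <- sum(J[m_gain]); pl[i] <- sum(J[m_loss])
      pe[i] <- sum(J[m_exp]); pc[i] <- sum(J[m_con])
    }
    rows[[fi]] <- data.frame(
      family = f, parent = labs[ti$edge[, 1L]], child = labs[children],
      p_gain = pg, p_loss = pl, p_expand = pe, p_contract = pc,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$call_gain <- out$p_gain > tau
  out$call_loss <- out$p_loss > tau
  out$call_expand <- out$p_expand > tau
  out$call_contract <- out$p_contract > tau
  attr(out, "tau") <- tau
  out
}

#' Ancestral genome content at the presence threshold
#'
#' A family is called present at a node when its posterior probability of
#' copy number >= 1 is strictly greater than `tau`, and multicopy when
#' P(copy number >= 2) is strictly greater than `tau`.
#'
#' @param posteriors a `node_posterior`.
#' @param tau presence threshold (default 0.5).
#' @return data.frame per node: `node`, `n_present`, `n_multicopy`,
#'   `is_leaf`; attribute `"families"` holds per-node present/multicopy
#'   family lists.
#' @export
ancestral_content <- function(posteriors, tau = 0.5) {
  stopifnot(inherits(posteriors, "node_posterior"), tau > 0, tau < 1)
  nodes <- posteriors$nodes
  p_present <- vapply(posteriors$posteriors, function(m) 1 - m[, "0"],
                      numeric(length(nodes)))
  p_multi <- vapply(posteriors$posteriors,
                    function(m) 1 - m[, "0"] - m[, "1"],
                    numeric(length(nodes)))
  pres <- p_present > tau
  multi <- p_multi > tau
  fam_lists <- lapply(seq_along(nodes), function(i) list(
    present = colnames(p_present)[pres[i, ]],
    multicopy = colnames(p_multi)[multi[i, ]]))
  names(fam_lists) <- nodes
  out <- data.frame(
    node = nodes,
    n_present = rowSums(pres),
    n_multicopy = rowSums(multi),
    is_leaf = seq_along(nodes) <= posteriors$n_tip,
    stringsAsFactors = FALSE)
  attr(out, "families") <- fam_lists
  attr(out, "tau") <- tau
  out
}

#' Per-branch gain rates
#'
#' Called gains per branch divided by branch length, with branches
#' partitioned into ancestral (internal child) and contemporary (leaf
#' child). Zero-length branches are excluded with a warning.
#'
#' @param events data.frame from [call_events()].
#' @param tree the tree the events were called on.
#' @return data.frame per branch: `parent`, `child`, `branch_length`,
#'   `n_gains`, `gain_rate`, `class`.
#' @export
gain_rates <- function(events, tree) {
  tree <- validate_tree(tree)
  bt <- branch_table(tree)
  gains <- stats::aggregate(call_gain ~ child, data = events, FUN = sum)
  bt$n_gains <- gains$call_gain[match(bt$child_id, gains$child)]
  bt$n_gains[is.na(bt$n_gains)] <- 0L
  zero <- bt$branch_length <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-length branch(es) from gain rates")
    bt <- bt[!zero, , drop = FALSE]
  }
  data.frame(
    parent = bt$parent_id, child = bt$child_id,
    branch_length = bt$branch_length, n_gains = bt$n_gains,
    gain_rate = bt$n_gains / bt$branch_length,
    class = ifelse(bt$child_is_leaf, "contemporary", "ancestral"),
    stringsAsFactors = FALSE)
}

#' Compare gain rates between branch classes
#'
#' Primary method is the Wilcoxon rank-sum test on two independent groups:
#' exact p-value by complete enumeration of rank assignments when the
#' combined sample size is at most 12 and there are no ties, a normal
#' approximation with tie correction otherwise. A paired signed-rank
#' variant (via [stats::wilcox.test()]) is available behind `method`.
#'
#' @param a,b numeric vectors of per-branch rates.
#' @param method `"ranksum"` (default) or `"signedrank"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative about group `a` relative to group `b`).
#' @return list with `statistic` (rank-sum W of group a), `p_value`,
#'   `method`, `exact`.
#' @export
compare_gain_rates <- function(a, b, method = c("ranksum", "signedrank"),
                               alternative = c("two.sided", "less", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (method == "signedrank") {
    ht <- stats::wilcox.test(a, b, paired = TRUE, alternative = alternative)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "signedrank", exact = is.null(ht$parameter)))
  }
  ranksum_test(a, b, alternative)
}

ranksum_test <- function(a, b, alternative) {
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(na)])                    # rank-sum of group a
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n <= 12L) {
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(rk[combos], nrow = na))
    p_le <- mean(sums <= W)
    p_ge <- mean(sums >= W)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = W, p_value = p, method = "ranksum", exact = TRUE))
  }
  mu <- na * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (W - mu) / sqrt(sigma2)
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p_value = min(1, p), method = "ranksum", exact = FALSE)
}

#' Relate gain proportion to branch length
#'
#' For ancestral branches, regresses the proportion of gains (called gains
#' divided by families present at the child node) on branch length
#' (substitutions/site); returns the Pearson correlation and the OLS line.
#'
#' @param events data.frame from [call_events()].
#' @param tree the reference tree.
#' @param content data.frame from [ancestral_content()].
#' @return list with `r`, `slope`, `intercept`, `n`, `data`.
#' @export
gains_vs_substitutions <- function(events, tree, content) {
  gr <- gain_rates(events, tree)
  gr <- gr[gr$class == "ancestral", , drop = FALSE]
  if (nrow(gr) < 3L) stop("need >= 3 ancestral branches")
  n_present <- stats::setNames(content$n_present, content$node)
  y <- gr$n_gains / n_present[gr$child]
  x <- gr$branch_length
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    stop("degenerate variance: correlation undefined")
  }
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = nrow(gr),
       data = data.frame(child = gr$child, branch_length = x,
                         gain_proportion = y, stringsAsFactors = FALSE))
}
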