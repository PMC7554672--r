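test_that("the gain-loss-duplication generator has the stated structure", {
  Q <- bd_generator(0.4, 0.2, 0.9, cmax = 5)
  expect_equal(rowSums(Q), rep(0, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Q["0", "1"], 0.4)
  expect_equal(Q["2", "3"], 0.4 + 2 * 0.2)
  expect_equal(Q["3", "2"], 3 * 0.9)
  expect_equal(Q["5", "4"], 5 * 0.9)
  expect_true(all(Q["5", 6] <= 0))          # no up-transition out of the cap

  # with no innovation, state 0 is absorbing
  Q0 <- bd_generator(0, 0.3, 0.5, cmax = 4)
  expect_equal(unname(Q0[1, ]), rep(0, 5))
})

test_that("the stationary distribution satisfies pi Q = 0", {
  for (r in list(c(0.4, 0.2, 0.9), c(1, 0, 0.5), c(0.05, 0.3, 1.5))) {
    pi <- bd_stationary(r[1], r[2], r[3], cmax = 8)
    Q <- bd_generator(r[1], r[2], r[3], cmax = 8)
    expect_equal(as.vector(pi %*% Q), rep(0, 9), tolerance = 1e-12)
    expect_equal(sum(pi), 1)
  }
  expect_equal(unname(bd_stationary(0, 0.3, 0.5, cmax = 3)), c(1, 0, 0, 0))
})

test_that("family likelihood reproduces closed forms on degenerate trees", {
  # pure death on a single branch: P(extinct by t) = 1 - exp(-mu t)
  tr <- read_newick("(tipA:0.7,tipB:0.0):0;")
  ll <- family_loglik(tr, c(tipA = 0, tipB = 1), g = 0, lam = 0, mu = 1.3,
                      cmax = 3, root_prior = c(0, 1, 0, 0))
  expect_equal(ll, log(1 - exp(-1.3 * 0.7)), tolerance = 1e-12)

  # zero-length branches: likelihood is the root prior of the shared state
  tr0 <- read_newick("((a:0,b:0):0,c:0);", missing_length = "error")
  prior <- c(0.2, 0.5, 0.2, 0.1)
  ll0 <- family_loglik(tr0, c(a = 1, b = 1, c = 1), g = 0.3, lam = 0.1,
                       mu = 0.4, cmax = 3, root_prior = prior)
  expect_equal(ll0, log(0.5), tolerance = 1e-12)
})

test_that("likelihood, posteriors and joints match exhaustive enumeration", {
  for (seed in 1:6) {
    set.seed(seed)
    n_tip <- sample(3:5, 1)
    tree <- random_tree(n_tip, seed + 40)
    cmax <- 3L
    g <- runif(1, 0.05, 1); lam <- runif(1, 0, 0.5); mu <- runif(1, 0.2, 1.5)
    counts <- stats::setNames(sample(0:cmax, n_tip, replace = TRUE),
                              tree$tip.label)
    prior <- bd_stationary(g, lam, mu, cmax)
    ti <- ancstate:::ctmc_index(tree)
    P <- ancstate:::bd_P_list(tree, g, lam, mu, cmax)
    tipp <- ancstate:::bd_tip_partials(tree, counts, cmax)
    oracle <- enum_ctmc(tree, P, tipp, prior)

    ll <- family_loglik(tree, counts, g, lam, mu, cmax = cmax)
    expect_equal(ll, oracle$loglik, tolerance = 1e-8)

    rates <- data.frame(family = "F1", g = g, lam = lam, mu = mu)
    mat <- matrix(counts, ncol = 1,
                  dimnames = list(names(counts), "F1"))
    post <- node_posteriors(tree, mat, rates, cmax = cmax)
    expect_equal(max(abs(post$posteriors$F1 - oracle$marg[, , 1])), 0,
                 tolerance = 1e-8)
    expect_equal(unname(rowSums(post$posteriors$F1)),
                 rep(1, ti$n_node), tolerance = 1e-9)
    # leaf posteriors are point masses at the observed counts
    for (tip in seq_len(n_tip)) {
      expect_equal(unname(post$posteriors$F1[tip, counts[tip] + 1L]), 1,
                   tolerance = 1e-9)
    }

    ud <- ancstate:::bd_updown(tree, ti, counts, g, lam, mu, cmax,
                               "stationary")
    for (child in ti$edge[, 2L]) {
      J <- ancstate:::ctmc_joint_branch(ti, ud$P, ud$ins, ud$outs, child)
      expect_equal(max(abs(J - oracle$joint[[child]][, , 1])), 0,
                   tolerance = 1e-8)
    }
  }
})

test_that("event probabilities partition and events match enumeration", {
  set.seed(9)
  tree <- random_tree(4, 77)
  cmax <- 3L
  counts <- stats::setNames(c(2, 0, 1, 1), tree$tip.label)
  g <- 0.5; lam <- 0.25; mu <- 0.8
  rates <- data.frame(family = "F1", g = g, lam = lam, mu = mu)
  mat <- matrix(counts, ncol = 1, dimnames = list(names(counts), "F1"))
  ev <- call_events(tree, mat, rates, tau = 0.5, cmax = cmax)

  ti <- ancstate:::ctmc_index(tree)
  P <- ancstate:::bd_P_list(tree, g, lam, mu, cmax)
  tipp <- ancstate:::bd_tip_partials(tree, counts, cmax)
  oracle <- enum_ctmc(tree, P, tipp, bd_stationary(g, lam, mu, cmax))
  labs <- node_labels(tree)
  for (i in seq_len(nrow(ti$edge))) {
    child <- ti$edge[i, 2L]
    J <- oracle$joint[[child]][, , 1]
    row <- ev[ev$child == labs[child], ]
    idx <- 0:cmax
    expect_equal(row$p_gain, sum(J[1, idx >= 1]), tolerance = 1e-8)
    expect_equal(row$p_loss, sum(J[idx >= 1, 1]), tolerance = 1e-8)
    pm <- matrix(idx, cmax + 1, cmax + 1)
    cm <- t(pm)
    expect_equal(row$p_expand, sum(J[cm > pm & pm >= 1]), tolerance = 1e-8)
    expect_equal(row$p_contract, sum(J[pm > cm & cm >= 1]), tolerance = 1e-8)
    # the four event classes plus "no change class" cover everything
    p_rest <- sum(J[pm == cm]) + sum(J[pm == 0 & cm == 0])
    expect_equal(row$p_gain + row$p_loss + row$p_expand + row$p_contract +
                   sum(J[pm == cm]), 1, tolerance = 1e-9)
  }
})

test_that("forcing constructions produce certain losses, called strictly", {
  # family fixed present everywhere except one subtree, near-zero rates:
  # the stem branch of the absent clade must carry a certain loss
  tree <- read_newick("((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  tree <- label_ancestors(tree, c("c,d" = "CD"))
  counts <- c(a = 1, b = 1, c = 0, d = 0)
  rates <- data.frame(family = "F1", g = 1e-4, lam = 1e-4, mu = 0.5)
  mat <- matrix(counts, ncol = 1, dimnames = list(names(counts), "F1"))
  # root known present: the absence under the (c,d) clade must be a loss
  ev <- call_events(tree, mat, rates, tau = 0.5, cmax = 4,
                    root_prior = c(0, 1, 0, 0, 0))
  stem <- ev[ev$child == "CD", ]
  expect_gt(stem$p_loss, 0.9)
  expect_true(stem$call_loss)
  expect_false(any(ev$call_gain))
})

test_that("presence calls use a strict threshold and are monotone in tau", {
  # hand-built posterior object: P(n >= 1) exactly 0.5 must NOT be present
  post <- structure(list(
    posteriors = list(F1 = matrix(c(0.5, 0.5, 0, 0.49, 0.26, 0.25),
                                  nrow = 2, byrow = TRUE,
                                  dimnames = list(c("t1", "N1"), 0:2))),
    nodes = c("t1", "N1"), cmax = 2L, n_tip = 1L), class = "node_posterior")
  content <- ancestral_content(post, tau = 0.5)
  expect_equal(content$n_present, c(0L, 1L))   # 0.5 excluded, 0.51 included
  expect_equal(content$n_multicopy, c(0L, 0L)) # P(n>=2)=0.25 not called

  set.seed(13)
  tree <- random_tree(8, 5)
  sim <- simulate_family_evolution(tree, 60, seed = 6)
  mat <- sim$matrix[, colSums(sim$matrix) > 0, drop = FALSE]
  rates <- data.frame(family = colnames(mat), g = 0.35, lam = 0, mu = 0.7)
  posts <- node_posteriors(tree, mat, rates, cmax = 6)
  taus <- c(0.3, 0.5, 0.7, 0.9)
  counts <- sapply(taus, function(tau)
    ancestral_content(posts, tau = tau)$n_present)
  for (j in seq_len(ncol(counts) - 1L)) {
    expect_true(all(counts[, j + 1L] <= counts[, j]))
  }
})

test_that("truncation cap barely moves posteriors when counts are small", {
  set.seed(17)
  tree <- random_tree(6, 91)
  counts <- stats::setNames(c(0, 1, 2, 4, 1, 0), tree$tip.label)
  rates <- data.frame(family = "F1", g = 0.3, lam = 0.2, mu = 0.8)
  mat <- matrix(counts, ncol = 1, dimnames = list(names(counts), "F1"))
  p8 <- node_posteriors(tree, mat, rates, cmax = 8)$posteriors$F1
  p12 <- node_posteriors(tree, mat, rates, cmax = 12)$posteriors$F1
  pres8 <- 1 - p8[, "0"]
  pres12 <- 1 - p12[, "0"]
  expect_equal(pres8, pres12, tolerance = 1e-6)
})

test_that("rate fitting improves the likelihood and respects bounds", {
  set.seed(23)
  tree <- random_tree(10, 30)
  sim <- simulate_family_evolution(tree, 40, seed = 31)
  mat <- sim$matrix[, colSums(sim$matrix) > 0, drop = FALSE]
  rates <- fit_rates(tree, mat, config = list(cmax = 6))
  expect_true(all(rates$logLik >= rates$init_logLik - 1e-6))
  expect_true(all(rates$g >= 1e-4 & rates$mu >= 1e-4))

  # single-copy family in every leaf of a long tree: no losses observed,
  # mu driven to the lower bound
  long_tree <- simulate_tree(10, seed = 30, scale = 2)
  ones <- matrix(1L, nrow = 10, ncol = 1,
                 dimnames = list(long_tree$tip.label, "FIXED"))
  r1 <- fit_rates(long_tree, ones, config = list(cmax = 4, model = "gl"))
  expect_lte(r1$mu, 1e-3)

  empty <- matrix(0L, nrow = length(tree$tip.label), ncol = 1,
                  dimnames = list(tree$tip.label, "EMPTY"))
  expect_error(fit_rates(tree, empty), "zero genomes")
})

test_that("pooled rate fitting recovers shared simulation rates", {
  tree <- simulate_tree(12, seed = 44, scale = 0.5)
  sim <- simulate_family_evolution(tree, 300,
                                   rates = list(g = 0.35, lam = 0, mu = 0.7),
                                   seed = 45)
  mat <- sim$matrix[, colSums(sim$matrix) > 0, drop = FALSE]
  fit <- fit_rates_pooled(tree, mat, config = list(cmax = 8, model = "gl"))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 0.7) / 0.7, 0.35)
  fit_c <- fit_rates_pooled(tree, mat,
                            config = list(cmax = 8, model = "gl",
                                          condition_on_observed = TRUE))
  expect_lt(abs(fit_c$g - 0.35) / 0.35, 0.35)
})

test_that("gain rates divide called gains by branch length", {
  events <- data.frame(family = "F1", parent = "N1", child = c("a", "N2"),
                       p_gain = c(0.9, 0.2), p_loss = 0, p_expand = 0,
                       p_contract = 0, call_gain = c(TRUE, FALSE),
                       call_loss = FALSE, call_expand = FALSE,
                       call_contract = FALSE, stringsAsFactors = FALSE)
  tree <- read_newick("((a:0.05,b:0.1):0.1,c:0.2);")
  ev10 <- events[rep(1, 10), ]
  ev10$child <- "a"
  gr <- gain_rates(ev10, tree)
  expect_equal(gr$gain_rate[gr$child == "a"], 10 / 0.05)
  expect_equal(gr$gain_rate[gr$child == "b"], 0)
  expect_equal(sum(gr$n_gains), sum(ev10$call_gain))
  expect_setequal(gr$class[gr$child %in% c("a", "b", "c")], "contemporary")
  expect_true(all(gr$class[!(gr$child %in% tree$tip.label)] == "ancestral"))
})

test_that("rank-sum comparison is exact by enumeration on small samples", {
  res <- compare_gain_rates(c(1, 2), c(3, 4), alternative = "less")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 6)
  res2 <- compare_gain_rates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$p_value, 1)

  # large-sample approximation tracks the exact enumeration
  set.seed(8)
  for (rep in 1:5) {
    a <- round(rnorm(6, 10, 2), 4); b <- round(rnorm(6, 11, 2), 4)
    exact <- compare_gain_rates(a, b)
    expect_true(exact$exact)
    approx <- ancstate:::ranksum_test(c(a, 100), c(b, -100),
                                      alternative = "two.sided")
    # independent check of the exact path against stats::wilcox.test
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(exact$p_value, wt$p.value, tolerance = 1e-12)
  }

  # tie-corrected normal approximation against wilcox.test's
  set.seed(9)
  a <- sample(1:8, 15, replace = TRUE); b <- sample(3:10, 15, replace = TRUE)
  mine <- compare_gain_rates(a, b)
  expect_false(mine$exact)
  wt <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE))
  expect_equal(mine$p_value, wt$p.value, tolerance = 1e-10)

  expect_error(compare_gain_rates(1, c(1, 2)), "n >= 2")
})

test_that("gain proportion vs branch length reduces to plain OLS", {
  tree <- read_newick("(((a:0.1,b:0.2):0.15,(c:0.1,d:0.3):0.25):0.05,e:0.4);")
  labs <- node_labels(tree)
  internal <- setdiff(labs, tree$tip.label)
  events <- do.call(rbind, lapply(internal, function(nd) {
    data.frame(family = "F1", parent = "root", child = nd,
               p_gain = 1, p_loss = 0, p_expand = 0, p_contract = 0,
               call_gain = TRUE, call_loss = FALSE, call_expand = FALSE,
               call_contract = FALSE, stringsAsFactors = FALSE)
  }))
  bt <- branch_table(tree)
  anc <- bt[!bt$child_is_leaf, ]
  # content chosen so y = gains / present is exactly proportional to length
  content <- data.frame(node = anc$child_id,
                        n_present = 1 / anc$branch_length,
                        n_multicopy = 0, is_leaf = FALSE)
  res <- gains_vs_substitutions(events, tree, content)
  expect_equal(res$r, 1, tolerance = 1e-10)

  set.seed(12)
  content2 <- content
  content2$n_present <- sample(5:50, nrow(content))
  res2 <- gains_vs_substitutions(events, tree, content2)
  y <- 1 / content2$n_present[match(res2$data$child, content2$node)]
  beta <- ols_oracle(res2$data$branch_length, res2$data$gain_proportion)
  expect_equal(res2$slope, unname(beta["slope"]), tolerance = 1e-10)
  expect_equal(res2$intercept, unname(beta["intercept"]), tolerance = 1e-10)
})
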