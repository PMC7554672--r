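test_that("stem masks follow the consensus rule and gaps do not vote", {
  aln <- rbind(s1 = c("A", "C", "G", "T"), s2 = c("G", "G", "A", "A"))
  # both annotate ungapped positions 1,2 -> unanimous stem columns 1,2
  mask <- build_stem_mask(aln, list(s1 = c(1, 2), s2 = c(1, 2)))
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE))

  # disagreeing annotations fail a strict consensus outright
  expect_error(build_stem_mask(aln, list(s1 = 1, s2 = 2)), "empty mask")
  # ... but pass at fraction 0.5
  mask2 <- build_stem_mask(aln, list(s1 = 1, s2 = 2), fraction = 0.5)
  expect_equal(mask2, c(TRUE, TRUE, FALSE, FALSE))

  # a gapped cell neither votes nor counts in the denominator: column 1 has
  # a single resident (s1) that votes yes; column 2 has two residents but
  # only s2's vote (its ungapped position 1), so strict consensus fails
  aln_gap <- rbind(s1 = c("A", "C", "G"), s2 = c("-", "G", "A"))
  mask3 <- build_stem_mask(aln_gap, list(s1 = 1, s2 = 1))
  expect_equal(mask3, c(TRUE, FALSE, FALSE))
  mask4 <- build_stem_mask(aln_gap, list(s1 = 1, s2 = 1), fraction = 0.5)
  expect_equal(mask4, c(TRUE, TRUE, FALSE))

  expect_error(build_stem_mask(aln, list(s1 = 9)), "beyond ungapped length")
  expect_error(build_stem_mask(aln, list(zz = 1)), "absent from alignment")
})

test_that("stem GC excludes gaps and N from both sides of the ratio", {
  expect_equal(stem_gc("GCGC", rep(TRUE, 4)), 100)
  expect_equal(stem_gc("ATAT", rep(TRUE, 4)), 0)
  expect_equal(stem_gc("GCAT", c(TRUE, TRUE, FALSE, TRUE)), 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(stem_gc("GC-N", rep(TRUE, 4)), 100)
  expect_error(stem_gc("--NN", rep(TRUE, 4)), "no counted bases")
  expect_error(stem_gc("GC", rep(TRUE, 3)), "mask length")
})

test_that("calibration is exact on collinear points and matches OLS", {
  tree <- read_newick("((a:1,b:1):1,c:2);")
  gc <- c(a = 50, b = 60, c = 70)
  ogt <- c(a = 40, b = 60, c = 80)
  cal <- suppressWarnings(calibrate_thermometer(tree, gc, ogt))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, -60, tolerance = 1e-12)
  expect_equal(cal$r_pearson, 1, tolerance = 1e-12)
  expect_equal(predict_ogt(cal, 55), 50)

  # constant OGT: zero slope, correlation flagged undefined
  flat <- suppressWarnings(
    calibrate_thermometer(tree, gc, c(a = 50, b = 50, c = 50)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r_pearson))

  expect_error(calibrate_thermometer(tree, c(a = 5, b = 5, c = 5), ogt),
               "degenerate")
  expect_error(calibrate_thermometer(tree, gc[1:2], ogt), ">= 3 taxa")

  set.seed(31)
  for (rep in 1:5) {
    tr <- random_tree(10, rep + 60)
    x <- stats::setNames(runif(10, 40, 70), tr$tip.label)
    y <- 1.8 * x - 40 + rnorm(10, 0, 5)
    cal <- calibrate_thermometer(tr, x, y)
    beta <- ols_oracle(x, y)
    expect_equal(cal$slope, unname(beta["slope"]), tolerance = 1e-10)
    expect_equal(cal$intercept, unname(beta["intercept"]), tolerance = 1e-10)
  }
})

test_that("contrast correlations behave like contrasts should", {
  tree <- random_tree(12, 3)
  x <- stats::setNames(runif(12, 0, 10), tree$tip.label)
  expect_equal(pic_correlation(tree, x, 2 * x + 3), 1, tolerance = 1e-10)
  expect_error(pic_correlation(tree, x * 0 + 1, x), "constant")
  two <- read_newick("(a:1,b:1);")
  expect_error(pic_correlation(two, c(a = 1, b = 2), c(a = 2, b = 1)),
               "at least 3")

  # bivariate Brownian traits with known correlation are recovered roughly
  set.seed(71)
  big <- simulate_tree(200, seed = 72, scale = 1)
  ti <- ancstate:::ctmc_index(big)
  rho <- 0.8
  xs <- numeric(ti$n_node); ys <- numeric(ti$n_node)
  for (i in rev(seq_len(nrow(ti$edge)))) {
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    sd <- sqrt(ti$edge.length[i])
    z1 <- rnorm(1, 0, sd); z2 <- rnorm(1, 0, sd)
    xs[ch] <- xs[p] + z1
    ys[ch] <- ys[p] + rho * z1 + sqrt(1 - rho^2) * z2
  }
  xt <- stats::setNames(xs[seq_len(200)], big$tip.label)
  yt <- stats::setNames(ys[seq_len(200)], big$tip.label)
  r <- pic_correlation(big, xt, yt)
  expect_lt(abs(r - rho), 0.1)
})

test_that("pruning likelihood matches hand results on degenerate trees", {
  # single leaf on a zero branch: logL is the root frequency of its state
  one <- read_newick("(L:0,x:0);", missing_length = "zero")
  aln1 <- stem_alignment(c(L = "G", x = "G"))
  model1 <- list(kappa = 2, theta_root = 0.6,
                 theta = c(L = 0.5, x = 0.5))
  expect_equal(pruning_loglik(one, aln1, model1), log(0.3), tolerance = 1e-12)

  # two identical leaves on zero branches: still the root frequency
  aln2 <- stem_alignment(c(L = "G", x = "A"))
  ll <- pruning_loglik(one, aln2, model1)
  expect_equal(ll, -Inf)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (seed in 1:5) {
    set.seed(seed)
    n_tip <- sample(3:5, 1)
    tree <- random_tree(n_tip, seed + 20)
    sim <- simulate_thermometer_dataset(tree, n_sites = 20, seed = seed)
    labs <- node_labels(tree)
    model <- list(kappa = runif(1, 1, 6), theta_root = runif(1, 0.2, 0.8),
                  theta = stats::setNames(runif(nrow(tree$edge), 0.2, 0.8),
                                          labs[tree$edge[, 2L]]))
    ti <- ancstate:::ctmc_index(tree)
    tipp <- ancstate:::nuc_tip_partials(tree, sim$aln)
    P <- ancstate:::nonhom_P_list(tree, model)
    oracle <- enum_ctmc(tree, P, tipp, t92_stationary(model$theta_root))
    expect_equal(pruning_loglik(tree, sim$aln, model), oracle$loglik,
                 tolerance = 1e-8)
    # marginal ancestral posteriors agree too and sum to one
    reps <- sample_ancestral_replicates(tree, sim$aln, model, R = 2, seed = 1)
    for (v in (n_tip + 1L):ti$n_node) {
      post <- reps$posteriors[[labs[v]]]
      expect_equal(colSums(post), rep(1, ncol(post)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(max(abs(post - oracle$marg[v, , ])), 0, tolerance = 1e-8)
    }
  }
})

test_that("model fitting ascends, is deterministic and recovers theta", {
  tree <- simulate_tree(16, seed = 81, scale = 0.5)
  sim <- simulate_thermometer_dataset(tree, calib = c(a = 2, b = -60),
                                      ogt_root = 80, ogt_sigma = 0.01,
                                      n_sites = 1000, seed = 82)
  # near-zero drift: effectively homogeneous theta = (80+60)/2/100 = 0.7
  fit <- fit_nonhom_t92(tree, sim$aln, config = list(multistart = 2, seed = 4))
  expect_gte(fit$logLik, fit$init_logLik - 1e-6)
  expect_lt(abs(stats::median(fit$theta) - 0.7), 0.05)
  fit2 <- fit_nonhom_t92(tree, sim$aln, config = list(multistart = 2, seed = 4))
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$kappa, fit2$kappa)
})

test_that("ancestral sampling reproduces forced states and posteriors", {
  # zero-length tree: every replicate at every node equals the tip sequence
  tr0 <- read_newick("((a:0,b:0):0,c:0);")
  seq0 <- "ACGTGC"
  aln0 <- stem_alignment(c(a = seq0, b = seq0, c = seq0))
  model0 <- list(kappa = 2, theta_root = 0.5,
                 theta = stats::setNames(rep(0.5, 4),
                                         node_labels(tr0)[tr0$edge[, 2L]]))
  reps <- sample_ancestral_replicates(tr0, aln0, model0, R = 10, seed = 3)
  for (nd in reps$nodes) expect_true(all(reps$sequences[[nd]] == seq0))

  # empirical root-state frequencies track the exact marginal posterior
  tree <- random_tree(4, 55)
  sim <- simulate_thermometer_dataset(tree, n_sites = 5, seed = 56)
  labs <- node_labels(tree)
  model <- list(kappa = 3, theta_root = 0.55,
                theta = stats::setNames(rep(0.6, nrow(tree$edge)),
                                        labs[tree$edge[, 2L]]))
  R <- 4000
  reps <- sample_ancestral_replicates(tree, sim$aln, model, R = R, seed = 9)
  root_lab <- labs[length(tree$tip.label) + 1L]
  post <- reps$posteriors[[root_lab]]
  seqs <- do.call(rbind, strsplit(reps$sequences[[root_lab]], ""))
  for (site in 1:5) {
    emp <- table(factor(seqs[, site], levels = c("A", "C", "G", "T"))) / R
    se <- sqrt(pmax(post[, site] * (1 - post[, site]), 1e-9) / R)
    expect_true(all(abs(emp - post[, site]) <= 3.5 * se + 1e-12))
  }
})

test_that("ancestral OGT prediction applies the calibration to replicates", {
  fake <- structure(list(
    nodes = c("N1", "N2"),
    sequences = list(N1 = rep(paste(rep(c("G", "C", "A", "T"), 5),
                                    collapse = ""), 4),
                     N2 = c("GGGG", "GGCC", "CCAA", "AATT")),
    posteriors = NULL, R = 4, seed = 1,
    n_sites = NA), class = "ancestral_replicates")
  fake$n_sites <- 20
  calib <- structure(list(slope = 2, intercept = -60),
                     class = "thermometer_calibration")
  fake2 <- fake
  fake2$sequences$N2 <- NULL
  fake2$nodes <- "N1"
  fake2$n_sites <- 20
  est <- predict_ancestral_ogt(fake2, calib)
  # every replicate has stem GC 50% -> OGT 40, a width-zero interval
  expect_equal(est$ogt, 40)
  expect_equal(est$ci_low, 40)
  expect_equal(est$ci_high, 40)
  expect_true(all(est$ci_low <= est$ogt & est$ogt <= est$ci_high))
})

test_that("alignment FASTA round-trips through disk", {
  tree <- random_tree(5, 14)
  sim <- simulate_thermometer_dataset(tree, n_sites = 30, seed = 15)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(sim$aln, tmp)
  back <- read_alignment_fasta(tmp)
  expect_equal(back, sim$aln$matrix)
})
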