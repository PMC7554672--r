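## Seeded simulators producing every input the pipeline consumes, with the
## generating truth recorded, so each stage can be tested against known
## ancestral states, rates, temperatures and family partitions.

#' Simulate a rooted ultrametric-ish tree
#'
#' Yule (pure-birth) tree via [ape::rphylo()], rescaled so the mean
#' root-to-tip path length equals `scale` substitutions/site. Internal nodes
#' get stable postorder labels.
#'
#' @param n_tips number of leaves (>= 2).
#' @param seed RNG seed.
#' @param scale target mean root-to-tip length (default 0.5).
#' @param model currently only `"yule"`.
#' @return a validated `phylo`.
#' @export
simulate_tree <- function(n_tips, seed = 1L, scale = 0.5, model = "yule") {
  stopifnot(n_tips >= 2L, model == "yule", scale > 0)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$node.label <- NULL
  tree <- validate_tree(tree)
  depth <- mean(root_to_tip(tree))
  tree$edge.length <- tree$edge.length * scale / depth
  tree
}

## Exact stochastic simulation of the gain-loss-duplication jump process on
## one branch, vectorized across independent families.
bd_branch_jump <- function(states, t, g, lam, mu, cmax = Inf) {
  n <- length(states)
  if (length(g) == 1L) g <- rep(g, n)
  if (length(lam) == 1L) lam <- rep(lam, n)
  if (length(mu) == 1L) mu <- rep(mu, n)
  elapsed <- numeric(n)
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    s <- states[idx]
    up <- ifelse(s < cmax, g[idx] + s * lam[idx], 0)
    down <- s * mu[idx]
    tot <- up + down
    frozen <- tot <= 0
    if (any(frozen)) {
      active[idx[frozen]] <- FALSE
      idx <- idx[!frozen]
      if (!length(idx)) break
      s <- states[idx]; up <- up[!frozen]; tot <- tot[!frozen]
    }
    dt <- stats::rexp(length(idx), rate = tot)
    elapsed[idx] <- elapsed[idx] + dt
    done <- elapsed[idx] > t
    active[idx[done]] <- FALSE
    jump <- idx[!done]
    if (length(jump)) {
      goes_up <- stats::runif(length(jump)) < (up[!done] / tot[!done])
      states[jump] <- states[jump] + ifelse(goes_up, 1L, -1L)
    }
  }
  states
}

#' Monte-Carlo transition distribution of the birth-death chain
#'
#' Simulates `n_paths` independent trajectories of the truncated
#' gain-loss-duplication jump process from a common starting copy number and
#' returns the empirical distribution of the end state. Serves as a
#' stochastic oracle for the transition kernel `expm(Q t)`.
#'
#' @param n0 starting copy number.
#' @param t elapsed time.
#' @param g,lam,mu rates as in [bd_generator()].
#' @param cmax truncation cap (shared with the generator being checked).
#' @param n_paths number of trajectories.
#' @param seed RNG seed.
#' @return probability vector over `0..cmax`.
#' @export
bd_simulate_transitions <- function(n0, t, g, lam, mu, cmax = 10L,
                                    n_paths = 1e5, seed = 1L) {
  set.seed(seed)
  final <- bd_branch_jump(rep(as.integer(n0), n_paths), t, g, lam, mu, cmax)
  tabulate(final + 1L, nbins = cmax + 1L) / n_paths
}

#' Simulate gene-family evolution on a tree
#'
#' Copy numbers evolve down the tree by exact simulation of the
#' gain-loss-duplication jump process, independently per family. Root states
#' are drawn from the per-family stationary distribution (truncated at
#' `cmax` for the draw only; the process itself is uncapped). All node
#' states, the realized per-branch events (obtained by diffing parent and
#' child states) and the rates used are recorded as ground truth.
#'
#' @param tree a validated `phylo`.
#' @param n_families number of families to simulate.
#' @param rates list `list(g =, lam =, mu =)` of global rates, or a
#'   data.frame with per-family columns `g`, `lam`, `mu`.
#' @param rate_prior optional list of gamma parameters, e.g.
#'   `list(g = c(shape, rate), mu = c(shape, rate), lam = 0)`; overrides
#'   `rates` by drawing per-family rates.
#' @param seed RNG seed.
#' @param cmax cap used for the stationary root draw (default 10).
#' @return list with `matrix` (tips x families occurrence matrix), `truth`
#'   (list: `states` node x family matrix, `events` per-branch data.frame,
#'   `rates` per-family data.frame, `tree`, `seed`).
#' @export
simulate_family_evolution <- function(tree, n_families,
                                      rates = list(g = 0.35, lam = 0, mu = 0.7),
                                      rate_prior = NULL, seed = 1L,
                                      cmax = 10L) {
  tree <- validate_tree(tree)
  set.seed(seed)
  if (!is.null(rate_prior)) {
    draw <- function(spec) {
      if (length(spec) == 1L) rep(spec, n_families)
      else stats::rgamma(n_families, shape = spec[1L], rate = spec[2L])
    }
    fam_rates <- data.frame(g = draw(rate_prior$g),
                            lam = draw(rate_prior$lam),
                            mu = draw(rate_prior$mu))
  } else if (is.data.frame(rates)) {
    fam_rates <- rates[rep_len(seq_len(nrow(rates)), n_families), , drop = FALSE]
  } else {
    fam_rates <- data.frame(g = rep(rates$g, n_families),
                            lam = rep(rates$lam, n_families),
                            mu = rep(rates$mu, n_families))
  }
  ti <- ctmc_index(tree)
  labs <- node_labels(tree)
  states <- matrix(NA_integer_, ti$n_node, n_families)
  root_draw <- function(g, lam, mu) {
    p <- bd_stationary(g, lam, mu, cmax)
    sample.int(cmax + 1L, 1L, prob = p) - 1L
  }
  states[ti$root, ] <- vapply(seq_len(n_families), function(j)
    root_draw(fam_rates$g[j], fam_rates$lam[j], fam_rates$mu[j]), integer(1))
  for (i in rev(seq_len(nrow(ti$edge)))) {          # preorder
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    states[ch, ] <- bd_branch_jump(states[p, ], ti$edge.length[i],
                                   fam_rates$g, fam_rates$lam, fam_rates$mu)
  }
  fam_ids <- sprintf("FAM%06d", seq_len(n_families))
  colnames(states) <- fam_ids
  rownames(states) <- labs
  mat <- states[seq_len(ti$n_tip), , drop = FALSE]
  events <- do.call(rbind, lapply(seq_len(nrow(ti$edge)), function(i) {
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    sp <- states[p, ]; sc <- states[ch, ]
    data.frame(parent = labs[p], child = labs[ch], family = fam_ids,
               gain = sp == 0 & sc >= 1, loss = sp >= 1 & sc == 0,
               expand = sc > sp & sp >= 1, contract = sp > sc & sc >= 1,
               stringsAsFactors = FALSE)
  }))
  rownames(fam_rates) <- fam_ids
  list(matrix = mat,
       truth = list(states = states, events = events, rates = fam_rates,
                    tree = tree, seed = seed, cmax = cmax))
}

## Sample child states for all sites given parent states and a transition
## matrix (rows = parent states).
sample_states <- function(parent_states, P) {
  k <- ncol(P)
  cw <- t(apply(P, 1L, cumsum))
  u <- stats::runif(length(parent_states))
  rowSums(cw[parent_states, , drop = FALSE] < u) + 1L
}

#' Simulate a molecular-thermometer dataset
#'
#' An OGT value is assigned to every node by Brownian drift along the
#' branches from a root value; each branch's equilibrium stem GC is the
#' inverse of the assumed calibration at the child's OGT, and sequences
#' evolve site-independently under the branch-specific T92 model. Every
#' column is a stem column. True node OGTs, thetas and realized GCs are
#' recorded.
#'
#' @param tree a validated `phylo` with branch lengths in substitutions/site.
#' @param calib numeric `c(a, b)`: true calibration OGT = a * GC% + b
#'   (`a != 0`).
#' @param ogt_root root OGT in degrees C.
#' @param ogt_sigma Brownian standard deviation per unit sqrt branch length
#'   (degrees C).
#' @param n_sites number of stem sites.
#' @param kappa transition/transversion ratio.
#' @param seed RNG seed.
#' @return list with `aln` (a `stem_alignment` over the tips), `ogt` (named
#'   tip OGT vector), `truth` (node OGTs, node thetas, realized node GC%,
#'   node sequences, calibration, seed).
#' @export
simulate_thermometer_dataset <- function(tree, calib = c(a = 2, b = -60),
                                         ogt_root = 60, ogt_sigma = 12,
                                         n_sites = 1000L, kappa = 4,
                                         seed = 1L) {
  a <- unname(calib[1L]); b <- unname(calib[2L])
  stopifnot(a != 0, n_sites >= 1L)
  tree <- validate_tree(tree)
  set.seed(seed)
  ti <- ctmc_index(tree)
  labs <- node_labels(tree)
  ogt <- numeric(ti$n_node)
  ogt[ti$root] <- ogt_root
  for (i in rev(seq_len(nrow(ti$edge)))) {          # preorder
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    ogt[ch] <- ogt[p] + stats::rnorm(1L, 0, ogt_sigma * sqrt(ti$edge.length[i]))
  }
  theta_of <- function(temp) pmin(pmax(((temp - b) / a) / 100, 0.01), 0.99)
  theta <- theta_of(ogt)
  seqs <- matrix(NA_integer_, ti$n_node, n_sites)
  seqs[ti$root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                prob = t92_stationary(theta[ti$root]))
  for (i in rev(seq_len(nrow(ti$edge)))) {
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    P <- t92_transition(theta[ch], kappa, ti$edge.length[i])
    seqs[ch, ] <- sample_states(seqs[p, ], P)
  }
  char_seqs <- matrix(NUC_STATES[seqs], ti$n_node, n_sites)
  rownames(char_seqs) <- labs
  gc_pct <- 100 * rowMeans(seqs == 2L | seqs == 3L)
  aln <- stem_alignment(char_seqs[seq_len(ti$n_tip), , drop = FALSE])
  list(aln = aln,
       ogt = stats::setNames(ogt[seq_len(ti$n_tip)], tree$tip.label),
       truth = list(node_ogt = stats::setNames(ogt, labs),
                    node_theta = stats::setNames(theta, labs),
                    node_gc = stats::setNames(gc_pct, labs),
                    node_sequences = char_seqs,
                    calibration = c(a = a, b = b), kappa = kappa,
                    seed = seed))
}

#' Plant a family partition across genomes
#'
#' Utility for clustering tests: distributes sequences of `n_families`
#' families over `n_genomes` genomes and returns the planted partition, the
#' per-sequence lengths and the sequence-to-genome mapping.
#'
#' @param n_families number of planted families.
#' @param n_genomes number of genomes.
#' @param mean_size mean family size (Poisson, minimum 1).
#' @param seed RNG seed.
#' @return list: `families` (list of member id vectors), `lengths` (named),
#'   `seq2genome` (named), `seed`.
#' @export
simulate_planted_families <- function(n_families, n_genomes = 4L,
                                      mean_size = 3, seed = 1L) {
  set.seed(seed)
  fams <- vector("list", n_families)
  lengths <- character(0)
  lens <- integer(0); s2g <- character(0)
  counter <- 0L
  for (f in seq_len(n_families)) {
    size <- max(1L, stats::rpois(1L, mean_size))
    base_len <- sample(200:500, 1L)
    ids <- character(size)
    for (m in seq_len(size)) {
      counter <- counter + 1L
      genome <- sprintf("G%02d", sample.int(n_genomes, 1L))
      ids[m] <- sprintf("%s_seq%05d", genome, counter)
      lens <- c(lens, base_len + sample(-10:10, 1L))
      s2g <- c(s2g, genome)
    }
    names(lens)[(counter - size + 1L):counter] <- ids
    names(s2g)[(counter - size + 1L):counter] <- ids
    fams[[f]] <- ids
  }
  names(fams) <- sprintf("TRUE%04d", seq_len(n_families))
  list(families = fams, lengths = lens, seq2genome = s2g, seed = seed)
}

#' Simulate an all-vs-all hit table with planted family structure
#'
#' Emits BLAST-tabular (outfmt 6) rows: every within-family pair passes the
#' clustering thresholds (identity >= 35, coverage >= 0.70 of both lengths,
#' E-value well below 1e-4); optional spurious cross-family hits fall below
#' the identity threshold and never create edges. Self-hits are included.
#' Output is byte-identical for a given seed.
#'
#' @param planted list from [simulate_planted_families()].
#' @param path optional path: when given, the table is written there as TSV.
#' @param noise expected number of spurious cross-family hits per family.
#' @param seed RNG seed.
#' @return data.frame of outfmt-6 columns (invisibly when `path` given).
#' @export
simulate_hit_table <- function(planted, path = NULL, noise = 0, seed = 1L) {
  set.seed(seed)
  lens <- planted$lengths
  rows <- list()
  emit <- function(q, s, pident, alen, evalue) {
    data.frame(qseqid = q, sseqid = s, pident = pident, length = alen,
               mismatch = round(alen * (100 - pident) / 100),
               gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L,
               send = alen, evalue = evalue, bitscore = round(alen * 1.9),
               stringsAsFactors = FALSE)
  }
  for (ids in planted$families) {
    for (id in ids) rows[[length(rows) + 1L]] <- emit(id, id, 100, lens[[id]], 0)
    if (length(ids) >= 2L) {
      prs <- utils::combn(ids, 2L)
      for (j in seq_len(ncol(prs))) {
        q <- prs[1L, j]; s <- prs[2L, j]
        alen <- ceiling(0.85 * max(lens[[q]], lens[[s]]))
        pid <- round(stats::runif(1L, 45, 95), 1)
        ev <- 10^stats::runif(1L, -60, -20)
        rows[[length(rows) + 1L]] <- emit(q, s, pid, alen, ev)
        rows[[length(rows) + 1L]] <- emit(s, q, pid, alen, ev)
      }
    }
  }
  if (noise > 0 && length(planted$families) >= 2L) {
    all_ids <- unlist(planted$families, use.names = FALSE)
    fam_of <- rep(names(planted$families), lengths(planted$families))
    names(fam_of) <- all_ids
    n_noise <- stats::rpois(1L, noise * length(planted$families))
    for (j in seq_len(n_noise)) {
      pair <- sample(all_ids, 2L)
      if (fam_of[[pair[1L]]] == fam_of[[pair[2L]]]) next
      alen <- ceiling(0.8 * max(lens[[pair[1L]]], lens[[pair[2L]]]))
      rows[[length(rows) + 1L]] <- emit(pair[1L], pair[2L],
                                        round(stats::runif(1L, 15, 34.5), 1),
                                        alen, 10^stats::runif(1L, -8, -5))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    fmt <- out
    fmt$pident <- sprintf("%.1f", out$pident)
    fmt$evalue <- sprintf("%.3e", out$evalue)
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(out))
  }
  out
}
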