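## The 16S rRNA "molecular thermometer": stem-region GC content of
## reconstructed ancestral sequences, mapped to optimal growth temperature
## (OGT) through a linear calibration fitted on extant taxa.

#' Construct a stem alignment
#'
#' A stem alignment is an aligned nucleotide matrix over {A,C,G,T,-,N}
#' together with a boolean column mask flagging the stem (paired) positions
#' over which GC content is computed.
#'
#' @param seqs named character vector of aligned sequences (equal lengths),
#'   or a character matrix with one row per taxon.
#' @param mask logical vector, one entry per alignment column; `NULL` marks
#'   every column as stem.
#' @return an object of class `stem_alignment`.
#' @export
stem_alignment <- function(seqs, mask = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("taxa labels must be present and unique")
  }
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("unsupported residue(s): ", paste(bad, collapse = ", "))
  if (is.null(mask)) mask <- rep(TRUE, ncol(mat))
  stopifnot(is.logical(mask), length(mask) == ncol(mat))
  if (!any(mask)) stop("stem mask is empty (no stem columns)")
  structure(list(matrix = mat, mask = mask), class = "stem_alignment")
}

#' @export
print.stem_alignment <- function(x, ...) {
  cat("stem_alignment:", nrow(x$matrix), "taxa,", ncol(x$matrix),
      "columns (", sum(x$mask), "stem )\n")
  invisible(x)
}

#' Read an aligned FASTA file into a character matrix
#'
#' @param path FASTA file of aligned sequences.
#' @return character matrix, rows named by taxa.
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path, type = "DNA")
  mat <- toupper(as.character(as.matrix(dna)))
  mat[!(mat %in% c("A", "C", "G", "T", "-", "N"))] <- "N"
  mat
}

#' Write an aligned character matrix to FASTA
#'
#' @param mat character matrix (rows = taxa) or `stem_alignment`.
#' @param path output path.
#' @export
write_alignment_fasta <- function(mat, path) {
  if (inherits(mat, "stem_alignment")) mat <- mat$matrix
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    writeLines(c(paste0(">", rownames(mat)[i]),
                 paste(mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Build a consensus stem mask from per-sequence stem annotations
#'
#' Stem annotations give, for each annotated sequence, the 1-based positions
#' of its *ungapped* sequence that fall in paired (stem) regions. These are
#' projected onto alignment columns; a column is marked stem when at least
#' `fraction` of the annotated sequences that have a residue in that column
#' place a stem position there. Gap cells do not vote. The default
#' `fraction = 1` is a strict consensus, the conservative choice.
#'
#' @param aln a `stem_alignment` (its existing mask is ignored) or character
#'   matrix.
#' @param stem_positions named list: label -> integer vector of 1-based
#'   ungapped stem positions.
#' @param fraction consensus fraction in (0, 1].
#' @return logical mask over alignment columns.
#' @export
build_stem_mask <- function(aln, stem_positions, fraction = 1) {
  mat <- if (inherits(aln, "stem_alignment")) aln$matrix else aln
  stopifnot(fraction > 0, fraction <= 1)
  missing_taxa <- setdiff(names(stem_positions), rownames(mat))
  if (length(missing_taxa)) {
    stop("annotated label(s) absent from alignment: ",
         paste(missing_taxa, collapse = ", "))
  }
  L <- ncol(mat)
  votes <- numeric(L)
  voters <- numeric(L)
  for (lab in names(stem_positions)) {
    row <- mat[lab, ]
    resid <- row != "-"
    ungapped_len <- sum(resid)
    pos <- as.integer(stem_positions[[lab]])
    if (any(pos < 1L) || any(pos > ungapped_len)) {
      stop("stem annotation for '", lab, "' references position ",
           max(pos), " beyond ungapped length ", ungapped_len)
    }
    ungapped_index <- cumsum(resid)          # 0 where gap precedes any residue
    is_stem_col <- resid & (ungapped_index %in% pos)
    votes <- votes + is_stem_col
    voters <- voters + resid
  }
  mask <- voters > 0 & votes >= fraction * voters
  if (!any(mask)) stop("empty mask: no alignment column reaches consensus fraction ", fraction)
  mask
}

#' Read stem annotations from TSV
#'
#' @param path TSV with columns: label, comma-separated 1-based ungapped
#'   positions.
#' @return named list of integer vectors.
#' @export
read_stem_annotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  stats::setNames(lapply(strsplit(as.character(tab[[2L]]), ","), as.integer),
                  as.character(tab[[1L]]))
}

#' Read an OGT table
#'
#' @param path TSV with a header row and columns label, ogt (degrees C).
#' @return named numeric vector of OGTs.
#' @export
read_ogt_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' GC percentage over masked columns of one sequence
#'
#' Gaps and N are excluded from both numerator and denominator.
#'
#' @param sequence character string or vector of single characters.
#' @param mask logical vector matching the sequence length.
#' @return GC percentage in `[0, 100]`.
#' @export
stem_gc <- function(sequence, mask) {
  chars <- if (length(sequence) == 1L) strsplit(toupper(sequence), "")[[1L]] else toupper(sequence)
  if (length(chars) != length(mask)) {
    stop("sequence length ", length(chars), " != mask length ", length(mask))
  }
  sel <- chars[mask]
  n_gc <- sum(sel %in% c("G", "C"))
  n_acgt <- sum(sel %in% c("A", "C", "G", "T"))
  if (n_acgt == 0L) stop("no counted bases under the stem mask")
  100 * n_gc / n_acgt
}

#' Stem GC percentage of every taxon in an alignment
#'
#' @param aln a `stem_alignment`.
#' @return named numeric vector of GC percentages.
#' @export
alignment_stem_gc <- function(aln) {
  stopifnot(inherits(aln, "stem_alignment"))
  apply(aln$matrix, 1L, stem_gc, mask = aln$mask)
}

#' Correlation of two traits by phylogenetic independent contrasts
#'
#' Computes Felsenstein's standardized contrasts for both traits on the same
#' tree (pruned to the taxa carrying both traits) and returns their
#' correlation through the origin.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param x,y named numeric trait vectors over (a subset of) the leaves.
#' @return correlation of contrasts in `[-1, 1]`.
#' @export
pic_correlation <- function(tree, x, y) {
  taxa <- intersect(names(x), names(y))
  taxa <- intersect(taxa, tree$tip.label)
  if (length(taxa) < 3L) {
    stop("need at least 3 taxa with both traits for contrasts (got ",
         length(taxa), ")")
  }
  tr <- prune_to_taxa(tree, taxa)
  tr <- ape::multi2di(tr)                    # pic() requires a binary tree
  tr$edge.length[tr$edge.length <= 0] <- 1e-8
  tr$node.label <- NULL
  cx <- ape::pic(x[tr$tip.label], tr)
  cy <- ape::pic(y[tr$tip.label], tr)
  sx <- sum(cx^2); sy <- sum(cy^2)
  if (sx == 0 || sy == 0) stop("degenerate contrasts: a trait is constant")
  sum(cx * cy) / sqrt(sx * sy)
}

#' Calibrate the molecular thermometer
#'
#' Ordinary least squares of OGT on stem GC percentage over extant taxa,
#' with the Pearson correlation, adjusted R-squared and the
#' contrasts-corrected correlation ([pic_correlation()]) as fit diagnostics.
#'
#' @param tree rooted `phylo` containing the calibration taxa as leaves.
#' @param gc named numeric vector, stem GC percent per taxon.
#' @param ogt named numeric vector, OGT in degrees C per taxon.
#' @return object of class `thermometer_calibration` with fields `slope`
#'   (degrees C per GC percentage point), `intercept` (degrees C),
#'   `r_pearson`, `r_pic`, `r2_adjusted`, `n_taxa`.
#' @export
calibrate_thermometer <- function(tree, gc, ogt) {
  taxa <- intersect(names(gc), names(ogt))
  if (length(taxa) < 3L) stop("need >= 3 taxa with both GC and OGT")
  gc <- gc[taxa]; ogt <- ogt[taxa]
  if (stats::var(gc) == 0) stop("degenerate fit: all GC values identical")
  fit <- stats::lm(ogt ~ gc)
  degenerate_y <- stats::var(ogt) == 0
  r <- if (degenerate_y) NA_real_ else stats::cor(gc, ogt)
  r_pic <- if (degenerate_y) NA_real_ else pic_correlation(tree, gc, ogt)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_pearson = r,
    r_pic = r_pic,
    r2_adjusted = if (degenerate_y) NA_real_ else summary(fit)$adj.r.squared,
    n_taxa = length(taxa),
    degenerate = degenerate_y,
    vcov_coef = stats::vcov(fit),        # (intercept, slope) covariance
    sigma_resid = summary(fit)$sigma
  ), class = "thermometer_calibration")
}

#' @export
print.thermometer_calibration <- function(x, ...) {
  cat(sprintf("thermometer calibration (n = %d): OGT = %.4f * GC%% %+.4f\n",
              x$n_taxa, x$slope, x$intercept))
  cat(sprintf("  r = %.4f, r_PIC = %.4f, adj. R^2 = %.4f\n",
              x$r_pearson, x$r_pic, x$r2_adjusted))
  invisible(x)
}

#' Predict OGT from stem GC percent
#'
#' @param calib a `thermometer_calibration`.
#' @param gc GC percentage(s).
#' @return predicted OGT(s) in degrees C.
#' @export
predict_ogt <- function(calib, gc) {
  calib$slope * gc + calib$intercept
}

## ---- nonhomogeneous T92 likelihood ----------------------------------------

## Tip partial-likelihood matrices (4 x sites) for the masked columns of an
## alignment; '-' and 'N' are missing data (all-ones partials).
nuc_tip_partials <- function(tree, aln) {
  mat <- aln$matrix[, aln$mask, drop = FALSE]
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing)) {
    stop("alignment lacks tree leaves: ", paste(missing, collapse = ", "))
  }
  s <- ncol(mat)
  lapply(tree$tip.label, function(lab) {
    p <- matrix(0, 4L, s)
    idx <- match(mat[lab, ], NUC_STATES)
    obs <- !is.na(idx)
    p[cbind(idx[obs], which(obs))] <- 1
    p[, !obs] <- 1
    p
  })
}

## Collapse identical site columns into patterns with weights.
compress_patterns <- function(tree, aln) {
  mat <- aln$matrix[tree$tip.label, aln$mask, drop = FALSE]
  key <- apply(mat, 2L, paste, collapse = "")
  uniq <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[uniq])))
  sub <- stem_alignment(mat[, uniq, drop = FALSE])
  list(aln = sub, weights = w)
}

## Per-edge transition matrices of a nonhomogeneous T92 model, indexed by
## child node.
nonhom_P_list <- function(tree, model) {
  labs <- node_labels(tree)
  P <- vector("list", length(labs))
  for (i in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[i, 2L]
    th <- model$theta[[labs[ch]]]
    if (is.null(th) || is.na(th)) stop("no theta for branch above ", labs[ch])
    P[[ch]] <- t92_transition(th, model$kappa, tree$edge.length[i])
  }
  P
}

#' Log-likelihood of an alignment under a nonhomogeneous T92 model
#'
#' Felsenstein pruning over the masked stem columns, with branch-specific
#' equilibrium GC (`model$theta`, named by child node), a global `kappa` and
#' root frequencies from `model$theta_root`. Gaps and N are missing data.
#'
#' @param tree rooted `phylo`, leaves matching the alignment taxa.
#' @param aln a `stem_alignment`.
#' @param model list/`nonhom_t92` with `kappa`, `theta_root`, `theta`
#'   (named numeric over non-root node labels).
#' @param site_weights optional site pattern weights.
#' @return log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, aln, model, site_weights = NULL) {
  tree <- validate_tree(tree)
  ti <- ctmc_index(tree)
  tipp <- nuc_tip_partials(tree, aln)
  P <- nonhom_P_list(tree, model)
  ins <- ctmc_inside(ti, P, tipp, t92_stationary(model$theta_root))
  if (is.null(site_weights)) sum(ins$site_loglik) else
    sum(site_weights * ins$site_loglik)
}

#' Fit the nonhomogeneous T92 model by maximum likelihood
#'
#' Estimates a global transition/transversion ratio `kappa`, the root
#' equilibrium GC `theta_root` and one equilibrium GC `theta_b` per branch,
#' holding branch lengths fixed at the values in the tree. Optimization is
#' bound-constrained quasi-Newton (L-BFGS-B) with multiple seeded starts;
#' each branch theta starts at the mean stem GC of the descendant tips.
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param aln a `stem_alignment` over the tree's leaves.
#' @param config list of options: `multistart` (default 3), `seed` (default
#'   1), `maxit` (default 200), `kappa_init` (default 4), `theta_bounds`
#'   (default `c(0.01, 0.99)`), `kappa_bounds` (default `c(0.05, 100)`).
#' @return object of class `nonhom_t92`: `kappa`, `theta_root`, `theta`
#'   (named by child node label), `logLik`, `convergence` (TRUE when the
#'   best start converged), `n_starts`, `seed`.
#' @export
fit_nonhom_t92 <- function(tree, aln, config = list()) {
  cfg <- utils::modifyList(list(
    multistart = 3L, seed = 1L, maxit = 200L, kappa_init = 4,
    theta_bounds = c(0.01, 0.99), kappa_bounds = c(0.05, 100),
    factr = 1e9
  ), config)
  tree <- validate_tree(tree)
  cp <- compress_patterns(tree, aln)
  ti <- ctmc_index(tree)
  tipp <- nuc_tip_partials(tree, cp$aln)
  w <- cp$weights
  labs <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  edge_child <- tree$edge[, 2L]

  ## mean descendant tip GC (as a fraction) per node, for initialization
  tip_gc <- alignment_stem_gc(
    stem_alignment(aln$matrix[tree$tip.label, , drop = FALSE], aln$mask)) / 100
  desc <- descendant_tip_means(tree, tip_gc)
  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-6), b[2] - 1e-6)

  edge_t <- tree$edge.length
  n_edge <- length(edge_child)

  ## the likelihood is multilinear in each branch's transition matrix, so
  ## one inside-outside pass gives every branch-theta derivative from a
  ## single 4x4 contraction per branch; only the 4x4 kernels themselves are
  ## differenced numerically
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  forward <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(invisible())
    kappa <- par[1L]
    P <- vector("list", ti$n_node)
    for (i in seq_len(n_edge)) {
      P[[edge_child[i]]] <- t92_transition(par[i + 2L], kappa, edge_t[i])
    }
    ins <- ctmc_inside(ti, P, tipp, t92_stationary(par[2L]))
    cache$par <- par; cache$P <- P; cache$ins <- ins
    cache$value <- {
      ll <- sum(w * ins$site_loglik)
      if (!is.finite(ll)) 1e10 else -ll
    }
    invisible()
  }
  negloglik <- function(par) {
    forward(par)
    cache$value
  }
  eps <- 1e-6
  neggrad <- function(par) {
    forward(par)
    if (!is.finite(sum(cache$ins$site_loglik))) return(rep(0, length(par)))
    kappa <- par[1L]
    ins <- cache$ins
    attr(ins, "root_prior") <- t92_stationary(par[2L])
    outs <- ctmc_outside(ti, cache$P, ins, keep_above = TRUE)
    grad <- numeric(length(par))
    for (i in seq_len(n_edge)) {
      ch <- edge_child[i]
      A <- outs$above[[ch]]
      den <- colSums(A * ins$msg[[ch]])
      dP_th <- (t92_transition(par[i + 2L] + eps, kappa, edge_t[i]) -
                t92_transition(par[i + 2L] - eps, kappa, edge_t[i])) / (2 * eps)
      dP_ka <- (t92_transition(par[i + 2L], kappa + eps, edge_t[i]) -
                t92_transition(par[i + 2L], kappa - eps, edge_t[i])) / (2 * eps)
      I <- ins$inside[[ch]]
      grad[i + 2L] <- sum(w * colSums(A * (dP_th %*% I)) / den)
      grad[1L] <- grad[1L] + sum(w * colSums(A * (dP_ka %*% I)) / den)
    }
    pi_root <- t92_stationary(par[2L])
    dpi <- c(-0.5, 0.5, 0.5, -0.5)
    root_in <- ins$inside[[ti$root]]
    grad[2L] <- sum(w * as.vector(crossprod(dpi, root_in)) /
                      as.vector(crossprod(pi_root, root_in)))
    -grad
  }

  init0 <- c(cfg$kappa_init,
             clamp(mean(tip_gc), cfg$theta_bounds),
             clamp(desc[edge_child], cfg$theta_bounds))
  lower <- c(cfg$kappa_bounds[1], rep(cfg$theta_bounds[1], length(init0) - 1L))
  upper <- c(cfg$kappa_bounds[2], rep(cfg$theta_bounds[2], length(init0) - 1L))

  set.seed(cfg$seed)
  best <- NULL
  for (s in seq_len(cfg$multistart)) {
    init <- init0
    if (s > 1L) {
      init[1L] <- clamp(init0[1L] * exp(stats::rnorm(1, 0, 0.5)), cfg$kappa_bounds)
      init[-1L] <- clamp(init0[-1L] + stats::runif(length(init0) - 1L, -0.1, 0.1),
                         cfg$theta_bounds)
    }
    fit <- tryCatch(
      stats::optim(init, negloglik, gr = neggrad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = cfg$maxit, factr = cfg$factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("nonhomogeneous T92 optimization failed on every start")
  structure(list(
    kappa = best$par[1L],
    theta_root = best$par[2L],
    theta = stats::setNames(best$par[-(1:2)], labs[edge_child]),
    logLik = -best$value,
    init_logLik = -negloglik(init0),
    convergence = best$convergence == 0L,
    n_starts = cfg$multistart,
    seed = cfg$seed
  ), class = "nonhom_t92")
}

#' @export
print.nonhom_t92 <- function(x, ...) {
  cat(sprintf("nonhomogeneous T92: kappa = %.3f, theta_root = %.3f, %d branch thetas\n",
              x$kappa, x$theta_root, length(x$theta)))
  cat(sprintf("  logLik = %.3f, converged: %s\n", x$logLik, x$convergence))
  invisible(x)
}

## Mean of a tip-level quantity over the tips descending from each node.
descendant_tip_means <- function(tree, tip_values) {
  ti <- ctmc_index(tree)
  sums <- numeric(ti$n_node)
  counts <- numeric(ti$n_node)
  sums[seq_len(ti$n_tip)] <- tip_values[tree$tip.label]
  counts[seq_len(ti$n_tip)] <- 1
  for (i in seq_len(nrow(ti$edge))) {
    p <- ti$edge[i, 1L]; ch <- ti$edge[i, 2L]
    sums[p] <- sums[p] + sums[ch]
    counts[p] <- counts[p] + counts[ch]
  }
  sums / counts
}

#' Sample replicate ancestral stem sequences from the joint posterior
#'
#' Draws `R` joint samples of the ancestral states at every internal node
#' under the fitted nonhomogeneous model: per site, the root state is drawn
#' from its marginal posterior and children are drawn conditionally down the
#' tree, so cross-node correlation in GC is preserved. Exact per-node,
#' per-site marginal posteriors are returned alongside.
#'
#' @param tree rooted `phylo`.
#' @param aln a `stem_alignment`.
#' @param model fitted `nonhom_t92`.
#' @param R number of replicates (>= 1), 100 by default.
#' @param seed RNG seed, recorded in the result.
#' @return object of class `ancestral_replicates`: `nodes` (internal node
#'   labels), `sequences` (list: node -> character vector of R stem
#'   sequences), `posteriors` (list: node -> 4 x L matrix), `R`, `seed`.
#' @export
sample_ancestral_replicates <- function(tree, aln, model, R = 100L, seed = 1L) {
  stopifnot(R >= 1L)
  tree <- validate_tree(tree)
  ti <- ctmc_index(tree)
  tipp <- nuc_tip_partials(tree, aln)
  P <- nonhom_P_list(tree, model)
  root_prior <- t92_stationary(model$theta_root)
  ins <- ctmc_inside(ti, P, tipp, root_prior)
  attr(ins, "root_prior") <- root_prior
  outs <- ctmc_outside(ti, P, ins)
  labs <- node_labels(tree)
  internal <- (ti$n_tip + 1L):ti$n_node
  posteriors <- lapply(internal, function(v) {
    m <- ins$inside[[v]] * outs[[v]]
    tot <- colSums(m); tot[tot <= 0] <- 1
    m <- sweep(m, 2L, tot, "/")
    rownames(m) <- NUC_STATES
    m
  })
  names(posteriors) <- labs[internal]
  set.seed(seed)
  st <- ctmc_sample_joint(ti, P, ins, root_prior, R = R)
  s <- ncol(ins$inside[[ti$root]])
  seqs <- vector("list", length(internal))
  names(seqs) <- labs[internal]
  gc <- matrix(NA_real_, length(internal), R,
               dimnames = list(labs[internal], NULL))
  for (j in seq_along(internal)) {
    node_states <- matrix(st[internal[j], ], nrow = s)      # sites x R
    gc[j, ] <- 100 * colMeans(node_states == 2L | node_states == 3L)
    seqs[[j]] <- apply(node_states, 2L, function(col)
      paste(NUC_STATES[col], collapse = ""))
  }
  structure(list(nodes = labs[internal], sequences = seqs, gc = gc,
                 posteriors = posteriors, R = R, seed = seed,
                 n_sites = ncol(ins$inside[[ti$root]])),
            class = "ancestral_replicates")
}

#' Predict ancestral OGTs with percentile confidence intervals
#'
#' Applies the thermometer calibration to the stem GC of every replicate
#' ancestral sequence. The point estimate is the mean replicate OGT and the
#' confidence interval the 2.5th-97.5th percentile range of replicate OGTs.
#' Uncertainty in the regression coefficients themselves is not propagated.
#'
#' @param replicates an `ancestral_replicates` object.
#' @param calib a `thermometer_calibration`.
#' @param level confidence level for the percentile interval (default 0.95).
#' @param regression_uncertainty when `TRUE`, each replicate is scored with
#'   its own coefficient pair drawn from the sampling distribution of the
#'   calibration fit (bivariate normal with the OLS covariance), so the
#'   interval reflects calibration uncertainty as well as reconstruction
#'   spread. Default `FALSE`: the point coefficients are applied to every
#'   replicate and the interval is purely the reconstruction percentile.
#' @param seed RNG seed for the coefficient draws.
#' @return data.frame with columns `node`, `ogt`, `ci_low`, `ci_high`, plus
#'   attribute `"replicate_ogt"` (nodes x R matrix).
#' @export
predict_ancestral_ogt <- function(replicates, calib, level = 0.95,
                                  regression_uncertainty = FALSE,
                                  seed = 1L) {
  stopifnot(inherits(replicates, "ancestral_replicates"),
            inherits(calib, "thermometer_calibration"))
  alpha <- (1 - level) / 2
  rep_gc <- if (!is.null(replicates$gc)) replicates$gc else {
    mask <- rep(TRUE, replicates$n_sites)
    t(vapply(replicates$sequences, function(sq) {
      vapply(sq, stem_gc, numeric(1), mask = mask, USE.NAMES = FALSE)
    }, numeric(replicates$R)))
  }
  rep_ogt <- predict_ogt(calib, rep_gc)
  if (regression_uncertainty) {
    set.seed(seed)
    ch <- chol(calib$vcov_coef)
    z <- matrix(stats::rnorm(2L * replicates$R), replicates$R, 2L) %*% ch
    coefs <- cbind(calib$intercept + z[, 1L], calib$slope + z[, 2L])
    rep_ogt <- sweep(rep_gc, 2L, coefs[, 2L], "*") +
      matrix(coefs[, 1L], nrow(rep_gc), replicates$R, byrow = TRUE)
  }
  # the point estimate always uses the point coefficients; only the
  # interval widens under regression_uncertainty
  point <- rowMeans(predict_ogt(calib, rep_gc))
  out <- data.frame(
    node = replicates$nodes,
    ogt = point,
    # percentile interval, widened to contain the mean when the replicate
    # distribution is so skewed that the mean falls outside it
    ci_low = pmin(apply(rep_ogt, 1L, stats::quantile, probs = alpha,
                        names = FALSE), point),
    ci_high = pmax(apply(rep_ogt, 1L, stats::quantile, probs = 1 - alpha,
                         names = FALSE), point),
    stringsAsFactors = FALSE
  )
  attr(out, "replicate_ogt") <- rep_ogt
  out
}
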