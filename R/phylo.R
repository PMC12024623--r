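#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: requires branch
#' lengths on every edge, unique tip labels, and a syntactically complete
#' Newick string. Polytomies are allowed.
#'
#' @param text Newick string (e.g. `"(A:1,B:1);"`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo"))
    stop("Newick parse error in: ", substr(text, 1, 60))
  validate_tree(tr)
  tr
}

#' Read a Newick tree from a file
#'
#' @param path Path to a Newick file.
#' @return A validated `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

# Bump zero-length terminal branches by 1e-8 x tree height so the Brownian
# covariance matrix stays invertible.
prep_tree <- function(tree) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  if (any(term & tree$edge.length == 0)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[term & tree$edge.length == 0] <- 1e-8 * max(h, 1)
  }
  tree
}

#' Brownian variance-covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j;
#' Pagel's lambda multiplies the off-diagonal entries only.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return A symmetric positive semi-definite matrix with tip-label
#'   dimnames, in `tree$tip.label` order.
#' @export
brownian_vcv <- function(tree, lambda = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  C <- ape::vcv.phylo(prep_tree(tree))
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  C
}

# Align a named trait vector or matrix with the tips of a tree, pruning the
# tree (with a warning) when it carries extra tips. Traits without a
# matching tip are an error.
match_traits_tree <- function(x, tree) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), "trait"))
  ids <- rownames(x)
  if (is.null(ids)) stop("traits must be named by tree tip labels")
  missing_tips <- setdiff(ids, tree$tip.label)
  if (length(missing_tips))
    stop("traits present for tips absent from the tree: ",
         paste(missing_tips, collapse = ", "))
  extra <- setdiff(tree$tip.label, ids)
  if (length(extra)) {
    warning("pruning ", length(extra), " tree tip(s) without trait values")
    tree <- ape::keep.tip(tree, ids)
  }
  list(x = x[tree$tip.label, , drop = FALSE], tree = tree)
}

# Profile log-likelihood of a multivariate Brownian model on covariance C:
# vec(X) ~ N(1 %x% a, Sigma %x% C) with a the GLS root state and Sigma the
# ML trait covariance. Returns the maximized log-likelihood.
bm_loglik <- function(X, C) {
  n <- nrow(X)
  p <- ncol(X)
  R <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is not positive definite"))
  logdetC <- 2 * sum(log(diag(R)))
  Xw <- backsolve(R, X, transpose = TRUE)
  ow <- backsolve(R, rep(1, n), transpose = TRUE)
  a <- crossprod(ow, Xw) / sum(ow^2)
  Z <- Xw - ow %*% a
  S <- crossprod(Z) / n
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * p * log(2 * pi) + n * ld + p * logdetC + n * p)
  if (!is.finite(ll)) stop("non-finite Brownian log-likelihood")
  ll
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes the (multivariate) Brownian log-likelihood over the lambda
#' transform of the tree covariance by bounded scalar optimization on
#' \[0, 1\] (tolerance 1e-6), with the endpoints checked explicitly. One
#' lambda is fitted jointly for all supplied trait columns.
#'
#' @param x Named numeric vector, or matrix with tip-label rownames.
#' @param tree A `phylo` object with branch lengths (>= 4 tips).
#' @return A list of class `lambda_fit`: `lambda`, `logLik`, and `flat`
#'   (`TRUE` when the likelihood carries no information about lambda, e.g.
#'   on a star tree).
#' @export
fit_lambda <- function(x, tree) {
  m <- match_traits_tree(x, tree)
  n <- nrow(m$x)
  if (n < 4) stop("lambda estimation needs at least 4 tips")
  C1 <- brownian_vcv(m$tree, 1)
  obj <- function(l) {
    C <- C1
    if (l != 1) { d <- diag(C); C <- C * l; diag(C) <- d }
    bm_loglik(m$x, C)
  }
  opt <- optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  lls <- vapply(cand, obj, 0)
  best <- which.max(lls)
  flat <- diff(range(vapply(seq(0, 1, by = 0.25), obj, 0))) < 1e-7
  structure(list(lambda = cand[best], logLik = lls[best], flat = flat),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda = %.4f (logLik %.3f)%s\n", x$lambda,
              x$logLik, if (x$flat) " [likelihood flat in lambda]" else ""))
  invisible(x)
}

# Whitened GLS pieces shared by the correlation / PCA paths: returns the
# GLS root state a, whitened residuals Z ((X-1a)' C^-1 (X-1a) = Z'Z) and
# the evolutionary covariance with n-1 denominator.
gls_pieces <- function(X, C) {
  n <- nrow(X)
  R <- chol(C)
  Xw <- backsolve(R, X, transpose = TRUE)
  ow <- backsolve(R, rep(1, n), transpose = TRUE)
  a <- crossprod(ow, Xw) / sum(ow^2)
  Z <- Xw - ow %*% a
  list(a = a, Z = Z, S = crossprod(Z) / (n - 1))
}

#' Phylogenetically informed correlation between two traits
#'
#' Fits Pagel's lambda for the trait pair, estimates the evolutionary
#' (GLS) covariance under the lambda-transformed Brownian covariance, and
#' tests the resulting correlation r with
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} against a Student t distribution
#' with n - 2 degrees of freedom (two-sided). The ordinary Pearson
#' correlation of the raw values is reported alongside.
#'
#' @param x,y Named numeric trait vectors (tip labels as names).
#' @param tree A `phylo` object (>= 4 matching tips).
#' @param lambda Optional fixed lambda; by default fitted by ML.
#' @return A list of class `phylo_corr`: `r`, `lambda`, `n`, `t`, `p`,
#'   `pearson_r`.
#' @export
phylo_correlation <- function(x, y, tree, lambda = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  common <- intersect(names(x), names(y))
  X <- cbind(x = x[common], y = y[common])
  m <- match_traits_tree(X, tree)
  n <- nrow(m$x)
  if (n < 4) stop("phylogenetic correlation needs at least 4 shared tips")
  # a numerically degenerate pair (e.g. y = x) has a singular bivariate
  # likelihood; fall back to the untransformed tree covariance
  if (is.null(lambda))
    lambda <- tryCatch(fit_lambda(m$x, m$tree)$lambda, error = function(e) 1)
  C <- brownian_vcv(m$tree, lambda)
  S <- gls_pieces(m$x, C)$S
  if (any(diag(S) <= .Machine$double.eps * max(diag(S), 1)))
    stop("correlation undefined: a trait has zero evolutionary variance")
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  r <- max(-1, min(1, r))
  t_stat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  structure(list(r = r, lambda = lambda, n = n, t = t_stat, p = p,
                 pearson_r = unname(cor(m$x[, 1], m$x[, 2]))),
            class = "phylo_corr")
}

#' @export
print.phylo_corr <- function(x, ...) {
  cat(sprintf(
    "<phylo_corr> r = %.4f (lambda = %.3f, n = %d): t = %.3f, p = %.4g; Pearson r = %.4f\n",
    x$r, x$lambda, x$n, x$t, x$p, x$pearson_r))
  invisible(x)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down familywise error-rate control; values are returned in input
#' order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numbers in [0, 1]")
  p.adjust(pvalues, method = "holm")
}

#' Blomberg's K phylogenetic signal
#'
#' \eqn{K = (MSE_0/MSE) / E_{BM}[MSE_0/MSE]}, where \eqn{MSE_0} is the mean
#' squared deviation of the trait from its GLS phylogenetic mean, MSE the
#' corresponding C-weighted deviation, and the Brownian expectation is
#' \eqn{(\mathrm{tr}(C) - n/(1'C^{-1}1))/(n-1)}. K = 1 is the Brownian
#' expectation; K > 1 indicates stronger clade-level signal. Significance
#' comes from tip-label permutations: the p-value is the fraction of
#' permutations whose MSE is at most the observed MSE.
#'
#' @param x Named numeric trait vector.
#' @param tree A `phylo` object (>= 4 matching tips, positive lengths).
#' @param n_perm Number of tip permutations (0 skips the test, `p = NA`).
#' @param seed Integer seed for the permutations.
#' @return A list of class `signal_result`: `K`, `p`, `n_perm`, `n`.
#' @export
blomberg_k <- function(x, tree, n_perm = 1000, seed = NULL) {
  m <- match_traits_tree(x, tree)
  n <- nrow(m$x)
  if (n < 4) stop("Blomberg's K needs at least 4 tips")
  xv <- m$x[, 1]
  if (var(xv) == 0) stop("K undefined: trait has zero variance")
  C <- brownian_vcv(m$tree, 1)
  invC <- chol2inv(chol(C))
  csum <- colSums(invC)
  stot <- sum(csum)
  mse_pair <- function(v) {
    a <- sum(csum * v) / stot
    d <- v - a
    c(mse0 = sum(d^2), mse = as.numeric(d %*% invC %*% d)) / (n - 1)
  }
  obs <- mse_pair(xv)
  expected <- (sum(diag(C)) - n / stot) / (n - 1)
  K <- (obs[["mse0"]] / obs[["mse"]]) / expected
  p <- NA_real_
  if (n_perm > 0) {
    perm_mse <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      mse_pair(xv[sample.int(n)])[["mse"]], 0))
    p <- mean(perm_mse <= obs[["mse"]])
  }
  structure(list(K = unname(K), p = p, n_perm = n_perm, n = n),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> K = %.4f (n = %d), permutation p = %s\n",
              x$K, x$n, format(x$p)))
  invisible(x)
}

# One-way ANOVA F statistic; columns of a matrix are handled at once.
anova_f <- function(X, groups) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  g <- as.factor(groups)
  n <- nrow(X)
  k <- nlevels(g)
  ng <- as.numeric(table(g))
  gm <- rowsum(X, g) / ng
  grand <- colMeans(X)
  ssb <- colSums(ng * (gm - matrix(grand, k, ncol(X), byrow = TRUE))^2)
  sst <- colSums(X^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Phylogenetic ANOVA
#'
#' Tests whether a trait differs between groups while accounting for
#' phylogenetic non-independence: the observed statistic is the ordinary
#' one-way ANOVA F, but its null distribution is generated by simulating
#' Brownian traits on the tree (rate = GLS-estimated sigma^2) and
#' recomputing F with the group labels fixed. The p-value uses the
#' add-one estimator \eqn{(1 + \#\{F_{sim} \ge F_{obs}\})/(1 + n_{sim})}.
#'
#' @param x Named numeric trait vector.
#' @param groups Group labels named by (or ordered as) the trait values;
#'   >= 2 groups with >= 2 tips each.
#' @param tree A `phylo` object.
#' @param n_sim Number of Brownian null simulations (>= 1).
#' @param seed Integer seed.
#' @return A list of class `anova_result`: `F`, `p_sim`, `n_sim`, `sigma2`,
#'   `n`, `seed`.
#' @export
phyl_anova <- function(x, groups, tree, n_sim = 1000, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be at least 1: null distribution undefined")
  m <- match_traits_tree(x, tree)
  xv <- m$x[, 1]
  if (!is.null(names(groups))) groups <- groups[rownames(m$x)]
  else if (length(groups) != length(xv))
    stop("groups must be named or match the trait length")
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 tips")
  C <- brownian_vcv(m$tree, 1)
  n <- nrow(C)
  f_obs <- anova_f(xv, g)
  R <- chol(C)
  ow <- backsolve(R, rep(1, n), transpose = TRUE)
  xw <- backsolve(R, xv, transpose = TRUE)
  a <- sum(ow * xw) / sum(ow^2)
  sigma2 <- sum((xw - ow * a)^2) / (n - 1)
  f_sim <- with_seed(seed, {
    Z <- matrix(rnorm(n * n_sim), n, n_sim)
    anova_f(sqrt(sigma2) * crossprod(R, Z), g)
  })
  p_sim <- (1 + sum(f_sim >= f_obs)) / (1 + n_sim)
  structure(list(F = unname(f_obs), p_sim = p_sim, n_sim = n_sim,
                 sigma2 = sigma2, n = n, seed = seed),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F = %.4f (n = %d), simulation p = %.4g (%d sims)\n",
              x$F, x$n, x$p_sim, x$n_sim))
  invisible(x)
}

#' Phylogenetically informed PCA on the evolutionary correlation matrix
#'
#' Fits a single Pagel's lambda for the whole trait matrix, estimates the
#' evolutionary (GLS) covariance of the traits, converts it to a
#' correlation matrix (the traits' scales differ widely), and
#' eigendecomposes it. Scores are the ancestral-mean-centred data scaled by
#' the evolutionary standard deviations and projected on the eigenvectors.
#' Each component's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param traits Numeric matrix (tips x traits) with tip-label rownames;
#'   >= 3 traits and more tips than traits.
#' @param tree A `phylo` object.
#' @param lambda Optional fixed lambda; fitted by ML when `NULL`.
#' @return A list of class `phylo_pca`: `loadings` (traits x components),
#'   `scores` (tips x components), `eigenvalues` (descending), `lambda`.
#' @export
phylo_pca <- function(traits, tree, lambda = NULL) {
  stopifnot(is.matrix(traits) || is.data.frame(traits))
  X <- as.matrix(traits)
  if (ncol(X) < 3) stop("phylogenetic PCA needs at least 3 traits")
  m <- match_traits_tree(X, tree)
  X <- m$x
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("phylogenetic PCA needs more tips than traits")
  # a singular trait matrix breaks the lambda likelihood before the
  # collinearity diagnostic below can name the offenders
  if (is.null(lambda))
    lambda <- tryCatch(fit_lambda(X, m$tree)$lambda, error = function(e) 1)
  C <- brownian_vcv(m$tree, lambda)
  gp <- gls_pieces(X, C)
  vars <- diag(gp$S)
  if (any(vars <= 0))
    stop("singular covariance: zero-variance trait(s): ",
         paste(colnames(X)[vars <= 0], collapse = ", "))
  Rmat <- gp$S / tcrossprod(sqrt(vars))
  eig <- eigen(Rmat, symmetric = TRUE)
  if (min(eig$values) < 1e-10) {
    off <- abs(Rmat) * (1 - diag(p))
    idx <- which(off > 1 - 1e-8, arr.ind = TRUE)
    pairs <- if (nrow(idx)) paste(colnames(X)[idx[idx[, 1] < idx[, 2], 1]],
                                  colnames(X)[idx[idx[, 1] < idx[, 2], 2]],
                                  sep = " ~ ") else "(numerically collinear set)"
    stop("singular correlation matrix; collinear traits: ",
         paste(pairs, collapse = ", "))
  }
  ncomp <- min(p, n - 1)
  V <- eig$vectors[, seq_len(ncomp), drop = FALSE]
  centred <- X - rep(1, n) %*% gp$a
  scores <- centred %*% diag(1 / sqrt(vars), p) %*% V
  for (j in seq_len(ncomp)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
  structure(list(loadings = V, scores = scores,
                 eigenvalues = eig$values[seq_len(ncomp)], lambda = lambda),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  pv <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<phylo_pca> %d components (lambda = %.3f); variance explained: %s\n",
              length(x$eigenvalues), x$lambda,
              paste0(sprintf("%.1f%%", pv[seq_len(min(3, length(pv)))]),
                     collapse = ", ")))
  invisible(x)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws from a multivariate normal with mean zero and covariance
#' `sigma2 * C(lambda)`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (>= 0).
#' @param lambda Pagel's lambda transform of the covariance.
#' @param seed Integer seed.
#' @param n Number of replicate trait vectors.
#' @return Named vector (if `n = 1`) or tips x n matrix.
#' @export
simulate_brownian <- function(tree, sigma2 = 1, lambda = 1, seed = NULL, n = 1) {
  stopifnot(sigma2 >= 0)
  C <- brownian_vcv(tree, lambda)
  ntip <- nrow(C)
  R <- chol(C)
  X <- with_seed(seed,
                 sqrt(sigma2) * crossprod(R, matrix(rnorm(ntip * n), ntip, n)))
  rownames(X) <- rownames(C)
  if (n == 1) X[, 1] else X
}
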