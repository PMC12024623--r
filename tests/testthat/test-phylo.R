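test_that("Newick parsing validates labels, lengths and syntax", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr2), 3)

  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
  expect_error(parse_newick("(A,B);"), "branch length")
  expect_error(parse_newick("((A:1,"), "parse error")
})

test_that("Brownian VCV encodes shared path lengths and the lambda transform", {
  expect_equal(unname(brownian_vcv(parse_newick("(A:1,B:1);"))), diag(2))
  C <- brownian_vcv(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  C0 <- brownian_vcv(parse_newick("((A:1,B:1):1,C:2);"), lambda = 0)
  expect_equal(unname(C0), diag(c(2, 2, 2)))
  C5 <- brownian_vcv(parse_newick("((A:1,B:1):1,C:2);"), lambda = 0.5)
  expect_equal(C5["A", "B"], 0.5)
  expect_equal(unname(diag(C5)), c(2, 2, 2))
})

test_that("VCV matrices are positive semi-definite for simulated trees and any lambda", {
  for (s in 1:5) {
    tr <- simulate_tree(12, 1, seed = s)
    for (lam in c(0, 0.3, 0.7, 1)) {
      C <- brownian_vcv(tr, lam)
      expect_true(isSymmetric(C))
      expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
      expect_true(all(diag(C) + 1e-12 >= apply(C - diag(diag(C)), 1, max)))
    }
  }
})

test_that("lambda likelihood is flat on a star tree and the fit is flagged", {
  x <- setNames(rnorm(6), paste0("s", 1:6))
  fit <- fit_lambda(x, star_tree(6))
  expect_true(fit$flat)
})

test_that("the lambda fit agrees with an independent ML implementation", {
  tr <- simulate_tree(60, 1, seed = 21)
  # moderate phylogenetic signal so the optimum is interior
  x <- simulate_brownian(tr, sigma2 = 1, lambda = 0.6, seed = 13)
  mine <- fit_lambda(x, tr)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(mine$lambda, min(ref$lambda, 1), tolerance = 5e-3)
})

test_that("phylogenetic correlation reduces to Pearson on a star tree", {
  n <- 27
  tr <- star_tree(n)
  set.seed(99)
  e1 <- rnorm(n); e1 <- (e1 - mean(e1)) / sd(e1)
  e2 <- rnorm(n); e2 <- residuals(lm(e2 ~ e1)); e2 <- e2 / sd(e2)
  x <- setNames(e1, tr$tip.label)
  y <- setNames(0.6 * e1 + sqrt(1 - 0.36) * e2, tr$tip.label)
  ct <- phylo_correlation(x, y, tr, lambda = 1)
  expect_equal(ct$r, cor(x, y), tolerance = 1e-10)
  expect_equal(ct$r, 0.6, tolerance = 1e-10)
  # printed t formula: r = 0.6, n = 27 -> t = 3.75
  expect_equal(ct$t, 3.75, tolerance = 1e-10)
  expect_equal(ct$p, 2 * pt(-3.75, df = 25), tolerance = 1e-12)
  expect_equal(sign(ct$t), sign(ct$r))
})

test_that("a trait correlates perfectly with itself and zero variance errors", {
  tr <- simulate_tree(8, 1, seed = 3)
  x <- simulate_brownian(tr, seed = 5)
  ct <- phylo_correlation(x, x, tr)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-12)
  expect_error(phylo_correlation(x, setNames(rep(1, 8), names(x)), tr),
               "zero")
})

test_that("Holm adjustment matches the brute-force step-down oracle", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(c(1, 1)), c(1, 1))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(808)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("Blomberg's K matches picante and behaves under the permutation null", {
  tr <- simulate_tree(40, 1, seed = 17)
  x <- simulate_brownian(tr, seed = 23)
  mine <- blomberg_k(x, tr, n_perm = 0)
  ref <- picante::Kcalc(x[tr$tip.label], tr, checkdata = FALSE)
  expect_equal(mine$K, as.numeric(ref), tolerance = 1e-8)

  # shuffled traits carry no signal: K low, permutation test not significant
  set.seed(31)
  xs <- setNames(sample(x), names(x))
  null_fit <- blomberg_k(xs, tr, n_perm = 300, seed = 7)
  expect_lt(null_fit$K, mine$K)
  expect_gt(null_fit$p, 0.05)
})

test_that("phylogenetic ANOVA F matches stats::anova and honors its contracts", {
  tr <- simulate_tree(20, 1, seed = 51)
  x <- simulate_brownian(tr, seed = 52)
  g <- setNames(rep(c("a", "b"), each = 10), names(x))
  fit <- phyl_anova(x, g, tr, n_sim = 50, seed = 1)
  ref <- anova(lm(x ~ g))
  expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-10)

  expect_error(phyl_anova(x, g, tr, n_sim = 0), "n_sim")
  bad <- setNames(c("a", rep("b", 19)), names(x))
  expect_error(phyl_anova(x, bad, tr, n_sim = 10), "at least 2 tips")
  expect_error(phyl_anova(x, setNames(rep("a", 20), names(x)), tr, n_sim = 10),
               "2 groups")
})

test_that("a large group shift on a star tree is detected", {
  n <- 30
  tr <- star_tree(n)
  set.seed(73)
  x <- setNames(rnorm(n), tr$tip.label)
  g <- setNames(rep(c("a", "b"), each = n / 2), tr$tip.label)
  x[g == "b"] <- x[g == "b"] + 4
  fit <- phyl_anova(x, g, tr, n_sim = 500, seed = 2)
  expect_lt(fit$p_sim, 0.05)
})

test_that("phylogenetic PCA reduces to ordinary correlation PCA on a star tree", {
  n <- 25
  tr <- star_tree(n)
  set.seed(61)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(tr$tip.label, paste0("tr", 1:4)))
  X[, 2] <- X[, 1] * 0.7 + X[, 2] * 0.5
  fit <- phylo_pca(X, tr, lambda = 1)
  ref <- eigen(cor(X), symmetric = TRUE)
  expect_equal(fit$eigenvalues, ref$values, tolerance = 1e-10)
  expect_equal(abs(unname(fit$loadings)), abs(ref$vectors), tolerance = 1e-8)
  expect_equal(sum(fit$eigenvalues), 4, tolerance = 1e-10)  # correlation trace
  # scores match prcomp on standardized data up to component signs
  ref_scores <- scale(X, center = TRUE, scale = FALSE) %*%
    diag(1 / apply(X, 2, sd)) %*% ref$vectors
  expect_equal(abs(unname(fit$scores)), abs(unname(ref_scores)),
               tolerance = 1e-8)
  # deterministic sign convention: dominant loading positive
  for (j in 1:4)
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
})

test_that("near-collinear traits concentrate variance; exact collinearity errors", {
  tr <- simulate_tree(20, 1, seed = 81)
  a <- simulate_brownian(tr, seed = 82)
  b <- a + rnorm(20, sd = sd(a) * 0.02)
  c_ <- simulate_brownian(tr, seed = 83)
  X <- cbind(a = a, b = setNames(b, names(a)), c = c_)
  fit <- phylo_pca(X, tr)
  expect_gt(fit$eigenvalues[1], 1.9)
  expect_lt(fit$eigenvalues[3], 0.05)
  X_bad <- cbind(a = a, b = 2 * a + 1, c = c_)
  expect_error(phylo_pca(X_bad, tr), "collinear")
})

test_that("Brownian simulation is seeded and matches its covariance", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  x1 <- simulate_brownian(tr, seed = 5)
  expect_identical(x1, simulate_brownian(tr, seed = 5))
  expect_false(identical(x1, simulate_brownian(tr, seed = 6)))
  expect_equal(unname(simulate_brownian(tr, sigma2 = 0, seed = 1)),
               c(0, 0, 0))

  X <- simulate_brownian(tr, sigma2 = 2, seed = 9, n = 5000)
  S <- tcrossprod(X) / 5000
  C <- 2 * brownian_vcv(tr)
  expect_equal(unname(S), unname(C), tolerance = 0.06)
})

test_that("trees prune to the trait set with a warning; unknown traits error", {
  tr <- simulate_tree(10, 1, seed = 91)
  x <- simulate_brownian(tr, seed = 92)
  x_sub <- x[1:6]
  expect_warning(fit <- blomberg_k(x_sub, tr, n_perm = 0), "pruning")
  expect_equal(fit$n, 6)
  x_bad <- setNames(rnorm(4), c("t1", "t2", "nope", "t4"))
  expect_error(blomberg_k(x_bad, tr, n_perm = 0), "absent from the tree")
})

test_that("zero-length terminal branches are bumped before inversion", {
  tr <- parse_newick("((A:0,B:1):1,(C:1,D:2):1);")
  x <- setNames(c(1.2, -0.5, 0.3, 0.9), c("A", "B", "C", "D"))
  expect_no_error(blomberg_k(x, tr, n_perm = 0))
  expect_no_error(fit_lambda(x, tr))
})
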