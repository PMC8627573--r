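test_that("Newick parsing validates structure and branch lengths", {
  t1 <- parse_newick("(A:1,B:1);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(t1)[1:2]), c(1, 1))
  t2 <- parse_newick("((A:1,B:1):1,C:2);")
  d <- stats::cophenetic(t2)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  # round trip preserves the tip set through a canonical serialization
  expect_equal(sort(parse_newick(ape::write.tree(t2))$tip.label),
               c("A", "B", "C"))
  expect_error(parse_newick("((A:1,B:1"), "malformed")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
  expect_error(parse_newick("(A,B);"), "branch lengths")
})

test_that("individuals attach as terminal polytomies at distance epsilon", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  map <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "c1"),
                    taxon = c("A", "A", "A", "B", "C"))
  eps <- 0.01
  ex <- attach_individuals(tr, map, epsilon = eps)
  d <- stats::cophenetic(ex)
  # conspecifics sit 2*eps apart
  expect_equal(d["a1", "a2"], 2 * eps)
  expect_equal(d["a2", "a3"], 2 * eps)
  # inter-species distances grow by exactly eps per expanded endpoint
  expect_equal(d["a1", "b1"], 2 + 2 * eps)
  expect_equal(d["a1", "c1"], 4 + 2 * eps)
  # a single individual is a relabeled tip with the branch extended by eps
  expect_true("b1" %in% ex$tip.label)
  expect_false("B" %in% ex$tip.label)
  expect_error(attach_individuals(tr, map, epsilon = 0), "> 0")
  expect_error(attach_individuals(tr, data.frame(sample_id = "x1",
                                                 taxon = "X")), "absent")
})

test_that("the OU correlation is exp(-alpha d) with the right limits", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(ou_correlation(d, 1)[1, 2], exp(-1))
  expect_equal(diag(ou_correlation(d, 2.5)), c(1, 1))
  c0 <- ou_correlation(d, 0)
  expect_true(all(c0 == 1))
  expect_false(attr(c0, "invertible"))
  expect_lt(ou_correlation(d, 50)[1, 2], 1e-21)
  expect_error(ou_correlation(d, -1), ">= 0")
  expect_error(ou_correlation(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("gls_fit reduces to OLS under the identity correlation", {
  set.seed(5)
  n <- 12
  X <- cbind(intercept = 1, slope = rnorm(n))
  y <- 1 + 2 * X[, 2] + rnorm(n)
  f <- gls_fit(y, X, diag(n))
  o <- lm(y ~ X[, 2])
  expect_equal(unname(f$coefficients), unname(coef(o)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(o)$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("gls_fit matches the dense-inverse oracle on random instances", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    A <- matrix(rnorm(n * n), n)
    V <- stats::cov2cor(crossprod(A) + diag(n))
    X <- cbind(intercept = 1, slope = rnorm(n))
    y <- rnorm(n)
    f <- gls_fit(y, X, V)
    o <- gls_oracle(y, X, V)
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-9)
    expect_equal(unname(f$se), unname(o$se), tolerance = 1e-9)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-9)
  }
  # perfectly collinear design is refused
  Xc <- cbind(1, 1:5, 2 * (1:5))
  expect_error(gls_fit(rnorm(5), Xc, diag(5)), "rank-deficient")
})

test_that("gls_fit agrees with nlme under a fixed OU correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(8, seed = 33)
  set.seed(33)
  dat <- data.frame(taxon = tr$tip.label, x = rnorm(8))
  dat$y <- 1 + 0.5 * dat$x + rnorm(8, sd = 0.3)
  alpha <- 2
  cs <- nlme::Initialize(ape::corMartins(alpha, phy = tr, form = ~taxon,
                                         fixed = TRUE), data = dat)
  ref <- nlme::gls(y ~ x, data = dat, correlation =
                     ape::corMartins(alpha, phy = tr, form = ~taxon,
                                     fixed = TRUE),
                   method = "ML")
  C <- nlme::corMatrix(cs)
  f <- gls_fit(dat$y, cbind(intercept = 1, slope = dat$x), C)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("the profiled alpha maximizes the likelihood over its own grid", {
  tr <- simulate_tree(10, seed = 17)
  set.seed(17)
  map <- data.frame(sample_id = paste0("i", 1:10), taxon = tr$tip.label)
  ex <- attach_individuals(tr, map)
  h <- max(ape::node.depth.edgelength(ex))
  dmat <- stats::cophenetic(ex)[map$sample_id, map$sample_id] / h
  y <- as.vector(rou_tips(ex, 2, 1)[map$sample_id, ])
  X <- cbind(intercept = 1, slope = rnorm(10))
  prof <- profile_ou_alpha(y, X, dmat)
  expect_true(all(prof$grid$loglik <= prof$loglik + 1e-8))
})

test_that("PGLS equals OLS on a star phylogeny", {
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, 10)
  star$tip.label <- sprintf("sp%02d", 1:10)
  set.seed(23)
  d <- data.frame(sample_id = paste0("s", 1:10), taxon = star$tip.label,
                  x = rnorm(10), y = rnorm(10))
  pg <- fit_pgls(d, "y", "x", star)
  ol <- fit_ols(d, "y", "x")
  expect_equal(pg$slope, ol$slope, tolerance = 1e-6)
  expect_equal(pg$se_slope, ol$se_slope, tolerance = 1e-6)
  expect_equal(pg$p, ol$p, tolerance = 1e-6)
})

test_that("with no phylogenetic signal the PGLS slope tracks OLS", {
  tr <- simulate_tree(15, seed = 29)
  set.seed(29)
  d <- data.frame(sample_id = paste0("s", 1:15), taxon = tr$tip.label,
                  x = rnorm(15))
  d$y <- 2 - 1.5 * d$x + rnorm(15, sd = 0.5)   # iid residuals: alpha large
  pg <- fit_pgls(d, "y", "x", tr)
  ol <- fit_ols(d, "y", "x")
  expect_lt(abs(pg$slope - ol$slope), 3 * ol$se_slope)
  expect_error(fit_pgls(transform(d, x = 1), "y", "x", tr), "degenerate")
})

test_that("discordant close relatives move the slope more than a distant tip", {
  tr <- parse_newick("((A:0.1,B:0.1):0.9,(C:0.9,D:0.9):0.1);")
  d0 <- data.frame(sample_id = c("a", "b", "c", "d"),
                   taxon = c("A", "B", "C", "D"),
                   x = c(0, 1, 0, 1), y = c(0.1, 0.2, 0.15, 0.25))
  slope_at <- function(dat) fit_pgls(dat, "y", "x", tr, alpha = 1)$slope
  base <- slope_at(d0)
  pert_close <- d0; pert_close$y[1] <- pert_close$y[1] + 0.5
  pert_far <- d0; pert_far$y[3] <- pert_far$y[3] + 0.5
  expect_gt(abs(slope_at(pert_close) - base),
            abs(slope_at(pert_far) - base))
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5)), c(1.0, 1.0))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(11)
  p <- runif(7)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  # permutation equivariance
  perm <- sample(7)
  expect_equal(holm_adjust(p[perm]), adj[perm])
  # agreement with the independent step-down oracle
  expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
})
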