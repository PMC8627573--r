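#' Parse a Newick tree with validation
#'
#' Thin, strict wrapper around [ape::read.tree()]: the tree must parse, have
#' unique tip labels, and carry finite non-negative branch lengths on every
#' edge (trees without lengths are rejected, since patristic distances are
#' the substrate of the OU correlation).
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  phy <- withCallingHandlers(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge))
    stop("tree has missing branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  phy
}

#' Attach individuals to a species tree as terminal polytomies
#'
#' Each species tip with k sampled individuals is replaced by a polytomy at
#' the end of its terminal branch whose k children are the individuals, on
#' branches of length `epsilon`; a species with a single individual is
#' relabelled with its terminal branch extended by `epsilon`. Every
#' individual therefore sits `epsilon` beyond its species node, conspecific
#' tips are `2 * epsilon` apart, and inter-species patristic distances grow
#' by exactly `epsilon` per expanded endpoint (at most `2 * epsilon`).
#' `epsilon` must be strictly positive: at zero, conspecific tips would be
#' at distance zero and the OU correlation matrix would have duplicate rows.
#'
#' @param tree species phylogeny ([ape::phylo]).
#' @param mapping data frame with columns `sample_id` and `taxon`.
#' @param epsilon attachment branch length; default `1e-3` x tree height.
#' @return the expanded [ape::phylo] tree, with unsampled species tips left
#'   in place.
#' @export
attach_individuals <- function(tree, mapping, epsilon = NULL) {
  stopifnot(all(c("sample_id", "taxon") %in% names(mapping)))
  if (anyDuplicated(mapping$sample_id))
    stop("duplicate sample ids in mapping")
  unknown <- setdiff(unique(mapping$taxon), tree$tip.label)
  if (length(unknown))
    stop("taxa absent from tree: ", paste(unknown, collapse = ", "))
  height <- max(ape::node.depth.edgelength(tree))
  if (is.null(epsilon)) epsilon <- 1e-3 * height
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0 (zero-length polytomies make the OU ",
         "correlation singular)")
  for (taxon in unique(mapping$taxon)) {
    ids <- mapping$sample_id[mapping$taxon == taxon]
    tip <- which(tree$tip.label == taxon)
    if (length(ids) == 1L) {
      ei <- which(tree$edge[, 2L] == tip)
      tree$edge.length[ei] <- tree$edge.length[ei] + epsilon
      tree$tip.label[tip] <- ids
    } else {
      star <- ape::stree(length(ids), type = "star")
      star$tip.label <- ids
      star$edge.length <- rep(epsilon, length(ids))
      tree <- ape::bind.tree(tree, star, where = tip)
    }
  }
  tree
}

#' Ornstein-Uhlenbeck tip correlation matrix
#'
#' Builds the OU correlation `exp(-alpha * d_ij)` from a patristic distance
#' matrix. At `alpha = 0` the matrix is all ones (flagged non-invertible);
#' as `alpha` grows it tends to the identity (an ordinary regression).
#'
#' @param distances symmetric patristic distance matrix with zero diagonal.
#' @param alpha selection strength >= 0, in units of inverse distance.
#' @return the correlation matrix, with attributes `alpha` and `invertible`.
#' @export
ou_correlation <- function(distances, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single finite value >= 0")
  if (!is.matrix(distances) || nrow(distances) != ncol(distances) ||
      !isTRUE(all.equal(distances, t(distances))) ||
      any(diag(distances) != 0))
    stop("distances must be a symmetric matrix with zero diagonal")
  cm <- exp(-alpha * distances)
  attr(cm, "alpha") <- alpha
  attr(cm, "invertible") <- alpha > 0
  cm
}

#' Generalized least squares with a known correlation matrix
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 * C)`, by whitening through the
#' triangular Cholesky factor of `C` (the correlation matrix is never
#' explicitly inverted). `sigma^2` is profiled by maximum likelihood
#' (`RSS_C / n`) for the reported log-likelihood; standard errors use the
#' unbiased `RSS_C / (n - p)` so that with `C = I` they coincide with
#' ordinary least squares.
#'
#' @param y response vector.
#' @param X design matrix (full column rank, `n > ncol(X)`).
#' @param correlation positive-definite correlation matrix `C`.
#' @return list with `coefficients`, `se`, `vcov`, `sigma2` (unbiased),
#'   `sigma2_ml`, `loglik`, `df_residual`, `rss` (the whitened residual sum
#'   of squares).
#' @export
gls_fit <- function(y, X, correlation) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) != n || nrow(correlation) != n)
    stop("dimension mismatch between y, X and correlation")
  if (n <= p) stop("need more observations than coefficients")
  U <- tryCatch(chol(correlation),
                error = function(e) stop("singular correlation matrix: ",
                                         conditionMessage(e)))
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  colnames(wX) <- colnames(X)
  qx <- qr(wX)
  if (qx$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qx, wy)
  names(beta) <- colnames(X)
  res <- wy - wX %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtxinv <- chol2inv(qr.R(qx))
  vcov <- sigma2 * xtxinv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  list(coefficients = beta, se = sqrt(diag(vcov)), vcov = vcov,
       sigma2 = sigma2, sigma2_ml = sigma2_ml, loglik = loglik,
       df_residual = n - p, rss = rss)
}

#' Profile the OU selection strength by maximum likelihood
#'
#' Evaluates the GLS profile log-likelihood over a grid of `log(alpha)`
#' values and refines the best interior point by golden-section search
#' ([stats::optimize()]). The upper bound of the default grid
#' (`log(alpha) = 6` in tree-height units) drives the correlation toward
#' the identity, so an ordinary regression is reachable as a special case.
#'
#' @param y,X response and design as in [gls_fit()].
#' @param distances patristic distance matrix aligned with `y`.
#' @param log_bounds range of `log(alpha)` searched.
#' @param n_grid number of grid points.
#' @return list `alpha`, `loglik`, and `grid` (data frame `log_alpha`,
#'   `loglik`).
#' @export
profile_ou_alpha <- function(y, X, distances, log_bounds = c(-6, 6),
                             n_grid = 25L) {
  ll <- function(la) {
    tryCatch(gls_fit(y, X, ou_correlation(distances, exp(la)))$loglik,
             error = function(e) -Inf)
  }
  grid_la <- seq(log_bounds[1L], log_bounds[2L], length.out = n_grid)
  grid_ll <- vapply(grid_la, ll, 1)
  if (all(!is.finite(grid_ll)))
    stop("profile likelihood undefined over the whole alpha grid")
  best <- which.max(grid_ll)
  la_hat <- grid_la[best]
  ll_hat <- grid_ll[best]
  if (best > 1L && best < n_grid) {
    opt <- stats::optimize(ll, interval = c(grid_la[best - 1L], grid_la[best + 1L]),
                           maximum = TRUE, tol = 1e-6)
    if (opt$objective > ll_hat) {
      la_hat <- opt$maximum
      ll_hat <- opt$objective
    }
  }
  list(alpha = exp(la_hat), loglik = ll_hat,
       grid = data.frame(log_alpha = grid_la, loglik = grid_ll))
}

#' Phylogenetically generalized regression of one response on one predictor
#'
#' Attaches the sampled individuals to the species tree as terminal
#' polytomies, normalizes tree height to 1 (so the OU selection strength is
#' comparable across trees), profiles `alpha` by maximum likelihood (unless
#' fixed), and reports the GLS slope with a two-sided t-test on `n - 2`
#' degrees of freedom. Closely related samples with discordant residuals
#' carry more weight than distant ones, which is the point of the method.
#'
#' @param data data frame containing `sample_id`, `taxon`, and the response
#'   and predictor columns.
#' @param response,predictor column names in `data`.
#' @param tree species phylogeny covering all taxa in `data`.
#' @param slice label recorded in the result (which specimen slice was fit).
#' @param epsilon attachment branch length (see [attach_individuals()]).
#' @param alpha fix the OU selection strength instead of profiling it.
#' @param log_bounds,n_grid profile-search controls (see
#'   [profile_ou_alpha()]).
#' @return one-row data frame: `response`, `predictor`, `slice`, `n`,
#'   `intercept`, `slope`, `se_intercept`, `se_slope`, `t`, `df`, `p`,
#'   `p_holm` (`NA` until family adjustment), `alpha_hat`, `loglik`,
#'   `method`.
#' @export
fit_pgls <- function(data, response, predictor, tree, slice = "all",
                     epsilon = NULL, alpha = NULL, log_bounds = c(-6, 6),
                     n_grid = 25L) {
  stopifnot(all(c("sample_id", "taxon", response, predictor) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(response, predictor)]), ]
  n <- nrow(data)
  if (n < 3L) stop("need >= 3 observations for a regression")
  x <- data[[predictor]]
  y <- data[[response]]
  if (stats::var(x) == 0) stop("degenerate predictor '", predictor,
                               "': no variance")
  expanded <- attach_individuals(tree, data[, c("sample_id", "taxon")],
                                 epsilon = epsilon)
  h <- max(ape::node.depth.edgelength(expanded))
  dmat <- stats::cophenetic(expanded)[data$sample_id, data$sample_id] / h
  X <- cbind(intercept = 1, slope = x)
  if (is.null(alpha)) {
    prof <- profile_ou_alpha(y, X, dmat, log_bounds = log_bounds,
                             n_grid = n_grid)
    alpha_hat <- prof$alpha
  } else {
    if (alpha <= 0) stop("fixed alpha must be > 0")
    alpha_hat <- alpha
  }
  fit <- gls_fit(y, X, ou_correlation(dmat, alpha_hat))
  tval <- fit$coefficients[["slope"]] / fit$se[["slope"]]
  df <- n - 2L
  data.frame(response = response, predictor = predictor, slice = slice,
             n = n,
             intercept = fit$coefficients[["intercept"]],
             slope = fit$coefficients[["slope"]],
             se_intercept = fit$se[["intercept"]],
             se_slope = fit$se[["slope"]],
             t = tval, df = df,
             p = 2 * stats::pt(-abs(tval), df),
             p_holm = NA_real_,
             alpha_hat = alpha_hat, loglik = fit$loglik,
             method = "PGLS-OU", stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit in the same report format as [fit_pgls()]
#'
#' @inheritParams fit_pgls
#' @return one-row data frame with the same columns as [fit_pgls()]
#'   (`alpha_hat = NA`, `method = "OLS"`).
#' @export
fit_ols <- function(data, response, predictor, slice = "all") {
  data <- data[stats::complete.cases(data[, c(response, predictor)]), ]
  n <- nrow(data)
  if (n < 3L) stop("need >= 3 observations for a regression")
  if (stats::var(data[[predictor]]) == 0)
    stop("degenerate predictor '", predictor, "': no variance")
  fm <- stats::lm(stats::reformulate(predictor, response), data = data)
  cf <- summary(fm)$coefficients
  data.frame(response = response, predictor = predictor, slice = slice,
             n = n,
             intercept = cf[1L, 1L], slope = cf[2L, 1L],
             se_intercept = cf[1L, 2L], se_slope = cf[2L, 2L],
             t = cf[2L, 3L], df = n - 2L, p = cf[2L, 4L],
             p_holm = NA_real_, alpha_hat = NA_real_,
             loglik = as.numeric(stats::logLik(fm)),
             method = "OLS", stringsAsFactors = FALSE)
}

#' Holm step-down familywise adjustment
#'
#' Step-down Holm procedure: p-values sorted ascending, the i-th multiplied
#' by `m - i + 1`, a running maximum enforced, capped at 1, and the result
#' returned in the input order. Delegates to [stats::p.adjust()] after
#' validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "holm")
}
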