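#' Coverage and sign-recovery simulation for the PGLS slope
#'
#' Repeatedly simulates data from the exact model the regression assumes —
#' a linear depth effect plus residuals drawn from the stationary OU
#' covariance on the individual-expanded tree — then refits with
#' [fit_pgls()] (selection strength profiled by ML) and records whether the
#' 95% confidence interval covers the true slope and whether its sign was
#' recovered. This is the calibration check for the regression machinery
#' itself; sign recovery through the compositional (softmax) generator is
#' exercised separately by the battery power analysis.
#'
#' @param n_reps number of replicate studies.
#' @param n_taxa,individuals_per_taxon study design per replicate.
#' @param beta true slope (response units per km of depth).
#' @param intercept true intercept.
#' @param ou_alpha,ou_sigma residual OU parameters (per unit tree height /
#'   response units).
#' @param level confidence level.
#' @param seed integer seed.
#' @return data frame with one row per replicate: `slope`, `se`, `lo`,
#'   `hi`, `covered`, `sign_ok`, `alpha_hat`.
#' @export
pgls_coverage_sim <- function(n_reps = 200L, n_taxa = 20L,
                              individuals_per_taxon = 10L, beta = 1,
                              intercept = 2, ou_alpha = 3, ou_sigma = 0.5,
                              level = 0.95, seed = 1L) {
  set.seed(seed)
  cfg <- sim_config(n_taxa = n_taxa,
                    individuals_per_taxon = individuals_per_taxon,
                    seed = seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tree <- simulate_tree(n_taxa)
    rec <- simulate_environment(cfg)
    expanded <- attach_individuals(tree, rec[, c("sample_id", "taxon")])
    h <- max(ape::node.depth.edgelength(expanded))
    dmat <- stats::cophenetic(expanded)[rec$sample_id, rec$sample_id] / h
    cv <- ou_sigma^2 * exp(-ou_alpha * dmat)
    e <- eigen(cv, symmetric = TRUE)
    resid <- as.vector(e$vectors %*% (sqrt(pmax(e$values, 0)) *
                                        stats::rnorm(nrow(dmat))))
    rec$depth_km <- rec$depth_m / 1000
    rec$y <- intercept + beta * rec$depth_km + resid
    fit <- fit_pgls(rec, "y", "depth_km", tree)
    halfw <- stats::qt(1 - (1 - level) / 2, fit$df) * fit$se_slope
    rows[[r]] <- data.frame(slope = fit$slope, se = fit$se_slope,
                            lo = fit$slope - halfw, hi = fit$slope + halfw,
                            covered = fit$slope - halfw <= beta &
                                      beta <= fit$slope + halfw,
                            sign_ok = sign(fit$slope) == sign(beta),
                            alpha_hat = fit$alpha_hat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Familywise error simulation for a Holm-corrected regression family
#'
#' Simulates null studies (all environmental effects zero) through the full
#' compositional generator, computes summary metrics, fits the summary
#' responses against depth within the cold slice, Holm-adjusts within the
#' family, and records whether any response was flagged. Holm controls the
#' familywise type I error of each family at the nominal level, so the
#' rejection rate across replicates should not exceed it beyond binomial
#' noise.
#'
#' @param n_reps number of replicate null studies.
#' @param n_taxa,individuals_per_taxon study design per replicate.
#' @param ou_alpha,ou_sigma,noise_sd generator variance parameters (the
#'   species and individual variance sources stay on; only the
#'   environmental effects are nulled).
#' @param alpha familywise level tested.
#' @param seed integer seed.
#' @return logical vector of length `n_reps`: any rejection in the family.
#' @export
battery_fwer_sim <- function(n_reps = 200L, n_taxa = 10L,
                             individuals_per_taxon = 6L, ou_alpha = 3,
                             ou_sigma = 0.3, noise_sd = 0.15, alpha = 0.05,
                             seed = 1L) {
  set.seed(seed)
  panel <- default_panel()
  panel$beta_depth[] <- 0
  panel$beta_temp[] <- 0
  cfg <- sim_config(n_taxa = n_taxa,
                    individuals_per_taxon = individuals_per_taxon,
                    panel = panel, ou_alpha = ou_alpha, ou_sigma = ou_sigma,
                    noise_sd = noise_sd, seed = seed)
  acfg <- analysis_config(alpha = alpha)
  any_flag <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    tree <- simulate_tree(n_taxa)
    rec <- simulate_environment(cfg)
    cmp <- simulate_compositions(tree, rec, cfg)
    metrics <- compute_metrics(cmp$composition)
    tab <- build_response_table(metrics, NULL, rec)
    dslice <- tab[tab$sample_id %in% slice_for_depth(rec, acfg)$sample_id, ]
    fam <- .fit_family(dslice, acfg$summary_responses, "depth_km", tree,
                       "summary x depth", "cold", acfg)
    any_flag[r] <- any(fam$significant)
  }
  any_flag
}
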