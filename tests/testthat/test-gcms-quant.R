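test_that("standard curves recover the slope through the origin", {
  splits <- c(5, 10, 15, 20, 30, 40, 60, 100)
  pts <- data.frame(split_ratio = splits,
                    integral = 1000 * on_column_fraction(splits))
  co <- fit_standard_curve(pts, molar_mass = 250, compound = "X")
  expect_equal(co$mass_coefficient, 1000)
  expect_equal(co$molar_coefficient, 4.0)
  expect_true(co$valid)

  # all-zero standard: slope 0, flagged invalid
  z <- fit_standard_curve(transform(pts, integral = 0), 250, "Z")
  expect_equal(z$mass_coefficient, 0)
  expect_false(z$valid)

  # noisy series matches the closed-form zero-intercept OLS slope (lm oracle)
  set.seed(4)
  x <- on_column_fraction(splits)
  yn <- 1000 * x + rnorm(8, sd = 1)
  noisy <- fit_standard_curve(data.frame(split_ratio = splits, integral = abs(yn)),
                              250, "N")
  oracle <- unname(coef(lm(abs(yn) ~ 0 + x)))
  expect_equal(noisy$mass_coefficient, oracle, tolerance = 1e-12)
  expect_gt(noisy$mass_coefficient, 990)
  expect_lt(noisy$mass_coefficient, 1010)

  expect_error(fit_standard_curve(pts[1, ], 250), "2 distinct")
  expect_error(fit_standard_curve(pts, -1), "> 0")
})

test_that("quantitation-ion selection follows the tenfold rule", {
  target <- c("74" = 1.0, "87" = 0.6, "143" = 0.2)
  coel <- c("74" = 0.9, "87" = 0.05)
  # 87: 0.6 >= 10 * 0.05; 74: 1.0 < 10 * 0.9
  expect_equal(select_quant_ion(target, list(coel)), 87)
  # no coeluters -> base peak
  expect_equal(select_quant_ion(target), 74)
  # identical coeluter -> no orthogonal ion exists
  expect_error(select_quant_ion(target, list(target)),
               "unresolvable coelution")
  # share form at thres_ortho = 0.9 is the >= 9x reading: an ion with a
  # 0.905 share passes "share" but fails the strict tenfold inequality
  tg <- c("50" = 1, "60" = 0.9)
  co2 <- c("50" = 1, "60" = 0.095)
  expect_equal(select_quant_ion(tg, list(co2), rule = "share"), 60)
  expect_error(select_quant_ion(tg, list(co2), rule = "tenfold"),
               "unresolvable")
  # ties break toward the lower m/z
  expect_equal(select_quant_ion(c("90" = 1, "60" = 1)), 60)
})

test_that("any returned quantitation ion satisfies the rule by brute force", {
  set.seed(6)
  for (i in 1:50) {
    mzs <- sort(sample(50:350, 6))
    tg <- stats::setNames(runif(6), mzs)
    co <- list(stats::setNames(runif(6), sort(sample(50:350, 6))),
               stats::setNames(runif(4), sort(sample(50:350, 4))))
    pick <- tryCatch(select_quant_ion(tg, co), error = function(e) NULL)
    if (is.null(pick)) {
      # the error is only legitimate when no ion at all passes
      expect_false(any(vapply(as.numeric(names(tg)), quant_ion_ok,
                              TRUE, target = tg, coeluters = co)))
    } else {
      expect_true(quant_ion_ok(pick, tg, co))
    }
  }
})

test_that("peak integration is trapezoidal with interpolated bounds", {
  tt <- seq(0, 10, by = 0.5)
  expect_equal(integrate_peak(tt, rep(0, length(tt)), c(1, 9)), 0)
  expect_equal(integrate_peak(c(0, 1, 2, 3), c(0, 1, 1, 0), c(1, 3)), 1.5)
  # unit rectangle of width 2
  expect_equal(integrate_peak(c(0, 2), c(1, 1), c(0, 2)), 2.0)
  # triangular peak height h over base b has area h*b/2
  h <- 3.7; b <- 4
  tri <- approx(c(0, b / 2, b), c(0, h, 0), xout = seq(0, b, by = 0.01))
  expect_equal(integrate_peak(tri$x, tri$y, c(0, b)), h * b / 2,
               tolerance = 1e-9)
  expect_equal(integrate_peak(tt, tt, c(3, 3)), 0)
  expect_error(integrate_peak(c(0, 1, 2), c(0, 1, 0), c(2, 1)), "unordered")
  expect_error(integrate_peak(c(0, 1, 2), c(0, 1, 0), c(-1, 2)), "outside")
})

test_that("mole fractions follow the coefficient-normalized closure", {
  coefs <- data.frame(compound = c("A", "B"), molar_mass = c(100, 100),
                      mass_coefficient = c(100, 300),
                      molar_coefficient = c(1, 3),
                      n_points = 8, valid = TRUE)
  x <- compute_mole_fractions(data.frame(compound = c("A", "B"),
                                         integral = c(100, 300)), coefs)
  expect_equal(unname(x), c(0.5, 0.5))
  coefs$molar_coefficient <- c(2, 2)
  x2 <- compute_mole_fractions(data.frame(compound = c("A", "B"),
                                          integral = c(200, 100)), coefs)
  expect_equal(unname(x2), c(2 / 3, 1 / 3))
  x3 <- compute_mole_fractions(data.frame(compound = "A", integral = 5), coefs)
  expect_equal(unname(x3), 1.0)
  expect_error(compute_mole_fractions(
    data.frame(compound = c("A", "B"), integral = c(0, 0)), coefs),
    "no positive peak")
  expect_warning(compute_mole_fractions(
    data.frame(compound = c("A", "unknown"), integral = c(5, 5)), coefs),
    "excluding")
})

test_that("mole fractions are invariant to a common integral scale", {
  st <- simulate_study(sim_config(n_taxa = 4, individuals_per_taxon = 3,
                                  seed = 31))
  coefs <- fit_standard_curves(st$standards)
  one <- st$peaks[st$peaks$sample_id == st$peaks$sample_id[1], ]
  x1 <- compute_mole_fractions(one, coefs)
  scaled <- transform(one, integral = integral * 37.5)
  expect_equal(compute_mole_fractions(scaled, coefs), x1)
})

test_that("noise-free synthetic GC-MS data round-trips exactly", {
  st <- simulate_study(sim_config(n_taxa = 6, individuals_per_taxon = 4,
                                  seed = 8))
  q <- quantify_run(st$standards, st$peaks, st$spectra,
                    coelution = st$coelution)
  truth <- st$truth$true_mole_fractions
  wide <- stats::reshape(q$composition, idvar = "sample_id",
                         timevar = "compound", direction = "wide")
  got <- as.matrix(wide[, -1])
  colnames(got) <- sub("^mole_fraction\\.", "", colnames(got))
  got <- got[, colnames(truth)]
  expect_lt(max(abs(got[match(rownames(truth), wide$sample_id), ] - truth)),
            1e-9)
})

test_that("the detection test flags real compounds and removes lone spikes", {
  set.seed(12)
  n <- 20
  comp <- rbind(
    data.frame(sample_id = paste0("s", 1:n), compound = "present",
               mole_fraction = abs(rnorm(n, 0.02, 0.001))),
    data.frame(sample_id = paste0("s", 1:n), compound = "absent",
               mole_fraction = 0),
    data.frame(sample_id = paste0("s", 1:n), compound = "spiky",
               mole_fraction = c(rep(0, n - 1), 0.5))
  )
  rep <- detect_significant_species(comp)
  expect_true(rep$detected[rep$compound == "present"])
  expect_false(rep$detected[rep$compound == "absent"])
  spiky <- rep[rep$compound == "spiky", ]
  expect_equal(spiky$n_outliers_removed, 1L)
  expect_false(spiky$detected)
  expect_error(detect_significant_species(comp[comp$sample_id %in%
                                                 c("s1", "s2"), ]), ">= 3")
})

test_that("detection Holm adjustment agrees with the step-down oracle", {
  set.seed(14)
  comp <- do.call(rbind, lapply(1:6, function(k)
    data.frame(sample_id = paste0("s", 1:15), compound = paste0("c", k),
               mole_fraction = abs(rnorm(15, mean = 0.002 * k,
                                         sd = 0.004)))))
  rep <- detect_significant_species(comp)
  expect_equal(rep$p_holm, holm_oracle(rep$p), tolerance = 1e-12)
})
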