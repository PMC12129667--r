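test_that("drift covariance matches brute-force accumulation on a toy", {
  withr::with_seed(61, {
    freq_mat <- matrix(runif(30, 0.2, 0.8), ncol = 3,
                       dimnames = list(NULL, c("F", "S", "O")))
  })
  g <- make_geno(matrix(0L, 4, 10), c("F", "S", "O", "F"))
  freqs <- dplyr::bind_rows(lapply(c("F", "S", "O"), function(p) {
    tibble::tibble(id = sprintf("v%04d", 1:10), chrom = "1",
                   pos = (0:9) * 3000 + 1, population = p,
                   freq = freq_mat[, p], allele_count = 0L,
                   n_haplotypes = 10)
  }))
  model <- estimate_drift_covariance(freqs, focal = "F", outgroup = "O")

  # direct summation oracle
  acc <- matrix(0, 2, 2)
  used <- 0
  for (i in 1:10) {
    y <- c(freq_mat[i, "F"] - freq_mat[i, "O"],
           freq_mat[i, "S"] - freq_mat[i, "O"])
    pbar <- mean(freq_mat[i, ])
    s <- pbar * (1 - pbar)
    if (s > 0) { acc <- acc + tcrossprod(y) / s; used <- used + 1 }
  }
  expect_equal(unname(model$C), acc / used, tolerance = 1e-12)
  expect_equal(model$n_snps_used, 10)
  expect_equal(model$populations, c("F", "S"))
  expect_equal(model$focal_index, 1L)

  # identical populations give the zero matrix
  freqs0 <- dplyr::mutate(freqs, freq = rep(freq_mat[, 1], 3))
  model0 <- estimate_drift_covariance(freqs0, "F", "O")
  expect_equal(unname(model0$C), matrix(0, 2, 2), tolerance = 1e-12)

  expect_error(estimate_drift_covariance(freqs[freqs$population != "S", ],
                                         "F", "O"),
               "3 populations")
})

test_that("covariance diagonal reflects the simulated branch drift", {
  # Balding-Nichols variance algebra: Var(p_i - p_out) = (F_i + F_out) * s,
  # Cov = F_out * s, so C has a known structure at matched branch drift
  fd <- c(focal = 0.01, sister = 0.01, outgroup = 0.02)
  panel <- simulate_panel(sim_params(50000, branch_drift = fd, seed = 63))
  freqs_mat <- panel$pop_freqs
  freqs <- dplyr::bind_rows(lapply(colnames(freqs_mat), function(p) {
    tibble::tibble(id = sprintf("v%05d", seq_len(nrow(freqs_mat))),
                   chrom = "1", pos = seq_len(nrow(freqs_mat)),
                   population = p, freq = freqs_mat[, p],
                   allele_count = 0L, n_haplotypes = 0)
  }))
  model <- estimate_drift_covariance(freqs, "JEJ", "CHS")
  expect_equal(model$C[1, 1], 0.03, tolerance = 0.15)
  expect_equal(model$C[2, 2], 0.03, tolerance = 0.15)
  expect_equal(model$C[1, 2], 0.02, tolerance = 0.2)
})

test_that("per-SNP test reproduces the diagonal closed form", {
  C <- diag(c(0.04, 0.03))
  model <- structure(
    list(C = C, populations = c("F", "S"), focal_index = 1L,
         focal = "F", outgroup = "O", n_snps_used = 1000L),
    class = "drift_cov"
  )
  s <- 0.25
  # z = y_f^2 / (s c_ff) = 4  ->  llr = z - 1 - ln z, gamma_hat = z
  y_f <- sqrt(4 * s * C[1, 1])
  rec <- scan_snp(c(y_f, 0), s, model)
  expect_equal(rec$llr, 4 - 1 - log(4), tolerance = 1e-6)
  expect_equal(rec$gamma_hat, 4, tolerance = 1e-6)

  # z < 1 sits on the boundary
  y_f2 <- sqrt(0.5 * s * C[1, 1])
  rec2 <- scan_snp(c(y_f2, 0), s, model)
  expect_equal(rec2$llr, 0)
  expect_equal(rec2$gamma_hat, 1)

  # zero contrast is the boundary optimum
  rec0 <- scan_snp(c(0, 0), s, model)
  expect_equal(rec0$llr, 0)
  expect_equal(rec0$gamma_hat, 1)

  expect_error(scan_snp(c(0.1, 0), 0, model), "`s` must be > 0")
})

test_that("numeric optimizer agrees with the closed form on random instances", {
  withr::with_seed(67, {
    for (i in 1:60) {
      c_ff <- runif(1, 0.005, 0.1)
      c_ss <- runif(1, 0.005, 0.1)
      s <- runif(1, 0.05, 0.25)
      model <- structure(
        list(C = diag(c(c_ff, c_ss)), populations = c("F", "S"),
             focal_index = 1L, focal = "F", outgroup = "O",
             n_snps_used = 1000L),
        class = "drift_cov"
      )
      z <- runif(1, 0.01, 40)
      y <- c(sqrt(z * s * c_ff) * sign(runif(1) - 0.5), rnorm(1, 0, 0.05))
      num <- scan_snp(y, s, model, method = "numeric")
      closed_llr <- if (z >= 1) z - 1 - log(z) else 0
      expect_equal(num$llr, closed_llr, tolerance = 1e-6)
      # non-diagonal covariance: numeric and analytic routes agree
      rho <- runif(1, -0.6, 0.6) * sqrt(c_ff * c_ss)
      model$C <- matrix(c(c_ff, rho, rho, c_ss), 2)
      ana <- scan_snp(y, s, model, method = "analytic")
      num2 <- scan_snp(y, s, model, method = "numeric")
      expect_equal(num2$llr, ana$llr, tolerance = 1e-6)
      expect_equal(num2$gamma_hat, ana$gamma_hat, tolerance = 1e-4)
    }
  })
})

test_that("the statistic is monotone in the focal displacement", {
  model <- structure(
    list(C = matrix(c(0.03, 0.01, 0.01, 0.04), 2),
         populations = c("F", "S"), focal_index = 1L, focal = "F",
         outgroup = "O", n_snps_used = 1000L),
    class = "drift_cov"
  )
  y_s <- 0.02
  llrs <- vapply(seq(0, 0.5, by = 0.01), function(yf) {
    scan_snp(c(yf, y_s), 0.2, model)$llr
  }, numeric(1))
  expect_true(all(diff(llrs) >= -1e-10))
})

test_that("genome scan output is invariant to SNP order and label-symmetric under the null", {
  g <- null_scan_fixture(n_snps = 2000, seed = 71)
  scan1 <- scan_genome(g, "JEJ", "CHS")

  # the fitted null model is order-invariant: permuting the rows of the
  # frequency table leaves the covariance (and hence the scan) unchanged
  freqs <- allele_frequencies(g)
  withr::with_seed(72, perm <- sample.int(nrow(freqs)))
  model_perm <- estimate_drift_covariance(freqs[perm, ], "JEJ", "CHS")
  model_orig <- attr(scan1, "model")
  expect_equal(model_perm$C, model_orig$C, tolerance = 1e-12)
  scan2 <- scan_genome(g, "JEJ", "CHS", model = model_perm)
  expect_equal(scan1$llr, scan2$llr, tolerance = 1e-12)

  # llr >= 0 with equality exactly when gamma_hat = 1
  expect_true(all(scan1$llr >= 0, na.rm = TRUE))
  expect_equal(scan1$llr == 0, scan1$gamma_hat == 1)

  # swapping focal and sister labels leaves the llr distribution unchanged
  scan_swap <- scan_genome(g, "KOR", "CHS")
  ks <- suppressWarnings(stats::ks.test(scan1$llr[scan1$llr > 0],
                                        scan_swap$llr[scan_swap$llr > 0]))
  expect_gt(ks$p.value, 0.01)
})

test_that("null zero fraction matches the exact boundary-LRT value", {
  # One observation per SNP makes the exact null zero-probability
  # P(chisq_1 <= 1) = 0.683, not the asymptotic 1/2 of the chi-bar-square
  # limit: gamma_hat > 1 iff a chi-square(1) pivot exceeds 1.
  g <- null_scan_fixture(n_snps = 6000, seed = 73)
  scan <- scan_genome(g, "JEJ", "CHS")
  expect_equal(mean(scan$llr == 0, na.rm = TRUE), pchisq(1, 1),
               tolerance = 0.04)
})

test_that("boosted-drift loci are strongly enriched among the top statistics", {
  # A variance boost makes selected loci *stochastically* larger, not
  # deterministically extreme: a boosted Balding-Nichols draw still lands
  # near its root with the chi-square(1) mass near zero. The honest check
  # is heavy enrichment over the chance expectation (40 * 21/20000 = 0.04
  # loci), not near-complete recovery.
  p <- sim_params(20000, n_selected = 21, selection_boost = 50, seed = 77)
  panel <- simulate_panel(p)
  g <- sample_genotypes(panel, seed = 78)
  scan <- scan_genome(g, "JEJ", "CHS")
  sel_ids <- g$variants$id[panel$selected_loci]
  top40 <- scan$id[order(-scan$llr)][1:40]
  expect_gte(sum(top40 %in% sel_ids), 6)
})

test_that("calibration scales with the statistic distribution and yields mixture p-values", {
  withr::with_seed(81, draws <- stats::rchisq(50000, df = 1))
  stats_mix <- c(rep(0, 50000), draws)
  cal1 <- calibrate_llrs(stats_mix)
  expect_equal(cal1$calibration$lambda, 1, tolerance = 0.1)
  expect_equal(cal1$calibration$fraction_zero, 0.5)

  cal2 <- calibrate_llrs(c(rep(0, 50000), 2 * draws))
  expect_equal(cal2$calibration$lambda, 2, tolerance = 0.2)

  # p = 1 exactly at llr = 0; p nonincreasing in llr
  sc <- cal1$scan
  expect_true(all(sc$p_calibrated[sc$llr == 0] == 1))
  ord <- order(sc$llr)
  expect_true(all(diff(sc$p_calibrated[ord]) <= 1e-12))
  expect_true(all(sc$p_calibrated > 0 & sc$p_calibrated <= 1))

  expect_error(calibrate_llrs(rep(0, 100)), "Degenerate")
})
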