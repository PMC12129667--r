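#' Estimate the genome-wide drift covariance of frequency contrasts
#'
#' For each SNP with all populations called, forms the outgroup-rooted
#' contrast vector `y` (each non-outgroup population's frequency minus the
#' outgroup frequency) and the per-SNP scale `s = pbar (1 - pbar)` with
#' `pbar` the unweighted across-population mean frequency. The genome-wide
#' covariance is the average of `y y' / s` over SNPs (sites with `s = 0`
#' skipped), projected to the nearest positive-semidefinite matrix if
#' numerically needed. This matrix is the scan's null model: it captures how
#' much correlated frequency change ordinary drift produces.
#'
#' @param freqs A long frequency table from [allele_frequencies()] covering
#'   at least three populations.
#' @param focal Label of the focal population (tested for excess change).
#' @param outgroup Label of the outgroup population (rooting the contrasts).
#' @return A `drift_cov` object: list with `C` (covariance of contrasts),
#'   `populations` (non-outgroup labels, in contrast order), `focal_index`,
#'   `focal`, `outgroup`, `n_snps_used`.
#' @export
estimate_drift_covariance <- function(freqs, focal, outgroup) {
  mat <- freq_matrix(freqs)
  pops <- colnames(mat)
  if (length(pops) < 3) abort("At least 3 populations are required.")
  if (!focal %in% pops || !outgroup %in% pops) {
    abort("`focal` and `outgroup` must be populations in the table.")
  }
  if (focal == outgroup) abort("`focal` and `outgroup` must differ.")
  non_out <- c(focal, sort(setdiff(pops, c(focal, outgroup))))
  y <- mat[, non_out, drop = FALSE] - mat[, outgroup]
  s <- rowMeans(mat) * (1 - rowMeans(mat))
  ok <- stats::complete.cases(mat) & s > 0
  if (sum(ok) < 2) abort("All SNPs are monomorphic or incomplete.")
  yw <- y[ok, , drop = FALSE] / sqrt(s[ok])
  C <- crossprod(yw) / sum(ok)
  eig <- eigen(C, symmetric = TRUE)
  if (any(eig$values < -1e-10)) {
    vals <- pmax(eig$values, 0)
    C <- eig$vectors %*% diag(vals, length(vals)) %*% t(eig$vectors)
    dimnames(C) <- list(non_out, non_out)
  }
  structure(
    list(C = C, populations = non_out,
         focal_index = match(focal, non_out), focal = focal,
         outgroup = outgroup, n_snps_used = sum(ok)),
    class = "drift_cov"
  )
}

#' @export
print.drift_cov <- function(x, ...) {
  cat(sprintf("<drift_cov> focal %s, outgroup %s, %d SNPs\n",
              x$focal, x$outgroup, x$n_snps_used))
  print(round(x$C, 6))
  invisible(x)
}

maybe_ridge <- function(C, ridge = 1e-9) {
  # ridge only when near-singular, so well-conditioned models are untouched
  if (!is.finite(rcond(C)) || rcond(C) < 1e-10) C + diag(ridge, nrow(C)) else C
}

scan_closed_form <- function(y, s, Ci, f, c_ff) {
  # Profile likelihood in gamma has an analytic optimum (Sherman-Morrison):
  # with z = ((C^-1 y)_f)^2 / (s [C^-1]_ff),
  #   gamma_hat = 1 + (z - 1) / (c_ff [C^-1]_ff)  when z > 1, else 1
  #   llr       = z - 1 - log z                   when z > 1, else 0
  # In the diagonal case z reduces to y_f^2 / (s c_ff).
  u <- drop(crossprod(Ci[, f], y))
  z <- u^2 / (s * Ci[f, f])
  a <- c_ff * Ci[f, f]
  list(
    z = z,
    gamma_hat = ifelse(z > 1, 1 + (z - 1) / a, 1),
    llr = ifelse(z > 1, z - 1 - log(z), 0)
  )
}

scan_loglik <- function(gamma, y, s, C, f, ridge = 1e-9) {
  # same (conditionally ridged) matrix as the analytic route
  Cg <- maybe_ridge(C, ridge)
  Cg[f, f] <- gamma * Cg[f, f]
  Cg <- s * Cg
  -0.5 * (as.numeric(determinant(2 * pi * Cg, logarithm = TRUE)$modulus) +
            drop(t(y) %*% solve(Cg, y)))
}

#' Per-SNP likelihood-ratio test for excess focal frequency change
#'
#' Null model: the contrast vector `y` is Gaussian with mean zero and
#' covariance `s C`, where `C` is the genome-wide drift covariance.
#' Alternative: the focal diagonal entry of `C` is multiplied by a scalar
#' `gamma >= 1`, estimated by maximum likelihood. The statistic is
#' `llr = 2 (l1 - l0)`, floored at zero by the boundary constraint.
#'
#' Two routes are provided: `"analytic"` (default) uses the exact
#' profile-likelihood optimum; `"numeric"` maximizes the log-likelihood over
#' `log(gamma)` on `[0, log(1e6)]` by bounded derivative-free search. The
#' two agree to optimizer tolerance; the diagonal-covariance closed form
#' `llr = z - 1 - log z` (for `z >= 1`) is reproduced exactly.
#'
#' @param y Numeric contrast vector (one SNP).
#' @param s Positive per-SNP scale `pbar (1 - pbar)`.
#' @param model A `drift_cov` from [estimate_drift_covariance()].
#' @param method `"analytic"` or `"numeric"`.
#' @param ridge Diagonal ridge added before inversion.
#' @return One-row tibble: `gamma_hat`, `llr`.
#' @export
scan_snp <- function(y, s, model, method = c("analytic", "numeric"),
                     ridge = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(model, "drift_cov"))
  if (s <= 0) abort("`s` must be > 0.")
  f <- model$focal_index
  C <- model$C
  if (method == "analytic") {
    Cr <- maybe_ridge(C, ridge)
    res <- scan_closed_form(matrix(y, ncol = 1), s, solve(Cr), f, Cr[f, f])
    tibble(gamma_hat = res$gamma_hat, llr = res$llr)
  } else {
    l0 <- scan_loglik(1, y, s, C, f, ridge)
    opt <- optimize(
      function(lg) scan_loglik(exp(lg), y, s, C, f, ridge),
      interval = c(0, log(1e6)), maximum = TRUE, tol = 1e-8
    )
    llr <- 2 * (opt$objective - l0)
    if (llr <= 0) {
      tibble(gamma_hat = 1, llr = 0)
    } else {
      tibble(gamma_hat = exp(opt$maximum), llr = llr)
    }
  }
}

#' Genome-wide selection scan
#'
#' Estimates the drift covariance from all usable SNPs, then applies the
#' per-SNP likelihood-ratio test to every SNP. SNPs with `s = 0` or a
#' missing population frequency are skipped with a reason.
#'
#' @param geno A [geno_matrix()] (run QC first; the pipeline order is
#'   biallelic -> heterozygote-excess -> flip removal -> MAF -> scan).
#' @param focal,outgroup Population labels.
#' @param method Gamma-estimation route, see [scan_snp()].
#' @param model Optional precomputed `drift_cov`; estimated from `geno` when
#'   `NULL`.
#' @return A `scan_table` tibble sorted by genomic coordinate: `id`, `chrom`,
#'   `pos`, `s`, `gamma_hat`, `llr`, with the model in attribute `"model"`
#'   and skipped SNPs in attribute `"skipped"`.
#' @export
scan_genome <- function(geno, focal, outgroup,
                        method = c("analytic", "numeric"), model = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  method <- match.arg(method)
  freqs <- allele_frequencies(geno)
  model <- model %||% estimate_drift_covariance(freqs, focal, outgroup)
  mat <- freq_matrix(freqs)
  non_out <- model$populations
  y <- t(mat[, non_out, drop = FALSE] - mat[, model$outgroup])
  s <- rowMeans(mat) * (1 - rowMeans(mat))
  usable <- stats::complete.cases(mat) & s > 0
  v <- geno$variants
  out <- tibble(
    id = v$id, chrom = v$chrom, pos = v$pos, s = unname(s),
    gamma_hat = NA_real_, llr = NA_real_
  )
  if (method == "analytic") {
    f <- model$focal_index
    Cr <- maybe_ridge(model$C)
    res <- scan_closed_form(y[, usable, drop = FALSE], s[usable], solve(Cr),
                            f, Cr[f, f])
    out$gamma_hat[usable] <- res$gamma_hat
    out$llr[usable] <- res$llr
  } else {
    rows <- which(usable)
    fits <- purrr::map(rows, function(i) {
      scan_snp(y[, i], s[i], model, method = "numeric")
    })
    fits <- bind_rows(fits)
    out$gamma_hat[rows] <- fits$gamma_hat
    out$llr[rows] <- fits$llr
  }
  out <- arrange(out, .data$chrom, .data$pos)
  skipped <- tibble(
    id = v$id[!usable],
    reason = ifelse(s[!usable] <= 0 | is.na(s[!usable]),
                    "monomorphic (s = 0)", "missing population frequency")
  )
  attr(out, "model") <- model
  attr(out, "skipped") <- skipped
  class(out) <- c("scan_table", class(out))
  out
}

#' Zero-inflation-aware genomic-control calibration
#'
#' The boundary-constrained test puts a point mass of statistics at exactly
#' zero, so median-based genomic control is not applicable. Instead, the
#' lowest 50% of statistics are discarded (ties at zero broken arbitrarily;
#' every discarded value is <= every retained value) and the inflation
#' factor is the ratio of 99th percentiles:
#' `lambda = P99(retained) / P99(chi-square_1)`.
#' Every SNP's statistic is divided by `lambda`, and the calibrated p-value
#' is the 50:50 mixture `p = 1` when `llr = 0`, else
#' `0.5 * S_chisq1(llr / lambda)`.
#'
#' @param scan A `scan_table` from [scan_genome()], or any data frame with an
#'   `llr` column, or a bare numeric vector of statistics.
#' @param quantile_base `"retained"` (default: the 99th percentile is taken
#'   over the retained upper half) or `"all"` (over all statistics).
#' @return A list: `calibration` (one-row tibble with `lambda`,
#'   `p99_observed`, `p99_chisq1`, `n_zero`, `fraction_zero`, `n_total`) and
#'   `scan` (input with `llr_corrected` and `p_calibrated` columns added).
#' @export
calibrate_llrs <- function(scan, quantile_base = c("retained", "all")) {
  quantile_base <- match.arg(quantile_base)
  if (is.numeric(scan)) scan <- tibble(llr = scan)
  if (!"llr" %in% names(scan)) abort("`scan` must have an `llr` column.")
  llr <- scan$llr[!is.na(scan$llr)]
  if (length(llr) == 0 || all(llr == 0)) {
    abort("Degenerate scan: all statistics are zero or missing.")
  }
  n <- length(llr)
  srt <- sort(llr)
  retained <- srt[(floor(n / 2) + 1L):n]
  base <- if (quantile_base == "retained") retained else srt
  p99_obs <- unname(quantile(base, 0.99, type = 7))
  p99_chisq <- qchisq(0.99, df = 1)
  lambda <- p99_obs / p99_chisq
  if (lambda <= 0) abort("Degenerate scan: nonpositive inflation factor.")
  scan$llr_corrected <- scan$llr / lambda
  scan$p_calibrated <- ifelse(
    scan$llr == 0, 1,
    0.5 * pchisq(scan$llr_corrected, df = 1, lower.tail = FALSE)
  )
  calibration <- tibble(
    lambda = lambda, p99_observed = p99_obs, p99_chisq1 = p99_chisq,
    n_zero = sum(llr == 0), fraction_zero = mean(llr == 0), n_total = n
  )
  list(calibration = calibration, scan = scan)
}
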