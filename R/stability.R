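# Bootstrap machinery: nonparametric edge-weight confidence intervals,
# case-drop correlation-stability coefficients, and bootstrap difference
# tests. All routines are reproducible bit-for-bit from (data, config,
# master seed): every replicate draws its own seed via derive_seed().

#' Nonparametric bootstrap of a network estimator
#'
#' Resamples rows with replacement `n_boot` times, refits the estimator, and
#' summarizes every estimand with its bootstrap mean and 2.5/97.5 percentile
#' confidence interval. The estimator must be deterministic given
#' `(data, seed)`; each replicate receives a child seed derived from the
#' master seed so stochastic estimators (e.g. a CLPN with internal
#' cross-validation) are reproducible.
#'
#' @param data matrix or data frame; rows are resampled.
#' @param estimator `function(data, seed)` returning a named numeric vector
#'   of estimands (e.g. flattened edge weights).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed master seed.
#' @param max_fail maximum tolerated proportion of failed replicates
#'   (default 0.05); failures beyond it raise an error.
#' @param conf confidence level (default 0.95, percentile intervals).
#' @return a `bootstrap_summary`: data frame with columns estimand, point,
#'   boot_mean, ci_low, ci_high, n_boot; the replicate matrix is kept in
#'   attribute `"samples"` for difference tests.
#' @export
bootstrap_edges <- function(data, estimator, n_boot = 1000L, seed,
                            max_fail = 0.05, conf = 0.95) {
  if (missing(seed)) pn_config_error("bootstrap_edges requires a master seed")
  data <- as.matrix(data)
  n <- nrow(data)
  point <- tryCatch(estimator(data, derive_seed(seed, 0L)),
                    error = function(e) pn_estimation_error(
                      "estimator failed on the full sample: %s",
                      conditionMessage(e)))
  k <- length(point)
  if (is.null(names(point))) names(point) <- paste0("est", seq_len(k))
  samples <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, names(point)))
  failures <- 0L
  for (i in seq_len(n_boot)) {
    rs <- derive_seed(seed, i)
    set.seed(rs)
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(estimator(data[idx, , drop = FALSE], rs),
                    error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else samples[i, ] <- est
  }
  if (failures > max_fail * n_boot)
    pn_estimation_error("%d of %d bootstrap replicates failed (> %.0f%%)",
                        failures, n_boot, 100 * max_fail)
  if (failures > 0)
    warning(sprintf("%d bootstrap replicate(s) failed and were skipped", failures),
            call. = FALSE)
  ok <- stats::complete.cases(samples)
  qs <- apply(samples[ok, , drop = FALSE], 2, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  out <- data.frame(
    estimand = names(point), point = as.numeric(point),
    boot_mean = colMeans(samples[ok, , drop = FALSE]),
    ci_low = qs[1, ], ci_high = qs[2, ], n_boot = sum(ok)
  )
  rownames(out) <- NULL
  structure(out, class = c("bootstrap_summary", "data.frame"),
            samples = samples[ok, , drop = FALSE], seed = seed, conf = conf)
}

#' Case-drop bootstrap correlation-stability coefficient
#'
#' For each drop proportion `q` in the grid, subsamples `(1 - q) * n` rows
#' without replacement `n_boot` times, recomputes the centralities, and
#' correlates them with the full-sample centralities. The CS coefficient is
#' the largest `q` such that the correlation stays at or above
#' `cor_threshold` with estimated probability at least `prob_threshold`.
#' The search walks the grid upward and stops at the first failing
#' proportion, enforcing a monotone decision rule. Values below 0.25 signal
#' unstable centrality ordering; above 0.50 is considered strong stability.
#'
#' @param data matrix or data frame; rows are subsampled.
#' @param centrality_fn `function(data, seed)` returning a numeric vector of
#'   centralities (same length and order every call).
#' @param drop_grid proportions of cases to drop; the conventional 10-point
#'   grid from 0.05 to 0.75.
#' @param n_boot subsamples per proportion (default 250).
#' @param seed master seed.
#' @param cor_threshold correlation the subsample centralities must reach
#'   (default 0.7).
#' @param prob_threshold required probability of reaching it (default 0.95).
#' @return a `cs_result`: list with `cs`, the per-proportion pass
#'   probabilities, and the thresholds used.
#' @export
case_drop_cs <- function(data, centrality_fn,
                         drop_grid = seq(0.05, 0.75, length.out = 10),
                         n_boot = 250L, seed, cor_threshold = 0.7,
                         prob_threshold = 0.95) {
  if (missing(seed)) pn_config_error("case_drop_cs requires a master seed")
  data <- as.matrix(data)
  n <- nrow(data)
  drop_grid <- sort(drop_grid)
  if (floor((1 - max(drop_grid)) * n) < 25)
    pn_data_error("n = %d leaves fewer than 25 rows at %.0f%% drop",
                  n, 100 * max(drop_grid))
  full <- centrality_fn(data, derive_seed(seed, 0L))
  cs <- 0
  probs <- rep(NA_real_, length(drop_grid))
  for (qi in seq_along(drop_grid)) {
    q <- drop_grid[qi]
    m <- max(3L, floor((1 - q) * n))
    cors <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      rs <- derive_seed(seed, qi * 100000L + i)
      set.seed(rs)
      idx <- sample.int(n, m)
      cent <- tryCatch(centrality_fn(data[idx, , drop = FALSE], rs),
                       error = function(e) rep(NA_real_, length(full)))
      cors[i] <- suppressWarnings(stats::cor(cent, full))
    }
    probs[qi] <- mean(!is.na(cors) & cors >= cor_threshold)
    if (probs[qi] >= prob_threshold) cs <- q else break
  }
  if (cs == 0)
    warning("centralities unstable even at the smallest drop proportion; CS = 0",
            call. = FALSE)
  structure(
    list(cs = cs, drop_grid = drop_grid, pass_prob = probs,
         cor_threshold = cor_threshold, prob_threshold = prob_threshold,
         n_boot = n_boot, seed = seed),
    class = "cs_result"
  )
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("Correlation-stability coefficient: CS(cor = %.1f) = %.2f\n",
              x$cor_threshold, x$cs))
  tested <- !is.na(x$pass_prob)
  cat("  drop proportion:", sprintf("%.2f", x$drop_grid[tested]), "\n")
  cat("  P(cor >= thr): ", sprintf("%.2f", x$pass_prob[tested]), "\n")
  invisible(x)
}

#' Bootstrap difference test
#'
#' Two estimands differ significantly when the percentile interval of their
#' replicate-wise differences excludes zero (paired comparison within the
#' same bootstrap replicates).
#'
#' @param boot a `bootstrap_summary` from [bootstrap_edges()].
#' @param estimand_a,estimand_b names of the two estimands.
#' @param alpha significance level (default 0.05, two-sided).
#' @return list with `significant`, the interval, and the estimand names.
#' @export
difference_test <- function(boot, estimand_a, estimand_b, alpha = 0.05) {
  samples <- attr(boot, "samples")
  if (is.null(samples)) pn_config_error("no bootstrap samples attached")
  for (e in c(estimand_a, estimand_b))
    if (!e %in% colnames(samples))
      pn_config_error("estimand '%s' not found in bootstrap samples", e)
  d <- samples[, estimand_a] - samples[, estimand_b]
  ci <- unname(stats::quantile(d, c(alpha / 2, 1 - alpha / 2)))
  list(significant = ci[1] > 0 || ci[2] < 0, ci_low = ci[1], ci_high = ci[2],
       estimand_a = estimand_a, estimand_b = estimand_b, alpha = alpha)
}

#' Pairwise bootstrap difference matrix
#'
#' @param boot a `bootstrap_summary`.
#' @param estimands subset of estimand names (default: all).
#' @param alpha significance level.
#' @return symmetric 0/1 matrix of significance flags with zero diagonal.
#' @export
difference_matrix <- function(boot, estimands = NULL, alpha = 0.05) {
  samples <- attr(boot, "samples")
  if (is.null(samples)) pn_config_error("no bootstrap samples attached")
  estimands <- estimands %||% colnames(samples)
  k <- length(estimands)
  M <- matrix(0L, k, k, dimnames = list(estimands, estimands))
  for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
    sig <- difference_test(boot, estimands[a], estimands[b], alpha)$significant
    M[a, b] <- M[b, a] <- as.integer(sig)
  }
  M
}
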