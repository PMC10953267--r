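# Synthetic two-wave panel generator with known network ground truth.
#
# Generating model: standardized latent scale scores at T1 follow a
# multivariate normal with the correlation structure implied by a sparse
# partial-correlation matrix; T2 scores follow a VAR(1) step T2 = T1 B + e.
# Covariates shift the scores additively (so residualization is
# consequential), and item responses are noisy indicators of each score
# whose unique noise sums to zero within a scale -- the scale mean then
# equals the latent score exactly while Cronbach's alpha hits its target,
# an exact-reliability construction. Likert responses discretize the items
# by (optionally skewed) normal thresholds.

#' Construct a simulation specification
#'
#' @param nodes node (scale) names.
#' @param constructs construct tag per node.
#' @param true_partial symmetric sparse partial-correlation matrix; the
#'   implied precision `I - P` must be positive definite.
#' @param B transition matrix, `B[i, j]` = effect of T1 node i on T2 node j
#'   (diagonal = autoregressive); spectral radius must be < 1.
#' @param innovation_sd per-node innovation standard deviations.
#' @param innovation_structure `"stationary"` (default) draws T2 innovations
#'   with the correlation structure that keeps the T2 contemporaneous
#'   covariance equal to the T1 covariance, so both waves share the same
#'   true network; `"diagonal"` draws independent innovations, leaving T2
#'   contemporaneous structure to arise from the dynamics alone.
#' @param covariate_effects named list per covariate of named slope vectors
#'   (covariates: gender 0/1, age in years, education and income ordinal).
#' @param items_per_scale named integer vector of item counts.
#' @param target_alpha named reliability targets in (0, 1).
#' @param response_range named list of `c(lo, hi)` Likert bounds per scale.
#' @param likert_levels `"auto"` (per-scale, from the response range), an
#'   integer overriding all scales, or `"continuous"` for undiscretized
#'   items.
#' @param likert_probs optional named list of cumulative threshold
#'   probabilities per scale (skewed response distributions); default
#'   equiprobable.
#' @param n sample size.
#' @param seed integer seed.
#' @return a validated `simulation_spec`.
#' @export
simulation_spec <- function(nodes, constructs, true_partial, B, innovation_sd,
                            covariate_effects = list(), items_per_scale,
                            target_alpha, response_range,
                            likert_levels = "auto", likert_probs = NULL,
                            innovation_structure = c("stationary", "diagonal"),
                            n = 591L, seed = 1L) {
  p <- length(nodes)
  innovation_structure <- match.arg(innovation_structure)
  spec <- structure(
    list(nodes = nodes, constructs = constructs,
         true_partial = true_partial, B = B, innovation_sd = innovation_sd,
         innovation_structure = innovation_structure,
         covariate_effects = covariate_effects,
         items_per_scale = items_per_scale, target_alpha = target_alpha,
         response_range = response_range, likert_levels = likert_levels,
         likert_probs = likert_probs, n = as.integer(n),
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
  validate_spec(spec)
  spec
}

#' Validate a simulation specification
#'
#' Checks positive definiteness of the implied precision matrix, stability
#' of the transition matrix (spectral radius < 1), and achievability of the
#' reliability targets.
#'
#' @param spec a `simulation_spec`.
#' @return the spec, invisibly; errors on any violated invariant.
#' @export
validate_spec <- function(spec) {
  p <- length(spec$nodes)
  P <- spec$true_partial
  if (!isSymmetric(unname(as.matrix(P)), tol = 1e-10))
    pn_config_error("true_partial must be symmetric")
  Theta <- diag(p) - as.matrix(P)
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    pn_config_error("implied precision matrix not positive definite (min eigenvalue %.3g)",
                    min(ev))
  sr <- max(Mod(eigen(spec$B, only.values = TRUE)$values))
  if (sr >= 1)
    pn_config_error("transition matrix unstable (spectral radius %.3f)", sr)
  for (nm in spec$nodes) {
    a <- spec$target_alpha[[nm]]; k <- spec$items_per_scale[[nm]]
    if (is.null(a) || is.null(k))
      pn_config_error("missing items_per_scale/target_alpha for node '%s'", nm)
    if (a <= 0 || a >= 1)
      pn_config_error("target_alpha for '%s' must be in (0, 1)", nm)
    rho <- a / (k - a * (k - 1))   # Spearman-Brown equi-correlation
    if (rho <= 0 || rho >= 1)
      pn_config_error("target_alpha %.2f unreachable with %d items for '%s'", a, k, nm)
  }
  if (length(spec$innovation_sd) != p || any(spec$innovation_sd <= 0))
    pn_config_error("innovation_sd must be %d positive values", p)
  if (identical(spec$innovation_structure, "stationary")) {
    Sigma1 <- stats::cov2cor(solve(Theta))
    Psi <- Sigma1 - t(spec$B) %*% Sigma1 %*% spec$B
    if (min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
      pn_config_error("stationary innovation covariance not positive definite")
  }
  invisible(spec)
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Two-wave panel simulation spec\n")
  cat(sprintf("  nodes: %d   n: %d   seed: %d   items: %s\n",
              length(x$nodes), x$n, x$seed,
              if (identical(x$likert_levels, "continuous")) "continuous"
              else "Likert"))
  cat(sprintf("  true contemporaneous edges: %d   cross-lagged edges: %d\n",
              sum(x$true_partial[upper.tri(x$true_partial)] != 0),
              sum(x$B != 0) - sum(diag(x$B) != 0)))
  invisible(x)
}

#' Default 9-node study-like simulation specification
#'
#' Emulates the structure of a two-wave maternal-parenting / adolescent
#' mental-health panel: positive partial-correlation blocks within positive
#' parenting (warmth, monitoring, inductive reasoning), within negative
#' parenting (hostility, harshness) and within the mental-health problems,
#' weak negative cross-construct edges (monitoring-conduct the strongest),
#' autoregressive stability 0.5, and cross-lagged ground truth led by
#' hostility -> depression (0.23), harshness -> hostility (0.20) and
#' anxiety -> depression (0.19). Item counts, response formats and
#' reliability targets (alpha 0.59-0.87) match the study instruments'
#' published characteristics. Innovation variances are set so T2 scores
#' remain approximately standardized. Deterministic: two calls yield
#' identical specs.
#'
#' @param n sample size (default 591, the study's retained cohort).
#' @param seed simulation seed.
#' @param likert_levels see [simulation_spec()]; default `"auto"`.
#' @return a `simulation_spec`.
#' @export
default_spec <- function(n = 591L, seed = 1L, likert_levels = "auto") {
  defs <- study_scales()
  nodes <- names(defs)
  p <- length(nodes)
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  edges <- list(
    c("warmth", "reasoning", .59), c("aggression", "conduct", .57),
    c("anxiety", "depression", .51), c("hostility", "harshness", .45),
    c("warmth", "monitoring", .32), c("anxiety", "aggression", .16),
    c("monitoring", "reasoning", .12), c("depression", "aggression", .09),
    c("hostility", "depression", .04), c("hostility", "conduct", .02),
    c("harshness", "conduct", .02), c("hostility", "aggression", .01),
    c("harshness", "aggression", .01), c("harshness", "depression", .01),
    c("depression", "conduct", .01), c("monitoring", "aggression", -.01),
    c("reasoning", "aggression", -.01), c("monitoring", "anxiety", -.01),
    c("reasoning", "anxiety", -.02), c("monitoring", "hostility", -.02),
    c("monitoring", "depression", -.03), c("warmth", "harshness", -.03),
    c("hostility", "reasoning", -.03), c("warmth", "anxiety", -.04),
    c("monitoring", "harshness", -.04), c("monitoring", "conduct", -.05),
    c("reasoning", "harshness", -.05), c("warmth", "hostility", -.07)
  )
  for (e in edges) {
    P[e[1], e[2]] <- as.numeric(e[3]); P[e[2], e[1]] <- as.numeric(e[3])
  }
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  diag(B) <- 0.5
  paths <- list(
    c("hostility", "depression", .23), c("harshness", "hostility", .20),
    c("anxiety", "depression", .19), c("warmth", "reasoning", .15),
    c("conduct", "anxiety", .12), c("reasoning", "warmth", .11),
    c("depression", "anxiety", .10), c("hostility", "aggression", .09),
    c("aggression", "conduct", .08), c("hostility", "anxiety", .07),
    c("warmth", "monitoring", .05), c("hostility", "conduct", .05),
    c("reasoning", "monitoring", .04), c("aggression", "depression", .03),
    c("aggression", "anxiety", .03), c("hostility", "harshness", .03),
    c("anxiety", "aggression", .02), c("monitoring", "warmth", .02),
    c("aggression", "reasoning", -.01), c("monitoring", "conduct", -.01),
    c("hostility", "reasoning", -.01), c("reasoning", "harshness", -.01),
    c("conduct", "reasoning", -.02), c("monitoring", "harshness", -.02),
    c("depression", "reasoning", -.02), c("harshness", "monitoring", -.02),
    c("aggression", "warmth", -.02), c("anxiety", "warmth", -.03),
    c("depression", "warmth", -.03), c("warmth", "anxiety", -.06),
    c("reasoning", "hostility", -.06), c("warmth", "depression", -.08)
  )
  for (e in paths) B[e[1], e[2]] <- as.numeric(e[3])

  Sigma1 <- stats::cov2cor(solve(diag(p) - P))
  # sds of the stationarity-preserving innovations, so T2 stays standardized
  innovation_sd <- sqrt(diag(Sigma1 - t(B) %*% Sigma1 %*% B))

  target_alpha <- c(anxiety = .86, depression = .77, aggression = .82,
                    conduct = .65, warmth = .87, monitoring = .87,
                    hostility = .83, reasoning = .82, harshness = .59)
  items <- vapply(defs, function(d) length(d$item_ids), integer(1))
  ranges <- lapply(defs, function(d) d$response_range)

  covariate_effects <- list(
    gender = c(aggression = .25, conduct = .20, depression = -.10),
    age = c(depression = .06, anxiety = .04, monitoring = -.05),
    education = c(warmth = .15, reasoning = .15, harshness = -.10),
    income = c(hostility = -.08)
  )

  simulation_spec(
    nodes = nodes, constructs = constructs_of(defs), true_partial = P, B = B,
    innovation_sd = innovation_sd, covariate_effects = covariate_effects,
    items_per_scale = items, target_alpha = target_alpha,
    response_range = ranges, likert_levels = likert_levels, n = n, seed = seed
  )
}

# covariate centering constants of the generating model (fixed, not
# data-dependent, so effects are reproducible across sample sizes)
covariate_centers <- c(gender = 0.5, age = 12.5, education = 2.28, income = 2.16)

#' Simulate a two-wave panel dataset
#'
#' Draws latent standardized scale scores from the spec's contemporaneous
#' and cross-lagged model, applies covariate effects, and generates
#' item-level responses calibrated to the per-scale reliability targets
#' (see the package vignette for the measurement model). Deterministic given
#' `spec$seed`.
#'
#' @param spec a `simulation_spec`.
#' @return a `panel_dataset` with item columns (and covariates); score the
#'   scales with [score_scales()]. The latent score matrices are attached in
#'   attribute `"latent"` for recovery diagnostics.
#' @export
simulate_panel <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  p <- length(spec$nodes)
  n <- spec$n
  Theta <- diag(p) - as.matrix(spec$true_partial)
  Sigma1 <- stats::cov2cor(solve(Theta))
  T1 <- matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma1)
  Psi_cor <- if (identical(spec$innovation_structure, "stationary"))
    stats::cov2cor(Sigma1 - t(spec$B) %*% Sigma1 %*% spec$B)
  else diag(p)
  Psi <- diag(spec$innovation_sd) %*% Psi_cor %*% diag(spec$innovation_sd)
  innov <- matrix(stats::rnorm(n * p), n, p) %*% chol(Psi)
  T2 <- T1 %*% spec$B + innov
  colnames(T1) <- colnames(T2) <- spec$nodes

  cov_df <- data.frame(
    gender = stats::rbinom(n, 1, 0.5),
    age = round(stats::runif(n, 8, 17), 1),
    education = sample(1:3, n, replace = TRUE, prob = c(.05, .62, .33)),
    income = sample(1:4, n, replace = TRUE, prob = c(.225, .508, .151, .116))
  )
  cov_add <- matrix(0, n, p, dimnames = list(NULL, spec$nodes))
  for (cv in names(spec$covariate_effects)) {
    eff <- spec$covariate_effects[[cv]]
    centered <- cov_df[[cv]] - covariate_centers[[cv]]
    for (nm in names(eff))
      cov_add[, nm] <- cov_add[, nm] + eff[[nm]] * centered
  }

  df <- data.frame(participant_id = seq_len(n))
  df <- cbind(df, cov_df)
  latent <- list(t1 = matrix(NA_real_, n, p, dimnames = list(NULL, spec$nodes)),
                 t2 = matrix(NA_real_, n, p, dimnames = list(NULL, spec$nodes)))
  scale_defs <- list()
  for (j in seq_len(p)) {
    nm <- spec$nodes[j]
    k <- spec$items_per_scale[[nm]]
    rr <- spec$response_range[[nm]]
    scale_defs[[nm]] <- scale_definition(nm, spec$constructs[[nm]],
                                         paste0(nm, "_i", seq_len(k)), rr)
    alpha <- spec$target_alpha[[nm]]
    for (w in 1:2) {
      f <- (if (w == 1) T1[, j] else T2[, j]) + cov_add[, j]
      f <- f / stats::sd(f)  # unit variance so reliability calibration is exact
      latent[[w]][, j] <- f
      items <- make_items(f, k, alpha)
      items <- render_items(items, nm, rr, spec)
      colnames(items) <- paste0(nm, "_i", seq_len(k), c("_t1", "_t2")[w])
      df <- cbind(df, items)
    }
  }
  pd <- new_panel_dataset(df, scale_defs, c("_t1", "_t2"),
                          c("gender", "age", "education", "income"))
  attr(pd, "latent") <- latent
  attr(pd, "spec") <- spec
  pd
}

# noisy indicators whose unique noise sums to zero across the scale's items:
# the scale mean equals the latent score and realized alpha equals the
# target in expectation (unique variance (1 - alpha)(k - 1) per item)
make_items <- function(f, k, alpha) {
  n <- length(f)
  if (k == 1) return(matrix(f, n, 1))
  U <- matrix(stats::rnorm(n * k, sd = sqrt((1 - alpha) * k)), n, k)
  U <- U - rowMeans(U)
  matrix(f, n, k) + U
}

# map continuous items onto the response scale (or leave continuous)
render_items <- function(items, nm, rr, spec) {
  ll <- spec$likert_levels
  if (identical(ll, "continuous")) return(items)
  L <- if (identical(ll, "auto")) as.integer(rr[2] - rr[1] + 1) else as.integer(ll)
  probs <- spec$likert_probs[[nm]] %||% seq_len(L - 1) / L
  z <- scale(items)  # thresholds on each item's own standardized scale
  cuts <- stats::qnorm(probs)
  coded <- matrix(findInterval(z, cuts), nrow(items), ncol(items))
  coded + rr[1]
}

#' Write a simulated panel to CSV
#'
#' The same wide dialect [read_panel()] ingests (round-trip safe).
#'
#' @param pd a `panel_dataset`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_panel <- function(pd, path) {
  utils::write.csv(pd$data, path, row.names = FALSE)
  invisible(path)
}

#' True centralities implied by a simulation spec
#'
#' Expected influence from the true partial-correlation matrix, and in-/
#' out-prediction (both variants) from the true transition matrix, under the
#' same exclusion rules as the estimation-side centrality functions.
#'
#' @param spec a `simulation_spec`.
#' @return named list of centrality tables: `ei`, `in_cross_lagged`,
#'   `in_cross_construct`, `out_cross_lagged`, `out_cross_construct`.
#' @export
true_centralities <- function(spec) {
  cn <- new_contemporaneous_network(
    as.matrix(spec$true_partial), spec$nodes, spec$constructs,
    lambda_selected = 0, ebic_gamma = NA_real_, n_used = 0L)
  tn <- new_temporal_network(as.matrix(spec$B), spec$nodes, spec$constructs,
                             lambda_per_node = rep(0, length(spec$nodes)),
                             cv_seed = NA_integer_)
  list(
    ei = expected_influence(cn),
    in_cross_lagged = in_prediction(tn, "cross_lagged"),
    in_cross_construct = in_prediction(tn, "cross_construct"),
    out_cross_lagged = out_prediction(tn, "cross_lagged"),
    out_cross_construct = out_prediction(tn, "cross_construct")
  )
}

#' Serialize a simulation spec to YAML
#'
#' @param spec a `simulation_spec`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spec <- function(spec, path) {
  x <- unclass(spec)
  x$true_partial <- apply(as.matrix(x$true_partial), 1, as.numeric,
                          simplify = FALSE)
  x$B <- apply(as.matrix(x$B), 1, as.numeric, simplify = FALSE)
  x$constructs <- as.list(x$constructs)
  x$items_per_scale <- as.list(x$items_per_scale)
  x$target_alpha <- as.list(x$target_alpha)
  x$innovation_sd <- as.numeric(x$innovation_sd)
  x$covariate_effects <- lapply(x$covariate_effects, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation spec from YAML
#'
#' @param path YAML file written by [write_spec()].
#' @return a validated `simulation_spec`.
#' @export
read_spec <- function(path) {
  x <- yaml::read_yaml(path)
  nodes <- unlist(x$nodes)
  p <- length(nodes)
  mk_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, unlist))
    dimnames(m) <- list(nodes, nodes)
    m
  }
  simulation_spec(
    nodes = nodes, constructs = unlist(x$constructs),
    true_partial = mk_mat(x$true_partial), B = mk_mat(x$B),
    innovation_sd = unlist(x$innovation_sd),
    covariate_effects = lapply(x$covariate_effects, unlist),
    items_per_scale = unlist(x$items_per_scale),
    target_alpha = unlist(x$target_alpha),
    response_range = lapply(x$response_range, unlist),
    likert_levels = if (is.character(x$likert_levels)) x$likert_levels
                    else as.integer(x$likert_levels),
    likert_probs = if (length(x$likert_probs) > 0) lapply(x$likert_probs, unlist),
    innovation_structure = x$innovation_structure %||% "stationary",
    n = x$n, seed = x$seed
  )
}
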