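# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial statistics packages (and the reporting convention this package
#' follows) round ties away from zero, unlike base R's banker's rounding:
#' 0.445 rounds to 0.45, -0.445 to -0.45.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# Condition constructors: every user-facing failure carries a class so
# callers (and tests) can distinguish configuration, data, estimation and
# convergence problems.
pn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "panelnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pn_config_error      <- function(msg, ...) pn_stop("panelnet_config_error", msg, ...)
pn_data_error        <- function(msg, ...) pn_stop("panelnet_data_error", msg, ...)
pn_estimation_error  <- function(msg, ...) pn_stop("panelnet_estimation_error", msg, ...)
pn_convergence_error <- function(msg, ...) pn_stop("panelnet_convergence_error", msg, ...)

#' Derive a reproducible child seed from a master seed
#'
#' Bootstrap replicates, cross-validation folds per node, and simulation
#' stages each consume their own RNG stream derived deterministically from a
#' single master seed, so serial and parallel execution (and re-runs) agree
#' bit for bit. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index = 0L) {
  m <- 2147483647
  s <- (as.double(master) %% m) + 1
  # two rounds of a Lehmer-style multiplicative step keep streams apart
  s <- (s * 48271) %% m
  s <- ((s + as.double(index) * 7919 + 1) * 16807) %% m
  as.integer(floor(s) %% (m - 1) + 1)
}

# stable small integer from a label, for label-keyed seed streams
label_seed_index <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100000L
}

# log-spaced descending grid, lambda_max down to ratio * lambda_max
lambda_grid <- function(lambda_max, nlambda = 100L, ratio = 0.01) {
  if (lambda_max <= 0) lambda_max <- 1e-4
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = nlambda))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
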