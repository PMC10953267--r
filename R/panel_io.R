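# Panel ingestion, scale scoring, descriptives, reliability screening and
# covariate residualization.

new_panel_dataset <- function(data, scale_defs, wave_suffix, covariates,
                              n_warnings = 0L) {
  structure(
    list(data = data, scale_defs = scale_defs, wave_suffix = wave_suffix,
         covariates = covariates, n_warnings = as.integer(n_warnings)),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Two-wave panel dataset\n")
  cat("  participants:", nrow(x$data), "\n")
  cat("  scales:      ", paste(names(x$scale_defs), collapse = ", "), "\n")
  cat("  covariates:  ", paste(intersect(x$covariates, names(x$data)),
                               collapse = ", "), "\n")
  scored <- any(grepl(paste0(x$wave_suffix[1], "$"),
                      setdiff(names(x$data), item_columns(x))))
  cat("  scores:      ", if (scored) "populated" else "not yet scored", "\n")
  if (x$n_warnings > 0) cat("  parse/range warnings:", x$n_warnings, "\n")
  invisible(x)
}

item_columns <- function(pd, scales = names(pd$scale_defs)) {
  unlist(lapply(pd$scale_defs[scales], function(d)
    as.vector(outer(d$item_ids, pd$wave_suffix, paste0))), use.names = FALSE)
}

score_column <- function(scale, wave, wave_suffix = c("_t1", "_t2")) {
  paste0(scale, wave_suffix[match(wave, c("t1", "t2"))])
}

#' Read wide-format two-wave panel data
#'
#' Reads a delimited text file with one row per mother-adolescent dyad and
#' item columns for both waves (wave encoded by column suffix, by default
#' `_t1` / `_t2`). Unparseable or out-of-range item responses are set to
#' missing and counted; the total is reported once as a warning and stored on
#' the returned object.
#'
#' @param path CSV/TSV file with a header row.
#' @param scale_defs named list of [scale_definition()]s (default:
#'   [study_scales()]).
#' @param wave_suffix length-2 character vector of column suffixes for T1/T2.
#' @param covariates covariate column names to carry along if present.
#' @param id_col participant identifier column.
#' @param sep field separator (`""` = auto: tab if the file is .tsv).
#' @return a `panel_dataset`.
#' @export
read_panel <- function(path, scale_defs = study_scales(),
                       wave_suffix = c("_t1", "_t2"),
                       covariates = c("gender", "age", "education", "income"),
                       id_col = "participant_id", sep = "") {
  if (!file.exists(path)) pn_config_error("input file not found: %s", path)
  if (identical(sep, ""))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)

  needed <- unlist(lapply(scale_defs, function(d)
    as.vector(outer(d$item_ids, wave_suffix, paste0))), use.names = FALSE)
  missing_cols <- setdiff(c(id_col, needed), names(df))
  if (length(missing_cols) > 0)
    pn_config_error("missing mandatory column(s): %s",
                    paste(utils::head(missing_cols, 8), collapse = ", "))

  dup <- df[[id_col]][duplicated(df[[id_col]])]
  if (length(dup) > 0)
    pn_data_error("duplicate (participant, wave) records for participant id(s): %s",
                  paste(unique(dup), collapse = ", "))

  n_warn <- 0L
  for (d in scale_defs) {
    lo <- d$response_range[1]; hi <- d$response_range[2]
    for (col in as.vector(outer(d$item_ids, wave_suffix, paste0))) {
      v <- df[[col]]
      was_na <- is.na(v)
      v <- suppressWarnings(as.numeric(v))
      bad <- (!is.na(v) & (v < lo | v > hi)) | (is.na(v) & !was_na)
      v[!is.na(v) & (v < lo | v > hi)] <- NA
      n_warn <- n_warn + sum(bad)
      df[[col]] <- v
    }
  }
  if (n_warn > 0)
    warning(sprintf("%d item response(s) unparseable or out of range; set to missing",
                    n_warn), call. = FALSE)
  names(df)[names(df) == id_col] <- "participant_id"
  new_panel_dataset(df, scale_defs, wave_suffix, covariates, n_warn)
}

#' Score scales from item responses
#'
#' Scale scores are the mean of keyed item responses: reverse-keyed items are
#' recoded as `lo + hi - x` first, keeping the Likert metric comparable
#' across scales with different item counts. A score is computed when at
#' least `min_prop` of the scale's items are answered, otherwise missing.
#'
#' @param pd a `panel_dataset`.
#' @param scale_defs scales to score (default: all on the dataset).
#' @param min_prop minimum proportion of answered items (default 0.75).
#' @return the `panel_dataset` with score columns `<scale><wave_suffix>` added.
#' @export
score_scales <- function(pd, scale_defs = pd$scale_defs, min_prop = 0.75) {
  df <- pd$data
  for (d in scale_defs) {
    for (w in pd$wave_suffix) {
      cols <- paste0(d$item_ids, w)
      absent <- setdiff(cols, names(df))
      if (length(absent) > 0)
        pn_config_error("scale '%s': item column(s) absent: %s", d$name,
                        paste(utils::head(absent, 5), collapse = ", "))
      m <- as.matrix(df[cols])
      if (length(d$reverse_keyed) > 0) {
        ridx <- match(paste0(d$reverse_keyed, w), cols)
        m[, ridx] <- sum(d$response_range) - m[, ridx]
      }
      answered <- rowSums(!is.na(m))
      score <- rowMeans(m, na.rm = TRUE)
      score[answered < min_prop * length(cols) | answered == 0] <- NA_real_
      df[[paste0(d$name, w)]] <- score
    }
  }
  pd$data <- df
  pd
}

# reverse-key an item matrix for one scale (used by tests of the involution
# property and by alpha computation, which must see keyed items)
reverse_key <- function(m, scale_def, which_items = scale_def$reverse_keyed) {
  idx <- match(which_items, scale_def$item_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) > 0) m[, idx] <- sum(scale_def$response_range) - m[, idx]
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(var_i)/var_total)`, with sample variances
#' (denominator n-1) over listwise-complete rows.
#'
#' @param item_matrix numeric matrix, rows = respondents, columns = keyed items.
#' @return alpha, a real number `<= 1`.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m); n <- nrow(m)
  if (k < 2) pn_config_error("cronbach_alpha needs at least 2 items, got %d", k)
  if (n < 3) pn_data_error("cronbach_alpha needs at least 3 complete rows, got %d", n)
  vt <- stats::var(rowSums(m))
  if (vt <= 0)
    pn_estimation_error("undefined reliability: total score has zero variance")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Descriptive statistics per scale and wave
#'
#' Mean, standard deviation, skewness, excess kurtosis, and Cronbach's alpha
#' for every scored scale at each wave. Skewness and kurtosis use the
#' bias-adjusted conventions of common commercial statistics software
#' (`e1071` type 2). Cells with fewer than 3 non-missing values, and
#' skewness/kurtosis of constant columns, are reported missing.
#'
#' @param pd a scored `panel_dataset`.
#' @return data frame with columns scale, wave, n, mean, sd, skewness,
#'   kurtosis, alpha.
#' @export
descriptives <- function(pd) {
  out <- list()
  for (d in pd$scale_defs) {
    for (wi in 1:2) {
      w <- pd$wave_suffix[wi]
      col <- paste0(d$name, w)
      if (!col %in% names(pd$data))
        pn_config_error("scale '%s' not scored; run score_scales() first", d$name)
      x <- pd$data[[col]]
      x <- x[!is.na(x)]
      row <- list(scale = d$name, wave = c("t1", "t2")[wi], n = length(x))
      if (length(x) < 3) {
        row[c("mean", "sd", "skewness", "kurtosis")] <- NA_real_
      } else {
        row$mean <- mean(x)
        row$sd <- stats::sd(x)
        if (row$sd > 0) {
          row$skewness <- e1071::skewness(x, type = 2)
          row$kurtosis <- e1071::kurtosis(x, type = 2)
        } else {
          row$skewness <- NA_real_
          row$kurtosis <- NA_real_
        }
      }
      items <- reverse_key(as.matrix(pd$data[paste0(d$item_ids, w)]), d)
      row$alpha <- tryCatch(cronbach_alpha(items), error = function(e) NA_real_)
      out[[length(out) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, out)
}

#' Reliability screen: drop scales unreliable at both waves
#'
#' A scale is excluded only when its Cronbach's alpha is strictly below the
#' threshold at *both* waves; a scale scraping under at one wave but adequate
#' at the other is retained.
#'
#' @param descr output of [descriptives()] (needs scale, wave, alpha columns).
#' @param threshold reliability threshold (default 0.60).
#' @return character vector of retained scale names, with the dropped names
#'   in attribute `"dropped"`.
#' @export
drop_unreliable <- function(descr, threshold = 0.60) {
  scales <- unique(descr$scale)
  a1 <- descr$alpha[match(paste0(scales, ".t1"), paste0(descr$scale, ".", descr$wave))]
  a2 <- descr$alpha[match(paste0(scales, ".t2"), paste0(descr$scale, ".", descr$wave))]
  if (anyNA(a1) || anyNA(a2))
    pn_config_error("alpha unavailable at both waves for: %s",
                    paste(scales[is.na(a1) | is.na(a2)], collapse = ", "))
  dropped <- scales[a1 < threshold & a2 < threshold]
  retained <- setdiff(scales, dropped)
  attr(retained, "dropped") <- dropped
  retained
}

#' Cohort attrition summary
#'
#' @param n_t1 dyads assessed at wave 1.
#' @param n_t2 dyads retained at wave 2.
#' @return list with counts and `attrition_pct`, the percentage lost,
#'   rounded to one decimal.
#' @examples
#' cohort_summary(642, 591)$attrition_pct # 7.9
#' @export
cohort_summary <- function(n_t1, n_t2) {
  if (n_t1 <= 0 || n_t2 <= 0) pn_data_error("cohort counts must be positive")
  if (n_t2 > n_t1)
    pn_data_error("n_t2 (%d) exceeds n_t1 (%d)", n_t2, n_t1)
  list(n_t1 = n_t1, n_t2 = n_t2, n_lost = n_t1 - n_t2,
       attrition_pct = round_half_out(100 * (n_t1 - n_t2) / n_t1, 1))
}

# encode a covariate data frame into numeric design columns:
# characters/factors -> 0/1 indicators (first level reference), logicals ->
# 0/1, numerics (incl. ordinal integer codes) passed through
encode_covariates <- function(covariates) {
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      lev <- levels(f)
      for (l in lev[-1]) cols[[paste0(nm, "_", l)]] <- as.numeric(f == l)
      if (length(lev) == 1) cols[[nm]] <- rep(0, length(v)) # constant, dropped later
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  as.matrix(as.data.frame(cols, check.names = FALSE))
}

#' Residualize scale scores on covariates
#'
#' Regresses each score column on an intercept plus the encoded covariates by
#' ordinary least squares and returns the residuals, so downstream networks
#' reflect covariate-adjusted associations. Rows with any missing score or
#' covariate are removed first (listwise deletion). Constant or collinear
#' covariate columns are dropped with a warning rather than failing.
#'
#' @param scores numeric matrix or data frame of scale scores (both waves).
#' @param covariates data frame of covariates aligned with `scores` rows.
#' @return residual matrix (class `residual_matrix`) with attributes
#'   `rows_kept` (row indices into the input), `covariates` (the encoded,
#'   retained design columns) and `dropped_covariates`.
#' @export
residualize <- function(scores, covariates) {
  S <- as.matrix(scores)
  Z <- encode_covariates(as.data.frame(covariates))
  keep <- stats::complete.cases(S) & stats::complete.cases(Z)
  S <- S[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  if (nrow(S) < ncol(Z) + 2)
    pn_data_error("too few complete rows (%d) for %d covariate column(s)",
                  nrow(S), ncol(Z))

  # drop constant columns, then collinear ones via pivoted QR
  const <- apply(Z, 2, function(x) stats::sd(x) == 0)
  dropped <- colnames(Z)[const]
  Z <- Z[, !const, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    dropped <- c(dropped, aliased)
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    qx <- qr(X)
  }
  if (length(dropped) > 0)
    warning(sprintf("dropped degenerate covariate column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  res <- qr.resid(qx, S)
  dimnames(res) <- dimnames(S)
  structure(res, class = c("residual_matrix", "matrix", "array"),
            rows_kept = which(keep),
            covariates = X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE],
            dropped_covariates = dropped)
}

#' Split a wave-suffixed matrix into per-wave matrices
#'
#' Separates the `_t1`/`_t2` columns of a residual (or score) matrix into a
#' list of two matrices with plain scale names, the form the temporal
#' network estimator consumes.
#'
#' @param res matrix with wave-suffixed column names, e.g. from
#'   [residualize()].
#' @param wave_suffix the two column suffixes.
#' @return named list of matrices `t1` and `t2`.
#' @export
split_waves <- function(res, wave_suffix = c("_t1", "_t2")) {
  out <- lapply(wave_suffix, function(w) {
    cols <- grep(paste0(w, "$"), colnames(res), value = TRUE)
    m <- res[, cols, drop = FALSE]
    colnames(m) <- sub(paste0(w, "$"), "", cols)
    m
  })
  names(out) <- c("t1", "t2")
  out
}
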