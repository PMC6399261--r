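#' Willmott's index of agreement
#'
#' `d = 1 - sum((P - O)^2) / sum((|P - Obar| + |O - Obar|)^2)` with `Obar`
#' the mean of the reference vector. One indicates perfect agreement, zero
#' complete disagreement. The index is not symmetric in its arguments: the
#' denominator is centred on the reference `obs`. If both vectors are
#' constant and identical (zero denominator) the index is 1 by convention.
#' Pairs with `NA` in either vector are removed.
#'
#' @param pred,obs numeric vectors of equal length (at least 2 valid pairs).
#' @return Scalar in \[0, 1\].
#' @examples
#' ioa(c(1, 2, 3), c(2, 2, 2)) # 0
#' ioa(c(1, 2, 3), c(1, 2, 4)) # 12/13
#' @export
ioa <- function(pred, obs) {
  v <- valid_pairs(pred, obs)
  num <- sum((v$pred - v$obs)^2)
  obar <- mean(v$obs)
  den <- sum((abs(v$pred - obar) + abs(v$obs - obar))^2)
  if (den == 0) return(1) # both vectors constant and equal
  1 - num / den
}

valid_pairs <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  keep <- !is.na(pred) & !is.na(obs)
  if (sum(keep) < 2)
    stop("fewer than 2 valid pairs after masking")
  list(pred = pred[keep], obs = obs[keep])
}

#' Pearson correlation of paired fields
#'
#' Standard Pearson r via [stats::cor] after pairwise masking. If either
#' vector has zero variance the result is `NA` with a `reason` attribute
#' rather than a propagated `NaN`.
#' @inheritParams ioa
#' @return Scalar in \[-1, 1\], or `NA` with attribute `reason`.
#' @export
pearson_r <- function(pred, obs) {
  v <- valid_pairs(pred, obs)
  if (stats::sd(v$pred) == 0 || stats::sd(v$obs) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  stats::cor(v$pred, v$obs)
}

#' Root mean square error of paired fields
#' @inheritParams ioa
#' @return Non-negative scalar in the fields' units.
#' @export
rmse <- function(pred, obs) {
  v <- valid_pairs(pred, obs)
  sqrt(mean((v$pred - v$obs)^2))
}

eval_metrics <- function(pred, obs) {
  c(ioa = ioa(pred, obs), r = as.numeric(pearson_r(pred, obs)),
    rmse = rmse(pred, obs))
}

#' Agreement metrics per land-cover class and globally
#'
#' Computes IoA, Pearson r and RMSE over the cells valid in both fields
#' (and in an optional extra shared mask), globally and within each
#' land-cover class. Cells are weighted equally within a class; an
#' area-weighted variant (weights proportional to cell area, applied to
#' all three metrics) is available behind `area_weighted`.
#'
#' @param pred,obs per-cell numeric vectors.
#' @param domain a [grid_domain].
#' @param pair descriptor of the comparison (e.g. `"model-vs-dataA"`).
#' @param shared_mask optional logical vector of cells admitted to the
#'   comparison (the area shared between all datasets under study).
#' @param area_weighted logical; weight cells by area.
#' @return data.frame with one row per scope (`global` first, then each
#'   class): `scope`, `pair`, `n`, `ioa`, `r`, `rmse`, `flag` (`"empty"`
#'   for classes with fewer than 2 valid cells, metrics NA).
#' @export
evaluate_by_class <- function(pred, obs, domain, pair = "pred-vs-obs",
                              shared_mask = NULL, area_weighted = FALSE) {
  stopifnot(inherits(domain, "grid_domain"))
  n <- nrow(domain$cells)
  stopifnot(length(pred) == n, length(obs) == n)
  keep <- !is.na(pred) & !is.na(obs)
  if (!is.null(shared_mask)) keep <- keep & shared_mask
  cls <- domain$cells$land_cover_class
  w <- if (area_weighted) domain$cells$area else rep(1, n)
  one <- function(scope, sel) {
    sel <- sel & keep
    if (sum(sel) < 2)
      return(data.frame(scope = scope, pair = pair, n = sum(sel),
                        ioa = NA_real_, r = NA_real_, rmse = NA_real_,
                        flag = "empty", stringsAsFactors = FALSE))
    m <- weighted_metrics(pred[sel], obs[sel], w[sel])
    data.frame(scope = scope, pair = pair, n = sum(sel), ioa = m["ioa"],
               r = m["r"], rmse = m["rmse"], flag = "",
               stringsAsFactors = FALSE, row.names = NULL)
  }
  scopes <- sort(unique(cls))
  nm <- if (!is.null(domain$class_names)) domain$class_names[scopes] else
    paste0("class_", scopes)
  out <- rbind(one("global", rep(TRUE, n)),
               do.call(rbind, lapply(seq_along(scopes), function(i)
                 one(nm[i], cls == scopes[i]))))
  rownames(out) <- NULL
  out
}

# weighted generalisations of the three metrics (weights all 1 reduce to
# the plain definitions)
weighted_metrics <- function(pred, obs, w) {
  w <- w / sum(w)
  obar <- sum(w * obs)
  den <- sum(w * (abs(pred - obar) + abs(obs - obar))^2)
  num <- sum(w * (pred - obs)^2)
  d <- if (den == 0) 1 else 1 - num / den
  pbar <- sum(w * pred)
  sp <- sqrt(sum(w * (pred - pbar)^2)); so <- sqrt(sum(w * (obs - obar)^2))
  r <- if (sp == 0 || so == 0) NA_real_ else
    sum(w * (pred - pbar) * (obs - obar)) / (sp * so)
  c(ioa = d, r = r, rmse = sqrt(num))
}

#' Classify model-data agreement against baseline knowledge
#'
#' Baseline knowledge is the agreement between two independent reference
#' datasets describing the same variable. Comparing a model's IoA against
#' it distinguishes three situations: (1) the model is below the baseline —
#' there is room for improvement towards current data agreement; (2)
#' comparable — the model captures what independent data support; (3) above
#' the baseline — higher agreement than the data support, to be interpreted
#' with caution. Because IoA is direction-dependent, the baseline used for
#' the rule is the mean of both directions; both are stored.
#'
#' @param model_ioa model-vs-reference IoA (scalar).
#' @param baseline_ioa baseline IoA: either a scalar or the two directed
#'   values `c(ioa(A, B), ioa(B, A))`, averaged for the rule.
#' @param tolerance half-width of the "comparable" band (IoA units,
#'   default 0.02).
#' @return A `baseline_comparison`: list with `situation` (1, 2 or 3),
#'   `model_ioa`, `baseline_ioa` (mean), `baseline_directions`, `tolerance`.
#' @export
classify_vs_baseline <- function(model_ioa, baseline_ioa, tolerance = 0.02) {
  stopifnot(is.finite(model_ioa), all(is.finite(baseline_ioa)),
            tolerance >= 0)
  base <- mean(baseline_ioa)
  situation <- if (model_ioa < base - tolerance) 1L
  else if (model_ioa > base + tolerance) 3L
  else 2L
  structure(list(situation = situation, model_ioa = model_ioa,
                 baseline_ioa = base,
                 baseline_directions = baseline_ioa, tolerance = tolerance),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  lab <- c("below baseline (room for improvement)",
           "comparable to baseline",
           "above baseline (interpret with caution)")
  cat("<baseline_comparison> situation ", x$situation, ": ",
      lab[x$situation], "\n  model IoA ", round(x$model_ioa, 4),
      " vs baseline ", round(x$baseline_ioa, 4), " (tol ", x$tolerance,
      ")\n", sep = "")
  invisible(x)
}

#' Symmetric baseline agreement between two reference datasets
#'
#' Returns the two directed IoA values and their mean, plus r and RMSE
#' (which are symmetric), over the shared valid cells.
#' @param a,b per-cell vectors of the two reference datasets.
#' @return list with `ioa_directions`, `ioa` (mean), `r`, `rmse`, `n`.
#' @export
baseline_agreement <- function(a, b) {
  v <- valid_pairs(a, b)
  d <- c(ioa(v$pred, v$obs), ioa(v$obs, v$pred))
  list(ioa_directions = d, ioa = mean(d),
       r = as.numeric(pearson_r(v$pred, v$obs)), rmse = rmse(v$pred, v$obs),
       n = length(v$pred))
}
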