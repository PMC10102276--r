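#' Annual intensity prediction
#'
#' Builds the predicted expected-count surface for one year:
#' `lambda_hat(cell) = exp(X beta_hat + u_hat) * cell_area`, with the
#' ecological design standardized by the training constants and the field
#' mode either year-specific or averaged across fitted years (required for
#' years beyond the fitted range, e.g. out-of-sample evaluation years).
#'
#' @param object A `fit_result`.
#' @param layers Layer registry (must contain the requested year for
#'   dynamic layers).
#' @param year Prediction year.
#' @param field_mode `"year_specific"` or `"averaged"`.
#' @param ... Unused.
#' @return Object of class `prediction_surface`: `year`, `lambda`
#'   (`raster_layer` of expected points per cell), `field_mode`, and —
#'   after [select_threshold()] — `tau` and `suitability`.
#' @export
predict.fit_result <- function(object, layers, year,
                               field_mode = c("year_specific", "averaged"),
                               ...) {
  field_mode <- match.arg(field_mode)
  idata <- object$idata
  spec <- idata$spec
  grid <- spec$grid
  fitted_years <- idata$grid_c$years
  if (!year %in% fitted_years && field_mode == "year_specific")
    stop("predict: year ", year,
         " is outside the fitted range; use field_mode = 'averaged'")
  X <- assemble_design(layers, spec$specs_eco, year, grid = grid)
  X <- apply_standardize(X, idata$std_eco$center, idata$std_eco$scale)
  beta <- object$coef$q50[object$coef$group == "beta"]
  eta <- beta[1] + drop(X %*% beta[-1])
  u_c <- if (field_mode == "averaged" || !year %in% fitted_years) {
    Reduce(`+`, lapply(object$field, function(r) r$values)) /
      length(object$field)
  } else object$field[[paste0("y", year)]]$values
  u_r <- raster_layer(idata$grid_c, u_c)
  cc <- cell_centers_xy(grid)
  u_fine <- raster_at_points(u_r, cc[, 1], cc[, 2])
  lam <- exp(eta + u_fine) * cell_area(grid)
  structure(list(year = year,
                 lambda = raster_layer(grid, matrix(lam, grid$ny, grid$nx,
                                                    byrow = TRUE)),
                 field_mode = field_mode, tau = NULL, suitability = NULL),
            class = "prediction_surface")
}

#' Symmetric Extremal Dependence Index
#'
#' Skill score on the hit rate `H` and false-alarm rate `F`:
#' `[ln F - ln H - ln(1-F) + ln(1-H)] / [ln F + ln H + ln(1-F) + ln(1-H)]`.
#' Zero when `H = F`; tends to 1 for perfect discrimination; robust for
#' rare events. Rates are clamped to `[eps, 1-eps]` so that perfect
#' classification stays finite.
#'
#' @param H Hit rate (sensitivity), in `[0, 1]` (vectorized).
#' @param F_ False alarm rate (1 - specificity).
#' @param eps Clamping constant (default 1e-6).
#' @return SEDI value(s) in `[-1, 1]`.
#' @export
sedi <- function(H, F_, eps = 1e-6) {
  H <- pmin(pmax(H, eps), 1 - eps)
  F_ <- pmin(pmax(F_, eps), 1 - eps)
  (log(F_) - log(H) - log(1 - F_) + log(1 - H)) /
    (log(F_) + log(H) + log(1 - F_) + log(1 - H))
}

#' SEDI-optimal suitability threshold
#'
#' Evaluates SEDI over candidate thresholds (midpoints of adjacent sorted
#' unique scores) given intensity scores at presence and background
#' locations, and returns the maximizing threshold; ties break toward the
#' larger (more conservative) threshold. Sensitivity is `H` and
#' specificity `1 - F` at the winner, with classification `score > tau`.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return List: `tau`, `sensitivity`, `specificity`, `sedi`.
#' @export
select_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("select_threshold: need at least one presence and one background score")
  s <- sort(unique(c(presence_scores, background_scores)))
  if (length(s) < 2)
    stop("select_threshold: all scores identical; no discrimination possible")
  cand <- (s[-1] + s[-length(s)]) / 2
  H <- vapply(cand, function(t) mean(presence_scores > t), 0)
  F_ <- vapply(cand, function(t) mean(background_scores > t), 0)
  sc <- sedi(H, F_)
  best <- max(which(sc >= max(sc) - 1e-12))   # ties -> larger threshold
  list(tau = cand[best], sensitivity = H[best], specificity = 1 - F_[best],
       sedi = sc[best])
}

#' @rdname select_threshold
#' @param surface A `prediction_surface`.
#' @param tau Threshold on the cell score.
#' @export
apply_threshold <- function(surface, tau) {
  surface$tau <- tau
  surface$suitability <- raster_layer(
    surface$lambda$grid,
    ifelse(is.na(surface$lambda$values), NA_real_,
           as.numeric(surface$lambda$values > tau)))
  surface
}

#' Relative abundance index
#'
#' Sum of predicted cell values strictly greater than the suitability
#' threshold.
#'
#' @param surface `prediction_surface`.
#' @param tau Threshold.
#' @return Scalar.
#' @export
abundance <- function(surface, tau) {
  v <- surface$lambda$values
  sum(v[!is.na(v) & v > tau])
}

#' Bootstrap confidence intervals for annual abundance
#'
#' Conditional nonparametric bootstrap: presence points are resampled with
#' replacement within stream and year, fixed effects and field modes are
#' refit with hyperparameters held at their fitted values (warm-started
#' Newton), the annual surfaces are re-predicted and abundance recomputed
#' at the fixed threshold, and percentile 2.5/97.5 intervals are taken per
#' year.
#'
#' @param fit A `fit_result` (fitted with a field or `hyper = "none"`).
#' @param layers Layer registry.
#' @param tau Suitability threshold (from [select_threshold()]).
#' @param n_boot Number of bootstrap replicates (default 10000; reduce for
#'   interactive use).
#' @param seed Integer seed.
#' @param field_mode Passed to [predict.fit_result()].
#' @param resampler `"bootstrap"` or `"identity"` (degenerate; every
#'   replicate reuses the original data — for testing).
#' @return data.frame: `year`, `estimate`, `lower`, `upper`, `n_failed`.
#' @export
abundance_ci <- function(fit, layers, tau, n_boot = 10000, seed = 1L,
                         field_mode = "year_specific",
                         resampler = c("bootstrap", "identity")) {
  resampler <- match.arg(resampler)
  if (n_boot < 100 && resampler == "bootstrap")
    stop("abundance_ci: n_boot must be >= 100")
  idata <- fit$idata
  years <- idata$spec$grid$years
  Q <- boot_precision(fit)
  point_est <- vapply(years, function(yr)
    abundance(predict(fit, layers, yr, field_mode = field_mode), tau), 0)
  pres_idx <- which(idata$rows$presence == 1)
  strata <- interaction(idata$rows$stream[pres_idx], idata$rows$year[pres_idx],
                        drop = TRUE)
  theta0 <- c(fit$coef$q50, rep(0, 0))
  boot <- with_seed(seed, {
    res <- matrix(NA_real_, n_boot, length(years))
    failed <- 0L
    for (b in seq_len(n_boot)) {
      take <- if (resampler == "identity") pres_idx else
        unlist(lapply(split(pres_idx, strata), function(ix)
          ix[sample.int(length(ix), length(ix), replace = TRUE)]),
          use.names = FALSE)
      id2 <- subset_idata(idata, take)
      ab <- tryCatch({
        nw <- inner_newton(id2, Q, idata$spec$prior_prec, max_iter = 50)
        f2 <- build_fit_result(id2, nw, fit$hyper, NA_real_, FALSE,
                               isTRUE(fit$diagnostics$no_field))
        vapply(years, function(yr)
          abundance(predict(f2, layers, yr, field_mode = field_mode), tau), 0)
      }, error = function(e) NULL)
      if (is.null(ab)) failed <- failed + 1L else res[b, ] <- ab
    }
    if (failed > 0.05 * n_boot)
      stop("abundance_ci: ", failed, " of ", n_boot, " replicate fits failed")
    if (failed > 0)
      message("abundance_ci: dropped ", failed, " failed replicate(s)")
    list(res = res, failed = failed)
  })
  qs <- apply(boot$res, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(year = years, estimate = point_est,
             lower = qs[1, ], upper = qs[2, ], n_failed = boot$failed)
}

# space-time prior precision at the fitted hyperparameters
boot_precision <- function(fit) {
  idata <- fit$idata
  if (isTRUE(fit$diagnostics$no_field) || is.null(fit$hyper)) {
    nu <- idata$grid_c$nx * idata$grid_c$ny * length(idata$grid_c$years)
    return(Matrix::Diagonal(nu, 1e8))
  }
  sp <- spatial_precision(idata$grid_c, fit$hyper$rho, fit$hyper$sigma)
  spacetime_precision(sp, fit$hyper$phi, length(idata$grid_c$years))$Q
}

# replace presence rows of an integrated_data by the given (possibly
# duplicated) row indices, keeping all background rows
subset_idata <- function(idata, presence_take) {
  keep <- c(which(idata$rows$presence == 0), presence_take)
  out <- idata
  out$rows <- idata$rows[keep, , drop = FALSE]
  out$X <- idata$X[keep, , drop = FALSE]
  if (!is.null(idata$Z)) out$Z <- idata$Z[keep, , drop = FALSE]
  out$P <- idata$P[keep, , drop = FALSE]
  out
}

#' Presentation-scale aggregation with min-max normalization
#'
#' Aggregates a surface to blocks of `factor x factor` cells by their mean
#' (edge blocks average over the available cells) and rescales the result
#' to `[0, 1]`. A constant surface has no min-max range; it returns zeros
#' with a warning.
#'
#' @param r `raster_layer` (or `prediction_surface`, whose `lambda` is
#'   used).
#' @param factor Aggregation factor in cells (e.g. 30 -> 900 m is factor
#'   30).
#' @return Aggregated, normalized `raster_layer`.
#' @export
aggregate_normalize <- function(r, factor) {
  if (inherits(r, "prediction_surface")) r <- r$lambda
  g <- r$grid
  factor <- as.integer(factor)
  nxa <- ceiling(g$nx / factor); nya <- ceiling(g$ny / factor)
  out <- matrix(NA_real_, nya, nxa)
  for (bj in seq_len(nya)) for (bi in seq_len(nxa)) {
    rows <- ((bj - 1L) * factor + 1L):min(bj * factor, g$ny)
    cols <- ((bi - 1L) * factor + 1L):min(bi * factor, g$nx)
    v <- r$values[rows, cols]
    out[bj, bi] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  ga <- grid_spec(g$x0, g$y0, g$dx * factor, g$dy * factor, nxa, nya, g$years)
  rng <- range(out, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("aggregate_normalize: constant surface; returning zeros")
    return(raster_layer(ga, ifelse(is.na(out), NA_real_, 0)))
  }
  raster_layer(ga, (out - rng[1]) / (rng[2] - rng[1]))
}
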