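#' Quadrature scheme for point process regression
#'
#' Builds the Berman-Turner style scheme that turns the inhomogeneous
#' Poisson point process likelihood into a weighted Poisson regression:
#' background points over the grid extent (uniform random, allocated
#' equally across years, or one per cell-year center) merged with the
#' presence points of the fitted stream, each carrying an areal weight.
#' Per-year weights always sum to the study area `|A|`.
#'
#' @param grid `grid_spec` defining the region and years.
#' @param presences `point_table` of the fitted stream (may be filtered to
#'   one stream beforehand); presences outside `grid$years` are excluded.
#' @param m Total number of background points; default
#'   `max(5000, 20 * n_presence)` for `type = "random"`; ignored for
#'   `type = "grid"` (one point per cell-year).
#' @param seed Integer seed (random background only).
#' @param type `"random"` — uniform background points as in the classical
#'   downweighted Poisson construction; `"grid"` — one deterministic
#'   background point per cell-year center, which makes the intensity
#'   integral exact for intensities that are piecewise constant at the
#'   analysis resolution.
#' @param weighting `"counting"` (default) — Berman-Turner counting
#'   weights: points in grid cell `(c, t)` share that cell's area,
#'   `w = cell_area / n_points_in_cell`; `"uniform"` — every point in year
#'   `t` gets `|A| / n_t`. Both conserve `sum(w) = |A|` per year exactly;
#'   counting weights remove the finite-m attenuation that uniform weights
#'   incur when presences cluster (see the methods vignette).
#' @return data.frame of class `quad_scheme` with columns `x`, `y`, `year`,
#'   `presence` (0/1), `w` (m^2 per point-year), plus attribute `area`.
#' @export
build_quadrature <- function(grid, presences = NULL, m = NULL, seed = NULL,
                             type = c("random", "grid"),
                             weighting = c("counting", "uniform")) {
  type <- match.arg(type)
  weighting <- match.arg(weighting)
  ext <- grid_extent(grid)
  A <- (ext["xmax"] - ext["xmin"]) * (ext["ymax"] - ext["ymin"])
  if (!(A > 0)) stop("build_quadrature: degenerate region (area 0)")
  years <- grid$years
  npres <- if (is.null(presences)) 0L else
    sum(presences$year %in% years)
  if (type == "grid") {
    cc <- cell_centers_xy(grid)
    bg <- do.call(rbind, lapply(years, function(yr)
      data.frame(x = cc[, 1], y = cc[, 2], year = yr, presence = 0)))
  } else {
    if (is.null(m)) m <- max(5000L, 20L * npres)
    m <- as.integer(m)
    if (m < 100L) stop("build_quadrature: need m >= 100 background points")
    per_year <- diff(round(seq(0, m, length.out = length(years) + 1L)))
    bg <- with_seed(seed, {
      do.call(rbind, lapply(seq_along(years), function(t) {
        k <- per_year[t]
        data.frame(x = stats::runif(k, ext["xmin"], ext["xmax"]),
                   y = stats::runif(k, ext["ymin"], ext["ymax"]),
                   year = years[t], presence = 0)
      }))
    })
  }
  if (!is.null(presences) && nrow(presences)) {
    keep <- presences$year %in% years
    pr <- data.frame(x = presences$x[keep], y = presences$y[keep],
                     year = presences$year[keep], presence = 1)
    sch <- rbind(bg, pr)
  } else sch <- bg
  if (weighting == "uniform") {
    cnt <- table(factor(sch$year, levels = years))
    sch$w <- as.numeric(A) / as.numeric(cnt[as.character(sch$year)])
  } else {
    pc <- point_to_cell(grid, sch$x, sch$y)
    tile <- paste(pc$i, pc$j, sch$year)
    ntile <- table(tile)
    sch$w <- cell_area(grid) / as.numeric(ntile[tile])
    # cell-years with no scheme point contribute nothing to the integral;
    # renormalize per year so sum(w) = |A| exactly
    for (yr in years) {
      sel <- sch$year == yr
      sch$w[sel] <- sch$w[sel] * as.numeric(A) / sum(sch$w[sel])
    }
  }
  rownames(sch) <- NULL
  attr(sch, "area") <- as.numeric(A)
  class(sch) <- c("quad_scheme", "data.frame")
  sch
}

# soft-threshold operator
soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Downweighted Poisson point process regression with L1 penalty
#'
#' Maximizes the quadrature-approximated point process log-likelihood
#' `sum_i w_i (y_i eta_i - exp(eta_i)) - penalty * sum_j |beta_j|` with
#' `y_i = presence_i / w_i` and `eta = b0 + X beta`, by iteratively
#' reweighted least squares with an inner coordinate descent (soft
#' thresholding). The intercept is never penalized. With `penalty = 0` this
#' is the unpenalized weighted Poisson GLM approximating the inhomogeneous
#' Poisson process MLE.
#'
#' @param X Design matrix (no intercept column), rows aligned with
#'   `scheme`; typically standardized columns. May be NULL for an
#'   intercept-only fit.
#' @param scheme `quad_scheme` (uses `presence` and `w`).
#' @param penalty L1 penalty on the natural (likelihood) scale; >= 0.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Maximum IRLS sweeps.
#' @param init Optional warm-start coefficient vector (intercept first).
#' @return Object of class `penalized_fit`: `coef` (intercept first),
#'   `penalty`, `loglik` (weighted likelihood term at the optimum),
#'   `converged`, `n_iter`.
#' @export
dwpr_fit <- function(X, scheme, penalty = 0, tol = 1e-8, max_iter = 500,
                     init = NULL) {
  if (penalty < 0) stop("dwpr_fit: penalty must be >= 0")
  w <- scheme$w
  y <- scheme$presence / w
  p <- if (is.null(X)) 0L else ncol(X)
  if (p > 0 && nrow(X) != nrow(scheme))
    stop("dwpr_fit: design rows do not align with scheme rows")
  if (p > 0 && anyNA(X)) stop("dwpr_fit: design contains missing values")
  b0 <- if (!is.null(init)) init[1] else log(sum(scheme$presence) / sum(w) + 1e-12)
  beta <- if (!is.null(init) && p > 0) init[-1] else numeric(p)
  xsq <- if (p > 0) X^2 else NULL
  eta_cap <- 40
  for (it in seq_len(max_iter)) {
    eta <- b0 + if (p > 0) drop(X %*% beta) else 0
    eta <- pmin(eta, eta_cap)
    mu <- exp(eta)
    W <- w * mu                         # IRLS weights
    z <- eta + (y - mu) / mu            # working response
    old <- c(b0, beta)
    # inner coordinate descent on the penalized weighted least squares
    for (cd in seq_len(200)) {
      prev <- c(b0, beta)
      r <- z - (b0 + if (p > 0) drop(X %*% beta) else 0)
      b0 <- b0 + sum(W * r) / sum(W)
      r <- z - (b0 + if (p > 0) drop(X %*% beta) else 0)
      if (p > 0) for (j in seq_len(p)) {
        rj <- r + X[, j] * beta[j]
        num <- sum(W * X[, j] * rj)
        den <- sum(W * xsq[, j])
        bj <- if (den > 0) soft(num, penalty) / den else 0
        r <- rj - X[, j] * bj
        beta[j] <- bj
      }
      if (max(abs(c(b0, beta) - prev)) < tol / 10) break
    }
    if (max(abs(c(b0, beta) - old)) < tol) {
      eta <- pmin(b0 + if (p > 0) drop(X %*% beta) else 0, eta_cap)
      ll <- sum(w * (y * eta - exp(eta)))
      cf <- c(intercept = b0, beta)
      if (p > 0 && !is.null(colnames(X))) names(cf)[-1] <- colnames(X)
      return(structure(list(coef = cf, penalty = penalty, loglik = ll,
                            converged = TRUE, n_iter = it),
                       class = "penalized_fit"))
    }
  }
  stop("dwpr_fit: IRLS failed to converge after ", max_iter,
       " iterations (last max change ",
       format(max(abs(c(b0, beta) - old))), ")")
}

#' @export
#' @method print penalized_fit
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit> penalty=%g loglik=%.4f (%s in %d iter)\n",
              x$penalty, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(x$coef, 4))
  invisible(x)
}

# presence score for CV: probability of >= 1 point in the quadrature tile
presence_score <- function(eta, w) 1 - exp(-exp(pmin(eta, 40)) * w)

# row-level fold assignment; refolds (with a logged message) until every
# fold contains at least one presence and one background row
make_folds <- function(scheme, k, seed = NULL) {
  n <- nrow(scheme)
  if (k < 2) stop("make_folds: need k >= 2")
  for (attempt in 0:24) {
    f <- with_seed(if (is.null(seed)) NULL else seed + 1000L * attempt,
                   sample(rep_len(seq_len(k), n)))
    ok <- all(vapply(seq_len(k), function(kk)
      any(scheme$presence[f == kk] == 1) && any(scheme$presence[f == kk] == 0),
      TRUE))
    if (ok) {
      if (attempt > 0)
        message("make_folds: refolded ", attempt, " time(s) to avoid empty-presence folds")
      return(f)
    }
  }
  stop("make_folds: could not build folds with presences in every fold")
}

cv_metrics_dwpr <- function(X, scheme, penalty, folds_vec, tol = 1e-6) {
  k <- max(folds_vec)
  se <- numeric(0); sc_pres <- numeric(0); sc_bg <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds_vec != f
    fit <- dwpr_fit(if (is.null(X)) NULL else X[tr, , drop = FALSE],
                    scheme[tr, , drop = FALSE], penalty = penalty, tol = tol)
    eta <- fit$coef[1] + if (is.null(X)) 0 else
      drop(X[!tr, , drop = FALSE] %*% fit$coef[-1])
    p_hat <- presence_score(eta, scheme$w[!tr])
    z <- scheme$presence[!tr]
    se <- c(se, (z - p_hat)^2)
    sc_pres <- c(sc_pres, eta[z == 1]); sc_bg <- c(sc_bg, eta[z == 0])
  }
  list(rmse = sqrt(mean(se)), auc = auc(sc_pres, sc_bg))
}

#' Scale selection for one covariate
#'
#' Fits a univariate unpenalized DWPR for each candidate moving-window
#' scale of a covariate and returns the scale with the smallest k-fold CV
#' RMSE, ties broken toward the smaller scale (candidate order
#' `pixel30 < neighbor < r90 < r150 < r300 < r750`).
#'
#' @param layers Layer registry (see [assemble_design()]).
#' @param layer Layer name.
#' @param scales Character vector of candidate scales.
#' @param scheme `quad_scheme` (single- or multi-year; dynamic layers are
#'   sampled per row year).
#' @param stat Summary statistic for the moving window.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return List with `scale` (winner), `rmse` (named per candidate).
#' @export
select_scale <- function(layers, layer, scales, scheme, stat = "mean",
                         folds = 10, seed = NULL) {
  ord <- names(MW_SCALES)
  scales <- scales[order(match(scales, ord))]
  if (length(scales) == 1L)
    return(list(scale = scales, rmse = stats::setNames(NA_real_, scales)))
  fv <- make_folds(scheme, folds, seed)
  rmse <- stats::setNames(numeric(length(scales)), scales)
  errs <- character(0)
  for (sc in scales) {
    col <- sample_scaled_layer(layers, layer, sc, stat, scheme)
    res <- tryCatch({
      st <- standardize(matrix(col, ncol = 1, dimnames = list(NULL, layer)))
      cv_metrics_dwpr(st$x, scheme, penalty = 0, folds_vec = fv)$rmse
    }, error = function(e) { errs <<- c(errs, conditionMessage(e)); NA_real_ })
    rmse[sc] <- res
  }
  if (all(is.na(rmse)))
    stop("select_scale: all candidate fits failed: ", paste(errs, collapse = "; "))
  best <- scales[which.min(rmse)]   # which.min takes the first (smallest scale) tie
  list(scale = best, rmse = rmse)
}

# sample a moving-window summarized layer at scheme rows (per-year dynamic)
sample_scaled_layer <- function(layers, layer, scale, stat, scheme) {
  out <- rep(NA_real_, nrow(scheme))
  for (yr in unique(scheme$year)) {
    r <- moving_window(get_layer(layers, layer, yr), scale, stat)
    sel <- scheme$year == yr
    out[sel] <- raster_at_points(r, scheme$x[sel], scheme$y[sel])
  }
  out
}

#' Cross-validated LASSO path for the DWPR
#'
#' Computes a 50-value penalty grid spanning two decades down from
#' `lambda_max` (the smallest penalty that zeroes every slope), evaluates
#' k-fold CV RMSE (presence indicator vs the per-row presence score
#' `1 - exp(-lambda_hat * w)`) and AUC along the path with warm starts, and
#' returns the full-data fit at the minimum-RMSE penalty (ties broken
#' toward the larger penalty, i.e. the sparser model).
#'
#' @param X Design matrix (standardized internally; constants persisted).
#' @param scheme `quad_scheme`.
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @param n_penalty,decades Path resolution and span.
#' @param rule Penalty selection rule: `"1se"` (default) picks the largest
#'   penalty whose CV RMSE is within one standard error (across folds) of
#'   the minimum — the standard sparsity-favoring cross-validation rule;
#'   `"min"` picks the exact minimizer (ties toward the larger penalty).
#' @param folds_vec Optional externally fixed fold assignment (used to
#'   share folds across candidate models).
#' @return List of class `lasso_cv`: `fit` (`penalized_fit` at the selected
#'   penalty, refit on all rows), `path` (data.frame: penalty, cv_rmse,
#'   cv_auc, n_nonzero), `penalty`, `standardization`, `folds`.
#' @export
lasso_cv <- function(X, scheme, folds = 10, seed = NULL, n_penalty = 50,
                     decades = 2, rule = c("1se", "min"), folds_vec = NULL) {
  rule <- match.arg(rule)
  st <- standardize(X)
  Xs <- st$x
  if (is.null(folds_vec)) folds_vec <- make_folds(scheme, folds, seed)
  w <- scheme$w; y <- scheme$presence / w
  fit0 <- dwpr_fit(NULL, scheme)
  mu0 <- exp(fit0$coef[1])
  lam_max <- max(abs(crossprod(Xs, w * (y - mu0))))
  grid <- exp(seq(log(lam_max), log(lam_max) - decades * log(10),
                  length.out = n_penalty))
  k <- max(folds_vec)
  # per-fold warm-started path fits
  fold_fits <- vector("list", k)
  path <- data.frame(penalty = grid, cv_rmse = NA_real_, cv_se = NA_real_,
                     cv_auc = NA_real_, n_nonzero = NA_integer_)
  full_init <- NULL
  full_fits <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    pen <- grid[g]
    sc_p <- numeric(0); sc_b <- numeric(0); se_all <- numeric(0)
    fold_rmse <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds_vec != f
      ft <- dwpr_fit(Xs[tr, , drop = FALSE], scheme[tr, , drop = FALSE],
                     penalty = pen, tol = 1e-6, init = fold_fits[[f]]$coef)
      fold_fits[[f]] <- ft
      eta <- ft$coef[1] + drop(Xs[!tr, , drop = FALSE] %*% ft$coef[-1])
      p_hat <- presence_score(eta, w[!tr])
      z <- scheme$presence[!tr]
      se_all <- c(se_all, (z - p_hat)^2)
      fold_rmse[f] <- sqrt(mean((z - p_hat)^2))
      sc_p <- c(sc_p, eta[z == 1]); sc_b <- c(sc_b, eta[z == 0])
    }
    path$cv_rmse[g] <- sqrt(mean(se_all))
    path$cv_se[g] <- stats::sd(fold_rmse) / sqrt(k)
    path$cv_auc[g] <- auc(sc_p, sc_b)
    full <- dwpr_fit(Xs, scheme, penalty = pen, tol = 1e-7, init = full_init)
    full_init <- full$coef
    full_fits[[g]] <- full
    path$n_nonzero[g] <- sum(full$coef[-1] != 0)
  }
  best_rmse <- min(path$cv_rmse)
  cut <- if (rule == "1se")
    best_rmse + path$cv_se[which.min(path$cv_rmse)] else best_rmse + 1e-12
  best <- which(path$cv_rmse <= cut)[1]  # grid descends: first = largest penalty
  structure(list(fit = full_fits[[best]], path = path,
                 penalty = grid[best],
                 cv_rmse = path$cv_rmse[best], cv_auc = path$cv_auc[best],
                 standardization = st[c("center", "scale")],
                 folds = folds_vec),
            class = "lasso_cv")
}

#' Compare candidate model forms under shared folds
#'
#' Runs the cross-validated LASSO for each candidate design on identical
#' fold assignments and ranks candidates by CV RMSE (AUC reported).
#'
#' @param candidates Named list of design matrices (rows aligned with
#'   `scheme`).
#' @param scheme `quad_scheme`.
#' @param folds,seed Fold settings (shared across candidates).
#' @return data.frame ranked by `cv_rmse` with attribute `"winner"`.
#' @export
compare_models <- function(candidates, scheme, folds = 10, seed = NULL) {
  if (length(candidates) < 2) stop("compare_models: need >= 2 candidates")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  fv <- make_folds(scheme, folds, seed)
  res <- lapply(candidates, function(X)
    lasso_cv(X, scheme, folds_vec = fv))
  out <- data.frame(model = names(candidates),
                    cv_rmse = vapply(res, `[[`, 0, "cv_rmse"),
                    cv_auc = vapply(res, `[[`, 0, "cv_auc"),
                    penalty = vapply(res, `[[`, 0, "penalty"),
                    n_nonzero = vapply(res, function(r) sum(r$fit$coef[-1] != 0), 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cv_rmse), ]
  rownames(out) <- NULL
  attr(out, "winner") <- out$model[1]
  attr(out, "fits") <- res
  out
}
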