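#' Area under the ROC curve (rank form)
#'
#' Mann-Whitney statistic: the probability that a random presence score
#' exceeds a random background score, with ties counted half.
#'
#' @param presence_scores,background_scores Numeric vectors (non-empty).
#' @return Scalar in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (!n1 || !n0) stop("auc: both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Temporal block folds
#'
#' Assigns each point to the period containing its year; periods must
#' cover every observed year.
#'
#' @param points `point_table`.
#' @param periods List of inclusive year ranges, e.g.
#'   `list(c(2000, 2006), c(2007, 2012), c(2013, 2019))`.
#' @return Object of class `fold_assignment`: `fold` (per point), `k`,
#'   `type = "temporal"`, `periods`.
#' @export
temporal_folds <- function(points, periods) {
  fold <- rep(NA_integer_, nrow(points))
  for (k in seq_along(periods))
    fold[points$year >= periods[[k]][1] & points$year <= periods[[k]][2]] <- k
  if (anyNA(fold))
    stop("temporal_folds: year(s) outside all periods: ",
         paste(unique(points$year[is.na(fold)]), collapse = ", "))
  structure(list(fold = fold, k = length(periods), type = "temporal",
                 periods = periods),
            class = "fold_assignment")
}

#' Spatial block folds
#'
#' Tiles the extent with square blocks and deals blocks to `k` folds
#' systematically: blocks ordered by presence count (seeded tie-break and
#' seeded starting fold) are assigned round-robin, giving every fold an
#' equal share of blocks and a balanced presence load; every point
#' inherits its block's fold, so points never straddle folds within a
#' block.
#'
#' @param points `point_table`.
#' @param grid `grid_spec` supplying the extent.
#' @param block_size Block side length, m.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return `fold_assignment` with `blocks` (data.frame: `bx`, `by`,
#'   `xmin`, `xmax`, `ymin`, `ymax`, `n`, `fold`).
#' @export
spatial_folds <- function(points, grid, block_size, k, seed = NULL) {
  if (!(block_size > 0)) stop("spatial_folds: block_size must be > 0")
  if (k < 2) stop("spatial_folds: need k >= 2")
  ext <- grid_extent(grid)
  bx <- pmin(floor((points$x - ext["xmin"]) / block_size),
             ceiling((ext["xmax"] - ext["xmin"]) / block_size) - 1)
  by <- pmin(floor((ext["ymax"] - points$y) / block_size),
             ceiling((ext["ymax"] - ext["ymin"]) / block_size) - 1)
  key <- paste(bx, by)
  blocks <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  blocks$bx <- as.integer(sub(" .*", "", blocks$key))
  blocks$by <- as.integer(sub(".* ", "", blocks$key))
  blocks$n <- as.integer(table(key)[blocks$key])
  if (nrow(blocks) < k)
    stop("spatial_folds: only ", nrow(blocks),
         " non-empty blocks for k = ", k, " folds")
  blocks <- with_seed(seed, {
    # systematic allocation: blocks ordered by presence count (seeded
    # tie-break), dealt round-robin so folds get equal block counts and
    # roughly balanced presences
    ord <- order(-blocks$n, stats::runif(nrow(blocks)))
    blocks <- blocks[ord, , drop = FALSE]
    start <- sample.int(k, 1L)
    blocks$fold <- ((seq_len(nrow(blocks)) - 1L + start - 1L) %% k) + 1L
    blocks
  })
  blocks$xmin <- ext["xmin"] + blocks$bx * block_size
  blocks$xmax <- blocks$xmin + block_size
  blocks$ymax <- ext["ymax"] - blocks$by * block_size
  blocks$ymin <- blocks$ymax - block_size
  fold <- blocks$fold[match(key, blocks$key)]
  structure(list(fold = fold, k = k, type = "spatial",
                 block_size = block_size,
                 blocks = blocks[, c("bx", "by", "xmin", "xmax", "ymin",
                                     "ymax", "n", "fold")]),
            class = "fold_assignment")
}

#' Random k-fold assignment
#'
#' @param points `point_table`.
#' @param k Folds.
#' @param seed Integer seed.
#' @return `fold_assignment` with `type = "random"`.
#' @export
random_folds <- function(points, k = 10, seed = NULL) {
  fold <- with_seed(seed, sample(rep_len(seq_len(k), nrow(points))))
  structure(list(fold = fold, k = k, type = "random"),
            class = "fold_assignment")
}

#' Variogram-informed block size
#'
#' Fits an exponential semivariogram `gamma(h) = c0 + c1 (1 - exp(-h/a))`
#' by Cressie-weighted least squares to binned empirical semivariances of
#' a subsample of cells of each continuous layer and returns the median
#' effective range `3a` across layers. Constant layers are skipped; so are non-convergent
#' fits.
#'
#' @param layer_list List of `raster_layer` (continuous).
#' @param max_cells Subsample cap per layer (default 5000).
#' @param n_bins Distance bins up to half the domain diameter.
#' @param seed Integer seed for the subsample.
#' @return Suggested block size, m.
#' @export
suggest_block_size <- function(layer_list, max_cells = 5000, n_bins = 15,
                               seed = 1L) {
  ranges <- c()
  for (r in layer_list) {
    v <- raster_values_rowmajor(r)
    cc <- cell_centers_xy(r$grid)
    ok <- !is.na(v)
    if (stats::sd(v[ok]) == 0) next
    idx <- which(ok)
    if (length(idx) > max_cells)
      idx <- with_seed(seed, sample(idx, max_cells))
    x <- cc[idx, 1]; y <- cc[idx, 2]; z <- v[idx]
    # pairwise semivariances on a further-thinned pair sample
    np <- min(length(idx), 1500L)
    sub <- with_seed(seed + 1L, sample(seq_along(idx), np))
    dx <- outer(x[sub], x[sub], "-"); dy <- outer(y[sub], y[sub], "-")
    h <- sqrt(dx^2 + dy^2)[upper.tri(dx)]
    gv <- (outer(z[sub], z[sub], "-")^2 / 2)[upper.tri(dx)]
    hmax <- max(h) / 2
    bins <- cut(h, breaks = seq(0, hmax, length.out = n_bins + 1L))
    gb <- tapply(gv, bins, mean)
    hb <- tapply(h, bins, mean)
    nb <- tapply(gv, bins, length)
    use <- !is.na(gb)
    if (sum(use) < 4) next
    gb <- gb[use]; hb <- hb[use]; nb <- nb[use]
    s2 <- stats::var(z)
    fit <- tryCatch(stats::optim(
      c(log(s2 / 10 + 1e-9), log(s2), log(hmax / 6)),
      function(p) {
        gam <- exp(p[1]) + exp(p[2]) * (1 - exp(-hb / exp(p[3])))
        sum(nb * (gb / gam - 1)^2)   # Cressie weights favor short lags
      }, method = "Nelder-Mead", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0) next
    ranges <- c(ranges, 3 * exp(fit$par[3]))
  }
  if (!length(ranges))
    stop("suggest_block_size: no layer yielded a variogram fit")
  stats::median(ranges)
}

# fold membership of grid cell-years (background for held-out metrics)
cells_in_fold <- function(assign, grid, f) {
  cc <- cell_centers_xy(grid)
  per_year <- function(sel_xy) {
    do.call(rbind, lapply(grid$years, function(yr)
      data.frame(x = cc[sel_xy, 1], y = cc[sel_xy, 2], year = yr)))
  }
  if (assign$type == "temporal") {
    pr <- assign$periods[[f]]
    yrs <- grid$years[grid$years >= pr[1] & grid$years <= pr[2]]
    do.call(rbind, lapply(yrs, function(yr)
      data.frame(x = cc[, 1], y = cc[, 2], year = yr)))
  } else if (assign$type == "spatial") {
    bl <- assign$blocks[assign$blocks$fold == f, , drop = FALSE]
    sel <- rep(FALSE, nrow(cc))
    for (b in seq_len(nrow(bl)))
      sel <- sel | (cc[, 1] >= bl$xmin[b] & cc[, 1] < bl$xmax[b] &
                      cc[, 2] > bl$ymin[b] & cc[, 2] <= bl$ymax[b])
    per_year(sel)
  } else {
    per_year(rep(TRUE, nrow(cc)))   # random folds: all cells as background
  }
}

#' Cross-validated transferability metrics
#'
#' For each fold: refit the integrated model on the training points,
#' predict every year with the averaged field (held-out structure has no
#' year-specific field information), and score the held-out presences
#' against held-out background cell-years; AUC is the rank statistic and
#' RMSE compares the presence indicator with `1 - exp(-lambda_hat)` per
#' cell. Pooled values are point-weighted means over held-out rows.
#'
#' @param assign `fold_assignment`.
#' @param spec `model_spec`.
#' @param layers Layer registry.
#' @param points `point_table` (rows aligned with `assign$fold`).
#' @param seed Integer seed.
#' @param hyper Passed to [fit_integrated()] (use a fixed `field_params`
#'   or `"none"` for speed).
#' @param drop_stream Optional stream excluded from training (ablation).
#' @return List: `per_fold` (data.frame fold/auc/rmse/n), `auc`, `rmse`
#'   (pooled).
#' @export
cv_run <- function(assign, spec, layers, points, seed = 1L, hyper = "none",
                   drop_stream = NULL) {
  stopifnot(length(assign$fold) == nrow(points))
  per <- list(); pooled_se <- numeric(0)
  pooled_p <- numeric(0); pooled_b <- numeric(0)
  skipped <- 0L
  for (f in seq_len(assign$k)) {
    train <- points[assign$fold != f, , drop = FALSE]
    test <- points[assign$fold == f, , drop = FALSE]
    ok <- tryCatch({
      if (!nrow(test)) stop("empty test fold")
      if (!any(train$stream == "nest")) stop("no training nests")
      ft <- fit_integrated(spec, layers, train, seed = seed + f,
                           hyper = hyper, drop_stream = drop_stream)
      surfs <- lapply(spec$grid$years, function(yr)
        predict(ft, layers, yr, field_mode = "averaged"))
      names(surfs) <- paste0("y", spec$grid$years)
      score_at <- function(df) {
        out <- rep(NA_real_, nrow(df))
        for (yr in unique(df$year)) {
          sel <- df$year == yr
          out[sel] <- raster_at_points(surfs[[paste0("y", yr)]]$lambda,
                                       df$x[sel], df$y[sel],
                                       method = "nearest")
        }
        out
      }
      sp <- score_at(test)
      sb <- score_at(cells_in_fold(assign, spec$grid, f))
      a <- auc(sp, sb)
      p_hat <- 1 - exp(-c(sp, sb))
      z <- c(rep(1, length(sp)), rep(0, length(sb)))
      list(auc = a, rmse = sqrt(mean((z - p_hat)^2)),
           se = (z - p_hat)^2, sp = sp, sb = sb, n = length(z))
    }, error = function(e) {
      message("cv_run: fold ", f, " skipped (", conditionMessage(e), ")")
      NULL
    })
    if (is.null(ok)) { skipped <- skipped + 1L; next }
    per[[length(per) + 1L]] <- data.frame(fold = f, auc = ok$auc,
                                          rmse = ok$rmse, n = ok$n)
    pooled_se <- c(pooled_se, ok$se)
    pooled_p <- c(pooled_p, ok$sp); pooled_b <- c(pooled_b, ok$sb)
  }
  if (!length(per)) stop("cv_run: all folds failed")
  list(per_fold = do.call(rbind, per),
       auc = auc(pooled_p, pooled_b),
       rmse = sqrt(mean(pooled_se)),
       skipped = skipped)
}

#' Buffered out-of-sample evaluation
#'
#' Each checklist is scored by the maximum predicted cell value among
#' cells whose centers fall within the disc of radius `effort_distance`
#' (km) around the checklist location (its containing cell for radius 0),
#' acknowledging that a traveling checklist surveys an area rather than a
#' point. Metrics compare scores of presence-labelled checklists against
#' the rest.
#'
#' @param checklists data.frame with `x`, `y`, `effort_distance` (km).
#' @param surface `prediction_surface`.
#' @param labels Logical/0-1 vector: whether the checklist recorded the
#'   species.
#' @return List: `auc`, `rmse`, `scores`, `n_dropped`.
#' @export
buffered_eval <- function(checklists, surface, labels) {
  g <- surface$lambda$grid
  cc <- cell_centers_xy(g)
  v <- raster_values_rowmajor(surface$lambda)
  scores <- rep(NA_real_, nrow(checklists))
  for (i in seq_len(nrow(checklists))) {
    rad <- checklists$effort_distance[i] * 1000
    if (is.na(rad) || rad <= 0) {
      scores[i] <- raster_at_points(surface$lambda, checklists$x[i],
                                    checklists$y[i], method = "nearest")
    } else {
      sel <- (cc[, 1] - checklists$x[i])^2 + (cc[, 2] - checklists$y[i])^2 <=
        rad^2
      if (any(sel)) scores[i] <- max(v[sel], na.rm = TRUE)
    }
  }
  drop <- is.na(scores)
  if (any(drop))
    message("buffered_eval: dropped ", sum(drop),
            " checklist(s) with empty buffers")
  scores2 <- scores[!drop]; lab <- as.logical(labels)[!drop]
  p_hat <- 1 - exp(-scores2)
  a <- if (!any(lab) || all(lab)) NA_real_ else
    auc(scores2[lab], scores2[!lab])
  list(auc = a,
       rmse = sqrt(mean((as.numeric(lab) - p_hat)^2)),
       scores = scores, n_dropped = sum(drop))
}

#' With/without-opportunistic-stream ablation
#'
#' Runs random k-fold cross-validation for the full integrated model and
#' for the nests-only model on identical folds, returning paired metrics.
#'
#' @param spec `model_spec`.
#' @param layers Layer registry.
#' @param points `point_table` with both streams.
#' @param folds Folds (default 10).
#' @param seed Integer seed.
#' @param hyper Passed to [fit_integrated()].
#' @return data.frame with rows `integrated` and `nests_only` and
#'   attribute `"folds"` (the shared assignment).
#' @export
stream_ablation <- function(spec, layers, points, folds = 10, seed = 1L,
                            hyper = "none") {
  fa <- random_folds(points, k = folds, seed = seed)
  full <- cv_run(fa, spec, layers, points, seed = seed, hyper = hyper)
  nest <- cv_run(fa, spec, layers, points, seed = seed, hyper = hyper,
                 drop_stream = "ebird")
  out <- data.frame(model = c("integrated", "nests_only"),
                    auc = c(full$auc, nest$auc),
                    rmse = c(full$rmse, nest$rmse),
                    stringsAsFactors = FALSE)
  attr(out, "folds") <- fa
  out
}
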