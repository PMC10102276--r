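#' Run the analysis pipeline from a configuration file
#'
#' Executes the stages `simulate -> prepare -> select -> fit -> predict ->
#' validate` (or the subset named in the config, in that canonical order)
#' against a JSON configuration, writing every stage's machine-readable
#' result plus a log (seed, package version, stage timings) into the
#' output directory. Identical config and seed give identical outputs.
#'
#' Config schema (JSON object):
#' \preformatted{
#' {
#'   "grid":   {"x0":0, "y0":1920, "dx":30, "nx":64, "ny":64,
#'              "years":[2001, 2005]},
#'   "seed":   1,
#'   "outdir": "out",
#'   "stages": ["simulate", "prepare", "select", "fit", "predict",
#'              "validate"],
#'   "quad_m": null,            // random-quadrature size (null = grid type)
#'   "field_coarsen": 4,
#'   "hyper":  "truth",         // "truth" | "estimate" | "none"
#'   "n_boot": 200,
#'   "cv":     {"scheme": "random", "k": 5},
#'   "select_scales": ["pixel30", "neighbor", "r90"]
#' }
#' }
#'
#' @param config Path to a JSON config file, or an equivalent list.
#' @param seed Optional seed override.
#' @param outdir Optional output directory override.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  cfg <- if (is.character(config)) jsonlite::fromJSON(config) else config
  for (req in c("grid", "seed", "outdir"))
    if (is.null(cfg[[req]]) && !(req == "seed" && !is.null(seed)) &&
        !(req == "outdir" && !is.null(outdir)))
      stop("run_pipeline: config is missing required field '", req, "'")
  gc_ <- cfg$grid
  for (req in c("x0", "y0", "dx", "nx", "ny", "years"))
    if (is.null(gc_[[req]]))
      stop("run_pipeline: config grid is missing field '", req, "'")
  grid <- grid_spec(gc_$x0, gc_$y0, gc_$dx, gc_$dx, gc_$nx, gc_$ny,
                    years = seq(gc_$years[1], gc_$years[2]))
  seed <- as.integer(seed %||% cfg$seed)
  outdir <- outdir %||% cfg$outdir
  stages <- cfg$stages %||% c("simulate", "prepare", "select", "fit",
                              "predict", "validate")
  canonical <- c("simulate", "prepare", "select", "fit", "predict",
                 "validate")
  bad <- setdiff(stages, canonical)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  stages <- canonical[canonical %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "log.txt")
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                             "\n", sep = "", file = logf, append = TRUE)
  cat(sprintf("pipeline seed=%d package=lgcpfuse %s R=%s\n", seed,
              as.character(utils::packageVersion("lgcpfuse")),
              getRversion()), file = logf)

  env <- new.env(parent = emptyenv())
  need <- function(what, stage, from) {
    if (is.null(env[[what]]))
      stop("run_pipeline: stage '", stage, "' needs the output of '", from,
           "'; rerun with that stage included")
    env[[what]]
  }

  for (st in stages) {
    logit("stage ", st, " start")
    switch(st,
      simulate = {
        layers <- make_landscape(grid, seed = seed)
        truth <- truth_spec(grid, layers,
                            target_nests = cfg$target_nests %||% 2000,
                            target_ebird = cfg$target_ebird %||% 300)
        fld <- sample_field(truth$field, grid, seed = seed + 7L)
        pts <- simulate_points(truth, layers, fld, seed = seed + 13L)
        env$layers <- layers; env$truth <- truth; env$points <- pts
        write_points(pts, file.path(outdir, "points.csv"))
        jsonlite::write_json(
          list(beta = as.list(truth$beta),
               delta = c(as.list(truth$delta_spatial),
                         as.list(truth$delta_effort)),
               intercept_nest = truth$intercept_nest,
               intercept_ebird = truth$intercept_ebird,
               field = truth$field[c("rho", "sigma", "phi")],
               seed = seed),
          file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
        write_raster(layers$static$dist_lake,
                     file.path(outdir, "dist_lake.asc"))
      },
      prepare = {
        pts <- need("points", st, "simulate")
        filt <- filter_checklists(pts)
        env$points_f <- filt
        write_points(filt, file.path(outdir, "points_filtered.csv"))
        truth <- need("truth", st, "simulate")
        X <- do.call(rbind, lapply(grid$years, function(yr)
          assemble_design(env$layers, truth$specs_eco, yr)))
        scr <- correlation_screen(standardize(X)$x)
        utils::write.csv(scr, file.path(outdir, "correlation_screen.csv"),
                         row.names = FALSE)
      },
      select = {
        pts <- env$points_f %||% need("points", st, "simulate")
        truth <- need("truth", st, "simulate")
        nests <- pts[pts$stream == "nest", , drop = FALSE]
        sch <- build_quadrature(grid, nests, type = "grid", seed = seed)
        scl <- select_scale(env$layers, "percent_water",
                            cfg$select_scales %||%
                              c("pixel30", "neighbor", "r90"),
                            sch, folds = cfg$cv$k %||% 5, seed = seed)
        X <- do.call(rbind, lapply(split(seq_len(nrow(sch)), sch$year),
          function(ix) cbind(ix = ix,
            assemble_design(env$layers, truth$specs_eco, sch$year[ix[1]],
                            at = sch[ix, c("x", "y")]))))
        X <- X[order(X[, "ix"]), -1, drop = FALSE]
        lc <- lasso_cv(X, sch, folds = cfg$cv$k %||% 5, seed = seed,
                       n_penalty = cfg$n_penalty %||% 25)
        env$selected <- lc
        jsonlite::write_json(
          list(scale_choice = scl$scale, scale_rmse = as.list(scl$rmse),
               penalty = lc$penalty, cv_rmse = lc$cv_rmse,
               cv_auc = lc$cv_auc, coef = as.list(lc$fit$coef)),
          file.path(outdir, "selection.json"), auto_unbox = TRUE,
          digits = NA)
        utils::write.csv(lc$path, file.path(outdir, "lasso_path.csv"),
                         row.names = FALSE)
      },
      fit = {
        pts <- env$points_f %||% need("points", st, "simulate")
        truth <- need("truth", st, "simulate")
        ms <- model_spec(grid, truth$specs_eco, truth$specs_obs,
                         field_coarsen = cfg$field_coarsen %||% 4,
                         quad_m = cfg$quad_m,
                         sample_method = "nearest")
        hyper <- switch(cfg$hyper %||% "truth",
                        truth = truth$field, none = "none", "estimate")
        ft <- fit_integrated(ms, env$layers, pts, seed = seed,
                             hyper = hyper)
        env$fit <- ft
        jsonlite::write_json(
          list(coef = ft$coef,
               hyper = if (!is.null(ft$hyper))
                 ft$hyper[c("rho", "sigma", "phi")],
               marginal_loglik = ft$marginal_loglik,
               diagnostics = ft$diagnostics[c("n_iter", "converged",
                                              "data_loglik")]),
          file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA)
      },
      predict = {
        ft <- need("fit", st, "fit")
        surfs <- lapply(grid$years, function(yr)
          predict(ft, env$layers, yr, field_mode = "year_specific"))
        pres <- ft$idata$rows$presence == 1
        sc_p <- raster_scores(surfs, ft$idata$rows[pres, ])
        sc_b <- raster_scores(surfs, ft$idata$rows[!pres, ])
        th <- select_threshold(sc_p, sc_b)
        ab <- data.frame(
          year = grid$years,
          abundance = vapply(surfs, abundance, 0, tau = th$tau))
        if (!is.null(cfg$n_boot) && cfg$n_boot >= 100) {
          ci <- abundance_ci(ft, env$layers, th$tau, n_boot = cfg$n_boot,
                             seed = seed)
          ab$lower <- ci$lower; ab$upper <- ci$upper
        }
        env$threshold <- th; env$surfaces <- surfs
        for (i in seq_along(surfs))
          write_raster(surfs[[i]]$lambda,
                       file.path(outdir,
                                 sprintf("lambda_%d.asc", grid$years[i])))
        utils::write.csv(ab, file.path(outdir, "abundance.csv"),
                         row.names = FALSE)
        jsonlite::write_json(th, file.path(outdir, "threshold.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      validate = {
        pts <- env$points_f %||% need("points", st, "simulate")
        truth <- need("truth", st, "simulate")
        ms <- model_spec(grid, truth$specs_eco, truth$specs_obs,
                         field_coarsen = cfg$field_coarsen %||% 4,
                         quad_m = cfg$quad_m, sample_method = "nearest")
        k <- cfg$cv$k %||% 3
        fa <- switch(cfg$cv$scheme %||% "random",
                     random = random_folds(pts, k, seed),
                     temporal = temporal_folds(pts, default_periods(grid)),
                     spatial = spatial_folds(pts, grid,
                                             cfg$cv$block_size %||%
                                               (grid$nx * grid$dx / 3),
                                             k, seed))
        cvres <- cv_run(fa, ms, env$layers, pts, seed = seed,
                        hyper = "none")
        utils::write.csv(cvres$per_fold,
                         file.path(outdir, "validation_folds.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(scheme = fa$type, auc = cvres$auc,
                                  rmse = cvres$rmse),
                             file.path(outdir, "validation.json"),
                             auto_unbox = TRUE, digits = NA)
      })
    logit("stage ", st, " done")
  }
  invisible(outdir)
}

# nearest-cell lambda score of arbitrary rows against per-year surfaces
raster_scores <- function(surfs, rows) {
  years <- vapply(surfs, `[[`, 0, "year")
  out <- rep(NA_real_, nrow(rows))
  for (i in seq_along(surfs)) {
    sel <- rows$year == years[i]
    if (any(sel))
      out[sel] <- raster_at_points(surfs[[i]]$lambda, rows$x[sel],
                                   rows$y[sel], method = "nearest")
  }
  out
}

default_periods <- function(grid) {
  yrs <- grid$years
  br <- round(stats::quantile(yrs, c(1 / 3, 2 / 3)))
  list(c(min(yrs), br[1]), c(br[1] + 1, br[2]), c(br[2] + 1, max(yrs)))
}
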