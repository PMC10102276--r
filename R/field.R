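#' Matern field hyperparameters
#'
#' `rho` is the nominal spatial range in meters — the distance at which
#' correlation has declined to approximately 0.1 (for the Matern with
#' smoothness nu = 1 used here the exact value at `rho` is ~0.14). `sigma`
#' is the stationary marginal standard deviation and `phi` the AR1
#' coefficient governing year-to-year persistence of the field.
#'
#' @param rho Spatial range, m; > 0.
#' @param sigma Marginal sd; > 0.
#' @param phi AR1 coefficient; in (-1, 1).
#' @return Object of class `field_params`.
#' @export
field_params <- function(rho, sigma, phi = 0) {
  if (!(rho > 0)) stop("field_params: rho must be > 0")
  if (!(sigma > 0)) stop("field_params: sigma must be > 0")
  if (!(abs(phi) < 1)) stop("field_params: phi must satisfy |phi| < 1 (stationarity)")
  structure(list(rho = rho, sigma = sigma, phi = phi), class = "field_params")
}

# 5-point Neumann stiffness matrix (graph Laplacian) of the nx x ny lattice,
# row-major (top row first) cell ordering. Dimensionless: dx = dy assumed.
lattice_stiffness <- function(nx, ny) {
  n <- nx * ny
  idx <- function(i, j) j * nx + i + 1L  # 0-based (i, j) -> 1-based vector pos
  ii <- integer(0); jj <- integer(0)
  if (nx > 1L) {
    i <- rep(0:(nx - 2L), times = ny); j <- rep(0:(ny - 1L), each = nx - 1L)
    ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i + 1L, j))
  }
  if (ny > 1L) {
    i <- rep(0:(nx - 1L), times = ny - 1L); j <- rep(0:(ny - 2L), each = nx)
    ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i, j + 1L))
  }
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

#' Spatial precision matrix of the lattice SPDE field
#'
#' Finite-difference discretization of the SPDE representation of a Matern
#' field with smoothness nu = 1 (alpha = 2 in 2-D): the precision is
#' `t(K) %*% C^-1 %*% K` with `K = kappa^2 C + G`, `kappa = sqrt(8)/rho`,
#' lumped mass `C` and Neumann boundaries. The result is rescaled so that
#' the marginal variance at the central (interior) cell equals `sigma^2`;
#' boundary cells have inflated variance, a documented consequence of the
#' Neumann condition.
#'
#' @param grid A `grid_spec` (square cells required).
#' @param rho Nominal range, m; must be at least `2 * dx` to be resolvable.
#' @param sigma Marginal sd.
#' @return Object of class `precision_op`: sparse symmetric positive
#'   definite precision `Q` over the `nx*ny` cells (row-major), with a
#'   cached Cholesky factorization.
#' @export
spatial_precision <- function(grid, rho, sigma) {
  if (!isTRUE(all.equal(grid$dx, grid$dy)))
    stop("spatial_precision: square cells required")
  if (rho < 2 * grid$dx)
    stop("spatial_precision: rho = ", rho,
         " is below the lattice resolution (need rho >= 2*dx = ", 2 * grid$dx, ")")
  if (!(sigma > 0)) stop("spatial_precision: sigma must be > 0")
  nx <- grid$nx; ny <- grid$ny; n <- nx * ny
  kappa <- sqrt(8) / rho
  h2 <- grid$dx^2                      # lumped mass per cell
  G <- lattice_stiffness(nx, ny)       # dimensionless stiffness
  K <- kappa^2 * h2 * Matrix::Diagonal(n) + G
  Q0 <- Matrix::forceSymmetric(Matrix::crossprod(K) / h2)
  # empirical variance calibration at the central cell
  c0 <- (ny %/% 2L) * nx + nx %/% 2L + 1L
  e <- numeric(n); e[c0] <- 1
  v0 <- as.numeric(Matrix::solve(Q0, e)[c0])
  Q <- Q0 * (v0 / sigma^2)
  new_precision_op(Q, grid, n_years = 1L,
                   params = list(rho = rho, sigma = sigma, phi = NA_real_))
}

new_precision_op <- function(Q, grid, n_years, params) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  structure(list(Q = Q, grid = grid, n_years = n_years, params = params,
                 chol = ch),
            class = "precision_op")
}

#' @export
#' @method print precision_op
print.precision_op <- function(x, ...) {
  cat(sprintf("<precision_op> %d cells x %d year(s); rho=%g sigma=%g phi=%g\n",
              nrow(x$Q) / x$n_years, x$n_years,
              x$params$rho, x$params$sigma, x$params$phi))
  invisible(x)
}

# Stationary AR1 precision with unit marginal variance: tridiagonal,
# (1/(1-phi^2)) * [1, 1+phi^2, ..., 1+phi^2, 1] on the diagonal, -phi off.
ar1_precision <- function(phi, n_years) {
  if (n_years == 1L) return(Matrix::Diagonal(1))
  d <- c(1, rep(1 + phi^2, n_years - 2L), 1) / (1 - phi^2)
  off <- rep(-phi / (1 - phi^2), n_years - 1L)
  Matrix::bandSparse(n_years, k = c(-1L, 0L, 1L),
                     diagonals = list(off, d, off), symmetric = FALSE)
}

#' Space-time precision (AR1 in years, Kronecker with space)
#'
#' Builds the precision of the stationary space-time field as the Kronecker
#' product of the unit-variance AR1 precision over years with the spatial
#' precision, so the stationary marginal variance stays `sigma^2` in every
#' year. Vector layout: year-major (all cells of year 1, then year 2, ...),
#' cells row-major.
#'
#' @param spatial A `precision_op` from [spatial_precision()].
#' @param phi AR1 coefficient, |phi| < 1.
#' @param n_years Number of years.
#' @return A `precision_op` over `n_cells * n_years`.
#' @export
spacetime_precision <- function(spatial, phi, n_years) {
  if (!(abs(phi) < 1)) stop("spacetime_precision: phi must satisfy |phi| < 1")
  n_years <- as.integer(n_years)
  params <- spatial$params; params$phi <- phi
  if (n_years == 1L)
    return(new_precision_op(spatial$Q, spatial$grid, 1L, params))
  Qt <- ar1_precision(phi, n_years)
  Q <- Matrix::forceSymmetric(Matrix::kronecker(Qt, spatial$Q))
  new_precision_op(Q, spatial$grid, n_years, params)
}

#' Sample from / evaluate a GMRF
#'
#' `sample_gmrf` draws fields by back-solving the permuted Cholesky factor
#' against white noise; `logdens_gmrf` evaluates the exact Gaussian
#' log-density `0.5 log|Q| - 0.5 u'Qu - (n/2) log 2pi`.
#'
#' @param op A `precision_op`.
#' @param n Number of independent draws.
#' @param seed Optional integer seed (local RNG; does not disturb the
#'   caller's RNG state).
#' @return `sample_gmrf`: an `n_total x n` matrix (one column per draw);
#'   `logdens_gmrf`: a scalar.
#' @export
sample_gmrf <- function(op, n = 1L, seed = NULL) {
  ntot <- nrow(op$Q)
  z <- with_seed(seed, matrix(stats::rnorm(ntot * n), ntot, n))
  y <- Matrix::solve(op$chol, z, system = "Lt")
  u <- Matrix::solve(op$chol, y, system = "Pt")
  as.matrix(u)
}

#' @rdname sample_gmrf
#' @param u Field vector (length `nrow(Q)`).
#' @export
logdens_gmrf <- function(op, u) {
  ntot <- nrow(op$Q)
  ld <- 2 * Matrix::determinant(op$chol, sqrt = TRUE,
                               logarithm = TRUE)$modulus  # log|Q|
  quad <- as.numeric(Matrix::crossprod(u, op$Q %*% u))
  as.numeric(0.5 * ld - 0.5 * quad - 0.5 * ntot * log(2 * pi))
}

#' Joint penalized-complexity prior for (range, sd)
#'
#' Log density of the PC prior of Fuglstad et al. for the Matern range and
#' marginal sd in d = 2, parameterized by tail probabilities
#' `P(rho < rho0) = alpha_rho` and `P(sigma > sigma0) = alpha_sigma`:
#' `pi(rho, sigma) = lam1 rho^-2 exp(-lam1/rho) * lam2 exp(-lam2 sigma)`
#' with `lam1 = -log(alpha_rho) * rho0`, `lam2 = -log(alpha_sigma)/sigma0`.
#'
#' @param rho,sigma Evaluation point (> 0).
#' @param rho0,alpha_rho,sigma0,alpha_sigma Prior settings; alphas in (0,1).
#' @return Log prior density (scalar; vectorized over rho/sigma).
#' @export
pc_prior_logdens <- function(rho, sigma, rho0, alpha_rho, sigma0, alpha_sigma) {
  if (!(rho0 > 0 && sigma0 > 0)) stop("pc_prior_logdens: rho0, sigma0 must be > 0")
  if (!(alpha_rho > 0 && alpha_rho < 1 && alpha_sigma > 0 && alpha_sigma < 1))
    stop("pc_prior_logdens: tail probabilities must lie in (0, 1)")
  if (any(rho <= 0) || any(sigma <= 0))
    stop("pc_prior_logdens: rho and sigma must be > 0")
  lam1 <- -log(alpha_rho) * rho0
  lam2 <- -log(alpha_sigma) / sigma0
  log(lam1) - 2 * log(rho) - lam1 / rho + log(lam2) - lam2 * sigma
}

# Evaluate f() under a temporary RNG state when seed is given.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample the space-time field as per-year rasters
#'
#' Convenience wrapper combining [spatial_precision()],
#' [spacetime_precision()] and [sample_gmrf()]: one stationary draw of
#' u(s, t) for every year of the grid. Year 1 is drawn from the stationary
#' distribution, so the process is stationary across years for any |phi|<1.
#'
#' @param params A `field_params`.
#' @param grid A `grid_spec` (its `years` set the number of annual layers).
#' @param seed Integer seed.
#' @return Named list of `raster_layer`, one per year (`"y<year>"`).
#' @export
sample_field <- function(params, grid, seed = NULL) {
  sp <- spatial_precision(grid, params$rho, params$sigma)
  op <- spacetime_precision(sp, params$phi, length(grid$years))
  u <- sample_gmrf(op, n = 1L, seed = seed)[, 1]
  n <- grid$nx * grid$ny
  out <- lapply(seq_along(grid$years), function(t)
    raster_layer(grid, u[((t - 1L) * n + 1L):(t * n)]))
  names(out) <- paste0("y", grid$years)
  out
}
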