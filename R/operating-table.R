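# Operating tables: the (mu, sigma) <-> (r_inf, CV) correspondence tabulated
# on a rectangular grid, with bilinear interpolation, inverse lookup, and
# direct calibration of an operating point to rate/CV targets.

#' Build an operating table over an input-parameter grid
#'
#' Tabulates the steady-state rate, ISI CV and (optionally) the dominant
#' nonzero eigenvalue \eqn{\lambda_1} of one integrate-and-fire model on a
#' rectangular `(mu, sigma)` grid. Forward lookups interpolate bilinearly;
#' inverse lookups solve the 2-D root problem on the interpolant. Queries
#' outside the grid hull raise an error (no silent extrapolation).
#'
#' @param params a [neuron_params()] object.
#' @param mu_grid,sigma_grid ascending grid node vectors (mV).
#' @param with_lambda also compute \eqn{\lambda_1} at every node.
#' @param n_fourier truncation order for the QIF eigenvalue solver.
#' @param dv voltage grid spacing for the steady/first-passage solvers (mV).
#' @param dv_eigen finer grid spacing used by the eigenvalue solver.
#' @returns an `operating_table`: tibble with columns `mu`, `sigma`,
#'   `rate_hz`, `cv`, `lambda_re`, `lambda_im`.
#' @export
build_operating_table <- function(params, mu_grid, sigma_grid,
                                  with_lambda = TRUE, n_fourier = 100,
                                  dv = 2^-4, dv_eigen = 2^-6) {
  stopifnot(length(mu_grid) >= 2, length(sigma_grid) >= 2,
            !is.unsorted(mu_grid), !is.unsorted(sigma_grid))
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  n <- nrow(grid)
  rate <- cv <- lre <- lim <- rep(NA_real_, n)
  last_lambda <- NULL
  for (i in seq_len(n)) {
    rc <- fp_rate_cv(params, grid$mu[i], grid$sigma[i], dv)
    rate[i] <- rc$rate_hz
    cv[i] <- rc$cv
    if (with_lambda) {
      guess <- lambda_from_fit(max(rc$rate_hz, 1), max(rc$cv, 0.02))
      if (rc$rate_hz < 1 && !is.null(last_lambda)) guess <- last_lambda
      ev <- tryCatch(
        fp_eigenvalue(params, grid$mu[i], grid$sigma[i], guess = guess,
                      n_fourier = n_fourier, dv = dv_eigen),
        error = function(e) NULL)
      if (!is.null(ev)) {
        lre[i] <- Re(ev$lambda)
        lim[i] <- Im(ev$lambda)
        last_lambda <- ev$lambda
      } else {
        last_lambda <- NULL
      }
    }
  }
  structure(
    tibble(mu = grid$mu, sigma = grid$sigma, rate_hz = rate, cv = cv,
           lambda_re = lre, lambda_im = lim),
    class = c("operating_table", class(tibble())),
    mu_grid = mu_grid, sigma_grid = sigma_grid, params = params)
}

#' @export
print.operating_table <- function(x, ...) {
  cat(sprintf("<operating_table %s: %d x %d nodes, mu in [%g, %g], sigma in [%g, %g]>\n",
              toupper(attr(x, "params")$model),
              length(attr(x, "mu_grid")), length(attr(x, "sigma_grid")),
              min(attr(x, "mu_grid")), max(attr(x, "mu_grid")),
              min(attr(x, "sigma_grid")), max(attr(x, "sigma_grid"))))
  NextMethod()
}

# value matrix (mu rows x sigma cols) for one column of the table
table_field <- function(table, field) {
  mg <- attr(table, "mu_grid"); sg <- attr(table, "sigma_grid")
  matrix(table[[field]], nrow = length(mg), ncol = length(sg))
}

# vectorized bilinear interpolation; errors outside the hull
bilinear <- function(xg, yg, zmat, x, y, what = "query") {
  eps_x <- 1e-9 * max(abs(xg)) + 1e-12
  eps_y <- 1e-9 * max(abs(yg)) + 1e-12
  if (any(x < xg[1] - eps_x | x > xg[length(xg)] + eps_x |
          y < yg[1] - eps_y | y > yg[length(yg)] + eps_y))
    abort(sprintf("%s outside the operating-table hull", what),
          class = "cvrate_hull_error")
  x <- pmin(pmax(x, xg[1]), xg[length(xg)])
  y <- pmin(pmax(y, yg[1]), yg[length(yg)])
  i <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  j <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  z00 <- zmat[cbind(i, j)]; z10 <- zmat[cbind(i + 1, j)]
  z01 <- zmat[cbind(i, j + 1)]; z11 <- zmat[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

#' Interpolate an operating table at query points
#'
#' @param table an `operating_table`.
#' @param mu,sigma query coordinates (vectors, mV).
#' @returns tibble with `mu`, `sigma`, `rate_hz`, `cv`, `lambda_re`,
#'   `lambda_im`.
#' @export
table_lookup <- function(table, mu, sigma) {
  mg <- attr(table, "mu_grid"); sg <- attr(table, "sigma_grid")
  out <- tibble(mu = mu, sigma = sigma)
  for (f in c("rate_hz", "cv", "lambda_re", "lambda_im")) {
    out[[f]] <- bilinear(mg, sg, table_field(table, f), mu, sigma,
                         what = sprintf("(mu, sigma) %s", f))
  }
  out
}

#' Invert an operating table: find (mu, sigma) for a (rate, CV) target
#'
#' 2-D Newton iteration on the bilinear interpolant, warm-started from the
#' nearest table node.
#'
#' @param table an `operating_table`.
#' @param rate_hz,cv targets.
#' @param tol convergence tolerance on the relative residual.
#' @returns named numeric vector `c(mu, sigma)`.
#' @export
table_invert <- function(table, rate_hz, cv, tol = 1e-9) {
  mg <- attr(table, "mu_grid"); sg <- attr(table, "sigma_grid")
  score <- (table$rate_hz / rate_hz - 1)^2 + (table$cv / cv - 1)^2
  k <- which.min(score)
  x <- c(table$mu[k], table$sigma[k])
  fn <- function(p) {
    lk <- table_lookup(table, p[1], p[2])
    c(lk$rate_hz - rate_hz, lk$cv - cv)
  }
  for (it in 1:60) {
    f <- fn(x)
    if (sqrt(sum((f / c(rate_hz, cv))^2)) < tol) break
    hm <- max(1e-6, 1e-6 * abs(x[1])); hs <- max(1e-6, 1e-6 * abs(x[2]))
    J <- cbind((fn(x + c(hm, 0)) - fn(x - c(hm, 0))) / (2 * hm),
               (fn(x + c(0, hs)) - fn(x - c(0, hs))) / (2 * hs))
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) abort("singular Jacobian in table inversion")
    # damped update, clipped to the hull
    lo <- c(mg[1], sg[1]); hi <- c(mg[length(mg)], sg[length(sg)])
    x_new <- pmin(pmax(x - step, lo), hi)
    x <- x_new
  }
  setNames(x, c("mu", "sigma"))
}

#' Calibrate an operating point to rate and CV targets
#'
#' Finds the input mean and noise amplitude `(mu, sigma)` at which the
#' Fokker-Planck solvers give the requested steady-state rate and ISI CV,
#' by damped 2-D Newton iteration on the direct solvers (no table
#' interpolation). The returned point reproduces the targets to `tol`
#' (default 0.1%).
#'
#' @param params a [neuron_params()] object.
#' @param rate_hz,cv targets (Hz, dimensionless).
#' @param init optional initial `c(mu, sigma)`.
#' @param tol relative tolerance on both targets.
#' @param dv solver grid spacing.
#' @returns tibble with `mu`, `sigma`, `rate_hz`, `cv` (achieved values).
#' @export
calibrate_operating_point <- function(params, rate_hz, cv, init = NULL,
                                      tol = 1e-3, dv = 2^-4) {
  stopifnot(rate_hz > 0, cv > 0)
  if (is.null(init)) {
    sig0 <- 1
    # bracket mu for the rate target at sigma = sig0
    f_rate <- function(m) fp_rate_cv(params, m, sig0, dv)$rate_hz - rate_hz
    lo <- -5; hi <- 5
    while (f_rate(hi) < 0 && hi < 400) hi <- hi * 1.6
    while (f_rate(lo) > 0 && lo > -400) lo <- lo * 1.6
    mu0 <- uniroot(f_rate, c(lo, hi), tol = 1e-4)$root
    init <- c(mu0, sig0)
  }
  x <- init
  fn <- function(p) {
    rc <- fp_rate_cv(params, p[1], max(p[2], 1e-3), dv)
    c(rc$rate_hz / rate_hz - 1, rc$cv / cv - 1)
  }
  for (it in 1:60) {
    f <- fn(x)
    if (max(abs(f)) < tol) break
    hm <- 1e-4 * max(1, abs(x[1])); hs <- 1e-4 * max(0.05, abs(x[2]))
    J <- cbind((fn(x + c(hm, 0)) - fn(x - c(hm, 0))) / (2 * hm),
               (fn(x + c(0, hs)) - fn(x - c(0, hs))) / (2 * hs))
    step <- solve(J, f)
    # damp and keep sigma positive
    lam <- 1
    repeat {
      x_new <- x - lam * step
      if (x_new[2] > 1e-3) break
      lam <- lam / 2
      if (lam < 1e-4) abort("calibration failed: sigma driven to zero")
    }
    x <- x_new
  }
  rc <- fp_rate_cv(params, x[1], x[2], dv)
  if (abs(rc$rate_hz / rate_hz - 1) > 5e-3 || abs(rc$cv / cv - 1) > 5e-3)
    abort(sprintf(
      "calibration did not converge: reached %.3f Hz, CV %.4f for target %.3f Hz, CV %.4f",
      rc$rate_hz, rc$cv, rate_hz, cv))
  tibble(mu = x[1], sigma = x[2], rate_hz = rc$rate_hz, cv = rc$cv)
}
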