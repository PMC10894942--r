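#' Powell's conjugate-direction minimization
#'
#' Derivative-free local minimization by successive line searches along an
#' evolving direction set (Powell's method). Each sweep minimizes along every
#' direction in turn (golden-section bracketing followed by Brent line
#' minimization via [stats::optimize()]); the direction of largest decrease
#' may then be replaced by the sweep's net displacement, building up
#' conjugate directions. The iteration stops when a full sweep reduces the
#' objective by less than `tol` in relative terms, or after `maxit` sweeps.
#'
#' Line searches only ever accept improvements, so the returned value never
#' exceeds the objective at the starting point.
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar (a non-finite value aborts the search with an error naming the
#'   offending point).
#' @param par numeric starting vector.
#' @param tol relative convergence tolerance on the objective (default 1e-6).
#' @param maxit maximum number of direction-set sweeps (default 1000).
#' @param step initial line-search step size (default 1).
#' @return A list with `par`, `value`, `counts` (number of function
#'   evaluations), `iterations` (sweeps) and `converged`.
#' @export
powell_minimize <- function(fn, par, tol = 1e-6, maxit = 1000, step = 1) {
  n <- length(par)
  assert_that(n >= 1 && all(is.finite(par)), "par must be a finite numeric vector")
  evals <- 0L
  f <- function(x) {
    evals <<- evals + 1L
    v <- fn(x)
    if (!is_number(v)) {
      stop_rscmlai(sprintf("non-finite objective at parameter vector (%s)",
                           paste(signif(x, 6), collapse = ", ")),
                   "rscmlai_optimization_error")
    }
    v
  }

  # Minimize f along p + t*dir: golden expansion to bracket, then Brent.
  line_min <- function(p, dir, fp) {
    f1 <- function(t) f(p + t * dir)
    gold <- 1.618034
    a <- 0; fa <- fp
    b <- step; fb <- f1(b)
    if (fb > fa) { dir <- -dir; b <- step; fb <- f1(b) }  # descend the other way
    if (fb > fa) {
      # minimum (if any) lies within [-step, step]
      opt <- stats::optimize(f1, c(-step, step), tol = 1e-8)
    } else {
      cc <- b * gold; fc <- f1(cc)
      iter <- 0L
      while (fc < fb && iter < 60L) {
        a <- b; fa <- fb
        b <- cc; fb <- fc
        cc <- cc * gold; fc <- f1(cc)
        iter <- iter + 1L
      }
      opt <- stats::optimize(f1, c(a, cc), tol = 1e-8)
    }
    if (opt$objective < fp) {
      list(p = p + opt$minimum * dir, fp = opt$objective, moved = opt$minimum * dir)
    } else {
      list(p = p, fp = fp, moved = rep(0, length(p)))
    }
  }

  p <- par
  fp <- f(p)
  converged <- FALSE
  iter <- 0L
  restart_f <- Inf
  dirs <- diag(1, n)
  while (iter < maxit) {
    iter <- iter + 1L
    p0 <- p; f0 <- fp
    del <- 0; ibig <- 1L
    for (i in seq_len(n)) {
      fprev <- fp
      res <- line_min(p, dirs[, i], fp)
      p <- res$p; fp <- res$fp
      if (fprev - fp > del) { del <- fprev - fp; ibig <- i }
    }
    if (2 * (f0 - fp) <= tol * (abs(f0) + abs(fp)) + 1e-25) {
      # Sweep stalled. Restart with a fresh (identity) direction set: the
      # accumulated directions can become degenerate and stall far from a
      # minimum. Stop only when a whole restart cycle brings no improvement.
      if (is.finite(restart_f) &&
          2 * (restart_f - fp) <= tol * (abs(restart_f) + abs(fp)) + 1e-25) {
        converged <- TRUE
        break
      }
      restart_f <- fp
      dirs <- diag(1, n)
      next
    }
    # Extrapolate along the sweep's net displacement; adopt it as a new
    # direction if the standard Powell criterion favors it.
    pe <- 2 * p - p0
    fe <- f(pe)
    if (fe < f0) {
      t <- 2 * (f0 - 2 * fp + fe) * (f0 - fp - del)^2 - del * (f0 - fe)^2
      if (t < 0) {
        newdir <- p - p0
        res <- line_min(p, newdir, fp)
        p <- res$p; fp <- res$fp
        dirs[, ibig] <- dirs[, n]
        dirs[, n] <- newdir
      }
    }
  }
  list(par = p, value = fp, counts = evals, iterations = iter, converged = converged)
}
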