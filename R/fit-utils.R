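# Internal nonlinear least-squares machinery.
#
# The fits in this package are small (3-5 parameters, 11-40 samples) but
# need box constraints: the trapping release rate kb legitimately sits on
# its lower bound 0 in most patients. Plain Levenberg-Marquardt has no
# bound support, so we use a projected LM step (damped normal equations,
# candidate projected onto the box, accepted only if the SSQ decreases)
# followed by an L-BFGS-B polish of the sum of squares.

num_jacobian <- function(fn, par, lower, upper, f0 = NULL) {
  p <- length(par)
  if (is.null(f0)) f0 <- fn(par)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(abs(par[j]), 1e-4) * 1e-7
    up <- min(par[j] + h, upper[j])
    dn <- max(par[j] - h, lower[j])
    if (up == dn) { J[, j] <- 0; next }
    pu <- par; pu[j] <- up
    pd <- par; pd[j] <- dn
    J[, j] <- (fn(pu) - fn(pd)) / (up - dn)
  }
  J
}

lm_bounded <- function(resid_fn, par, lower, upper,
                       max_iter = 200L, ftol = 1e-14, ptol = 1e-13) {
  par <- pmin(pmax(as.numeric(par), lower), upper)
  r <- resid_fn(par)
  ss <- sum(r * r)
  damp <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (ss == 0) { converged <- TRUE; break }
    J <- num_jacobian(resid_fn, par, lower, upper, f0 = r)
    g <- crossprod(J, r)
    A <- crossprod(J)
    dscale <- pmax(diag(A), 1e-12)
    accepted <- FALSE
    for (k in 1:40) {
      H <- A + damp * diag(dscale, nrow = length(par))
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- pmin(pmax(par + as.numeric(delta), lower), upper)
        rc <- resid_fn(cand)
        ssc <- sum(rc * rc)
        if (is.finite(ssc) && ssc <= ss) {
          prel <- max(abs(cand - par) / pmax(abs(par), 1e-12))
          frel <- (ss - ssc) / max(ss, .Machine$double.xmin)
          par <- cand; r <- rc; ss <- ssc
          damp <- max(damp / 10, 1e-14)
          accepted <- TRUE
          if (frel < ftol || prel < ptol) converged <- TRUE
          break
        }
      }
      damp <- damp * 10
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  # quasi-Newton polish on the scalar objective; keeps whichever is better
  obj <- function(p) sum(resid_fn(p)^2)
  pol <- tryCatch(
    stats::optim(par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 10, maxit = 200)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < ss) {
    par <- pmin(pmax(pol$par, lower), upper)
    r <- resid_fn(par)
    ss <- sum(r * r)
  }
  list(par = par, residuals = r, ssq = ss, converged = converged,
       iterations = it)
}

# Pearson R between model predictions and observations, guarded for the
# degenerate zero-variance case.
fit_correlation <- function(fitted, observed) {
  if (stats::sd(fitted) == 0 || stats::sd(observed) == 0) return(NA_real_)
  stats::cor(fitted, observed)
}
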