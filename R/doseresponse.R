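## Concentration-response fitting and affinity arithmetic.

#' Four-parameter Hill (logistic) response
#'
#' Evaluates `y = A + (B - A) / (1 + (C / x)^D)`. `A` is the response as
#' concentration approaches zero, `B` the asymptotic response at high
#' concentration, `C` the midpoint (IC50/EC50) and `D` the Hill coefficient.
#'
#' @param x concentrations (same units as `C`, must be > 0).
#' @param A,B,C,D Hill parameters; `C > 0`, `D != 0`.
#' @return numeric vector of responses.
#' @export
hill_response <- function(x, A, B, C, D) {
  stop_if_not_positive(x, "x")
  stop_if_not_positive(C, "C")
  if (D == 0) stop("Hill coefficient `D` must be non-zero", call. = FALSE)
  A + (B - A) / (1 + (C / x)^D)
}

#' Fit the four-parameter Hill equation
#'
#' Least-squares fit of `y = A + (B - A)/(1 + (C/x)^D)` with any subset of
#' `A`, `B`, `D` (or even `C`) held fixed. Optimization is performed on
#' log-concentration (`log C`) with box constraints
#' (`C` in `[min(x)/100, max(x) * 100]`, `D` in `[0.1, 10]`) and is
#' multi-started from three initial midpoints, because the model is
#' ill-conditioned on the linear concentration scale.
#'
#' Replicate responses at the same concentration all enter the loss; means
#' per concentration are used only to pick starting values.
#'
#' @param x concentrations (> 0).
#' @param y responses (percent of control binding, percent modulation,
#'   percent occupancy, ...).
#' @param fixed optional named list fixing parameters, e.g.
#'   `list(A = 0)` for modulation curves or `list(A = 0, D = 1)` for
#'   exposure-occupancy curves.
#' @param weights optional per-observation weights (default equal).
#' @return an object of class `hill_fit`: list with `estimates` (named vector
#'   A, B, C, D), `se` (standard errors, `NA` for fixed parameters),
#'   `fixed`, `converged`, `rss`, `sigma` (residual SD), `n`, and `fitted`.
#' @export
fit_hill <- function(x, y, fixed = list(), weights = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  stop_if_not_positive(x, "x")
  if (is.null(weights)) weights <- rep(1, length(x))
  pars <- c("A", "B", "C", "D")
  if (length(fixed) && !all(names(fixed) %in% pars)) {
    stop("`fixed` may only name A, B, C, D", call. = FALSE)
  }
  free <- setdiff(pars, names(fixed))
  n_distinct <- length(unique(x))
  if (n_distinct < length(free)) {
    stop("need at least as many distinct concentrations as free parameters",
         call. = FALSE)
  }

  out <- list(
    estimates = c(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_),
    se = c(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_),
    fixed = fixed, converged = FALSE, rss = NA_real_, sigma = NA_real_,
    n = length(x), fitted = rep(NA_real_, length(x))
  )
  class(out) <- "hill_fit"

  if (stats::sd(y) == 0 && !("C" %in% names(fixed))) {
    # degenerate: flat response carries no information about the midpoint
    return(out)
  }

  # means per concentration, used for initialization only
  ord <- order(x)
  ybar <- tapply(y, x, mean)
  xu <- as.numeric(names(ybar))
  o <- order(xu); xu <- xu[o]; ybar <- as.numeric(ybar)[o]

  lo <- c(A = -Inf, B = -Inf, C = log(min(x) / 100), D = 0.1)
  hi <- c(A = Inf, B = Inf, C = log(max(x) * 100), D = 10)

  A0 <- if ("A" %in% names(fixed)) fixed$A else ybar[1L]
  B0 <- if ("B" %in% names(fixed)) fixed$B else ybar[length(ybar)]
  D0 <- if ("D" %in% names(fixed)) fixed$D else 1
  C_starts <- if ("C" %in% names(fixed)) {
    fixed$C
  } else {
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  }

  model <- function(p) {
    # p: named full parameter set on internal scale (C stored as logC)
    hill_response(x, p[["A"]], p[["B"]], exp(p[["C"]]), p[["D"]])
  }
  objective <- function(theta, template) {
    template[free] <- theta
    r <- y - model(template)
    sum(weights * r * r)
  }

  template <- c(A = A0, B = B0, C = log(C_starts[1L]), D = D0)
  if ("C" %in% names(fixed)) template[["C"]] <- log(fixed$C)
  for (nm in names(fixed)) if (nm != "C") template[[nm]] <- fixed[[nm]]

  best <- NULL
  for (C0 in C_starts) {
    start <- template
    start[["C"]] <- log(C0)
    fit <- try(stats::optim(start[free], objective, template = template,
                            method = "L-BFGS-B",
                            lower = lo[free], upper = hi[free],
                            control = list(maxit = 1000, factr = 1,
                                           pgtol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(out)

  theta <- gauss_newton_polish(best$par, template, free, model, y, weights,
                               lo, hi)
  full <- template
  full[free] <- theta
  est <- c(A = full[["A"]], B = full[["B"]], C = exp(full[["C"]]),
           D = full[["D"]])
  fitted <- model(full)
  rss <- best$value
  dof <- length(x) - length(free)
  sigma <- if (dof > 0) sqrt(rss / dof) else NA_real_

  # SEs via the Jacobian of the model wrt the free parameters (natural scale)
  se <- c(A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_)
  if (dof > 0 && is.finite(sigma) && sigma >= 0) {
    J <- matrix(0, length(x), length(free))
    eps <- pmax(abs(est[free]), 1e-6) * 1e-6
    for (j in seq_along(free)) {
      pj <- est
      pj[free[j]] <- pj[free[j]] + eps[j]
      fj <- hill_response(x, pj[["A"]], pj[["B"]], pj[["C"]], pj[["D"]])
      J[, j] <- (fj - fitted) / eps[j]
    }
    XtX <- crossprod(J * sqrt(weights))
    cv <- try(solve(XtX), silent = TRUE)
    if (!inherits(cv, "try-error")) {
      se[free] <- sigma * sqrt(pmax(diag(cv), 0))
    }
  }

  out$estimates <- est
  out$se <- se
  out$converged <- best$convergence == 0 && est[["C"]] > 0
  out$rss <- rss
  out$sigma <- sigma
  out$fitted <- fitted
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit: y = A + (B - A)/(1 + (C/x)^D)\n")
  if (!x$converged) cat("  ** did not converge **\n")
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %s = %.6g", nm, est[[nm]]))
    if (nm %in% names(x$fixed)) {
      cat("  (fixed)")
    } else if (is.finite(x$se[[nm]])) {
      cat(sprintf("  (SE %.3g)", x$se[[nm]]))
    }
    cat("\n")
  }
  cat(sprintf("  residual SD %.4g on %d observations\n", x$sigma, x$n))
  invisible(x)
}

## Damped Gauss-Newton refinement of the L-BFGS-B solution; near the optimum
## this converges quadratically, which matters for exact recovery on
## noise-free data. Steps are clipped to the box constraints.
gauss_newton_polish <- function(theta, template, free, model, y, weights,
                                lo, hi, iter = 20) {
  rss_of <- function(th) {
    template[free] <- th
    r <- y - model(template)
    sum(weights * r * r)
  }
  rss <- rss_of(theta)
  for (it in seq_len(iter)) {
    template[free] <- theta
    f0 <- model(template)
    r <- y - f0
    J <- matrix(0, length(y), length(free))
    eps <- pmax(abs(theta), 1e-8) * 1e-7
    for (j in seq_along(free)) {
      tj <- theta
      tj[j] <- tj[j] + eps[j]
      template[free] <- tj
      J[, j] <- (model(template) - f0) / eps[j]
    }
    JW <- J * weights
    step <- tryCatch(solve(crossprod(J, JW) +
                             diag(1e-12, length(free)),
                           crossprod(JW, r)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:8) {
      cand <- pmin(pmax(theta + lambda * drop(step), lo[free]), hi[free])
      rss_new <- rss_of(cand)
      if (is.finite(rss_new) && rss_new < rss) {
        theta <- cand
        rss <- rss_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 4
    }
    if (!improved) break
  }
  theta
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` where `L` is the radioligand concentration used
#' in the competition assay and `Kd` its affinity for the receptor.
#'
#' @param ic50 half-maximal inhibitory concentration (nM).
#' @param L radioligand concentration (nM, >= 0).
#' @param Kd radioligand equilibrium dissociation constant (nM, > 0).
#' @return Ki in nM.
#' @export
cheng_prusoff <- function(ic50, L, Kd) {
  stop_if_not_positive(ic50, "ic50")
  stop_if_not_positive(Kd, "Kd")
  if (any(L < 0)) stop("`L` must be >= 0", call. = FALSE)
  ic50 / (1 + L / Kd)
}

#' Percent modulation of a control current
#'
#' Ratio-based modulation used for two-electrode voltage-clamp data:
#' `100 * (test / control - 1)`. Negative values indicate inhibition
#' (negative allosteric modulation), positive values potentiation.
#'
#' @param control_current amplitude without test compound (> 0).
#' @param test_current amplitude in the presence of the test compound.
#' @return percent change of the GABA-evoked current.
#' @export
modulation_percent <- function(control_current, test_current) {
  stop_if_not_positive(control_current, "control_current")
  100 * (test_current / control_current - 1)
}

#' Fold-selectivity ratios between receptor subtypes
#'
#' For each non-reference subtype, `ratio = Ki_subtype / Ki_reference`.
#' Subtypes whose affinity is only bounded ("no binding above X nM") enter as
#' lower-bound ratios `X / Ki_reference` and are flagged censored; the
#' minimum ratio is reported over all subtypes.
#'
#' @param ki named numeric vector of Ki values (nM), including the reference.
#' @param reference name of the reference subtype.
#' @param censored optional named numeric vector of no-binding concentration
#'   bounds (nM) for subtypes without a measurable Ki.
#' @return list with `ratios` (named), `censored` (logical, parallel to
#'   `ratios`) and `min_ratio`.
#' @export
fold_selectivity <- function(ki, reference, censored = NULL) {
  if (!reference %in% names(ki)) {
    stop("reference subtype not present in `ki`", call. = FALSE)
  }
  stop_if_not_positive(ki, "ki")
  ref <- ki[[reference]]
  others <- ki[setdiff(names(ki), reference)]
  ratios <- others / ref
  cens <- rep(FALSE, length(ratios))
  names(cens) <- names(ratios)
  if (length(censored)) {
    stop_if_not_positive(censored, "censored")
    bound <- censored / ref
    ratios <- c(ratios, bound)
    cens <- c(cens, stats::setNames(rep(TRUE, length(bound)), names(bound)))
  }
  list(ratios = ratios, censored = cens,
       min_ratio = if (length(ratios)) min(ratios) else NA_real_)
}
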