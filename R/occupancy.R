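## Ex vivo autoradiography occupancy quantification and exposure-occupancy
## model fitting.

#' Specific binding from an autoradiography cohort
#'
#' The non-displaceable component (binding to off-target receptor subtypes
#' plus classical nonspecific binding) is estimated as the mean signal of the
#' full-block ("blocker") cohort in the same brain region, and subtracted
#' from every other animal's signal: `S = signal - mean(blocker signals)`.
#' Negative `S` can arise from measurement noise and is kept but flagged.
#'
#' @param cohort data.frame with columns `animal_id`, `treatment`
#'   (`"vehicle"`, `"blocker"`, or a drug dose label), `region`,
#'   `signal_fmol_mg`, and optionally `plasma_ng_ml`.
#' @param region brain region to quantify.
#' @return list with `S` (data.frame: animal_id, treatment, S, plasma_ng_ml),
#'   `nonspecific` (blocker mean), `vehicle_mean` (mean S of vehicle
#'   animals) and `negative_flagged` (logical vector along `S`).
#' @export
specific_binding <- function(cohort, region) {
  stopifnot(all(c("animal_id", "treatment", "region",
                  "signal_fmol_mg") %in% names(cohort)))
  rec <- cohort[cohort$region == region, , drop = FALSE]
  blk <- rec$signal_fmol_mg[rec$treatment == "blocker"]
  veh <- rec$treatment == "vehicle"
  if (!length(blk)) {
    stop("no blocker (full-block) animals in region '", region,
         "': nonspecific binding cannot be estimated", call. = FALSE)
  }
  if (!any(veh)) {
    stop("no vehicle animals in region '", region, "'", call. = FALSE)
  }
  ns <- mean(blk)
  keep <- rec$treatment != "blocker"
  S <- rec$signal_fmol_mg[keep] - ns
  out <- data.frame(
    animal_id = rec$animal_id[keep],
    treatment = rec$treatment[keep],
    S = S,
    plasma_ng_ml = if ("plasma_ng_ml" %in% names(rec)) {
      rec$plasma_ng_ml[keep]
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
  list(S = out, nonspecific = ns,
       vehicle_mean = mean(out$S[out$treatment == "vehicle"]),
       negative_flagged = out$S < 0)
}

#' Percent receptor occupancy from specific binding
#'
#' `y = 100 * (1 - S_drug / S_vehicle_mean)`. Values outside `[0, 100]`
#' (possible with noisy data) are returned unclipped.
#'
#' @param S_drug specific binding of drug-treated animals (fmol/mg).
#' @param S_vehicle_mean mean specific binding of the vehicle group (> 0).
#' @return percent occupancy.
#' @export
percent_occupancy <- function(S_drug, S_vehicle_mean) {
  if (!is.finite(S_vehicle_mean) || S_vehicle_mean <= 0) {
    stop("`S_vehicle_mean` must be > 0", call. = FALSE)
  }
  100 * (1 - S_drug / S_vehicle_mean)
}

#' Fit occupancy versus plasma concentration (Hill with D = 1)
#'
#' Hill fit of percent occupancy against individual plasma concentration with
#' floor `A = 0` and Hill coefficient `D = 1` fixed; the asymptotic maximum
#' `B` is free and may stay below 100% when the radioligand is not fully
#' subtype-selective.
#'
#' @param plasma plasma concentrations (ng/mL, > 0), one per animal.
#' @param occupancy percent occupancies, same length.
#' @param rescale_to_asymptote if `TRUE` (the rat-study convention) the
#'   returned `occupancy_rescaled` expresses each occupancy as a fraction of
#'   the fitted asymptote `B`, treating the asymptote as 100% of the
#'   drug-accessible sites.
#' @return a `hill_fit` (see [fit_hill()]) with extra fields `EC50`
#'   (alias of `C`) and optionally `occupancy_rescaled`.
#' @export
fit_occupancy_vs_plasma <- function(plasma, occupancy,
                                    rescale_to_asymptote = TRUE) {
  if (length(unique(plasma)) < 3L) {
    stop("need >= 3 distinct plasma levels", call. = FALSE)
  }
  fit <- fit_hill(plasma, occupancy, fixed = list(A = 0, D = 1))
  fit$EC50 <- fit$estimates[["C"]]
  if (rescale_to_asymptote && fit$converged && fit$estimates[["B"]] > 0) {
    fit$occupancy_rescaled <- 100 * occupancy / fit$estimates[["B"]]
  }
  fit
}

#' Convert a total plasma concentration to a free molar concentration
#'
#' `free_nM = conc_ng_ml * 1000 / MW * free_fraction`, i.e. ng/mL to nM via
#' the molecular weight, then scaled by the unbound (free) fraction measured
#' in plasma-protein-binding assays.
#'
#' @param conc_ng_ml total plasma concentration (ng/mL, >= 0).
#' @param mw molecular weight (g/mol, > 0).
#' @param free_fraction unbound fraction in plasma, in (0, 1].
#' @return free concentration in nM.
#' @export
total_to_free_nM <- function(conc_ng_ml, mw, free_fraction) {
  if (any(conc_ng_ml < 0)) stop("`conc_ng_ml` must be >= 0", call. = FALSE)
  stop_if_not_positive(mw, "mw")
  if (free_fraction <= 0 || free_fraction > 1) {
    stop("`free_fraction` must be in (0, 1]", call. = FALSE)
  }
  conc_ng_ml * 1000 / mw * free_fraction
}

#' Fit an Emax exposure-occupancy model
#'
#' `E = Emax * C / (EC50 + C)` fitted by least squares, with 95%
#' profile-likelihood confidence intervals for both parameters. For a fixed
#' EC50 the model is linear in Emax, so the profile is computed exactly.
#'
#' @param conc plasma concentrations (> 0).
#' @param occupancy occupancies (fraction or percent; the Emax estimate is on
#'   the same scale as the input).
#' @param fix_emax optional value to hold Emax at (e.g. `1` or `100`).
#' @param level confidence level for the profile intervals.
#' @return list of class `emax_fit` with `Emax`, `EC50`, `ci` (2 x 2 matrix),
#'   `rss`, `sigma`, `converged`, `wide_ci` flag and `fitted`.
#' @export
fit_emax <- function(conc, occupancy, fix_emax = NULL, level = 0.95) {
  stopifnot(length(conc) == length(occupancy), length(conc) >= 3L)
  stop_if_not_positive(conc, "conc")
  n <- length(conc)

  prof <- function(log_ec50) {
    g <- conc / (exp(log_ec50) + conc)
    emax <- if (is.null(fix_emax)) sum(occupancy * g) / sum(g * g) else fix_emax
    c(rss = sum((occupancy - emax * g)^2), emax = emax)
  }
  grid <- seq(log(min(conc) / 100), log(max(conc) * 100), length.out = 200)
  rss_grid <- vapply(grid, function(l) prof(l)[["rss"]], 0)
  i0 <- which.min(rss_grid)
  opt <- stats::optimize(function(l) prof(l)[["rss"]],
                         interval = grid[c(max(1, i0 - 1), min(length(grid), i0 + 1))],
                         tol = 1e-12)
  log_ec50 <- opt$minimum
  at <- prof(log_ec50)
  emax <- at[["emax"]]
  ec50 <- exp(log_ec50)
  rss <- at[["rss"]]
  p <- if (is.null(fix_emax)) 2L else 1L
  dof <- n - p
  sigma <- if (dof > 0) sqrt(rss / dof) else NA_real_

  # profile-likelihood CI: RSS(theta) <= RSS_min * (1 + F(level;1,dof)/dof)
  ci <- matrix(NA_real_, 2, 2,
               dimnames = list(c("Emax", "EC50"), c("lower", "upper")))
  wide <- FALSE
  if (dof > 0) {
    cut <- rss * (1 + stats::qf(level, 1, dof) / dof)
    inside <- rss_grid <= cut
    idx <- which(inside)
    if (length(idx)) {
      ci["EC50", ] <- exp(range(grid[idx]))
      wide <- idx[1L] == 1L || idx[length(idx)] == length(grid)
    }
    if (is.null(fix_emax)) {
      g <- conc / (ec50 + conc)
      se_emax <- sigma / sqrt(sum(g * g))
      tq <- stats::qt(1 - (1 - level) / 2, dof)
      ci["Emax", ] <- emax + c(-1, 1) * tq * se_emax
    }
  }
  out <- list(Emax = emax, EC50 = ec50, ci = ci, rss = rss, sigma = sigma,
              converged = is.finite(ec50) && ec50 > 0, wide_ci = wide,
              fitted = emax * conc / (ec50 + conc), n = n)
  class(out) <- "emax_fit"
  out
}

#' @export
print.emax_fit <- function(x, ...) {
  cat(sprintf("Emax model: E = Emax * C/(EC50 + C)\n  Emax = %.4g  EC50 = %.4g\n",
              x$Emax, x$EC50))
  cat(sprintf("  95%% profile CI for EC50: [%.4g, %.4g]%s\n",
              x$ci["EC50", 1], x$ci["EC50", 2],
              if (x$wide_ci) "  (poorly bounded)" else ""))
  invisible(x)
}

#' Occupancy from binding-potential reduction
#'
#' Fractional reduction of the non-displaceable binding potential between a
#' baseline and a post-dose scan:
#' `Occ = (BP_baseline - BP_drug) / BP_baseline`.
#'
#' @param bp_baseline baseline BP_ND (> 0).
#' @param bp_drug post-dose BP_ND.
#' @return occupancy fraction.
#' @export
occupancy_from_bp <- function(bp_baseline, bp_drug) {
  if (any(!is.finite(bp_baseline)) || any(bp_baseline <= 0)) {
    stop("`bp_baseline` must be > 0", call. = FALSE)
  }
  (bp_baseline - bp_drug) / bp_baseline
}
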