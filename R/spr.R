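#' Kinetic parameters of the two-site (heterogeneous-ligand) model
#'
#' The heterogeneous-ligand SPR model treats the immobilized partner
#' (A-beta-40) as two independent classes of binding sites, each with its
#' own association rate `ka_i` (1/M/s), dissociation rate `kd_i` (1/s) and
#' equilibrium dissociation constant `KD_i = kd_i/ka_i` (M). By convention
#' site 1 is the higher-affinity class (`KD1 <= KD2`); parameters are
#' relabelled to honour it.
#'
#' @param ka1,ka2 Association rate constants, 1/M/s, positive.
#' @param kd1,kd2 Dissociation rate constants, 1/s, positive.
#' @param sd Optional named numeric of per-parameter standard deviations.
#' @param relabel Enforce the `KD1 <= KD2` convention by swapping site
#'   labels if needed (default `TRUE`).
#' @return An object of class `kinetic_params` with elements `ka1`, `kd1`,
#'   `ka2`, `kd2`, `KD1`, `KD2` and optionally `sd`.
#' @export
#' @examples
#' kp <- kinetic_params(ka1 = 2.7e2, kd1 = 0.216e-4,
#'                      ka2 = 8.9e2, kd2 = 26e-4)
#' kp$KD1  # 8e-08
kinetic_params <- function(ka1, kd1, ka2, kd2, sd = NULL, relabel = TRUE) {
  for (nm in c("ka1", "kd1", "ka2", "kd2")) {
    check_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  KD1 <- kd1 / ka1
  KD2 <- kd2 / ka2
  if (relabel && KD1 > KD2) {
    tmp <- c(ka1, kd1, KD1)
    ka1 <- ka2; kd1 <- kd2; KD1 <- KD2
    ka2 <- tmp[1]; kd2 <- tmp[2]; KD2 <- tmp[3]
    if (!is.null(sd)) {
      swp <- sd
      nm1 <- grep("1$", names(sd), value = TRUE)
      for (a in nm1) {
        b <- sub("1$", "2", a)
        if (b %in% names(sd)) { swp[a] <- sd[b]; swp[b] <- sd[a] }
      }
      sd <- swp
    }
  }
  structure(list(ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2,
                 KD1 = KD1, KD2 = KD2, sd = sd),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-site kinetic parameters (site 1 = higher affinity):\n")
  cat(sprintf("  site 1: ka = %.3g 1/M/s, kd = %.3g 1/s, KD = %.3g M\n",
              x$ka1, x$kd1, x$KD1))
  cat(sprintf("  site 2: ka = %.3g 1/M/s, kd = %.3g 1/s, KD = %.3g M\n",
              x$ka2, x$kd2, x$KD2))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (inherits(x, "spr_fit")) {
    est <- x$estimates
    # averaged KD columns are carried through unchanged (they are averages
    # of per-concentration ratios, not ratios of the averaged rates)
    kp <- kinetic_params(est[["ka1"]], est[["kd1"]], est[["ka2"]],
                         est[["kd2"]], sd = x$sds, relabel = FALSE)
    kp$KD1 <- est[["KD1"]]
    kp$KD2 <- est[["KD2"]]
    return(kp)
  }
  stopf("cannot interpret object of class '%s' as kinetic parameters",
        paste(class(x), collapse = "/"))
}

#' Construct a sensorgram
#'
#' A surface-plasmon-resonance time series: response (RU) against time (s)
#' at one analyte concentration, with an association phase on
#' `[0, t_assoc]` followed by a dissociation phase.
#'
#' @param times Strictly increasing times, s.
#' @param response Response, RU, same length as `times`.
#' @param conc Analyte concentration, M.
#' @param t_assoc Association/dissociation phase boundary, s.
#' @return A `data.frame` of class `sensorgram` with columns `time` and
#'   `response` and attributes `conc` and `t_assoc`.
#' @export
sensorgram <- function(times, response, conc, t_assoc) {
  if (length(times) != length(response)) {
    stopf("'times' and 'response' lengths differ")
  }
  if (any(diff(times) <= 0)) stopf("'times' must be strictly increasing")
  check_number(conc, "conc", min = 0)
  check_number(t_assoc, "t_assoc", min = min(times), max = max(times))
  if (any(!is.finite(response))) stopf("'response' must be finite")
  structure(data.frame(time = times, response = response),
            conc = conc, t_assoc = t_assoc,
            class = c("sensorgram", "data.frame"))
}

#' @export
plot.sensorgram <- function(x, ...) {
  plot(x$time, x$response, type = "l", xlab = "time (s)",
       ylab = "response (RU)",
       main = sprintf("Sensorgram, analyte %.3g M", attr(x, "conc")), ...)
  abline(v = attr(x, "t_assoc"), lty = 3)
  invisible(x)
}

# Closed-form response of one site class; vectorised over time.
# Association: R(t) = Rmax * kaC/(kaC + kd) * (1 - exp(-(kaC + kd) t));
# dissociation: exponential decay at kd from the level reached at t_assoc.
one_site_response <- function(times, t_assoc, ka, kd, rmax, conc) {
  kobs <- ka * conc + kd
  req <- if (kobs > 0) rmax * ka * conc / kobs else 0
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(times <= t_assoc,
         req * (1 - exp(-kobs * times)),
         r_end * exp(-kd * (times - t_assoc)))
}

two_site_response <- function(times, t_assoc, ka1, kd1, ka2, kd2,
                              rmax1, rmax2, conc) {
  one_site_response(times, t_assoc, ka1, kd1, rmax1, conc) +
    one_site_response(times, t_assoc, ka2, kd2, rmax2, conc)
}

#' Simulate a noiseless two-site sensorgram
#'
#' Evaluates the closed-form response of the heterogeneous-ligand model:
#' two independent site classes binding the analyte pseudo-first-order at
#' constant analyte concentration. During association each class rises as
#' `Rmax_i * ka_i*C/(ka_i*C + kd_i) * (1 - exp(-(ka_i*C + kd_i) t))`;
#' after `t_assoc` each decays as `exp(-kd_i (t - t_assoc))`. The total
#' response is the sum over the two classes.
#'
#' @param kp A [kinetic_params()] object.
#' @param rmax1,rmax2 Response capacity of each site class, RU.
#' @param conc Analyte concentration, M.
#' @param times Sampling times, s.
#' @param t_assoc Association-phase end, s.
#' @return A [sensorgram()].
#' @export
simulate_sensorgram <- function(kp, rmax1, rmax2, conc,
                                times = seq(0, 2700), t_assoc = 300) {
  kp <- as_kinetic_params(kp)
  check_number(rmax1, "rmax1", min = 0)
  check_number(rmax2, "rmax2", min = 0)
  check_number(conc, "conc", min = 0)
  resp <- two_site_response(times, t_assoc, kp$ka1, kp$kd1, kp$ka2, kp$kd2,
                            rmax1, rmax2, conc)
  sensorgram(times, resp, conc, t_assoc)
}

#' Subtract a blank sensorgram (baseline / non-specific binding)
#'
#' Pointwise subtraction of a blank (buffer or reference-channel) trace
#' from a sensorgram. Time grids must match unless `interpolate = TRUE`,
#' in which case the blank is linearly interpolated onto the sensorgram's
#' grid.
#'
#' @param sg,blank [sensorgram()] objects.
#' @param interpolate Allow linear interpolation of the blank?
#' @return The corrected [sensorgram()] (metadata of `sg` preserved).
#' @export
baseline_correct <- function(sg, blank, interpolate = FALSE) {
  stopifnot(inherits(sg, "sensorgram"), inherits(blank, "sensorgram"))
  if (isTRUE(all.equal(sg$time, blank$time))) {
    b <- blank$response
  } else if (interpolate) {
    b <- approx(blank$time, blank$response, xout = sg$time, rule = 2)$y
  } else {
    stopf("time grids differ; set interpolate = TRUE to resample the blank")
  }
  sensorgram(sg$time, sg$response - b, attr(sg, "conc"), attr(sg, "t_assoc"))
}

# ---- fitting -------------------------------------------------------------

# Default multi-start grid over log-spaced rates; biexponential fits are
# initialisation-sensitive, so every fit tries each start and keeps the
# best-residual solution (stopping early once a start reaches the data to
# numerical precision).
default_starts <- function() {
  pairs <- expand.grid(ka = 10^c(1, 3, 5), kd = 10^c(-5, -3, -1))
  combos <- expand.grid(i = seq_len(nrow(pairs)), j = seq_len(nrow(pairs)))
  kd_over_ka <- pairs$kd / pairs$ka
  combos <- combos[kd_over_ka[combos$i] <= kd_over_ka[combos$j], ]
  lapply(seq_len(nrow(combos)), function(r) {
    c(ka1 = pairs$ka[combos$i[r]], kd1 = pairs$kd[combos$i[r]],
      ka2 = pairs$ka[combos$j[r]], kd2 = pairs$kd[combos$j[r]])
  })
}

fit_one_sensorgram <- function(sg, starts = default_starts(),
                               lower = c(ka1 = 1e-2, kd1 = 1e-8,
                                         ka2 = 1e-2, kd2 = 1e-8,
                                         rmax1 = 1e-4, rmax2 = 1e-4),
                               upper = c(ka1 = 1e9, kd1 = 10,
                                         ka2 = 1e9, kd2 = 10,
                                         rmax1 = 1e6, rmax2 = 1e6)) {
  conc <- attr(sg, "conc")
  t_assoc <- attr(sg, "t_assoc")
  y <- sg$response
  tt <- sg$time
  resid_fun <- function(lp) {
    p <- 10^lp
    two_site_response(tt, t_assoc, p[1], p[2], p[3], p[4], p[5], p[6],
                      conc) - y
  }
  rmax0 <- max(max(y), 1) * 0.6
  tol_rss <- 1e-12 * max(1, sum(y^2))
  best <- NULL
  for (st in starts) {
    lp0 <- log10(c(st[["ka1"]], st[["kd1"]], st[["ka2"]], st[["kd2"]],
                   rmax0, rmax0))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = lp0, fn = resid_fun,
        lower = log10(lower), upper = log10(upper),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance <= tol_rss) break
  }
  if (is.null(best)) {
    stopf("two-site fit failed to converge from any start (conc = %.3g M)",
          conc)
  }
  p <- 10^best$par
  names(p) <- c("ka1", "kd1", "ka2", "kd2", "rmax1", "rmax2")
  # canonical site labels: site 1 = higher affinity
  if (p[["kd1"]] / p[["ka1"]] > p[["kd2"]] / p[["ka2"]]) {
    p <- p[c("ka2", "kd2", "ka1", "kd1", "rmax2", "rmax1")]
    names(p) <- c("ka1", "kd1", "ka2", "kd2", "rmax1", "rmax2")
  }
  c(p, KD1 = p[["kd1"]] / p[["ka1"]], KD2 = p[["kd2"]] / p[["ka2"]],
    rss = best$deviance)
}

#' Fit the heterogeneous-ligand model to sensorgrams
#'
#' Fits the two-site closed-form model to each sensorgram independently by
#' bounded nonlinear least squares over `(ka1, kd1, ka2, kd2, rmax1,
#' rmax2)` (Levenberg-Marquardt in log-parameter space, multi-start from a
#' log-spaced grid of rate constants), then averages the per-concentration
#' estimates arithmetically and reports their standard deviations. `KD_i`
#' is computed per fit as `kd_i/ka_i` and then averaged, so the averaged
#' `KD` columns are averages of ratios, not ratios of the averaged rates --
#' matching how per-concentration SPR estimates are conventionally pooled.
#'
#' @param sensorgrams A [sensorgram()] or list of them (typically one per
#'   analyte concentration).
#' @param starts Optional list of named start vectors `(ka1, kd1, ka2,
#'   kd2)`; default is a log-spaced grid with `KD1 <= KD2`.
#' @param global Experimental: if `TRUE`, fit all sensorgrams jointly with
#'   shared rates and per-curve `Rmax` (not the per-concentration-averaging
#'   protocol; off by default).
#' @return An object of class `spr_fit` with elements `per_conc`
#'   (data.frame of per-sensorgram estimates), `estimates` (averaged named
#'   vector), `sds`, and the input sensorgrams. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @export
#' @examples
#' kp <- kinetic_params(1e3, 1e-3, 1e4, 1e-2)
#' sg <- simulate_sensorgram(kp, 60, 40, 1e-5, seq(0, 900, 2), 300)
#' fit <- fit_heterogeneous(sg)
#' coef(fit)[c("KD1", "KD2")]
fit_heterogeneous <- function(sensorgrams, starts = default_starts(),
                              global = FALSE) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  if (length(sensorgrams) < 1L) stopf("need at least one sensorgram")
  lapply(sensorgrams, function(s) stopifnot(inherits(s, "sensorgram")))
  if (global) return(fit_heterogeneous_global(sensorgrams, starts))
  per <- lapply(sensorgrams, fit_one_sensorgram, starts = starts)
  per_conc <- data.frame(
    conc = vapply(sensorgrams, attr, numeric(1), "conc"),
    do.call(rbind, per)
  )
  par_cols <- c("ka1", "kd1", "KD1", "ka2", "kd2", "KD2", "rmax1", "rmax2")
  est <- vapply(par_cols, function(cn) mean(per_conc[[cn]]), numeric(1))
  sds <- vapply(par_cols, function(cn)
    if (nrow(per_conc) > 1L) sd(per_conc[[cn]]) else NA_real_, numeric(1))
  structure(
    list(per_conc = per_conc, estimates = est, sds = sds,
         sensorgrams = sensorgrams, global = FALSE),
    class = "spr_fit"
  )
}

# Joint fit with shared rates and per-curve Rmax; provided for comparison
# only -- the screen's protocol is per-concentration fitting + averaging.
fit_heterogeneous_global <- function(sensorgrams, starts) {
  nsg <- length(sensorgrams)
  y <- unlist(lapply(sensorgrams, `[[`, "response"))
  resid_fun <- function(lp) {
    p <- 10^lp
    unlist(lapply(seq_len(nsg), function(i) {
      sg <- sensorgrams[[i]]
      two_site_response(sg$time, attr(sg, "t_assoc"),
                        p[1], p[2], p[3], p[4],
                        p[4 + i], p[4 + nsg + i],
                        attr(sg, "conc")) - sg$response
    }))
  }
  rmax0 <- max(vapply(sensorgrams, function(s) max(s$response), numeric(1)))
  best <- NULL
  tol_rss <- 1e-12 * max(1, sum(y^2))
  for (st in starts) {
    lp0 <- log10(c(st[["ka1"]], st[["kd1"]], st[["ka2"]], st[["kd2"]],
                   rep(rmax0 * 0.6, 2L * nsg)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = lp0, fn = resid_fun,
                         lower = c(log10(c(1e-2, 1e-8, 1e-2, 1e-8)),
                                   rep(-4, 2L * nsg)),
                         upper = c(log10(c(1e9, 10, 1e9, 10)),
                                   rep(6, 2L * nsg)),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance <= tol_rss) break
  }
  if (is.null(best)) stopf("global two-site fit failed to converge")
  p <- 10^best$par[1:4]
  names(p) <- c("ka1", "kd1", "ka2", "kd2")
  if (p[["kd1"]] / p[["ka1"]] > p[["kd2"]] / p[["ka2"]]) {
    p <- p[c("ka2", "kd2", "ka1", "kd1")]
    names(p) <- c("ka1", "kd1", "ka2", "kd2")
  }
  est <- c(p, KD1 = p[["kd1"]] / p[["ka1"]], KD2 = p[["kd2"]] / p[["ka2"]])
  structure(
    list(per_conc = NULL, estimates = est,
         sds = setNames(rep(NA_real_, length(est)), names(est)),
         sensorgrams = sensorgrams, global = TRUE, rss = best$deviance),
    class = "spr_fit"
  )
}

#' @export
coef.spr_fit <- function(object, ...) object$estimates

#' @export
print.spr_fit <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("Heterogeneous-ligand SPR fit (%s, %d sensorgram%s)\n",
              if (x$global) "global" else "per-concentration averaged",
              length(x$sensorgrams),
              if (length(x$sensorgrams) > 1L) "s" else ""))
  fmt <- function(nm) {
    s <- x$sds[[nm]]
    if (is.null(s) || is.na(s)) sprintf("%.3g", est[[nm]])
    else sprintf("%.3g +/- %.2g", est[[nm]], s)
  }
  cat("  site 1: ka =", fmt("ka1"), "1/M/s, kd =", fmt("kd1"),
      "1/s, KD =", fmt("KD1"), "M\n")
  cat("  site 2: ka =", fmt("ka2"), "1/M/s, kd =", fmt("kd2"),
      "1/s, KD =", fmt("KD2"), "M\n")
  invisible(x)
}

#' @export
summary.spr_fit <- function(object, ...) {
  out <- list(per_conc = object$per_conc,
              estimates = object$estimates, sds = object$sds,
              dG = c(site1 = free_energy(object$estimates[["KD1"]]),
                     site2 = free_energy(object$estimates[["KD2"]])))
  class(out) <- "summary.spr_fit"
  out
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  if (!is.null(x$per_conc)) {
    cat("Per-concentration estimates:\n")
    print(format(x$per_conc, digits = 3), row.names = FALSE)
  }
  cat("\nAveraged parameters (+/- sd over concentrations):\n")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    sd = signif(x$sds, 3))
  print(tab)
  cat(sprintf("\nBinding free energy at 298.15 K: dG1 = %.1f, dG2 = %.1f kJ/mol\n",
              x$dG[["site1"]], x$dG[["site2"]]))
  invisible(x)
}

#' @export
predict.spr_fit <- function(object, times = NULL, conc = NULL,
                            t_assoc = NULL, ...) {
  est <- object$estimates
  sg1 <- object$sensorgrams[[1L]]
  if (is.null(times)) times <- sg1$time
  if (is.null(conc)) conc <- attr(sg1, "conc")
  if (is.null(t_assoc)) t_assoc <- attr(sg1, "t_assoc")
  rmax1 <- if ("rmax1" %in% names(est)) est[["rmax1"]] else 100
  rmax2 <- if ("rmax2" %in% names(est)) est[["rmax2"]] else 100
  two_site_response(times, t_assoc, est[["ka1"]], est[["kd1"]],
                    est[["ka2"]], est[["kd2"]], rmax1, rmax2, conc)
}

#' @export
residuals.spr_fit <- function(object, ...) {
  if (object$global || is.null(object$per_conc)) {
    stopf("per-curve residuals are only available for per-concentration fits")
  }
  lapply(seq_along(object$sensorgrams), function(i) {
    sg <- object$sensorgrams[[i]]
    p <- object$per_conc[i, ]
    sg$response - two_site_response(sg$time, attr(sg, "t_assoc"),
                                    p$ka1, p$kd1, p$ka2, p$kd2,
                                    p$rmax1, p$rmax2, attr(sg, "conc"))
  })
}

#' @export
plot.spr_fit <- function(x, ...) {
  cols <- seq_along(x$sensorgrams)
  ylim <- range(vapply(x$sensorgrams, function(s) range(s$response),
                       numeric(2)))
  sg1 <- x$sensorgrams[[1L]]
  plot(sg1$time, sg1$response, type = "n", ylim = ylim,
       xlab = "time (s)", ylab = "response (RU)",
       main = "Heterogeneous-ligand model fit", ...)
  for (i in cols) {
    sg <- x$sensorgrams[[i]]
    lines(sg$time, sg$response, col = "grey60")
    if (!is.null(x$per_conc)) {
      p <- x$per_conc[i, ]
      lines(sg$time,
            two_site_response(sg$time, attr(sg, "t_assoc"), p$ka1, p$kd1,
                              p$ka2, p$kd2, p$rmax1, p$rmax2,
                              attr(sg, "conc")),
            col = i, lty = 2)
    }
  }
  invisible(x)
}

#' @export
simulate.spr_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 1, ...) {
  est <- object$estimates
  kp <- kinetic_params(est[["ka1"]], est[["kd1"]], est[["ka2"]],
                       est[["kd2"]], relabel = FALSE)
  rmax1 <- if ("rmax1" %in% names(est)) est[["rmax1"]] else 100
  rmax2 <- if ("rmax2" %in% names(est)) est[["rmax2"]] else 100
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      sg <- object$sensorgrams[[(i - 1L) %% length(object$sensorgrams) + 1L]]
      out <- simulate_sensorgram(kp, rmax1, rmax2, attr(sg, "conc"),
                                 sg$time, attr(sg, "t_assoc"))
      out$response <- out$response + rnorm(nrow(out), sd = noise_sd)
      out
    })
  })
}

# ---- equilibrium & thermodynamics ---------------------------------------

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate constant, 1/M/s, positive.
#' @param kd Dissociation rate constant, 1/s.
#' @return `kd/ka`, in M.
#' @export
equilibrium_kd <- function(ka, kd) {
  if (any(ka <= 0)) stopf("'ka' must be positive")
  kd / ka
}

GAS_CONSTANT_KJ <- 8.314e-3   # kJ/mol/K
WATER_MOLARITY <- 55.3        # M, standard-state convention

#' Binding free energy from a dissociation constant
#'
#' `dG = -R*T*ln(55.3/KD)`, with 55.3 M the molar concentration of water
#' (the unitary standard-state convention); negative for favorable binding,
#' zero exactly at `KD = 55.3` M.
#'
#' @param KD Equilibrium dissociation constant, M, positive. Vectorised.
#' @param temperature Temperature, K (default 298.15, i.e. 25 C).
#' @param unit `"kJ"` (default) or `"kcal"` per mol.
#' @return Free energy change.
#' @export
#' @examples
#' free_energy(0.64e-7)  # about -51 kJ/mol
free_energy <- function(KD, temperature = 298.15, unit = c("kJ", "kcal")) {
  unit <- match.arg(unit)
  if (any(KD <= 0)) stopf("'KD' must be positive")
  check_number(temperature, "temperature", min = 0, strict_min = TRUE)
  dg <- -GAS_CONSTANT_KJ * temperature * log(WATER_MOLARITY / KD)
  if (unit == "kcal") dg <- dg / 4.184
  dg
}

#' Ligand-induced change in binding free energy
#'
#' For each site class, `ddG_i = dG_i(ligand) - dG_i(baseline) =
#' R*T*ln(KD_i^ligand / KD_i^baseline)`. Negative values mean the ligand
#' favors the interaction (tighter binding); the measure is antisymmetric
#' under swapping ligand and baseline.
#'
#' @param kp_ligand,kp_baseline [kinetic_params()] or [fit_heterogeneous()]
#'   objects for the ligand-treated and solvent-matched baseline conditions.
#' @param temperature Temperature, K.
#' @param unit `"kJ"` or `"kcal"` per mol.
#' @return Named numeric `c(site1 = , site2 = )`.
#' @export
delta_delta_g <- function(kp_ligand, kp_baseline, temperature = 298.15,
                          unit = c("kJ", "kcal")) {
  unit <- match.arg(unit)
  l <- as_kinetic_params(kp_ligand)
  b <- as_kinetic_params(kp_baseline)
  c(site1 = free_energy(l$KD1, temperature, unit) -
      free_energy(b$KD1, temperature, unit),
    site2 = free_energy(l$KD2, temperature, unit) -
      free_energy(b$KD2, temperature, unit))
}

#' Fold change in dissociation constants between conditions
#'
#' For each site class, the ratio `max(KD_ligand, KD_baseline) /
#' min(KD_ligand, KD_baseline)` with a direction flag: `"increase"` when
#' the ligand raises `KD` (weakens binding), `"decrease"` when it lowers it
#' (strengthens binding). The rounded column (half away from zero, nearest
#' integer) reproduces how such factors are quoted in prose.
#'
#' @inheritParams delta_delta_g
#' @return `data.frame` with `site`, `KD_ligand`, `KD_baseline`, `factor`,
#'   `factor_rounded`, `direction`.
#' @export
#' @examples
#' base <- kinetic_params(2.7e2, 0.216e-4, 8.9e2, 26e-4)
#' lig <- kinetic_params(2.73e2, 0.11e-4, 36e2, 13.6e-4)
#' fold_change(lig, base)
fold_change <- function(kp_ligand, kp_baseline) {
  l <- as_kinetic_params(kp_ligand)
  b <- as_kinetic_params(kp_baseline)
  kd_l <- c(l$KD1, l$KD2)
  kd_b <- c(b$KD1, b$KD2)
  fac <- pmax(kd_l, kd_b) / pmin(kd_l, kd_b)
  data.frame(
    site = 1:2,
    KD_ligand = kd_l, KD_baseline = kd_b,
    factor = fac,
    factor_rounded = round_half_up(fac),
    direction = ifelse(kd_l > kd_b, "increase",
                       ifelse(kd_l < kd_b, "decrease", "unchanged")),
    stringsAsFactors = FALSE
  )
}
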