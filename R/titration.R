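#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987e-3

#' ITC injection schedule
#'
#' Defaults mirror the titration protocol used throughout:
#' phosphoinositide headgroup at 0.5 mM in the syringe titrated into
#' 20 uM protein in 13 injections of 3.22 ul at 25 C. The cell volume of
#' the instrument class is 200 ul.
#'
#' @param n_injections Number of injections.
#' @param injection_volume_ul Volume per injection (ul).
#' @param syringe_conc_M Ligand concentration in the syringe (M).
#' @param cell_conc_M Macromolecule concentration in the cell (M).
#' @param cell_volume_ul Working cell volume (ul).
#' @param temperature_K Temperature (K).
#' @return List of class `itc_schedule`.
#' @export
itc_schedule <- function(n_injections = 13, injection_volume_ul = 3.22,
                         syringe_conc_M = 0.5e-3, cell_conc_M = 0.020e-3,
                         cell_volume_ul = 200, temperature_K = 298.15) {
  vals <- c(n_injections, injection_volume_ul, syringe_conc_M,
            cell_conc_M, cell_volume_ul, temperature_K)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all schedule parameters must be positive")
  structure(list(n_injections = as.integer(n_injections),
                 injection_volume_ul = injection_volume_ul,
                 syringe_conc_M = syringe_conc_M,
                 cell_conc_M = cell_conc_M,
                 cell_volume_ul = cell_volume_ul,
                 temperature_K = temperature_K),
            class = "itc_schedule")
}

#' 1:1 binding parameters
#' @param Kd Dissociation constant (M), positive.
#' @param dH Binding enthalpy (kcal/mol); negative for exothermic binding.
#' @param N Stoichiometry (sites per macromolecule), positive.
#' @return List of class `binding_params`.
#' @export
binding_params <- function(Kd, dH, N = 1) {
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be positive")
  if (!is.finite(dH)) stop("dH must be finite")
  if (!is.finite(N) || N <= 0) stop("N must be positive")
  structure(list(Kd = Kd, dH = dH, N = N), class = "binding_params")
}

# Bound-complex concentration from the 1:1 closed form.
.bound_complex <- function(Mt, Lt, Kd, N) {
  s <- Mt * N + Lt + Kd
  (s - sqrt(pmax(s^2 - 4 * Mt * N * Lt, 0))) / 2
}

# Cumulative cell concentrations after i injections, with optional
# perfusion-displacement bookkeeping (each injection displaces a fraction
# v/V0 of the cell contents).
.cumulative_concs <- function(schedule, displacement = TRUE,
                              initial_ligand_M = 0) {
  i <- 0:schedule$n_injections
  v <- schedule$injection_volume_ul
  V0 <- schedule$cell_volume_ul
  if (displacement) {
    d <- (1 - v / V0)^i
    Mt <- schedule$cell_conc_M * d
    Lt <- initial_ligand_M * d + schedule$syringe_conc_M * (1 - d)
  } else {
    Mt <- rep(schedule$cell_conc_M, length(i))
    Lt <- initial_ligand_M + schedule$syringe_conc_M * i * v / V0
  }
  list(Mt = Mt, Lt = Lt)
}

#' Simulate a single-site (Wiseman) ITC isotherm
#'
#' Computes the normalized heat per injection for a 1:1 binding model.
#' After each injection the total macromolecule and ligand concentrations
#' in the cell are updated with perfusion-displacement bookkeeping
#' (a fraction v/V0 of the cell contents is displaced per injection); the
#' bound-complex concentration follows the closed-form quadratic and the
#' heat of injection i is `dH * V0 * d[ML]_i / (moles injected)`, in kcal
#' per mole of injectant; in displacement mode `d[ML]_i` carries the
#' standard perfusion correction (complex leaving the cell in the
#' displaced volume releases no heat).
#'
#' @param params A [binding_params()].
#' @param schedule An [itc_schedule()].
#' @param displacement Use displacement bookkeeping (default); the
#'   simpler no-displacement mode supports closed-form cross-checks.
#' @param initial_ligand_M Ligand concentration already present in the
#'   cell before the first injection (used by the competition model).
#' @return Data frame of class `itc_isotherm` with columns `injection`,
#'   `molar_ratio` (cumulative ligand:protein), `heat` (kcal/mol of
#'   injectant); the schedule is attached as attribute `schedule`.
#' @export
simulate_isotherm <- function(params, schedule = itc_schedule(),
                              displacement = TRUE, initial_ligand_M = 0) {
  stopifnot(inherits(params, "binding_params"),
            inherits(schedule, "itc_schedule"))
  cc <- .cumulative_concs(schedule, displacement, initial_ligand_M)
  ml <- .bound_complex(cc$Mt, cc$Lt, params$Kd, params$N)
  inj_conc <- schedule$syringe_conc_M *
    schedule$injection_volume_ul / schedule$cell_volume_ul
  d_ml <- diff(ml)
  if (displacement) {
    # complex carried out in the displaced volume left the cell intact:
    # credit its heat content back (standard perfusion correction)
    frac <- schedule$injection_volume_ul / schedule$cell_volume_ul
    n1 <- length(ml)
    d_ml <- d_ml + frac * (ml[-1] + ml[-n1]) / 2
  }
  heat <- params$dH * d_ml / inj_conc
  out <- data.frame(injection = seq_len(schedule$n_injections),
                    molar_ratio = (cc$Lt / cc$Mt)[-1],
                    heat = heat)
  attr(out, "schedule") <- schedule
  class(out) <- c("itc_isotherm", "data.frame")
  out
}

#' Free energy and entropy from Kd and enthalpy
#'
#' `dG = R T ln(Kd)` (Kd in molar) and `dS = (dH - dG) / T`, so that
#' `dG = dH - T dS` holds exactly as stored. Units are kcal/mol and
#' kcal/(mol K), with `R = 1.987e-3` kcal/(mol K).
#'
#' @param Kd Dissociation constant (M), positive.
#' @param dH Enthalpy (kcal/mol).
#' @param temperature_K Temperature (K), positive.
#' @return List with `dG` and `dS`.
#' @export
#' @examples
#' compute_thermodynamics(1e-5, -10)
compute_thermodynamics <- function(Kd, dH, temperature_K = 298.15) {
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be positive")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature must be positive")
  dG <- R_KCAL * temperature_K * log(Kd)
  list(dG = dG, dS = (dH - dG) / temperature_K)
}

#' Fit a 1:1 binding model to an ITC isotherm
#'
#' Least-squares fit of (Kd, dH) -- and N unless `fix_N` -- to the
#' normalized heats, by Levenberg-Marquardt with Kd parameterised on the
#' log scale. Three starts log-spaced in Kd guard against local minima.
#' Stoichiometry is fixed at 1 by default, the usual practice once an
#' initial refinement has shown N close to 1. A flat isotherm is reported
#' as a no-binding outcome rather than an error.
#'
#' @param iso An `itc_isotherm` (or data frame with columns `injection`,
#'   `heat`).
#' @param schedule The [itc_schedule()] used to collect `iso`.
#' @param fix_N Fix stoichiometry at 1.0 (default TRUE).
#' @param displacement Dilution bookkeeping to use in the model.
#' @param flat_tol Heats with range below this (kcal/mol) are treated as
#'   no detectable binding.
#' @return List of class `itc_fit`: `Kd`, `dH`, `N`, `dG`, `dS`,
#'   `residual_norm`, `converged`, `no_binding`.
#' @export
fit_isotherm <- function(iso, schedule = attr(iso, "schedule"),
                         fix_N = TRUE, displacement = TRUE,
                         flat_tol = 1e-4) {
  stopifnot(inherits(schedule, "itc_schedule"))
  heat <- iso$heat
  if (length(heat) < 5) stop("need at least 5 injections to fit")
  if (diff(range(heat)) < flat_tol && max(abs(heat)) < flat_tol)
    return(structure(list(Kd = NA_real_, dH = NA_real_, N = NA_real_,
                          dG = NA_real_, dS = NA_real_,
                          residual_norm = 0, converged = TRUE,
                          no_binding = TRUE),
                     class = "itc_fit"))
  model_heat <- function(logKd, dH, N) {
    p <- binding_params(exp(logKd), dH, N)
    simulate_isotherm(p, schedule, displacement = displacement)$heat
  }
  resid_fn <- function(par) {
    N <- if (fix_N) 1.0 else exp(par[3])
    heat - model_heat(par[1], par[2], N)
  }
  dH0 <- heat[which.max(abs(heat))]
  starts <- lapply(c(1e-7, 1e-5, 1e-3), function(kd0)
    c(log(kd0), dH0, if (!fix_N) 0))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best))
    stop("isotherm fit failed to converge from any start")
  par <- best$fit$par
  Kd <- exp(par[1]); dH <- par[2]
  N <- if (fix_N) 1.0 else exp(par[3])
  th <- compute_thermodynamics(Kd, dH, schedule$temperature_K)
  structure(list(Kd = Kd, dH = dH, N = N, dG = th$dG, dS = th$dS,
                 residual_norm = sqrt(best$ss),
                 converged = best$fit$info %in% 1:4,
                 no_binding = FALSE),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (x$no_binding) {
    cat("ITC fit: no detectable binding\n")
  } else {
    cat(sprintf(
      "ITC fit: Kd = %.3g uM, dH = %.3f kcal/mol, N = %.3f\n",
      x$Kd * 1e6, x$dH, x$N))
    cat(sprintf("         dG = %.3f kcal/mol, -TdS = %.3f kcal/mol\n",
                x$dG, x$dG - x$dH))
  }
  invisible(x)
}

#' Predicted isotherm for the two-independent-site competition experiment
#'
#' Models the pre-incubation design: a macromolecule with two independent
#' sites is pre-incubated with the ligand of one site, then titrated with
#' a ligand. If the pre-incubated ligand targets the *other* site, the
#' titration is unaffected and the returned isotherm equals the plain
#' single-site simulation; if it targets the *same* site, the
#' pre-equilibrium occupancy by the resident ligand suppresses the
#' observed heats (at saturating pre-incubation, heats vanish).
#'
#' @param site1,site2 [binding_params()] for the two sites.
#' @param titrated_site,preincubated_site Site index (1 or 2) of the
#'   titrant and of the pre-incubated ligand.
#' @param preincubation_conc Pre-incubated ligand concentration in the
#'   cell (M) before the first injection.
#' @param schedule An [itc_schedule()].
#' @param displacement Dilution bookkeeping mode.
#' @return An `itc_isotherm` data frame.
#' @export
predict_competition <- function(site1, site2, titrated_site = 1,
                                preincubated_site = 2,
                                preincubation_conc = 0,
                                schedule = itc_schedule(),
                                displacement = TRUE) {
  sites <- list(site1, site2)
  for (s in sites) stopifnot(inherits(s, "binding_params"))
  if (!titrated_site %in% 1:2 || !preincubated_site %in% 1:2)
    stop("site ids must be 1 or 2")
  if (preincubation_conc < 0) stop("preincubation_conc must be >= 0")
  params <- sites[[titrated_site]]
  if (preincubated_site != titrated_site) {
    # independent sites: resident ligand on the other site is invisible
    return(simulate_isotherm(params, schedule, displacement))
  }
  simulate_isotherm(params, schedule, displacement,
                    initial_ligand_M = preincubation_conc)
}

#' Read an isotherm CSV
#'
#' @param path CSV with columns `injection_index` and either
#'   `heat_kcal_per_mol` (already normalized) or `heat_ucal` plus a
#'   schedule to normalize with.
#' @param schedule Required when heats are raw (ucal per injection).
#' @return An `itc_isotherm` data frame.
#' @export
read_isotherm_csv <- function(path, schedule = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("heat_kcal_per_mol" %in% names(df)) {
    heat <- df$heat_kcal_per_mol
  } else if ("heat_ucal" %in% names(df)) {
    if (is.null(schedule))
      stop("raw heats (ucal) need a schedule for normalization")
    inj_mol <- schedule$syringe_conc_M *
      schedule$injection_volume_ul * 1e-6           # liters -> moles
    heat <- df$heat_ucal * 1e-6 / 1e3 / inj_mol     # ucal -> kcal
  } else stop("isotherm CSV needs heat_kcal_per_mol or heat_ucal")
  out <- data.frame(injection = df$injection_index, heat = heat)
  if (!is.null(schedule)) attr(out, "schedule") <- schedule
  class(out) <- c("itc_isotherm", "data.frame")
  out
}
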