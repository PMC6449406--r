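#' Simulate a 1:1 biolayer-interferometry trace
#'
#' Association phase follows `R(t) = Req (1 - exp(-(kon C + koff) t))`
#' with `Req = Rmax C / (C + Kd)` and `Kd = koff/kon`; after `t_assoc` the
#' sensor is moved to buffer and the response decays exponentially with
#' rate `koff`.
#'
#' @param kon Association rate constant (1/(M s)).
#' @param koff Dissociation rate constant (1/s); may be 0.
#' @param Rmax Maximal response (nm).
#' @param analyte_conc_M Analyte concentration during association (M);
#'   default 20 uM.
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Additive Gaussian noise on the response (nm).
#' @return Data frame of class `bli_trace` with columns `time`,
#'   `response`, `phase` ("association"/"dissociation");
#'   `analyte_conc_M` attached as an attribute.
#' @export
simulate_kinetic_trace <- function(kon, koff, Rmax,
                                   analyte_conc_M = 20e-6,
                                   t_assoc = 300, t_dissoc = 300,
                                   dt = 1, noise_sd = 0) {
  if (kon <= 0 || koff < 0 || Rmax <= 0 || analyte_conc_M <= 0)
    stop("kon, Rmax and analyte concentration must be positive; koff >= 0")
  kobs <- kon * analyte_conc_M + koff
  Kd <- koff / kon
  Req <- Rmax * analyte_conc_M / (analyte_conc_M + Kd)
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  r_assoc <- Req * (1 - exp(-kobs * ta))
  r0 <- r_assoc[length(r_assoc)]
  r_dissoc <- r0 * exp(-koff * td)
  out <- data.frame(
    time = c(ta, t_assoc + td),
    response = c(r_assoc, r_dissoc),
    phase = c(rep("association", length(ta)),
              rep("dissociation", length(td))),
    stringsAsFactors = FALSE)
  if (noise_sd > 0)
    out$response <- out$response + stats::rnorm(nrow(out), 0, noise_sd)
  attr(out, "analyte_conc_M") <- analyte_conc_M
  class(out) <- c("bli_trace", "data.frame")
  out
}

#' Fit 1:1 kinetics to a BLI trace
#'
#' The dissociation phase is fit first to a single exponential decay to
#' estimate `koff`; the association phase is then fit to
#' `R(t) = Req (1 - exp(-kobs t))`, giving `kon = (kobs - koff)/C`,
#' `Kd = koff/kon`, and `Rmax = Req (C + Kd)/C`. A dissociation phase
#' that is flat within `flat_tol` (relative decay) reports `koff = 0`
#' with the `koff_below_tolerance` flag.
#'
#' @param trace A `bli_trace` (columns `time`, `response`, `phase`).
#' @param analyte_conc_M Analyte concentration (M); defaults to the
#'   attribute stored on the trace.
#' @param flat_tol Relative decay below which the dissociation phase is
#'   considered flat.
#' @return List of class `bli_fit`: `kon`, `koff`, `Rmax`, `Kd`, `Req`,
#'   `koff_below_tolerance`, `residual_norm`.
#' @export
fit_kinetic_trace <- function(trace, analyte_conc_M =
                                attr(trace, "analyte_conc_M"),
                              flat_tol = 1e-6) {
  stopifnot(all(c("time", "response", "phase") %in% names(trace)))
  if (is.null(analyte_conc_M))
    stop("analyte concentration is required")
  assoc <- trace[trace$phase == "association", ]
  diss <- trace[trace$phase == "dissociation", ]
  if (nrow(assoc) < 5 || nrow(diss) < 5)
    stop("trace must contain both association and dissociation phases")
  if (any(diff(trace$time) <= 0)) stop("time must be strictly increasing")

  # dissociation: R = A exp(-koff (t - t0))
  t0 <- diss$time[1]
  A0 <- diss$response[1]
  decay <- 1 - diss$response[nrow(diss)] / A0
  koff_below <- FALSE
  if (!is.finite(decay) || decay < flat_tol) {
    koff <- 0
    koff_below <- TRUE
    ss_d <- 0
  } else {
    fd <- minpack.lm::nlsLM(
      response ~ A * exp(-koff * (time - t0)),
      data = diss, start = list(A = A0, koff = max(decay, 1e-3) /
                                  (diss$time[nrow(diss)] - t0)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    koff <- coef(fd)[["koff"]]
    ss_d <- sum(stats::residuals(fd)^2)
  }

  # association: R = Req (1 - exp(-kobs t))
  Req0 <- max(assoc$response)
  fa <- minpack.lm::nlsLM(
    response ~ Req * (1 - exp(-kobs * time)),
    data = assoc, start = list(Req = Req0, kobs = 5 / max(assoc$time)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  Req <- coef(fa)[["Req"]]
  kobs <- coef(fa)[["kobs"]]
  kon <- (kobs - koff) / analyte_conc_M
  if (kon <= 0) stop("non-physical fit: kobs <= koff")
  Kd <- koff / kon
  Rmax <- Req * (analyte_conc_M + Kd) / analyte_conc_M
  structure(list(kon = kon, koff = koff, Rmax = Rmax, Kd = Kd, Req = Req,
                 koff_below_tolerance = koff_below,
                 residual_norm = sqrt(ss_d + sum(stats::residuals(fa)^2))),
            class = "bli_fit")
}

#' Read a BLI trace CSV
#' @param path CSV with columns `time_s`, `response_nm`, `phase`.
#' @param analyte_conc_M Analyte concentration (M) to attach.
#' @return A `bli_trace` data frame.
#' @export
read_trace_csv <- function(path, analyte_conc_M = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(time = df$time_s, response = df$response_nm,
                    phase = df$phase, stringsAsFactors = FALSE)
  attr(out, "analyte_conc_M") <- analyte_conc_M
  class(out) <- c("bli_trace", "data.frame")
  out
}
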