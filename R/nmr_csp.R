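#' Combined amide chemical-shift perturbation
#'
#' The weighted combined shift change for a backbone amide is
#' `delta_delta = sqrt((0.17 * delta_NH)^2 + delta_HN^2)`, where
#' `delta_HN` is the proton shift change (ppm) and `delta_NH` the
#' nitrogen shift change (ppm). The 0.17 nitrogen weight compensates the
#' wider 15N shift range; it is a fixed constant of the formula, exposed
#' only for sensitivity analysis.
#'
#' @param delta_HN 1H shift change(s), ppm.
#' @param delta_NH 15N shift change(s), ppm.
#' @param n_weight Nitrogen weight (default 0.17).
#' @return Non-negative combined shift change(s), ppm.
#' @export
#' @examples
#' compute_csp(0, 1.0)  # 0.17
compute_csp <- function(delta_HN, delta_NH, n_weight = 0.17) {
  if (any(!is.finite(delta_HN)) || any(!is.finite(delta_NH)))
    stop("shift changes must be finite")
  sqrt((n_weight * delta_NH)^2 + delta_HN^2)
}

.check_spectrum <- function(spectrum, label) {
  stopifnot(is.data.frame(spectrum),
            all(c("residue_id", "h_ppm", "n_ppm") %in% names(spectrum)))
  if (anyDuplicated(spectrum$residue_id))
    stop("duplicate residue_id in ", label, " spectrum")
  if (any(!is.finite(spectrum$h_ppm)) || any(!is.finite(spectrum$n_ppm)))
    stop("non-finite shift in ", label, " spectrum")
  spectrum
}

#' Per-residue CSPs between a reference and a titrated spectrum
#'
#' Peaks are matched by residue assignment (`residue_id`), not by
#' proximity in ppm space. Residues present in the reference but absent
#' from the titrated spectrum are flagged `missing` (typically
#' exchange-broadened beyond detection) and carry no shift values;
#' residues found only in the titrated spectrum are reported with a
#' warning and otherwise ignored.
#'
#' @param reference,titrated Data frames with columns `residue_id`,
#'   `h_ppm`, `n_ppm`.
#' @param threshold Significance cutoff on `delta_delta` (ppm), strict.
#' @param n_weight Nitrogen weight for [compute_csp()].
#' @return Data frame with columns `residue_id`, `delta_HN`, `delta_NH`,
#'   `delta_delta`, `significant`, `missing`, sorted by residue.
#' @export
csp_profile <- function(reference, titrated, threshold = 0.1,
                        n_weight = 0.17) {
  reference <- .check_spectrum(reference, "reference")
  titrated <- .check_spectrum(titrated, "titrated")
  extra <- setdiff(titrated$residue_id, reference$residue_id)
  if (length(extra) > 0)
    warning("residue(s) only in titrated spectrum: ",
            paste(extra, collapse = ", "))
  idx <- match(reference$residue_id, titrated$residue_id)
  missing <- is.na(idx)
  d_hn <- titrated$h_ppm[idx] - reference$h_ppm
  d_nh <- titrated$n_ppm[idx] - reference$n_ppm
  dd <- ifelse(missing, NA_real_, compute_csp(ifelse(missing, 0, d_hn),
                                              ifelse(missing, 0, d_nh),
                                              n_weight))
  out <- data.frame(residue_id = reference$residue_id,
                    delta_HN = d_hn, delta_NH = d_nh, delta_delta = dd,
                    significant = !missing & !is.na(dd) & dd > threshold,
                    missing = missing)
  out[order(out$residue_id), , drop = FALSE]
}

#' Residues with significant perturbations
#'
#' A residue is significant when its combined shift change strictly
#' exceeds the threshold (default 0.1 ppm); a residue at exactly the
#' threshold is not flagged. Raising the threshold can only remove
#' residues.
#'
#' @param records Output of [csp_profile()] or [series_max_csp()].
#' @param threshold Cutoff (ppm), non-negative.
#' @return Ascending integer vector of significant residue ids.
#' @export
flag_significant <- function(records, threshold = 0.1) {
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be non-negative")
  dd <- records$delta_delta
  sort(records$residue_id[!is.na(dd) & !records$missing & dd > threshold])
}

#' Per-residue maximum CSP over a titration series
#'
#' A titration series is the apo reference spectrum followed by spectra
#' at non-decreasing ligand concentrations. For each residue the summary
#' is the maximum combined shift change relative to apo over all titrated
#' points (mode "max", the default) or the change at the final point
#' (mode "final"). A residue missing from any titrated point is flagged
#' missing.
#'
#' @param series List with `ligand` (label) and `points`, a list of
#'   `list(conc, spectrum)` entries whose first entry is the apo
#'   reference (`conc = 0`).
#' @param threshold,n_weight Passed to [csp_profile()].
#' @param mode `"max"` or `"final"`.
#' @return Data frame like [csp_profile()], one row per apo residue.
#' @export
series_max_csp <- function(series, threshold = 0.1, n_weight = 0.17,
                           mode = c("max", "final")) {
  mode <- match.arg(mode)
  stopifnot(is.list(series$points))
  if (length(series$points) < 2)
    stop("a titration series needs the apo point plus at least one ",
         "titrated point")
  concs <- vapply(series$points, function(p) p$conc, numeric(1))
  if (is.unsorted(concs)) stop("ligand concentrations must be non-decreasing")
  apo <- series$points[[1]]$spectrum
  profs <- lapply(series$points[-1], function(p)
    csp_profile(apo, p$spectrum, threshold, n_weight))
  if (mode == "final") {
    out <- profs[[length(profs)]]
  } else {
    out <- profs[[1]]
    for (p in profs[-1]) {
      better <- !is.na(p$delta_delta) &
        (is.na(out$delta_delta) | p$delta_delta > out$delta_delta)
      better[is.na(better)] <- FALSE
      out[better, c("delta_HN", "delta_NH", "delta_delta")] <-
        p[better, c("delta_HN", "delta_NH", "delta_delta")]
      out$missing <- out$missing | p$missing
    }
    out$delta_delta[out$missing] <- NA_real_
    out$significant <- !out$missing & !is.na(out$delta_delta) &
      out$delta_delta > threshold
  }
  out
}

#' Read an assigned HSQC peak list
#' @param path CSV with columns `residue_id`, `h_ppm`, `n_ppm`.
#' @return Data frame spectrum.
#' @export
read_peaklist_csv <- function(path) {
  .check_spectrum(utils::read.csv(path, stringsAsFactors = FALSE), path)
}
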