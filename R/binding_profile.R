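#' Pellet/supernatant ratio from a pair of band intensities
#'
#' The pelleting assay splits each binding reaction into a liposome pellet
#' (bound protein, P) and a supernatant (unbound, S); the P/S ratio of the
#' Coomassie band intensities is the binding-strength statistic. A lane in
#' which all protein pellets (S = 0, P > 0) is reported as `Inf`, a
#' saturated ratio that exceeds any band threshold.
#'
#' @param pellet_intensity,supernatant_intensity Non-negative densitometry
#'   values; they must not both be zero.
#' @return A non-negative number (possibly `Inf`).
#' @export
#' @examples
#' compute_ps_ratio(100, 40) # 2.5
compute_ps_ratio <- function(pellet_intensity, supernatant_intensity) {
  if (length(pellet_intensity) != 1L || length(supernatant_intensity) != 1L)
    stop("compute_ps_ratio() takes one band pair at a time")
  if (is.na(pellet_intensity) || is.na(supernatant_intensity) ||
      pellet_intensity < 0 || supernatant_intensity < 0)
    stop("band intensities must be non-negative numbers")
  if (pellet_intensity == 0 && supernatant_intensity == 0)
    stop("invalid lane: both pellet and supernatant intensities are zero")
  if (supernatant_intensity == 0) return(Inf)
  pellet_intensity / supernatant_intensity
}

#' Ordered binding-strength bands
#' @return Character vector of the four bands, weakest first.
#' @export
binding_bands <- function() c("none", "weak", "strong", "very_strong")

#' Classify a P/S ratio into a binding-strength band
#'
#' Bands follow the assay's quantification rule: no binding for P/S in
#' `[0, 0.1)`, weak for `[0.1, 1)`, strong for `[1, 2]`, and very strong
#' for `> 2`. "Greater than twofold" is read as strictly exclusive, so a
#' ratio of exactly 2 is strong. Classification is monotone in the ratio.
#'
#' @param ps_ratio Non-negative ratio(s); `Inf` (saturated lane) is
#'   `very_strong`.
#' @return Ordered factor over `binding_bands()`.
#' @export
#' @examples
#' classify_strength(c(0.05, 0.5, 1.5, 2, 2.5))
classify_strength <- function(ps_ratio) {
  if (any(is.na(ps_ratio)) || any(ps_ratio < 0))
    stop("ps_ratio must be non-negative")
  band <- ifelse(ps_ratio < 0.1, "none",
          ifelse(ps_ratio < 1,   "weak",
          ifelse(ps_ratio <= 2,  "strong", "very_strong")))
  factor(band, levels = binding_bands(), ordered = TRUE)
}

#' Build a per-protein binding profile from pelleting lanes
#'
#' @param protein Protein identifier.
#' @param lanes Data frame with columns `lipid`, `pellet_intensity`,
#'   `supernatant_intensity`: exactly one lane per panel channel, with the
#'   PC/PE control present. Lipid labels are matched with
#'   [match_lipid_channel()].
#' @return An object of class `px_profile`: a list with `protein`, a
#'   `lanes` data frame (`lipid`, `category`, `ps_ratio`, `band`), and a
#'   `control_violation` flag (control band other than `none`, which makes
#'   the profile ineligible for group assignment).
#' @export
build_binding_profile <- function(protein, lanes) {
  stopifnot(is.data.frame(lanes),
            all(c("lipid", "pellet_intensity", "supernatant_intensity")
                %in% names(lanes)))
  lipid <- match_lipid_channel(lanes$lipid)
  if (anyDuplicated(lipid))
    stop("duplicate lane(s) for channel: ",
         paste(unique(lipid[duplicated(lipid)]), collapse = ", "))
  if (!"PC/PE-control" %in% lipid)
    stop("profile for ", protein, " is missing the PC/PE control lane")
  ratio <- mapply(compute_ps_ratio,
                  lanes$pellet_intensity, lanes$supernatant_intensity)
  out <- data.frame(lipid = lipid,
                    category = channel_category(lipid),
                    ps_ratio = ratio,
                    band = classify_strength(ratio),
                    stringsAsFactors = FALSE)
  # keep panel order
  out <- out[order(match(out$lipid, lipid_channels()$name)), , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(protein = protein, lanes = out,
         control_violation =
           out$band[out$category == "control"] != "none"),
    class = "px_profile")
}

#' @export
print.px_profile <- function(x, ...) {
  cat("PX binding profile:", x$protein,
      if (x$control_violation) "(CONTROL VIOLATION)" else "", "\n")
  print(x$lanes, ...)
  invisible(x)
}

#' Assign the experimental binding group of a profile
#'
#' The four groups partition valid profiles by two booleans: binding (band
#' at or above `binding_threshold`) in the PtdIns3P channel (A), and
#' binding in any other specific channel, i.e. any doped species other
#' than PtdIns3P (B). Group I is neither, II is PtdIns3P only, III is
#' other-specific only, IV is both. The Folch broad-indicator channel is
#' diagnostic, not decisive: it is excluded from the rule, and a warning
#' is emitted when Folch binds while no specific channel does.
#'
#' @param profile A `px_profile`.
#' @param binding_threshold Minimum band that counts as binding
#'   (default `"weak"`, i.e. P/S >= 0.1).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
assign_group <- function(profile, binding_threshold = "weak") {
  stopifnot(inherits(profile, "px_profile"))
  binding_threshold <- match.arg(binding_threshold, binding_bands()[-1])
  if (isTRUE(profile$control_violation))
    stop("control violation for ", profile$protein,
         ": group assignment refused")
  ln <- profile$lanes
  binds <- ln$band >= factor(binding_threshold, binding_bands(),
                             ordered = TRUE)
  a <- any(binds[ln$category == "ptdins3p"])
  b <- any(binds[ln$category == "other-specific"])
  if (!a && !b && any(binds[ln$category == "broad"]))
    warning("Folch binding without any specific-channel binding for ",
            profile$protein)
  if (a && b) "IV" else if (a) "II" else if (b) "III" else "I"
}

#' Tally group assignments over a set of profiles
#'
#' @param profiles List of `px_profile` objects.
#' @param binding_threshold Passed to [assign_group()].
#' @return Named integer vector with counts for groups I-IV; counts sum to
#'   `length(profiles)`.
#' @export
group_census <- function(profiles, binding_threshold = "weak") {
  groups <- vapply(profiles, assign_group, character(1),
                   binding_threshold = binding_threshold)
  out <- table(factor(groups, levels = c("I", "II", "III", "IV")))
  stats::setNames(as.integer(out), names(out))
}

#' Read a pelleting lane table and build all profiles
#'
#' @param path CSV with columns `protein`, `lipid`, `pellet_intensity`,
#'   `supernatant_intensity`.
#' @return Named list of `px_profile` objects, one per protein.
#' @export
read_lanes_csv <- function(path) {
  lanes <- utils::read.csv(path, stringsAsFactors = FALSE)
  profiles_from_lanes(lanes)
}

#' @rdname read_lanes_csv
#' @param lanes An in-memory lane table with the same columns.
#' @export
profiles_from_lanes <- function(lanes) {
  stopifnot(all(c("protein", "lipid", "pellet_intensity",
                  "supernatant_intensity") %in% names(lanes)))
  split_lanes <- split(lanes, factor(lanes$protein,
                                     levels = unique(lanes$protein)))
  lapply(split_lanes, function(df)
    build_binding_profile(df$protein[[1L]], df))
}

#' Flatten profiles into ratio and group tables
#'
#' @param profiles Named list of `px_profile` objects.
#' @param binding_threshold Passed to [assign_group()].
#' @return `profile_table()`: data frame (`protein`, `lipid`, `ps_ratio`,
#'   `band`); `group_table()`: data frame (`protein`, `group`).
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    cbind(protein = p$protein,
          p$lanes[, c("lipid", "ps_ratio", "band")],
          row.names = NULL)))
}

#' @rdname profile_table
#' @export
group_table <- function(profiles, binding_threshold = "weak") {
  data.frame(
    protein = vapply(profiles, function(p) p$protein, character(1)),
    group = vapply(profiles, assign_group, character(1),
                   binding_threshold = binding_threshold),
    row.names = NULL, stringsAsFactors = FALSE)
}
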