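#' Curated roster of the 49 human PX-domain proteins
#'
#' One record per human PX-domain protein: whether the domain was cloned
#' and purified, the experimental binding group for the 39 purified
#' domains, curated per-channel binding calls (booleans read from the
#' pelleting-assay lanes), and a provenance note. Calls named only
#' indirectly in the source figures are flagged as curator judgement in
#' `encoding_note`.
#'
#' @return Data frame with 49 rows: `protein`, `cloned`, `purified`,
#'   `experimental_group`, one logical column per lipid channel, and
#'   `encoding_note`.
#' @export
px_roster <- function() {
  path <- system.file("extdata", "px_roster.tsv", package = "pxbinding",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_roster(df)
  df
}

.roster_call_cols <- c("pcpe_control", "folch", "ptdins3p", "ptdins4p",
                       "ptdins5p", "ptdins34p2", "ptdins35p2",
                       "ptdins45p2", "ptdins345p3", "ps")

.validate_roster <- function(roster) {
  stopifnot(all(c("protein", "cloned", "purified") %in% names(roster)))
  if (anyDuplicated(roster$protein))
    stop("duplicate protein names in roster")
  if (any(roster$purified & !roster$cloned))
    stop("roster invariant violated: purified protein not marked cloned")
  if ("experimental_group" %in% names(roster)) {
    has_grp <- !is.na(roster$experimental_group)
    if (any(has_grp & !roster$purified))
      stop("roster invariant violated: group assigned to unpurified protein")
    if (!all(roster$experimental_group[has_grp] %in% c("I", "II", "III", "IV")))
      stop("invalid group label in roster")
  }
  invisible(roster)
}

#' Roster counts: total, cloned, purified
#'
#' @param roster A roster data frame (default the packaged one).
#' @return Named integer vector `c(n_total, n_cloned, n_purified)`.
#' @export
#' @examples
#' roster_census()
roster_census <- function(roster = px_roster()) {
  .validate_roster(roster)
  c(n_total = nrow(roster),
    n_cloned = sum(roster$cloned, na.rm = TRUE),
    n_purified = sum(roster$purified, na.rm = TRUE))
}

#' Binding profiles from the curated roster calls
#'
#' Converts the boolean binding calls of purified roster records into
#' binding profiles for [assign_group()]: a positive call becomes a
#' mid-band strong lane (P/S = 1.5), a negative call an empty pellet lane
#' (P/S = 0.02). Records without calls are skipped with a warning.
#'
#' @param roster A roster data frame (default the packaged one).
#' @return Named list of `px_profile` objects (39 for the packaged
#'   roster).
#' @export
fixture_group_profiles <- function(roster = px_roster()) {
  .validate_roster(roster)
  has_calls <- roster$purified &
    stats::complete.cases(roster[, .roster_call_cols])
  skipped <- roster$purified & !has_calls
  if (any(skipped))
    warning("purified record(s) without binding calls skipped: ",
            paste(roster$protein[skipped], collapse = ", "))
  sub <- roster[has_calls, , drop = FALSE]
  profiles <- lapply(seq_len(nrow(sub)), function(i) {
    calls <- unlist(sub[i, .roster_call_cols])
    build_binding_profile(sub$protein[i], data.frame(
      lipid = .roster_call_cols,
      pellet_intensity = ifelse(calls, 150, 2),
      supernatant_intensity = 100,
      stringsAsFactors = FALSE))
  })
  stats::setNames(profiles, sub$protein)
}

#' SNX25 NMR structure statistics
#'
#' Restraint-category counts and NOESY cross-peak assignment counts for
#' the SNX25 PX-domain solution structure, as packaged records for the
#' arithmetic validation operations.
#'
#' @return List with `restraints` (intraresidue, sequential,
#'   medium_range, long_range, total_distance, phi, psi, chi) and
#'   `noesy` (assigned, total).
#' @export
snx25_nmr_stats <- function() {
  path <- system.file("extdata", "snx25_nmr_stats.json",
                      package = "pxbinding", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Total interproton distance restraints
#'
#' Sums the four distance-restraint categories; if the table also stores
#' a `total_distance` that disagrees with the sum, a consistency warning
#' is raised.
#'
#' @param restraints List or one-row data frame with `intraresidue`,
#'   `sequential`, `medium_range`, `long_range` and optionally
#'   `total_distance`.
#' @return Integer total.
#' @export
#' @examples
#' restraint_totals(snx25_nmr_stats()$restraints)  # 3024
restraint_totals <- function(restraints = snx25_nmr_stats()$restraints) {
  cats <- c("intraresidue", "sequential", "medium_range", "long_range")
  vals <- unlist(restraints[cats])
  if (length(vals) != 4 || any(is.na(vals)))
    stop("restraint table must contain the four distance categories")
  if (any(vals < 0)) stop("restraint counts must be non-negative")
  total <- sum(vals)
  stored <- restraints[["total_distance"]]
  if (!is.null(stored) && !is.na(stored) && stored != total)
    warning("stored distance-restraint total (", stored,
            ") disagrees with category sum (", total, ")")
  as.integer(total)
}

#' NOESY cross-peak assignment percentage
#'
#' @param stats List with `assigned` and `total` cross-peak counts.
#' @return Percentage assigned, rounded to one decimal place.
#' @export
#' @examples
#' noesy_assignment_fraction(snx25_nmr_stats()$noesy)  # 91.8
noesy_assignment_fraction <- function(stats = snx25_nmr_stats()$noesy) {
  assigned <- stats[["assigned"]]; total <- stats[["total"]]
  if (is.null(total) || total <= 0) stop("total cross-peak count must be > 0")
  if (assigned < 0 || assigned > total)
    stop("assigned count must lie in [0, total]")
  round(100 * assigned / total, 1)
}

#' Packaged reference column annotation
#'
#' A 110-column scaffold annotation of the PX fold (beta1-beta2-beta3,
#' alpha1, PPK loop, alpha2, alpha3) with the five determinant anchors,
#' following the reference secondary-structure layout used for
#' structure-guided alignment. User-replaceable via
#' [read_annotation_tsv()].
#'
#' @return A `px_annotation`.
#' @export
px_reference_annotation <- function() {
  read_annotation_tsv(system.file("extdata", "px_reference_annotation.tsv",
                                  package = "pxbinding", mustWork = TRUE))
}
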