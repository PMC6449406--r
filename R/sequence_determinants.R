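AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP <- "-"

.check_sequence <- function(sequence, allow_gap = FALSE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  ok <- chars %in% c(AA20, if (allow_gap) GAP)
  if (!all(ok))
    stop("invalid residue character(s): ",
         paste(unique(chars[!ok]), collapse = ", "))
  chars
}

#' Scan a sequence for the PPK-loop motif
#'
#' The PPK loop of the PX fold carries a conserved seven-residue
#' Psi-P-x-x-P-x-K motif, where Psi is a large aliphatic residue
#' (V, I, L or M) and x is any amino acid. All matches are reported,
#' left to right; overlapping matches are allowed.
#'
#' @param sequence Ungapped amino-acid string (one-letter code).
#' @return Data frame with one row per match: `start` (1-based position
#'   in the ungapped sequence), `matched_text` (the 7-mer), and
#'   `psi_residue`.
#' @export
#' @examples
#' detect_ppk_motif("AAVPQRPGKAA")
detect_ppk_motif <- function(sequence) {
  .check_sequence(sequence)
  sequence <- toupper(sequence)
  # lookahead so overlapping occurrences are all captured
  m <- gregexpr("(?=([VILM]P[A-Z]{2}P[A-Z]K))", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), matched_text = character(0),
                      psi_residue = character(0), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  txt <- substring(sequence, starts, starts + 6L)
  data.frame(start = starts, matched_text = txt,
             psi_residue = substring(txt, 1L, 1L),
             stringsAsFactors = FALSE)
}

#' Read and validate a reference column annotation
#'
#' The determinant rules operate on a structure-guided multiple alignment.
#' A reference annotation maps every alignment column to a secondary
#' structure element of the PX fold (beta1-beta3, alpha1-alpha3, the PPK
#' loop, or other) and names five anchor columns: the sequential Arg/Tyr
#' pair at the beta3 to alpha1 junction, the PPK-loop Lys, the alpha2 Arg,
#' and the first alpha1 position (the His/Tyr site).
#'
#' @param path TSV with columns `column`, `element`, `anchor` (empty for
#'   non-anchor columns).
#' @return Object of class `px_annotation`: list with `element` (character
#'   vector over columns) and `anchors` (named integer vector).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  as_px_annotation(df)
}

#' @rdname read_annotation_tsv
#' @param df In-memory annotation data frame with the same columns.
#' @export
as_px_annotation <- function(df) {
  stopifnot(all(c("column", "element", "anchor") %in% names(df)))
  df <- df[order(df$column), , drop = FALSE]
  if (!identical(as.integer(df$column), seq_len(nrow(df))))
    stop("annotation columns must be 1..width with no gaps")
  elements <- c("beta1", "beta2", "beta3", "alpha1", "alpha2", "alpha3",
                "ppk_loop", "other")
  if (!all(df$element %in% elements))
    stop("unknown element label(s): ",
         paste(setdiff(unique(df$element), elements), collapse = ", "))
  anchor_names <- c("junction_arg", "junction_tyr", "ppk_lys",
                    "alpha2_arg", "alpha1_first")
  has <- df$anchor != ""
  anchors <- stats::setNames(as.integer(df$column[has]), df$anchor[has])
  if (!setequal(names(anchors), anchor_names) ||
      anyDuplicated(names(anchors)))
    stop("annotation must name each anchor exactly once: ",
         paste(anchor_names, collapse = ", "))
  ann <- structure(list(element = df$element, anchors = anchors[anchor_names]),
                   class = "px_annotation")
  .validate_annotation(ann)
  ann
}

.validate_annotation <- function(ann) {
  el <- ann$element
  a <- ann$anchors
  a1 <- which(el == "alpha1")
  if (el[a["junction_arg"]] != "beta3" || el[a["junction_tyr"]] != "beta3")
    stop("junction anchors must lie in beta3")
  if (a["junction_tyr"] != a["junction_arg"] + 1L ||
      a["junction_tyr"] + 1L != min(a1))
    stop("junction Arg/Tyr must be the last two beta3 columns before alpha1")
  if (el[a["ppk_lys"]] != "ppk_loop") stop("ppk_lys must lie in the PPK loop")
  if (el[a["alpha2_arg"]] != "alpha2") stop("alpha2_arg must lie in alpha2")
  if (a["alpha1_first"] != min(a1))
    stop("alpha1_first must be the first alpha1 column")
  invisible(ann)
}

#' Alignment columns of the secondary-site basic window
#'
#' The basic residues of the secondary site are not positionally conserved
#' but sit at the C-terminus of helix alpha1 and the start of the PPK
#' loop, so they are counted over a window rather than at fixed anchors:
#' by default the last `n_alpha1_tail` alpha1 columns plus the first
#' `n_ppk_head` PPK-loop columns.
#'
#' @param annotation A `px_annotation`.
#' @param n_alpha1_tail,n_ppk_head Window extent (columns).
#' @return Integer vector of alignment columns.
#' @export
secondary_site_window <- function(annotation, n_alpha1_tail = 4,
                                  n_ppk_head = 6) {
  a1 <- which(annotation$element == "alpha1")
  ppk <- which(annotation$element == "ppk_loop")
  c(utils::tail(a1, n_alpha1_tail), utils::head(ppk, n_ppk_head))
}

.check_aligned <- function(aligned_sequence, annotation) {
  chars <- .check_sequence(aligned_sequence, allow_gap = TRUE)
  if (length(chars) != length(annotation$element))
    stop("aligned sequence length (", length(chars),
         ") does not match annotation width (",
         length(annotation$element), ")")
  chars
}

#' Assess the canonical PtdIns3P-binding site
#'
#' Four residues are strictly required for canonical, stereospecific
#' coordination of the PtdIns3P headgroup: a sequential Arg/Tyr pair at
#' the beta3 to alpha1 junction, the Lys of the PPK-loop motif, and an
#' Arg in helix alpha2. A gap at an anchor column counts as absent.
#'
#' @param aligned_sequence Gapped amino-acid string matching the
#'   annotation width.
#' @param annotation A `px_annotation`.
#' @return List of class `px_canonical_report`: the four presence
#'   booleans, `residues_at_anchors`, and `complete` (all four present).
#' @export
assess_canonical_site <- function(aligned_sequence, annotation) {
  chars <- .check_aligned(aligned_sequence, annotation)
  a <- annotation$anchors
  obs <- stats::setNames(chars[a], names(a))
  rep <- list(
    junction_arg_present = unname(obs["junction_arg"] == "R"),
    junction_tyr_present = unname(obs["junction_tyr"] == "Y"),
    ppk_lys_present      = unname(obs["ppk_lys"] == "K"),
    alpha2_arg_present   = unname(obs["alpha2_arg"] == "R"),
    residues_at_anchors  = obs[c("junction_arg", "junction_tyr",
                                 "ppk_lys", "alpha2_arg")])
  rep$complete <- rep$junction_arg_present && rep$junction_tyr_present &&
    rep$ppk_lys_present && rep$alpha2_arg_present
  structure(rep, class = "px_canonical_report")
}

#' Assess the His/Tyr-basic secondary site
#'
#' Noncanonical binding of di- and tri-phosphorylated phosphoinositides is
#' associated with a His or Tyr at the first alpha1 position together with
#' a stretch of nearby basic Lys/Arg residues leading into the PPK loop.
#' The site is called present when the His/Tyr is there and at least
#' `min_basics` K/R residues fall in the window.
#'
#' @inheritParams assess_canonical_site
#' @param min_basics Minimum K/R count in the window (default 2).
#' @param n_alpha1_tail,n_ppk_head Window extent, see
#'   [secondary_site_window()].
#' @return List of class `px_secondary_report`: `hy_residue`,
#'   `hy_present`, `basic_count`, `basic_positions` (alignment columns)
#'   and `present`.
#' @export
assess_secondary_site <- function(aligned_sequence, annotation,
                                  min_basics = 2, n_alpha1_tail = 4,
                                  n_ppk_head = 6) {
  chars <- .check_aligned(aligned_sequence, annotation)
  hy <- chars[annotation$anchors["alpha1_first"]]
  window <- secondary_site_window(annotation, n_alpha1_tail, n_ppk_head)
  basic_at <- window[chars[window] %in% c("K", "R")]
  rep <- list(
    hy_residue = unname(hy),
    hy_present = unname(hy %in% c("H", "Y")),
    basic_count = length(basic_at),
    basic_positions = basic_at)
  rep$present <- rep$hy_present && rep$basic_count >= min_basics
  structure(rep, class = "px_secondary_report")
}

#' Known exceptions to the sequence-based group rule
#'
#' Proteins whose experimental behaviour departs from the plain
#' two-site rule: SNX11 binds broadly despite lacking the alpha1 His/Tyr
#' (a large basic surface substitutes), SNX17 and SNX27 are
#' PtdIns3P-specific despite carrying an apparent secondary site, and
#' SNX15 forms a domain-swapped dimer with atypical binding. The notes
#' annotate predictions; they never override the rule output.
#'
#' @return Named character vector of notes.
#' @export
known_exceptions <- function() {
  c(SNX11 = "binds broadly despite no alpha1 His/Tyr (basic surface)",
    SNX17 = "PtdIns3P-specific despite apparent secondary site",
    SNX27 = "PtdIns3P-specific despite apparent secondary site",
    SNX15 = "domain-swapped dimer; atypical binding")
}

#' Predict the binding group from the two site reports
#'
#' Rule table: canonical site complete and secondary site present gives
#' group IV; complete only, group II; secondary only, group III; neither,
#' group I.
#'
#' @param canonical A `px_canonical_report`.
#' @param secondary A `px_secondary_report`.
#' @param protein Optional identifier, used to attach the note for
#'   proteins on [known_exceptions()].
#' @return List of class `px_group_prediction`: `protein`,
#'   `predicted_group`, the two reports and `exception_note` (or `NA`).
#' @export
predict_group <- function(canonical, secondary, protein = NA_character_) {
  stopifnot(inherits(canonical, "px_canonical_report"),
            inherits(secondary, "px_secondary_report"))
  grp <- if (canonical$complete && secondary$present) "IV"
         else if (canonical$complete) "II"
         else if (secondary$present) "III"
         else "I"
  note <- unname(known_exceptions()[protein])
  structure(list(protein = protein, predicted_group = grp,
                 canonical = canonical, secondary = secondary,
                 exception_note = if (is.null(note)) NA_character_ else note),
            class = "px_group_prediction")
}

#' Predict groups for every sequence in an alignment
#'
#' @param alignment Named character vector of gapped sequences (or a
#'   `Biostrings::AAStringSet`), all of the annotation width.
#' @param annotation A `px_annotation`.
#' @param min_basics,n_alpha1_tail,n_ppk_head Secondary-site
#'   configuration.
#' @return Data frame with one row per sequence (order preserved):
#'   observed anchor residues, `canonical_complete`, `hy_residue`,
#'   `basic_count`, `secondary_present`, `predicted_group`,
#'   `exception_note`, and `error` for records that could not be
#'   processed (other records are unaffected).
#' @export
predict_proteome <- function(alignment, annotation, min_basics = 2,
                             n_alpha1_tail = 4, n_ppk_head = 6) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  proteins <- names(alignment)
  if (is.null(proteins)) proteins <- paste0("seq", seq_along(alignment))
  rows <- lapply(seq_along(alignment), function(i) {
    tryCatch({
      can <- assess_canonical_site(alignment[[i]], annotation)
      sec <- assess_secondary_site(alignment[[i]], annotation, min_basics,
                                   n_alpha1_tail, n_ppk_head)
      pred <- predict_group(can, sec, proteins[[i]])
      data.frame(protein = proteins[[i]],
                 junction_arg = can$residues_at_anchors[["junction_arg"]],
                 junction_tyr = can$residues_at_anchors[["junction_tyr"]],
                 ppk_lys = can$residues_at_anchors[["ppk_lys"]],
                 alpha2_arg = can$residues_at_anchors[["alpha2_arg"]],
                 canonical_complete = can$complete,
                 hy_residue = sec$hy_residue,
                 basic_count = sec$basic_count,
                 secondary_present = sec$present,
                 predicted_group = pred$predicted_group,
                 exception_note = pred$exception_note,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(protein = proteins[[i]], junction_arg = NA, junction_tyr = NA,
                 ppk_lys = NA, alpha2_arg = NA, canonical_complete = NA,
                 hy_residue = NA, basic_count = NA, secondary_present = NA,
                 predicted_group = NA_character_,
                 exception_note = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(0), predicted_group = character(0))
  rownames(out) <- NULL
  out
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA of PX-domain sequences.
#' @return Named character vector of gapped sequences.
#' @export
read_alignment_fasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aln), names(aln))
}

#' Write an alignment to FASTA
#' @param alignment Named character vector of gapped sequences.
#' @param path Output file.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path)
  invisible(path)
}
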