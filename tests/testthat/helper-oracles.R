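# Independent oracles and small constructors used across the suite.

# Brute-force motif oracle: test every 7-mer against the pattern directly.
brute_force_ppk <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  starts <- integer(0)
  if (n >= 7) {
    for (i in 1:(n - 6)) {
      w <- chars[i:(i + 6)]
      if (w[1] %in% c("V", "I", "L", "M") && w[2] == "P" &&
          w[5] == "P" && w[7] == "K")
        starts <- c(starts, i)
    }
  }
  starts
}

# Build a profile from a named vector of P/S ratios (unspecified channels
# get an empty-pellet lane).
profile_from_ratios <- function(protein, ratios) {
  ch <- lipid_channels()$name
  r <- setNames(rep(0.02, length(ch)), ch)
  r[names(ratios)] <- ratios
  build_binding_profile(protein, data.frame(
    lipid = ch, pellet_intensity = r * 100, supernatant_intensity = 100,
    stringsAsFactors = FALSE))
}

# A width-matched aligned sequence with chosen residues at chosen columns
# and a fixed neutral background.
scaffold_sequence <- function(annotation, at = integer(0),
                              background = "A") {
  s <- rep(background, length(annotation$element))
  s[as.integer(names(at))] <- at
  paste(s, collapse = "")
}

# Residue placements for a complete canonical site / a present secondary
# site on the packaged annotation.
canonical_residues <- function(ann) {
  a <- ann$anchors
  setNames(c("R", "Y", "K", "R"),
           c(a[["junction_arg"]], a[["junction_tyr"]],
             a[["ppk_lys"]], a[["alpha2_arg"]]))
}
secondary_residues <- function(ann, n_basics = 2, hy = "H") {
  w <- secondary_site_window(ann)
  setNames(c(hy, rep("K", n_basics)),
           c(ann$anchors[["alpha1_first"]], w[seq_len(n_basics)]))
}

# Insert all-gap columns (annotated "other") at the given column indices
# of the original annotation; returns re-indexed annotation + alignment.
insert_gap_columns <- function(alignment, annotation, after_cols) {
  width <- length(annotation$element)
  el <- annotation$element
  pieces <- as.list(el)
  for (col in sort(after_cols, decreasing = TRUE))
    pieces <- append(pieces, list("other"), after = col)
  new_el <- unlist(pieces)
  # positions of the original columns in the widened layout
  offset <- vapply(seq_len(width), function(i) sum(after_cols < i),
                   integer(1))
  orig_pos <- seq_len(width) + offset
  anchor <- rep("", length(new_el))
  anchor[orig_pos[annotation$anchors]] <- names(annotation$anchors)
  ann_df <- data.frame(column = seq_along(new_el), element = new_el,
                       anchor = anchor, stringsAsFactors = FALSE)
  new_aln <- vapply(alignment, function(s) {
    chars <- strsplit(s, "")[[1]]
    out <- rep("-", length(new_el))
    out[orig_pos] <- chars
    paste(out, collapse = "")
  }, character(1))
  list(alignment = new_aln, annotation = as_px_annotation(ann_df))
}

# Canonical/secondary report stubs for rule-table enumeration.
stub_canonical <- function(complete) {
  structure(list(junction_arg_present = complete,
                 junction_tyr_present = complete,
                 ppk_lys_present = complete,
                 alpha2_arg_present = complete,
                 residues_at_anchors = c(junction_arg = "X",
                                         junction_tyr = "X",
                                         ppk_lys = "X", alpha2_arg = "X"),
                 complete = complete),
            class = "px_canonical_report")
}
stub_secondary <- function(present) {
  structure(list(hy_residue = "X", hy_present = present,
                 basic_count = if (present) 2L else 0L,
                 basic_positions = integer(0), present = present),
            class = "px_secondary_report")
}
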