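#' Controlled vocabulary of liposome channels
#'
#' The pelleting assay probes each PX domain against a fixed panel of
#' liposome compositions: a POPC/POPE negative control, Folch fraction I
#' brain extract as a broad-binding indicator, and PC/PE liposomes doped
#' with a single phosphoinositide species or phosphatidylserine (PS).
#' Channels are grouped into four categories used by the classification
#' rule: `control`, `broad` (Folch), `ptdins3p` (the canonical endosomal
#' lipid), and `other-specific` (every other doped species).
#'
#' @return A data frame with columns `name` and `category`, one row per
#'   channel, in panel order.
#' @export
#' @examples
#' lipid_channels()
lipid_channels <- function() {
  data.frame(
    name = c("PC/PE-control", "Folch", "PtdIns3P", "PtdIns4P", "PtdIns5P",
             "PtdIns(3,4)P2", "PtdIns(3,5)P2", "PtdIns(4,5)P2",
             "PtdIns(3,4,5)P3", "PS"),
    category = c("control", "broad", "ptdins3p", rep("other-specific", 7)),
    stringsAsFactors = FALSE
  )
}

# Accepted spellings (lower-cased, punctuation-stripped) per canonical name.
.channel_aliases <- function() {
  list(
    "PC/PE-control"   = c("pcpecontrol", "pcpe", "control", "popcpope"),
    "Folch"           = c("folch", "folchi", "folch1", "folchfraction"),
    "PtdIns3P"        = c("ptdins3p", "pi3p", "ptdins3"),
    "PtdIns4P"        = c("ptdins4p", "pi4p"),
    "PtdIns5P"        = c("ptdins5p", "pi5p"),
    "PtdIns(3,4)P2"   = c("ptdins34p2", "pi34p2"),
    "PtdIns(3,5)P2"   = c("ptdins35p2", "pi35p2"),
    "PtdIns(4,5)P2"   = c("ptdins45p2", "pi45p2"),
    "PtdIns(3,4,5)P3" = c("ptdins345p3", "pi345p3", "pip3"),
    "PS"              = c("ps", "phosphatidylserine", "pops", "dops")
  )
}

#' Match free-text lipid labels to the channel vocabulary
#'
#' Matching is case-insensitive and ignores punctuation, so `"PI(3,4)P2"`,
#' `"ptdins34p2"` and `"PtdIns(3,4)P2"` all resolve to the same channel.
#'
#' @param x Character vector of lipid labels.
#' @return Character vector of canonical channel names.
#' @export
match_lipid_channel <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  aliases <- .channel_aliases()
  canon <- rep(NA_character_, length(x))
  for (name in names(aliases)) {
    hit <- key %in% c(gsub("[^a-z0-9]", "", tolower(name)), aliases[[name]])
    canon[hit] <- name
  }
  if (anyNA(canon)) {
    stop("unrecognised lipid label(s): ",
         paste(unique(x[is.na(canon)]), collapse = ", "))
  }
  canon
}

#' @rdname lipid_channels
#' @param name Canonical channel name(s).
#' @return For `channel_category()`, the category of each channel.
#' @export
channel_category <- function(name) {
  ch <- lipid_channels()
  idx <- match(name, ch$name)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(unique(name[is.na(idx)]), collapse = ", "))
  ch$category[idx]
}
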