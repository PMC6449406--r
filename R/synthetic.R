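#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study conditions: a 39-protein screen with the
#' observed group proportions, multiplicative gel-band noise at 20% CV,
#' additive injection-heat noise, 0.01 ppm spectral jitter, and no
#' sequence corruption. A single root seed fans out to fixed
#' per-component substreams so each generator is a pure function of the
#' configuration and can be regenerated independently.
#'
#' @param seed Integer root seed.
#' @param n_proteins Number of synthetic proteins.
#' @param group_mix Proportions over groups I-IV (sum to 1).
#' @param gel_noise_cv Coefficient of variation of the lognormal band
#'   noise.
#' @param itc_noise_sd Gaussian noise on normalized heats (kcal/mol).
#' @param csp_noise_sd Gaussian jitter on peak positions (ppm).
#' @param mutation_rate Per-site corruption probability for planted
#'   determinant residues.
#' @return List of class `px_sim_config`.
#' @export
synthetic_config <- function(seed = 1, n_proteins = 39,
                             group_mix = c(I = 10, II = 12, III = 9,
                                           IV = 8) / 39,
                             gel_noise_cv = 0.2, itc_noise_sd = 0.1,
                             csp_noise_sd = 0.01, mutation_rate = 0) {
  if (abs(sum(group_mix) - 1) > 1e-8) stop("group_mix must sum to 1")
  if (length(group_mix) != 4 || any(group_mix < 0))
    stop("group_mix needs four non-negative proportions (I-IV)")
  if (any(c(gel_noise_cv, itc_noise_sd, csp_noise_sd, mutation_rate) < 0))
    stop("noise parameters must be >= 0")
  if (mutation_rate > 1) stop("mutation_rate is a probability")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 group_mix = stats::setNames(group_mix,
                                             c("I", "II", "III", "IV")),
                 gel_noise_cv = gel_noise_cv, itc_noise_sd = itc_noise_sd,
                 csp_noise_sd = csp_noise_sd, mutation_rate = mutation_rate),
            class = "px_sim_config")
}

# Substream seed for a named component, kept within 32-bit range.
.sub_seed <- function(config, component) {
  offset <- c(gel = 101L, itc = 211L, hsqc = 307L, alignment = 401L)[component]
  (config$seed * 1009L + offset) %% 2147483647L
}

# Deterministic group allocation matching the configured proportions.
.allocate_groups <- function(n, mix) {
  counts <- floor(n * mix)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- n * mix - counts
    bump <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[bump] <- counts[bump] + 1
  }
  rep(names(mix), counts)
}

# True per-channel binding booleans for a group (control/Folch handled
# separately): II binds PtdIns3P only; III one to three other-specific
# channels; IV both.
.sample_calls <- function(group) {
  ch <- lipid_channels()
  other <- ch$name[ch$category == "other-specific"]
  calls <- stats::setNames(rep(FALSE, nrow(ch)), ch$name)
  if (group %in% c("II", "IV")) calls["PtdIns3P"] <- TRUE
  if (group %in% c("III", "IV"))
    calls[sample(other, sample(1:3, 1))] <- TRUE
  calls["Folch"] <- any(calls[other])  # Folch co-occurs with broad binding
  calls
}

#' Synthetic pelleting-gel dataset with ground truth
#'
#' For every synthetic protein and panel channel a band pair is drawn so
#' that the noiseless P/S ratio sits mid-band for the channel archetype
#' (none 0.02, weak 0.5, strong 1.5, very strong 3.0); bound channels
#' draw their archetype strength uniformly from the three binding bands.
#' Both band intensities are then multiplied by lognormal noise with the
#' configured CV. Control lanes are always archetype none.
#'
#' @param config A [synthetic_config()].
#' @return List with `lanes` (data frame `protein`, `lipid`,
#'   `pellet_intensity`, `supernatant_intensity`) and `truth` (data
#'   frame `protein`, `group`, plus one logical column per channel).
#' @export
generate_gel_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "px_sim_config"))
  mid <- c(none = 0.02, weak = 0.5, strong = 1.5, very_strong = 3.0)
  withr::with_seed(.sub_seed(config, "gel"), {
    groups <- sample(.allocate_groups(config$n_proteins, config$group_mix))
    proteins <- sprintf("PX%03d", seq_len(config$n_proteins))
    sdlog <- sqrt(log(1 + config$gel_noise_cv^2))
    rows <- lapply(seq_along(proteins), function(i) {
      calls <- .sample_calls(groups[i])
      band <- ifelse(calls, sample(c("weak", "strong", "very_strong"),
                                   length(calls), replace = TRUE), "none")
      s <- rep(100, length(calls))
      p <- mid[band] * s
      if (config$gel_noise_cv > 0) {
        noise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
        p <- p * noise(length(p)); s <- s * noise(length(s))
      }
      list(lanes = data.frame(protein = proteins[i], lipid = names(calls),
                              pellet_intensity = unname(p),
                              supernatant_intensity = unname(s),
                              stringsAsFactors = FALSE),
           calls = calls)
    })
    truth <- data.frame(protein = proteins, group = groups,
                        do.call(rbind, lapply(rows, function(r)
                          as.data.frame(t(r$calls), check.names = TRUE))),
                        stringsAsFactors = FALSE, row.names = NULL)
    list(lanes = do.call(rbind, lapply(rows, `[[`, "lanes")), truth = truth)
  })
}

#' Synthetic ITC isotherm with ground truth
#'
#' Wraps [simulate_isotherm()] with additive Gaussian noise on the
#' normalized heats.
#'
#' @param config A [synthetic_config()].
#' @param params True [binding_params()].
#' @param schedule An [itc_schedule()].
#' @return List with `isotherm` (an `itc_isotherm`) and `truth` (the
#'   parameters and noise level).
#' @export
generate_itc_dataset <- function(config = synthetic_config(),
                                 params = binding_params(1e-5, -10),
                                 schedule = itc_schedule()) {
  stopifnot(inherits(config, "px_sim_config"))
  iso <- simulate_isotherm(params, schedule)
  withr::with_seed(.sub_seed(config, "itc"), {
    if (config$itc_noise_sd > 0)
      iso$heat <- iso$heat + stats::rnorm(nrow(iso), 0, config$itc_noise_sd)
  })
  list(isotherm = iso,
       truth = list(Kd = params$Kd, dH = params$dH, N = params$N,
                    noise_sd = config$itc_noise_sd))
}

#' Synthetic HSQC titration series with planted perturbed residues
#'
#' The apo spectrum scatters peaks over typical amide ranges
#' (1H 6.5-10 ppm, 15N 103-133 ppm). Planted residues move along a fixed
#' random direction, scaled by a hyperbolic saturation curve of ligand
#' concentration so that the combined shift change reaches `max_shift`
#' ppm at the final point; every other residue (and every point) jitters
#' with `csp_noise_sd`.
#'
#' @param config A [synthetic_config()].
#' @param n_residues Length of the synthetic domain.
#' @param planted_residues Residue ids to perturb (within the domain).
#' @param max_shift Combined shift change (ppm) of planted residues at
#'   the final titration point.
#' @param concs Non-decreasing ligand concentrations (M), first must
#'   be 0 (apo).
#' @param k_app Apparent Kd (M) of the saturation curve.
#' @param n_weight Nitrogen weight of the combined-shift formula.
#' @return List with `series` (as consumed by [series_max_csp()]) and
#'   `truth` (planted residue ids and `max_shift`).
#' @export
generate_hsqc_titration <- function(config = synthetic_config(),
                                    n_residues = 110,
                                    planted_residues = c(734, 762) - 660,
                                    max_shift = 0.3,
                                    concs = c(0, 25, 50, 100, 200, 400) * 1e-6,
                                    k_app = 50e-6, n_weight = 0.17) {
  stopifnot(inherits(config, "px_sim_config"))
  if (any(planted_residues < 1 | planted_residues > n_residues))
    stop("planted residues must lie within the domain")
  if (concs[1] != 0 || is.unsorted(concs))
    stop("concentrations must start at 0 (apo) and be non-decreasing")
  withr::with_seed(.sub_seed(config, "hsqc"), {
    apo <- data.frame(residue_id = seq_len(n_residues),
                      h_ppm = stats::runif(n_residues, 6.5, 10),
                      n_ppm = stats::runif(n_residues, 103, 133))
    theta <- stats::runif(length(planted_residues), 0, 2 * pi)
    sat <- concs / (concs + k_app)
    sat <- sat / sat[length(sat)]
    points <- lapply(seq_along(concs), function(j) {
      sp <- apo
      if (j > 1) {
        if (config$csp_noise_sd > 0) {
          sp$h_ppm <- sp$h_ppm +
            stats::rnorm(n_residues, 0, config$csp_noise_sd)
          sp$n_ppm <- sp$n_ppm +
            stats::rnorm(n_residues, 0, config$csp_noise_sd)
        }
        k <- match(planted_residues, sp$residue_id)
        sp$h_ppm[k] <- apo$h_ppm[k] + sat[j] * max_shift * cos(theta)
        sp$n_ppm[k] <- apo$n_ppm[k] +
          sat[j] * max_shift * sin(theta) / n_weight
      }
      list(conc = concs[j], spectrum = sp)
    })
    list(series = list(ligand = "synthetic-PIP", points = points),
         truth = list(planted_residues = sort(planted_residues),
                      max_shift = max_shift))
  })
}

#' Synthetic structure-guided alignment with planted determinants
#'
#' Builds an alignment on the packaged scaffold annotation. Each protein
#' gets random residues everywhere, then determinants planted per its
#' true group: groups II/IV receive the canonical four residues
#' (junction Arg/Tyr, PPK Lys inside a planted Psi-P-x-x-P-x-K motif,
#' alpha2 Arg); groups III/IV receive a His or Tyr at the first alpha1
#' column and 2-4 basic residues in the secondary window. Positions that
#' must not fake a determinant (anchors of absent sites, window basics,
#' the alpha1-first His/Tyr) are drawn from reduced alphabets. Planted
#' determinant positions are corrupted independently with probability
#' `mutation_rate`.
#'
#' @param config A [synthetic_config()].
#' @param annotation A `px_annotation` (default the packaged scaffold).
#' @return List with `alignment` (named character vector), `annotation`,
#'   and `truth` (data frame `protein`, `group`).
#' @export
generate_alignment_with_planted_sites <- function(
    config = synthetic_config(), annotation = px_reference_annotation()) {
  stopifnot(inherits(config, "px_sim_config"),
            inherits(annotation, "px_annotation"))
  width <- length(annotation$element)
  anch <- annotation$anchors
  window <- secondary_site_window(annotation)
  ppk_start <- min(which(annotation$element == "ppk_loop"))
  motif_cols <- anch[["ppk_lys"]] - 6:0          # Psi..K, K at the anchor
  if (any(motif_cols < ppk_start))
    stop("annotation PPK anchor too close to the loop start for the motif")
  no_basic <- setdiff(AA20, c("K", "R"))
  no_hy <- setdiff(AA20, c("H", "Y"))
  withr::with_seed(.sub_seed(config, "alignment"), {
    groups <- sample(.allocate_groups(config$n_proteins, config$group_mix))
    proteins <- sprintf("PX%03d", seq_len(config$n_proteins))
    seqs <- vapply(seq_along(proteins), function(i) {
      g <- groups[i]
      s <- sample(AA20, width, replace = TRUE)
      canonical <- g %in% c("II", "IV")
      secondary <- g %in% c("III", "IV")
      if (canonical) {
        s[anch[["junction_arg"]]] <- "R"
        s[anch[["junction_tyr"]]] <- "Y"
        s[anch[["alpha2_arg"]]] <- "R"
        s[motif_cols] <- c(sample(c("V", "I", "L", "M"), 1), "P",
                           sample(no_basic, 2, replace = TRUE), "P",
                           sample(no_basic, 1), "K")
      } else {
        for (a in c("junction_arg", "junction_tyr", "alpha2_arg"))
          s[anch[[a]]] <- sample(setdiff(AA20, c("R", "Y", "K")), 1)
        s[anch[["ppk_lys"]]] <- sample(setdiff(AA20, "K"), 1)
      }
      # secondary window: clear of basics first, then plant if needed
      clear <- setdiff(window, motif_cols)
      s[clear] <- sample(no_basic, length(clear), replace = TRUE)
      if (secondary) {
        s[anch[["alpha1_first"]]] <- sample(c("H", "Y"), 1)
        spots <- setdiff(window, c(anch[["ppk_lys"]],
                                   motif_cols[c(1, 2, 5)]))
        plant <- sample(spots, sample(2:4, 1))
        s[plant] <- sample(c("K", "R"), length(plant), replace = TRUE)
      } else {
        s[anch[["alpha1_first"]]] <- sample(no_hy, 1)
      }
      if (config$mutation_rate > 0) {
        planted <- unique(c(anch, if (canonical) motif_cols,
                            if (secondary) window))
        hit <- planted[stats::runif(length(planted)) < config$mutation_rate]
        for (col in hit) s[col] <- sample(setdiff(AA20, s[col]), 1)
      }
      paste(s, collapse = "")
    }, character(1))
    list(alignment = stats::setNames(seqs, proteins),
         annotation = annotation,
         truth = data.frame(protein = proteins, group = groups,
                            stringsAsFactors = FALSE))
  })
}
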