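ann <- px_reference_annotation()

test_that("PPK motif scanning matches constructed and frozen cases", {
  hit <- detect_ppk_motif("AAVPQRPGKAA")
  expect_equal(hit$start, 3L)          # spec example, 1-based
  expect_equal(hit$psi_residue, "V")
  expect_equal(nrow(detect_ppk_motif("AAAPQRPGKAA")), 0L)  # A not in Psi
  two <- detect_ppk_motif("MPAAPAKVPAAPAK")
  expect_equal(two$start, c(1L, 8L))
  expect_equal(two$matched_text, c("MPAAPAK", "VPAAPAK"))
  expect_error(detect_ppk_motif("AXB-"), "invalid residue")
})

test_that("PPK motif scanner agrees with the brute-force 7-mer oracle", {
  withr::with_seed(42, {
    # enriched alphabet so matches actually occur
    alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  rep(c("V", "I", "L", "M", "P", "K"), 4))
    for (rep_i in 1:200) {
      s <- paste(sample(alphabet, sample(1:50, 1), replace = TRUE),
                 collapse = "")
      expect_identical(detect_ppk_motif(s)$start, brute_force_ppk(s),
                       label = s)
    }
  })
})

test_that("canonical-site assessment reads the four anchors", {
  full <- scaffold_sequence(ann, canonical_residues(ann))
  rep <- assess_canonical_site(full, ann)
  expect_true(rep$complete)
  expect_equal(unname(rep$residues_at_anchors), c("R", "Y", "K", "R"))

  # mutating the alpha2 Arg alone breaks completeness
  mut <- canonical_residues(ann)
  mut[as.character(ann$anchors[["alpha2_arg"]])] <- "A"
  rep2 <- assess_canonical_site(scaffold_sequence(ann, mut), ann)
  expect_false(rep2$complete)
  expect_false(rep2$alpha2_arg_present)
  expect_true(rep2$junction_arg_present && rep2$ppk_lys_present)

  allgap <- paste(rep("-", length(ann$element)), collapse = "")
  rep3 <- assess_canonical_site(allgap, ann)
  expect_false(any(unlist(rep3[c("junction_arg_present",
                                 "junction_tyr_present", "ppk_lys_present",
                                 "alpha2_arg_present")])))
  expect_error(assess_canonical_site("RYKR", ann), "width")
})

test_that("secondary-site assessment needs His/Tyr plus enough basics", {
  rep <- assess_secondary_site(
    scaffold_sequence(ann, secondary_residues(ann, 2, "H")), ann)
  expect_true(rep$hy_present)
  expect_equal(rep$basic_count, 2L)
  expect_true(rep$present)

  # no His/Tyr: absent regardless of basics
  noHY <- secondary_residues(ann, 4, "H")
  noHY[as.character(ann$anchors[["alpha1_first"]])] <- "A"
  expect_false(assess_secondary_site(
    scaffold_sequence(ann, noHY), ann)$present)

  # Tyr with a single basic fails the default minimum of two
  oneK <- assess_secondary_site(
    scaffold_sequence(ann, secondary_residues(ann, 1, "Y")), ann)
  expect_true(oneK$hy_present)
  expect_false(oneK$present)
  expect_true(assess_secondary_site(
    scaffold_sequence(ann, secondary_residues(ann, 1, "Y")), ann,
    min_basics = 1)$present)
})

test_that("group prediction agrees with exhaustive rule enumeration", {
  for (complete in c(FALSE, TRUE)) for (present in c(FALSE, TRUE)) {
    want <- if (complete && present) "IV" else if (complete) "II"
            else if (present) "III" else "I"
    pred <- predict_group(stub_canonical(complete), stub_secondary(present))
    expect_equal(pred$predicted_group, want)
  }
  # exception notes annotate, never override
  pred <- predict_group(stub_canonical(TRUE), stub_secondary(TRUE), "SNX15")
  expect_equal(pred$predicted_group, "IV")
  expect_match(pred$exception_note, "domain-swapped")
  plain <- predict_group(stub_canonical(TRUE), stub_secondary(TRUE), "SNX3")
  expect_true(is.na(plain$exception_note))
})

test_that("proteome prediction preserves order and isolates bad records", {
  aln <- c(canon = scaffold_sequence(ann, canonical_residues(ann)),
           secon = scaffold_sequence(ann, secondary_residues(ann)),
           broken = "TOOSHORT")
  out <- predict_proteome(aln, ann)
  expect_equal(out$protein, names(aln))
  expect_equal(out$predicted_group[1:2], c("II", "III"))
  expect_true(is.na(out$predicted_group[3]) && !is.na(out$error[3]))
  empty <- predict_proteome(character(0), ann)
  expect_equal(nrow(empty), 0L)
})

test_that("planted-site alignments are recovered exactly without noise", {
  g <- generate_alignment_with_planted_sites(
    synthetic_config(seed = 11, n_proteins = 20))
  pred <- predict_proteome(g$alignment, g$annotation)
  expect_equal(pred$predicted_group, g$truth$group)
})

test_that("reports are insensitive to gap columns outside the windows", {
  g <- generate_alignment_with_planted_sites(
    synthetic_config(seed = 23, n_proteins = 8))
  before <- predict_proteome(g$alignment, g$annotation)
  # insert gaps in beta1, the beta2/beta3 linker, and alpha3
  shifted <- insert_gap_columns(g$alignment, g$annotation, c(2, 28, 100))
  after <- predict_proteome(shifted$alignment, shifted$annotation)
  expect_equal(after$predicted_group, before$predicted_group)
  expect_equal(after$canonical_complete, before$canonical_complete)
  expect_equal(after$basic_count, before$basic_count)
})

test_that("alignment FASTA and annotation TSV round trips", {
  g <- generate_alignment_with_planted_sites(
    synthetic_config(seed = 5, n_proteins = 4))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(g$alignment, fa)
  expect_identical(read_alignment_fasta(fa), g$alignment)
  expect_error(as_px_annotation(data.frame(
    column = 1:3, element = c("beta1", "nonsense", "alpha1"),
    anchor = "")), "element")
})
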