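test_that("P/S ratio arithmetic, saturation and invalid lanes", {
  expect_equal(compute_ps_ratio(50, 50), 1.0)
  expect_equal(compute_ps_ratio(100, 40), 2.5)
  expect_equal(compute_ps_ratio(0, 100), 0.0)
  expect_identical(compute_ps_ratio(100, 0), Inf)
  expect_error(compute_ps_ratio(0, 0), "invalid lane")
  expect_error(compute_ps_ratio(-1, 10), "non-negative")
})

test_that("band classification follows the quantification rule", {
  expect_equal(as.character(classify_strength(2.5)), "very_strong")
  expect_equal(as.character(classify_strength(0.05)), "none")
  expect_equal(as.character(classify_strength(1.5)), "strong")
  # interval edges: 0.1 opens weak, 1 opens strong, 2 is still strong
  expect_equal(as.character(classify_strength(c(0.1, 1, 2, 2 + 1e-9))),
               c("weak", "strong", "strong", "very_strong"))
  expect_equal(as.character(classify_strength(Inf)), "very_strong")
  expect_error(classify_strength(-0.1), "non-negative")
})

test_that("band classification is monotone and scale invariant", {
  ratios <- sort(c(0, 10^runif(200, -3, 1), 0.1, 1, 2, Inf))
  bands <- classify_strength(ratios)
  expect_true(all(diff(as.integer(bands)) >= 0))
  # scaling both intensities leaves ratio and band unchanged
  for (k in c(0.25, 3, 117)) {
    expect_equal(compute_ps_ratio(40 * k, 80 * k), 0.5)
    expect_equal(classify_strength(compute_ps_ratio(40 * k, 80 * k)),
                 classify_strength(0.5))
  }
})

test_that("profiles compose lanes and flag control violations", {
  ch <- lipid_channels()$name
  all_unbound <- build_binding_profile("test", data.frame(
    lipid = ch, pellet_intensity = 0, supernatant_intensity = 100))
  expect_s3_class(all_unbound, "px_profile")
  expect_true(all(all_unbound$lanes$band == "none"))
  expect_false(all_unbound$control_violation)

  p3p_only <- profile_from_ratios("test", c("PtdIns3P" = 2.5))
  lanes <- p3p_only$lanes
  expect_equal(as.character(lanes$band[lanes$lipid == "PtdIns3P"]),
               "very_strong")
  expect_true(all(lanes$band[lanes$lipid != "PtdIns3P"] == "none"))

  dirty <- profile_from_ratios("test", c("PC/PE-control" = 2.5))
  expect_true(dirty$control_violation)
  expect_error(assign_group(dirty), "control violation")

  expect_error(build_binding_profile("x", data.frame(
    lipid = c("PtdIns3P", "PtdIns3P", "PC/PE-control"),
    pellet_intensity = 1, supernatant_intensity = 1)), "duplicate")
  expect_error(build_binding_profile("x", data.frame(
    lipid = "PtdIns3P", pellet_intensity = 1, supernatant_intensity = 1)),
    "control")
})

test_that("group assignment matches the published class definitions", {
  expect_equal(assign_group(profile_from_ratios("a", c(PtdIns3P = 1.5))),
               "II")
  expect_equal(assign_group(profile_from_ratios("b", numeric(0))), "I")
  expect_equal(assign_group(profile_from_ratios(
    "c", c("PtdIns(4,5)P2" = 1.5, "PS" = 0.5))), "III")
  expect_equal(assign_group(profile_from_ratios(
    "d", c(PtdIns3P = 1.5, "PtdIns(3,4)P2" = 2.5))), "IV")
  # threshold is configurable: a weak-only binder is Group I at "strong"
  weakish <- profile_from_ratios("e", c(PtdIns3P = 0.5))
  expect_equal(assign_group(weakish), "II")
  expect_equal(assign_group(weakish, binding_threshold = "strong"), "I")
})

test_that("group rule agrees with brute-force enumeration over channels", {
  specific <- lipid_channels()
  specific <- specific$name[specific$category != "control"]
  # every binding/non-binding combination of the nine non-control channels
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(specific)))
  names(combos) <- specific
  for (i in seq_len(nrow(combos))) {
    on <- specific[unlist(combos[i, ])]
    prof <- profile_from_ratios("x", setNames(rep(1.5, length(on)), on))
    a <- "PtdIns3P" %in% on
    b <- length(setdiff(on, c("PtdIns3P", "Folch"))) > 0
    want <- if (a && b) "IV" else if (a) "II" else if (b) "III" else "I"
    got <- suppressWarnings(assign_group(prof))
    expect_equal(got, want, info = paste(on, collapse = "+"))
  }
})

test_that("Folch binding without specific binding warns but stays Group I", {
  prof <- profile_from_ratios("f", c(Folch = 1.5))
  expect_warning(g <- assign_group(prof), "Folch")
  expect_equal(g, "I")
})

test_that("census counts partition the input", {
  profs <- list(profile_from_ratios("a", c(PtdIns3P = 1.5)),
                profile_from_ratios("b", numeric(0)),
                profile_from_ratios("c", c(PS = 1.5)))
  cens <- group_census(profs)
  expect_equal(sum(cens), length(profs))
  expect_equal(unname(cens), c(1L, 1L, 1L, 0L))
  expect_equal(sum(group_census(list())), 0L)
  one <- group_census(list(profile_from_ratios("z", numeric(0))))
  expect_equal(unname(one), c(1L, 0L, 0L, 0L))
})

test_that("lane CSV round trip preserves profiles", {
  ch <- lipid_channels()$name
  lanes <- expand.grid(protein = c("A", "B"), lipid = ch,
                       stringsAsFactors = FALSE)
  lanes$pellet_intensity <- ifelse(
    lanes$protein == "A" & lanes$lipid == "PtdIns3P", 150, 2)
  lanes$supernatant_intensity <- 100
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(lanes, tmp, row.names = FALSE)
  profs <- read_lanes_csv(tmp)
  expect_named(profs, c("A", "B"))
  expect_equal(group_table(profs)$group, c("II", "I"))
  tab <- profile_table(profs)
  expect_equal(nrow(tab), 2 * length(ch))
})
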