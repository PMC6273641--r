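test_that("carbon positions reproduce the published C15/C13/C2 anchors", {
  expect_equal(carbon_positions(13, 7)$beta, 15)
  expect_equal(carbon_positions(13, 8)$beta, 13)
  expect_equal(carbon_positions(13, 13)$alpha, 2)
  expect_equal(carbon_positions(13, 13)$carbonyl, 1)
  expect_equal(carbon_positions(13, 0)$carbonyl, 27)
  expect_equal(carbon_positions(13, 0)$alpha, 28)
})

test_that("carbon pairs over all modules tile 1..2M+2 exactly once", {
  for (M in 1:6) {
    pairs <- unlist(lapply(0:M, function(m) {
      p <- carbon_positions(M, m)
      c(p$carbonyl, p$alpha)
    }))
    expect_setequal(pairs, seq_len(2 * M + 2))
  }
  expect_error(carbon_positions(5, 6), "outside")
  expect_error(carbon_positions(5, -1), "outside")
})

test_that("beta states follow the reductive domain rule table", {
  arch <- parse_architecture(paste0(
    "P [(KS-AT-ACP)-(KS-AT-KR-ACP)-(KS-AT-DH-KR-ACP)-",
    "(KS-AT-DH-ER-KR-ACP)-(KS-AT-ACP)-TE]"
  ))
  line <- segment_modules(architecture_to_hits(arch))
  asg <- tibble::tibble(module_index = 0:4, unit = "malonyl",
                        side_chain_carbons = 0L)
  units <- walk_assembly(line, asg)
  ext <- units[units$m > 0, ]
  expect_equal(ext$beta_state, c("hydroxyl", "enoyl", "methylene", "keto"))
})

test_that("the worked-example walk reproduces the published state pattern", {
  ext <- tha_units[tha_units$m > 0, ]
  expect_equal(ext$beta_state[ext$m == 1], "hydroxyl")
  expect_true(all(ext$beta_state[ext$m %in% 2:6] == "enoyl"))
  expect_equal(ext$beta_state[ext$m == 7], "hydroxyl")   # inactive DH -> C15-OH
  expect_equal(ext$beta_state[ext$m == 8], "keto")       # overridden KR -> C13 keto
  expect_true(all(ext$beta_state[ext$m %in% 9:13] == "hydroxyl"))
  expect_equal(ext$side_chain_carbons[ext$m == 6], 1L)
  expect_equal(ext$side_chain_carbons[ext$m == 13], 4L)
})

test_that("without the KR8 override the keto (and hemiketal) disappear", {
  units <- walk_assembly(tha_line, tha_asg_rec)
  expect_equal(units$beta_state[units$m == 8], "hydroxyl")
  prod <- apply_post_pks(units, thailandin_post_pks())
  expect_false("hemiketal" %in% prod$rings$type)
})

test_that("beta states match generator truth on random plans", {
  for (s in c(3, 14, 27)) {
    sim <- generate_cluster(random_module_plan(s), seed = s + 100)
    line <- segment_modules(suppressWarnings(annotate_proteins(sim$proteins)))
    asg <- assign_extenders(line)
    truth <- sim$truth$modules
    units <- walk_assembly(line, asg)
    ext <- units[units$m > 0, ]
    expect_identical(ext$beta_state,
                     truth$beta_state[truth$role == "extension"],
                     label = paste("seed", s))
  }
})

test_that("the thailandin product reproduces rings, hydroxyls and masses", {
  feat <- compute_features(tha_product)
  expect_equal(feat$formula, "C33H52O10")
  expect_equal(feat$monoisotopic_mass, oracle_mono_mass(33, 52, 10),
               tolerance = 1e-9)
  expect_equal(feat$monoisotopic_mass_int, 608L)
  expect_equal(feat$macrolactone_members, 28L)
  expect_equal(feat$hemiketal_members, 6L)
  expect_equal(tha_product$free_hydroxyl_positions,
               c(3L, 5L, 7L, 11L, 13L, 15L, 26L))
  expect_equal(feat$conjugated_double_bond_count, 5L)
  expect_equal(feat$methyl_count, 2L)
  # hemiketal partners: keto C13 with the C9 hydroxyl
  hemi <- tha_product$rings[tha_product$rings$type == "hemiketal", ]
  expect_true(all(c("C9", "C13") %in% hemi$members[[1]]))
})

test_that("rhamnosylation at C15 adds the sugar mass and consumes one OH", {
  prodA <- apply_post_pks(tha_units, thailandin_post_pks(rhamnosylation = TRUE))
  featA <- compute_features(prodA)
  featB <- compute_features(tha_product)
  expect_equal(featA$n_free_hydroxyls, featB$n_free_hydroxyls - 1L)
  expect_false(15 %in% prodA$free_hydroxyl_positions)
  expect_equal(featA$monoisotopic_mass - featB$monoisotopic_mass,
               146.0579, tolerance = 1e-4 / 146)
  expect_equal(featA$monoisotopic_mass_int, 754L)
  expect_equal(featA$formula, "C39H62O14")
})

test_that("glycosylation demands a free hydroxyl and a supported sugar", {
  cfg <- thailandin_post_pks()
  cfg$glycosylations <- list(list(carbon = 13L, sugar = "mycosamine"))
  expect_error(apply_post_pks(tha_units, cfg), "unsupported sugar")
  cfg$glycosylations <- list(list(carbon = 9L, sugar = "rhamnose"))
  expect_error(apply_post_pks(tha_units, cfg), "not a free hydroxyl")
})

test_that("hemiketal formation conserves atoms; lactonization removes H2O", {
  cfg_no_hemi <- thailandin_post_pks()
  cfg_no_hemi$hemiketal <- "off"
  open <- apply_post_pks(tha_units, cfg_no_hemi)
  expect_equal(compute_features(open)$formula,
               compute_features(tha_product)$formula)
  expect_equal(compute_features(open)$monoisotopic_mass,
               compute_features(tha_product)$monoisotopic_mass)

  cfg_acid <- thailandin_post_pks()
  cfg_acid$macrolactonization <- "off"
  acid <- apply_post_pks(tha_units, cfg_acid)
  d_formula <- compute_features(acid)$monoisotopic_mass -
    compute_features(tha_product)$monoisotopic_mass
  expect_equal(d_formula, oracle_mono_mass(0, 2, 1), tolerance = 1e-9)
})

test_that("macrolactonization without any hydroxyl is a linear product error", {
  arch <- parse_architecture("P [(KS-AT-ACP)-(KS-AT-ACP)-TE]")
  line <- segment_modules(architecture_to_hits(arch))
  asg <- tibble::tibble(module_index = 0:1, unit = "malonyl",
                        side_chain_carbons = 0L)
  units <- walk_assembly(line, asg)
  expect_error(apply_post_pks(units, post_pks_config(hemiketal = "off")),
               "linear product")
})

test_that("unsaturation bookkeeping is consistent on random products", {
  for (s in 0:9) {
    tl <- random_token_line(s)
    units <- walk_assembly(tl$line, tl$assignments)
    prod <- apply_post_pks(units, post_pks_config())
    feat <- compute_features(prod)  # errors if graph and formula disagree
    gl <- prod$graph
    expect_equal(feat$degrees_of_unsaturation,
                 (2 * feat$n_carbon + 2 - feat$n_hydrogen) / 2)
    # mass monotone in chain length under all-malonyl follows separately
    expect_gt(feat$monoisotopic_mass, 0)
  }
})

test_that("all-malonyl product mass grows with the number of modules", {
  masses <- vapply(2:7, function(M) {
    groups <- paste(rep("(KS-AT-KR-ACP)", M), collapse = "-")
    arch <- parse_architecture(paste0("P [(KS-AT-ACP)-", groups, "-TE]"))
    line <- segment_modules(architecture_to_hits(arch))
    asg <- tibble::tibble(module_index = 0:M, unit = "malonyl",
                          side_chain_carbons = 0L)
    prod <- apply_post_pks(walk_assembly(line, asg),
                           post_pks_config(hemiketal = "off"))
    compute_features(prod)$monoisotopic_mass
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("a conjugation gap caps the longest enoyl run", {
  gap <- walk_assembly(tha_line, tha_asg_rec, overrides = dplyr::bind_rows(
    thailandin_overrides(),
    tibble::tibble(module_index = 4L, domain_type = "DH", active = FALSE)
  ))
  prod <- apply_post_pks(gap, thailandin_post_pks())
  expect_equal(compute_features(prod)$conjugated_double_bond_count, 2L)
})

test_that("spec matching passes the worked example and fails the variant", {
  ms <- match_spec(tha_product, thailandin_compound())
  expect_true(all(ms$pass))
  expect_true(attr(ms, "pass"))

  asg_ethyl <- tha_asg_rec
  asg_ethyl$unit[asg_ethyl$module_index == 13] <- "ethylmalonyl"
  asg_ethyl$side_chain_carbons[asg_ethyl$module_index == 13] <- 2L
  variant <- walk_assembly(tha_line, asg_ethyl,
                           overrides = thailandin_overrides()) |>
    apply_post_pks(thailandin_post_pks())
  msv <- match_spec(variant, thailandin_compound())
  mass_row <- msv[msv$constraint == "monoisotopic_mass", ]
  expect_false(mass_row$pass)
  expect_equal(mass_row$deviation,
               thailandin_compound()$target_monoisotopic_mass -
                 oracle_mono_mass(31, 48, 10),
               tolerance = 1e-9)
  expect_false(attr(msv, "pass"))
})

test_that("a minimal product fails every thailandin constraint", {
  arch <- parse_architecture("P [(KS-AT-ACP)-(KS-AT-KR-ACP)-TE]")
  line <- segment_modules(architecture_to_hits(arch))
  asg <- tibble::tibble(module_index = 0:1, unit = "malonyl",
                        side_chain_carbons = 0L)
  prod <- apply_post_pks(walk_assembly(line, asg),
                         post_pks_config(hemiketal = "off"))
  ms <- match_spec(prod, thailandin_compound())
  expect_false(any(ms$pass))
  expect_false(attr(ms, "pass"))
})

test_that("malformed modules stop the walk with their index", {
  arch <- parse_architecture("P [(KS-AT-ACP)-(KS-AT-KR-ACP)]")
  hits <- architecture_to_hits(arch)
  hits <- hits[hits$domain_type != "ACP" | hits$start < 300, ]  # drop one ACP
  line <- segment_modules(hits)
  expect_true(any(line$modules$malformed))
  asg <- tibble::tibble(module_index = 0:1, unit = "malonyl",
                        side_chain_carbons = 0L)
  expect_error(walk_assembly(line, asg), "malformed")
})
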