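test_that("extender classification follows the motif decision table", {
  expect_equal(classify_extender("L", "HAFH")$unit, "malonyl")
  expect_equal(classify_extender("L", "HAFH")$evidence, "motif")
  expect_equal(classify_extender("Q", NA)$unit, "methylmalonyl")
  expect_equal(classify_extender("Q", NA)$evidence, "motif")
  expect_equal(classify_extender("Q", "YASH")$unit, "methylmalonyl")
  res <- classify_extender("Q", "AAGH")
  expect_equal(res$unit, "ethylmalonyl")
  expect_equal(res$evidence, "motif_flagged")
  # flagged core motif alone is enough to mark the AT unusual
  res2 <- classify_extender("Q", NA, core_flagged = TRUE)
  expect_equal(res2$evidence, "motif_flagged")
})

test_that("extender classification is total over letters and motifs", {
  for (x in LETTERS) {
    for (sec in c("HAFH", "YASH", "AAGH", NA_character_)) {
      res <- classify_extender(x, sec)
      expect_true(res$unit %in% c(extender_units()$name, "unknown"))
      expect_true(res$evidence %in% c("motif", "motif_flagged", "unknown"))
      if (!is.na(sec) && sec == "AAGH") {
        expect_equal(res$evidence, "motif_flagged")
      } else if (x %in% c("L", "V", "I", "F", "A", "M")) {
        expect_equal(res$unit, "malonyl")
      } else if (x == "Q") {
        expect_equal(res$unit, "methylmalonyl")
      } else {
        expect_true("unrecognized_x" %in% res$flags[[1]])
      }
    }
  }
  expect_equal(classify_extender(NA_character_)$unit, "unknown")
})

test_that("unit catalogue spans malonyl to hexylmalonyl in CH2 steps", {
  u <- extender_units()
  expect_equal(u$side_chain_carbons, 0:6)
  expect_equal(diff(u$mass_delta), rep(14.01565, 6))
})

test_that("reconciliation selects butylmalonyl for the flagged module 13", {
  rec <- tha_asg_rec
  m13 <- rec[rec$module_index == 13, ]
  expect_equal(m13$unit, "butylmalonyl")
  expect_equal(m13$side_chain_carbons, 4L)
  expect_equal(m13$evidence, "reconciled")
  expect_lte(attr(rec, "mass_error"), 0.5)
  expect_true(attr(rec, "ccr_present"))
  expect_true("ccr_supported" %in% m13$flags[[1]])
})

test_that("the ethylmalonyl alternative misses the target mass by ~28 Da", {
  asg_ethyl <- tha_asg_rec
  asg_ethyl$unit[asg_ethyl$module_index == 13] <- "ethylmalonyl"
  asg_ethyl$side_chain_carbons[asg_ethyl$module_index == 13] <- 2L
  prod <- walk_assembly(tha_line, asg_ethyl, overrides = thailandin_overrides()) |>
    apply_post_pks(thailandin_post_pks())
  feat <- compute_features(prod)
  expect_equal(feat$formula, "C31H48O10")
  expect_equal(feat$monoisotopic_mass, oracle_mono_mass(31, 48, 10),
               tolerance = 1e-9)
  expect_equal(feat$monoisotopic_mass, 580.33, tolerance = 0.01 / 580)
  expect_equal(
    abs(feat$monoisotopic_mass -
          thailandin_compound()$target_monoisotopic_mass - 0.356),
    28.03, tolerance = 0.01
  )
})

test_that("reconciliation never alters motif-evidence assignments", {
  rec <- tha_asg_rec
  motif_rows <- tha_asg$evidence == "motif"
  expect_identical(rec$unit[motif_rows], tha_asg$unit[motif_rows])
  expect_identical(rec$evidence[motif_rows], tha_asg$evidence[motif_rows])
})

test_that("reconciliation is a no-op without flagged assignments", {
  asg <- tha_asg
  asg$evidence[asg$evidence == "motif_flagged"] <- "motif"
  out <- reconcile_with_compound(tha_line, asg, thailandin_compound(),
                                 post_pks = thailandin_post_pks())
  expect_identical(out, asg)
})

test_that("an unreachable target mass leaves the motif call flagged", {
  out <- reconcile_with_compound(
    tha_line, tha_asg,
    compound_spec(target_monoisotopic_mass = 1000),
    post_pks = thailandin_post_pks(),
    overrides = thailandin_overrides()
  )
  m13 <- out[out$module_index == 13, ]
  expect_equal(m13$evidence, "motif_flagged")
  expect_true("unreconciled" %in% m13$flags[[1]])
  expect_equal(m13$unit, "ethylmalonyl")
})

test_that("CCR gene detection matches annotation text only", {
  expect_true(detect_ccr_gene(thailandin_genes()))
  expect_false(detect_ccr_gene(tibble::tibble(gene = character(),
                                              product = character())))
  expect_false(detect_ccr_gene(tibble::tibble(
    gene = "x", product = "enoyl-CoA hydratase"
  )))
})

test_that("the loading module records its acetate starter", {
  m0 <- tha_asg[tha_asg$module_index == 0, ]
  expect_equal(m0$unit, "malonyl")
  expect_true("starter_acetate_via_decarboxylation" %in% m0$flags[[1]])
})
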