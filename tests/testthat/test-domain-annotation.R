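test_that("planted KS-AT-ACP protein yields exactly those hits in order", {
  plan <- module_plan(tibble::tibble(
    protein = "p1", domains = list(c("KS", "AT", "ACP"))
  ), proteins = tibble::tibble(name = "p1", n_term_dock = FALSE,
                               c_term_dock = FALSE))
  sim <- generate_cluster(plan, seed = 1)
  hits <- scan_domains(sim$proteins[1, ])
  expect_equal(hits$domain_type, c("KS", "AT", "ACP"))
  expect_true(all(hits$start < hits$end))
  expect_true(all(hits$end <= nchar(sim$proteins$sequence[1])))
})

test_that("a ThaBI-like five-module protein yields the planted domain census", {
  # loading (KS-AT-ACP), (KS-AT-KR-ACP), 3x (KS-AT-DH-KR-ACP)
  hits <- tha_sim$proteins[1, ] |> scan_domains()
  census <- table(hits$domain_type)
  expect_equal(as.vector(census[c("KS", "AT", "DH", "KR", "ACP")]),
               c(5L, 5L, 3L, 4L, 5L))
})

test_that("hits never overlap and stay within the protein", {
  for (s in c(2, 17, 31)) {
    sim <- generate_cluster(random_module_plan(s), seed = s)
    for (i in seq_len(nrow(sim$proteins))) {
      h <- scan_domains(sim$proteins[i, ])
      expect_true(all(h$start >= 0 & h$end <= nchar(sim$proteins$sequence[i])))
      if (nrow(h) > 1) {
        expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
      }
    }
  }
})

test_that("degenerate motif patterns are rejected as a config error", {
  cfg <- default_motif_config()
  cfg$domains$KS$motifs[[1]]$pattern <- "A"
  expect_error(scan_domains(strrep("A", 2000), cfg), "degenerate")
})

test_that("AT active-site extraction reads x and flags the GHSQH variant", {
  mk <- function(window) {
    domain_hit("p", "AT", 0, 310,
               matched = c(at_anchor = TRUE, at_core = TRUE),
               motif_windows = list(at_core = window))
  }
  expect_equal(at_active_site(mk("GHSLG"))$x, "L")
  expect_equal(at_active_site(mk("GHSQG"))$x, "Q")
  res <- at_active_site(mk("GHSQH"))
  expect_equal(res$x, "Q")
  expect_true("noncanonical_fifth_residue" %in% res$flags)
  missing <- at_active_site(domain_hit("p", "AT", 0, 310,
                                       matched = c(at_anchor = TRUE)))
  expect_true(is.na(missing$x))
  expect_true("at_core_motif_missing" %in% missing$flags)
})

test_that("KS active-site residue maps to condensing/loading/unknown", {
  mk <- function(res) {
    domain_hit("p", "KS", 0, 420,
               matched = c(ks_box = TRUE, ks_active_site = TRUE),
               active_site = list(ks_active_site = res))
  }
  expect_equal(ks_loading_call(mk("C"))$call, "condensing")
  expect_equal(ks_loading_call(mk("Q"))$call, "decarboxylative_loading")
  s <- ks_loading_call(mk("S"))
  expect_equal(s$call, "unknown")
  expect_true("noncanonical_ks_active_site" %in% s$flags)
  expect_equal(ks_loading_call(domain_hit("p", "KS", 0, 420))$call, "unknown")
})

test_that("DH activity is a pure function of the four motif booleans", {
  for (core in c(TRUE, FALSE)) {
    for (a1 in c(TRUE, FALSE)) {
      for (a2 in c(TRUE, FALSE)) {
        for (a3 in c(TRUE, FALSE)) {
          res <- dh_activity(synthetic_dh_hit(core, a1, a2, a3))
          n_fail <- sum(!c(a1, a2, a3))
          expect_equal(res$active, core && n_fail <= 1)
          expect_length(res$reasons, n_fail + !core)
        }
      }
    }
  }
  # the published inactive-DH case: core intact, all auxiliaries altered
  res <- dh_activity(synthetic_dh_hit(TRUE, FALSE, FALSE, FALSE))
  expect_false(res$active)
  expect_setequal(res$reasons,
                  c("dh_aux_gyxygpxf", "dh_aux_lpfxw", "dh_aux_dxxxqh"))
  # one benign substitution does not cross the threshold
  expect_true(dh_activity(synthetic_dh_hit(TRUE, TRUE, FALSE, TRUE))$active)
})

test_that("KR typing reads the triad and the A/B fingerprints", {
  res <- kr_typing(synthetic_kr_hit(TRUE, TRUE, FALSE))
  expect_true(res$sequence_active)
  expect_equal(res$stereo_type, "A")
  res <- kr_typing(synthetic_kr_hit(FALSE, FALSE, TRUE))
  expect_false(res$sequence_active)
  expect_equal(res$stereo_type, "B")
  res <- kr_typing(synthetic_kr_hit(TRUE, TRUE, TRUE))
  expect_equal(res$stereo_type, "unknown")
  expect_true("ambiguous_kr_type" %in% res$flags)
  expect_equal(kr_typing(synthetic_kr_hit(TRUE, FALSE, FALSE))$stereo_type,
               "unknown")
})

test_that("annotation recovers planted domain order on random plans", {
  for (s in 0:9) {
    sim <- generate_cluster(random_module_plan(s), seed = s + 500)
    hits <- suppressWarnings(annotate_proteins(sim$proteins))
    got <- segment_modules(hits) |> tidy()
    expect_identical(got$domains, sim$truth$modules$domains,
                     label = paste("seed", s))
  }
})
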