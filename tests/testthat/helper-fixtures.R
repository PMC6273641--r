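# Shared worked-example objects, built once per test run.

tha_arch <- thailandin_architecture()
tha_sim <- generate_cluster(thailandin_plan(), seed = 42)
tha_line <- segment_modules(annotate_proteins(tha_sim$proteins))
tha_asg <- assign_extenders(tha_line)
tha_asg_rec <- reconcile_with_compound(
  tha_line, tha_asg, thailandin_compound(),
  post_pks = thailandin_post_pks(),
  overrides = thailandin_overrides(),
  ccr_present = detect_ccr_gene(thailandin_genes())
)
tha_units <- walk_assembly(tha_line, tha_asg_rec,
                           overrides = thailandin_overrides())
tha_product <- apply_post_pks(tha_units, thailandin_post_pks())

# independent mass oracle: sum atomic masses over a hand-derived formula
oracle_mono_mass <- function(C, H, O) {
  C * 12 + H * 1.0078250319 + O * 15.9949146
}

# brute-force GC oracle: plain character counting, no Biostrings
brute_gc <- function(sequence, start0, width) {
  chars <- strsplit(substr(sequence, start0 + 1, start0 + width), "")[[1]]
  n_n <- sum(chars == "N")
  sum(chars %in% c("G", "C")) / (width - n_n)
}

# grammar fuzzer: a random architecture string in canonical printed form
random_architecture_string <- function(seed) {
  withr::with_seed(seed, {
    n_prot <- sample(1:3, 1)
    pieces <- vapply(seq_len(n_prot), function(i) {
      n_groups <- sample(1:4, 1)
      groups <- vapply(seq_len(n_groups), function(g) {
        red <- sample(list(character(), "KR", c("DH", "KR"),
                           c("DH", "ER", "KR")), 1)[[1]]
        paste0("(", paste(c("KS", "AT", red, "ACP"), collapse = "-"), ")")
      }, character(1))
      body <- paste(groups, collapse = "-")
      if (sample(c(TRUE, FALSE), 1)) body <- paste0("Dock-", body)
      if (i == n_prot && sample(c(TRUE, FALSE), 1)) body <- paste0(body, "-TE")
      if (sample(c(TRUE, FALSE), 1)) body <- paste0(body, "-Dock")
      paste0("P", i, " [", body, "]")
    }, character(1))
    paste(pieces, collapse = " ")
  })
}

# random token-level assembly line + assignments, for product-level
# invariant tests (no sequence generation; domains taken at face value)
random_token_line <- function(seed) {
  withr::with_seed(seed, {
    n_ext <- sample(2:8, 1)
    groups <- c("(KS-AT-ACP)", vapply(seq_len(n_ext), function(i) {
      red <- if (i == 1) {
        "KR"  # guarantee at least one beta-hydroxyl for lactonization
      } else {
        sample(list(character(), "KR", c("DH", "KR"), c("DH", "ER", "KR")),
               1)[[1]]
      }
      paste0("(", paste(c("KS", "AT", red, "ACP"), collapse = "-"), ")")
    }, character(1)))
    arch <- parse_architecture(
      paste0("P1 [", paste(groups, collapse = "-"), "-TE]")
    )
    line <- segment_modules(architecture_to_hits(arch))
    units_tbl <- extender_units()
    asg <- tibble::tibble(
      module_index = line$modules$module_index,
      unit = sample(units_tbl$name, nrow(line$modules), replace = TRUE)
    )
    asg$side_chain_carbons <- units_tbl$side_chain_carbons[
      match(asg$unit, units_tbl$name)
    ]
    list(line = line, assignments = asg)
  })
}

# a one-row DH or KR hit with prescribed motif-match booleans
synthetic_dh_hit <- function(core, aux1, aux2, aux3) {
  domain_hit(
    "p", "DH", 0, 280,
    matched = c(dh_core = core, dh_aux_gyxygpxf = aux1,
                dh_aux_lpfxw = aux2, dh_aux_dxxxqh = aux3)
  )
}
synthetic_kr_hit <- function(triad, fp_a, fp_b) {
  domain_hit(
    "p", "KR", 0, 450,
    matched = c(kr_anchor = TRUE, kr_triad = triad,
                kr_type_a = fp_a, kr_type_b = fp_b)
  )
}
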