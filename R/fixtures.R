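#' Thailandin worked-example fixtures
#'
#' Accessors for the worked example shipped with the package: the thailandin
#' assembly line of *Actinokineospora bangkokensis* (four PKS proteins
#' ThaBI–ThaBIV, one loading plus thirteen extension modules), its target
#' compound, tailoring configuration, module plan for the synthetic
#' generator, and the cluster gene catalogue.
#'
#' * `thailandin_architecture()` parses the published assembly-line
#'   architecture string.
#' * `thailandin_compound()` returns the target [compound_spec()]:
#'   28-membered macrolactone, 7 free hydroxyls, 5 conjugated double bonds,
#'   2 ring methyls, C4 side chain at C2, mass 608.
#' * `thailandin_post_pks()` returns the tailoring [post_pks_config()]
#'   (auto lactone, auto hemiketal, C26 hydroxylation; optionally C15
#'   rhamnosylation for the A-form).
#' * `thailandin_overrides()` returns the module-8 KR override: that KR has
#'   an intact type-A catalytic set, yet the C13 keto retained in the
#'   compound shows it must be inactive in vivo.
#' * `thailandin_plan()` returns the [module_plan()] that generates a
#'   synthetic cluster with the published motif evidence: KSQ loading
#'   module, methylmalonyl (x = Q, YASH) at module 6, the noncanonical
#'   GHSQH/AAGH acyltransferase at module 13, and an inactive DH at module 7
#'   (core motif intact, all three auxiliary motifs altered).
#' * `thailandin_genes()` returns the gene/product catalogue, including the
#'   crotonyl-CoA carboxylase/reductase `thaC`.
#'
#' @return See above; `_path` variants return file paths.
#' @name thailandin_fixture
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "pksline", mustWork = TRUE)
}

#' @rdname thailandin_fixture
#' @export
thailandin_architecture_path <- function() extdata("thailandin_architecture.txt")

#' @rdname thailandin_fixture
#' @export
thailandin_architecture <- function() {
  parse_architecture(readLines(thailandin_architecture_path()))
}

#' @rdname thailandin_fixture
#' @export
thailandin_compound <- function() {
  read_compound_spec(extdata("thailandin_compound.yaml"))
}

#' @rdname thailandin_fixture
#' @param rhamnosylation Attach the C15 rhamnosyl (the thailandin A form)?
#' @export
thailandin_post_pks <- function(rhamnosylation = FALSE) {
  cfg <- read_post_pks_config(extdata("thailandin_postpks.yaml"))
  if (rhamnosylation) {
    cfg$glycosylations <- list(list(carbon = 15L, sugar = "rhamnose"))
  }
  cfg
}

#' @rdname thailandin_fixture
#' @export
thailandin_overrides <- function() {
  tibble(module_index = 8L, domain_type = "KR", active = FALSE)
}

#' @rdname thailandin_fixture
#' @export
thailandin_genes <- function() {
  readr::read_tsv(extdata("thailandin_genes.tsv"), show_col_types = FALSE)
}

#' @rdname thailandin_fixture
#' @export
thailandin_plan <- function() {
  arch <- thailandin_architecture()
  rows <- list()
  mod_no <- 0L
  for (i in seq_len(nrow(arch$proteins))) {
    for (g in arch$groups[[i]]) {
      domains <- g
      row <- tibble(
        protein = arch$proteins$name[[i]],
        domains = list(domains),
        ks_residue = if (mod_no == 0L) "Q" else "C",
        at_x = "L",
        at_core_window = NA_character_,
        at_secondary = "HAFH",
        dh_core_present = TRUE,
        dh_aux_present = list(c(TRUE, TRUE, TRUE)),
        kr_triad_present = TRUE,
        kr_fingerprint = "A"
      )
      if (mod_no == 6L) {         # methylmalonyl module
        row$at_x <- "Q"
        row$at_secondary <- "YASH"
      }
      if (mod_no == 7L) {         # DH with intact core, altered auxiliaries
        row$dh_aux_present <- list(c(FALSE, FALSE, FALSE))
      }
      if (mod_no == 13L) {        # noncanonical AT: GHSQH core, AAGH motif
        row$at_x <- "Q"
        row$at_core_window <- "GHSQH"
        row$at_secondary <- "AAGH"
      }
      rows[[length(rows) + 1L]] <- row
      mod_no <- mod_no + 1L
    }
  }
  module_plan(
    list_rbind(rows),
    proteins = tibble(
      name = arch$proteins$name,
      n_term_dock = arch$proteins$n_term_dock,
      c_term_dock = arch$proteins$c_term_dock
    )
  )
}
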