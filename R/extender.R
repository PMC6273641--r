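#' Catalogue of malonyl-derived extender units
#'
#' One row per supported extender unit, from malonyl-CoA (no side chain) to
#' hexylmalonyl-CoA. `mass_delta` is the monoisotopic mass added relative to
#' a plain malonyl extension, i.e. side-chain carbons times CH2 (14.01565).
#'
#' @return Tibble with `name`, `side_chain_carbons`, `mass_delta`.
#' @export
extender_units <- function() {
  tibble(
    name = c("malonyl", "methylmalonyl", "ethylmalonyl", "propylmalonyl",
             "butylmalonyl", "pentylmalonyl", "hexylmalonyl"),
    side_chain_carbons = 0:6,
    mass_delta = (0:6) * 14.01565
  )
}

malonyl_x <- c("L", "V", "I", "F", "A", "M")
canonical_secondary <- c("HAFH", "YASH")

#' Classify an acyltransferase's extender unit from active-site evidence
#'
#' Decision table over the GHSxG specificity residue x and the downstream
#' secondary motif: x in LVIFAM reads malonyl-CoA; x = Q reads
#' methylmalonyl-CoA (the YASH-class pairing); a noncanonical secondary
#' motif such as AAGH — or a flagged core motif — marks the AT as unusual
#' and is provisionally classed ethylmalonyl-CoA pending reconciliation
#' against the target compound. The function is total over (letter, motif).
#'
#' @param x_residue Single uppercase letter, or `NA` when the core motif was
#'   not found.
#' @param secondary_motif `"HAFH"`, `"YASH"`, `"AAGH"`, another short motif,
#'   or `NA`/`"none"` when not observed.
#' @param core_flagged `TRUE` when the GHSxG core motif raised a flag (e.g.
#'   the GHSQH fifth-residue variant).
#' @return Tibble row: `unit`, `side_chain_carbons`, `evidence` (`"motif"`,
#'   `"motif_flagged"` or `"unknown"`), `flags`.
#' @export
classify_extender <- function(x_residue, secondary_motif = NA_character_,
                              core_flagged = FALSE) {
  out <- function(unit, evidence, flags = character()) {
    u <- extender_units() |> filter(.data$name == unit)
    tibble(
      unit = unit,
      side_chain_carbons = if (nrow(u)) u$side_chain_carbons else NA_integer_,
      evidence = evidence,
      flags = list(flags)
    )
  }
  if (is.na(x_residue) || !nzchar(x_residue)) {
    return(out("unknown", "unknown", "at_core_motif_missing"))
  }
  sec <- if (is.na(secondary_motif) || secondary_motif %in% c("", "none")) {
    NA_character_
  } else {
    secondary_motif
  }
  noncanonical_sec <- !is.na(sec) && !sec %in% canonical_secondary
  if (noncanonical_sec || isTRUE(core_flagged)) {
    return(out("ethylmalonyl", "motif_flagged",
               c(if (noncanonical_sec) "noncanonical_secondary_motif",
                 if (isTRUE(core_flagged)) "noncanonical_core_motif")))
  }
  if (x_residue %in% malonyl_x) return(out("malonyl", "motif"))
  if (x_residue == "Q") return(out("methylmalonyl", "motif"))
  out("malonyl", "motif", "unrecognized_x")
}

#' Assign an extender unit to every module of an assembly line
#'
#' Applies [classify_extender()] to each module's AT evidence. The loading
#' module's row records the acetate starter (malonyl loaded, then
#' decarboxylated by the KSQ domain).
#'
#' @param line A `pks_assembly_line` from [segment_modules()].
#' @return Assignment tibble: `module_index`, `role`, `x_residue`,
#'   `secondary_motif`, `unit`, `side_chain_carbons`, `evidence`, `flags`.
#' @export
assign_extenders <- function(line) {
  stopifnot(inherits(line, "pks_assembly_line"))
  rows <- map(seq_len(nrow(line$modules)), function(i) {
    m <- line$modules[i, ]
    at <- line$domains |>
      filter(.data$module_index == m$module_index, .data$domain_type == "AT")
    x <- if (nrow(at)) at$x_residue[[1]] else NA_character_
    sec <- if (nrow(at)) at$secondary_motif[[1]] else NA_character_
    core_flagged <- nrow(at) > 0 &&
      "noncanonical_fifth_residue" %in% at$flags[[1]]
    if (m$role == "loading") {
      return(tibble(
        module_index = m$module_index, role = m$role,
        x_residue = x, secondary_motif = sec,
        unit = "malonyl", side_chain_carbons = 0L,
        evidence = "motif", flags = list("starter_acetate_via_decarboxylation")
      ))
    }
    cls <- classify_extender(x, sec, core_flagged)
    tibble(
      module_index = m$module_index, role = m$role,
      x_residue = x, secondary_motif = sec,
      unit = cls$unit, side_chain_carbons = cls$side_chain_carbons,
      evidence = cls$evidence, flags = cls$flags
    )
  })
  list_rbind(rows)
}

#' Reconcile flagged acyltransferases against a target compound
#'
#' For each assignment with evidence `"motif_flagged"`, enumerates candidate
#' extender units (side-chain lengths 1–6), predicts the product's
#' monoisotopic mass for every combination via the product pipeline, and
#' keeps the combination minimizing the absolute mass error against the
#' target (ties broken toward fewer total side-chain carbons). Successful
#' reconciliation (error within `tolerance`) upgrades the evidence to
#' `"reconciled"`; otherwise the motif prediction is kept and flagged
#' `"unreconciled"`. Assignments with evidence `"motif"` are never altered.
#' A detected crotonyl-CoA carboxylase/reductase gene (`ccr_present`) is
#' recorded as supporting evidence for elongated units, never required.
#'
#' @param line A `pks_assembly_line`.
#' @param assignments Output of [assign_extenders()].
#' @param compound_spec A [compound_spec()] with a target monoisotopic mass.
#' @param post_pks [post_pks_config()] used when predicting candidate masses.
#' @param overrides Domain activity overrides passed to [walk_assembly()].
#' @param ccr_present Logical flag from [detect_ccr_gene()].
#' @param tolerance Maximum absolute mass error (Da) accepted as reconciled;
#'   default 0.5 (candidate units are >= 14 Da apart).
#' @return The assignment tibble with reconciled units, plus attributes
#'   `mass_error` (Da) and `ccr_present`.
#' @export
reconcile_with_compound <- function(line, assignments, compound_spec,
                                    post_pks = post_pks_config(),
                                    overrides = NULL, ccr_present = FALSE,
                                    tolerance = 0.5) {
  flagged <- which(assignments$evidence == "motif_flagged")
  if (length(flagged) == 0) return(assignments)
  target <- compound_spec$target_monoisotopic_mass
  if (is.null(target)) {
    abort("compound spec has no target_monoisotopic_mass; cannot reconcile")
  }

  units <- extender_units() |> filter(.data$side_chain_carbons >= 1)
  combos <- expand.grid(rep(list(seq_len(nrow(units))), length(flagged)))
  predict_mass <- function(choice) {
    asg <- assignments
    asg$unit[flagged] <- units$name[choice]
    asg$side_chain_carbons[flagged] <- units$side_chain_carbons[choice]
    prod <- walk_assembly(line, asg, overrides = overrides) |>
      apply_post_pks(post_pks)
    compute_features(prod)$monoisotopic_mass
  }
  masses <- map_dbl(seq_len(nrow(combos)), function(i) {
    predict_mass(as.integer(combos[i, ]))
  })
  err <- abs(masses - target)
  total_carbons <- map_int(seq_len(nrow(combos)), function(i) {
    sum(units$side_chain_carbons[as.integer(combos[i, ])])
  })
  best <- order(err, total_carbons)[[1]]

  if (err[[best]] <= tolerance) {
    choice <- as.integer(combos[best, ])
    assignments$unit[flagged] <- units$name[choice]
    assignments$side_chain_carbons[flagged] <- units$side_chain_carbons[choice]
    assignments$evidence[flagged] <- "reconciled"
    for (i in flagged) {
      fl <- assignments$flags[[i]]
      if (isTRUE(ccr_present)) fl <- c(fl, "ccr_supported")
      assignments$flags[[i]] <- fl
    }
    attr(assignments, "mass_error") <- err[[best]]
  } else {
    for (i in flagged) {
      assignments$flags[[i]] <- c(assignments$flags[[i]], "unreconciled")
    }
    attr(assignments, "mass_error") <- err[[best]]
  }
  attr(assignments, "ccr_present") <- isTRUE(ccr_present)
  assignments
}

#' Detect a crotonyl-CoA carboxylase/reductase gene in a cluster catalogue
#'
#' CCR enzymes supply elongated (e.g. butylmalonyl-CoA) extender units; their
#' presence in a cluster supports an unusual-extender call. Matching is a
#' case-insensitive substring test on the product annotation.
#'
#' @param cluster_gene_table Tibble with columns `gene` and `product` (free
#'   annotation text).
#' @param patterns Character vector of annotation substrings counted as CCR.
#' @return `TRUE` iff any annotation matches.
#' @export
detect_ccr_gene <- function(cluster_gene_table,
                            patterns = c("crotonyl-coa carboxylase/reductase",
                                         "crotonyl-coa carboxylase")) {
  if (nrow(cluster_gene_table) == 0) return(FALSE)
  txt <- tolower(cluster_gene_table$product)
  any(map_lgl(patterns, ~ any(str_detect(txt, stringr::fixed(.x)))))
}
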