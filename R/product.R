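## Atomic masses used throughout (C/H/O only: polyketide aglycones and
## neutral sugars carry no other elements here).
MONO_MASS <- c(C = 12.0, H = 1.0078250319, O = 15.9949146)
AVG_MASS <- c(C = 12.011, H = 1.008, O = 15.999)
VALENCE <- c(C = 4L, O = 2L)

#' Backbone carbon positions contributed by a module
#'
#' Maps an extension module m of an M-extension-module line to its carbonyl,
#' alpha and beta backbone carbons, numbering from the thioester/acid
#' carbonyl carbon C1: carbonyl = 2(M-m)+1, alpha = 2(M-m)+2,
#' beta = 2(M-m)+3. The loading module (m = 0) contributes the two terminal
#' carbons 2M+1 (which is also module 1's beta carbon) and the omega-methyl
#' 2M+2. Over m = 0..M the (carbonyl, alpha) pairs cover 1..2M+2 exactly
#' once.
#'
#' @param M Number of extension modules (>= 1).
#' @param m Module number: 0 for loading, 1..M for extension modules.
#' @return Tibble with `carbonyl`, `alpha`, `beta` (`beta` is `NA` for the
#'   loading module).
#' @examples
#' carbon_positions(13, 7)  # beta = 15
#' @export
carbon_positions <- function(M, m) {
  stopifnot(M >= 1)
  if (m < 0 || m > M) {
    abort(paste0("module number m = ", m, " outside 0..M (M = ", M, ")"))
  }
  if (m == 0) {
    return(tibble(carbonyl = 2 * M + 1, alpha = 2 * M + 2, beta = NA_real_))
  }
  tibble(
    carbonyl = 2 * (M - m) + 1,
    alpha = 2 * (M - m) + 2,
    beta = 2 * (M - m) + 3
  )
}

#' Walk an assembly line into backbone units
#'
#' Converts an annotated assembly line plus extender assignments into the
#' per-unit backbone description: carbon positions and the beta-carbon
#' processing state implied by the module's reductive domain set — keto with
#' no (active) KR, hydroxyl with KR only, enoyl with KR+DH, methylene with
#' KR+DH+ER. `overrides` force individual domains active or inactive
#' regardless of their sequence-level call, the standard recourse when the
#' compound shows that a domain with an intact catalytic set is skipped in
#' vivo.
#'
#' @param line A `pks_assembly_line`.
#' @param assignments Extender assignments from [assign_extenders()] (or
#'   [reconcile_with_compound()]).
#' @param overrides Optional tibble (`module_index`, `domain_type`, `active`)
#'   forcing domain activity.
#' @return A `backbone_units` tibble: `module_index`, `m`, `carbonyl`,
#'   `alpha`, `beta`, `beta_state`, `side_chain_carbons`, with the extension
#'   count `M` as an attribute.
#' @export
walk_assembly <- function(line, assignments, overrides = NULL) {
  stopifnot(inherits(line, "pks_assembly_line"))
  ext <- line$modules |> filter(.data$role == "extension")
  M <- nrow(ext)
  if (M == 0) abort("assembly line has no extension modules")
  bad <- ext |> filter(.data$malformed)
  if (nrow(bad) > 0) {
    abort(paste0("malformed module(s): ",
                 paste(bad$module_index, collapse = ", ")))
  }

  get_override <- function(mi, type) {
    if (is.null(overrides)) return(NULL)
    hit <- overrides |>
      filter(.data$module_index == mi, .data$domain_type == type)
    if (nrow(hit) == 0) NULL else hit$active[[nrow(hit)]]
  }
  domain_state <- function(mi, type) {
    d <- line$domains |>
      filter(.data$module_index == mi, .data$domain_type == type)
    present <- nrow(d) > 0
    active_col <- c(DH = "dh_active", KR = "kr_active", ER = "er_active")[[type]]
    active <- present && !isFALSE(d[[active_col]][[1]])
    ov <- get_override(mi, type)
    if (present && !is.null(ov)) active <- ov
    list(present = present, active = active)
  }

  rows <- map(seq_len(M), function(k) {
    mi <- ext$module_index[[k]]
    asg <- assignments |> filter(.data$module_index == mi)
    if (nrow(asg) == 0 || asg$unit[[1]] == "unknown") {
      abort(paste0("extension module ", mi, " has no usable extender assignment"))
    }
    kr <- domain_state(mi, "KR")
    dh <- domain_state(mi, "DH")
    er <- domain_state(mi, "ER")
    state <- if (!kr$present || !kr$active) {
      "keto"
    } else if (!dh$present || !dh$active) {
      "hydroxyl"
    } else if (!er$present || !er$active) {
      "enoyl"
    } else {
      "methylene"
    }
    pos <- carbon_positions(M, k)
    tibble(
      module_index = mi, m = k,
      carbonyl = pos$carbonyl, alpha = pos$alpha, beta = pos$beta,
      beta_state = state,
      side_chain_carbons = as.integer(asg$side_chain_carbons[[1]])
    )
  })
  loading_pos <- carbon_positions(M, 0)
  loading <- tibble(
    module_index = if (any(line$modules$role == "loading")) {
      line$modules$module_index[line$modules$role == "loading"][[1]]
    } else {
      NA_integer_
    },
    m = 0L,
    carbonyl = loading_pos$carbonyl, alpha = loading_pos$alpha,
    beta = NA_real_, beta_state = "none", side_chain_carbons = 0L
  )
  out <- bind_rows(loading, list_rbind(rows))
  structure(out, M = M, class = c("backbone_units", class(out)))
}

## ---- molecular graph (C/H/O, implicit hydrogens) ---------------------------

mg_new <- function() {
  e <- new.env(parent = emptyenv())
  e$element <- character()
  e$a <- integer()
  e$b <- integer()
  e$order <- integer()
  e
}
mg_add_atom <- function(g, element) {
  g$element <- c(g$element, element)
  length(g$element)
}
mg_add_bond <- function(g, x, y, order = 1L) {
  g$a <- c(g$a, as.integer(x))
  g$b <- c(g$b, as.integer(y))
  g$order <- c(g$order, as.integer(order))
  invisible(g)
}
mg_set_order <- function(g, x, y, order) {
  i <- which((g$a == x & g$b == y) | (g$a == y & g$b == x))
  stopifnot(length(i) == 1)
  g$order[[i]] <- as.integer(order)
  invisible(g)
}
mg_snapshot <- function(g) {
  list(element = g$element,
       bonds = tibble(a = g$a, b = g$b, order = g$order))
}
mg_order_sum <- function(gl) {
  s <- numeric(length(gl$element))
  for (i in seq_len(nrow(gl$bonds))) {
    s[[gl$bonds$a[[i]]]] <- s[[gl$bonds$a[[i]]]] + gl$bonds$order[[i]]
    s[[gl$bonds$b[[i]]]] <- s[[gl$bonds$b[[i]]]] + gl$bonds$order[[i]]
  }
  s
}
mg_implicit_h <- function(gl) {
  h <- VALENCE[gl$element] - mg_order_sum(gl)
  if (any(h < 0)) abort("molecular graph exceeds valence")
  unname(h)
}
mg_formula <- function(gl) {
  c(C = sum(gl$element == "C"),
    H = sum(mg_implicit_h(gl)),
    O = sum(gl$element == "O"))
}
mg_n_components <- function(gl) {
  n <- length(gl$element)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(gl$bonds))) {
    ra <- find(gl$bonds$a[[i]])
    rb <- find(gl$bonds$b[[i]])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(map_int(seq_len(n), find)))
}
mg_n_rings <- function(gl) {
  nrow(gl$bonds) - length(gl$element) + mg_n_components(gl)
}
formula_string <- function(f) {
  paste0("C", f[["C"]], "H", f[["H"]], "O", f[["O"]])
}

# free hydroxyl oxygens: single-bonded O atoms with one neighbour
mg_free_oh <- function(gl) {
  deg <- mg_order_sum(gl)
  which(gl$element == "O" & deg == 1)
}
# the carbon each single-neighbour O hangs from
mg_oh_carbon <- function(gl, o_id) {
  i <- which((gl$bonds$a == o_id) | (gl$bonds$b == o_id))
  stopifnot(length(i) == 1)
  other <- if (gl$bonds$a[[i]] == o_id) gl$bonds$b[[i]] else gl$bonds$a[[i]]
  other
}

## ---- post-PKS configuration and compound spec ------------------------------

#' Post-PKS tailoring configuration
#'
#' @param macrolactonization `"auto"` (esterify C1 with the most distal free
#'   beta-hydroxyl), a carbon position, or `"off"` (free acid).
#' @param hemiketal `"auto"` (pair each retained keto carbon with a free
#'   hydroxyl 4 carbons away, preferring the N-terminal side, then 3), a
#'   length-2 vector `c(keto_carbon, oh_carbon)`, or `"off"`.
#' @param hydroxylations Integer vector of backbone carbons hydroxylated by
#'   tailoring oxygenases.
#' @param glycosylations List of `list(carbon =, sugar = "rhamnose")`
#'   entries; the sugar replaces the H of a free hydroxyl.
#' @return A `post_pks_config` list.
#' @export
post_pks_config <- function(macrolactonization = "auto", hemiketal = "auto",
                            hydroxylations = integer(),
                            glycosylations = list()) {
  structure(
    list(
      macrolactonization = macrolactonization,
      hemiketal = hemiketal,
      hydroxylations = as.integer(hydroxylations),
      glycosylations = glycosylations
    ),
    class = "post_pks_config"
  )
}

#' @rdname post_pks_config
#' @param path YAML file with the same fields.
#' @export
read_post_pks_config <- function(path) {
  y <- yaml::read_yaml(path)
  glyc <- map(y$glycosylations %||% list(), function(g) {
    list(carbon = as.integer(g$carbon), sugar = g$sugar %||% "rhamnose")
  })
  post_pks_config(
    macrolactonization = y$macrolactonization %||% "auto",
    hemiketal = y$hemiketal %||% "auto",
    hydroxylations = unlist(y$hydroxylations) %||% integer(),
    glycosylations = glyc
  )
}

#' Target compound constraints
#'
#' Constraints a predicted product is matched against; all fields optional,
#' at least one required.
#'
#' @param name Compound name.
#' @param ring_size Macrolactone ring member count (atoms in the ring).
#' @param hydroxyl_count Number of free hydroxyl groups.
#' @param conjugated_double_bonds Longest conjugated C=C run.
#' @param methyl_count Single-carbon substituents on macrolactone ring atoms.
#' @param side_chain_position,side_chain_length Position and carbon count of
#'   a multi-carbon side chain.
#' @param target_monoisotopic_mass Target neutral monoisotopic mass (Da).
#' @param backbone_carbons Number of backbone carbons (2M+2).
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(name = NULL, ring_size = NULL, hydroxyl_count = NULL,
                          conjugated_double_bonds = NULL, methyl_count = NULL,
                          side_chain_position = NULL, side_chain_length = NULL,
                          target_monoisotopic_mass = NULL,
                          backbone_carbons = NULL) {
  out <- structure(
    list(
      name = name, ring_size = ring_size, hydroxyl_count = hydroxyl_count,
      conjugated_double_bonds = conjugated_double_bonds,
      methyl_count = methyl_count,
      side_chain_position = side_chain_position,
      side_chain_length = side_chain_length,
      target_monoisotopic_mass = target_monoisotopic_mass,
      backbone_carbons = backbone_carbons
    ),
    class = "compound_spec"
  )
  if (all(map_lgl(out[setdiff(names(out), "name")], is.null))) {
    abort("compound spec needs at least one constraint")
  }
  out
}

#' @rdname compound_spec
#' @param path YAML file with the same fields.
#' @export
read_compound_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(compound_spec, y[intersect(names(y), names(formals(compound_spec)))])
}

## ---- product assembly ------------------------------------------------------

#' Apply post-PKS tailoring and build the polyketide product
#'
#' Builds the explicit atom/bond graph of the released polyketide from its
#' backbone units, then applies tailoring: thioesterase macrolactonization
#' (C1 esterified onto a beta-hydroxyl; the released product is modeled as
#' the lactone directly), hemiketal (tetrahydropyran) ring closure between a
#' retained keto group and a nearby hydroxyl, tailoring hydroxylations, and
#' O-glycosylation. Hydrogens are implicit (valence-completing), so the
#' molecular formula, masses and degrees of unsaturation all derive from the
#' same graph.
#'
#' @param units A `backbone_units` tibble from [walk_assembly()].
#' @param config A [post_pks_config()].
#' @return A `polyketide_product` object: `units`, `graph`, `rings`,
#'   `free_hydroxyl_positions`, plus bookkeeping used by
#'   [compute_features()].
#' @export
apply_post_pks <- function(units, config = post_pks_config()) {
  stopifnot(inherits(units, "backbone_units"))
  M <- attr(units, "M")
  n <- 2L * M + 2L

  g <- mg_new()
  for (i in seq_len(n)) mg_add_atom(g, "C")
  for (i in seq_len(n - 1L)) mg_add_bond(g, i, i + 1L)

  # C1 ester/acid carbonyl
  o_c1 <- mg_add_atom(g, "O")
  mg_add_bond(g, 1L, o_c1, 2L)
  if (identical(config$macrolactonization, "off")) {
    mg_add_bond(g, 1L, mg_add_atom(g, "O"), 1L)  # free acid
  }

  oh_at <- integer()    # carbon -> its hydroxyl O atom id
  keto_at <- integer()  # carbon -> its keto O atom id
  ext <- units |> filter(.data$m > 0)
  for (i in seq_len(nrow(ext))) {
    beta <- ext$beta[[i]]
    state <- ext$beta_state[[i]]
    if (state == "keto") {
      o <- mg_add_atom(g, "O")
      mg_add_bond(g, beta, o, 2L)
      keto_at[[as.character(beta)]] <- o
    } else if (state == "hydroxyl") {
      o <- mg_add_atom(g, "O")
      mg_add_bond(g, beta, o, 1L)
      oh_at[[as.character(beta)]] <- o
    } else if (state == "enoyl") {
      mg_set_order(g, ext$alpha[[i]], beta, 2L)
    }
  }

  side_chains <- ext |>
    filter(.data$side_chain_carbons > 0) |>
    select(position = "alpha", length = "side_chain_carbons")
  for (i in seq_len(nrow(side_chains))) {
    prev <- side_chains$position[[i]]
    for (k in seq_len(side_chains$length[[i]])) {
      cc <- mg_add_atom(g, "C")
      mg_add_bond(g, prev, cc, 1L)
      prev <- cc
    }
  }

  rings <- list()
  beta_oh_carbons <- as.integer(names(oh_at))

  # macrolactonization
  lactone_carbon <- NA_integer_
  if (!identical(config$macrolactonization, "off")) {
    target <- if (identical(config$macrolactonization, "auto")) {
      if (length(beta_oh_carbons) == 0) {
        abort("linear product: no free hydroxyl available for macrolactonization")
      }
      max(beta_oh_carbons)
    } else {
      as.integer(config$macrolactonization)
    }
    if (!as.character(target) %in% names(oh_at)) {
      abort(paste0("no free hydroxyl at C", target, " for macrolactonization"))
    }
    mg_add_bond(g, 1L, oh_at[[as.character(target)]], 1L)
    lactone_carbon <- target
    rings[[length(rings) + 1L]] <- tibble(
      type = "macrolactone", member_count = target + 1L,
      members = list(c(paste0("C", 1:target), "O"))
    )
    oh_at <- oh_at[names(oh_at) != as.character(target)]
  }

  # hemiketal ring(s)
  if (!identical(config$hemiketal, "off")) {
    pairs <- list()
    if (identical(config$hemiketal, "auto")) {
      for (j in sort(as.integer(names(keto_at)))) {
        for (p in c(j - 4L, j + 4L, j - 3L, j + 3L)) {
          if (p >= 2L && p <= n && as.character(p) %in% names(oh_at)) {
            pairs[[length(pairs) + 1L]] <- c(j, p)
            break
          }
        }
      }
    } else {
      pairs <- list(as.integer(config$hemiketal))
    }
    for (pr in pairs) {
      j <- pr[[1]]
      p <- pr[[2]]
      if (!as.character(j) %in% names(keto_at)) {
        abort(paste0("no keto group at C", j, " for hemiketal formation"))
      }
      if (!as.character(p) %in% names(oh_at)) {
        abort(paste0("no free hydroxyl at C", p, " for hemiketal formation"))
      }
      # keto C=O becomes the hemiketal hydroxyl; partner OH becomes ring ether
      mg_set_order(g, j, keto_at[[as.character(j)]], 1L)
      oh_at[[as.character(j)]] <- keto_at[[as.character(j)]]
      keto_at <- keto_at[names(keto_at) != as.character(j)]
      mg_add_bond(g, j, oh_at[[as.character(p)]], 1L)
      oh_at <- oh_at[names(oh_at) != as.character(p)]
      lo <- min(j, p)
      hi <- max(j, p)
      rings[[length(rings) + 1L]] <- tibble(
        type = "hemiketal", member_count = hi - lo + 2L,
        members = list(c(paste0("C", lo:hi), "O"))
      )
    }
  }

  # tailoring hydroxylations
  for (cc in config$hydroxylations) {
    if (cc < 1L || cc > n) abort(paste0("hydroxylation target C", cc, " not on backbone"))
    snap <- mg_snapshot(g)
    if (mg_implicit_h(snap)[[cc]] < 1) {
      abort(paste0("no free valence for hydroxylation at C", cc))
    }
    o <- mg_add_atom(g, "O")
    mg_add_bond(g, cc, o, 1L)
    oh_at[[as.character(cc)]] <- o
  }

  # glycosylation
  for (gl in config$glycosylations) {
    cc <- as.integer(gl$carbon)
    sugar <- gl$sugar %||% "rhamnose"
    if (!identical(sugar, "rhamnose")) {
      abort(paste0("unsupported sugar '", sugar, "' (only rhamnose is modeled)"))
    }
    if (!as.character(cc) %in% names(oh_at)) {
      abort(paste0("glycosylation target C", cc, " is not a free hydroxyl"))
    }
    attach_rhamnosyl(g, oh_at[[as.character(cc)]])
    oh_at <- oh_at[names(oh_at) != as.character(cc)]
  }

  rings <- if (length(rings)) list_rbind(rings) else
    tibble(type = character(), member_count = integer(), members = list())

  gl <- mg_snapshot(g)
  free_oh <- sort(map_int(mg_free_oh(gl), ~ mg_oh_carbon(gl, .x)))
  free_oh <- free_oh[free_oh <= n]  # backbone positions only

  structure(
    list(
      units = units,
      graph = gl,
      rings = rings,
      lactone_carbon = lactone_carbon,
      free_hydroxyl_positions = as.integer(free_oh),
      side_chains = side_chains,
      n_backbone = n,
      M = M,
      config = config
    ),
    class = "polyketide_product"
  )
}

# attach an O-linked rhamnosyl (6-deoxyhexose, net C6H10O4) to hydroxyl
# oxygen o_id; its H is replaced by the anomeric carbon
attach_rhamnosyl <- function(g, o_id) {
  c1 <- mg_add_atom(g, "C")
  c2 <- mg_add_atom(g, "C")
  c3 <- mg_add_atom(g, "C")
  c4 <- mg_add_atom(g, "C")
  c5 <- mg_add_atom(g, "C")
  c6 <- mg_add_atom(g, "C")
  o_ring <- mg_add_atom(g, "O")
  mg_add_bond(g, o_id, c1, 1L)
  mg_add_bond(g, c1, c2, 1L)
  mg_add_bond(g, c2, c3, 1L)
  mg_add_bond(g, c3, c4, 1L)
  mg_add_bond(g, c4, c5, 1L)
  mg_add_bond(g, c5, o_ring, 1L)
  mg_add_bond(g, o_ring, c1, 1L)
  mg_add_bond(g, c5, c6, 1L)
  for (cx in c(c2, c3, c4)) mg_add_bond(g, cx, mg_add_atom(g, "O"), 1L)
  invisible(g)
}

#' Derived features of a predicted polyketide product
#'
#' Computes the comparable feature set from the product's atom graph:
#' molecular formula, monoisotopic/average masses (with integer roundings),
#' ring sizes, free hydroxyls, the longest conjugated C=C run (adjacent
#' enoyl units), the count of single-carbon substituents on macrolactone
#' ring atoms, side chains and degrees of unsaturation. The graph-counted
#' unsaturation (rings + double bonds) is checked against the
#' formula-derived value and any mismatch is an error.
#'
#' @param product A `polyketide_product`.
#' @return One-row tibble of features.
#' @export
compute_features <- function(product) {
  stopifnot(inherits(product, "polyketide_product"))
  gl <- product$graph
  f <- mg_formula(gl)
  mono <- sum(f * MONO_MASS[names(f)])
  avg <- sum(f * AVG_MASS[names(f)])

  dou_formula <- (2 * f[["C"]] + 2 - f[["H"]]) / 2
  dou_graph <- mg_n_rings(gl) + sum(gl$bonds$order == 2)
  if (dou_formula != dou_graph) {
    abort(paste0("internal inconsistency: formula DoU ", dou_formula,
                 " != graph rings+double bonds ", dou_graph))
  }

  ext <- product$units |> filter(.data$m > 0)
  enoyl_m <- sort(ext$m[ext$beta_state == "enoyl"])
  conj <- longest_run(enoyl_m)

  ring_carbons <- if (!is.na(product$lactone_carbon)) {
    seq_len(product$lactone_carbon)
  } else {
    integer()
  }
  omega_methyl <- as.integer(!is.na(product$lactone_carbon) &&
                               (product$n_backbone - 1L) %in% ring_carbons)
  branch_methyls <- sum(product$side_chains$length == 1 &
                          product$side_chains$position %in% ring_carbons)
  macro <- product$rings |> filter(.data$type == "macrolactone")
  hemi <- product$rings |> filter(.data$type == "hemiketal")

  tibble(
    formula = formula_string(f),
    n_carbon = f[["C"]], n_hydrogen = f[["H"]], n_oxygen = f[["O"]],
    monoisotopic_mass = mono,
    monoisotopic_mass_int = as.integer(round(mono)),
    average_mass = avg,
    average_mass_int = as.integer(round(avg)),
    macrolactone_members = if (nrow(macro)) macro$member_count[[1]] else NA_integer_,
    hemiketal_members = if (nrow(hemi)) hemi$member_count[[1]] else NA_integer_,
    n_free_hydroxyls = length(product$free_hydroxyl_positions),
    free_hydroxyl_positions = list(product$free_hydroxyl_positions),
    conjugated_double_bond_count = conj,
    methyl_count = omega_methyl + branch_methyls,
    side_chains = list(product$side_chains),
    degrees_of_unsaturation = dou_formula
  )
}

longest_run <- function(x) {
  if (length(x) == 0) return(0L)
  best <- 1L
  run <- 1L
  for (i in seq_along(x)[-1]) {
    run <- if (x[[i]] - x[[i - 1L]] == 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Match a predicted product against a target compound spec
#'
#' Per-constraint pass/fail with absolute deviations; the overall call
#' (attribute `pass`) requires every present constraint to hold, with mass
#' compared at `mass_tolerance`.
#'
#' @param product A `polyketide_product`.
#' @param spec A [compound_spec()].
#' @param mass_tolerance Monoisotopic mass tolerance in Da (default 0.5).
#' @return Tibble (`constraint`, `target`, `observed`, `deviation`, `pass`)
#'   with attribute `pass`.
#' @export
match_spec <- function(product, spec, mass_tolerance = 0.5) {
  stopifnot(inherits(product, "polyketide_product"), inherits(spec, "compound_spec"))
  feat <- compute_features(product)
  side_ok <- function() {
    sc <- product$side_chains
    any(sc$position == spec$side_chain_position &
          sc$length == spec$side_chain_length)
  }
  rows <- list()
  add <- function(constraint, target, observed, pass,
                  deviation = abs(observed - target)) {
    rows[[length(rows) + 1L]] <<- tibble(
      constraint = constraint, target = as.numeric(target),
      observed = as.numeric(observed), deviation = as.numeric(deviation),
      pass = pass
    )
  }
  if (!is.null(spec$ring_size)) {
    add("ring_size", spec$ring_size, feat$macrolactone_members %||% NA,
        isTRUE(feat$macrolactone_members == spec$ring_size))
  }
  if (!is.null(spec$hydroxyl_count)) {
    add("hydroxyl_count", spec$hydroxyl_count, feat$n_free_hydroxyls,
        feat$n_free_hydroxyls == spec$hydroxyl_count)
  }
  if (!is.null(spec$conjugated_double_bonds)) {
    add("conjugated_double_bonds", spec$conjugated_double_bonds,
        feat$conjugated_double_bond_count,
        feat$conjugated_double_bond_count == spec$conjugated_double_bonds)
  }
  if (!is.null(spec$methyl_count)) {
    add("methyl_count", spec$methyl_count, feat$methyl_count,
        feat$methyl_count == spec$methyl_count)
  }
  if (!is.null(spec$side_chain_position) && !is.null(spec$side_chain_length)) {
    add("side_chain", spec$side_chain_length,
        if (side_ok()) spec$side_chain_length else NA_real_, side_ok(),
        deviation = as.numeric(!side_ok()))
  }
  if (!is.null(spec$target_monoisotopic_mass)) {
    dev <- abs(feat$monoisotopic_mass - spec$target_monoisotopic_mass)
    add("monoisotopic_mass", spec$target_monoisotopic_mass,
        feat$monoisotopic_mass, dev <= mass_tolerance, deviation = dev)
  }
  if (!is.null(spec$backbone_carbons)) {
    add("backbone_carbons", spec$backbone_carbons, product$n_backbone,
        product$n_backbone == spec$backbone_carbons)
  }
  out <- list_rbind(rows)
  attr(out, "pass") <- nrow(out) > 0 && all(out$pass)
  out
}

#' @export
print.polyketide_product <- function(x, ...) {
  feat <- compute_features(x)
  cat("<polyketide_product> ", feat$formula,
      "  monoisotopic ", sprintf("%.4f", feat$monoisotopic_mass), " Da\n",
      sep = "")
  if (nrow(x$rings)) {
    for (i in seq_len(nrow(x$rings))) {
      cat("  ", x$rings$type[[i]], " ring, ", x$rings$member_count[[i]],
          " members\n", sep = "")
    }
  }
  cat("  free OH at C", paste(x$free_hydroxyl_positions, collapse = ", C"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.polyketide_product <- function(x, ...) as_tibble(x$units)

#' @export
glance.polyketide_product <- function(x, ...) compute_features(x)

#' @export
as_report.polyketide_product <- function(x) {
  feat <- compute_features(x)
  list(
    formula = feat$formula,
    monoisotopic_mass = feat$monoisotopic_mass,
    monoisotopic_mass_int = feat$monoisotopic_mass_int,
    average_mass = feat$average_mass,
    rings = as_report(select(x$rings, -"members")),
    free_hydroxyl_positions = x$free_hydroxyl_positions,
    conjugated_double_bond_count = feat$conjugated_double_bond_count,
    methyl_count = feat$methyl_count,
    side_chains = as_report(as_tibble(x$side_chains)),
    units = as_report(as_tibble(x$units))
  )
}

#' @export
report_table.polyketide_product <- function(x) as_tibble(x$units)

#' Plot the backbone state map of a product
#'
#' One tile per backbone unit showing its beta-carbon processing state, with
#' side-chain lengths annotated — a quick visual check of the predicted
#' polyol/polyene pattern.
#'
#' @param object A `polyketide_product`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyketide_product <- function(object, ...) {
  d <- object$units |> filter(.data$m > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = 1, fill = .data$beta_state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      .data$side_chain_carbons > 0, paste0("+C", .data$side_chain_carbons), ""
    )), nudge_y = 0.6, size = 3) +
    ggplot2::scale_x_reverse(breaks = d$beta) +
    ggplot2::labs(x = "beta carbon position", y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
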