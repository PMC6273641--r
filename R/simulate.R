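## Filler alphabet for linkers and domain-block padding. D, H, W and Q are
## reserved for planted motifs: without them the anchored patterns that rely
## on those letters cannot arise by chance, which keeps the rejection
## sampling against the motif config cheap.
filler_alphabet <- strsplit("ACEFGIKLMNPRSTVY", "")[[1]]

#' Build a module plan for the synthetic-cluster generator
#'
#' A module plan is the ground truth a synthetic cluster is generated from:
#' per module, the domain set, the AT specificity evidence to plant, and any
#' activity lesions; per protein, the docking placement.
#'
#' @param modules Tibble with one row per module, columns `protein`,
#'   `domains` (list of ordered domain-token vectors), and optionally
#'   `ks_residue` (default `"C"`; `"Q"` for a decarboxylative loading KS),
#'   `at_x` (default `"L"`), `at_core_window` (5-mer to plant; default
#'   `GHS<x>G`), `at_secondary` (`"HAFH"`, `"YASH"`, `"AAGH"` or `NA`),
#'   `dh_core_present`, `dh_aux_present` (list of 3 logicals),
#'   `kr_triad_present`, `kr_fingerprint` (`"A"`, `"B"`, `"both"`,
#'   `"none"`).
#' @param proteins Optional tibble (`name`, `n_term_dock`, `c_term_dock`);
#'   defaults to docks on every inter-protein junction.
#' @return A `pks_module_plan`.
#' @export
module_plan <- function(modules, proteins = NULL) {
  modules <- as_tibble(modules)
  defaults <- list(
    ks_residue = "C", at_x = "L", at_core_window = NA_character_,
    at_secondary = NA_character_, dh_core_present = TRUE,
    kr_triad_present = TRUE, kr_fingerprint = "A", has_te = FALSE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(modules)) modules[[nm]] <- defaults[[nm]]
  }
  if (!"dh_aux_present" %in% names(modules)) {
    modules$dh_aux_present <- rep(list(c(TRUE, TRUE, TRUE)), nrow(modules))
  }
  modules$dh_aux_present <- map(modules$dh_aux_present, function(x) {
    if (is.null(x)) c(TRUE, TRUE, TRUE) else x
  })
  for (nm in names(defaults)) {
    modules[[nm]][is.na(modules[[nm]]) & nm != "at_core_window"] <- defaults[[nm]]
  }
  modules$at_core_window <- ifelse(
    is.na(modules$at_core_window),
    paste0("GHS", modules$at_x, "G"),
    modules$at_core_window
  )
  # module grammar checks, before any generation happens
  for (i in seq_len(nrow(modules))) {
    d <- modules$domains[[i]]
    bad <- setdiff(d, arch_tokens)
    if (length(bad)) abort(paste0("unknown domain token in plan: ", bad[[1]]))
    if (sum(d == "KS") != 1 || sum(d == "AT") != 1 || sum(d == "ACP") != 1) {
      abort(paste0("module ", i, " must contain exactly one KS, AT and ACP"))
    }
    if (any(table(d[d %in% c("DH", "ER", "KR")]) > 1)) {
      abort(paste0("module ", i, " repeats a reductive domain"))
    }
    if ("Dock" %in% d) abort("Dock belongs to protein termini, not modules")
  }
  prot_names <- unique(modules$protein)
  if (is.null(proteins)) {
    proteins <- tibble(
      name = prot_names,
      n_term_dock = seq_along(prot_names) > 1,
      c_term_dock = seq_along(prot_names) < length(prot_names)
    )
  }
  structure(list(modules = modules, proteins = as_tibble(proteins)),
            class = "pks_module_plan")
}

# planted motif realizations for one domain instance, as named character
planted_motifs_for <- function(type, mod, config) {
  dom <- config$domains[[type]]
  out <- character()
  for (m in dom$motifs) {
    plant <- switch(
      m$motif_id,
      ks_active_site = paste0("TA", mod$ks_residue, "SSG"),
      at_core = mod$at_core_window,
      at_secondary = if (is.na(mod$at_secondary)) NA else mod$at_secondary,
      dh_core = if (isTRUE(mod$dh_core_present)) m$plant else NA,
      dh_aux_gyxygpxf = if (isTRUE(mod$dh_aux_present[[1]])) m$plant else NA,
      dh_aux_lpfxw = if (isTRUE(mod$dh_aux_present[[2]])) m$plant else NA,
      dh_aux_dxxxqh = if (isTRUE(mod$dh_aux_present[[3]])) m$plant else NA,
      kr_triad = if (isTRUE(mod$kr_triad_present)) m$plant else NA,
      kr_type_a = if (mod$kr_fingerprint %in% c("A", "both")) m$plant else NA,
      kr_type_b = if (mod$kr_fingerprint %in% c("B", "both")) m$plant else NA,
      m$plant
    )
    if (!is.na(plant)) out[[m$motif_id]] <- plant
  }
  out
}

rand_filler <- function(len) {
  paste(sample(filler_alphabet, len, replace = TRUE), collapse = "")
}

# render one domain block: filler with motifs overwritten at block offsets
render_block <- function(type, mod, config) {
  dom <- config$domains[[type]]
  block <- strsplit(rand_filler(dom$block_length), "")[[1]]
  motifs <- planted_motifs_for(type, mod, config)
  offsets <- setNames(
    map_int(dom$motifs, ~ as.integer(.x$block_offset)),
    map_chr(dom$motifs, "motif_id")
  )
  planted <- list()
  for (mid in names(motifs)) {
    s <- strsplit(motifs[[mid]], "")[[1]]
    at <- offsets[[mid]]
    block[(at + 1):(at + length(s))] <- s
    planted[[length(planted) + 1L]] <- tibble(motif_id = mid, offset = at)
  }
  list(sequence = paste(block, collapse = ""), planted = list_rbind(planted))
}

#' Generate a synthetic PKS cluster with planted ground truth
#'
#' Renders each planned module as a series of domain blocks — filler
#' sequence with the configured motifs planted at fixed offsets — separated
#' by random linkers (10–60 aa). Linkers and filler are drawn from an
#' alphabet that cannot complete the planted motif patterns, and every
#' assembled protein is rejection-sampled against the full motif
#' configuration until its only pattern matches are the planted ones, so
#' annotation ground truth is exact by construction. The same seed yields
#' byte-identical output.
#'
#' @param plan A [module_plan()].
#' @param seed Integer seed.
#' @param config Motif configuration (also used for rejection scanning).
#' @param linker_range Length-2 integer vector: inclusive range linker
#'   lengths are drawn from (default 10–60 aa).
#' @return List with `proteins` (tibble `id`, `gene_order_index`,
#'   `sequence`) and `truth` (list: the plan, per-module expectations
#'   `modules`, planted motif coordinates `planted`, linker coordinates
#'   `linkers`).
#' @export
generate_cluster <- function(plan, seed, config = default_motif_config(),
                             linker_range = c(10L, 60L)) {
  stopifnot(inherits(plan, "pks_module_plan"), length(linker_range) == 2L)
  withr::with_seed(seed, generate_cluster_impl(plan, config, linker_range))
}

generate_cluster_impl <- function(plan, config, linker_range) {
  tab <- motif_table(config)
  patterns <- setNames(tab$pattern, tab$motif_id)

  gen_protein <- function(pname) {
    pinfo <- plan$proteins |> filter(.data$name == pname)
    mods <- plan$modules |> filter(.data$protein == pname)
    parts <- character()    # sequence pieces
    planted <- list()       # (motif_id, start) absolute, 1-based
    linkers <- list()       # (start, end) 0-based half-open
    pos <- 0L

    push_linker <- function() {
      len <- sample(linker_range[[1]]:linker_range[[2]], 1L)
      parts[[length(parts) + 1L]] <<- rand_filler(len)
      linkers[[length(linkers) + 1L]] <<- tibble(start = pos, end = pos + len)
      pos <<- pos + len
    }
    push_block <- function(type, mod) {
      blk <- render_block(type, mod, config)
      blk$planted$start <- pos + blk$planted$offset + 1L
      planted[[length(planted) + 1L]] <<- blk$planted |> select("motif_id", "start")
      parts[[length(parts) + 1L]] <<- blk$sequence
      pos <<- pos + nchar(blk$sequence)
    }

    dock_mod <- list()  # Dock blocks need no per-module fields
    if (isTRUE(pinfo$n_term_dock)) {
      push_block("Dock", dock_mod)
      push_linker()
    }
    for (i in seq_len(nrow(mods))) {
      mod <- as.list(mods[i, ])
      mod$dh_aux_present <- mods$dh_aux_present[[i]]
      for (type in mods$domains[[i]]) {
        push_block(type, mod)
        push_linker()
      }
    }
    if (isTRUE(pinfo$c_term_dock)) push_block("Dock", dock_mod)

    seqstr <- paste(parts, collapse = "")
    list(
      sequence = seqstr,
      planted = list_rbind(planted),
      linkers = if (length(linkers)) list_rbind(linkers) else
        tibble(start = integer(), end = integer())
    )
  }

  # rejection: regenerate a protein until its matches are exactly the plant
  gen_protein_checked <- function(pname) {
    for (try in 1:200) {
      cand <- gen_protein(pname)
      ok <- TRUE
      for (mid in names(patterns)) {
        found <- regex_matches(patterns[[mid]], cand$sequence)$start
        want <- sort(cand$planted$start[cand$planted$motif_id == mid])
        if (!identical(sort(found), as.numeric(want)) &&
            !identical(as.integer(sort(found)), as.integer(want))) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(cand)
    }
    abort("failed to generate a motif-clean protein in 200 attempts")
  }

  prots <- map(plan$proteins$name, gen_protein_checked)
  proteins <- tibble(
    id = plan$proteins$name,
    gene_order_index = seq_along(prots) - 1L,
    sequence = map_chr(prots, "sequence")
  )

  truth_modules <- plan_truth(plan)
  list(
    proteins = proteins,
    truth = list(
      plan = plan,
      modules = truth_modules,
      planted = list_rbind(map2(plan$proteins$name, prots, function(nm, p) {
        mutate(p$planted, protein_id = nm)
      })),
      linkers = list_rbind(map2(plan$proteins$name, prots, function(nm, p) {
        mutate(p$linkers, protein_id = nm)
      }))
    )
  )
}

# expected pipeline outcome for every module of a plan
plan_truth <- function(plan) {
  mods <- plan$modules
  rows <- map(seq_len(nrow(mods)), function(i) {
    d <- mods$domains[[i]]
    # a DH planted without its core motif carries no anchor, so the scanner
    # cannot detect it: the expected pipeline view omits it
    if ("DH" %in% d && !isTRUE(mods$dh_core_present[[i]])) {
      d <- setdiff(d, "DH")
    }
    first <- i == 1L
    loading <- first &&
      (mods$ks_residue[[i]] == "Q" || !any(d %in% c("DH", "ER", "KR")))
    dh_active <- sum(!mods$dh_aux_present[[i]]) <= 1
    kr_active <- isTRUE(mods$kr_triad_present[[i]])
    state <- if (loading) {
      NA_character_
    } else if (!"KR" %in% d || !kr_active) {
      "keto"
    } else if (!"DH" %in% d || !dh_active) {
      "hydroxyl"
    } else if (!"ER" %in% d) {
      "enoyl"
    } else {
      "methylene"
    }
    core_flagged <- str_sub(mods$at_core_window[[i]], 5, 5) == "H"
    cls <- classify_extender(mods$at_x[[i]], mods$at_secondary[[i]], core_flagged)
    tibble(
      module_index = i - 1L,
      protein_id = mods$protein[[i]],
      role = if (loading) "loading" else "extension",
      domains = paste(d, collapse = "-"),
      beta_state = state,
      unit = if (loading) "malonyl" else cls$unit,
      evidence = if (loading) "motif" else cls$evidence,
      has_te = "TE" %in% d
    )
  })
  list_rbind(rows)
}

#' Draw a random module plan
#'
#' Samples a random but grammar-valid assembly line: 1–3 proteins, a KSQ
#' loading module, extension modules with reductive sets drawn from
#' (none, KR, KR+DH, KR+DH+ER), random AT specificities (including
#' occasional noncanonical AAGH cases), random DH/KR lesions, and a TE on
#' the final module. Used by the recovery property tests.
#'
#' @param seed Integer seed.
#' @param max_extension Maximum number of extension modules (default 7).
#' @return A `pks_module_plan`.
#' @export
random_module_plan <- function(seed, max_extension = 7L) {
  withr::with_seed(seed, {
    n_ext <- sample(1:max_extension, 1L)
    n_prot <- sample(1:min(3L, n_ext + 1L), 1L)
    # split loading + extensions over proteins, contiguous, in order
    cuts <- sort(sample(seq_len(n_ext), n_prot - 1L))
    assign_prot <- findInterval(seq_len(n_ext + 1L) - 1L, c(0L, cuts + 1L))
    prot_names <- paste0("syn", seq_len(n_prot))

    rows <- map(seq_len(n_ext + 1L), function(i) {
      if (i == 1L) {
        return(tibble(
          protein = prot_names[[assign_prot[[i]]]],
          domains = list(c("KS", "AT", "ACP")),
          ks_residue = "Q", at_x = "L", at_secondary = "HAFH"
        ))
      }
      red <- sample(list(character(), "KR", c("DH", "KR"), c("DH", "ER", "KR")),
                    1L, prob = c(0.2, 0.35, 0.35, 0.1))[[1]]
      # domain order within a module follows the canonical KS-AT-DH-ER-KR-ACP
      d <- c("KS", "AT", intersect(c("DH", "ER", "KR"), red), "ACP")
      x <- sample(c("L", "V", "I", "F", "A", "M", "Q"), 1L)
      sec <- if (stats::runif(1) < 0.15) {
        "AAGH"
      } else if (x == "Q") {
        "YASH"
      } else {
        "HAFH"
      }
      tibble(
        protein = prot_names[[assign_prot[[i]]]],
        domains = list(if (i == n_ext + 1L) c(d, "TE") else d),
        ks_residue = "C", at_x = x, at_secondary = sec,
        dh_core_present = !("DH" %in% d && stats::runif(1) < 0.1),
        dh_aux_present = list(stats::runif(3) > 0.15),
        kr_triad_present = !("KR" %in% d && stats::runif(1) < 0.15),
        kr_fingerprint = sample(c("A", "B"), 1L)
      )
    })
    module_plan(list_rbind(rows))
  })
}

#' Generate a synthetic genome with planted GC structure
#'
#' Draws an i.i.d. background sequence at a target GC and overwrites
#' non-overlapping cluster regions with sequence at their own GC targets.
#' Regions of at least 2 kb are redrawn until their realized GC is within
#' 0.002 of target, so planted GC contrasts are recovered tightly.
#'
#' @param genome_length Total contig length in bp.
#' @param background_gc Background GC fraction in (0, 1).
#' @param cluster_specs Tibble with `cluster_id`, `start`, `end` (0-based
#'   half-open) and `gc` target per region; may be empty.
#' @param seed Integer seed.
#' @param contig_id Name of the single generated contig.
#' @return List with `dna` (tibble `id`, `sequence`), `intervals` (cluster
#'   interval tibble) and `truth` (targets and realized GC values).
#' @export
generate_genome <- function(genome_length, background_gc, cluster_specs = NULL,
                            seed = 1L, contig_id = "contig1") {
  if (is.null(cluster_specs)) {
    cluster_specs <- tibble(cluster_id = character(), start = integer(),
                            end = integer(), gc = double())
  }
  stopifnot(background_gc > 0, background_gc < 1,
            all(cluster_specs$gc > 0 & cluster_specs$gc < 1))
  cs <- cluster_specs |> arrange(.data$start)
  if (nrow(cs) > 1 && any(cs$end[-nrow(cs)] > cs$start[-1])) {
    abort("cluster intervals overlap")
  }
  if (nrow(cs) > 0 && (min(cs$start) < 0 || max(cs$end) > genome_length)) {
    abort("cluster interval outside genome bounds")
  }

  withr::with_seed(seed, {
    draw <- function(len, gc, tol = NA) {
      repeat {
        b <- sample(c("G", "C", "A", "T"), len, replace = TRUE,
                    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
        realized <- mean(b %in% c("G", "C"))
        if (is.na(tol) || abs(realized - gc) <= tol) {
          return(list(seq = b, gc = realized))
        }
      }
    }
    bg <- draw(genome_length, background_gc)
    genome <- bg$seq
    realized <- map_dbl(seq_len(nrow(cs)), function(i) {
      len <- cs$end[[i]] - cs$start[[i]]
      tol <- if (len >= 2000L) 0.002 else NA
      reg <- draw(len, cs$gc[[i]], tol)
      genome[(cs$start[[i]] + 1L):cs$end[[i]]] <<- reg$seq
      reg$gc
    })
    dna <- tibble(id = contig_id, sequence = paste(genome, collapse = ""))
    intervals <- tibble(
      cluster_id = as.character(cs$cluster_id), contig_id = contig_id,
      start = as.integer(cs$start), end = as.integer(cs$end),
      kind = "cluster"
    )
    list(
      dna = dna,
      intervals = intervals,
      truth = list(
        background_gc = background_gc,
        regions = mutate(cs, realized_gc = realized)
      )
    )
  })
}
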