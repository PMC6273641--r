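#' Construct a domain hit
#'
#' Builds a one-row domain-hit tibble of the shape produced by
#' [scan_domains()]. Mostly useful for testing the per-domain classification
#' rules on hand-crafted hits.
#'
#' @param protein_id Protein identifier.
#' @param domain_type One of KS, AT, DH, ER, KR, ACP, TE, Dock.
#' @param start,end 0-based half-open residue coordinates.
#' @param matched Named logical vector: which motif ids matched.
#' @param active_site Named list of extracted active-site residues.
#' @param motif_windows Named list of matched motif substrings.
#' @param flags Character vector of qualitative flags.
#' @return A one-row domain-hit tibble.
#' @export
domain_hit <- function(protein_id, domain_type, start = 0L, end = 1L,
                       matched = logical(), active_site = list(),
                       motif_windows = list(), flags = character()) {
  stopifnot(domain_type %in% arch_tokens, start < end)
  tibble(
    protein_id = protein_id,
    domain_type = domain_type,
    start = as.integer(start),
    end = as.integer(end),
    required_matched = sum(matched),
    matched = list(matched),
    active_site = list(active_site),
    motif_windows = list(motif_windows),
    flags = list(flags)
  )
}

#' Scan a protein for catalytic domains by anchored motif matching
#'
#' Finds candidate domains by matching each domain type's anchor motif, then
#' looks for the type's remaining motifs inside the canonical domain block
#' implied by the anchor position. Overlapping candidates are resolved
#' deterministically: more required motifs win, then leftmost start, then the
#' fixed domain-type priority (KS > AT > DH > ... > Dock). A hit's extent is
#' the span of its matched motifs padded by the configured flank.
#'
#' @param protein A one-row tibble with `id` and `sequence`, or a single
#'   amino-acid string.
#' @param config A [read_motif_config()] configuration.
#' @return A domain-hit tibble sorted by `start`, with per-hit `matched`,
#'   `active_site`, `motif_windows` and `flags` list-columns. Zero rows when
#'   nothing matches.
#' @export
scan_domains <- function(protein, config = default_motif_config()) {
  if (is.character(protein)) {
    protein <- tibble(id = "protein", sequence = protein)
  }
  stopifnot(nrow(protein) == 1L)
  seq <- protein$sequence[[1]]
  len <- nchar(seq)
  tab <- motif_table(config)

  all_matches <- map(seq_len(nrow(tab)), function(i) {
    m <- regex_matches(tab$pattern[[i]], seq)
    if (nrow(m) > config$max_matches_per_pattern) {
      abort(paste0(
        "degenerate motif pattern '", tab$motif_id[[i]], "' matches ",
        nrow(m), " sites on one protein"
      ))
    }
    m
  })
  names(all_matches) <- tab$motif_id

  candidates <- list()
  for (type in names(config$domains)) {
    sub <- tab |> filter(.data$domain_type == type)
    anchor <- sub |> filter(.data$anchor)
    amatch <- all_matches[[anchor$motif_id]]
    if (nrow(amatch) == 0) next
    for (k in seq_len(nrow(amatch))) {
      a_start <- amatch$start[[k]]
      block_start <- a_start - anchor$block_offset
      win_lo <- block_start - config$slack
      win_hi <- block_start + anchor$block_length + config$slack

      matched <- setNames(logical(nrow(sub)), sub$motif_id)
      windows <- list()
      sites <- list()
      spans <- matrix(c(amatch$start[[k]], amatch$end[[k]]), ncol = 2)

      for (j in seq_len(nrow(sub))) {
        mid <- sub$motif_id[[j]]
        if (mid == anchor$motif_id) {
          matched[[mid]] <- TRUE
          windows[[mid]] <- str_sub(seq, amatch$start[[k]], amatch$end[[k]])
          next
        }
        mm <- all_matches[[mid]]
        mm <- mm[mm$start >= win_lo & mm$start <= win_hi, , drop = FALSE]
        if (nrow(mm) == 0) next
        expected <- block_start + sub$block_offset[[j]]
        pick <- which.min(abs(mm$start - expected))
        matched[[mid]] <- TRUE
        windows[[mid]] <- str_sub(seq, mm$start[[pick]], mm$end[[pick]])
        spans <- rbind(spans, c(mm$start[[pick]], mm$end[[pick]]))
        if (!is.na(sub$extract_offset[[j]])) {
          sites[[mid]] <- str_sub(
            seq,
            mm$start[[pick]] + sub$extract_offset[[j]],
            mm$start[[pick]] + sub$extract_offset[[j]]
          )
        }
      }
      # anchor extraction, if any
      if (!is.na(anchor$extract_offset)) {
        sites[[anchor$motif_id]] <- str_sub(
          seq, a_start + anchor$extract_offset, a_start + anchor$extract_offset
        )
      }
      ext_lo <- max(1L, min(spans[, 1]) - config$flank)
      ext_hi <- min(len, max(spans[, 2]) + config$flank)
      candidates[[length(candidates) + 1L]] <- tibble(
        protein_id = protein$id[[1]],
        domain_type = type,
        start = ext_lo - 1L,
        end = as.integer(ext_hi),
        required_matched = sum(matched[sub$motif_id[sub$required]]),
        priority = anchor$priority,
        matched = list(matched),
        active_site = list(sites),
        motif_windows = list(windows),
        flags = list(character())
      )
    }
  }
  empty <- tibble(
    protein_id = character(), domain_type = character(),
    start = integer(), end = integer(), required_matched = integer(),
    matched = list(), active_site = list(), motif_windows = list(),
    flags = list()
  )
  if (length(candidates) == 0) return(empty)
  cand <- list_rbind(candidates) |>
    arrange(desc(.data$required_matched), .data$start, .data$priority)

  # greedy non-overlap resolution
  taken <- logical(0)
  acc_lo <- integer(0)
  acc_hi <- integer(0)
  keep_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    lo <- cand$start[[i]]
    hi <- cand$end[[i]]
    if (all(hi <= acc_lo | lo >= acc_hi)) {
      keep_idx <- c(keep_idx, i)
      acc_lo <- c(acc_lo, lo)
      acc_hi <- c(acc_hi, hi)
    }
  }
  cand |>
    slice(keep_idx) |>
    select(-"priority") |>
    arrange(.data$start)
}

# internal: fetch list-column entries from a one-row hit
hit_field <- function(hit, col, key) {
  v <- hit[[col]][[1]]
  v[[key]] %||% NULL
}
hit_matched <- function(hit, key) isTRUE(hit$matched[[1]][[key]])

#' Extract the acyltransferase active-site residue x
#'
#' Acyltransferase substrate choice is read from the GHSxG-family active-site
#' serine motif: the residue at position 4 of the matched 5-mer is the
#' specificity residue x. The match pattern is deliberately relaxed to
#' `GHS.[GH]` so that the noncanonical GHSQH variant still yields x = Q, with
#' a flag on the unusual fifth residue.
#'
#' @param hit A one-row AT domain hit from [scan_domains()].
#' @return List with `x` (single residue or `NA`), `window` (the matched
#'   5-mer or `NA`) and `flags`.
#' @export
at_active_site <- function(hit) {
  stopifnot(hit$domain_type[[1]] == "AT")
  window <- hit_field(hit, "motif_windows", "at_core")
  if (is.null(window)) {
    return(list(x = NA_character_, window = NA_character_,
                flags = "at_core_motif_missing"))
  }
  flags <- character()
  if (str_sub(window, 5, 5) == "H") flags <- "noncanonical_fifth_residue"
  list(x = str_sub(window, 4, 4), window = window, flags = flags)
}

#' Classify a ketosynthase as condensing or decarboxylative loading
#'
#' Condensing KS domains carry a catalytic cysteine; in loading-module KS
#' domains ("KSQ") that cysteine is replaced by glutamine and the domain
#' decarboxylates the loaded malonyl unit to an acetyl starter.
#'
#' @param hit A one-row KS domain hit.
#' @return List with `call` (`"condensing"`, `"decarboxylative_loading"` or
#'   `"unknown"`) and `flags`.
#' @export
ks_loading_call <- function(hit) {
  stopifnot(hit$domain_type[[1]] == "KS")
  res <- hit_field(hit, "active_site", "ks_active_site")
  if (is.null(res)) {
    return(list(call = "unknown", flags = "ks_active_site_missing"))
  }
  if (res == "C") return(list(call = "condensing", flags = character()))
  if (res == "Q") return(list(call = "decarboxylative_loading", flags = character()))
  list(call = "unknown", flags = "noncanonical_ks_active_site")
}

dh_aux_ids <- c("dh_aux_gyxygpxf", "dh_aux_lpfxw", "dh_aux_dxxxqh")

#' Call dehydratase activity from its motif set
#'
#' A DH domain is called active when its catalytic HxxxGxxxxP core is present
#' and at most `max_aux_failures` of the three auxiliary motifs (GYxYGPxF,
#' LPFxW, Dxxx(Q/H)) fail to match within the hit. The default threshold
#' (inactive at two or more failed auxiliaries) calls a domain with an intact
#' core but all three auxiliaries altered inactive, while tolerating a single
#' benign substitution. The call is a pure function of the four motif-match
#' booleans.
#'
#' @param hit A one-row DH domain hit.
#' @param max_aux_failures Auxiliary failures tolerated while still calling
#'   the domain active (default 1).
#' @return List with `active` (logical) and `reasons` (names of every failed
#'   motif; empty when active with a full motif set).
#' @export
dh_activity <- function(hit, max_aux_failures = 1L) {
  stopifnot(hit$domain_type[[1]] == "DH")
  core <- hit_matched(hit, "dh_core")
  aux <- map_lgl(dh_aux_ids, ~ hit_matched(hit, .x))
  reasons <- character()
  if (!core) reasons <- c(reasons, "dh_core")
  reasons <- c(reasons, dh_aux_ids[!aux])
  active <- core && sum(!aux) <= max_aux_failures
  list(active = active, reasons = reasons)
}

#' Type a ketoreductase and call its sequence-level activity
#'
#' Sequence-level activity requires the catalytic triad pattern; the
#' stereochemical type is read from the mutually exclusive type-A (tryptophan
#' fingerprint) and type-B (LDD fingerprint) markers. A domain displaying
#' both fingerprints is typed `unknown` and flagged ambiguous.
#'
#' @param hit A one-row KR domain hit.
#' @return List with `sequence_active` (logical), `stereo_type`
#'   (`"A"`, `"B"` or `"unknown"`) and `flags`.
#' @export
kr_typing <- function(hit) {
  stopifnot(hit$domain_type[[1]] == "KR")
  active <- hit_matched(hit, "kr_triad")
  a <- hit_matched(hit, "kr_type_a")
  b <- hit_matched(hit, "kr_type_b")
  flags <- character()
  stereo <- if (a && !b) "A" else if (b && !a) "B" else "unknown"
  if (a && b) flags <- "ambiguous_kr_type"
  list(sequence_active = active, stereo_type = stereo, flags = flags)
}

#' Scan and classify domains for a whole protein set
#'
#' Runs [scan_domains()] on every protein and attaches the per-domain calls
#' ([at_active_site()], [ks_loading_call()], [dh_activity()], [kr_typing()])
#' as plain columns, giving the annotated hit table consumed by
#' [segment_modules()].
#'
#' @param proteins Tibble with `id`, `sequence` and optionally
#'   `gene_order_index` (defaults to row order).
#' @param config A [read_motif_config()] configuration.
#' @return Annotated domain-hit tibble with call columns `ks_call`,
#'   `x_residue`, `secondary_motif`, `dh_active`, `kr_active`, `kr_type`,
#'   `er_active`, plus accumulated `flags`.
#' @export
annotate_proteins <- function(proteins, config = default_motif_config()) {
  if (!"gene_order_index" %in% names(proteins)) {
    proteins$gene_order_index <- seq_len(nrow(proteins)) - 1L
  }
  hits <- map(seq_len(nrow(proteins)), function(i) {
    h <- scan_domains(proteins[i, ], config)
    if (nrow(h) == 0) return(NULL)
    h$gene_order_index <- proteins$gene_order_index[[i]]
    h
  })
  hits <- list_rbind(keep(hits, ~ !is.null(.x)))
  if (is.null(hits) || nrow(hits) == 0) {
    return(annotate_hits(tibble()))
  }
  annotate_hits(hits)
}

# internal: add classification columns to a raw hit table (also accepts
# pseudo-hits from architecture_to_hits(), which have no motif evidence)
annotate_hits <- function(hits) {
  base_cols <- list(
    ks_call = NA_character_, x_residue = NA_character_,
    secondary_motif = NA_character_, dh_active = NA, kr_active = NA,
    kr_type = NA_character_, er_active = NA
  )
  if (nrow(hits) == 0) {
    for (nm in names(base_cols)) hits[[nm]] <- base_cols[[nm]][0]
    return(hits)
  }
  has_evidence <- "matched" %in% names(hits)
  if (!"flags" %in% names(hits)) hits$flags <- rep(list(character()), nrow(hits))
  for (nm in names(base_cols)) hits[[nm]] <- base_cols[[nm]]

  if (!has_evidence) {
    # token-only hits: domains are taken at face value (present = active)
    hits$dh_active[hits$domain_type == "DH"] <- TRUE
    hits$kr_active[hits$domain_type == "KR"] <- TRUE
    hits$er_active[hits$domain_type == "ER"] <- TRUE
    return(hits)
  }

  for (i in seq_len(nrow(hits))) {
    row <- hits[i, ]
    type <- row$domain_type[[1]]
    fl <- row$flags[[1]]
    if (type == "KS") {
      call <- ks_loading_call(row)
      hits$ks_call[[i]] <- call$call
      fl <- c(fl, call$flags)
    } else if (type == "AT") {
      site <- at_active_site(row)
      hits$x_residue[[i]] <- site$x
      fl <- c(fl, site$flags)
      sec <- hit_field(row, "motif_windows", "at_secondary")
      hits$secondary_motif[[i]] <- sec %||% NA_character_
    } else if (type == "DH") {
      act <- dh_activity(row)
      hits$dh_active[[i]] <- act$active
      if (!act$active) fl <- c(fl, "dh_inactive")
    } else if (type == "KR") {
      ty <- kr_typing(row)
      hits$kr_active[[i]] <- ty$sequence_active
      hits$kr_type[[i]] <- ty$stereo_type
      fl <- c(fl, ty$flags)
      if (!ty$sequence_active) fl <- c(fl, "kr_inactive")
    } else if (type == "ER") {
      hits$er_active[[i]] <- TRUE
    }
    hits$flags[[i]] <- fl
  }
  hits
}
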