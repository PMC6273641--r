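#' Load a motif configuration
#'
#' Reads and validates the YAML motif configuration driving domain scanning
#' and synthetic-cluster generation. Every pattern must compile as a regular
#' expression, each of KS, AT, DH, KR, ACP, TE and Dock must carry at least
#' one motif, and each domain type must designate exactly one required
#' `anchor` motif.
#'
#' @param path Path to a YAML motif configuration; defaults to the
#'   configuration shipped with the package.
#' @return A `motif_config` list with elements `flank`, `slack`,
#'   `max_matches_per_pattern` and `domains` (per-type list of `priority`,
#'   `block_length`, `motifs`).
#' @export
read_motif_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "motif_config.yaml", package = "pksline")
  cfg <- yaml::read_yaml(path)
  validate_motif_config(cfg)
}

#' @rdname read_motif_config
#' @export
default_motif_config <- function() read_motif_config()

validate_motif_config <- function(cfg) {
  need <- c("KS", "AT", "DH", "KR", "ACP", "TE", "Dock")
  missing <- setdiff(need, names(cfg$domains))
  if (length(missing) > 0) {
    abort(paste0("motif config lacks domain types: ", paste(missing, collapse = ", ")))
  }
  cfg$flank <- cfg$flank %||% 10L
  cfg$slack <- cfg$slack %||% 30L
  cfg$max_matches_per_pattern <- cfg$max_matches_per_pattern %||% 1000L
  for (type in names(cfg$domains)) {
    dom <- cfg$domains[[type]]
    if (length(dom$motifs) < 1) {
      abort(paste0("motif config: domain type ", type, " has no motifs"))
    }
    anchors <- 0L
    for (m in dom$motifs) {
      ok <- tryCatch({
        grepl(m$pattern, "AAAA", perl = TRUE)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) abort(paste0("motif pattern does not compile: ", m$motif_id))
      if (isTRUE(m$anchor)) {
        anchors <- anchors + 1L
        if (!isTRUE(m$required)) {
          abort(paste0("anchor motif must be required: ", m$motif_id))
        }
      }
    }
    if (anchors != 1L) {
      abort(paste0("domain type ", type, " must have exactly one anchor motif"))
    }
  }
  structure(cfg, class = "motif_config")
}

# internal: tibble of all motifs with their domain type
motif_table <- function(config) {
  rows <- imap(config$domains, function(dom, type) {
    list_rbind(map(dom$motifs, function(m) {
      tibble(
        domain_type = type,
        motif_id = m$motif_id,
        pattern = m$pattern,
        block_offset = as.integer(m$block_offset),
        required = isTRUE(m$required),
        anchor = isTRUE(m$anchor),
        extract_offset = if (is.null(m$extract_offset)) NA_integer_ else as.integer(m$extract_offset),
        plant = m$plant %||% NA_character_,
        priority = as.integer(dom$priority),
        block_length = as.integer(dom$block_length)
      )
    }))
  })
  list_rbind(unname(rows))
}

# internal: all match start/end (1-based inclusive) of a regex in a sequence
regex_matches <- function(pattern, sequence) {
  loc <- str_locate_all(sequence, pattern)[[1]]
  tibble(start = loc[, 1], end = loc[, 2])
}
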