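#' Read protein or DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble, one row per record in file order. The
#' file position (0-based) becomes `gene_order_index`, the declared gene order
#' used when proteins are concatenated into an assembly line. Sequences are
#' uppercased and whitespace/gap characters are stripped.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (default) or `"dna"`; controls the alphabet used
#'   for the sanity warning, characters are never altered or dropped.
#' @return A tibble with columns `id`, `gene_order_index`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKT", ">b", "GHS"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no records in FASTA file: ", path))
  seqs <- str_to_upper(as.character(set))
  seqs <- str_replace_all(seqs, "[\\s.\\-*]", "")
  if (any(!nzchar(seqs))) abort("FASTA record with empty sequence")
  alphabet <- if (type == "protein") {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  } else {
    c("A", "C", "G", "T", "N")
  }
  letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  odd <- setdiff(letters_seen, alphabet)
  if (length(odd) > 0) {
    warn(paste0(
      "unexpected characters in ", type, " FASTA (kept as-is): ",
      paste(odd, collapse = ", ")
    ))
  }
  # header up to first whitespace, as common FASTA tooling does
  ids <- str_extract(names(set), "^\\S+")
  tibble(
    id = ids,
    gene_order_index = seq_along(ids) - 1L,
    sequence = unname(seqs)
  )
}

#' Write sequences to a FASTA file
#'
#' Counterpart of [read_fasta()]; used mainly to persist synthetic clusters.
#' Round-trips sequence content byte-exactly.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  lines <- as.vector(rbind(paste0(">", records$id), records$sequence))
  writeLines(lines, path)
  invisible(path)
}

## ---- assembly-line architecture string grammar -----------------------------

arch_tokens <- c("KS", "AT", "DH", "ER", "KR", "ACP", "TE", "Dock")

#' Parse an assembly-line architecture string
#'
#' Parses the compact textual notation for multi-protein PKS assembly lines,
#' e.g. `"ThaBI [(KS-AT-ACP)-(KS-AT-KR-ACP)-Dock]"`. Each protein is a name
#' followed by a bracketed body: an optional leading `Dock`, parenthesised
#' module groups separated by `-`, an optional trailing `TE` (attached to the
#' final module) and an optional trailing `Dock` (attached to the protein).
#' Proteins are separated by whitespace and/or commas.
#'
#' @param text Architecture string, possibly spanning several lines.
#' @return A `pks_architecture` object: a list with a `proteins` tibble
#'   (`name`, `n_term_dock`, `c_term_dock`) and a `groups` list of per-protein
#'   lists of domain-token character vectors.
#' @examples
#' arch <- parse_architecture("P [(KS-AT-ACP)]")
#' format(arch)
#' @export
parse_architecture <- function(text) {
  text <- paste(text, collapse = "\n")
  n <- nchar(text)
  pos <- 1L

  err <- function(msg, at = pos) {
    abort(paste0("architecture parse error at character ", at, ": ", msg))
  }
  skip_ws <- function() {
    while (pos <= n && str_detect(substr(text, pos, pos), "[\\s,]")) {
      pos <<- pos + 1L
    }
  }
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  take_word <- function() {
    m <- regexpr("^[A-Za-z0-9_]+", substr(text, pos, n))
    if (m == -1L) return("")
    w <- regmatches(substr(text, pos, n), m)
    pos <<- pos + nchar(w)
    w
  }

  parse_token <- function() {
    at <- pos
    w <- take_word()
    if (w == "") err("expected a domain token")
    if (!w %in% arch_tokens) err(paste0("unknown domain token '", w, "'"), at)
    w
  }
  parse_group <- function() {
    at <- pos
    if (peek() != "(") err("expected '('")
    pos <<- pos + 1L
    toks <- parse_token()
    while (peek() == "-") {
      pos <<- pos + 1L
      toks <- c(toks, parse_token())
    }
    if (peek() != ")") err("unbalanced parentheses: expected ')'", at)
    pos <<- pos + 1L
    toks
  }

  proteins <- list()
  groups <- list()
  skip_ws()
  while (pos <= n) {
    at <- pos
    name <- take_word()
    if (name == "") err("expected a protein name")
    skip_ws()
    if (peek() != "[") err(paste0("expected '[' after protein name '", name, "'"))
    pos <- pos + 1L
    skip_ws()

    n_dock <- FALSE
    c_dock <- FALSE
    pgroups <- list()

    # optional leading Dock-
    save <- pos
    w <- take_word()
    if (w == "Dock") {
      if (peek() != "-") err("expected '-' after leading Dock")
      pos <- pos + 1L
      n_dock <- TRUE
    } else {
      pos <- save
    }

    pgroups[[1]] <- parse_group()
    repeat {
      if (peek() != "-") break
      save <- pos
      pos <- pos + 1L
      if (peek() == "(") {
        pgroups[[length(pgroups) + 1L]] <- parse_group()
        next
      }
      w <- take_word()
      if (w == "TE") {
        pgroups[[length(pgroups)]] <- c(pgroups[[length(pgroups)]], "TE")
      } else if (w == "Dock") {
        c_dock <- TRUE
        break
      } else {
        err("expected '(' or trailing 'TE'/'Dock' after '-'", save)
      }
    }
    if (peek() != "]") err("unbalanced brackets: expected ']'", at)
    pos <- pos + 1L

    bad <- map_lgl(pgroups, ~ "Dock" %in% .x)
    if (any(bad)) err("Dock tokens may only appear at protein termini", at)

    proteins[[length(proteins) + 1L]] <-
      tibble(name = name, n_term_dock = n_dock, c_term_dock = c_dock)
    groups[[length(groups) + 1L]] <- pgroups
    skip_ws()
  }
  if (length(proteins) == 0L) abort("architecture parse error: empty input")

  structure(
    list(proteins = list_rbind(proteins), groups = groups),
    class = "pks_architecture"
  )
}

#' @export
format.pks_architecture <- function(x, ...) {
  pieces <- map_chr(seq_len(nrow(x$proteins)), function(i) {
    p <- x$proteins[i, ]
    gs <- x$groups[[i]]
    # TE is printed outside the final group's parentheses (canonical form)
    has_te <- "TE" %in% gs[[length(gs)]]
    if (has_te) {
      gs[[length(gs)]] <- setdiff(gs[[length(gs)]], "TE")
    }
    body <- paste0("(", map_chr(gs, paste, collapse = "-"), ")", collapse = "-")
    if (p$n_term_dock) body <- paste0("Dock-", body)
    if (has_te) body <- paste0(body, "-TE")
    if (p$c_term_dock) body <- paste0(body, "-Dock")
    paste0(p$name, " [", body, "]")
  })
  paste(pieces, collapse = " ")
}

#' @export
print.pks_architecture <- function(x, ...) {
  cat("<pks_architecture>", nrow(x$proteins), "proteins,",
      sum(map_int(x$groups, length)), "module groups\n")
  cat(format(x), "\n")
  invisible(x)
}

#' Convert a parsed architecture to a pseudo domain-hit table
#'
#' Lays the tokens of a [parse_architecture()] result onto synthetic residue
#' coordinates (one token per 100-residue slot) so that an architecture known
#' only as text can be segmented with [segment_modules()] exactly like scanned
#' sequences.
#'
#' @param arch A `pks_architecture`.
#' @return A domain-hit tibble (`protein_id`, `gene_order_index`,
#'   `domain_type`, `start`, `end`).
#' @export
architecture_to_hits <- function(arch) {
  stopifnot(inherits(arch, "pks_architecture"))
  out <- map(seq_len(nrow(arch$proteins)), function(i) {
    p <- arch$proteins[i, ]
    toks <- unlist(arch$groups[[i]], use.names = FALSE)
    if (p$n_term_dock) toks <- c("Dock", toks)
    if (p$c_term_dock) toks <- c(toks, "Dock")
    tibble(
      protein_id = p$name,
      gene_order_index = i - 1L,
      domain_type = toks,
      start = (seq_along(toks) - 1L) * 100L,
      end = (seq_along(toks) - 1L) * 100L + 80L
    )
  })
  list_rbind(out)
}

#' Read a cluster interval table
#'
#' Minimal four-plus-column TSV carrying cluster calls (e.g. exported from an
#' antiSMASH run): `cluster_id`, `contig_id`, `start`, `end`, optional `kind`.
#' Coordinates are 0-based, half-open.
#'
#' @param path TSV path.
#' @return Tibble with those columns (`kind` filled with `NA` if absent).
#' @export
read_interval_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("cluster_id", "contig_id", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0("interval table must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"kind" %in% names(x)) x$kind <- NA_character_
  if (any(x$start < 0 | x$start >= x$end)) {
    abort("interval table: require 0 <= start < end")
  }
  as_tibble(x[, c(need, "kind")])
}

## ---- reports ---------------------------------------------------------------

signif6 <- function(x) {
  if (is.list(x)) return(lapply(x, signif6))
  if (is.double(x)) return(signif(x, 6))
  x
}

sort_keys <- function(x) {
  if (is.data.frame(x)) {
    return(lapply(sort(names(x)), function(nm) x[[nm]]) |> setNames(sort(names(x))) |> as_tibble())
  }
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms) && all(nzchar(nms))) {
      x <- x[order(nms)]
    }
    return(lapply(x, sort_keys))
  }
  x
}

#' Serialize an assembly line or product report to disk
#'
#' Writes a deterministic report: keys in sorted order, doubles at 6
#' significant digits, so the same object always produces byte-identical
#' files.
#'
#' @param x A `pks_assembly_line`, `polyketide_product`, or any tibble/list.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`. TSV requires a tabular report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  rep <- as_report(x)
  rep <- sort_keys(signif6(rep))
  if (format == "json") {
    json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                             na = "null", pretty = TRUE)
    con <- tryCatch(file(path, "wb"), error = function(e) {
      abort(paste0("cannot open path for writing: ", path))
    })
    on.exit(close(con))
    writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  } else {
    tab <- report_table(x)
    tab <- tab[, sort(names(tab))]
    tab <- as_tibble(lapply(tab, function(col) {
      if (is.double(col)) signif(col, 6) else col
    }))
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

# internal: plain-list view of an object for JSON serialization
as_report <- function(x) UseMethod("as_report")

#' @export
as_report.default <- function(x) {
  if (is.data.frame(x)) return(lapply(as.list(x), unname))
  x
}

# internal: tabular view for TSV serialization
report_table <- function(x) UseMethod("report_table")

#' @export
report_table.default <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  abort("object has no tabular report; use format = 'json'")
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
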