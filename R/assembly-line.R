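#' Segment ordered domain hits into assembly-line modules
#'
#' Concatenates proteins in declared gene order and cuts each protein's
#' ordered domain hits into modules: a module starts at each KS and runs to
#' the residue before the next KS (or the protein end). Terminal Dock hits
#' are attached to the protein, not to a module. Module 0 is called the
#' loading module when its KS carries the decarboxylative (KSQ) active site,
#' or when it is first and lacks all reductive domains; every other module is
#' an extension module. Modules violating the one-KS/one-AT/one-ACP grammar
#' are flagged `malformed`, never dropped.
#'
#' @param hits Domain-hit tibble from [annotate_proteins()] (or pseudo-hits
#'   from [architecture_to_hits()]). Proteins with no KS hit are excluded
#'   with a warning.
#' @param gene_order Optional character vector of protein ids giving the gene
#'   order; defaults to the `gene_order_index` column, then first appearance.
#' @return A `pks_assembly_line` object: list with tibbles `proteins`
#'   (`protein_id`, `gene_order_index`, `n_term_dock`, `c_term_dock`),
#'   `modules` (`module_index`, `protein_id`, `role`, `has_te`, `malformed`,
#'   `flags`) and `domains` (the hits, with `module_index` attached).
#' @export
segment_modules <- function(hits, gene_order = NULL) {
  if (nrow(hits) == 0) {
    return(new_pks_assembly_line(
      proteins = tibble(protein_id = character(), gene_order_index = integer(),
                        n_term_dock = logical(), c_term_dock = logical()),
      modules = tibble(module_index = integer(), protein_id = character(),
                       role = character(), has_te = logical(),
                       malformed = logical(), flags = list()),
      domains = tibble()
    ))
  }
  if (!"ks_call" %in% names(hits)) hits <- annotate_hits(hits)

  if (is.null(gene_order)) {
    if ("gene_order_index" %in% names(hits)) {
      gene_order <- hits |>
        distinct(.data$protein_id, .data$gene_order_index) |>
        arrange(.data$gene_order_index) |>
        pull("protein_id")
    } else {
      gene_order <- unique(hits$protein_id)
    }
  }

  proteins_out <- list()
  modules_out <- list()
  domains_out <- list()
  mod_idx <- 0L

  for (pi in seq_along(gene_order)) {
    pid <- gene_order[[pi]]
    ph <- hits |> filter(.data$protein_id == pid) |> arrange(.data$start)
    core <- ph |> filter(.data$domain_type != "Dock")
    ks_pos <- which(core$domain_type == "KS")
    if (length(ks_pos) == 0) {
      warn(paste0("protein '", pid, "' has no KS hit; excluded from assembly line"))
      next
    }
    docks <- ph |> filter(.data$domain_type == "Dock")
    first_core_start <- core$start[[1]]
    last_core_end <- core$end[[nrow(core)]]
    n_dock <- any(docks$end <= first_core_start)
    c_dock <- any(docks$start >= last_core_end)

    proteins_out[[length(proteins_out) + 1L]] <- tibble(
      protein_id = pid, gene_order_index = pi - 1L,
      n_term_dock = n_dock, c_term_dock = c_dock
    )
    if (ks_pos[[1]] > 1) {
      warn(paste0(
        "protein '", pid, "' has domains before its first KS; ",
        "they are not assigned to any module"
      ))
    }

    bounds <- c(ks_pos, nrow(core) + 1L)
    for (k in seq_along(ks_pos)) {
      mod_rows <- core[bounds[[k]]:(bounds[[k + 1L]] - 1L), ]
      types <- mod_rows$domain_type
      flags <- character()
      malformed <- sum(types == "KS") != 1L || sum(types == "AT") != 1L ||
        sum(types == "ACP") != 1L || any(table(types[types %in% c("DH", "ER", "KR")]) > 1)
      if (malformed) flags <- c(flags, "malformed")

      role <- "extension"
      if (mod_idx == 0L) {
        ksq <- identical(mod_rows$ks_call[[1]], "decarboxylative_loading")
        bare <- !any(types %in% c("DH", "ER", "KR"))
        if (ksq || bare) role <- "loading"
      }
      mod_rows$module_index <- mod_idx
      domains_out[[length(domains_out) + 1L]] <- mod_rows
      modules_out[[length(modules_out) + 1L]] <- tibble(
        module_index = mod_idx, protein_id = pid, role = role,
        has_te = "TE" %in% types, malformed = malformed, flags = list(flags)
      )
      mod_idx <- mod_idx + 1L
    }
  }

  modules <- list_rbind(modules_out)
  # TE anywhere but the final module is kept but flagged
  te_at <- which(modules$has_te)
  internal_te <- te_at[te_at != nrow(modules)]
  for (i in internal_te) {
    modules$flags[[i]] <- c(modules$flags[[i]], "internal_te")
  }

  new_pks_assembly_line(
    proteins = list_rbind(proteins_out),
    modules = modules,
    domains = list_rbind(domains_out)
  )
}

new_pks_assembly_line <- function(proteins, modules, domains) {
  structure(
    list(proteins = proteins, modules = modules, domains = domains),
    class = "pks_assembly_line"
  )
}

#' Count extension modules of an assembly line
#'
#' @param line A `pks_assembly_line`.
#' @return Number of modules with role `"extension"`.
#' @export
count_extension_modules <- function(line) {
  stopifnot(inherits(line, "pks_assembly_line"))
  sum(line$modules$role == "extension")
}

#' Render an assembly line in architecture-string notation
#'
#' @param line A `pks_assembly_line`.
#' @return A `pks_architecture` object (print with [format()]).
#' @export
line_to_architecture <- function(line) {
  stopifnot(inherits(line, "pks_assembly_line"))
  groups <- map(line$proteins$protein_id, function(pid) {
    idx <- line$modules$module_index[line$modules$protein_id == pid]
    map(idx, function(mi) {
      line$domains |>
        filter(.data$module_index == mi) |>
        pull("domain_type")
    })
  })
  structure(
    list(
      proteins = tibble(
        name = line$proteins$protein_id,
        n_term_dock = line$proteins$n_term_dock,
        c_term_dock = line$proteins$c_term_dock
      ),
      groups = groups
    ),
    class = "pks_architecture"
  )
}

#' @export
print.pks_assembly_line <- function(x, ...) {
  cat("<pks_assembly_line> ", nrow(x$proteins), " proteins, ",
      nrow(x$modules), " modules (", count_extension_modules(x),
      " extension)\n", sep = "")
  if (nrow(x$modules) > 0) cat(format(line_to_architecture(x)), "\n")
  invisible(x)
}

#' @export
tidy.pks_assembly_line <- function(x, ...) {
  if (nrow(x$modules) == 0) return(x$modules)
  dom_summary <- x$domains |>
    group_by(.data$module_index) |>
    summarise(domains = paste(.data$domain_type, collapse = "-"),
              .groups = "drop")
  x$modules |>
    left_join(dom_summary, by = "module_index") |>
    mutate(flags = map_chr(.data$flags, paste, collapse = ";"))
}

#' @export
glance.pks_assembly_line <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$proteins),
    n_modules = nrow(x$modules),
    n_extension = count_extension_modules(x),
    n_loading = sum(x$modules$role == "loading"),
    has_te = any(x$modules$has_te),
    n_malformed = sum(x$modules$malformed)
  )
}

#' @export
as_report.pks_assembly_line <- function(x) {
  list(
    proteins = as_report(x$proteins),
    modules = as_report(tidy(x)),
    architecture = format(line_to_architecture(x))
  )
}

#' @export
report_table.pks_assembly_line <- function(x) tidy(x)

#' Domain map of an assembly line
#'
#' Tile plot of domain composition per module, faceted by protein — the
#' linear rendition of the usual assembly-line cartoon.
#'
#' @param object A `pks_assembly_line`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pks_assembly_line <- function(object, ...) {
  d <- object$domains |>
    group_by(.data$module_index) |>
    mutate(slot = row_number()) |>
    ungroup() |>
    left_join(select(object$modules, "module_index", "role"),
              by = "module_index")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$module_index, y = .data$slot,
    fill = .data$domain_type
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$domain_type), size = 2.6) +
    ggplot2::facet_grid(. ~ protein_id, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "module", y = NULL, fill = "domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
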