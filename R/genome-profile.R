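#' Sliding-window GC content of DNA sequences
#'
#' Computes GC fraction in fixed-width windows (default 500 bp) advanced by a
#' fixed step (default 250 bp), the classic track used to spot putative
#' horizontally transferred regions against the genome background. Only
#' full-length windows are kept; `N` bases are excluded from the denominator
#' and windows with more than 50% `N` are dropped.
#'
#' @param dna_records Tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()] with `type = "dna"`), or a named character vector.
#' @param window_size Window width in bp (default 500).
#' @param step Step between window starts in bp (default 250);
#'   `1 <= step <= window_size`.
#' @return A `gc_profile` tibble: `contig_id`, `start` (0-based), `gc`
#'   (fraction in `[0, 1]`), sorted by (`contig_id`, `start`), with the
#'   window geometry stored in attributes `window_size` and `step`.
#' @examples
#' gc_windows(tibble::tibble(id = "c", sequence = strrep("ATGC", 250)))
#' @export
gc_windows <- function(dna_records, window_size = 500L, step = 250L) {
  dna_records <- normalize_dna_records(dna_records)
  if (window_size < 1L) abort("window_size must be >= 1")
  if (step < 1L || step > window_size) abort("require 1 <= step <= window_size")

  rows <- map(seq_len(nrow(dna_records)), function(i) {
    seq <- dna_records$sequence[[i]]
    len <- nchar(seq)
    if (len < window_size) return(NULL)
    x <- Biostrings::DNAString(seq)
    freq <- Biostrings::letterFrequencyInSlidingView(
      x, view.width = window_size, letters = c("G", "C", "N")
    )
    starts <- seq.int(1L, len - window_size + 1L, by = step)
    gcn <- freq[starts, , drop = FALSE]
    n_count <- gcn[, "N"]
    denom <- window_size - n_count
    gc <- ifelse(denom > 0, (gcn[, "G"] + gcn[, "C"]) / denom, NA_real_)
    keep <- n_count <= window_size / 2 & denom > 0
    tibble(
      contig_id = dna_records$id[[i]],
      start = starts[keep] - 1L,
      gc = unname(gc[keep])
    )
  })
  rows <- keep(rows, ~ !is.null(.x))
  out <- if (length(rows) == 0) {
    tibble(contig_id = character(), start = integer(), gc = double())
  } else {
    list_rbind(rows) |> arrange(.data$contig_id, .data$start)
  }
  structure(out, window_size = as.integer(window_size), step = as.integer(step),
            class = c("gc_profile", class(out)))
}

normalize_dna_records <- function(dna_records) {
  if (is.character(dna_records)) {
    ids <- names(dna_records) %||% paste0("contig", seq_along(dna_records))
    dna_records <- tibble(id = ids, sequence = unname(dna_records))
  }
  stopifnot(all(c("id", "sequence") %in% names(dna_records)))
  dna_records
}

#' Exact GC fraction of a genomic interval
#'
#' Counts bases over the interval directly (no window averaging); `N` bases
#' are excluded from the denominator.
#'
#' @param dna_records DNA records as in [gc_windows()].
#' @param contig_id Contig to read from.
#' @param start,end 0-based half-open interval; must lie within the contig.
#' @return GC fraction in `[0, 1]`.
#' @export
region_gc <- function(dna_records, contig_id, start, end) {
  dna_records <- normalize_dna_records(dna_records)
  i <- match(contig_id, dna_records$id)
  if (is.na(i)) abort(paste0("unknown contig: ", contig_id))
  len <- nchar(dna_records$sequence[[i]])
  if (start < 0 || end > len || start >= end) {
    abort(paste0(
      "interval [", start, ", ", end, ") out of bounds for contig '",
      contig_id, "' of length ", len
    ))
  }
  x <- Biostrings::DNAString(str_sub(dna_records$sequence[[i]], start + 1L, end))
  counts <- Biostrings::letterFrequency(x, c("G", "C", "N"))
  denom <- (end - start) - counts[["N"]]
  if (denom == 0) return(NA_real_)
  (counts[["G"]] + counts[["C"]]) / denom
}

#' GC contrast of candidate regions against the genome background
#'
#' For each interval, reports its exact GC, the whole-genome GC, their
#' difference, and the min/max of profile windows falling entirely inside the
#' region. A positive `delta` for a gene cluster mirrors the
#' horizontal-transfer signal used when triaging candidate clusters.
#'
#' @param dna_records DNA records as in [gc_windows()].
#' @param intervals Tibble with `cluster_id`, `contig_id`, `start`, `end`.
#' @param profile Optional precomputed [gc_windows()] profile; computed with
#'   defaults when omitted.
#' @return Tibble: `cluster_id`, `region_gc`, `genome_gc`, `delta`,
#'   `min_window`, `max_window` (the last two `NA` when no full window fits).
#' @export
gc_contrast <- function(dna_records, intervals, profile = NULL) {
  dna_records <- normalize_dna_records(dna_records)
  if (is.null(profile)) profile <- gc_windows(dna_records)
  wsize <- attr(profile, "window_size") %||% 500L

  total <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(dna_records$sequence), c("G", "C", "N")
  )
  denom <- sum(nchar(dna_records$sequence)) - sum(total[, "N"])
  genome_gc <- sum(total[, "G"] + total[, "C"]) / denom

  rows <- map(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    rgc <- region_gc(dna_records, iv$contig_id, iv$start, iv$end)
    inside <- profile |>
      filter(
        .data$contig_id == iv$contig_id,
        .data$start >= iv$start,
        .data$start + wsize <= iv$end
      )
    tibble(
      cluster_id = as.character(iv$cluster_id),
      region_gc = rgc,
      genome_gc = genome_gc,
      delta = rgc - genome_gc,
      min_window = if (nrow(inside)) min(inside$gc) else NA_real_,
      max_window = if (nrow(inside)) max(inside$gc) else NA_real_
    )
  })
  list_rbind(rows)
}

#' Plot a GC profile track
#'
#' Line plot of windowed GC along each contig, optionally with candidate
#' regions shaded and the genome-average GC as a dashed rule — a flat
#' rendition of the circular GC track of genome-mining figures.
#'
#' @param profile A [gc_windows()] profile.
#' @param intervals Optional interval tibble (`cluster_id`, `contig_id`,
#'   `start`, `end`) to shade.
#' @param genome_gc Optional genome-average GC fraction for the dashed rule.
#' @return A ggplot object.
#' @export
plot_gc_profile <- function(profile, intervals = NULL, genome_gc = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$start, y = .data$gc)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~contig_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "GC fraction") +
    ggplot2::theme_minimal()
  if (!is.null(intervals)) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick"
    )
  }
  if (!is.null(genome_gc)) {
    p <- p + ggplot2::geom_hline(yintercept = genome_gc, linetype = "dashed")
  }
  p
}

#' @export
autoplot.gc_profile <- function(object, ...) plot_gc_profile(object, ...)
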