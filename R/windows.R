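#' Tile a genotype matrix into non-overlapping windows
#'
#' Windows tile each chromosome starting at position 1 (the anchoring
#' convention declared by this package), with the per-window variant count
#' attached. The tiling covers position 1 through the last variant.
#'
#' @param g a `genotype_matrix`
#' @param size window size in bp (default 10 kb)
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, empty trailing windows up to the chromosome end are included.
#' @return a tibble with columns `chrom`, `start`, `end`, `n_variants`
#' @export
make_windows <- function(g, size = 10000L, chrom_lengths = NULL) {
  stopifnot(size > 0)
  chroms <- unique(g$sites$chrom)
  if (length(chroms) == 0 && !is.null(chrom_lengths))
    chroms <- names(chrom_lengths)
  out <- lapply(chroms, function(ch) {
    pos <- g$sites$pos[g$sites$chrom == ch]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (length(pos)) max(pos) else size
    n_win <- ceiling(len / size)
    idx <- if (length(pos)) (pos - 1L) %/% size + 1L else integer(0)
    counts <- tabulate(idx, nbins = n_win)
    tibble(chrom = ch,
           start = (seq_len(n_win) - 1L) * size + 1L,
           end = seq_len(n_win) * size,
           n_variants = counts)
  })
  bind_rows(out)
}

#' Remove variant-sparse windows
#'
#' Removes windows whose variant count is at or below the given quantile of
#' the per-window count distribution (the "bottom q" rule used before
#' computing windowed differentiation statistics, since sparse windows give
#' artificially extreme values). Counts tied with the quantile threshold
#' are all removed; if that empties the set, a warning is raised.
#'
#' @param windows a window tibble from [make_windows()]
#' @param quantile proportion in \[0, 1) of windows to cut from the bottom
#'   (default 0.10)
#' @return the retained windows, with an attribute `n_dropped`
#' @export
drop_sparse_windows <- function(windows, quantile = 0.10) {
  stopifnot(quantile >= 0, quantile < 1)
  if (nrow(windows) == 0) stop("empty window list")
  thr <- stats::quantile(windows$n_variants, probs = quantile, type = 7,
                         names = FALSE)
  keep <- windows$n_variants > thr
  if (!any(keep))
    warning("all windows tie at the sparse-window threshold; none retained")
  out <- windows[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Window row index per site (NA where a site falls in no window)
#' @noRd
site_window_map <- function(g, windows) {
  wid <- rep(NA_integer_, nrow(g$sites))
  for (ch in unique(windows$chrom)) {
    wrows <- which(windows$chrom == ch)
    srows <- which(g$sites$chrom == ch)
    if (!length(srows)) next
    k <- findInterval(g$sites$pos[srows], windows$start[wrows])
    kk <- pmax(k, 1L)
    ok <- k >= 1L & g$sites$pos[srows] <= windows$end[wrows][kk]
    wid[srows[ok]] <- wrows[k[ok]]
  }
  wid
}
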