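#' Sliding-window grid over a genomic segment
#'
#' Builds the ordered set of fixed-size sliding windows used by the read-depth
#' caller. Coordinates are 0-based half-open; with the default 200 bp windows
#' and 100 bp steps, consecutive windows overlap by half.
#'
#' @param segment_start,segment_end Segment bounds in bp (0-based half-open).
#' @param window Window size in bp (default 200).
#' @param step Slide step in bp (default 100).
#' @return Tibble with columns `window` (1-based index), `start`, `end`,
#'   `masked` (all `FALSE` initially).
#' @export
window_grid <- function(segment_start, segment_end, window = 200L,
                        step = 100L) {
  abort_if(segment_end <= segment_start, "window_grid(): empty segment")
  abort_if(window < 1 || step < 1, "window_grid(): window and step must be positive")
  starts <- seq(segment_start, segment_end - window, by = step)
  abort_if(length(starts) == 0L, "window_grid(): segment shorter than one window")
  ends <- as.integer(starts + window)
  tibble::tibble(
    window = seq_along(starts),
    start = as.integer(starts),
    end = ends,
    masked = FALSE
  )
}

#' Count read starts per sliding window
#'
#' Each read contributes to every window containing its start position (with
#' 200/100 geometry, at most two), so a read's total contribution is constant
#' across the grid. An `overlap` mode counting any-overlap of `[start, end)`
#' read intervals is available as a dialect switch.
#'
#' @param reads Tibble of aligned reads: `animal_id`, `start` (0-based bp) and,
#'   for `count_mode = "overlap"`, `end`.
#' @param grid Window grid from [window_grid()].
#' @param count_mode `"start"` (default) or `"overlap"`.
#' @param animal_ids Animals the panel should cover (rows with zero reads are
#'   kept as all-zero tracks); defaults to the animals present in `reads`.
#' @return Long depth tibble: `animal_id`, `window`, `window_start`,
#'   `window_end`, `count`, with every animal x window combination present.
#' @export
count_windows <- function(reads, grid, count_mode = c("start", "overlap"),
                          animal_ids = NULL) {
  count_mode <- match.arg(count_mode)
  abort_if(!all(c("animal_id", "start") %in% names(reads)),
           "count_windows(): reads need animal_id and start columns")
  seg_lo <- grid$start[1]
  seg_hi <- grid$end[nrow(grid)]
  bad <- reads$start < seg_lo | reads$start >= seg_hi
  abort_if(any(bad), sprintf(
    "count_windows(): %d read(s) start outside segment [%d, %d)",
    sum(bad), seg_lo, seg_hi))

  animals <- as.character(animal_ids %||% unique(reads$animal_id))
  abort_if(length(animals) == 0L, "count_windows(): no animals in panel")
  abort_if(!all(as.character(reads$animal_id) %in% animals),
           "count_windows(): reads contain animals not in animal_ids")
  w <- nrow(grid)
  counts <- matrix(0L, nrow = length(animals), ncol = w,
                   dimnames = list(animals, NULL))
  step <- if (w > 1L) grid$start[2] - grid$start[1] else grid$end[1] - grid$start[1]
  size <- grid$end[1] - grid$start[1]
  span <- ceiling(size / step)  # max windows containing one position

  by_animal <- split(reads, reads$animal_id)
  for (aid in names(by_animal)) {
    pos <- by_animal[[aid]]$start
    if (count_mode == "start") {
      # window j contains pos iff start_j <= pos < start_j + size
      last <- pmin(floor((pos - seg_lo) / step) + 1L, w)
      for (k in seq_len(span)) {
        j <- last - k + 1L
        valid <- j >= 1L
        jj <- j[valid]
        pp <- pos[valid]
        ok <- pp >= grid$start[jj] & pp < grid$start[jj] + size
        counts[aid, ] <- counts[aid, ] + tabulate(jj[ok], nbins = w)
      }
    } else {
      ends <- by_animal[[aid]]$end
      for (j in seq_len(w)) {
        counts[aid, j] <- sum(pos < grid$end[j] & ends > grid$start[j])
      }
    }
  }
  depth_panel_from_matrix(counts, grid)
}

depth_panel_from_matrix <- function(counts, grid) {
  tidyr::expand_grid(animal_id = rownames(counts), window = grid$window) |>
    dplyr::mutate(
      window_start = grid$start[.data$window],
      window_end = grid$end[.data$window],
      count = as.integer(t(counts))[seq_len(dplyr::n())]
    )
}

depth_matrix <- function(depth) {
  wide <- tidyr::pivot_wider(
    depth[c("animal_id", "window", "count")],
    names_from = "window", values_from = "count"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$animal_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' Mask windows overlapping gap or repeat annotation
#'
#' A window is masked iff it overlaps any gap or repeat interval by at least
#' one bp. Masked windows are excluded from every downstream statistic and
#' break run continuity in the callers.
#'
#' @param grid Window grid from [window_grid()].
#' @param gaps,repeats Tibbles of half-open intervals with `start`, `end`
#'   columns (same coordinate system as the grid); `NULL` for none.
#' @return The grid with its `masked` column updated.
#' @export
mask_windows <- function(grid, gaps = NULL, repeats = NULL) {
  iv <- dplyr::bind_rows(gaps, repeats)
  if (is.null(iv) || nrow(iv) == 0L) return(grid)
  masked <- vapply(seq_len(nrow(grid)), function(j) {
    any(iv$start < grid$end[j] & iv$end > grid$start[j])
  }, logical(1))
  grid$masked <- grid$masked | masked
  grid
}

#' Per-animal depth summaries and fold depth
#'
#' Computes each animal's mean and standard deviation of counts over unmasked
#' windows, and each window's fold depth (count divided by the animal's own
#' mean), the normalisation used by the deletion/alternate caller.
#'
#' @param depth Long depth tibble from [count_windows()] or
#'   [sim_depth_panel()].
#' @param grid Window grid (for the mask).
#' @return List with `animal` (tibble: `animal_id`, `mean`, `sd`, computed on
#'   unmasked windows) and `fold` (depth tibble with a `fold` column; masked
#'   windows get `NA`).
#' @export
depth_summary <- function(depth, grid) {
  unmasked <- grid$window[!grid$masked]
  abort_if(length(unmasked) == 0L, "depth_summary(): all windows masked")
  animal <- depth |>
    dplyr::filter(.data$window %in% unmasked) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                     .groups = "drop")
  fold <- depth |>
    dplyr::left_join(animal, by = "animal_id") |>
    dplyr::mutate(
      fold = dplyr::if_else(.data$window %in% unmasked & .data$mean > 0,
                            .data$count / .data$mean, NA_real_)
    ) |>
    dplyr::select(-"mean", -"sd")
  list(animal = animal, fold = fold)
}
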