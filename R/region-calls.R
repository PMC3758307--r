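# Run-rule machinery shared by both callers.
#
# Given a logical "qualifying" flag per unmasked window (in genomic order),
# mark every frame of `frame` consecutive unmasked windows containing at least
# `min_run` qualifying windows; a window enters a call iff it qualifies and
# lies inside a marked frame; overlapping marked spans merge. Masked windows
# break continuity: frames are taken over consecutive unmasked windows only.
run_rule_spans <- function(qualifies, min_run = 5L, frame = 7L) {
  n <- length(qualifies)
  if (n < frame) return(integer(0))
  in_frame <- logical(n)
  run_sums <- vapply(seq_len(n - frame + 1L), function(i) {
    sum(qualifies[i:(i + frame - 1L)])
  }, numeric(1))
  for (i in which(run_sums >= min_run)) {
    in_frame[i:(i + frame - 1L)] <- TRUE
  }
  which(qualifies & in_frame)
}

# Merge a sorted vector of grid window indices into contiguous-overlap region
# rows; windows whose intervals touch or overlap coalesce.
merge_window_calls <- function(win_idx, grid) {
  if (length(win_idx) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_windows = integer(), windows = list()))
  }
  win_idx <- sort(unique(win_idx))
  iv <- grid[match(win_idx, grid$window), ]
  grp <- cumsum(c(1L, as.integer(iv$start[-1] > cummax(iv$end[-nrow(iv)]))))
  iv |>
    dplyr::mutate(grp = grp, window = win_idx) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(),
                     windows = list(.data$window), .groups = "drop") |>
    dplyr::select(-"grp")
}

#' Call duplications from a depth panel
#'
#' Per-animal scan for runs of elevated read depth: within every frame of
#' `frame` consecutive unmasked windows, if at least `min_run` windows have a
#' count above the animal's own mean plus `sd_mult` standard deviations (mean
#' and SD over that animal's unmasked windows), the qualifying windows in all
#' triggering frames are merged into duplication calls.
#'
#' @param depth Long depth tibble ([count_windows()] / [sim_depth_panel()]).
#' @param grid Window grid carrying the mask.
#' @param sd_mult Threshold multiplier: elevated means count > mean +
#'   `sd_mult` * SD (default 2).
#' @param min_run,frame Run rule: `min_run` qualifying windows out of `frame`
#'   consecutive unmasked windows (defaults 5 of 7).
#' @return Tibble of calls: `class` (`"duplication"`), `animal_id`, `start`,
#'   `end`, `n_windows`, `windows` (list column of grid indices), sorted by
#'   animal then start. Animals with zero mean depth are skipped with a
#'   warning.
#' @export
call_duplications <- function(depth, grid, sd_mult = 2, min_run = 5L,
                              frame = 7L) {
  unmasked <- grid$window[!grid$masked]
  abort_if(length(unmasked) < frame,
           sprintf("call_duplications(): need >= %d unmasked windows", frame))
  sm <- depth_summary(depth, grid)
  m <- depth_matrix(dplyr::filter(depth, .data$window %in% unmasked))

  calls <- purrr::map_dfr(rownames(m), function(aid) {
    st <- sm$animal[sm$animal$animal_id == aid, ]
    if (st$mean <= 0) {
      warning("call_duplications(): animal '", aid,
              "' has zero mean depth; skipped", call. = FALSE)
      return(NULL)
    }
    thr <- st$mean + sd_mult * st$sd
    hits <- run_rule_spans(m[aid, ] > thr, min_run = min_run, frame = frame)
    regions <- merge_window_calls(unmasked[hits], grid)
    if (nrow(regions) == 0L) return(NULL)
    dplyr::mutate(regions, class = "duplication", animal_id = aid,
                  .before = 1L)
  })
  if (nrow(calls) == 0L) {
    return(tibble::tibble(class = character(), animal_id = character(),
                          start = integer(), end = integer(),
                          n_windows = integer(), windows = list()))
  }
  dplyr::arrange(calls, .data$animal_id, .data$start)
}

#' Call deletion or alternate (divergent) regions from a depth panel
#'
#' Population-level scan for regions where most animals retain normal depth
#' while at least one drops to near zero, the signature of a deleted or a
#' highly divergent non-mapping haplotype. A window is polymorphic-low iff
#' more than `min_high_animals - 1` animals have fold depth above `high_fold`
#' and at least `min_low_animals` animals fall below `low_fold` (fold depth =
#' count / the animal's own unmasked mean). The 5-of-7 run rule then defines
#' regions, and the high- and low-depth animal sets are recorded per region
#' (an animal is listed iff it meets the criterion in every defining window).
#'
#' @inheritParams call_duplications
#' @param high_fold Fold depth above which an animal counts as "normal"
#'   (default 0.5).
#' @param low_fold Fold depth below which an animal counts as "low" (default
#'   0.1).
#' @param min_high_animals Minimum animals above `high_fold` per window
#'   (default 5, the literal reading of "more than 4 animals").
#' @param min_low_animals Minimum animals below `low_fold` per window
#'   (default 1, "some other animals").
#' @return Tibble of calls: `class` (`"deletion_or_alternate"`), `start`,
#'   `end`, `n_windows`, `windows`, `high_animals`, `low_animals` (list
#'   columns), sorted by start.
#' @export
call_deletion_or_alternate <- function(depth, grid, high_fold = 0.5,
                                       low_fold = 0.1, min_high_animals = 5L,
                                       min_low_animals = 1L, min_run = 5L,
                                       frame = 7L) {
  n_animals <- dplyr::n_distinct(depth$animal_id)
  abort_if(n_animals < min_high_animals + min_low_animals,
           sprintf(paste0("call_deletion_or_alternate(): rule needs >= %d ",
                          "animals, got %d"),
                   min_high_animals + min_low_animals, n_animals))
  unmasked <- grid$window[!grid$masked]
  abort_if(length(unmasked) < frame,
           sprintf("call_deletion_or_alternate(): need >= %d unmasked windows",
                   frame))
  sm <- depth_summary(depth, grid)
  fold <- sm$fold |>
    dplyr::filter(.data$window %in% unmasked) |>
    dplyr::select("animal_id", "window", count = "fold")
  fm <- depth_matrix(fold)

  n_high <- colSums(fm > high_fold, na.rm = TRUE)
  n_low <- colSums(fm < low_fold, na.rm = TRUE)
  poly_low <- n_high >= min_high_animals & n_low >= min_low_animals

  hits <- run_rule_spans(poly_low, min_run = min_run, frame = frame)
  regions <- merge_window_calls(unmasked[hits], grid)
  if (nrow(regions) == 0L) {
    return(tibble::tibble(class = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          windows = list(), high_animals = list(),
                          low_animals = list()))
  }
  regions |>
    dplyr::mutate(
      class = "deletion_or_alternate", .before = 1L
    ) |>
    dplyr::mutate(
      # an animal joins a set when it meets the criterion in a majority of
      # the region's defining windows (robust to edge windows straddling the
      # region boundary)
      high_animals = purrr::map(.data$windows, function(w) {
        cols <- match(w, unmasked)
        rownames(fm)[rowMeans(fm[, cols, drop = FALSE] > high_fold) > 0.5]
      }),
      low_animals = purrr::map(.data$windows, function(w) {
        cols <- match(w, unmasked)
        rownames(fm)[rowMeans(fm[, cols, drop = FALSE] < low_fold) > 0.5]
      })
    ) |>
    dplyr::arrange(.data$start)
}

#' Region length in bp
#'
#' @param calls Region-call tibble (or any tibble with `start`, `end`).
#' @return The input with a `length_bp = end - start` column.
#' @export
region_length <- function(calls) {
  dplyr::mutate(calls, length_bp = .data$end - .data$start)
}
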