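#' Read genotypes from PLINK text .ped/.map files
#'
#' Parses the whitespace-delimited PLINK text dialect: the .map gives one
#' marker per line (`chrom`, `marker`, cM, 1-based `bp`), the .ped one animal
#' per line (six leading pedigree columns, then two allele columns per
#' marker; `0` is the missing allele code). Calls are returned as copies of
#' allele A, where allele A is the first non-missing allele observed for each
#' marker in the file (alphabetical tie-break when both appear on first use).
#'
#' @param ped,map Paths to the .ped and .map files.
#' @return List with `calls` (tibble: `animal_id` + one 0/1/2/`NA` column per
#'   marker) and `map` (tibble: `marker`, `chrom`, `bp`, `allele_a`,
#'   `allele_b`).
#' @export
read_ped_map <- function(ped, map) {
  abort_if(!file.exists(ped) || !file.exists(map),
           "read_ped_map(): file not found")
  map_tbl <- utils::read.table(map, header = FALSE,
                               colClasses = "character")
  abort_if(ncol(map_tbl) < 4, "read_ped_map(): .map needs 4 columns")
  names(map_tbl)[1:4] <- c("chrom", "marker", "cm", "bp")
  n_markers <- nrow(map_tbl)

  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  abort_if(length(lines) == 0L, "read_ped_map(): empty .ped")
  fields <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(fields)
  abort_if(length(unique(widths)) != 1L,
           sprintf("read_ped_map(): ragged .ped rows (widths %s)",
                   paste(unique(widths), collapse = ", ")))
  n_geno_cols <- widths[1] - 6L
  abort_if(n_geno_cols != 2L * n_markers, sprintf(
    "read_ped_map(): .ped has %d genotype columns but .map lists %d markers (expected %d columns)",
    n_geno_cols, n_markers, 2L * n_markers))

  valid <- c("A", "C", "G", "T", "0", "1", "2", "B")
  alle <- t(vapply(fields, function(f) f[-(1:6)], character(n_geno_cols)))
  bad <- which(matrix(!(alle %in% valid), nrow = nrow(alle)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("read_ped_map(): invalid allele code '%s' at .ped line %d",
                 alle[bad[1, 1], bad[1, 2]], bad[1, 1]), call. = FALSE)
  }

  ids <- vapply(fields, function(f) f[2], character(1))
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = n_markers)
  allele_a <- allele_b <- character(n_markers)
  for (j in seq_len(n_markers)) {
    a1 <- alle[, 2L * j - 1L]
    a2 <- alle[, 2L * j]
    obs <- setdiff(sort(unique(c(a1, a2))), "0")
    allele_a[j] <- if (length(obs) >= 1L) obs[1] else NA_character_
    allele_b[j] <- if (length(obs) >= 2L) obs[2] else NA_character_
    miss <- a1 == "0" | a2 == "0"
    calls[, j] <- ifelse(miss, NA_integer_,
                         (a1 == allele_a[j]) + (a2 == allele_a[j]))
  }
  colnames(calls) <- map_tbl$marker
  calls_tbl <- tibble::as_tibble(as.data.frame(calls))
  calls_tbl <- dplyr::mutate(calls_tbl, animal_id = ids, .before = 1L)
  list(
    calls = calls_tbl,
    map = tibble::tibble(marker = map_tbl$marker, chrom = map_tbl$chrom,
                         bp = as.integer(map_tbl$bp), allele_a = allele_a,
                         allele_b = allele_b)
  )
}

#' Write genotypes to PLINK text .ped/.map files
#'
#' Inverse of [read_ped_map()]: calls counting copies of allele A become
#' allele pairs (`NA` becomes `0 0`), positions stay 1-based in the .map.
#'
#' @param geno Genotype tibble (`animal_id` + call columns).
#' @param map Marker map tibble (`marker`, `chrom`, `bp`, `allele_a`,
#'   `allele_b`).
#' @param ped,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(geno, map, ped, map_path) {
  mk <- geno_cols(geno)
  abort_if(!identical(sort(mk), sort(map$marker)),
           "write_ped_map(): geno markers and map markers differ")
  map <- map[match(mk, map$marker), ]
  readr::write_tsv(
    tibble::tibble(chrom = map$chrom, marker = map$marker, cm = 0,
                   bp = map$bp),
    map_path, col_names = FALSE)
  pairs <- vapply(seq_along(mk), function(j) {
    calls <- geno[[mk[j]]]
    a <- map$allele_a[j]
    b <- map$allele_b[j]
    if (is.na(a)) a <- "A"
    if (is.na(b)) b <- "G"
    out <- dplyr::case_when(
      is.na(calls) ~ "0 0",
      calls == 2L ~ paste(a, a),
      calls == 1L ~ paste(a, b),
      TRUE ~ paste(b, b)
    )
    out
  }, character(nrow(geno)))
  if (is.null(dim(pairs))) pairs <- matrix(pairs, nrow = nrow(geno))
  lines <- paste(geno$animal_id, geno$animal_id, 0, 0, 0, -9,
                 apply(pairs, 1, paste, collapse = " "))
  writeLines(lines, ped)
  invisible(c(ped = ped, map = map_path))
}

#' Write region calls as BED6 plus a supporting-animal sidecar
#'
#' Emits calls in BED6 (0-based half-open: `chrom`, `start`, `end`,
#' `name` = class, `score` = number of supporting windows, `strand` = "."),
#' sorted by (chrom, start) with a header comment, and a TSV sidecar listing
#' supporting animals per region when animal sets are present.
#'
#' @param calls Region-call tibble from [call_duplications()] or
#'   [call_deletion_or_alternate()].
#' @param path Output BED path; the sidecar gets `.animals.tsv` appended.
#' @param chrom Chromosome label for the segment (default `"seg"`).
#' @return Invisibly, the BED path.
#' @export
write_bed_regions <- function(calls, path, chrom = "seg") {
  con <- file(path, "w")
  writeLines("# BED6: chrom start end name score strand", con)
  if (nrow(calls)) {
    ord <- order(calls$start, calls$end)
    calls <- calls[ord, ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", chrom, calls$start,
                       calls$end, calls$class, calls$n_windows), con)
  }
  close(con)
  sidecar <- paste0(path, ".animals.tsv")
  animals <- if ("animal_id" %in% names(calls)) {
    calls$animal_id
  } else if ("low_animals" %in% names(calls)) {
    purrr::map_chr(calls$low_animals, paste, collapse = ",")
  } else NULL
  if (!is.null(animals) && nrow(calls)) {
    readr::write_tsv(tibble::tibble(start = calls$start, end = calls$end,
                                    class = calls$class,
                                    supporting_animals = animals), sidecar)
  }
  invisible(path)
}

#' Read or write a long depth panel TSV
#'
#' Columns: `animal_id`, `window_start`, `window_end`, `count` (`window`
#' indices are reconstructed from the sorted unique starts on read).
#'
#' @param depth Long depth tibble.
#' @param path File path.
#' @return `write_depth_tsv()`: the path, invisibly; `read_depth_tsv()`: the
#'   depth tibble.
#' @export
write_depth_tsv <- function(depth, path) {
  readr::write_tsv(depth[c("animal_id", "window_start", "window_end",
                           "count")], path)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(animal_id = "c"))
  starts <- sort(unique(d$window_start))
  dplyr::mutate(d, window = match(.data$window_start, starts),
                .after = "animal_id")
}
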