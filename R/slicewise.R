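#' Label slices relative to the injury zone
#'
#' Partitions the slices of a nerve segment along its axis into proximal /
#' injury / distal regions. Indices are 0-based and the injury interval is
#' inclusive at both ends.
#'
#' @param n_slices total number of slices.
#' @param injury_start,injury_end 0-based first and last slice of the
#'   injury zone, `0 <= injury_start <= injury_end < n_slices`.
#' @return character vector of length `n_slices` with values `"proximal"`,
#'   `"injury"`, `"distal"`.
#' @examples
#' table(label_slices(16, 7, 9))  # 7 proximal, 3 injury, 6 distal
#' @export
label_slices <- function(n_slices, injury_start, injury_end) {
  if (injury_start > injury_end) {
    abort(sprintf("inverted injury interval: start %d > end %d",
                  injury_start, injury_end))
  }
  if (injury_start < 0 || injury_end >= n_slices) {
    abort("injury interval must lie within [0, n_slices - 1]")
  }
  idx <- seq_len(n_slices) - 1L
  dplyr::case_when(idx < injury_start ~ "proximal",
                   idx > injury_end ~ "distal",
                   TRUE ~ "injury")
}

#' Aggregate voxel maps to per-slice ROI means
#'
#' Reduces fitted scalar-index maps to the study's unit of analysis: one
#' record per slice holding the arithmetic mean of each index over the
#' valid (unflagged, finite) ROI voxels of that slice. Slices with no valid
#' ROI voxel are omitted with a message.
#'
#' @param maps a `dki_maps` object from [fit_volume()], or a named list of
#'   3-D arrays (must include `fa`, `md`, `ad`, `rd`, `mk`, `ak`, `rk`).
#' @param roi_mask 3-D 0/1 array of ROI voxels.
#' @param labels per-slice region labels from [label_slices()].
#' @param animal,cohort,week metadata attached to every record.
#' @return tibble of slice records: `animal`, `cohort`, `week`, `region`,
#'   `slice` (0-based), `n_voxels`, and the seven index means.
#' @export
aggregate_slices <- function(maps, roi_mask, labels,
                             animal = NA_character_, cohort = NA_character_,
                             week = NA_real_) {
  m <- if (inherits(maps, "dki_maps")) maps$maps else maps
  index_names <- c("fa", "md", "ad", "rd", "mk", "ak", "rk")
  if (!all(index_names %in% names(m))) {
    abort(sprintf("maps must include all of: %s", paste(index_names, collapse = ", ")))
  }
  dm <- dim(m$fa)
  if (!identical(dm, dim(roi_mask))) {
    abort(sprintf("map dims (%s) do not match mask dims (%s)",
                  paste(dm, collapse = "x"), paste(dim(roi_mask), collapse = "x")))
  }
  n_slices <- dm[3]
  if (length(labels) != n_slices) abort("one label per slice is required")
  rows <- vector("list", n_slices)
  for (z in seq_len(n_slices)) {
    in_roi <- roi_mask[, , z] > 0
    valid <- in_roi & is.finite(m$fa[, , z])
    nv <- sum(valid)
    if (nv == 0) {
      message(sprintf("slice %d: no valid ROI voxels, record omitted", z - 1L))
      next
    }
    means <- vapply(index_names,
                    function(nm) mean(m[[nm]][, , z][valid]), numeric(1))
    rows[[z]] <- tibble(animal = animal, cohort = cohort, week = week,
                        region = labels[z], slice = z - 1L, n_voxels = nv,
                        !!!as.list(means))
  }
  dplyr::bind_rows(rows)
}

#' Apply the slice-record outlier rules
#'
#' A slice record is deemed an outlier iff RD > 1 um^2/ms, RK < 0, or
#' RK > 2 -- strict inequalities, so records exactly on a threshold are
#' kept. The input partitions exactly into the two returned tables and the
#' excluded table carries the triggering rule(s).
#'
#' @param records tibble of slice records with numeric columns `rd`, `rk`.
#' @return list with `kept` (records passing all rules) and `excluded`
#'   (failing records with an extra `reason` column).
#' @export
filter_outliers <- function(records) {
  if (!all(c("rd", "rk") %in% names(records))) {
    abort("records must carry 'rd' and 'rk' columns for outlier filtering")
  }
  reason <- purrr::map2_chr(records$rd, records$rk, function(rd, rk) {
    r <- c(if (isTRUE(rd > 1)) "RD > 1",
           if (isTRUE(rk < 0)) "RK < 0",
           if (isTRUE(rk > 2)) "RK > 2")
    if (length(r) == 0) NA_character_ else paste(r, collapse = "; ")
  })
  out <- !is.na(reason)
  excluded <- dplyr::mutate(records[out, , drop = FALSE], reason = reason[out])
  if (nrow(excluded) > 0) {
    message(sprintf("filter_outliers: excluded %d of %d records", nrow(excluded), nrow(records)))
  }
  list(kept = records[!out, , drop = FALSE], excluded = excluded)
}
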