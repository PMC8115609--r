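#' Default sampling-time bin scheme
#'
#' Discretizes continuous sampling days into the scheme used throughout the
#' meta-analysis: mothers into pregnancy (gestational days 189-224), delivery
#' (postnatal days 0-7 of infant age) and postpartum (8-480); infants into
#' birth (0-1 days), 1 wk. (2-7), 1 mo. (8-30), 3 mo. (31-90), 6 mo.
#' (91-180) and 12 mo. (181-480). Ranges are closed integer day ranges; the
#' `scale` column disambiguates gestational from postnatal days.
#'
#' @return data.frame with columns `role`, `bin`, `scale`, `day_min`,
#'   `day_max`.
#' @export
default_time_bins <- function() {
  rbind(
    data.frame(role = "mother",
               bin = c("pregnancy", "delivery", "postpartum"),
               scale = c("gestational", "postnatal", "postnatal"),
               day_min = c(189, 0, 8), day_max = c(224, 7, 480),
               stringsAsFactors = FALSE),
    data.frame(role = "infant",
               bin = c("birth", "1 wk.", "1 mo.", "3 mo.", "6 mo.", "12 mo."),
               scale = "postnatal",
               day_min = c(0, 2, 8, 31, 91, 181),
               day_max = c(1, 7, 30, 90, 180, 480),
               stringsAsFactors = FALSE)
  )
}

#' Assign sampling-time bins to samples
#'
#' Each sample whose (role, day scale, day) falls inside a bin range gets the
#' bin label in a new/overwritten `time_bin` column; samples outside every
#' range get `"unbinned"` and should be excluded from bin-stratified
#' analyses.
#'
#' @param metadata sample metadata (see [read_sample_metadata()]).
#' @param scheme bin scheme as from [default_time_bins()].
#' @return `metadata` with a `time_bin` column.
#' @export
assign_time_bins <- function(metadata, scheme = default_time_bins()) {
  metadata <- validate_metadata(metadata)
  # partition check: within a role, ranges on the same scale must not overlap
  for (r in unique(scheme$role)) for (sc in unique(scheme$scale)) {
    s <- scheme[scheme$role == r & scheme$scale == sc, , drop = FALSE]
    if (nrow(s) > 1L) {
      s <- s[order(s$day_min), ]
      if (any(s$day_min[-1L] <= s$day_max[-nrow(s)]))
        stop("overlapping bins for role ", r)
    }
  }
  bin <- rep("unbinned", nrow(metadata))
  for (i in seq_len(nrow(scheme))) {
    hit <- metadata$role == scheme$role[i] &
      metadata$day_scale == scheme$scale[i] &
      metadata$day >= scheme$day_min[i] &
      metadata$day <= scheme$day_max[i]
    bin[hit] <- scheme$bin[i]
  }
  metadata$time_bin <- bin
  metadata
}

# Ordered infant bin labels of a scheme (for trend displays).
infant_bin_levels <- function(scheme = default_time_bins()) {
  s <- scheme[scheme$role == "infant", ]
  s$bin[order(s$day_min)]
}
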