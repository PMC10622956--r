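#' Scalp-region lookup for 10-20 electrode names
#'
#' Tags each electrode with the broad scalp region its 10-20 name implies:
#' `frontal` (Fp/AF/F/FC rows), `central` (C row), `parietal` (CP/P/PO
#' rows), `temporal` (T/FT/TP rows) or `occipital` (O row). Names that do
#' not parse as 10-20 positions are tagged `unmapped`.
#'
#' @param channels Character vector of electrode names.
#' @return Character vector of region tags, same length.
#' @export
channel_region <- function(channels) {
  prefix <- toupper(sub("^([A-Za-z]+).*$", "\\1", channels))
  prefix <- sub("Z$", "", prefix)               # Cz -> C, POz -> PO, ...
  region <- rep("unmapped", length(channels))
  region[prefix %in% c("FP", "AF", "F", "FC")] <- "frontal"
  region[prefix == "C"] <- "central"
  region[prefix %in% c("CP", "P", "PO")] <- "parietal"
  region[prefix %in% c("T", "FT", "TP")] <- "temporal"
  region[prefix == "O"] <- "occipital"
  region[!nzchar(channels)] <- "unmapped"
  region
}

#' Textual scalp-position report for a channel subset
#'
#' A text substitute for a scalp topography: one row per selected
#' electrode with its 10-20 label and scalp-region tag, so a selection can
#' be read against the montage (e.g. whether a subject's subset clusters
#' near the central sulcus or drifts parietal/frontal).
#'
#' @param subset A [select_subset()] result, `channel_ranking`, or
#'   character vector of electrode names.
#' @param montage Known electrode names; anything outside it is reported
#'   under region `unmapped`.
#' @return A tibble with columns `channel`, `position` and `region`.
#' @export
subset_report <- function(subset, montage = mi_montage_22) {
  chans <- if (is.character(subset)) subset else subset$channel
  known <- chans %in% montage
  region <- channel_region(chans)
  region[!known] <- "unmapped"
  tibble::tibble(channel = chans,
                 position = ifelse(known, chans, NA_character_),
                 region = region)
}
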