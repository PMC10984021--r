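#' Campaign manifest totals
#'
#' Sums plate and readout counts across the assay stages of a campaign
#' manifest (e.g. BCA, MTDR, CS/CI/CII colorimetry, CIV colorimetry,
#' respirometry, qPCR).
#'
#' @param manifest A `data.frame` with columns `assay`, `plates`,
#'   `readouts`.
#' @return A list: `total_plates`, `total_readouts`.
#' @export
manifest_totals <- function(manifest) {
  if (!nrow(manifest)) return(list(total_plates = 0, total_readouts = 0))
  if (any(manifest$plates < 0) || any(manifest$readouts < 0))
    stopf("negative manifest entries")
  list(total_plates = sum(manifest$plates),
       total_readouts = sum(manifest$readouts))
}

#' Default campaign manifest
#'
#' Plate and readout counts of the full phenotyping campaign, per assay
#' stage.
#' @return A `data.frame` with columns `assay`, `plates`, `readouts`.
#' @export
default_campaign_manifest <- function() {
  data.frame(
    assay = c("BCA", "MTDR", "colorimetry_CS_CI_CII", "colorimetry_CIV",
              "respirometry", "qPCR"),
    plates = c(8, 8, 48, 32, 44, 24),
    readouts = c(768, 768, 13608, 3024, 7384, 2268),
    stringsAsFactors = FALSE
  )
}

#' Colorimetric plate-count bookkeeping
#'
#' `sample_plates * assays * (replicate_plates + negcontrol_plates)`;
#' the negative-control term may be fractional when nonspecific plates are
#' shared across assays (8 x 4 x (3 + 2.5) = 176 analyzed plates).
#'
#' @param sample_plates Base sample plates per assay batch.
#' @param assays Number of colorimetric assays.
#' @param replicate_plates Replicate plates per sample plate.
#' @param negcontrol_plates Negative-control plates per sample plate (may be
#'   fractional).
#' @return Total plate count.
#' @export
colorimetric_plate_count <- function(sample_plates, assays, replicate_plates,
                                     negcontrol_plates) {
  args <- c(sample_plates, assays, replicate_plates, negcontrol_plates)
  if (any(args < 0)) stopf("negative plate-count inputs")
  sample_plates * assays * (replicate_plates + negcontrol_plates)
}
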