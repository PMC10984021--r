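#' Well names of a 96-well plate in row-major order
#'
#' A1..A12, B1..B12, ..., H1..H12.
#' @return Character vector of length 96.
#' @export
well_names_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Randomize voxels to 96-well assay plates
#'
#' Assigns every voxel to exactly one sample well across `n_plates` plates
#' using a seeded permutation (samples are blinded to their grid origin until
#' deconvolution). Sample wells fill the plate in row-major order; the last
#' six wells of every plate hold duplicate wells of the three pooled loading
#' controls (GM, WM, mixed). Unused sample wells are recorded as `blank`.
#'
#' @param voxel_ids Character vector of unique voxel ids.
#' @param n_plates Number of plates (default 8, the campaign batch count).
#' @param samples_per_plate Sample wells per plate (default 90; the remaining
#'   6 wells hold the controls).
#' @param seed Integer seed for the permutation.
#' @return A `data.frame` with columns `plate_id`, `well`, `content`
#'   (`sample`, `control_GM`, `control_WM`, `control_mixed`, `blank`) and
#'   `voxel_id` (`NA` except for samples).
#' @export
randomize_to_plates <- function(voxel_ids, n_plates = 8L,
                                samples_per_plate = 90L, seed = 1L) {
  voxel_ids <- as.character(voxel_ids)
  if (anyDuplicated(voxel_ids)) stopf("voxel ids must be unique")
  if (samples_per_plate < 1 || samples_per_plate > 90)
    stopf("samples_per_plate must be in [1, 90]")
  capacity <- n_plates * samples_per_plate
  if (length(voxel_ids) > capacity)
    stopf("capacity shortfall: %d voxels > %d sample wells",
          length(voxel_ids), capacity)

  set.seed(derive_seed(seed, 404L))
  shuffled <- sample(voxel_ids)
  wells <- well_names_96()
  sample_wells <- wells[seq_len(samples_per_plate)]
  control_wells <- wells[91:96]
  control_content <- rep(c("control_GM", "control_WM", "control_mixed"),
                         each = 2)

  per_plate <- lapply(seq_len(n_plates), function(p) {
    lo <- (p - 1L) * samples_per_plate + 1L
    hi <- min(p * samples_per_plate, length(shuffled))
    ids <- if (lo <= hi) shuffled[lo:hi] else character(0)
    n_s <- length(ids)
    data.frame(
      plate_id = sprintf("P%02d", p),
      well = c(sample_wells, control_wells),
      content = c(rep("sample", n_s),
                  rep("blank", samples_per_plate - n_s),
                  control_content),
      voxel_id = c(ids, rep(NA_character_, samples_per_plate - n_s),
                   rep(NA_character_, 6L)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_plate)
  rownames(out) <- NULL
  out
}

#' Map well-level results back to voxels (derandomization)
#'
#' Joins measured well results to the plate assignment and returns them keyed
#' by voxel id. The round trip randomize -> measure -> deconvolve is the
#' identity on voxel ids.
#'
#' @param assignments Output of [randomize_to_plates()].
#' @param well_results A `data.frame` with columns `plate_id`, `well`, plus
#'   any measurement columns.
#' @return `well_results` with a `voxel_id` column, sample wells only.
#' @export
deconvolve <- function(assignments, well_results) {
  stopifnot(all(c("plate_id", "well") %in% names(well_results)))
  key_a <- paste(assignments$plate_id, assignments$well)
  key_r <- paste(well_results$plate_id, well_results$well)
  hit <- match(key_r, key_a)
  if (anyNA(hit)) {
    miss <- unique(key_r[is.na(hit)])
    stopf("results for unassigned wells: %s",
          paste(head(miss, 3), collapse = ", "))
  }
  out <- well_results
  out$voxel_id <- assignments$voxel_id[hit]
  out$content <- assignments$content[hit]
  sample_rows <- out$content == "sample"
  if (anyDuplicated(key_r[sample_rows]))
    stopf("duplicate voxel mapping: repeated sample wells in results")
  out <- out[sample_rows, setdiff(names(out), "content"), drop = FALSE]
  rownames(out) <- NULL
  out
}
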