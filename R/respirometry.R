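#' Complex-specific OCR from injection-phase plateaus
#'
#' CI OCR = post-NADH minus post-antimycin A; CII OCR = post-succinate/
#' rotenone minus post-antimycin A; CIV OCR = post-TMPD/ascorbate minus
#' post-azide. Only the phases present on the well's plate type are required
#' (NADH plates carry CI + CIV, succinate/rotenone plates CII + CIV).
#'
#' @param phases A list or one-row `data.frame` with any of `post_nadh`,
#'   `post_succrot`, `post_antimycin`, `post_tmpd`, `post_azide`
#'   (pmol O2/min).
#' @return Named list with the computable of `ci`, `cii`, `civ`.
#' @export
complex_ocr <- function(phases) {
  get <- function(nm) if (!is.null(phases[[nm]]) && is.finite(phases[[nm]]))
    phases[[nm]] else NA_real_
  out <- list()
  if (is.finite(get("post_nadh"))) {
    if (!is.finite(get("post_antimycin"))) stopf("missing post-antimycin phase")
    out$ci <- get("post_nadh") - get("post_antimycin")
  }
  if (is.finite(get("post_succrot"))) {
    if (!is.finite(get("post_antimycin"))) stopf("missing post-antimycin phase")
    out$cii <- get("post_succrot") - get("post_antimycin")
  }
  if (is.finite(get("post_tmpd"))) {
    if (!is.finite(get("post_azide"))) stopf("missing post-azide phase")
    out$civ <- get("post_tmpd") - get("post_azide")
  }
  if (!length(out)) stopf("no substrate phase present")
  out
}

#' Normalize an OCR to protein content
#'
#' @param ocr OCR in pmol/min.
#' @param protein_ug Protein per well in ug (> 0).
#' @return OCR in pmol/min/ug.
#' @export
normalize_protein <- function(ocr, protein_ug) {
  if (any(protein_ug <= 0)) stopf("protein must be positive")
  ocr / protein_ug
}

#' Respirometry acceptance criteria
#'
#' Minimal protein-normalized OCR thresholds are 0.5 pmol/min/ug for
#' complexes I and II and 1.5 pmol/min/ug for complex IV; in addition each
#' CIV value must exceed 80% of the CI (or CII) OCR measured on the same
#' plate type. A sample passes when one CI value, one CII value and both CIV
#' values pass. Failing samples at 15 uL loading are flagged for a 25 uL
#' rerun; failure after rerun excludes the sample.
#'
#' @param ci,cii Normalized OCRs (pmol/min/ug).
#' @param civ_pair Length-2 vector: CIV from the CI-type and CII-type plates.
#' @param thresholds Named vector `c(ci, cii, civ)` of minimal OCRs.
#' @param civ_relative CIV must exceed this fraction of its companion complex
#'   (default 0.8).
#' @param compare_to `"respective"` compares each CIV value to the companion
#'   complex of its own plate; `"max"` compares both to the larger of CI/CII.
#' @return A list of logical flags `ci_pass`, `cii_pass`, `civ_pass`
#'   (length 2), overall `pass`, and `rerun` (TRUE when the sample should be
#'   re-assayed at 25 uL).
#' @export
respirometry_acceptance <- function(ci, cii, civ_pair,
                                    thresholds = c(ci = 0.5, cii = 0.5,
                                                   civ = 1.5),
                                    civ_relative = 0.8,
                                    compare_to = c("respective", "max")) {
  compare_to <- match.arg(compare_to)
  stopifnot(length(civ_pair) == 2L)
  ci_pass <- is.finite(ci) && ci >= thresholds[["ci"]]
  cii_pass <- is.finite(cii) && cii >= thresholds[["cii"]]
  companion <- switch(compare_to,
                      respective = c(ci, cii),
                      max = rep(max(ci, cii, na.rm = TRUE), 2))
  civ_pass <- vapply(seq_len(2L), function(i) {
    v <- civ_pair[i]
    is.finite(v) && v >= thresholds[["civ"]] &&
      (!is.finite(companion[i]) || v > civ_relative * companion[i])
  }, logical(1))
  pass <- ci_pass && cii_pass && all(civ_pass)
  list(ci_pass = ci_pass, cii_pass = cii_pass, civ_pass = civ_pass,
       pass = pass, rerun = !pass)
}

#' Process respirometry phase tables into accepted per-voxel OCR activities
#'
#' Applies [complex_ocr()] and [normalize_protein()] per well, batch-corrects
#' each plate with its loading-control wells, evaluates the acceptance
#' criteria at 15 uL, substitutes the 25 uL rerun measurement for failing
#' samples, and averages accepted values.
#'
#' @param phases Long table from [generate_assay_data()]: `plate_id`,
#'   `base_plate`, `well`, `plate_type` (`"CI"`/`"CII"`), `load_volume`,
#'   `protein_ug`, phase columns.
#' @param assignments Plate assignments from [randomize_to_plates()].
#' @param normalization_direction Passed to [apply_normalization()].
#' @param ... Passed to [respirometry_acceptance()].
#' @return A `data.frame`: `voxel_id`, `ci`, `cii`, `civ` (accepted,
#'   protein-normalized, batch-corrected OCRs; `NA` when excluded), `pass`,
#'   `rerun_used`, `qc`.
#' @export
process_respirometry <- function(phases, assignments,
                                 normalization_direction = c("divide",
                                                             "multiply"),
                                 ...) {
  normalization_direction <- match.arg(normalization_direction)
  ph <- phases
  # per-well complex OCRs, protein-normalized
  ph$ci <- ifelse(is.finite(ph$post_nadh),
                  (ph$post_nadh - ph$post_antimycin) / ph$protein_ug, NA_real_)
  ph$cii <- ifelse(is.finite(ph$post_succrot),
                   (ph$post_succrot - ph$post_antimycin) / ph$protein_ug,
                   NA_real_)
  ph$civ <- (ph$post_tmpd - ph$post_azide) / ph$protein_ug

  # batch correction per plate and complex, from this plate's control wells
  content <- assignments$content[match(paste(ph$base_plate, ph$well),
                                       paste(assignments$plate_id,
                                             assignments$well))]
  ph$content <- content
  for (col in c("ci", "cii", "civ")) {
    sub <- ph[is.finite(ph[[col]]), ]
    if (!nrow(sub)) next
    long <- data.frame(plate_id = sub$plate_id, content = sub$content,
                       value = sub[[col]], stringsAsFactors = FALSE)
    corrected <- normalize_plates(long, normalization_direction)
    ph[[col]][is.finite(ph[[col]])] <- corrected$value
  }

  samp <- ph[ph$content == "sample", ]
  per_vox <- split(samp, assignments$voxel_id[match(
    paste(samp$base_plate, samp$well),
    paste(assignments$plate_id, assignments$well))])

  res <- lapply(per_vox, function(v) {
    eval_at <- function(volume) {
      vv <- v[v$load_volume == volume, ]
      ci <- mean(vv$ci[vv$plate_type == "CI"], na.rm = TRUE)
      cii <- mean(vv$cii[vv$plate_type == "CII"], na.rm = TRUE)
      civ_pair <- c(mean(vv$civ[vv$plate_type == "CI"], na.rm = TRUE),
                    mean(vv$civ[vv$plate_type == "CII"], na.rm = TRUE))
      acc <- respirometry_acceptance(ci, cii, civ_pair, ...)
      list(ci = ci, cii = cii, civ = mean(civ_pair), acc = acc)
    }
    first <- eval_at(15)
    rerun_used <- FALSE
    final <- first
    if (!first$acc$pass && any(v$load_volume == 25)) {
      final <- eval_at(25)
      rerun_used <- TRUE
    }
    pass <- final$acc$pass
    data.frame(voxel_id = NA_character_,
               ci = if (pass) final$ci else NA_real_,
               cii = if (pass) final$cii else NA_real_,
               civ = if (pass) final$civ else NA_real_,
               pass = pass, rerun_used = rerun_used,
               qc = if (pass) "ok" else "excluded",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$voxel_id <- names(per_vox)
  rownames(out) <- NULL
  out
}
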