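#' Summarize a qPCR triplicate
#'
#' Mean, SD and CV over the (nominally three) Ct replicates, with the
#' exclusion cutoff applied to the mean: samples with mean Ct above 33 carry
#' too little template for reliable quantification and are excluded.
#'
#' @param cts Numeric vector of Ct values (NAs tolerated, >= 1 finite).
#' @param cutoff Exclusion cutoff on the mean Ct (default 33).
#' @return A list: `mean`, `sd`, `cv`, `excluded`, `qc`.
#' @export
triplicate_ct <- function(cts, cutoff = 33) {
  finite <- cts[is.finite(cts)]
  if (!length(finite)) stopf("all-missing Ct triplicate")
  m <- mean(finite)
  s <- if (length(finite) > 1L) sd(finite) else NA_real_
  qc <- if (length(finite) < 3L) "incomplete_triplicate" else "ok"
  list(mean = m, sd = s, cv = if (is.na(s)) NA_real_ else s / m,
       excluded = m > cutoff, qc = qc)
}

#' mtDNA copy number per diploid nucleus
#'
#' `delta_ct = Ct(nDNA) - Ct(mtDNA)`; each cycle is one doubling, and the
#' nuclear amplicon is present at two copies per diploid genome, so
#' `mtDNAcn = 2^delta_ct * 2`.
#'
#' @param ct_nd1_mean Mean mtDNA (ND1) Ct.
#' @param ct_b2m_mean Mean nDNA (B2M) Ct.
#' @return Copies per diploid nucleus (`NA` if either input is `NA`).
#' @export
mtdnacn <- function(ct_nd1_mean, ct_b2m_mean) {
  ifelse(is.na(ct_nd1_mean) | is.na(ct_b2m_mean), NA_real_,
         2^(ct_b2m_mean - ct_nd1_mean) * 2)
}

#' Linearize a Ct value into relative DNA density
#'
#' Template amount halves for every extra cycle, so relative abundance per
#' tissue unit is `1e12 * 2^(-Ct)` (strictly decreasing in Ct; the 1e12
#' factor scales typical Ct values to convenient magnitudes). The config
#' switch `literal = TRUE` applies the increasing form `2^Ct * 1e12`
#' instead.
#'
#' @param ct_mean Mean Ct (vectorized; `NA` propagates).
#' @param literal Use the increasing-in-Ct variant (default `FALSE`).
#' @return Relative DNA abundance per tissue unit.
#' @export
dna_density <- function(ct_mean, literal = FALSE) {
  if (literal) 2^ct_mean * 1e12 else 1e12 * 2^(-ct_mean)
}

#' Process qPCR triplicate wells into per-voxel DNA features
#'
#' Triplicate Ct values for ND1 (mtDNA) and B2M (nDNA) are summarized per
#' well ([triplicate_ct()]), plate-corrected with the loading-control wells
#' using the control-ratio scheme applied directly to Ct values (the
#' campaign's convention; a caveat, since Ct is a log-scale quantity), then
#' converted to mtDNA/nDNA densities and mtDNA copy number.
#'
#' @param qpcr Long table from [generate_assay_data()]: `plate_id`,
#'   `base_plate`, `well`, `ct_nd1_1..3`, `ct_b2m_1..3`.
#' @param assignments Plate assignments from [randomize_to_plates()].
#' @param cutoff Ct exclusion cutoff.
#' @param normalize Apply the plate Ct correction (default TRUE).
#' @param normalization_direction Passed to [apply_normalization()].
#' @return A `data.frame`: `voxel_id`, `ct_nd1`, `ct_b2m`, `mtdna_density`,
#'   `ndna_density`, `mtdnacn`, `qc`.
#' @export
process_qpcr <- function(qpcr, assignments, cutoff = 33, normalize = TRUE,
                         normalization_direction = c("divide", "multiply")) {
  normalization_direction <- match.arg(normalization_direction)
  summarize <- function(cols) {
    t(apply(as.matrix(qpcr[, cols]), 1, function(x) {
      s <- triplicate_ct(x, cutoff)
      c(mean = s$mean, excluded = as.numeric(s$excluded))
    }))
  }
  nd1 <- summarize(paste0("ct_nd1_", 1:3))
  b2m <- summarize(paste0("ct_b2m_", 1:3))
  df <- data.frame(plate_id = qpcr$plate_id, base_plate = qpcr$base_plate,
                   well = qpcr$well,
                   ct_nd1 = nd1[, "mean"], ct_b2m = b2m[, "mean"],
                   excluded = nd1[, "excluded"] > 0 | b2m[, "excluded"] > 0,
                   stringsAsFactors = FALSE)
  content <- assignments$content[match(paste(df$base_plate, df$well),
                                       paste(assignments$plate_id,
                                             assignments$well))]
  df$content <- content

  if (normalize) {
    for (col in c("ct_nd1", "ct_b2m")) {
      long <- data.frame(plate_id = df$plate_id, content = df$content,
                         value = df[[col]], stringsAsFactors = FALSE)
      corrected <- normalize_plates(long, normalization_direction)
      df[[col]] <- corrected$value
      df$plate_factor <- corrected$plate_factor
    }
  }

  samp <- df[df$content == "sample", ]
  samp$voxel_id <- assignments$voxel_id[match(
    paste(samp$base_plate, samp$well),
    paste(assignments$plate_id, assignments$well))]
  out <- data.frame(
    voxel_id = samp$voxel_id,
    ct_nd1 = ifelse(samp$excluded, NA_real_, samp$ct_nd1),
    ct_b2m = ifelse(samp$excluded, NA_real_, samp$ct_b2m),
    stringsAsFactors = FALSE
  )
  out$mtdna_density <- dna_density(out$ct_nd1)
  out$ndna_density <- dna_density(out$ct_b2m)
  out$mtdnacn <- mtdnacn(out$ct_nd1, out$ct_b2m)
  out$qc <- ifelse(samp$excluded, "ct_above_cutoff", "ok")
  if ("plate_factor" %in% names(samp)) out$plate_factor <- samp$plate_factor
  rownames(out) <- NULL
  out
}
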