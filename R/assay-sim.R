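#' Measurement-noise configuration for the synthetic assay campaign
#'
#' @param od_sd Relative SD of per-timepoint absorbance noise (fraction of
#'   the assay's typical late-window OD change).
#' @param resp_sd Relative SD of respirometry phase OCRs at 15 uL loading
#'   (the 25 uL rerun halves it).
#' @param ct_sd Absolute SD of single-replicate Ct values (cycles).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(od_sd = 0.02, resp_sd = 0.05, ct_sd = 0.1) {
  stopifnot(od_sd >= 0, resp_sd >= 0, ct_sd >= 0)
  structure(list(od_sd = od_sd, resp_sd = resp_sd, ct_sd = ct_sd),
            class = "noise_config")
}

# Raw feature value for every non-blank well of a base plate.
well_truth <- function(assignments, base, truth, voxels, feature) {
  a <- assignments[assignments$plate_id == base &
                     assignments$content != "blank", ]
  raw <- truth$raw[[feature]][match(a$voxel_id, truth$raw$voxel_id)]
  ctrl_type <- sub("^control_", "", a$content)
  is_ctrl <- a$content != "sample"
  raw[is_ctrl] <- truth$controls$raw[ctrl_type[is_ctrl], feature]
  prot <- voxels$protein[match(a$voxel_id, voxels$voxel_id)]
  prot[is_ctrl] <- truth$controls$protein[ctrl_type[is_ctrl]]
  ndna <- voxels$ndna[match(a$voxel_id, voxels$voxel_id)]
  ndna[is_ctrl] <- truth$controls$ndna[ctrl_type[is_ctrl]]
  data.frame(well = a$well, content = a$content, voxel_id = a$voxel_id,
             raw = raw, protein = prot, ndna = ndna,
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic assay campaign
#'
#' Forward model of the three measurement stages, sharing one set of
#' multiplicative log-normal plate factors (one per physical plate):
#'
#' * Colorimetry: three replicate sample plates per base plate and assay plus
#'   nonspecific plates (three for CS/CI/CII, one for CIV). Kinetic traces
#'   are linear in time with slope `plate_factor * (raw + nonspecific)` for
#'   totals and `plate_factor * nonspecific` for the negative controls; the
#'   nonspecific slope is an assay-wide constant
#'   (`nonspecific_frac * cohort mean raw`). Per-timepoint Gaussian noise.
#' * Respirometry: per base plate one NADH-type (CI + CIV) and one
#'   succinate/rotenone-type (CII + CIV) plate at 15 uL, plus 25 uL rerun
#'   plates with halved relative noise. Phase plateaus are
#'   `plate_factor * (floor + raw * protein_ug)` above inhibitor floors.
#' * qPCR: one duplex plate per base plate; triplicate Ct values follow
#'   `Ct = log2(1e12) - log2(amount * plate_factor) + noise` with ND1
#'   amounts equal to raw mtDNA truth and B2M amounts to the voxel's
#'   relative nDNA content.
#'
#' Every plate carries the duplicate GM/WM/mixed loading-control wells that
#' drive the downstream batch correction.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param voxels The voxel table the truth was generated for.
#' @param assignments Plate assignments from [randomize_to_plates()].
#' @param noise A [noise_config()].
#' @param batch_sdlog Overrides the `effect_config` batch SD when not `NULL`.
#' @param seed Integer seed.
#' @param ocr_floor Non-mitochondrial OCR floor (pmol/min) under the
#'   respirometry phases.
#' @param time_step Sampling interval of the kinetic traces (s).
#' @return A list of class `assay_campaign`: `traces`, `respirometry`,
#'   `qpcr`, `plate_factors` (named per physical plate), `ns_rates` (named
#'   per assay).
#' @export
generate_assay_data <- function(truth, voxels, assignments,
                                noise = noise_config(), batch_sdlog = NULL,
                                seed = 1L, ocr_floor = 10, time_step = 20) {
  stopifnot(inherits(truth, "synthetic_truth"))
  miss <- setdiff(assignments$voxel_id[assignments$content == "sample"],
                  truth$raw$voxel_id)
  if (length(miss)) stopf("sample wells map to unknown voxels: %s",
                          paste(head(miss, 3), collapse = ", "))
  has_controls <- tapply(grepl("^control_", assignments$content),
                         assignments$plate_id, any)
  if (!all(has_controls)) stopf("missing control wells on plate(s): %s",
                                paste(names(has_controls)[!has_controls],
                                      collapse = ", "))
  set.seed(derive_seed(seed, 505L))
  sdlog <- batch_sdlog %||% truth$config$batch_sdlog
  bases <- unique(assignments$plate_id)
  windows <- assay_windows()
  assay_feature <- c(CS = "cs", CI = "ci", CII = "cii", CIV = "civ")
  ns_rates <- vapply(names(assay_feature), function(a) {
    truth$config$nonspecific_frac * mean(truth$raw[[assay_feature[[a]]]])
  }, 0)

  plate_factors <- c()
  draw_factor <- function(id) {
    f <- if (sdlog > 0) rlnorm(1, 0, sdlog) else 1
    plate_factors[id] <<- f
    f
  }

  ## ---- colorimetry traces ----
  traces <- list()
  for (a in names(assay_feature)) {
    w <- windows[windows$assay == a, ]
    times <- seq(0, w$late_end + time_step, by = time_step)
    od0 <- if (w$direction > 0) 0.1 else 2
    typical <- ns_rates[[a]] / truth$config$nonspecific_frac  # cohort mean raw
    od_sd_abs <- noise$od_sd * typical * (w$late_end - w$late_start)
    n_ns_rep <- if (a == "CIV") 1L else 3L
    for (base in bases) {
      wt <- well_truth(assignments, base, truth, voxels, assay_feature[[a]])
      for (r in seq_len(3L)) {
        pid <- sprintf("%s-%s-r%d", a, base, r)
        pf <- draw_factor(pid)
        rate <- pf * (wt$raw + ns_rates[[a]])
        traces[[pid]] <- trace_block(pid, base, a, r, FALSE, wt$well, rate,
                                     times, od0, w$direction, od_sd_abs)
      }
      for (r in seq_len(n_ns_rep)) {
        pid <- sprintf("%s-%s-ns%d", a, base, r)
        pf <- draw_factor(pid)
        rate <- pf * rep(ns_rates[[a]], nrow(wt))
        traces[[pid]] <- trace_block(pid, base, a, r, TRUE, wt$well, rate,
                                     times, od0, w$direction, od_sd_abs)
      }
    }
  }
  traces <- do.call(rbind, traces)
  rownames(traces) <- NULL

  ## ---- respirometry phases ----
  resp <- list()
  for (base in bases) {
    wt_ci <- well_truth(assignments, base, truth, voxels, "ci")
    wt_cii <- well_truth(assignments, base, truth, voxels, "cii")
    wt_civ <- well_truth(assignments, base, truth, voxels, "civ")
    for (vol in c(15, 25)) {
      rel_sd <- if (vol == 15) noise$resp_sd else noise$resp_sd / 2
      for (type in c("CI", "CII")) {
        pid <- sprintf("RESP-%s-%s-v%d", type, base, vol)
        pf <- draw_factor(pid)
        wt <- if (type == "CI") wt_ci else wt_cii
        prot <- wt$protein * vol
        jig <- function(x) x * (1 + rnorm(length(x), 0, rel_sd))
        block <- data.frame(
          plate_id = pid, base_plate = base, well = wt$well,
          plate_type = type, load_volume = vol, protein_ug = prot,
          post_nadh = NA_real_, post_succrot = NA_real_,
          post_antimycin = jig(pf * rep(ocr_floor, nrow(wt))),
          post_tmpd = jig(pf * (ocr_floor + wt_civ$raw * prot)),
          post_azide = jig(pf * rep(ocr_floor, nrow(wt))),
          stringsAsFactors = FALSE)
        substrate <- jig(pf * (ocr_floor + wt$raw * prot))
        if (type == "CI") block$post_nadh <- substrate
        else block$post_succrot <- substrate
        resp[[pid]] <- block
      }
    }
  }
  resp <- do.call(rbind, resp)
  rownames(resp) <- NULL

  ## ---- qPCR ----
  qpcr <- list()
  for (base in bases) {
    wt <- well_truth(assignments, base, truth, voxels, "mtdna")
    pid <- sprintf("QPCR-%s", base)
    pf <- draw_factor(pid)
    ct_mt <- CT_REF - log2(wt$raw * pf)
    ct_n <- CT_REF - log2(wt$ndna * pf)
    block <- data.frame(plate_id = pid, base_plate = base, well = wt$well,
                        stringsAsFactors = FALSE)
    for (k in 1:3) {
      block[[paste0("ct_nd1_", k)]] <- ct_mt + rnorm(nrow(wt), 0, noise$ct_sd)
      block[[paste0("ct_b2m_", k)]] <- ct_n + rnorm(nrow(wt), 0, noise$ct_sd)
    }
    qpcr[[pid]] <- block
  }
  qpcr <- do.call(rbind, qpcr)
  rownames(qpcr) <- NULL

  structure(list(traces = traces, respirometry = resp, qpcr = qpcr,
                 plate_factors = plate_factors, ns_rates = ns_rates),
            class = "assay_campaign")
}

# Linear kinetic traces for one plate: one row per (well, timepoint).
trace_block <- function(pid, base, assay, replicate, is_ns, wells, rate,
                        times, od0, direction, od_sd_abs) {
  nw <- length(wells)
  nt <- length(times)
  od <- od0 + direction * outer(rate, times)
  if (od_sd_abs > 0) od <- od + rnorm(nw * nt, 0, od_sd_abs)
  data.frame(
    plate_id = pid, base_plate = base, assay = assay, replicate = replicate,
    is_nonspecific = is_ns,
    well = rep(wells, times = nt),
    time_s = rep(times, each = nw),
    od = as.vector(od),
    stringsAsFactors = FALSE
  )
}
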