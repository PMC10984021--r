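#' Default kinetic integration windows (seconds)
#'
#' Each assay has an early and a late integration window; nonspecific
#' (negative-control) traces are integrated once over the union of the two.
#' The reporter direction is the sign of the absorbance change: DTNB
#' reduction increases OD412 for CS, while CI/CII (DCIP) and CIV
#' (cytochrome c) readings decrease.
#'
#' @return A `data.frame` with one row per assay: `assay`, `early_start`,
#'   `early_end`, `late_start`, `late_end`, `ns_start`, `ns_end`,
#'   `direction` (+1 increase, -1 decrease).
#' @export
assay_windows <- function() {
  data.frame(
    assay = c("CS", "CI", "CII", "CIV"),
    early_start = c(150, 50, 100, 50),
    early_end   = c(250, 300, 400, 150),
    late_start  = c(250, 300, 400, 150),
    late_end    = c(500, 600, 700, 300),
    ns_start    = c(150, 50, 100, 50),
    ns_end      = c(500, 600, 700, 300),
    direction   = c(1, -1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Integrate the absorbance change of a kinetic trace over a window
#'
#' Returns the magnitude of the OD change between the window edges,
#' `|OD(end) - OD(start)|` in the assay's reporter direction, with linear
#' interpolation at the edges.
#'
#' @param time,od Numeric vectors (strictly increasing times).
#' @param window Length-2 numeric `c(start, end)` in seconds.
#' @param direction +1 for increasing reporters (CS), -1 for decreasing.
#' @return Non-negative OD change over the window.
#' @export
integrate_window <- function(time, od, window, direction = 1) {
  if (length(time) < 2L || length(time) != length(od))
    stopf("trace needs >= 2 (time, od) points")
  if (is.unsorted(time, strictly = TRUE)) stopf("times must be strictly increasing")
  if (window[1] >= window[2]) stopf("window start must precede end")
  if (window[1] < time[1] || window[2] > time[length(time)])
    stopf("window [%g, %g] outside trace span [%g, %g]",
          window[1], window[2], time[1], time[length(time)])
  edges <- stats::approx(time, od, xout = window)$y
  max(direction * (edges[2] - edges[1]), 0)
}

#' Select the higher of the two integration-window values
#'
#' Samples with delayed kinetics are captured by the late window and quickly
#' saturating samples by the early one; the larger value is used.
#'
#' @param value_early,value_late Finite numeric scalars (or vectors,
#'   compared elementwise).
#' @return `pmax(value_early, value_late)`.
#' @export
pick_window <- function(value_early, value_late) {
  if (any(!is.finite(value_early)) || any(!is.finite(value_late)))
    stopf("window values must be finite")
  pmax(value_early, value_late)
}

#' Keep the two closest of three replicate values
#'
#' Of the three replicate measurements, the pair with the smallest absolute
#' difference is kept and the least similar value discarded; ties keep the
#' lowest-index pair. Fewer than three finite values pass through with a QC
#' flag.
#'
#' @param values Numeric vector of (nominally) 3 replicate values.
#' @return A list: `pair` (indices kept), `mean`, `qc` (`"ok"` or
#'   `"incomplete_triplicate"`).
#' @export
select_two_closest <- function(values) {
  finite <- which(is.finite(values))
  if (length(finite) < 3L) {
    if (!length(finite)) stopf("no finite replicate values")
    return(list(pair = finite, mean = mean(values[finite]),
                qc = "incomplete_triplicate"))
  }
  v <- values[finite[1:3]]
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  gaps <- abs(v[pairs[, 1]] - v[pairs[, 2]])
  best <- pairs[which.min(gaps), ]  # which.min keeps the lowest-index pair on ties
  list(pair = finite[best], mean = mean(v[best]), qc = "ok")
}

#' Specific activity: total minus nonspecific, clipped at zero
#'
#' @param total,nonspecific Activities on a common normalized scale.
#' @return A list: `activity` (`max(total - nonspecific, 0)`) and `qc`
#'   (`"below_detection"` when clipped).
#' @export
specific_activity <- function(total, nonspecific) {
  diff <- total - nonspecific
  clipped <- diff < 0
  list(activity = pmax(diff, 0),
       qc = ifelse(clipped, "below_detection", "ok"))
}

#' Convert an OD change to enzymatic activity per tissue unit
#'
#' `activity = delta_od * dilution_factor / (extinction_coeff * path_correction)`.
#' The default unit coefficients leave the value unchanged; campaign-specific
#' extinction coefficients and the 1:50 (g:mL) homogenate dilution are
#' supplied through the processing config.
#'
#' @param delta_od OD change (or slope) magnitude.
#' @param extinction_coeff Molar extinction coefficient (> 0).
#' @param dilution_factor Homogenate dilution factor.
#' @param path_correction Optical path-length correction.
#' @return Activity in (arbitrary) units per tissue unit.
#' @export
od_to_activity <- function(delta_od, extinction_coeff = 1,
                           dilution_factor = 1, path_correction = 1) {
  check_scalar_positive(extinction_coeff, "extinction_coeff")
  delta_od * dilution_factor / (extinction_coeff * path_correction)
}

#' Process kinetic colorimetric traces into per-voxel specific activities
#'
#' Implements the full derivation: (1) integrate each sample trace over the
#' assay's early and late windows and each nonspecific trace over their
#' union, converting every integral to a per-second slope so all values share
#' a scale; (2) compute per-plate correction factors from the late-window
#' duplicate loading controls and normalize every plate (see
#' [plate_factor()]); (3) keep the higher of the two windows per well; (4)
#' across the three replicate plates keep the two closest values and average
#' them (same for nonspecific, except CIV which uses the plate-mean
#' nonspecific of its single negative-control plate); (5) subtract
#' nonspecific from total, clipping at zero; (6) convert to activity units
#' via [od_to_activity()].
#'
#' @param traces Long-format kinetic traces: `plate_id`, `base_plate`,
#'   `well`, `assay`, `replicate`, `is_nonspecific`, `time_s`, `od`
#'   (as produced by [generate_assay_data()]).
#' @param assignments Plate assignments from [randomize_to_plates()].
#' @param windows Integration windows, see [assay_windows()].
#' @param extinction_coeff,dilution_factor,path_correction Passed to
#'   [od_to_activity()]; either scalars or named per-assay vectors.
#' @param normalization_direction Passed to [apply_normalization()].
#' @param normalize Apply the control-based batch correction (disable to
#'   inspect uncorrected activities).
#' @return A `data.frame`: `voxel_id`, `assay`, `activity`, `qc`,
#'   `plate_factor` (audit: factor of the replicate plate whose value
#'   contributed first to the kept pair).
#' @export
process_colorimetry <- function(traces, assignments,
                                windows = assay_windows(),
                                extinction_coeff = 1, dilution_factor = 1,
                                path_correction = 1,
                                normalization_direction = c("divide",
                                                            "multiply"),
                                normalize = TRUE) {
  normalization_direction <- match.arg(normalization_direction)
  per_assay <- lapply(split(traces, traces$assay), function(tr) {
    w <- windows[windows$assay == tr$assay[1], ]
    slopes <- trace_slopes(tr, w)
    normalized <- normalize_colorimetry_plates(slopes, assignments,
                                               normalization_direction,
                                               normalize)
    combine_replicates(normalized, assignments, tr$assay[1],
                       coef_for(extinction_coeff, tr$assay[1]),
                       coef_for(dilution_factor, tr$assay[1]),
                       coef_for(path_correction, tr$assay[1]))
  })
  out <- do.call(rbind, per_assay)
  rownames(out) <- NULL
  out
}

coef_for <- function(x, assay) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!assay %in% names(x)) stopf("no coefficient supplied for assay %s", assay)
  unname(x[[assay]])
}

# Per-well window slopes (OD/s). Sample wells get early+late slopes, wells of
# nonspecific plates a single union-window slope. Traces within one plate
# share a time grid, so integration is a vectorized interpolation.
trace_slopes <- function(tr, w) {
  key <- paste(tr$plate_id, tr$well)
  per_well <- split(seq_len(nrow(tr)), key)
  first <- vapply(per_well, `[`, 0L, 1L)
  meta <- tr[first, c("plate_id", "base_plate", "well", "replicate",
                      "is_nonspecific")]
  dirn <- w$direction

  edge_od <- function(rows, at) {
    stats::approx(tr$time_s[rows], tr$od[rows], xout = at)$y
  }
  slope <- function(rows, from, to) {
    od <- edge_od(rows, c(from, to))
    max(dirn * (od[2] - od[1]), 0) / (to - from)
  }
  meta$early <- NA_real_; meta$late <- NA_real_; meta$ns <- NA_real_
  for (i in seq_along(per_well)) {
    rows <- per_well[[i]]
    if (meta$is_nonspecific[i]) {
      meta$ns[i] <- slope(rows, w$ns_start, w$ns_end)
    } else {
      meta$early[i] <- slope(rows, w$early_start, w$early_end)
      meta$late[i] <- slope(rows, w$late_start, w$late_end)
    }
  }
  rownames(meta) <- NULL
  meta
}

# Control-ratio batch correction per physical plate; sample and nonspecific
# plates are corrected within their own kind. The late-window slope (the more
# consistent of the two) defines the control values; nonspecific plates only
# have the union-window slope.
normalize_colorimetry_plates <- function(slopes, assignments, direction,
                                         normalize = TRUE) {
  content <- assignments$content[match(paste(slopes$base_plate, slopes$well),
                                       paste(assignments$plate_id,
                                             assignments$well))]
  slopes$content <- content
  out <- lapply(split(slopes, slopes$is_nonspecific), function(sl) {
    value_col <- if (sl$is_nonspecific[1]) "ns" else "late"
    ctrl <- sl[grepl("^control_", sl$content), ]
    controls <- data.frame(plate_id = ctrl$plate_id,
                           control_type = sub("^control_", "", ctrl$content),
                           value = ctrl[[value_col]],
                           stringsAsFactors = FALSE)
    if (normalize) {
      grand <- control_grand_means(controls)
      factors <- vapply(split(controls, controls$plate_id),
                        plate_factor, 0, grand_means = grand)
      f <- factors[sl$plate_id]
    } else {
      f <- setNames(rep(1, nrow(sl)), sl$plate_id)
    }
    for (col in c("early", "late", "ns")) {
      sl[[col]] <- apply_normalization(sl[[col]], f, direction)
    }
    sl$plate_factor <- unname(f)
    sl
  })
  do.call(rbind, out)
}

# Deconvolve one replicate set at a time: wells are keyed by the base plate
# layout that the physical replicate plates copy.
deconvolve_replicates <- function(df, assignments) {
  per_rep <- lapply(split(df, df$replicate), function(d) {
    d2 <- d
    d2$plate_id <- d2$base_plate
    deconvolve(assignments, d2[, setdiff(names(d2), "base_plate")])
  })
  out <- do.call(rbind, per_rep)
  rownames(out) <- NULL
  out
}

combine_replicates <- function(sl, assignments, assay, ext, dil, path) {
  samp <- sl[!sl$is_nonspecific & sl$content == "sample", ]
  nonspec <- sl[sl$is_nonspecific, ]
  samp$value <- pick_window(samp$early, samp$late)
  samp$base <- samp$base_plate
  vox <- deconvolve_replicates(
    samp[, c("plate_id", "base_plate", "well", "replicate", "value",
             "plate_factor", "base")], assignments)
  per_vox <- split(vox, vox$voxel_id)

  civ_plate_ns <- NULL
  if (assay == "CIV") {
    civ_plate_ns <- tapply(nonspec$ns, nonspec$base_plate, mean)
  } else {
    ns_samp <- nonspec[nonspec$content == "sample", ]
    ns_vox <- deconvolve_replicates(
      ns_samp[, c("plate_id", "base_plate", "well", "replicate", "ns")],
      assignments)
    ns_by_vox <- split(ns_vox, ns_vox$voxel_id)
  }

  res <- lapply(per_vox, function(v) {
    v <- v[order(v$replicate), ]
    sel <- select_two_closest(v$value)
    total <- sel$mean
    if (assay == "CIV") {
      ns_val <- unname(civ_plate_ns[[v$base[1]]])
    } else {
      nv <- ns_by_vox[[v$voxel_id[1]]]
      nv <- nv[order(nv$replicate), ]
      ns_val <- select_two_closest(nv$ns)$mean
    }
    spec <- specific_activity(total, ns_val)
    qc <- unique(c(sel$qc, spec$qc))
    qc <- paste(qc[qc != "ok"], collapse = ";")
    data.frame(voxel_id = v$voxel_id[1], assay = assay,
               activity = od_to_activity(spec$activity, ext, dil, path),
               qc = if (nzchar(qc)) qc else "ok",
               plate_factor = v$plate_factor[sel$pair[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
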