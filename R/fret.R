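#' Measure per-synapse intersubunit FRET from a three-channel acquisition
#'
#' For each synaptic cluster, sums and means are taken from the unsmoothed
#' donor image (surface pHluorin-tagged subunit under 488 nm excitation), the
#' FRET channel (acceptor emission under donor excitation) and the
#' total-acceptor image (direct 561 nm excitation). Clusters must contain
#' both fluorophores: a cluster lacking donor or total-acceptor signal is
#' dropped and the drop is counted. Presence is decided against binary masks
#' of the donor and total channels; when not supplied, these are built with
#' [threshold_mask()] so that the FRET and total channels share identical
#' threshold ranges.
#'
#' @param donor_img,fret_img,total_img Same-shaped [channel_image()]s.
#' @param clusters A `cluster_set` of candidate synaptic ROIs.
#' @param donor_mask,total_mask Optional logical masks defining signal
#'   presence; defaults to Otsu masks of the respective images.
#' @param min_overlap_px Pixels of mask overlap required for "presence"
#'   (default 1).
#' @return Data frame of class `fret_synapse_records` with one row per
#'   retained cluster: `synapse_id`, `donor_sum`, `donor_mean`, `fret_sum`,
#'   `fret_mean`, `total_acceptor_sum`; attribute `n_dropped` counts clusters
#'   lacking either signal.
#' @export
measure_synapse_fret <- function(donor_img, fret_img, total_img, clusters,
                                 donor_mask = NULL, total_mask = NULL,
                                 min_overlap_px = 1) {
  stopifnot(is_channel_image(donor_img), is_channel_image(fret_img),
            is_channel_image(total_img), inherits(clusters, "cluster_set"))
  check_same_shape(donor_img, fret_img)
  check_same_shape(donor_img, total_img)
  if (!identical(attr(clusters, "img_dim"), dim(donor_img$pixels)))
    stop("cluster set and image dimensions differ", call. = FALSE)
  if (is.null(donor_mask))
    donor_mask <- threshold_mask(donor_img, method = "otsu")
  if (is.null(total_mask))
    total_mask <- threshold_mask(total_img, method = "otsu")
  px <- attr(clusters, "pixels")
  don_idx <- which(donor_mask)
  tot_idx <- which(total_mask)
  rows <- lapply(seq_along(px), function(i) {
    idx <- px[[i]]
    if (sum(idx %in% don_idx) < min_overlap_px ||
        sum(idx %in% tot_idx) < min_overlap_px) return(NULL)
    data.frame(synapse_id = clusters$id[i],
               donor_sum = sum(donor_img$pixels[idx]),
               donor_mean = mean(donor_img$pixels[idx]),
               fret_sum = sum(fret_img$pixels[idx]),
               fret_mean = mean(fret_img$pixels[idx]),
               total_acceptor_sum = sum(total_img$pixels[idx]))
  })
  kept <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(synapse_id = integer(), donor_sum = numeric(),
               donor_mean = numeric(), fret_sum = numeric(),
               fret_mean = numeric(), total_acceptor_sum = numeric())
  structure(out, class = c("fret_synapse_records", class(out)),
            n_dropped = length(px) - length(kept))
}

#' Ordered restriction criteria for per-cell FRET records
#'
#' Applies the four acceptance criteria strictly in order:
#' \enumerate{
#'   \item at least `min_synapses` synapses measured per cell, otherwise the
#'     whole cell is rejected;
#'   \item the FRET:total acceptor sum-intensity ratio of a synapse must be
#'     less than one (physically impossible otherwise);
#'   \item synaptic donor mean intensity of at least `donor_mean_floor`
#'     ("at least", so the boundary value is kept);
#'   \item donor sum intensity limited to `donor_sum_cap_pct` percent of the
#'     average donor sum — the average being computed over the synapses that
#'     survived criteria 2–3 of the same cell; values at the cap are kept.
#' }
#' Per-criterion drop counts are recorded for audit.
#'
#' @param records A `fret_synapse_records` data frame from one cell.
#' @param donor_mean_floor Minimum donor mean intensity (default 500).
#' @param donor_sum_cap_pct Donor sum cap as percent of the average (default
#'   300).
#' @param min_synapses Minimum synapses measured per cell (default 15).
#' @param cell_id Cell identifier carried into the result.
#' @return A `fret_cell_result` list: `cell_id`, `records` (survivors),
#'   `dropped` (per-criterion counts), `participation_ratio`, `rejected`
#'   (TRUE with `reason` when criterion 1 fails or no synapse survives).
#' @export
apply_restriction_criteria <- function(records, donor_mean_floor = 500,
                                       donor_sum_cap_pct = 300,
                                       min_synapses = 15, cell_id = "cell") {
  stopifnot(is.data.frame(records))
  n0 <- nrow(records)
  dropped <- c(criterion1_cell = 0L, criterion2_ratio = 0L,
               criterion3_donor_mean = 0L, criterion4_donor_sum = 0L)
  reject <- function(reason) {
    structure(list(cell_id = cell_id, records = records[0, ],
                   dropped = dropped, participation_ratio = NA_real_,
                   rejected = TRUE, reason = reason),
              class = "fret_cell_result")
  }
  if (n0 < min_synapses) {
    dropped["criterion1_cell"] <- n0
    return(reject(sprintf("only %d synapses measured (need %d)",
                          n0, min_synapses)))
  }
  ratio <- records$fret_sum / records$total_acceptor_sum
  keep2 <- ratio < 1
  dropped["criterion2_ratio"] <- sum(!keep2)
  rec <- records[keep2, , drop = FALSE]
  keep3 <- rec$donor_mean >= donor_mean_floor
  dropped["criterion3_donor_mean"] <- sum(!keep3)
  rec <- rec[keep3, , drop = FALSE]
  if (!nrow(rec)) return(reject("no valid synapses"))
  cap <- (donor_sum_cap_pct / 100) * mean(rec$donor_sum)
  keep4 <- rec$donor_sum <= cap
  dropped["criterion4_donor_sum"] <- sum(!keep4)
  rec <- rec[keep4, , drop = FALSE]
  if (!nrow(rec)) return(reject("no valid synapses"))
  structure(list(cell_id = cell_id, records = rec, dropped = dropped,
                 participation_ratio = sum(rec$fret_sum) /
                   sum(rec$total_acceptor_sum),
                 rejected = FALSE, reason = NA_character_),
            class = "fret_cell_result")
}

#' @export
print.fret_cell_result <- function(x, ...) {
  if (x$rejected)
    cat(sprintf("<fret_cell_result %s: REJECTED (%s)>\n", x$cell_id, x$reason))
  else
    cat(sprintf(
      "<fret_cell_result %s: %d synapses kept, participation %.3f>\n",
      x$cell_id, nrow(x$records), x$participation_ratio))
  invisible(x)
}

#' Fraction of acceptor participating in FRET
#'
#' The FRET:total acceptor ratio over a cell's surviving synapses: summed
#' FRET-channel intensity divided by summed directly-excited acceptor
#' intensity. After the restriction criteria this ratio lies in `[0, 1)`.
#'
#' @param result A `fret_cell_result` (or a survivors data frame).
#' @return Scalar participation ratio.
#' @export
fret_participation <- function(result) {
  rec <- if (inherits(result, "fret_cell_result")) result$records else result
  if (!nrow(rec)) stop("no surviving synapses", call. = FALSE)
  tot <- sum(rec$total_acceptor_sum)
  if (tot <= 0) stop("zero total acceptor intensity", call. = FALSE)
  sum(rec$fret_sum) / tot
}

#' Acceptor-photobleaching FRET time course analysis
#'
#' Quantifies donor dequenching after acceptor photobleaching: with transfer
#' efficiency `E`, the donor rises from `D (1 - E)` to `D`, so
#' `E = 1 - pre/post` donor. Reports the percent change in donor, the
#' donor/FRET ratio trajectory, and warns when the FRET channel was not
#' reduced by at least half (incomplete bleach).
#'
#' @param series Data frame with columns `donor` and `fret` (one row per
#'   frame), e.g. from [simulate_bleach_series()].
#' @param bleach_index Index of the first post-bleach frame.
#' @param background Per-channel background to subtract (scalar or named
#'   vector with `donor`, `fret`).
#' @return List with `donor_dequench_pct`, `fret_efficiency`
#'   (`1 - pre/post`), `ratio_trajectory` (donor/FRET per frame),
#'   `fret_drop_pct` and `incomplete_bleach` flag.
#' @export
acceptor_bleach_timecourse <- function(series, bleach_index,
                                       background = 0) {
  stopifnot(is.data.frame(series), all(c("donor", "fret") %in% names(series)))
  n <- nrow(series)
  if (bleach_index < 3 || bleach_index > n)
    stop("need >= 2 pre-bleach frames and bleach_index within the series",
         call. = FALSE)
  bg <- if (length(background) == 1)
    c(donor = unname(background), fret = unname(background)) else background
  donor <- pmax(series$donor - bg[["donor"]], 0)
  fretv <- pmax(series$fret - bg[["fret"]], 0)
  pre <- seq_len(bleach_index - 1)
  post <- bleach_index:n
  pre_d <- mean(donor[pre]); post_d <- mean(donor[post])
  pre_f <- mean(fretv[pre]); post_f <- mean(fretv[post])
  drop_pct <- if (pre_f > 0) (pre_f - post_f) / pre_f * 100 else NA_real_
  incomplete <- is.na(drop_pct) || drop_pct < 50
  if (incomplete)
    warning("incomplete bleach: FRET channel not reduced by >= 50%",
            call. = FALSE)
  list(donor_dequench_pct = (post_d - pre_d) / pre_d * 100,
       fret_efficiency = 1 - pre_d / post_d,
       ratio_trajectory = ifelse(fretv > 0, donor / fretv, NA_real_),
       fret_drop_pct = drop_pct,
       incomplete_bleach = incomplete)
}

#' pH-quench control for surface-dependent FRET
#'
#' The FRET-channel mean under acidic saline (MES, donor pHluorin quenched)
#' divided by the mean under neutral saline (HBS). Genuine surface FRET
#' collapses toward zero when the donor is quenched; a bleed-through-only
#' signal is unaffected and stays near one.
#'
#' @param hbs_frames,mes_frames FRET-channel mean intensities per frame under
#'   each condition (`>= 1` frame each).
#' @return Scalar normalized change (MES/HBS).
#' @export
ph_quench_control <- function(hbs_frames, mes_frames) {
  if (!length(hbs_frames) || !length(mes_frames))
    stop("need at least one frame per condition", call. = FALSE)
  h <- mean(hbs_frames)
  if (h <= 0) stop("zero HBS mean intensity", call. = FALSE)
  mean(mes_frames) / h
}

#' Normalize per-cell summaries to a control cohort
#'
#' Reporting step expressing treated-cell summaries as percent of the control
#' cohort mean; stored per-synapse records are never altered.
#'
#' @param values Numeric summaries for the treated cells.
#' @param control_values Numeric summaries for the control cohort.
#' @return `values / mean(control_values) * 100`.
#' @export
percent_of_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m == 0)
    stop("control cohort mean must be finite and nonzero", call. = FALSE)
  values / m * 100
}
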