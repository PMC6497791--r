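#' Surface/total receptor ratio from a paired acquisition
#'
#' In the intracellular-pool reveal assay the first image shows only surface
#' receptors (pHluorin quenched inside acidic compartments) and the second,
#' taken after collapsing the pH gradient, shows surface plus intracellular
#' signal. The ratio is `(surface sum - background) / (total sum -
#' background)` per ROI, with the background taken as a per-pixel level times
#' the ROI pixel count.
#'
#' @param surface_img,total_img Same-shaped [channel_image()]s.
#' @param rois List of [roi_spec()]s; `NULL` uses the whole image.
#' @param background_surface,background_total Per-pixel background levels.
#' @return Data frame with one row per ROI: `roi`, `surface_sum`,
#'   `total_sum`, `ratio`, `flagged` (TRUE when the denominator was not
#'   positive; `ratio` is `NA` there).
#' @export
surface_total_ratio <- function(surface_img, total_img, rois = NULL,
                                background_surface = 0, background_total = 0) {
  stopifnot(is_channel_image(surface_img), is_channel_image(total_img))
  check_same_shape(surface_img, total_img)
  dims <- dim(surface_img$pixels)
  if (is.null(rois)) {
    idx_list <- list(whole_image = seq_len(prod(dims)))
  } else {
    idx_list <- lapply(rois, roi_pixel_index, dim_px = dims)
    names(idx_list) <- if (is.null(names(rois)))
      paste0("roi", seq_along(rois)) else names(rois)
  }
  rows <- lapply(names(idx_list), function(nm) {
    idx <- idx_list[[nm]]
    s <- sum(surface_img$pixels[idx]) - background_surface * length(idx)
    t <- sum(total_img$pixels[idx]) - background_total * length(idx)
    flagged <- t <= 0
    data.frame(roi = nm, surface_sum = s, total_sum = t,
               ratio = if (flagged) NA_real_ else s / t, flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Detect bright circular vesicle spots at a nominal size
#'
#' Scale-matched blob detection for the large intracellular vesicles counted
#' in the reveal assay: the image is smoothed at the nominal object scale,
#' thresholded at `intensity_floor`, 8-connected components are labeled, and
#' candidates are kept only when their equivalent-circle diameter falls in
#' `diameter_window` times the nominal size and their circularity (minor over
#' major axis length from second moments) is at least `circularity_min`.
#'
#' @param img A [channel_image()].
#' @param nominal_size_um Nominal object diameter in micrometres (default
#'   0.75); must exceed two pixels.
#' @param intensity_floor Minimum smoothed intensity of a spot pixel.
#' @param diameter_window Acceptable equivalent-diameter range as multiples
#'   of `nominal_size_um` (default `c(0.4, 2)`).
#' @param circularity_min Minimum circularity (default 0.8).
#' @return A `spot_set` data frame: `id`, `x_um`, `y_um`, `diameter_um`,
#'   `peak`, `circularity`.
#' @export
detect_spots <- function(img, nominal_size_um = 0.75, intensity_floor,
                         diameter_window = c(0.4, 2), circularity_min = 0.8) {
  stopifnot(is_channel_image(img))
  if (nominal_size_um <= 2 * img$pixel_size_um)
    stop("`nominal_size_um` must exceed two pixel widths", call. = FALSE)
  px <- img$pixel_size_um
  sigma_px <- nominal_size_um / (2 * sqrt(2 * log(2))) / 2 / px
  sm <- smooth_image(img$pixels, sigma_px)
  comp <- label_components8(sm >= intensity_floor)
  nr <- nrow(img$pixels)
  rows <- lapply(comp, function(idx) {
    if (length(idx) < 3) return(NULL)
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    d_eq <- 2 * sqrt(length(idx) / pi) * px
    if (d_eq < diameter_window[1] * nominal_size_um ||
        d_eq > diameter_window[2] * nominal_size_um) return(NULL)
    circ <- component_circularity(r, c)
    if (circ < circularity_min) return(NULL)
    data.frame(x_um = (mean(c) - 0.5) * px, y_um = (mean(r) - 0.5) * px,
               diameter_um = d_eq, peak = max(img$pixels[idx]),
               circularity = circ)
  })
  kept <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(x_um = numeric(), y_um = numeric(), diameter_um = numeric(),
               peak = numeric(), circularity = numeric())
  out <- cbind(id = seq_len(nrow(out)), out)
  structure(out, class = c("spot_set", class(out)),
            source_channel = img$channel, nominal_size_um = nominal_size_um)
}

# Minor/major axis ratio from the second moments of a pixel blob; 1 for a
# disc, 1/3 for a 3:1 elongated object.
component_circularity <- function(r, c) {
  if (length(r) < 3) return(1)
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(1)
  sqrt(max(ev[2], 0) / ev[1])
}

#' Count vesicles newly visible in the post image
#'
#' Greedy nearest-neighbour matching of post spots to pre spots in ascending
#' distance order (ties broken by spot id); each pre spot can absorb one post
#' spot within `match_radius_um`. The new-vesicle count is the number of post
#' spots left unmatched, i.e. objects only seen after the reveal.
#'
#' @param pre,post `spot_set`s from registered images.
#' @param match_radius_um Maximum matching distance (default 0.5).
#' @return Integer count of new vesicles, with attribute `matched` (the
#'   number of matched pairs).
#' @export
count_new_vesicles <- function(pre, post, match_radius_um = 0.5) {
  stopifnot(inherits(pre, "spot_set"), inherits(post, "spot_set"))
  if (!nrow(post)) return(structure(0L, matched = 0L))
  if (!nrow(pre)) return(structure(nrow(post), matched = 0L))
  d <- outer(seq_len(nrow(post)), seq_len(nrow(pre)),
             function(i, j) sqrt((post$x_um[i] - pre$x_um[j])^2 +
                                 (post$y_um[i] - pre$y_um[j])^2))
  cand <- which(d <= match_radius_um, arr.ind = TRUE)
  if (!nrow(cand)) return(structure(nrow(post), matched = 0L))
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_post <- logical(nrow(post)); used_pre <- logical(nrow(pre))
  matched <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_post[i] && !used_pre[j]) {
      used_post[i] <- TRUE; used_pre[j] <- TRUE
      matched <- matched + 1L
    }
  }
  structure(nrow(post) - matched, matched = matched)
}

#' Receptor colocalization at lysosomes
#'
#' Mean receptor intensity and area over the lysosome mask, reported per ROI
#' (soma, dendrite segments, whole cell) when ROIs are given. An empty mask
#' yields zero area and an undefined (flagged) mean.
#'
#' @param receptor_img A [channel_image()] (e.g. the far-red dye channel
#'   pulse-labeling surface receptors).
#' @param lysosome_mask Logical mask of lysosome pixels, same shape, e.g.
#'   from [threshold_mask()] on the lysosomal-dye channel.
#' @param receptor_mask Optional logical mask of receptor-positive pixels;
#'   when given, the colocalized area is the receptor-and-lysosome overlap
#'   instead of the full lysosome area.
#' @param rois Optional named list of [roi_spec()]s; `NULL` uses the whole
#'   image.
#' @return Data frame per ROI: `roi`, `coloc_mean` (mean receptor intensity
#'   over lysosome pixels), `coloc_area_um2`, `n_px`, `flagged` (empty mask
#'   within the ROI).
#' @export
lysosomal_colocalization <- function(receptor_img, lysosome_mask,
                                     receptor_mask = NULL, rois = NULL) {
  stopifnot(is_channel_image(receptor_img))
  if (!identical(dim(lysosome_mask), dim(receptor_img$pixels)))
    stop("mask and image must have identical dimensions", call. = FALSE)
  dims <- dim(receptor_img$pixels)
  mask_idx <- which(lysosome_mask)
  area_idx <- if (is.null(receptor_mask)) mask_idx else
    which(lysosome_mask & receptor_mask)
  if (is.null(rois)) {
    idx_list <- list(whole_image = seq_len(prod(dims)))
  } else {
    idx_list <- lapply(rois, roi_pixel_index, dim_px = dims)
    names(idx_list) <- if (is.null(names(rois)))
      paste0("roi", seq_along(rois)) else names(rois)
  }
  px_area <- receptor_img$pixel_size_um^2
  rows <- lapply(names(idx_list), function(nm) {
    idx <- intersect(idx_list[[nm]], mask_idx)
    a_idx <- intersect(idx_list[[nm]], area_idx)
    flagged <- !length(idx)
    data.frame(roi = nm,
               coloc_mean = if (flagged) NA_real_
                            else mean(receptor_img$pixels[idx]),
               coloc_area_um2 = length(a_idx) * px_area,
               n_px = length(idx), flagged = flagged)
  })
  do.call(rbind, rows)
}
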