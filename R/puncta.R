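#' Binary threshold mask with optional Gaussian smoothing
#'
#' Reproducible replacement for interactive binary thresholding: the image is
#' optionally smoothed with an isotropic Gaussian, then thresholded either at
#' a fixed intensity or at the Otsu threshold (maximizing between-class
#' variance). The mask is true where the smoothed intensity is greater than
#' or equal to the threshold, and the threshold actually used is recorded on
#' the result.
#'
#' @param img A [channel_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold intensity, required when `method = "fixed"`.
#' @param smoothing_sigma_um Gaussian smoothing sigma in micrometres
#'   (0 disables smoothing).
#' @return Logical matrix of class `binary_mask` with attributes `threshold`,
#'   `method` and `smoothing_sigma_um`.
#' @export
threshold_mask <- function(img, method = c("otsu", "fixed"),
                           fixed_value = NULL, smoothing_sigma_um = 0) {
  stopifnot(is_channel_image(img))
  method <- match.arg(method)
  sm <- smooth_image(img$pixels, smoothing_sigma_um / img$pixel_size_um)
  thr <- if (method == "fixed") {
    if (is.null(fixed_value))
      stop("`fixed_value` is required when method = 'fixed'", call. = FALSE)
    fixed_value
  } else {
    otsu_threshold(sm)
  }
  mask <- sm >= thr
  structure(mask, class = c("binary_mask", class(mask)), threshold = thr,
            method = method, smoothing_sigma_um = smoothing_sigma_um)
}

smooth_image <- function(pixels, sigma_px) {
  if (sigma_px <= 0) return(pixels)
  as.matrix(EBImage::gblur(pixels, sigma = sigma_px))
}

#' Otsu threshold of an intensity matrix
#'
#' Picks the intensity level that maximizes the between-class variance of the
#' two classes `{x < t}` and `{x >= t}`. Candidate levels are the unique
#' intensities when there are at most `max_levels` of them, otherwise
#' `max_levels` equal-width histogram bin edges. Ties resolve to the lowest
#' maximizing threshold.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param max_levels Maximum number of candidate levels (default 256).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, max_levels = 256) {
  v <- sort(unique(as.numeric(x)))
  if (length(v) < 2)
    stop("degenerate histogram: image has a single intensity level",
         call. = FALSE)
  if (length(v) > max_levels) {
    edges <- seq(min(v), max(v), length.out = max_levels + 1)
    lev <- edges[-length(edges)]
    bin <- findInterval(as.numeric(x), edges, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nbins = max_levels)
    mid <- (edges[-length(edges)] + edges[-1]) / 2
  } else {
    lev <- v
    cnt <- tabulate(match(as.numeric(x), v), nbins = length(v))
    mid <- v
  }
  n <- sum(cnt)
  cum_n <- cumsum(cnt)
  cum_s <- cumsum(cnt * mid)
  total <- cum_s[length(cum_s)]
  # split after level k: background = levels 1..k, foreground = k+1..end
  k <- seq_len(length(lev) - 1)
  w0 <- cum_n[k] / n
  w1 <- 1 - w0
  mu0 <- cum_s[k] / cum_n[k]
  mu1 <- (total - cum_s[k]) / (n - cum_n[k])
  sb <- w0 * w1 * (mu0 - mu1)^2
  lev[which.max(sb) + 1]
}

#' Segment clusters from a binary mask
#'
#' Labels 8-connected components of the mask, discards components outside the
#' configured area window or smaller than `min_pixels`, and summarizes each
#' surviving cluster with intensities taken from the original (unsmoothed)
#' image. The 2-pixel minimum stands in for the manual single-pixel cleanup
#' used in interactive analysis.
#'
#' @param mask A `binary_mask` (or plain logical matrix).
#' @param img The [channel_image()] the mask came from.
#' @param size_window_um2 Length-2 numeric `(min, max]`: clusters are kept
#'   when `min < area <= max` in square micrometres. Default `c(0, 3)`, the
#'   size-exclusion window used for synaptic clusters.
#' @param min_pixels Minimum component size in pixels (default 2).
#' @return A `cluster_set`: data frame with one row per cluster (`id`,
#'   `n_px`, `area_um2`, `centroid_x_px`, `centroid_y_px`, `sum`, `mean`,
#'   `synaptic`) plus attributes `pixels` (list of linear pixel indices),
#'   `dim` and `pixel_size_um`.
#' @export
detect_clusters <- function(mask, img, size_window_um2 = c(0, 3),
                            min_pixels = 2) {
  stopifnot(is_channel_image(img))
  if (!identical(dim(mask), dim(img$pixels)))
    stop("mask and image must have identical dimensions", call. = FALSE)
  comp <- label_components8(mask)
  px_area <- img$pixel_size_um^2
  keep <- which(lengths(comp) >= min_pixels &
                lengths(comp) * px_area > size_window_um2[1] &
                lengths(comp) * px_area <= size_window_um2[2])
  comp <- comp[keep]
  nr <- nrow(img$pixels)
  rows <- lapply(seq_along(comp), function(i) {
    idx <- comp[[i]]
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    data.frame(id = i, n_px = length(idx), area_um2 = length(idx) * px_area,
               centroid_x_px = mean(c) - 0.5, centroid_y_px = mean(r) - 0.5,
               sum = sum(img$pixels[idx]), mean = mean(img$pixels[idx]),
               synaptic = NA)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), n_px = integer(), area_um2 = numeric(),
               centroid_x_px = numeric(), centroid_y_px = numeric(),
               sum = numeric(), mean = numeric(), synaptic = logical())
  structure(df, class = c("cluster_set", class(df)), pixels = comp,
            img_dim = dim(img$pixels), pixel_size_um = img$pixel_size_um)
}

# 8-connected component labeling via a pixel adjacency graph.
label_components8 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  edges <- list()
  # forward neighbours: S, E, SE, NE cover all 8-connections once
  offs <- list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- (c2[ok] - 1) * nr + r2[ok]
    hit <- pos[j] > 0
    if (any(hit))
      edges[[length(edges) + 1]] <- cbind(pos[idx[ok]][hit], pos[j][hit])
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  g <- igraph::make_graph(edges = as.vector(t(em)), n = length(idx),
                          directed = FALSE)
  mem <- igraph::components(g)$membership
  unname(split(idx, mem))
}

#' Per-channel intensity summaries for an existing cluster set
#'
#' Re-measures the clusters of `clusters` on another channel of the same
#' scene (original, unsmoothed intensities).
#'
#' @param clusters A `cluster_set`.
#' @param img A [channel_image()] with the same dimensions.
#' @return Data frame with `id`, `sum`, `mean` on the new channel.
#' @export
cluster_channel_stats <- function(clusters, img) {
  stopifnot(inherits(clusters, "cluster_set"), is_channel_image(img))
  if (!identical(attr(clusters, "img_dim"), dim(img$pixels)))
    stop("cluster set and image dimensions differ", call. = FALSE)
  px <- attr(clusters, "pixels")
  data.frame(id = clusters$id,
             sum = vapply(px, function(i) sum(img$pixels[i]), numeric(1)),
             mean = vapply(px, function(i) mean(img$pixels[i]), numeric(1)))
}

#' Flag receptor clusters as synaptic by marker colocalization
#'
#' A receptor cluster is synaptic when it shares at least `min_overlap_px`
#' pixels with any presynaptic-marker cluster (GAD65-style colocalization);
#' all other clusters are extrasynaptic.
#'
#' @param receptor,marker `cluster_set`s segmented from same-shaped images.
#' @param min_overlap_px Minimum shared pixel count (default 1).
#' @return `receptor` with its `synaptic` column filled in.
#' @export
label_synaptic <- function(receptor, marker, min_overlap_px = 1) {
  stopifnot(inherits(receptor, "cluster_set"), inherits(marker, "cluster_set"))
  if (!identical(attr(receptor, "img_dim"), attr(marker, "img_dim")))
    stop("cluster sets must come from same-shaped images", call. = FALSE)
  marker_px <- unlist(attr(marker, "pixels"), use.names = FALSE)
  rec_px <- attr(receptor, "pixels")
  receptor$synaptic <- vapply(rec_px, function(i)
    sum(i %in% marker_px) >= min_overlap_px, logical(1))
  receptor
}

#' Partition ROI intensity into synaptic, extrasynaptic and background
#'
#' Implements the dendritic intensity decomposition: the extrasynaptic signal
#' is the total ROI sum intensity minus background and synaptic fluorescence.
#' The background contribution is `background * (ROI pixel count)` so that
#' `synaptic + extrasynaptic + background_total == total` holds exactly.
#'
#' @param img A [channel_image()].
#' @param roi An [roi_spec()].
#' @param clusters A `cluster_set` with synaptic flags (see
#'   [label_synaptic()]); only synaptic-flagged cluster pixels inside the ROI
#'   count toward the synaptic sum.
#' @param background Per-pixel background intensity (`>= 0`). Defaults to the
#'   median ROI intensity outside all clusters ([estimate_background()]).
#' @return List with `synaptic_sum`, `extrasynaptic_sum`, `total_sum`,
#'   `background_total`, `n_roi_px` and `over_subtracted` (TRUE when the
#'   extrasynaptic sum came out negative; the value is retained).
#' @export
partition_intensity <- function(img, roi, clusters, background = NULL) {
  stopifnot(is_channel_image(img), inherits(clusters, "cluster_set"))
  roi_idx <- roi_pixel_index(roi, dim(img$pixels))
  if (!length(roi_idx)) stop("ROI covers no pixels", call. = FALSE)
  if (is.null(background))
    background <- estimate_background(img, clusters, roi)
  stop_if_not_scalar_num(background, "background", 0)
  total <- sum(img$pixels[roi_idx])
  syn_px <- unlist(attr(clusters, "pixels")[which(clusters$synaptic %in% TRUE)],
                   use.names = FALSE)
  syn_px <- intersect(syn_px, roi_idx)
  synaptic <- sum(img$pixels[syn_px])
  bg_total <- background * length(roi_idx)
  extra <- total - bg_total - synaptic
  list(synaptic_sum = synaptic, extrasynaptic_sum = extra, total_sum = total,
       background_total = bg_total, n_roi_px = length(roi_idx),
       over_subtracted = extra < 0)
}

#' Median-outside-clusters background estimate
#'
#' The per-pixel background is the median intensity of pixels outside every
#' cluster, restricted to the ROI when one is given.
#'
#' @inheritParams partition_intensity
#' @return Scalar background intensity.
#' @export
estimate_background <- function(img, clusters, roi = NULL) {
  stopifnot(is_channel_image(img), inherits(clusters, "cluster_set"))
  idx <- if (is.null(roi)) seq_along(img$pixels)
         else roi_pixel_index(roi, dim(img$pixels))
  cl_px <- unlist(attr(clusters, "pixels"), use.names = FALSE)
  idx <- setdiff(idx, cl_px)
  if (!length(idx)) return(0)
  stats::median(img$pixels[idx])
}

#' Average per-ROI summaries to the cell level
#'
#' The cell is the experimental unit downstream: measurements from (typically
#' three) 10-micrometre dendritic ROIs are averaged to one value per cell.
#'
#' @param per_roi_values Numeric vector with one summary per ROI (length
#'   `>= 1`).
#' @return Arithmetic mean across ROIs.
#' @export
summarize_cell <- function(per_roi_values) {
  if (!length(per_roi_values))
    stop("need at least one ROI value", call. = FALSE)
  mean(as.numeric(per_roi_values))
}

#' Grubbs test removal of a single outlier
#'
#' Two-sided Grubbs test at significance `alpha`: computes
#' `G = max |x - mean| / sd` and removes the most extreme value if `G`
#' exceeds the critical value
#' `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha / (2 n), n - 2)`. At most one value is ever removed;
#' the test is not iterated.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return List with `values` (possibly shortened by one), `removed` (the
#'   removed value or `NULL`), `G` and `G_crit`.
#' @export
grubbs_remove_outlier <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    return(list(values = values, removed = NULL, G = 0, G_crit = Inf))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  G_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  if (G > G_crit) {
    drop <- which.max(dev)
    list(values = values[-drop], removed = values[drop], G = G,
         G_crit = G_crit)
  } else {
    list(values = values, removed = NULL, G = G, G_crit = G_crit)
  }
}
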