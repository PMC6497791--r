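#' Write a rendered scene as multi-page TIFF with a JSON truth sidecar
#'
#' Channels are stored as one 32-bit float page each, rescaled to `[0, 1]`
#' by a common scale factor recorded in the sidecar, which also carries the
#' channel names, pixel size and the full scene ground truth.
#'
#' @param scene A list with `images` and `truth` as returned by
#'   [make_dendrite_scene()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.json`.
#' @return The TIFF path, invisibly.
#' @export
write_scene_tiff <- function(scene, path_prefix) {
  imgs <- scene$images
  scale <- max(1, max(vapply(imgs, function(im) max(im$pixels), numeric(1))))
  pages <- lapply(imgs, function(im) im$pixels / scale)
  tif <- paste0(path_prefix, ".tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  truth <- scene$truth
  sidecar <- list(channels = names(imgs), intensity_scale = scale,
                  pixel_size_um = imgs[[1]]$pixel_size_um,
                  truth = list(puncta = truth$puncta,
                               width_um = truth$width_um,
                               height_um = truth$height_um,
                               background = truth$background,
                               poisson_scale = truth$poisson_scale,
                               gaussian_sd = truth$gaussian_sd,
                               pixel_size_um = truth$pixel_size_um,
                               seed = truth$seed))
  jsonlite::write_json(sidecar, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a scene written by [write_scene_tiff()]
#'
#' @param path_prefix Path prefix used at write time.
#' @return List with `images` (named [channel_image()]s, intensities
#'   restored to their original scale) and `truth` (a [scene_truth()]).
#' @export
read_scene_tiff <- function(path_prefix) {
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_prefix, ".tif"), all = TRUE)
  imgs <- lapply(seq_along(pages), function(k)
    channel_image(pages[[k]] * side$intensity_scale,
                  side$pixel_size_um, side$channels[k]))
  names(imgs) <- side$channels
  tr <- side$truth
  puncta <- if (length(tr$puncta)) as.data.frame(tr$puncta) else
    empty_puncta()
  list(images = imgs,
       truth = scene_truth(puncta, tr$width_um, tr$height_um,
                           tr$background, tr$poisson_scale, tr$gaussian_sd,
                           tr$pixel_size_um, tr$seed))
}

#' Write FRAP traces as long-format CSV
#'
#' Columns: `synapse_id`, `site`, `t_min`, `intensity`, `pre_bleach`,
#' `channel` — one row per timepoint.
#'
#' @param traces List of [frap_trace()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr)
    data.frame(synapse_id = tr$synapse_id, site = tr$site,
               t_min = tr$series$t_min, intensity = tr$series$intensity,
               pre_bleach = tr$pre_bleach, channel = tr$channel)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read FRAP traces from long-format CSV
#'
#' @param path CSV written by [write_frap_csv()] (or hand-assembled with the
#'   same columns).
#' @return List of [frap_trace()]s, one per `synapse_id`.
#' @export
read_frap_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$synapse_id), function(d) {
    d <- d[order(d$t_min), ]
    frap_trace(d$synapse_id[1], d$site[1], d$pre_bleach[1], d$t_min,
               d$intensity, d$channel[1])
  })
}

#' Write a spectral-count table as three TSV files
#'
#' @param table A [spectral_count_table()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"coip"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_spectral_counts <- function(table, dir, prefix = "coip") {
  stopifnot(inherits(table, "spectral_count_table"))
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             peptides = file.path(dir, paste0(prefix, "_peptides.tsv")),
             meta = file.path(dir, paste0(prefix, "_samples.tsv")))
  utils::write.table(data.frame(protein = rownames(table$counts),
                                table$counts, check.names = FALSE),
                     paths["counts"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(protein = rownames(table$unique_peptides),
                                table$unique_peptides, check.names = FALSE),
                     paths["peptides"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$sample_meta, paths["meta"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a spectral-count table from TSV files
#'
#' @param counts_path,peptides_path,meta_path Paths to the three TSVs
#'   written by [write_spectral_counts()].
#' @return A [spectral_count_table()].
#' @export
read_spectral_counts <- function(counts_path, peptides_path, meta_path) {
  read_mat <- function(p) {
    d <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  spectral_count_table(read_mat(counts_path), read_mat(peptides_path),
                       utils::read.delim(meta_path,
                                         stringsAsFactors = FALSE))
}
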