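#' Ground truth for a synthetic dendrite scene
#'
#' Describes a multi-channel fluorescence scene of Gaussian-profile synaptic
#' puncta on a uniform background, with a confocal-like noise model: shot
#' noise approximated as Gaussian with variance proportional to the signal
#' (`poisson_scale`) plus additive read noise (`gaussian_sd`). The recorded
#' truth travels with every rendered image so downstream segmentation and
#' intensity measurements can be scored against known answers.
#'
#' @param puncta Data frame with columns `x_um`, `y_um` (centroid in
#'   micrometres from the top-left corner), `peak` (peak intensity above
#'   background, arbitrary units), `sigma_um` (isotropic Gaussian width) and
#'   `synaptic` (logical; rendered also in the presynaptic-marker channel).
#'   May have zero rows.
#' @param width_um,height_um Physical extent of the image.
#' @param background Uniform background intensity (`>= 0`, below every peak).
#' @param poisson_scale Shot-noise scale: noise variance contribution is
#'   `poisson_scale * signal`. Zero disables shot noise.
#' @param gaussian_sd Additive read-noise standard deviation.
#' @param pixel_size_um Micrometres per pixel (default 0.1).
#' @param seed Integer seed; identical truth + seed gives identical pixels.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(puncta = empty_puncta(), width_um = 20, height_um = 20,
                        background = 10, poisson_scale = 0, gaussian_sd = 0,
                        pixel_size_um = 0.1, seed = 1L) {
  puncta <- as.data.frame(puncta)
  needed <- c("x_um", "y_um", "peak", "sigma_um", "synaptic")
  if (!all(needed %in% names(puncta)))
    stop("`puncta` needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  stop_if_not_scalar_num(background, "background", 0)
  stop_if_not_scalar_num(poisson_scale, "poisson_scale", 0)
  stop_if_not_scalar_num(gaussian_sd, "gaussian_sd", 0)
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  if (nrow(puncta)) {
    if (any(puncta$sigma_um <= 0)) stop("punctum sigma must be > 0", call. = FALSE)
    if (any(puncta$peak <= 0))
      stop("punctum peak intensities must exceed 0", call. = FALSE)
  }
  structure(list(puncta = puncta, width_um = width_um, height_um = height_um,
                 background = background, poisson_scale = poisson_scale,
                 gaussian_sd = gaussian_sd, pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "scene_truth")
}

#' @rdname scene_truth
#' @export
empty_puncta <- function() {
  data.frame(x_um = numeric(), y_um = numeric(), peak = numeric(),
             sigma_um = numeric(), synaptic = logical())
}

#' Randomly placed puncta along a horizontal dendrite band
#'
#' Convenience generator of a plausible dendritic field: puncta centred in a
#' band of the given half-width around mid-height, with jittered peaks and
#' widths. Typical inhibitory-synapse puncta are a few hundred nanometres
#' across, hence the default `sigma_um` of 0.25.
#'
#' @param n_synaptic,n_extrasynaptic Punctum counts of each kind.
#' @param width_um,height_um Scene extent.
#' @param band_halfwidth_um Vertical half-width of the dendrite band.
#' @param peak Mean peak intensity; individual peaks jittered +/- 20%.
#' @param sigma_um Mean Gaussian width; jittered +/- 20%.
#' @param min_sep_um Minimum centre-to-centre separation enforced greedily.
#' @param seed Integer seed.
#' @return A puncta data frame suitable for [scene_truth()].
#' @export
random_puncta <- function(n_synaptic = 5, n_extrasynaptic = 5, width_um = 20,
                          height_um = 20, band_halfwidth_um = 2, peak = 200,
                          sigma_um = 0.25, min_sep_um = 1.5, seed = 1L) {
  n <- n_synaptic + n_extrasynaptic
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < n && tries < 5000) {
      tries <- tries + 1
      x <- stats::runif(1, 2, width_um - 2)
      y <- height_um / 2 + stats::runif(1, -band_halfwidth_um, band_halfwidth_um)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep_um) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n)
      stop("could not place puncta with the requested separation", call. = FALSE)
    data.frame(
      x_um = xs, y_um = ys,
      peak = peak * stats::runif(n, 0.8, 1.2),
      sigma_um = sigma_um * stats::runif(n, 0.8, 1.2),
      synaptic = rep(c(TRUE, FALSE), c(n_synaptic, n_extrasynaptic))
    )
  })
}

# Noiseless render of selected puncta on a pixel-centre grid.
render_puncta <- function(truth, which_puncta, gain = 1) {
  nr <- round(truth$height_um / truth$pixel_size_um)
  nc <- round(truth$width_um / truth$pixel_size_um)
  img <- matrix(truth$background, nr, nc)
  if (!length(which_puncta)) return(img)
  px <- truth$pixel_size_um
  cx <- (seq_len(nc) - 0.5) * px
  cy <- (seq_len(nr) - 0.5) * px
  for (i in which_puncta) {
    p <- truth$puncta[i, ]
    gx <- exp(-(cx - p$x_um)^2 / (2 * p$sigma_um^2))
    gy <- exp(-(cy - p$y_um)^2 / (2 * p$sigma_um^2))
    img <- img + gain * p$peak * outer(gy, gx)
  }
  img
}

resolve_puncta_selector <- function(truth, sel) {
  n <- nrow(truth$puncta)
  if (is.character(sel) && length(sel) == 1) {
    switch(sel,
           all = seq_len(n),
           synaptic = which(truth$puncta$synaptic),
           nonsynaptic = which(!truth$puncta$synaptic),
           none = integer(0),
           stop("unknown puncta selector '", sel, "'", call. = FALSE))
  } else {
    idx <- as.integer(sel)
    if (any(idx < 1 | idx > n)) stop("puncta index out of range", call. = FALSE)
    idx
  }
}

#' Render a multi-channel dendrite scene from recorded ground truth
#'
#' Each punctum is rendered as an isotropic 2D Gaussian evaluated at pixel
#' centres on top of the uniform background; synaptic puncta are co-rendered
#' in the presynaptic-marker channel so colocalization-based synaptic
#' classification can be exercised with a known answer. Noise is applied
#' per the truth's noise model, independently per channel but reproducibly
#' from the truth's seed.
#'
#' @param truth A [scene_truth()].
#' @param channels List of channel specs, each `list(name=, puncta=, gain=)`
#'   where `puncta` is `"all"`, `"synaptic"`, `"nonsynaptic"`, `"none"` or an
#'   index vector into `truth$puncta`. Channel names must be unique. The
#'   default renders a receptor channel (all puncta) and a marker channel
#'   (synaptic puncta only).
#' @return A list with elements `images` (named list of [channel_image()]s)
#'   and `truth` (the input truth, unchanged).
#' @export
make_dendrite_scene <- function(truth,
                                channels = list(
                                  list(name = "receptor", puncta = "all"),
                                  list(name = "marker", puncta = "synaptic"))) {
  stopifnot(inherits(truth, "scene_truth"))
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms)) stop("channel names must be unique", call. = FALSE)
  if (nrow(truth$puncta)) {
    out <- truth$puncta$x_um < 0 | truth$puncta$x_um > truth$width_um |
      truth$puncta$y_um < 0 | truth$puncta$y_um > truth$height_um
    if (any(out))
      stop("punctum ", which(out)[1], " lies outside the image extent",
           call. = FALSE)
  }
  images <- with_seed(truth$seed, {
    lapply(seq_along(channels), function(k) {
      ch <- channels[[k]]
      gain <- if (is.null(ch$gain)) 1 else ch$gain
      idx <- resolve_puncta_selector(truth, ch$puncta)
      img <- render_puncta(truth, idx, gain = gain)
      if (truth$poisson_scale > 0 || truth$gaussian_sd > 0) {
        noise_sd <- sqrt(truth$poisson_scale * img + truth$gaussian_sd^2)
        img <- img + stats::rnorm(length(img), 0, noise_sd)
        img <- pmax(img, 0)
      }
      channel_image(img, truth$pixel_size_um, ch$name)
    })
  })
  names(images) <- nms
  list(images = images, truth = truth)
}

#' Analytic integral of a planted punctum over the whole plane
#'
#' For an isotropic Gaussian punctum of peak `A` and width `sigma` rendered at
#' pixel centres, the summed intensity above background approaches
#' `A * 2 * pi * sigma^2 / pixel_size^2`. Used to score measured synaptic
#' intensity sums against planted truth.
#'
#' @param truth A [scene_truth()].
#' @param which_puncta Indices of puncta to integrate (default all).
#' @return Numeric vector of per-punctum integrals in intensity-pixel units.
#' @export
punctum_integral <- function(truth, which_puncta = seq_len(nrow(truth$puncta))) {
  p <- truth$puncta[which_puncta, , drop = FALSE]
  p$peak * 2 * pi * p$sigma_um^2 / truth$pixel_size_um^2
}

#' Kinetic and effect-size ground truth for simulated experiments
#'
#' Houses the parameters shared by the FRAP, FRET, vesicle and spectral-count
#' simulators: the synaptic exchange rate and mobile fraction of the two-pool
#' recovery model, the FRET efficiency, vesicle counts before and after
#' intracellular-pool reveal, and planted per-protein DZP/vehicle ratios.
#'
#' @param k_exchange Exchange rate in 1/min (`>= 0`).
#' @param mobile_fraction Fraction of fluorescence able to exchange, in
#'   `[0, 1]`.
#' @param bleach_depth Fraction of pre-bleach fluorescence remaining
#'   immediately post-bleach, in `[0, 1)`.
#' @param fret_efficiency Donor-quenching FRET efficiency `E` in `[0, 1)`.
#' @param n_vesicles_pre,n_vesicles_post Planted vesicle counts before and
#'   after the reveal; `n_vesicles_post >= n_vesicles_pre`.
#' @param planted_effects Named numeric vector mapping protein id to its true
#'   DZP/vehicle ratio (`Inf` plants a DZP-only protein).
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(k_exchange = 0.05, mobile_fraction = 0.8,
                          bleach_depth = 0.2, fret_efficiency = 0.2,
                          n_vesicles_pre = 5, n_vesicles_post = 12,
                          planted_effects = numeric(0)) {
  stop_if_not_scalar_num(k_exchange, "k_exchange", 0)
  stop_if_not_scalar_num(mobile_fraction, "mobile_fraction", 0, 1)
  stop_if_not_scalar_num(bleach_depth, "bleach_depth", 0)
  if (bleach_depth >= 1) stop("`bleach_depth` must be < 1", call. = FALSE)
  stop_if_not_scalar_num(fret_efficiency, "fret_efficiency", 0)
  if (fret_efficiency >= 1)
    stop("`fret_efficiency` must be < 1", call. = FALSE)
  if (n_vesicles_post < n_vesicles_pre)
    stop("`n_vesicles_post` must be >= `n_vesicles_pre`", call. = FALSE)
  structure(list(k_exchange = k_exchange, mobile_fraction = mobile_fraction,
                 bleach_depth = bleach_depth, fret_efficiency = fret_efficiency,
                 n_vesicles_pre = n_vesicles_pre,
                 n_vesicles_post = n_vesicles_post,
                 planted_effects = planted_effects),
            class = "kinetic_truth")
}

#' Noiseless two-pool FRAP recovery model
#'
#' `f(t) = pre * [b + m * (1 - b) * (1 - exp(-k t))]` where `b` is the bleach
#' depth, `m` the mobile fraction and `k` the exchange rate. At `t = 0` the
#' fluorescence equals `pre * b`; as `t` grows it approaches
#' `pre * (b + m * (1 - b))`, i.e. full recovery only when `m = 1`.
#'
#' @param t_min Time in minutes.
#' @param pre_bleach Pre-bleach fluorescence.
#' @param k,mobile,bleach Model parameters (see [kinetic_truth()]).
#' @return Fluorescence at `t_min`, same units as `pre_bleach`.
#' @export
frap_model <- function(t_min, pre_bleach, k, mobile, bleach) {
  pre_bleach * (bleach + mobile * (1 - bleach) * (1 - exp(-k * t_min)))
}

#' Simulate a per-synapse FRAP trace
#'
#' Draws a post-bleach intensity time series from the two-pool model in
#' [frap_model()] with additive Gaussian measurement noise, mimicking the
#' every-2-minutes live-imaging protocol.
#'
#' @param kin A [kinetic_truth()].
#' @param timepoints_min Ordered vector of acquisition times starting at 0.
#' @param pre_bleach Pre-bleach fluorescence (`> 0`).
#' @param noise_sd Additive Gaussian noise SD (`>= 0`).
#' @param seed Integer seed.
#' @param synapse_id,site,channel Trace metadata.
#' @return A [frap_trace()].
#' @export
simulate_frap <- function(kin, timepoints_min = seq(0, 30, by = 2),
                          pre_bleach = 100, noise_sd = 0, seed = 1L,
                          synapse_id = "sim", site = "synaptic",
                          channel = "receptor") {
  stopifnot(inherits(kin, "kinetic_truth"))
  if (timepoints_min[1] != 0 || is.unsorted(timepoints_min, strictly = TRUE))
    stop("`timepoints_min` must be strictly increasing and start at 0",
         call. = FALSE)
  stop_if_not_scalar_num(pre_bleach, "pre_bleach", 0, strict_lower = TRUE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", 0)
  mean_f <- frap_model(timepoints_min, pre_bleach, kin$k_exchange,
                       kin$mobile_fraction, kin$bleach_depth)
  y <- if (noise_sd > 0)
    with_seed(seed, mean_f + stats::rnorm(length(mean_f), 0, noise_sd))
  else mean_f
  frap_trace(synapse_id = synapse_id, site = site, pre_bleach = pre_bleach,
             t_min = timepoints_min, intensity = y, channel = channel)
}

#' Simulate one donor/acceptor FRET observation
#'
#' Emission model: observed donor `= donor_true * (1 - E)`; the FRET channel
#' carries `acceptor_true * E * coupling + bleed_through`; the directly
#' excited acceptor channel carries `acceptor_true`. The coupling constant
#' folds detector gain and spectral overlap into one factor `<= 1`, so the
#' FRET-channel value can never exceed the total-acceptor value. Acceptor
#' photobleaching (`bleached = TRUE`) zeroes the acceptor and restores the
#' donor to `donor_true` (dequenching).
#'
#' @param kin A [kinetic_truth()] supplying `E`.
#' @param donor_true,acceptor_true Unquenched fluorophore intensities (`>= 0`).
#' @param noise_sd Additive Gaussian noise SD per channel.
#' @param seed Integer seed.
#' @param coupling FRET-channel coupling constant in `(0, 1]` (default 0.5).
#' @param bleed_through Constant FRET-channel offset emulating spectral
#'   bleed-through (default 0).
#' @param bleached Whether the acceptor has been photobleached.
#' @param donor_quenched Whether the donor pHluorin is pH-quenched (acidic
#'   saline), which abolishes both donor emission and energy transfer.
#' @return Named numeric vector with elements `donor`, `fret`, `total`.
#' @export
simulate_fret_pair <- function(kin, donor_true = 100, acceptor_true = 100,
                               noise_sd = 0, seed = 1L, coupling = 0.5,
                               bleed_through = 0, bleached = FALSE,
                               donor_quenched = FALSE) {
  stopifnot(inherits(kin, "kinetic_truth"))
  stop_if_not_scalar_num(donor_true, "donor_true", 0)
  stop_if_not_scalar_num(acceptor_true, "acceptor_true", 0)
  stop_if_not_scalar_num(coupling, "coupling", 0, 1, strict_lower = TRUE)
  stop_if_not_scalar_num(noise_sd, "noise_sd", 0)
  E <- kin$fret_efficiency
  acc <- if (bleached) 0 else acceptor_true
  don <- if (donor_quenched) 0 else donor_true
  transfer <- if (donor_quenched || bleached) 0 else E
  vals <- c(donor = don * (1 - transfer),
            fret = acc * transfer * coupling + bleed_through,
            total = acc)
  if (noise_sd > 0)
    vals <- pmax(0, with_seed(seed, vals + stats::rnorm(3, 0, noise_sd)))
  vals
}

#' Simulate an acceptor-photobleaching time course
#'
#' Frames before `n_pre + 1` are unbleached; from the bleach frame onward the
#' acceptor is zero and the donor is dequenched. Noise is fractional (its SD
#' is `noise_frac` of each channel's noiseless value), matching how
#' photobleaching series are normally corrupted by laser and detector noise.
#'
#' @inheritParams simulate_fret_pair
#' @param n_pre,n_post Frame counts before and after the bleach event.
#' @param noise_frac Fractional noise level (e.g. 0.02 for 2%).
#' @return Data frame with columns `frame`, `donor`, `fret`, `total` and
#'   attribute `bleach_index = n_pre + 1`.
#' @export
simulate_bleach_series <- function(kin, donor_true = 100, acceptor_true = 100,
                                   n_pre = 6, n_post = 24, noise_frac = 0,
                                   seed = 1L, coupling = 0.5,
                                   bleed_through = 0) {
  frames <- lapply(seq_len(n_pre + n_post), function(i) {
    simulate_fret_pair(kin, donor_true, acceptor_true, noise_sd = 0,
                       coupling = coupling, bleed_through = bleed_through,
                       bleached = i > n_pre)
  })
  out <- as.data.frame(do.call(rbind, frames))
  out$frame <- seq_len(nrow(out))
  if (noise_frac > 0) {
    out[c("donor", "fret", "total")] <- with_seed(seed, {
      m <- as.matrix(out[c("donor", "fret", "total")])
      pmax(0, m + stats::rnorm(length(m), 0, noise_frac * m))
    })
  }
  out <- out[c("frame", "donor", "fret", "total")]
  attr(out, "bleach_index") <- n_pre + 1L
  out
}

#' Simulate a pH-quench control series for the FRET channel
#'
#' Under neutral saline (HBS) the FRET channel carries transfer signal plus
#' any bleed-through; under acidic saline (MES) the pH-sensitive donor is
#' quenched so only bleed-through remains. A surface-dependent FRET signal
#' therefore collapses toward 0, while a bleed-through-only control stays
#' near 1 when normalized to HBS.
#'
#' @inheritParams simulate_bleach_series
#' @param n_hbs,n_mes Frame counts per condition.
#' @return List with numeric vectors `hbs` and `mes` of FRET-channel means.
#' @export
simulate_ph_quench <- function(kin, acceptor_true = 100, n_hbs = 4, n_mes = 7,
                               noise_frac = 0, seed = 1L, coupling = 0.5,
                               bleed_through = 0) {
  hbs <- rep(simulate_fret_pair(kin, acceptor_true = acceptor_true,
                                coupling = coupling,
                                bleed_through = bleed_through)[["fret"]], n_hbs)
  mes <- rep(simulate_fret_pair(kin, acceptor_true = acceptor_true,
                                coupling = coupling,
                                bleed_through = bleed_through,
                                donor_quenched = TRUE)[["fret"]], n_mes)
  if (noise_frac > 0) {
    with_seed(seed, {
      hbs <- pmax(0, hbs + stats::rnorm(n_hbs, 0, noise_frac * pmax(hbs, 1)))
      mes <- pmax(0, mes + stats::rnorm(n_mes, 0, noise_frac * pmax(mes, 1)))
    })
  }
  list(hbs = hbs, mes = mes)
}

#' Simulate paired pre/post vesicle scenes
#'
#' Renders `n_vesicles_pre` bright circular vesicles, then a post-reveal image
#' containing the same vesicles plus `n_vesicles_post - n_vesicles_pre` new
#' ones, emulating the intracellular-pool reveal where collapsing organellar
#' pH unquenches receptors held in large vesicles. Vesicles are isotropic
#' Gaussians whose full width at half maximum equals `diameter_um`.
#'
#' @param kin A [kinetic_truth()] supplying the planted counts.
#' @param width_um,height_um Scene extent.
#' @param diameter_um Vesicle diameter (default 0.75, the size class counted
#'   in the assay).
#' @param peak Vesicle peak intensity above background.
#' @param background,gaussian_sd Background level and additive noise SD.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_sep_um Minimum vesicle separation.
#' @param seed Integer seed.
#' @return List with `pre` and `post` [channel_image()]s and data frames
#'   `truth_pre`, `truth_post` of planted centres (`x_um`, `y_um`).
#' @export
simulate_vesicle_pair <- function(kin, width_um = 20, height_um = 20,
                                  diameter_um = 0.75, peak = 400,
                                  background = 10, gaussian_sd = 0,
                                  pixel_size_um = 0.1, min_sep_um = 2,
                                  seed = 1L) {
  stopifnot(inherits(kin, "kinetic_truth"))
  sigma <- diameter_um / (2 * sqrt(2 * log(2)))  # FWHM = diameter
  n_post <- kin$n_vesicles_post
  pts <- with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0); tries <- 0
    while (length(xs) < n_post && tries < 10000) {
      tries <- tries + 1
      x <- stats::runif(1, 2, width_um - 2)
      y <- stats::runif(1, 2, height_um - 2)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep_um) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n_post)
      stop("could not place vesicles with the requested separation",
           call. = FALSE)
    data.frame(x_um = xs, y_um = ys)
  })
  render <- function(n, stream) {
    tr <- scene_truth(
      puncta = data.frame(x_um = pts$x_um[seq_len(n)],
                          y_um = pts$y_um[seq_len(n)],
                          peak = peak, sigma_um = sigma, synaptic = FALSE),
      width_um = width_um, height_um = height_um, background = background,
      poisson_scale = 0, gaussian_sd = gaussian_sd,
      pixel_size_um = pixel_size_um, seed = child_seed(seed, stream))
    make_dendrite_scene(tr, channels = list(
      list(name = "vesicle", puncta = "all")))$images$vesicle
  }
  list(pre = render(kin$n_vesicles_pre, 1),
       post = render(n_post, 2),
       truth_pre = pts[seq_len(kin$n_vesicles_pre), ],
       truth_post = pts)
}

#' Simulate a co-IP spectral-count table with planted effects
#'
#' Weighted spectrum counts are drawn from a gamma-Poisson (negative
#' binomial) mixture: protein baselines are log-normal shares of each
#' sample's library size, DZP samples multiply flagged proteins by their
#' planted DZP/vehicle ratio (`Inf` plants a protein expressed only under
#' DZP), and IgG control samples receive `igg_background` times each
#' protein's specific-IP mean. Exclusive-unique-peptide counts are generated
#' `>= 1` wherever a protein is detected and grow with the count.
#'
#' @param planted Named numeric vector mapping protein ids (e.g. `"P007"`)
#'   to true DZP/V ratios; unnamed proteins are null (ratio 1).
#' @param n_proteins Number of proteins.
#' @param samples Data frame with columns `sample`, `treatment`
#'   (`"VEH"`, `"DZP"` or `"IgG"`) and `animal`. Needs at least 2 VEH, 2 DZP
#'   and 1 IgG samples.
#' @param library_sizes Per-sample expected total counts; recycled.
#' @param igg_background IgG binding level as a fraction of the specific-IP
#'   mean, in `[0, 1)`.
#' @param dispersion Negative-binomial dispersion `alpha` (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param seed Integer seed.
#' @return A [spectral_count_table()] with attribute `truth`, a data frame of
#'   planted per-protein ratios.
#' @export
simulate_spectral_counts <- function(planted = numeric(0), n_proteins = 400,
                                     samples = default_coip_samples(),
                                     library_sizes = 1e4,
                                     igg_background = 0.05, dispersion = 0.3,
                                     seed = 1L) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample", "treatment") %in% names(samples)))
  n_veh <- sum(samples$treatment == "VEH")
  n_dzp <- sum(samples$treatment == "DZP")
  n_igg <- sum(samples$treatment == "IgG")
  if (n_veh < 2 || n_dzp < 2 || n_igg < 1)
    stop("need >= 2 VEH, >= 2 DZP and >= 1 IgG samples", call. = FALSE)
  stop_if_not_scalar_num(igg_background, "igg_background", 0)
  if (igg_background >= 1) stop("`igg_background` must be < 1", call. = FALSE)
  stop_if_not_scalar_num(dispersion, "dispersion", 0)
  ns <- nrow(samples)
  library_sizes <- rep_len(library_sizes, ns)
  prot <- sprintf("P%03d", seq_len(n_proteins))
  ratio <- rep(1, n_proteins); names(ratio) <- prot
  if (length(planted)) {
    unknown <- setdiff(names(planted), prot)
    if (length(unknown))
      stop("planted ids not among proteins: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    ratio[names(planted)] <- planted
  }
  with_seed(seed, {
    w <- stats::rlnorm(n_proteins, 0, 1)
    w <- w / sum(w)                       # baseline library share per protein
    base <- outer(w, library_sizes)       # protein x sample expected counts
    mu <- base
    is_dzp <- samples$treatment == "DZP"
    is_veh <- samples$treatment == "VEH"
    is_igg <- samples$treatment == "IgG"
    fin <- is.finite(ratio)
    mu[fin, is_dzp] <- base[fin, is_dzp] * ratio[fin]
    if (any(!fin)) {                      # DZP-only proteins
      mu[!fin, is_veh] <- 0
      mu[!fin, is_dzp] <- base[!fin, is_dzp]
    }
    specific_mean <- rowMeans(mu[, is_dzp | is_veh, drop = FALSE])
    mu[, is_igg] <- specific_mean * igg_background
    draw <- function(m) {
      if (dispersion > 0) stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
      else stats::rpois(length(m), m)
    }
    counts <- matrix(draw(mu), n_proteins, ns,
                     dimnames = list(prot, samples$sample))
    counts[mu == 0] <- 0
    pept <- matrix(0L, n_proteins, ns, dimnames = dimnames(counts))
    det <- counts > 0
    pept[det] <- 1L + stats::rpois(sum(det), sqrt(counts[det]) / 2)
    tab <- spectral_count_table(counts, pept, samples)
    attr(tab, "truth") <- data.frame(protein = prot, true_ratio = ratio,
                                     row.names = NULL)
    tab
  })
}

#' Default co-IP sample sheet: 3 vehicle, 3 DZP, 1 IgG
#'
#' Mirrors the study design retained for quantification: three animals per
#' treatment group plus a nonspecific-IgG control pulldown.
#'
#' @return Data frame with columns `sample`, `treatment`, `animal`.
#' @export
default_coip_samples <- function() {
  data.frame(
    sample = c("VEH1", "VEH2", "VEH3", "DZP1", "DZP2", "DZP3", "IgG1"),
    treatment = c("VEH", "VEH", "VEH", "DZP", "DZP", "DZP", "IgG"),
    animal = c("v1", "v2", "v3", "d1", "d2", "d3", "ig1")
  )
}
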