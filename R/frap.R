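#' Per-synapse FRAP intensity trace
#'
#' Holds one photobleached site's pre-bleach intensity and its post-bleach
#' time series, acquired at `t = 0, 2, ...` minutes.
#'
#' @param synapse_id Identifier of the bleached site.
#' @param site `"synaptic"` or `"extrasynaptic"`.
#' @param pre_bleach Pre-bleach fluorescence (`> 0`).
#' @param t_min Strictly increasing times in minutes, starting at 0.
#' @param intensity Post-bleach intensities, same length as `t_min`.
#' @param channel Channel label.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(synapse_id, site = c("synaptic", "extrasynaptic"),
                       pre_bleach, t_min, intensity, channel = "receptor") {
  site <- match.arg(site)
  stop_if_not_scalar_num(pre_bleach, "pre_bleach", 0, strict_lower = TRUE)
  if (length(t_min) != length(intensity))
    stop("`t_min` and `intensity` lengths differ", call. = FALSE)
  if (t_min[1] != 0 || is.unsorted(t_min, strictly = TRUE))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  structure(list(synapse_id = as.character(synapse_id), site = site,
                 pre_bleach = pre_bleach,
                 series = data.frame(t_min = t_min, intensity = intensity),
                 channel = channel),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace %s (%s): pre = %.3g, %d timepoints over %g min>\n",
              x$synapse_id, x$site, x$pre_bleach, nrow(x$series),
              max(x$series$t_min)))
  invisible(x)
}

#' Normalize a FRAP trace to percent of the first post-bleach frame
#'
#' Post-bleach intensities are first expressed relative to the pre-bleach
#' intensity, then rescaled to percent of the `t = 0` value:
#' `r(t) = (I(t)/pre) / (I(0)/pre) * 100 = I(t)/I(0) * 100`, so `r(0)` is
#' exactly 100. Recovery on this scale routinely exceeds 100%.
#'
#' @param trace A [frap_trace()].
#' @return A `normalized_recovery`: data frame with `t_min` and
#'   `percent_of_t0`, carrying the pre-bleach-fraction series as attribute
#'   `pre_fraction` (used for model fitting, where the t0-normalized scale
#'   would diverge as `I(0) -> 0`).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  i0 <- trace$series$intensity[1]
  if (i0 <= 0) stop("unusable bleach baseline: I(0) <= 0", call. = FALSE)
  out <- data.frame(t_min = trace$series$t_min,
                    percent_of_t0 = trace$series$intensity / i0 * 100)
  structure(out, class = c("normalized_recovery", class(out)),
            pre_fraction = trace$series$intensity / trace$pre_bleach)
}

#' Average normalized recoveries across synapses
#'
#' Pointwise mean and standard error over synapses sharing one acquisition
#' grid. Traces on different grids are rejected rather than interpolated.
#'
#' @param traces List of `normalized_recovery` objects.
#' @return Data frame with `t_min`, `mean`, `sem`, `n`.
#' @export
average_recovery <- function(traces) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  grid <- traces[[1]]$t_min
  for (tr in traces)
    if (!isTRUE(all.equal(tr$t_min, grid)))
      stop("traces must share the same time grid (no interpolation)",
           call. = FALSE)
  m <- vapply(traces, function(tr) tr$percent_of_t0,
              numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n <- ncol(m)
  data.frame(t_min = grid, mean = rowMeans(m),
             sem = apply(m, 1, stats::sd) / sqrt(n), n = n)
}

#' Fit two-pool exchange kinetics to a FRAP trace
#'
#' Least-squares fit of the two-pool model
#' `g(t) = b + m (1 - b) (1 - exp(-k t))` on the pre-bleach-fraction scale
#' (`g = I/pre`), with bounds `k >= 0`, `0 <= m <= 1`, `0 <= b < 1`. The
#' t0-normalized percent scale is deliberately not used for fitting because
#' it diverges for deep bleaches.
#'
#' @param trace A [frap_trace()], or a `normalized_recovery` carrying its
#'   `pre_fraction` attribute.
#' @param start Optional named list of starting values `k`, `mobile`,
#'   `bleach`.
#' @return List with `k_exchange`, `mobile_fraction`, `bleach_depth`,
#'   `converged`, `resid_norm`. On non-convergence the parameters are `NA`
#'   and `converged` is `FALSE`.
#' @export
fit_exchange <- function(trace, start = NULL) {
  if (inherits(trace, "frap_trace")) {
    t_min <- trace$series$t_min
    g <- trace$series$intensity / trace$pre_bleach
  } else if (inherits(trace, "normalized_recovery")) {
    t_min <- trace$t_min
    g <- attr(trace, "pre_fraction")
    if (is.null(g))
      stop("normalized recovery lacks the pre-bleach fraction series",
           call. = FALSE)
  } else stop("`trace` must be a frap_trace or normalized_recovery",
              call. = FALSE)
  if (length(t_min) < 5)
    stop("need at least 5 timepoints to fit exchange kinetics", call. = FALSE)
  failed <- list(k_exchange = NA_real_, mobile_fraction = NA_real_,
                 bleach_depth = NA_real_, converged = FALSE,
                 resid_norm = NA_real_)
  b0 <- min(max(g[1], 1e-4), 0.95)
  span <- max(g) - g[1]
  if (is.null(start))
    start <- list(k = 0.05,
                  mobile = min(max(span / max(1 - b0, 1e-6), 0.05), 1),
                  bleach = b0)
  df <- data.frame(t = t_min, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ b + m * (1 - b) * (1 - exp(-k * t)), data = df,
                      start = list(k = start$k, m = start$mobile,
                                   b = start$bleach),
                      lower = c(0, 0, 0), upper = c(Inf, 1, 0.999),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (e.g. flat) traces: fall back to the boundary solution
    if (stats::sd(g) < 1e-12)
      return(list(k_exchange = 0, mobile_fraction = 0, bleach_depth = g[1],
                  converged = TRUE, resid_norm = 0))
    return(failed)
  }
  cf <- stats::coef(fit)
  list(k_exchange = unname(cf["k"]), mobile_fraction = unname(cf["m"]),
       bleach_depth = unname(cf["b"]), converged = TRUE,
       resid_norm = sqrt(sum(stats::residuals(fit)^2)))
}

#' Cohort-constrained exchange-rate estimation across conditions
#'
#' Per-trace fits of the two-pool model suffer a strong trade-off between
#' the exchange rate and the mobile fraction when the acquisition window
#' covers less than about one time constant, which skews single-trace rate
#' estimates. Conditions imaged with one bleach protocol share the mobile
#' fraction and bleach depth, so this estimator first fits the group-averaged
#' curves of all conditions jointly with shared `m` and `b` and one `k` per
#' condition, then re-fits only `k` per trace holding `m` and `b` at the
#' cohort estimates. The per-trace rates (and their median) are then close
#' to unbiased even for slow exchange.
#'
#' @param groups Named list of conditions, each a list of [frap_trace()]s
#'   sharing one time grid.
#' @return List with `shared` (named vector `mobile_fraction`,
#'   `bleach_depth`), `group_k` (named vector of cohort-level rates) and
#'   `per_trace` (named list of per-trace `k` vectors, `NA` where a trace
#'   fit failed).
#' @export
fit_exchange_cohort <- function(groups) {
  if (length(groups) < 1 || is.null(names(groups)))
    stop("`groups` must be a named list of trace sets", call. = FALSE)
  t_min <- groups[[1]][[1]]$series$t_min
  gmat <- lapply(groups, function(traces) {
    m <- vapply(traces, function(tr) {
      if (!isTRUE(all.equal(tr$series$t_min, t_min)))
        stop("all traces must share one time grid", call. = FALSE)
      tr$series$intensity / tr$pre_bleach
    }, numeric(length(t_min)))
    matrix(m, nrow = length(t_min))
  })
  ng <- length(groups)
  df <- data.frame(t = rep(t_min, ng),
                   g = unlist(lapply(gmat, rowMeans)),
                   grp = rep(seq_len(ng), each = length(t_min)))
  knames <- paste0("k", seq_len(ng))
  rhs <- paste0("b + m * (1 - b) * (1 - exp(-(",
                paste(sprintf("(grp == %d) * %s", seq_len(ng), knames),
                      collapse = " + "),
                ") * t))")
  start <- c(stats::setNames(as.list(rep(0.03, ng)), knames),
             list(m = 0.5, b = max(df$g[1], 1e-3)))
  fit <- minpack.lm::nlsLM(stats::as.formula(paste("g ~", rhs)), data = df,
                           start = start,
                           lower = c(rep(0, ng), 0, 0),
                           upper = c(rep(Inf, ng), 1, 0.999),
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  m <- cf[["m"]]; b <- cf[["b"]]
  per_trace <- lapply(seq_len(ng), function(gi) {
    k0 <- max(cf[[knames[gi]]], 1e-3)
    apply(gmat[[gi]], 2, function(gvec) {
      ff <- tryCatch(
        minpack.lm::nlsLM(gvec ~ b + m * (1 - b) * (1 - exp(-k * t)),
                          data = data.frame(t = t_min, gvec = gvec),
                          start = list(k = k0), lower = 0),
        error = function(e) NULL)
      if (is.null(ff)) NA_real_ else stats::coef(ff)[["k"]]
    })
  })
  names(per_trace) <- names(groups)
  list(shared = c(mobile_fraction = m, bleach_depth = b),
       group_k = stats::setNames(cf[knames], names(groups)),
       per_trace = per_trace)
}

#' Compare FRAP recovery between treatment groups over time
#'
#' Two-factor fixed-effects ANOVA (treatment x time) on the t0-normalized
#' recoveries, followed by Tukey's honestly-significant-difference test on
#' the treatment factor and within each timepoint. Each synapse contributes
#' one observation per timepoint.
#'
#' @param groups Named list of groups; each group is a list of
#'   `normalized_recovery` objects sharing one time grid across all groups.
#' @return List with `anova` (the treatment/time/interaction F table),
#'   `tukey_treatment` (overall treatment contrasts with adjusted p), and
#'   `per_timepoint` (data frame of Tukey-adjusted treatment contrasts at
#'   each timepoint).
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2 || is.null(names(groups)))
    stop("`groups` must be a named list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 traces", call. = FALSE)
  grid <- groups[[1]][[1]]$t_min
  long <- do.call(rbind, lapply(names(groups), function(gn) {
    do.call(rbind, lapply(seq_along(groups[[gn]]), function(i) {
      tr <- groups[[gn]][[i]]
      if (!isTRUE(all.equal(tr$t_min, grid)))
        stop("all traces must share one time grid", call. = FALSE)
      data.frame(treatment = gn, trace = paste0(gn, "_", i),
                 t_min = tr$t_min, recovery = tr$percent_of_t0)
    }))
  }))
  long$treatment <- factor(long$treatment)
  long$time <- factor(long$t_min)
  if (nlevels(long$time) < 2)
    stop("need at least two timepoints", call. = FALSE)
  fit <- stats::aov(recovery ~ treatment * time, data = long)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  tuk <- stats::TukeyHSD(fit, which = "treatment")$treatment
  per_tp <- do.call(rbind, lapply(levels(long$time), function(tp) {
    sub <- long[long$time == tp, ]
    f <- stats::aov(recovery ~ treatment, data = sub)
    tk <- stats::TukeyHSD(f)$treatment
    data.frame(t_min = as.numeric(tp), contrast = rownames(tk),
               diff = tk[, "diff"], p_adj = tk[, "p adj"], row.names = NULL)
  }))
  list(anova = tab, tukey_treatment = tuk, per_timepoint = per_tp,
       n_traces = table(long$treatment[!duplicated(long$trace)]))
}
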