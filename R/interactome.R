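#' Protein-by-sample spectral-count table
#'
#' Container for label-free co-IP quantification: a matrix of weighted
#' spectrum counts, a parallel matrix of exclusive unique peptide counts and
#' per-sample metadata with treatment (`VEH`, `DZP`, or the nonspecific
#' `IgG` control) and animal id. Proteins with no counts anywhere are
#' dropped at construction.
#'
#' @param counts Numeric protein x sample matrix of weighted spectrum
#'   counts (`>= 0`), with protein row names and sample column names.
#' @param unique_peptides Integer matrix of exclusive unique peptide counts,
#'   same dimensions and dimnames.
#' @param sample_meta Data frame with columns `sample`, `treatment` and
#'   optionally `animal`; `sample` must match the count columns.
#' @return An object of class `spectral_count_table`.
#' @export
spectral_count_table <- function(counts, unique_peptides, sample_meta) {
  counts <- as.matrix(counts)
  unique_peptides <- as.matrix(unique_peptides)
  sample_meta <- as.data.frame(sample_meta)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs protein row names and sample column names",
         call. = FALSE)
  if (!identical(dim(counts), dim(unique_peptides)))
    stop("count and peptide matrices must match in shape", call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (!all(c("sample", "treatment") %in% names(sample_meta)))
    stop("`sample_meta` needs `sample` and `treatment` columns", call. = FALSE)
  if (!identical(as.character(sample_meta$sample), colnames(counts)))
    stop("`sample_meta$sample` must match count columns in order",
         call. = FALSE)
  bad <- setdiff(unique(sample_meta$treatment), c("VEH", "DZP", "IgG"))
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nonzero <- rowSums(counts) > 0
  structure(list(counts = counts[nonzero, , drop = FALSE],
                 unique_peptides = unique_peptides[nonzero, , drop = FALSE],
                 sample_meta = sample_meta),
            class = "spectral_count_table",
            n_dropped_empty = sum(!nonzero))
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("<spectral_count_table: %d proteins x %d samples (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%d %s", table(x$sample_meta$treatment),
                            names(table(x$sample_meta$treatment))),
                    collapse = ", ")))
  invisible(x)
}

#' Post-search inclusion filter for co-IP spectral counts
#'
#' Retains a protein only when all three criteria hold:
#' \enumerate{
#'   \item peptide evidence: at least `min_peptides` exclusive unique
#'     peptides in some sample;
#'   \item detection breadth: detected (count `> 0`) in at least
#'     `min_samples_overall` specific-IP samples overall, or in at least
#'     `min_samples_in_group` samples of one treatment group;
#'   \item specificity: at least `igg_enrichment`:1 enrichment over the IgG
#'     reference in at least `igg_support` specific-IP samples (a zero IgG
#'     reference satisfies the enrichment clause vacuously, so proteins
#'     absent from the IgG control are never removed by it).
#' }
#' The IgG reference is the per-protein mean over IgG samples
#' (`igg_mode = "pooled"`) or their maximum (`"max"`). Removal reasons are
#' logged per protein.
#'
#' @param table A [spectral_count_table()] containing IgG samples.
#' @param min_peptides,min_samples_overall,min_samples_in_group,igg_enrichment,igg_support
#'   Filter thresholds; defaults follow the published criteria (2, 3, 2,
#'   3.0, 3).
#' @param igg_mode `"pooled"` (default) or `"max"`.
#' @return The filtered [spectral_count_table()] with attribute
#'   `removal_log`, a data frame of `protein`, `reason`.
#' @export
apply_inclusion_filter <- function(table, min_peptides = 2,
                                   min_samples_overall = 3,
                                   min_samples_in_group = 2,
                                   igg_enrichment = 3.0, igg_support = 3,
                                   igg_mode = c("pooled", "max")) {
  stopifnot(inherits(table, "spectral_count_table"))
  igg_mode <- match.arg(igg_mode)
  tr <- table$sample_meta$treatment
  if (!any(tr == "IgG"))
    stop("inclusion filter requires IgG control samples", call. = FALSE)
  spec <- tr %in% c("VEH", "DZP")
  cts <- table$counts[, spec, drop = FALSE]
  pep <- table$unique_peptides
  igg <- table$counts[, tr == "IgG", drop = FALSE]
  igg_ref <- if (igg_mode == "pooled") rowMeans(igg) else
    apply(igg, 1, max)
  ok_pep <- apply(pep, 1, max) >= min_peptides
  det <- cts > 0
  n_overall <- rowSums(det)
  grp <- tr[spec]
  n_by_group <- vapply(unique(grp), function(g)
    rowSums(det[, grp == g, drop = FALSE]), numeric(nrow(cts)))
  ok_det <- n_overall >= min_samples_overall |
    apply(n_by_group, 1, max) >= min_samples_in_group
  # a zero IgG reference satisfies 3:1 enrichment vacuously in every sample
  enr <- cts >= igg_enrichment * igg_ref
  ok_igg <- rowSums(enr) >= igg_support | igg_ref == 0
  keep <- ok_pep & ok_det & ok_igg
  reason <- character(nrow(cts))
  reason[!ok_pep] <- "insufficient unique peptides"
  reason[ok_pep & !ok_det] <- "detected in too few samples"
  reason[ok_pep & ok_det & !ok_igg] <- "insufficient IgG enrichment"
  removal_log <- data.frame(protein = rownames(cts)[!keep],
                            reason = reason[!keep], row.names = NULL)
  out <- spectral_count_table(table$counts[keep, , drop = FALSE],
                              table$unique_peptides[keep, , drop = FALSE],
                              table$sample_meta)
  attr(out, "removal_log") <- removal_log
  out
}

#' DZP/vehicle association ratios with sentinel classes
#'
#' For each protein the ratio of mean DZP counts to mean vehicle counts is
#' computed over specific-IP samples, with a two-sided Student's t-test
#' (equal variances) on the per-sample counts. Proteins absent from all
#' vehicle samples but present under DZP are classed `NF_V` (ratio
#' undefined); the mirror case is `NF_DZP`; proteins absent everywhere are
#' dropped with a log entry. Finite-ratio proteins are classed `increased`
#' (`ratio > 1`), `decreased` (`ratio < 1`) or `unchanged` (`ratio == 1`).
#' Records are sorted by descending ratio with the NF classes grouped last,
#' mirroring the layout of published association tables.
#'
#' @param table A (filtered) [spectral_count_table()] with `>= 2` samples in
#'   each of VEH and DZP.
#' @param p_adjust `"none"` (default, matching the raw p-values reported in
#'   the tables) or any method accepted by [stats::p.adjust()].
#' @return Data frame of class `association_records`: `protein`, `ratio`
#'   (`NA` for NF classes), `mean_dzp`, `mean_veh`, `p_value`, `class`;
#'   attribute `dropped_log` lists proteins with zero counts in both groups.
#' @export
compute_ratios <- function(table, p_adjust = "none") {
  stopifnot(inherits(table, "spectral_count_table"))
  tr <- table$sample_meta$treatment
  if (sum(tr == "VEH") < 2 || sum(tr == "DZP") < 2)
    stop("ratio analysis needs >= 2 samples per treatment group",
         call. = FALSE)
  veh <- table$counts[, tr == "VEH", drop = FALSE]
  dzp <- table$counts[, tr == "DZP", drop = FALSE]
  mv <- rowMeans(veh)
  md <- rowMeans(dzp)
  both_zero <- mv == 0 & md == 0
  dropped <- rownames(table$counts)[both_zero]
  keep <- !both_zero
  prot <- rownames(table$counts)[keep]
  mv <- mv[keep]; md <- md[keep]
  cls <- ifelse(mv == 0, "NF_V",
         ifelse(md == 0, "NF_DZP",
         ifelse(md / mv > 1, "increased",
         ifelse(md / mv < 1, "decreased", "unchanged"))))
  ratio <- ifelse(cls %in% c("NF_V", "NF_DZP"), NA_real_, md / mv)
  dzpk <- dzp[keep, , drop = FALSE]
  vehk <- veh[keep, , drop = FALSE]
  p <- vapply(seq_along(prot), function(i) {
    x <- dzpk[i, ]
    y <- vehk[i, ]
    tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(protein = prot, ratio = ratio, mean_dzp = md,
                    mean_veh = mv, p_value = p, class = cls,
                    row.names = NULL)
  grp <- match(out$class, c("increased", "decreased", "unchanged",
                            "NF_V", "NF_DZP"))
  finite_first <- ifelse(grp <= 3, 0L, grp)
  out <- out[order(finite_first, -ifelse(is.na(out$ratio), -Inf, out$ratio)), ]
  rownames(out) <- NULL
  structure(out, class = c("association_records", class(out)),
            dropped_log = dropped)
}

#' Partition association records into increased and decreased sets
#'
#' Increased association means `ratio > 1` or not found in vehicle (`NF_V`);
#' decreased means `ratio < 1` or not found under DZP (`NF_DZP`); a ratio of
#' exactly 1 is unchanged. The three classes partition the records.
#'
#' @param records An `association_records` data frame (or any data frame
#'   with `ratio` and `class` columns, e.g. the packaged table fixture via
#'   [as_association_records()]).
#' @return List with `increased` and `decreased` record subsets and `counts`
#'   (named vector: `increased`, `nf_v`, `decreased`, `nf_dzp`,
#'   `unchanged`).
#' @export
classify_association <- function(records) {
  stopifnot(is.data.frame(records), all(c("ratio", "class") %in%
                                        names(records)))
  inc <- records[records$class %in% c("increased", "NF_V"), , drop = FALSE]
  dec <- records[records$class %in% c("decreased", "NF_DZP"), , drop = FALSE]
  unch <- records[records$class == "unchanged", , drop = FALSE]
  list(increased = inc, decreased = dec,
       counts = c(increased = nrow(inc),
                  nf_v = sum(records$class == "NF_V"),
                  decreased = nrow(dec),
                  nf_dzp = sum(records$class == "NF_DZP"),
                  unchanged = nrow(unch)))
}

#' Convert association ratios to signed pathway-analysis fold changes
#'
#' Ratio values of at least 1 pass through unchanged; ratios between 0 and 1
#' become their negative inverse (`-1/x`); proteins never found in vehicle
#' (`NF_V`) are assigned the sentinel `+1e99` and proteins never found under
#' DZP (`NF_DZP`) the sentinel `-1e99`, so pathway software treats them as
#' extreme changes of the right sign.
#'
#' @param records An `association_records` data frame.
#' @return Named numeric vector mapping protein id to signed fold change.
#' @export
to_pathway_input <- function(records) {
  stopifnot(is.data.frame(records), all(c("protein", "ratio", "class") %in%
                                        names(records)))
  fc <- ifelse(records$class == "NF_V", 1e99,
        ifelse(records$class == "NF_DZP", -1e99,
        ifelse(records$ratio >= 1, records$ratio, -1 / records$ratio)))
  stats::setNames(fc, records$protein)
}

#' Generic overrepresentation test over an annotation map
#'
#' For each annotation term, the fold enrichment of the hit set over the
#' background and a two-sided Fisher's exact p-value on the 2x2 table
#' (hit/non-hit x in-term/not-in-term), Bonferroni-corrected over the tested
#' terms. The annotation source is user-supplied (e.g. a GO slice); no
#' database is queried.
#'
#' @param hit_set Character vector of protein ids, a subset of `background`.
#' @param annotation Named list mapping term to its protein-id set; each set
#'   must be a subset of `background`.
#' @param background Character vector of all tested protein ids.
#' @return Data frame per term: `term`, `n_term`, `n_hit_in_term`,
#'   `fold_enrichment`, `p_raw`, `p_bonferroni`, sorted by `p_raw`.
#' @export
overrepresentation <- function(hit_set, annotation, background) {
  if (!length(background) || !length(hit_set))
    stop("`hit_set` and `background` must be non-empty", call. = FALSE)
  hit_set <- unique(hit_set); background <- unique(background)
  if (!all(hit_set %in% background))
    stop("`hit_set` must be a subset of `background`", call. = FALSE)
  N <- length(background); n <- length(hit_set)
  rows <- lapply(names(annotation), function(term) {
    set <- unique(annotation[[term]])
    if (!all(set %in% background))
      stop("annotation term '", term, "' is not a subset of the background",
           call. = FALSE)
    K <- length(set)
    k <- length(intersect(hit_set, set))
    fe <- (k / n) / (K / N)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(term = term, n_term = K, n_hit_in_term = k,
               fold_enrichment = fe, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw), ]
}
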