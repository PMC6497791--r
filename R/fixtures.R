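#' Published gamma2 co-IP association table (transcribed)
#'
#' Transcription of the published DZP/vehicle association tables for the
#' gamma2 GABA-A receptor co-IP interactome: 46 proteins with increased
#' association (10 of them never found in vehicle samples, `NF-V`) and 23
#' with decreased association (7 never found under DZP, `NF-DZP`). The
#' `ratio` column is `NA` for NF rows; one protein (RAB10) has no reported
#' p-value.
#'
#' @return Data frame with 69 rows: `gene`, `uniprot`, `ratio`, `nf`
#'   (`NA`, `"NF-V"` or `"NF-DZP"`), `p_value`, `direction`
#'   (`"increased"`/`"decreased"` table of origin).
#' @export
dzp_association_table <- function() {
  inc <- data.frame(
    ratio = c(9.6, 9.5, 7.0, 5.4, 5.4, 5.0, 5.0, 4.9, 4.7, 4.2, 4.2, 4.2,
              4.0, 3.8, 3.3, 2.6, 2.4, 2.4, 2.4, 2.2, 1.9, 1.8, 1.8, 1.8,
              1.7, 1.7, 1.7, 1.7, 1.6, 1.6, 1.6, 1.5, 1.5, 1.5, 1.5, 1.3,
              rep(NA_real_, 10)),
    p_value = c(8.9e-2, 4.3e-2, 5.9e-2, 2.7e-2, 3.1e-2, 5.0e-3, 7.8e-2,
                1.9e-5, 6.4e-2, 6.4e-2, 7.2e-2, 3.3e-2, 7.9e-2, 8.6e-2,
                4.2e-2, 8.0e-2, 2.2e-2, 9.2e-2, 3.7e-2, 3.8e-2, NA,
                9.6e-2, 1.8e-2, 1.3e-2, 9.1e-2, 8.2e-2, 4.0e-2, 7.1e-2,
                5.7e-2, 1.8e-2, 1.6e-2, 5.3e-2, 7.8e-3, 8.1e-2, 7.5e-2,
                3.3e-2,
                7.9e-4, 1.0e-2, 1.6e-2, 3.7e-2, 4.1e-2, 6.0e-2, 6.3e-2,
                1.2e-6, 2.8e-6, 2.8e-6),
    uniprot = c("Q14BI2", "P12960", "P11276", "E9Q4P0", "Q62277", "Q9QXY6",
                "P48774", "P38647", "Q91V41", "P48758", "Q8K3F6",
                "A0A0R4J036", "Q921I1", "Q9CYZ2", "Q99KI0", "Q9EQF6",
                "P56480", "P46096", "Q6P1J1", "Q9DB20", "P61027", "P63017",
                "P63011", "P17426-2", "P18760", "Q9Z2I9", "P63328",
                "Q8R191", "Q8BHJ7", "O35129", "P61982", "P07901", "P67778",
                "Q3UGC7", "Q8VEM8", "P60710",
                "P62259", "P63044", "P46660", "Q9QYM9", "Q6PHN9", "P19246",
                "Q9CZ13", "Q9CQQ7", "P80317", "Q9CWS0"),
    gene = c("GRM2", "CNTN1", "FN1", "KXD1", "SYP", "EHD3", "GSTM3",
             "HSPA9", "RAB14", "CBR1", "KCNQ3", "Nefm", "TF", "TPD52L2",
             "ACO2", "DPYSL5", "ATP5F1B", "SYT1", "CRMP1", "ATP5PO",
             "RAB10", "HSPA8", "RAB3A", "AP2A1", "CFL1", "SUCLA2",
             "PPP3CA", "SYNGR3", "GABRA5", "PHB2", "YWHAG", "HSP90AA1",
             "PHB", "EIF3J", "SLC25A3", "ACTB",
             "YWHAE", "VAMP2", "INA", "TMEFF2", "RAB35", "NEFH", "UQCRC1",
             "ATP5PB", "CCT6A", "DDAH1"),
    direction = "increased"
  )
  inc$nf <- ifelse(is.na(inc$ratio), "NF-V", NA_character_)
  dec <- data.frame(
    ratio = c(0.2, 0.2, 0.2, 0.2, 0.3, 0.3, 0.4, 0.4, 0.4, 0.5, 0.5, 0.5,
              0.7, 0.7, 0.8, 0.8, rep(NA_real_, 7)),
    p_value = c(3.4e-2, 3.9e-2, 4.2e-2, 5.8e-2, 2.0e-2, 3.4e-2, 6.9e-2,
                8.5e-2, 7.9e-2, 5.2e-2, 2.9e-4, 3.6e-2, 6.8e-2, 7.6e-2,
                1.4e-2, 8.0e-2,
                1.5e-2, 3.5e-2, 5.5e-2, 2.8e-6, 2.8e-6, 2.8e-6, 2.8e-6),
    uniprot = c("P62717", "P62874", "Q60900-2", "Q920I9", "P53026",
                "Q91VM5", "P49312", "Q8BG05", "Q922F4", "P62334", "P11798",
                "E9PV14", "P16330", "O35643", "P68369", "P52480",
                "P61358", "Q9Z1X4-3", "Q80UJ0", "Q3UHB8", "P49615",
                "Q6ZWV3", "Q9CQ69"),
    gene = c("RPL18A", "GNB1", "ELAVL3", "WDR7", "RPL10A", "Rbmxl1",
             "Hnrnpa1", "Hnrnpa3", "TUBB6", "PSMC6", "CAMK2A", "EPB41L1",
             "CNP", "AP1B1", "TUBA1A", "PKM",
             "RPL27", "ILF3", "ELAVL2", "CCDC177", "CDK5", "RPL10",
             "UQCRQ"),
    direction = "decreased"
  )
  dec$nf <- ifelse(is.na(dec$ratio), "NF-DZP", NA_character_)
  out <- rbind(inc, dec)
  out[c("gene", "uniprot", "ratio", "nf", "p_value", "direction")]
}

#' Convert the fixture table to association records
#'
#' Assigns the record class from the ratio and the NF flag so the fixture
#' can flow through [classify_association()] and [to_pathway_input()] like
#' computed records.
#'
#' @param fixture Data frame from [dzp_association_table()].
#' @return An `association_records`-shaped data frame (`protein`, `ratio`,
#'   `p_value`, `class`).
#' @export
as_association_records <- function(fixture = dzp_association_table()) {
  cls <- ifelse(!is.na(fixture$nf) & fixture$nf == "NF-V", "NF_V",
         ifelse(!is.na(fixture$nf) & fixture$nf == "NF-DZP", "NF_DZP",
         ifelse(fixture$ratio > 1, "increased",
         ifelse(fixture$ratio < 1, "decreased", "unchanged"))))
  out <- data.frame(protein = fixture$gene, ratio = fixture$ratio,
                    p_value = fixture$p_value, class = cls,
                    row.names = NULL)
  structure(out, class = c("association_records", class(out)))
}

#' Published GO overrepresentation results (transcribed)
#'
#' The biological-process terms reported as enriched among proteins with
#' increased gamma2 association, with their fold enrichment and p-values.
#' Kept as a reference point for the generic [overrepresentation()] test.
#'
#' @return Data frame: `go_term`, `go_id`, `fold_enrichment`, `p_value`.
#' @export
go_enrichment_table <- function() {
  data.frame(
    go_term = c("Transport", "Establishment of localization",
                "Establishment of localization in cell", "Localization",
                "Intracellular transport", "Regulation of localization",
                "Intracellular protein transport",
                "Regulation of transport", "Cellular localization",
                "Protein transport"),
    go_id = c("GO:0006810", "GO:0051234", "GO:0051649", "GO:0051179",
              "GO:0046907", "GO:0032879", "GO:0006886", "GO:0051049",
              "GO:0051641", "GO:0015031"),
    fold_enrichment = c(4.2, 4.0, 6.8, 3.3, 7.2, 4.3, 9.1, 5.1, 4.8, 6.1),
    p_value = c(9.8e-9, 2.5e-8, 2.0e-7, 2.5e-7, 1.6e-6, 3.7e-6, 7.8e-6,
                2.2e-5, 4.8e-5, 2.2e-4)
  )
}

#' Write the fixture bundle used by the analysis scripts
#'
#' Materializes the packaged inputs as plain-text files: the 69-row
#' association table, the default co-IP sample sheet, a synthetic dendrite
#' scene (TIFF plus JSON ground truth), simulated FRAP traces and a
#' simulated spectral-count table, plus a YAML file of the default
#' simulation parameters.
#'
#' @param target_dir Directory to write into (created if missing).
#' @param seed Integer seed for the simulated components.
#' @return Invisibly, a named character vector of the written paths.
#' @export
build_fixtures <- function(target_dir, seed = 1L) {
  dir.create(target_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- file.path(target_dir, "dzp_association_table.csv")
  utils::write.csv(dzp_association_table(), p, row.names = FALSE)
  paths["association"] <- p
  p <- file.path(target_dir, "coip_samples.tsv")
  utils::write.table(default_coip_samples(), p, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths["samples"] <- p
  truth <- scene_truth(random_puncta(seed = child_seed(seed, 1)),
                       gaussian_sd = 2, seed = child_seed(seed, 2))
  scene <- make_dendrite_scene(truth)
  paths["scene"] <- write_scene_tiff(scene, file.path(target_dir, "scene"))
  kin <- kinetic_truth()
  traces <- lapply(1:6, function(i)
    simulate_frap(kin, noise_sd = 2, seed = child_seed(seed, 10 + i),
                  synapse_id = paste0("syn", i)))
  p <- file.path(target_dir, "frap_traces.csv")
  write_frap_csv(traces, p)
  paths["frap"] <- p
  tab <- simulate_spectral_counts(c(P001 = 4, P002 = 4, P003 = 0.25),
                                  n_proteins = 50,
                                  seed = child_seed(seed, 20))
  paths <- c(paths, write_spectral_counts(tab, target_dir))
  p <- file.path(target_dir, "simulation_params.yaml")
  yaml::write_yaml(list(
    scene = list(pixel_size_um = 0.1, background = 10,
                 punctum_sigma_um = 0.25, punctum_peak = 200),
    frap = list(k_exchange = kin$k_exchange,
                mobile_fraction = kin$mobile_fraction,
                bleach_depth = kin$bleach_depth,
                timepoints_min = "0..30 by 2"),
    fret = list(efficiency = kin$fret_efficiency, coupling = 0.5),
    vesicles = list(n_pre = kin$n_vesicles_pre,
                    n_post = kin$n_vesicles_post, diameter_um = 0.75),
    seed = as.integer(seed)), p)
  paths["params"] <- p
  invisible(paths)
}
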