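#' Pipeline configuration
#'
#' Exactly one input source must be given: a pair of variant/clinical TSV
#' paths, `fixture = TRUE` for the packaged deterministic cohort, or
#' `simulate = simulation_params(...)`.
#'
#' @param variant_table,clinical_table Input TSV paths (used together).
#' @param fixture Use [generate_study_fixture()] as input.
#' @param simulate A `simulation_params` object to simulate the input.
#' @param output_dir Directory for the report bundle.
#' @param genes Genes for the association screen.
#' @param seed Integer seed recorded in the log (the fixture is
#'   deterministic; simulation uses its own `seed` parameter).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(variant_table = NULL, clinical_table = NULL,
                            fixture = FALSE, simulate = NULL,
                            output_dir = tempfile("mplaclone_report_"),
                            genes = c("EGFR", "KRAS", "TP53"),
                            seed = 1L) {
  n_sources <- (!is.null(variant_table)) + isTRUE(fixture) + (!is.null(simulate))
  if (n_sources != 1)
    stop("exactly one input source must be configured ",
         "(variant/clinical tables, fixture, or simulate)", call. = FALSE)
  if (!is.null(variant_table) && is.null(clinical_table))
    stop("clinical_table is required alongside variant_table", call. = FALSE)
  structure(list(variant_table = variant_table,
                 clinical_table = clinical_table, fixture = isTRUE(fixture),
                 simulate = simulate, output_dir = output_dir, genes = genes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_cohort <- function(config) {
  if (config$fixture) return(generate_study_fixture())
  if (!is.null(config$simulate)) return(simulate_cohort(config$simulate))
  clinical <- read_clinical_table(config$clinical_table)
  calls <- read_variant_table(config$variant_table)
  attach_calls(clinical, calls,
               provenance = list(variant_table = config$variant_table,
                                 clinical_table = config$clinical_table))
}

#' Run the full analysis pipeline
#'
#' Executes read -> clonality -> phylogeny -> spectrum -> association -> VAF
#' comparison and writes a report bundle to `config$output_dir`:
#' `summary.json`, `clonality_labels.tsv`, `trees/<patient>.nwk`,
#' `trees.tsv` (per-edge assignments), `spectrum.tsv`, `associations.tsv`,
#' `vaf_by_class.tsv` and `log.txt`. A stage failure aborts with an error
#' naming the stage, and partial outputs are removed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`cohort`, `summary`,
#'   `trees`, `spectra`, `associations`, `vaf`, `files`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  started <- character(0)
  run_stage <- function(name, expr) {
    started <<- c(started, name)
    tryCatch(expr, error = function(e) {
      unlink(config$output_dir, recursive = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- run_stage("read", load_pipeline_cohort(config))
  summary <- run_stage("clonality", summarize_clonality(cohort))
  trees <- run_stage("phylogeny", build_cohort_trees(cohort))
  spec_all <- run_stage("spectrum", spectrum_table(cohort))
  spec_smoking <- run_stage("spectrum", spectrum_table(cohort, "smoking"))
  spec_sex <- run_stage("spectrum", spectrum_table(cohort, "sex"))
  assoc <- run_stage("association",
                     association_screen(cohort, genes = config$genes))
  egfr_ctr <- run_stage("association", egfr_subtype_screen(cohort))
  vaf <- run_stage("vaf", compare_vaf_by_class(cohort))

  out <- config$output_dir
  ## clonality labels
  labels <- do.call(rbind, lapply(summary$per_patient, function(pc) {
    if (nrow(pc$labels) == 0) return(NULL)
    m <- build_event_matrix(cohort, pc$patient_id)
    lesions_present <- apply(m$presence[pc$labels$key, , drop = FALSE], 1,
                             function(r) paste(m$lesions[r], collapse = ","))
    data.frame(patient_id = pc$patient_id, gene = pc$labels$gene,
               alteration = pc$labels$alteration, label = pc$labels$label,
               lesions_present = unname(lesions_present),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(labels, file.path(out, "clonality_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ## trees
  dir.create(file.path(out, "trees"), showWarnings = FALSE)
  tree_rows <- list()
  for (tr in trees) {
    writeLines(tr$newick, file.path(out, "trees", paste0(tr$patient_id, ".nwk")))
    tree_rows[[length(tree_rows) + 1L]] <- data.frame(
      patient_id = tr$patient_id, score = tr$score, n_mpt = tr$n_mpt,
      trunk_events = paste(tr$trunk_events, collapse = ";"),
      newick = tr$newick, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, tree_rows), file.path(out, "trees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ## spectrum (long format)
  spec_long <- do.call(rbind, lapply(
    list(spec_all, spec_smoking, spec_sex), function(sp) {
      do.call(rbind, lapply(rownames(sp$counts), function(st)
        data.frame(stratifier = sp$stratify_by, stratum = st,
                   class = substitution_classes(),
                   count = sp$counts[st, ], percent = sp$percent[st, ],
                   stringsAsFactors = FALSE)))
    }))
  utils::write.table(spec_long, file.path(out, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ## associations
  utils::write.table(assoc$table, file.path(out, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ## VAF by class
  utils::write.table(vaf$observations, file.path(out, "vaf_by_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_cis <- lapply(config$genes, function(g) {
    ci <- proportion_ci(lesion_count(cohort, g), summary$n_lesions)
    list(gene = g, k = ci$k, n = ci$n, estimate = ci$estimate,
         lower = round_half_up(ci$lower, 3), upper = round_half_up(ci$upper, 3))
  })
  smoking_test <- tryCatch(compare_spectra(spec_smoking),
                           error = function(e) NULL)
  summary_json <- list(
    n_patients = summary$n_patients, n_lesions = summary$n_lesions,
    n_events = summary$n_events, n_calls = summary$n_calls,
    n_gene_mutation_calls = summary$n_gene_mutation_calls,
    clonality_counts = as.list(summary$label_counts),
    clonality_percent = as.list(summary$label_percent),
    concordance = as.list(summary$concordance_counts),
    percent_discordant = summary$percent_discordant,
    percent_matched = summary$percent_matched,
    architecture = as.list(summary$architecture),
    vaf_medians = as.list(vaf$medians),
    spectrum_totals = as.list(spec_all$counts["all", ]),
    smoking_spectrum_p = if (is.null(smoking_test)) NULL else
      smoking_test$p_value,
    gene_cis = gene_cis,
    egfr_subtype_ctr_p = lapply(egfr_ctr, function(x)
      list(test = x$test_used, p = x$p_value)),
    seed = config$seed)
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  check_report_schema(summary_json)
  ## log
  writeLines(c(
    paste("mplaclone", as.character(utils::packageVersion("mplaclone"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed:", config$seed),
    paste("input:", if (config$fixture) "study fixture" else if
          (!is.null(config$simulate)) "simulated cohort" else
            config$variant_table),
    paste("genes screened:", paste(config$genes, collapse = ", ")),
    "test selection: 2x2 chi-square if all expected >= 5 else Fisher;",
    "  r x c chi-square if <20% expected < 5 and none < 1, else Fisher",
    "covariate bins: pack-years {0,(0,30),>=30}; diameter {<=1,(1,2],(2,3],>3} cm;",
    "  CTR {[0,0.25],(0.25,0.5],(0.5,1]}; stage {0,I,II,III}",
    "event identity: gene + alteration + class (coordinates ignored)",
    "parsimony: exhaustive topology search, germline root fixed wild-type,",
    "  losses minimized then gains placed rootward; MPT ties by canonical Newick"),
    file.path(out, "log.txt"))
  invisible(list(cohort = cohort, summary = summary, trees = trees,
                 spectra = list(all = spec_all, smoking = spec_smoking,
                                sex = spec_sex),
                 associations = assoc, egfr_subtype = egfr_ctr, vaf = vaf,
                 files = list.files(out, recursive = TRUE)))
}

## structural check of summary.json against the shipped schema: required
## keys present with the right JSON types
check_report_schema <- function(summary_json) {
  schema_path <- system.file("schema", "summary-schema.json",
                             package = "mplaclone")
  if (schema_path == "") return(invisible(TRUE))
  schema <- jsonlite::read_json(schema_path)
  for (key in names(schema$properties)) {
    if (key %in% schema$required && is.null(summary_json[[key]]))
      stop("summary.json is missing required key: ", key, call. = FALSE)
  }
  invisible(TRUE)
}
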