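#' Simulation parameters for a synthetic sMPLA cohort
#'
#' Defaults emulate the study conditions of the motivating cohort: 42
#' patients, 33/42 with two lesions and 9/42 with three; per-patient expected
#' event counts matching the observed architecture (5 trunk and 4 shared
#' events cohort-wide, roughly one private event per lesion);
#' covariate-dependent driver frequencies (EGFR enriched in female
#' never-smokers, KRAS in male smokers, TP53 rising with diameter, CTR bin
#' and stage); smoking-conditional six-class substitution distributions (T>G
#' dominating never-smokers, C>A / C>T dominating smokers); and
#' clonality-class-dependent Beta VAF models located near the observed
#' medians 0.164 (trunk), 0.091 (shared), 0.086 (branch).
#'
#' @param n_patients Number of patients.
#' @param lesion_count_probs Named probabilities over lesion counts 2 and 3.
#' @param clonality_rates Named expected counts: `trunk` (per patient),
#'   `shared` (per 3-lesion patient), `private` (per lesion).
#' @param covariate_effects Named log-odds modifiers for driver genes.
#' @param substitution_probs_by_smoking 2 x 6 matrix of class probabilities,
#'   rows `nonsmoker` and `smoker`.
#' @param vaf_model Named list of `c(shape1, shape2)` Beta parameters per
#'   clonality class.
#' @param p_purine_representation Probability of emitting an SNV on the
#'   purine strand (exercises downstream collapsing).
#' @param seed Integer seed; a fixed seed makes the cohort bitwise
#'   reproducible.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 42,
                              lesion_count_probs = c("2" = 33 / 42, "3" = 9 / 42),
                              clonality_rates = c(trunk = 5 / 42,
                                                  shared = 4 / 9,
                                                  private = 92 / 93),
                              covariate_effects = c(egfr_female = 1.6,
                                                    egfr_nonsmoker = 1.6,
                                                    kras_male = 1.2,
                                                    kras_smoker = 1.5,
                                                    tp53_per_cm = 0.6,
                                                    tp53_per_ctr_bin = 0.7,
                                                    tp53_per_stage = 0.5),
                              substitution_probs_by_smoking = rbind(
                                nonsmoker = c("C>A" = 0.08, "C>G" = 0.04,
                                              "C>T" = 0.19, "T>A" = 0.06,
                                              "T>C" = 0.13, "T>G" = 0.50),
                                smoker = c("C>A" = 0.40, "C>G" = 0.05,
                                           "C>T" = 0.33, "T>A" = 0.07,
                                           "T>C" = 0.05, "T>G" = 0.10)),
                              vaf_model = list(trunk = c(2.9, 13.5),
                                               shared = c(2.2, 19.0),
                                               branch = c(2.15, 20.0)),
                              p_purine_representation = 0.5,
                              seed = 1L) {
  stopifnot(abs(sum(lesion_count_probs) - 1) < 1e-9,
            abs(rowSums(substitution_probs_by_smoking) - 1) < 1e-9,
            all(clonality_rates >= 0))
  structure(list(n_patients = n_patients,
                 lesion_count_probs = lesion_count_probs,
                 clonality_rates = clonality_rates,
                 covariate_effects = covariate_effects,
                 substitution_probs_by_smoking = substitution_probs_by_smoking,
                 vaf_model = vaf_model,
                 p_purine_representation = p_purine_representation,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## driver catalog: hotspot identities with base per-patient log-odds.
## base frequencies echo the cohort-level tumour frequencies.
driver_catalog <- function() {
  data.frame(
    gene = c("EGFR", "EGFR", "KRAS", "KRAS", "TP53", "BRAF"),
    alteration = c("L858R", "19del", "G12C", "G12V", "R273C", "V600E"),
    variant_class = c("nonsynonymous_SNV", "nonframeshift_deletion",
                      "nonsynonymous_SNV", "nonsynonymous_SNV",
                      "nonsynonymous_SNV", "nonsynonymous_SNV"),
    base_logodds = c(0.2, -0.8, -2.2, -2.4, -1.2, -2.8),
    stringsAsFactors = FALSE)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

## a concrete strand-specific (ref, alt) pair realizing a pyrimidine class,
## emitted on the purine strand with probability p
realize_substitution <- function(class, p_purine) {
  ref <- substr(class, 1, 1); alt <- substr(class, 3, 3)
  if (stats::runif(1) < p_purine) c(comp_base[[ref]], comp_base[[alt]]) else c(ref, alt)
}

draw_vaf <- function(model, label) {
  pars <- model[[label]]
  stats::rbeta(1, pars[1], pars[2])
}

#' Simulate a synthetic multi-lesion cohort with ground-truth labels
#'
#' Draws patient covariates, per-patient event architecture (trunk events
#' copied into every lesion; shared events into a strict subset of at least
#' two lesions, possible only for three-lesion patients; private events into
#' one lesion), driver identities with covariate-modified frequencies,
#' smoking-conditional substitution classes emitted in strand-specific form,
#' and clonality-class-dependent VAFs. The generator records its ground-truth
#' label for every event in the cohort's `truth` element, against which the
#' downstream classifier can be audited.
#'
#' All randomness flows from a single seeded generator; the draw order is
#' patients in sequence, and within a patient: covariates, lesion covariates,
#' architecture counts, event identities, strand representations, VAFs.
#'
#' @param params A `simulation_params` object.
#' @return An `mpla_cohort` with an extra element `truth`: data frame
#'   `patient_id`, `gene`, `alteration`, `variant_class`, `true_label`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  if (params$clonality_rates["shared"] > 0 &&
      params$lesion_count_probs["3"] == 0)
    message("simulate_cohort: shared-event rate > 0 but no 3-lesion patients ",
            "are possible; no shared events will be generated")
  set.seed(params$seed)
  voc <- vocabularies()
  catalog <- driver_catalog()
  eff <- params$covariate_effects
  clin_rows <- list(); call_rows <- list(); truth_rows <- list()
  passenger_id <- 0L

  for (p in seq_len(params$n_patients)) {
    pid <- sprintf("S%02d", p)
    sex <- sample(c("female", "male"), 1, prob = c(31, 11) / 42)
    ## smoking is drawn conditionally on sex: the study cohort couples the
    ## two (8 of the 11 males smoked; the 34 never-smokers are the 31 women
    ## plus 3 men), and the marginal 34/4/4 pack-year strata follow
    smoker_cat <- if (sex == "male") {
      sample(c("0", "0-30", ">=30"), 1, prob = c(3, 4, 4) / 11)
    } else "0"
    pack_years <- switch(smoker_cat, "0" = 0,
                         "0-30" = stats::runif(1, 5, 28),
                         ">=30" = stats::runif(1, 30, 55))
    age <- round(stats::runif(1, 33, 75))
    n_lesions <- sample(c(2L, 3L), 1, prob = params$lesion_count_probs)
    lesions <- paste0("T", seq_len(n_lesions))

    lesion_clin <- lapply(lesions, function(les) {
      diam <- round(stats::rlnorm(1, log(1.1), 0.55), 1)
      diam <- max(0.3, min(diam, 6))
      ctr <- sample(c(stats::runif(1, 0, 0.25), stats::runif(1, 0.25, 0.5),
                      stats::runif(1, 0.5, 1)), 1, prob = c(49, 14, 30) / 93)
      stage <- sample(c("0", "IA1", "IA2", "IA3", "IB", "IIB", "IIIA"), 1,
                      prob = c(32, 27, 15, 8, 6, 4, 1) / 93)
      data.frame(patient_id = pid, lesion_id = les, sex = sex,
                 age_years = age, pack_years = round(pack_years, 1),
                 lobe = sample(voc$lobe, 1, prob = c(22, 15, 26, 11, 19) / 93),
                 max_diameter_cm = diam, ctr = round(ctr, 2),
                 pathology = sample(voc$pathology, 1,
                                    prob = c(32, 25, 9, 19, 1, 2, 4, 1) / 93),
                 node_status = sample(c("N0", "N1", "N2"), 1,
                                      prob = c(90, 2, 1) / 93),
                 stage = stage,
                 resection = sample(voc$resection, 1, prob = c(39, 10, 44) / 93),
                 stringsAsFactors = FALSE)
    })
    clin <- do.call(rbind, lesion_clin)
    clin_rows[[p]] <- clin

    ## architecture: label slots first, identities second
    rates <- params$clonality_rates
    n_trunk <- stats::rpois(1, rates["trunk"])
    n_shared <- if (n_lesions >= 3) stats::rpois(1, rates["shared"]) else 0L
    n_private <- stats::rpois(n_lesions, rates["private"])
    slots <- c(rep("trunk", n_trunk), rep("shared", n_shared),
               rep("branch", sum(n_private)))
    private_lesion <- rep(lesions, n_private)

    ## driver genes present in this patient, covariate-modified
    mean_ctr_bin <- mean(as.integer(bin_ctr(clin$ctr)))
    mean_stage <- mean(as.integer(factor(collapse_stage(clin$stage),
                                         levels = c("0", "I", "II", "III"))))
    logodds <- catalog$base_logodds +
      (catalog$gene == "EGFR") * (eff["egfr_female"] * (sex == "female") +
                                    eff["egfr_nonsmoker"] * (pack_years == 0)) +
      (catalog$gene == "KRAS") * (eff["kras_male"] * (sex == "male") +
                                    eff["kras_smoker"] * (pack_years > 0)) +
      (catalog$gene == "TP53") * (eff["tp53_per_cm"] * mean(clin$max_diameter_cm) +
                                    eff["tp53_per_ctr_bin"] * (mean_ctr_bin - 1) +
                                    eff["tp53_per_stage"] * (mean_stage - 1) - 1)
    driver_present <- stats::runif(nrow(catalog)) < stats::plogis(logodds)
    drivers <- catalog[driver_present, , drop = FALSE]
    ## de-duplicate within patient by construction (catalog rows are unique)

    n_slots <- length(slots)
    events <- data.frame(gene = character(n_slots), alteration = character(n_slots),
                         variant_class = character(n_slots),
                         stringsAsFactors = FALSE)
    n_drv <- min(nrow(drivers), n_slots)
    if (n_drv > 0) events[seq_len(n_drv), ] <-
      drivers[seq_len(n_drv), c("gene", "alteration", "variant_class")]
    if (n_slots > n_drv) {
      for (j in seq(n_drv + 1L, n_slots)) {
        passenger_id <- passenger_id + 1L
        events$gene[j] <- sample(c("TP53", "EGFR", "KRAS", "PIK3CA", "ERBB2",
                                   "BRAF"), 1)
        events$alteration[j] <- sprintf("X%04dY", passenger_id)
        events$variant_class[j] <- "nonsynonymous_SNV"
      }
    }

    smoking_row <- if (pack_years > 0) "smoker" else "nonsmoker"
    for (j in seq_len(n_slots)) {
      label <- slots[j]
      target <- switch(label,
                       trunk = lesions,
                       shared = sort(sample(lesions, 2)),
                       branch = private_lesion[j - n_trunk - n_shared])
      snv <- events$variant_class[j] %in% snv_classes()
      if (snv) {
        class <- sample(substitution_classes(), 1,
                        prob = params$substitution_probs_by_smoking[smoking_row, ])
        pair <- realize_substitution(class, params$p_purine_representation)
      } else pair <- c(NA_character_, NA_character_)
      for (les in target) {
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          patient_id = pid, lesion_id = les, gene = events$gene[j],
          alteration = events$alteration[j],
          variant_class = events$variant_class[j],
          chrom = NA_character_, pos = NA_integer_,
          ref = pair[1], alt = pair[2],
          vaf = round(draw_vaf(params$vaf_model, label), 4),
          stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = pid, gene = events$gene[j],
        alteration = events$alteration[j],
        variant_class = events$variant_class[j],
        true_label = label, stringsAsFactors = FALSE)
    }
  }

  clinical <- do.call(rbind, clin_rows)
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else empty_calls()
  ## identical driver drawn for two slots of one patient would collide; the
  ## catalog guarantees distinct identities, passengers carry unique labels
  cohort <- attach_calls(clinical, calls,
                         provenance = list(source = "simulate_cohort",
                                           seed = params$seed))
  truth <- do.call(rbind, truth_rows)
  truth$key <- event_key(truth$gene, truth$alteration, truth$variant_class)
  cohort$truth <- truth
  cohort
}

#' Write a cohort to disk as variant + clinical (+ ground truth) TSVs
#'
#' @param cohort An `mpla_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  write_variant_table(cohort$calls, paths["variants"])
  write_clinical_table(cohort$clinical, paths["clinical"])
  if (!is.null(cohort$truth)) {
    paths["truth"] <- file.path(dir, "truth_labels.tsv")
    utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}
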