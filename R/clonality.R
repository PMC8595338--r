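#' Per-patient event presence matrix
#'
#' Builds the events-by-lesions boolean presence matrix for one patient: rows
#' are the distinct mutation events observed in any of the patient's lesions
#' (identity = normalized gene + alteration + variant class), columns the
#' patient's lesions. A parallel matrix holds the per-call VAFs (NA where the
#' event is absent or the VAF was not reported).
#'
#' @param cohort An `mpla_cohort`.
#' @param patient_id Patient identifier; the patient must have at least two
#'   lesions.
#' @return An object of class `event_matrix`: list with `patient_id`, `events`
#'   (data frame gene/alteration/variant_class/key, ordered by gene then
#'   alteration), `lesions`, `presence` (logical matrix), `vaf` (numeric
#'   matrix).
#' @export
build_event_matrix <- function(cohort, patient_id) {
  lesions <- patient_lesions(cohort, patient_id)
  if (length(lesions) < 2)
    stop("patient ", patient_id, " has fewer than 2 lesions; ",
         "clonality requires multi-lesion patients", call. = FALSE)
  calls <- cohort$calls[cohort$calls$patient_id == patient_id, , drop = FALSE]
  if (nrow(calls) == 0) {
    events <- data.frame(gene = character(), alteration = character(),
                         variant_class = character(), key = character(),
                         stringsAsFactors = FALSE)
    presence <- matrix(FALSE, 0, length(lesions),
                       dimnames = list(NULL, lesions))
    vaf <- matrix(NA_real_, 0, length(lesions), dimnames = list(NULL, lesions))
    return(structure(list(patient_id = patient_id, events = events,
                          lesions = lesions, presence = presence, vaf = vaf),
                     class = "event_matrix"))
  }
  calls$key <- event_key(calls$gene, calls$alteration, calls$variant_class)
  events <- unique(calls[, c("gene", "alteration", "variant_class", "key")])
  events <- events[order(events$gene, events$alteration, events$variant_class), ,
                   drop = FALSE]
  rownames(events) <- NULL
  presence <- matrix(FALSE, nrow(events), length(lesions),
                     dimnames = list(events$key, lesions))
  vaf <- matrix(NA_real_, nrow(events), length(lesions),
                dimnames = list(events$key, lesions))
  for (i in seq_len(nrow(calls))) {
    presence[calls$key[i], calls$lesion_id[i]] <- TRUE
    vaf[calls$key[i], calls$lesion_id[i]] <- calls$vaf[i]
  }
  structure(list(patient_id = patient_id, events = events, lesions = lesions,
                 presence = presence, vaf = vaf),
            class = "event_matrix")
}

#' Trunk / shared / branch classification and concordance call
#'
#' Labels every distinct event of a patient by its carrier-lesion count:
#' trunk = present in all lesions, shared = in at least two but not all
#' (possible only with three or more lesions), branch = private to exactly
#' one. Patient concordance: `concordant_wildtype` if there are no events;
#' `concordant_mutant` if all lesion event sets are identical and non-empty
#' (equivalently, every event is trunk); otherwise `discordant`.
#'
#' @param matrix An `event_matrix` from [build_event_matrix()].
#' @return A list of class `patient_clonality`: `patient_id`, `labels`
#'   (data frame gene/alteration/variant_class/key/label/n_lesions_present),
#'   `counts` (named integer: trunk, shared, branch), `concordance`.
#' @export
classify_events <- function(matrix) {
  n_lesions <- length(matrix$lesions)
  carriers <- if (nrow(matrix$presence)) rowSums(matrix$presence) else integer(0)
  stopifnot(all(carriers >= 1 | length(carriers) == 0))
  label <- character(length(carriers))
  label[carriers == n_lesions] <- "trunk"
  label[carriers == 1L] <- "branch"
  label[carriers > 1L & carriers < n_lesions] <- "shared"
  labels <- matrix$events
  labels$label <- label
  labels$n_lesions_present <- as.integer(carriers)
  counts <- c(trunk = sum(label == "trunk"),
              shared = sum(label == "shared"),
              branch = sum(label == "branch"))
  concordance <- if (length(label) == 0) {
    "concordant_wildtype"
  } else if (all(label == "trunk")) {
    "concordant_mutant"
  } else {
    "discordant"
  }
  structure(list(patient_id = matrix$patient_id, labels = labels,
                 counts = counts, concordance = concordance),
            class = "patient_clonality")
}

## classify all multi-lesion patients of a cohort
classify_cohort <- function(cohort) {
  ids <- unique(cohort$clinical$patient_id)
  out <- lapply(ids, function(p) classify_events(build_event_matrix(cohort, p)))
  names(out) <- ids
  out
}

#' Cohort-level clonality summary
#'
#' Pools distinct per-patient events across a cohort (each trunk/shared event
#' counts once per patient, not once per lesion) and tabulates
#' trunk/shared/branch totals and percentages, concordance tallies, and
#' per-patient architecture counts. Both denominators the field reports are
#' returned explicitly: distinct events (`n_events`) and per-lesion calls
#' (`n_calls`, with `n_gene_mutation_calls` excluding amplification/fusion).
#'
#' @param cohort An `mpla_cohort` whose patients all have >= 2 lesions.
#' @return A list of class `clonality_summary`; see Details.
#' @details Elements: `n_patients`, `n_lesions`, `n_events`, `n_calls`,
#'   `n_gene_mutation_calls`, `label_counts`, `label_percent` (of distinct
#'   events, rounded to 2 dp), `concordance_counts`, `percent_discordant` and
#'   `percent_matched` (of patients, 1 dp), `architecture` (patients with
#'   trunk+branch / with shared / trunk-only / private-only), and
#'   `per_patient` (the list of `patient_clonality` objects).
#' @export
summarize_clonality <- function(cohort) {
  if (nrow(cohort$clinical) == 0) stop("empty cohort", call. = FALSE)
  per_patient <- classify_cohort(cohort)
  counts <- rowSums(vapply(per_patient, function(x) x$counts, numeric(3)))
  n_events <- sum(counts)
  conc <- vapply(per_patient, function(x) x$concordance, character(1))
  n_pat <- length(per_patient)
  arch <- c(
    trunk_and_branch = sum(vapply(per_patient, function(x)
      x$counts["trunk"] > 0 && x$counts["branch"] > 0, logical(1))),
    with_shared = sum(vapply(per_patient, function(x)
      x$counts["shared"] > 0, logical(1))),
    trunk_only = sum(vapply(per_patient, function(x)
      x$counts["trunk"] > 0 && x$counts["shared"] == 0 && x$counts["branch"] == 0,
      logical(1))),
    private_only = sum(vapply(per_patient, function(x)
      x$counts["trunk"] == 0 && x$counts["shared"] == 0, logical(1)))
  )
  gene_mut <- !cohort$calls$variant_class %in% vaf_optional_classes()
  structure(list(
    n_patients = n_pat,
    n_lesions = nrow(cohort$clinical),
    n_events = n_events,
    n_calls = nrow(cohort$calls),
    n_gene_mutation_calls = sum(gene_mut),
    label_counts = counts,
    label_percent = round_half_up(100 * counts / n_events, 2),
    concordance_counts = c(
      concordant_wildtype = sum(conc == "concordant_wildtype"),
      concordant_mutant = sum(conc == "concordant_mutant"),
      discordant = sum(conc == "discordant")),
    percent_discordant = round_half_up(100 * mean(conc == "discordant"), 1),
    percent_matched = round_half_up(100 * mean(conc == "concordant_mutant"), 1),
    architecture = arch,
    per_patient = per_patient
  ), class = "clonality_summary")
}

#' @export
print.clonality_summary <- function(x, ...) {
  cat("Clonality over", x$n_events, "distinct events in", x$n_patients,
      "patients (", x$n_calls, "calls )\n")
  cat(sprintf("  trunk %d (%.2f%%), shared %d (%.2f%%), branch %d (%.2f%%)\n",
              x$label_counts["trunk"], x$label_percent["trunk"],
              x$label_counts["shared"], x$label_percent["shared"],
              x$label_counts["branch"], x$label_percent["branch"]))
  cat(sprintf("  discordant patients: %.1f%%; matched-mutation: %.1f%%\n",
              x$percent_discordant, x$percent_matched))
  invisible(x)
}

#' VAF comparison across clonality classes
#'
#' Collects one VAF observation per (event, lesion) call with a reported VAF,
#' grouped by the event's clonality label, and compares classes pairwise with
#' the two-sided Wilcoxon rank-sum test. Pairs in which a class has no
#' observations are skipped with a notice.
#'
#' @param cohort An `mpla_cohort`.
#' @return List with `observations` (data frame patient_id/key/label/vaf),
#'   `medians` (named numeric, NA for empty classes), `tests` (data frame
#'   pair/n1/n2/p_value), `skipped` (character vector of skipped pairs).
#' @export
compare_vaf_by_class <- function(cohort) {
  per_patient <- classify_cohort(cohort)
  obs <- list()
  for (pc in per_patient) {
    if (nrow(pc$labels) == 0) next
    m <- build_event_matrix(cohort, pc$patient_id)
    for (i in seq_len(nrow(pc$labels))) {
      v <- m$vaf[pc$labels$key[i], ]
      v <- v[m$presence[pc$labels$key[i], ] & !is.na(v)]
      if (length(v))
        obs[[length(obs) + 1L]] <- data.frame(
          patient_id = pc$patient_id, key = pc$labels$key[i],
          label = pc$labels$label[i], vaf = unname(v),
          stringsAsFactors = FALSE)
    }
  }
  obs <- if (length(obs)) do.call(rbind, obs) else
    data.frame(patient_id = character(), key = character(),
               label = character(), vaf = numeric())
  classes <- c("trunk", "shared", "branch")
  medians <- vapply(classes, function(cl)
    if (any(obs$label == cl)) stats::median(obs$vaf[obs$label == cl]) else NA_real_,
    numeric(1))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  tests <- list()
  skipped <- character()
  for (pr in pairs) {
    x <- obs$vaf[obs$label == pr[1]]
    y <- obs$vaf[obs$label == pr[2]]
    if (length(x) == 0 || length(y) == 0) {
      skipped <- c(skipped, paste(pr, collapse = "_vs_"))
      message("VAF comparison: no observations for one class in ",
              paste(pr, collapse = " vs "), "; pair skipped")
      next
    }
    res <- wilcoxon_rank_sum(x, y)
    tests[[length(tests) + 1L]] <- data.frame(
      pair = paste(pr, collapse = "_vs_"), n1 = length(x), n2 = length(y),
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(pair = character(), n1 = integer(), n2 = integer(),
               p_value = numeric())
  list(observations = obs, medians = medians, tests = tests, skipped = skipped)
}
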