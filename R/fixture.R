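## Deterministic study-constrained fixture cohort: 42 patients, 93 lesions,
## assembled so that every required cohort-level constraint (lesion
## architecture, smoking strata, clonality totals 5/4/92, concordance 3/42
## with 1 matched, six-class SNV totals and their smoking/sex marginals) holds
## simultaneously, and the individually described patients (P2, P9, P19, P20,
## P25, P27, P35, P37, plus the trunk patients P16/P42 and shared patients
## P5/P15/P30) are embedded verbatim. Construction is static assembly - no
## RNG anywhere.

## genomic-strand (ref, alt) representation per alteration; genes on the
## minus strand are stored purine-first so that pyrimidine collapsing is
## genuinely exercised
fixture_allele_map <- function() {
  out <- rbind(
    c("EGFR", "L858R",  "T", "G"),
    c("EGFR", "L833V",  "T", "G"),
    c("EGFR", "S768I",  "G", "T"),
    c("EGFR", "G719A",  "G", "C"),
    c("EGFR", "L861Q",  "T", "A"),
    c("KRAS", "G12C",   "C", "A"),
    c("KRAS", "G12V",   "C", "A"),
    c("KRAS", "G12D",   "C", "T"),
    c("KRAS", "Q61P",   "T", "G"),
    c("TP53", "R273C",  "G", "A"),
    c("TP53", "R175H",  "C", "T"),
    c("TP53", "H193Y",  "G", "A"),
    c("TP53", "Y205H",  "A", "G"),
    c("TP53", "R248Q",  "C", "T"),
    c("TP53", "R273H",  "G", "A"),
    c("TP53", "H179R",  "T", "C"),
    c("TP53", "E336*",  "C", "A"),
    c("TP53", "V157F",  "C", "A"),
    c("TP53", "R282W",  "G", "A"),
    c("TP53", "Y220C",  "T", "C"),
    c("TP53", "G245V",  "C", "A"),
    c("BRAF", "V600E",  "A", "T"),
    c("PIK3CA", "E545A", "A", "C"))
  data.frame(gene = out[, 1], alteration = out[, 2], ref = out[, 3],
             alt = out[, 4], stringsAsFactors = FALSE)
}

fixture_roster <- function() {
  pid <- sprintf("P%d", 1:42)
  smoker_py <- c(P1 = 40, P4 = 25, P9 = 20, P10 = 45, P13 = 15, P22 = 10,
                 P28 = 30, P31 = 50)
  male <- c(names(smoker_py), "P6", "P12", "P24")
  three_lesion <- c("P3", "P5", "P8", "P15", "P21", "P25", "P30", "P33", "P40")
  data.frame(
    patient_id = pid,
    sex = ifelse(pid %in% male, "male", "female"),
    pack_years = ifelse(pid %in% names(smoker_py), smoker_py[pid], 0),
    n_lesions = ifelse(pid %in% three_lesion, 3L, 2L),
    stringsAsFactors = FALSE)
}

## the full distinct-event ledger: one row per (patient, event, lesion-set)
fixture_events <- function() {
  ev <- function(pid, lesions, gene, alteration, class, label)
    data.frame(patient_id = pid, lesions = lesions, gene = gene,
               alteration = alteration, variant_class = class, label = label,
               stringsAsFactors = FALSE)
  snv <- "nonsynonymous_SNV"
  rows <- list(
    ## ---- individually described patients ----
    ev("P2", "T1,T2", "EGFR", "L858R", snv, "trunk"),
    ev("P2", "T1", "TP53", "R273C", snv, "branch"),
    ev("P2", "T1", "ERBB2", "amplification", "amplification", "branch"),
    ev("P2", "T2", "TP53", "R175H", snv, "branch"),
    ev("P9", "T1", "KRAS", "G12V", snv, "branch"),
    ev("P9", "T1", "TP53", "H193Y", snv, "branch"),
    ev("P9", "T1", "A1CF-RET", "fusion", "fusion", "branch"),
    ev("P9", "T2", "KRAS", "G12C", snv, "branch"),
    ev("P16", "T1,T2", "EGFR", "L858R", snv, "trunk"),
    ev("P16", "T1", "EGFR", "L833V", snv, "branch"),
    ev("P20", "T1,T2", "EGFR", "L858R", snv, "trunk"),
    ev("P25", "T1,T3", "EGFR", "L858R", snv, "shared"),
    ev("P25", "T2", "EGFR", "19del", "nonframeshift_deletion", "branch"),
    ev("P25", "T3", "TP53", "R175H", snv, "branch"),
    ev("P27", "T1,T2", "EGFR", "19del", "nonframeshift_deletion", "trunk"),
    ev("P27", "T1", "TP53", "Y205H", snv, "branch"),
    ev("P27", "T1", "TP53", "S90Pfs*33", "frameshift_substitution", "branch"),
    ev("P37", "T1", "EGFR", "19del", "nonframeshift_deletion", "branch"),
    ev("P37", "T1", "TP53", "R273C", snv, "branch"),
    ev("P37", "T1", "PIK3CA", "H14_L15delinsKW", "nonframeshift_substitution",
       "branch"),
    ev("P37", "T2", "EGFR", "L858R", snv, "branch"),
    ev("P37", "T2", "EGFR", "S768I", snv, "branch"),
    ev("P42", "T1,T2", "EGFR", "L858R", snv, "trunk"),
    ev("P42", "T1", "EGFR", "L833V", snv, "branch"),
    ## shared-mutation patients (three lesions each)
    ev("P5", "T1,T2", "EGFR", "L858R", snv, "shared"),
    ev("P15", "T1,T2", "EGFR", "L858R", snv, "shared"),
    ev("P30", "T1,T2", "EGFR", "L858R", snv, "shared")
  )
  ## ---- smoker-male branch fillers (KRAS/BRAF; SNV strata: 3 C>A, 3 C>T,
  ## ---- 1 T>A, 2 T>G) ----
  sm <- rbind(
    c("P1", "T1", "KRAS", "G12C"), c("P10", "T1", "KRAS", "G12C"),
    c("P22", "T1", "KRAS", "G12C"),
    c("P4", "T1", "KRAS", "G12D"), c("P13", "T1", "KRAS", "G12D"),
    c("P28", "T1", "KRAS", "G12D"),
    c("P31", "T1", "BRAF", "V600E"),
    c("P31", "T2", "KRAS", "Q61P"), c("P1", "T2", "KRAS", "Q61P"))
  for (i in seq_len(nrow(sm)))
    rows[[length(rows) + 1L]] <- ev(sm[i, 1], sm[i, 2], sm[i, 3], sm[i, 4],
                                    snv, "branch")
  ## ---- nonsmoker-male branch fillers (1 C>A, 1 C>T, 1 T>C, 1 T>G) ----
  nm <- rbind(
    c("P6", "T1", "KRAS", "G12V"), c("P12", "T1", "TP53", "R273H"),
    c("P24", "T1", "TP53", "H179R"), c("P24", "T2", "PIK3CA", "E545A"))
  for (i in seq_len(nrow(nm)))
    rows[[length(rows) + 1L]] <- ev(nm[i, 1], nm[i, 2], nm[i, 3], nm[i, 4],
                                    snv, "branch")
  ## ---- female never-smoker branch fillers ----
  l858r_pat <- c("P3", "P7", "P8", "P11", "P14", "P17", "P18", "P21", "P23",
                 "P26", "P29", "P32", "P33", "P34")
  for (p in l858r_pat)
    rows[[length(rows) + 1L]] <- ev(p, "T1", "EGFR", "L858R", snv, "branch")
  for (p in c("P3", "P7", "P8", "P11"))  # compound EGFR in the same lesion
    rows[[length(rows) + 1L]] <- ev(p, "T1", "EGFR", "L833V", snv, "branch")
  del19 <- rbind(
    c("P36", "T1"), c("P38", "T1"), c("P39", "T1"), c("P41", "T1"),
    c("P40", "T1"), c("P5", "T3"), c("P15", "T3"), c("P30", "T3"),
    c("P3", "T2"), c("P7", "T2"), c("P8", "T2"), c("P11", "T2"),
    c("P14", "T2"), c("P17", "T2"))
  for (i in seq_len(nrow(del19)))
    rows[[length(rows) + 1L]] <- ev(del19[i, 1], del19[i, 2], "EGFR", "19del",
                                    "nonframeshift_deletion", "branch")
  other_egfr <- rbind(
    c("P18", "T2", "G719A"), c("P21", "T2", "G719A"), c("P23", "T2", "G719A"),
    c("P26", "T2", "L861Q"), c("P29", "T2", "L861Q"), c("P32", "T2", "L861Q"),
    c("P33", "T2", "L861Q"), c("P34", "T2", "S768I"))
  for (i in seq_len(nrow(other_egfr)))
    rows[[length(rows) + 1L]] <- ev(other_egfr[i, 1], other_egfr[i, 2], "EGFR",
                                    other_egfr[i, 3], snv, "branch")
  ## primary TP53 fillers, co-located with EGFR-filler lesions
  tp53 <- rbind(
    c("P3", "T1", "R248Q"), c("P7", "T1", "R248Q"), c("P8", "T1", "R248Q"),
    c("P11", "T1", "R248Q"), c("P36", "T1", "R248Q"), c("P38", "T1", "R248Q"),
    c("P39", "T1", "H179R"), c("P40", "T1", "H179R"), c("P41", "T1", "H179R"),
    c("P5", "T3", "E336*"), c("P15", "T3", "V157F"))
  for (i in seq_len(nrow(tp53)))
    rows[[length(rows) + 1L]] <- ev(tp53[i, 1], tp53[i, 2], "TP53", tp53[i, 3],
                                    if (tp53[i, 3] == "E336*") "stopgain" else snv,
                                    "branch")
  ## compound TP53 in already-TP53-mutant lesions
  tp53b <- rbind(
    c("P3", "T1", "R282W"), c("P7", "T1", "R282W"), c("P8", "T1", "R282W"),
    c("P11", "T1", "Y220C"), c("P36", "T1", "Y220C"), c("P38", "T1", "Y220C"),
    c("P39", "T1", "Y220C"),
    c("P40", "T1", "G245V"), c("P5", "T3", "G245V"))
  for (i in seq_len(nrow(tp53b)))
    rows[[length(rows) + 1L]] <- ev(tp53b[i, 1], tp53b[i, 2], "TP53",
                                    tp53b[i, 3], snv, "branch")
  ## one ERBB2 exon-20 insertion
  rows[[length(rows) + 1L]] <- ev("P30", "T3", "ERBB2", "YVMA insertion",
                                  "nonframeshift_insertion", "branch")
  do.call(rbind, rows)
}

## strand-specific (ref, alt) per fixture event; L858R branch fillers
## alternate between the pyrimidine and purine representation so both occur
fixture_alleles <- function(events) {
  map <- fixture_allele_map()
  idx <- match(paste(events$gene, events$alteration),
               paste(map$gene, map$alteration))
  ref <- map$ref[idx]; alt <- map$alt[idx]
  snv <- events$variant_class %in% snv_classes()
  ref[!snv] <- NA_character_; alt[!snv] <- NA_character_
  flip <- snv & events$label == "branch" & events$alteration == "L858R" &
    (seq_len(nrow(events)) %% 2L == 0L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[flip] <- comp[ref[flip]]; alt[flip] <- comp[alt[flip]]
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

## deterministic per-class VAF ladders with exact medians 0.164/0.091/0.086
fixture_vafs <- function(n_trunk_calls, n_shared_calls, n_branch_calls) {
  sym <- function(n, spread) {
    half <- (seq_len(n) - (n + 1) / 2) / ((n + 1) / 2) * spread
    round(half, 4)
  }
  list(trunk = 0.164 + sym(n_trunk_calls, 0.05),
       shared = 0.091 + sym(n_shared_calls, 0.03),
       branch = 0.086 + sym(n_branch_calls, 0.05))
}

## clinical covariate pools sized to the printed lesion-level marginals
fixture_clinical <- function(roster) {
  lesions <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    data.frame(patient_id = roster$patient_id[i],
               lesion_id = paste0("T", seq_len(roster$n_lesions[i])),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(lesions)
  stopifnot(n == 93)
  lesion_key <- paste(lesions$patient_id, lesions$lesion_id)

  preset <- function(values) {
    out <- rep(NA_character_, n)
    out[match(names(values), lesion_key)] <- unname(values)
    out
  }
  fill <- function(col, pool) {
    pool <- pool[order(match(pool, unique(pool)))]
    remaining <- pool
    for (v in col[!is.na(col)]) {
      hit <- match(v, remaining)
      if (!is.na(hit)) remaining <- remaining[-hit]
    }
    col[is.na(col)] <- remaining
    col
  }

  pathology <- preset(c("P20 T1" = "Lepidic", "P20 T2" = "AIS",
                        "P19 T1" = "AIS", "P19 T2" = "AIS",
                        "P35 T1" = "AIS", "P35 T2" = "AIS",
                        "P2 T1" = "Mucinous", "P2 T2" = "Solid",
                        "P9 T1" = "Solid", "P9 T2" = "AIS",
                        "P37 T1" = "Acinar", "P37 T2" = "MIA"))
  pathology <- fill(pathology, rep(c("AIS", "MIA", "Lepidic", "Acinar",
                                     "Papillary", "Micropapillary", "Solid",
                                     "Mucinous"), c(32, 25, 9, 19, 1, 2, 4, 1)))
  lobe <- preset(c("P19 T1" = "RUL", "P19 T2" = "RUL",
                   "P35 T1" = "LUL", "P35 T2" = "RLL"))
  lobe <- fill(lobe, rep(c("LUL", "LLL", "RUL", "RML", "RLL"),
                         c(22, 15, 26, 11, 19)))
  ctr <- preset(c("P19 T1" = "0", "P19 T2" = "0", "P35 T1" = "0",
                  "P35 T2" = "0"))
  ## the four preset pure-GGO lesions (ctr 0) occupy the 0-0.25 bin
  ctr <- as.numeric(fill(ctr, rep(c("0", "0.1", "0.4", "0.8"),
                                  c(4, 45, 14, 30))))
  resection <- fill(rep(NA_character_, n),
                    rep(c("wedge", "segmentectomy", "lobectomy"), c(39, 10, 44)))
  node <- fill(rep(NA_character_, n), rep(c("N0", "N1", "N2"), c(90, 2, 1)))
  stage <- fill(rep(NA_character_, n),
                rep(c("0", "IA1", "IA2", "IA3", "IB", "IIB", "IIIA"),
                    c(32, 27, 15, 8, 6, 4, 1)))
  diameter <- as.numeric(fill(rep(NA_character_, n),
                              rep(c("0.8", "1.5", "2.5", "3.5"),
                                  c(52, 25, 11, 5))))
  ages <- c(33, 36, 39, 42, 44, 46, 48, 50, 51, 52, 53, 54, 55, 56, 56, 57,
            57, 57, 58, 58, 58, 58, 59, 59, 60, 60, 61, 61, 62, 62, 63, 63,
            64, 65, 66, 67, 68, 69, 70, 72, 74, 75)
  stopifnot(length(ages) == 42, stats::median(ages) == 58)

  idx <- match(lesions$patient_id, roster$patient_id)
  data.frame(patient_id = lesions$patient_id, lesion_id = lesions$lesion_id,
             sex = roster$sex[idx], age_years = as.integer(ages[idx]),
             pack_years = roster$pack_years[idx], lobe = lobe,
             max_diameter_cm = diameter, ctr = ctr, pathology = pathology,
             node_status = node, stage = stage, resection = resection,
             stringsAsFactors = FALSE)
}

#' Deterministic study-constrained fixture cohort
#'
#' Assembles a 42-patient, 93-lesion cohort whose cohort-level statistics
#' reproduce the motivating study's printed values by construction: 33
#' two-lesion and 9 three-lesion patients; smoking strata 34/4/4; exactly 3
#' concordant patients of which 1 matched-mutant (P20, EGFR L858R in both
#' lesions; P19 and P35 wild-type pairs); 5 trunk, 4 shared and 92 branch
#' events (101 distinct; trunk patients P2/P16/P20/P42 with L858R and P27
#' with 19del; shared patients P5/P15/P25/P30, all L858R); six-class SNV
#' totals 12/3/18/5/9/32 with smoker SNVs 12 (5 C>A, 4 C>T), nonsmoker 67
#' (30 T>G), male 16 (6 C>A, 5 C>T) and female 63 (29 T>G); per-class VAF
#' medians 0.164/0.091/0.086; and the individually described patient
#' profiles embedded verbatim. Raw substitutions are stored
#' strand-specifically (a mix of purine- and pyrimidine-reference rows) so
#' that collapsing is genuinely exercised. Construction is static assembly
#' with no random number generation.
#'
#' @return An `mpla_cohort`.
#' @examples
#' fx <- generate_study_fixture()
#' summarize_clonality(fx)
#' @export
generate_study_fixture <- function() {
  roster <- fixture_roster()
  events <- fixture_events()
  alleles <- fixture_alleles(events)

  label_order <- c("trunk", "shared", "branch")
  vaf_optional <- events$variant_class %in% vaf_optional_classes()
  n_calls_by_label <- vapply(label_order, function(l) {
    idx <- events$label == l & !vaf_optional
    sum(lengths(strsplit(events$lesions[idx], ",")))
  }, numeric(1))
  vafs <- fixture_vafs(n_calls_by_label["trunk"], n_calls_by_label["shared"],
                       n_calls_by_label["branch"])
  taken <- c(trunk = 0L, shared = 0L, branch = 0L)

  rows <- vector("list", nrow(events) * 2L)
  k <- 0L
  for (i in seq_len(nrow(events))) {
    lesion_set <- strsplit(events$lesions[i], ",")[[1]]
    for (les in lesion_set) {
      vaf <- NA_real_
      if (!vaf_optional[i]) {
        lab <- events$label[i]
        taken[lab] <- taken[lab] + 1L
        vaf <- vafs[[lab]][taken[lab]]
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = events$patient_id[i], lesion_id = les,
        gene = events$gene[i], alteration = events$alteration[i],
        variant_class = events$variant_class[i],
        chrom = NA_character_, pos = NA_integer_,
        ref = alleles$ref[i], alt = alleles$alt[i], vaf = vaf,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows[seq_len(k)])
  clinical <- fixture_clinical(roster)
  cohort <- attach_calls(clinical, calls,
                         provenance = list(source = "study_fixture",
                                           deterministic = TRUE))
  cohort$truth <- data.frame(patient_id = events$patient_id,
                             gene = events$gene,
                             alteration = events$alteration,
                             variant_class = events$variant_class,
                             true_label = events$label,
                             key = event_key(events$gene, events$alteration,
                                             events$variant_class),
                             stringsAsFactors = FALSE)
  cohort
}
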