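#' Six substitution classes
#' @return Character vector of the pyrimidine-reference classes in canonical
#'   order.
#' @export
substitution_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Collapse a base substitution to its pyrimidine-strand class
#'
#' Maps each of the 12 raw ref>alt base pairs to one of the six classes by
#' complementing both alleles whenever the reference base is a purine (A or
#' G), so complementary pairs (e.g. G>T and C>A) classify identically.
#'
#' @param ref,alt Single-base character vectors (A/C/G/T), `ref != alt`
#'   elementwise.
#' @return Character vector of classes ("C>A", ..., "T>G").
#' @examples
#' collapse_substitution(c("C", "G", "A"), c("T", "T", "C"))
#' @export
collapse_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases))
    stop("ref and alt must be single bases in {A,C,G,T}", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp[ref[purine]]
  alt[purine] <- comp[alt[purine]]
  paste0(ref, ">", alt)
}

## distinct qualifying SNV events, one row per (patient, event), carrying the
## patient-level stratifiers and the collapsed class
distinct_snv_events <- function(cohort, qualifying = snv_classes()) {
  calls <- cohort$calls
  keep <- calls$variant_class %in% qualifying &
    !is.na(calls$ref) & !is.na(calls$alt) &
    nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0)
    return(data.frame(patient_id = character(), key = character(),
                      class = character(), sex = character(),
                      smoking = character(), stringsAsFactors = FALSE))
  calls$key <- event_key(calls$gene, calls$alteration, calls$variant_class)
  calls <- calls[!duplicated(paste(calls$patient_id, calls$key)), , drop = FALSE]
  calls$class <- collapse_substitution(calls$ref, calls$alt)
  pt <- patient_table(cohort)
  idx <- match(calls$patient_id, pt$patient_id)
  data.frame(patient_id = calls$patient_id, key = calls$key,
             class = calls$class, sex = pt$sex[idx],
             smoking = ifelse(pt$pack_years[idx] > 0, "smoker", "nonsmoker"),
             stringsAsFactors = FALSE)
}

#' Stratified substitution spectrum table
#'
#' Counts distinct qualifying SNV events (nonsynonymous SNV and stopgain by
#' default, single-base ref/alt required) per six-class substitution category,
#' one count per (patient, event) - consistent with the clonality
#' denominators. Optional stratification by a binary patient-level covariate:
#' smoking (pack-years 0 vs > 0) or sex. Strata with zero SNVs keep their row
#' of zeros.
#'
#' @param cohort An `mpla_cohort`.
#' @param stratify_by `NULL` (pooled), `"smoking"` or `"sex"`.
#' @param qualifying Variant classes that enter the spectrum.
#' @return Object of class `spectrum_table`: `counts` (strata x 6 matrix),
#'   `totals` (row sums), `percent` (row percentages, 1 dp), `stratify_by`.
#' @export
spectrum_table <- function(cohort, stratify_by = NULL,
                           qualifying = snv_classes()) {
  ev <- distinct_snv_events(cohort, qualifying)
  strata <- if (is.null(stratify_by)) {
    factor(rep("all", nrow(ev)), levels = "all")
  } else if (stratify_by == "smoking") {
    factor(ev$smoking, levels = c("nonsmoker", "smoker"))
  } else if (stratify_by == "sex") {
    factor(ev$sex, levels = c("female", "male"))
  } else stop("unknown stratifier: ", stratify_by, call. = FALSE)
  counts <- table(strata, factor(ev$class, levels = substitution_classes()))
  counts <- matrix(as.integer(counts), nrow = nlevels(strata),
                   dimnames = list(levels(strata), substitution_classes()))
  totals <- rowSums(counts)
  percent <- counts / ifelse(totals == 0, 1, totals) * 100
  structure(list(counts = counts, totals = totals,
                 percent = round_half_up(percent, 1),
                 stratify_by = if (is.null(stratify_by)) "none" else stratify_by),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Substitution spectrum (stratified by ", x$stratify_by, "):\n", sep = "")
  print(cbind(x$counts, total = x$totals))
  invisible(x)
}

#' Between-stratum spectrum comparison
#'
#' Tests the 2 x 6 stratified spectrum table for association between stratum
#' and substitution class using the [select_test()] rule (chi-square when
#' expected counts permit, Fisher exact otherwise). Classes with zero counts
#' in both strata are dropped before testing; a stratum with no SNVs at all is
#' degenerate and rejected.
#'
#' @param table A `spectrum_table` with two strata.
#' @return A `contingency_result`.
#' @export
compare_spectra <- function(table) {
  m <- table$counts
  if (nrow(m) != 2) stop("compare_spectra expects exactly two strata", call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("degenerate spectrum table: a stratum has no SNVs", call. = FALSE)
  m <- m[, colSums(m) > 0, drop = FALSE]
  select_test(m)
}
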