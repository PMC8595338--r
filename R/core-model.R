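#' @keywords internal
"_PACKAGE"

## Closed category sets. The association screen depends on these being closed:
## unknown tokens are rejected, never coerced.

#' Controlled vocabularies
#'
#' Closed sets of tokens accepted by the readers and the downstream screens.
#'
#' @return A named list of character vectors: `variant_class`, `lobe`,
#'   `pathology`, `node_status`, `stage`, `resection`, `sex`.
#' @examples
#' vocabularies()$variant_class
#' @export
vocabularies <- function() {
  list(
    variant_class = c("nonsynonymous_SNV", "stopgain",
                      "frameshift_deletion", "frameshift_substitution",
                      "nonframeshift_deletion", "nonframeshift_insertion",
                      "nonframeshift_substitution", "amplification", "fusion"),
    lobe       = c("LUL", "LLL", "RUL", "RML", "RLL"),
    pathology  = c("AIS", "MIA", "Lepidic", "Acinar", "Papillary",
                   "Micropapillary", "Solid", "Mucinous"),
    node_status = c("N0", "N1", "N2"),
    stage      = c("0", "IA1", "IA2", "IA3", "IB", "IIA", "IIB", "IIIA", "IIIB"),
    resection  = c("wedge", "segmentectomy", "lobectomy"),
    sex        = c("female", "male")
  )
}

## variant classes that qualify as single-nucleotide substitutions
snv_classes <- function() c("nonsynonymous_SNV", "stopgain")

## classes for which a VAF may legitimately be absent
vaf_optional_classes <- function() c("amplification", "fusion")

#' Normalized mutation-event identity key
#'
#' Two calls denote the same mutation event iff their normalized
#' (gene, alteration, variant_class) triples match; genomic coordinates do not
#' participate in identity (events are identified at the protein/label level,
#' e.g. "EGFR L858R"), they are used only for spectrum collapsing.
#'
#' @param gene,alteration,variant_class Character vectors (recycled).
#' @return Character vector of identity keys.
#' @examples
#' event_key("EGFR", " l858r ", "nonsynonymous_SNV")
#' @export
event_key <- function(gene, alteration, variant_class) {
  norm <- function(x) toupper(gsub("[[:space:]]+", " ", trimws(as.character(x))))
  paste(norm(gene), norm(alteration), norm(variant_class), sep = "|")
}

required_call_cols <- c("patient_id", "lesion_id", "gene", "alteration", "variant_class")
optional_call_cols <- c("chrom", "pos", "ref", "alt", "vaf")

clinical_cols <- c("patient_id", "lesion_id", "sex", "age_years", "pack_years",
                   "lobe", "max_diameter_cm", "ctr", "pathology", "node_status",
                   "stage", "resection")
patient_level_cols <- c("sex", "age_years", "pack_years")

## canonical empty calls table
empty_calls <- function() {
  data.frame(patient_id = character(), lesion_id = character(),
             gene = character(), alteration = character(),
             variant_class = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             vaf = numeric(), stringsAsFactors = FALSE)
}

normalize_calls <- function(calls) {
  calls$patient_id <- as.character(calls$patient_id)
  calls$lesion_id <- as.character(calls$lesion_id)
  calls$gene <- trimws(as.character(calls$gene))
  calls$alteration <- trimws(as.character(calls$alteration))
  calls$variant_class <- trimws(as.character(calls$variant_class))
  for (col in optional_call_cols) {
    if (is.null(calls[[col]])) calls[[col]] <- NA
    blank <- !is.na(calls[[col]]) & !nzchar(trimws(as.character(calls[[col]])))
    calls[[col]][blank] <- NA        # writers emit NA as ""
  }
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- suppressWarnings(as.integer(calls$pos))
  calls$ref <- toupper(as.character(calls$ref))
  calls$alt <- toupper(as.character(calls$alt))
  calls$vaf <- suppressWarnings(as.numeric(calls$vaf))
  calls[, c(required_call_cols, optional_call_cols)]
}

validate_calls <- function(calls) {
  if (any(!nzchar(calls$gene)))
    stop("variant table: empty gene symbol at row(s) ",
         paste(which(!nzchar(calls$gene)), collapse = ", "), call. = FALSE)
  bad_class <- !calls$variant_class %in% vocabularies()$variant_class
  if (any(bad_class))
    stop("variant table: unknown variant_class token(s): ",
         paste(unique(calls$variant_class[bad_class]), collapse = ", "), call. = FALSE)
  bad_vaf <- !is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1)
  if (any(bad_vaf))
    stop("variant table: vaf outside [0,1] at row(s) ",
         paste(which(bad_vaf), collapse = ", "), call. = FALSE)
  snv <- calls$variant_class %in% snv_classes()
  has_alleles <- snv & !is.na(calls$ref) & !is.na(calls$alt)
  bad_allele <- has_alleles &
    (nchar(calls$ref) != 1L | nchar(calls$alt) != 1L | calls$ref == calls$alt)
  if (any(bad_allele))
    stop("variant table: SNV rows must carry single, differing ref/alt bases; row(s) ",
         paste(which(bad_allele), collapse = ", "), call. = FALSE)
  key <- paste(calls$patient_id, calls$lesion_id,
               event_key(calls$gene, calls$alteration, calls$variant_class))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("variant table: duplicate (patient, lesion, event) record(s) at row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(calls)
}

#' Read a MAF-like somatic variant table
#'
#' Reads a tab-separated table with one somatic variant call per row. Required
#' columns: `patient_id`, `lesion_id`, `gene`, `alteration`, `variant_class`;
#' optional: `chrom`, `pos`, `ref`, `alt`, `vaf`. Column names can be remapped
#' through `dialect` for files using other headers (e.g. MAF's
#' `Hugo_Symbol`).
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(gene = "Hugo_Symbol")`.
#' @return A data frame of validated variant calls (class `mpla_calls`).
#' @seealso [write_variant_table()], [attach_calls()]
#' @export
read_variant_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("variant table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(raw))
        names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing <- setdiff(required_call_cols, names(raw))
  if (length(missing))
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  calls <- normalize_calls(raw)
  validate_calls(calls)
  class(calls) <- c("mpla_calls", class(calls))
  calls
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: emits a UTF-8, tab-separated file with a
#' header, one call per row, round-trippable up to column order.
#'
#' @param calls A calls data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  out <- as.data.frame(calls)[, c(required_call_cols, optional_call_cols)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical table
#'
#' One row per lesion; patient-level columns (`sex`, `age_years`, `pack_years`)
#' must agree across a patient's rows. Lesion-level columns: `lobe`,
#' `max_diameter_cm`, `ctr`, `pathology`, `node_status`, `stage`, `resection`.
#' Unknown category tokens are rejected (the downstream association screen
#' relies on closed category sets).
#'
#' @param path Path to a TSV file.
#' @return A lesion-level data frame (class `mpla_clinical`).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(clinical_cols, names(raw))
  if (length(missing))
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  clin <- raw[, clinical_cols]
  clin$age_years <- as.integer(clin$age_years)
  clin$pack_years <- as.numeric(clin$pack_years)
  clin$max_diameter_cm <- as.numeric(clin$max_diameter_cm)
  clin$ctr <- as.numeric(clin$ctr)
  validate_clinical(clin)
  class(clin) <- c("mpla_clinical", class(clin))
  clin
}

validate_clinical <- function(clin) {
  voc <- vocabularies()
  for (col in c("sex", "lobe", "pathology", "node_status", "stage", "resection")) {
    bad <- !clin[[col]] %in% voc[[col]]
    if (any(bad))
      stop("clinical table: unknown ", col, " token(s): ",
           paste(unique(clin[[col]][bad]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(clin$ctr)) || any(clin$ctr < 0 | clin$ctr > 1))
    stop("clinical table: ctr must lie in [0,1]", call. = FALSE)
  if (any(is.na(clin$max_diameter_cm)) || any(clin$max_diameter_cm <= 0))
    stop("clinical table: max_diameter_cm must be positive", call. = FALSE)
  if (any(clin$pack_years < 0))
    stop("clinical table: pack_years must be non-negative", call. = FALSE)
  key <- paste(clin$patient_id, clin$lesion_id)
  if (anyDuplicated(key))
    stop("clinical table: duplicate (patient, lesion) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  for (col in patient_level_cols) {
    n_lev <- tapply(clin[[col]], clin$patient_id, function(x) length(unique(x)))
    if (any(n_lev > 1))
      stop("clinical table: conflicting patient-level '", col, "' for patient(s) ",
           paste(names(n_lev)[n_lev > 1], collapse = ", "), call. = FALSE)
  }
  invisible(clin)
}

#' Write a clinical table
#' @param clinical A clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical)[, clinical_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read somatic calls from a multi-sample VCF
#'
#' One call is emitted per (record, sample with a non-reference genotype).
#' The VAF is taken from the per-sample `AF` field when present, otherwise
#' derived as alt depth / total depth from `AD`. Gene and protein-change
#' annotations are read from the INFO keys named in `info_keys`; records
#' lacking a gene annotation get `gene = "."` (excluded from gene-level
#' statistics downstream but retained for clonality). Symbolic alternate
#' alleles are mapped to structural classes via `symbolic_map`.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param sample_to_lesion Data frame with columns `sample`, `patient_id`,
#'   `lesion_id` mapping every VCF sample name.
#' @param info_keys Named character vector: INFO keys for `gene`,
#'   `alteration`, `variant_class` annotations.
#' @param symbolic_map Named character vector mapping symbolic ALT alleles to
#'   variant classes.
#' @return A validated calls data frame, as from [read_variant_table()].
#' @export
read_vcf_calls <- function(path, sample_to_lesion,
                           info_keys = c(gene = "GENE", alteration = "PCHANGE",
                                         variant_class = "VCLASS"),
                           symbolic_map = c("<DUP>" = "amplification",
                                            "<CNV>" = "amplification",
                                            "<BND>" = "fusion")) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  unmapped <- setdiff(samples, sample_to_lesion$sample)
  if (length(unmapped))
    stop("VCF sample(s) not mapped to a lesion: ",
         paste(unmapped, collapse = ", "), call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  af <- tryCatch(vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE),
                 error = function(e) NULL)
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)

  info_get <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, n_rec) else val
  }
  gene <- info_get(info_keys[["gene"]])
  alteration <- info_get(info_keys[["alteration"]])
  vclass <- info_get(info_keys[["variant_class"]])

  infer_class <- function(ref, alt) {
    if (alt %in% names(symbolic_map)) return(symbolic_map[[alt]])
    if (nchar(ref) == 1L && nchar(alt) == 1L) return("nonsynonymous_SNV")
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L != 0L
    if (nchar(ref) > nchar(alt))
      return(if (shift) "frameshift_deletion" else "nonframeshift_deletion")
    if (nchar(ref) < nchar(alt))
      return(if (shift) "frameshift_deletion" else "nonframeshift_insertion")
    "nonframeshift_substitution"
  }

  rows <- list()
  for (i in seq_len(n_rec)) {
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || !grepl("1", g)) next
      map <- sample_to_lesion[sample_to_lesion$sample == s, , drop = FALSE]
      vaf <- NA_real_
      if (!is.null(af) && !is.na(af[i, s])) {
        vaf <- af[i, s]
      } else if (!is.null(ad) && !is.na(ad[i, s])) {
        depths <- suppressWarnings(as.numeric(strsplit(ad[i, s], ",")[[1]]))
        if (length(depths) >= 2 && sum(depths) > 0)
          vaf <- depths[2] / sum(depths)
      }
      alt_i <- fix$ALT[i]
      cls <- if (!is.na(vclass[i])) vclass[i] else infer_class(fix$REF[i], alt_i)
      symbolic <- alt_i %in% names(symbolic_map)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = map$patient_id, lesion_id = map$lesion_id,
        gene = if (!is.na(gene[i])) gene[i] else ".",
        alteration = if (!is.na(alteration[i])) alteration[i] else
          paste0(fix$CHROM[i], ":", fix$POS[i], fix$REF[i], ">", alt_i),
        variant_class = cls,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = if (symbolic) NA_character_ else fix$REF[i],
        alt = if (symbolic) NA_character_ else alt_i,
        vaf = vaf, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  calls <- normalize_calls(calls)
  validate_calls(calls)
  class(calls) <- c("mpla_calls", class(calls))
  calls
}

#' Assemble a cohort from clinical rows and variant calls
#'
#' Links every call to a lesion of the clinical table and returns a cohort
#' container. Lesions with zero calls are first-class ("wild-type"): they are
#' required for concordance semantics. Calls are stored in a stable order
#' (patient, lesion, gene, alteration); the call count is preserved exactly.
#'
#' @param clinical Lesion-level clinical data frame ([read_clinical_table()]).
#' @param calls Variant calls data frame ([read_variant_table()]); may be
#'   empty.
#' @param provenance Optional free-text/list metadata stored on the cohort.
#' @return An object of class `mpla_cohort`: a list with elements `clinical`,
#'   `calls`, `provenance` and optionally `truth` (simulator ground truth).
#' @export
attach_calls <- function(clinical, calls = empty_calls(), provenance = list()) {
  clinical <- as.data.frame(clinical)
  calls <- normalize_calls(as.data.frame(calls))
  if (nrow(calls)) validate_calls(calls)
  lesion_key <- paste(clinical$patient_id, clinical$lesion_id)
  call_key <- paste(calls$patient_id, calls$lesion_id)
  orphan <- !call_key %in% lesion_key
  if (any(orphan))
    stop("calls reference unknown (patient, lesion) pair(s): ",
         paste(unique(call_key[orphan]), collapse = "; "), call. = FALSE)
  ord <- order(calls$patient_id, calls$lesion_id, calls$gene, calls$alteration)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  clinical <- clinical[order(clinical$patient_id, clinical$lesion_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(clinical = clinical, calls = calls, provenance = provenance),
            class = "mpla_cohort")
}

#' Patient-level view of a cohort
#'
#' @param cohort An `mpla_cohort`.
#' @return Data frame with one row per patient: `patient_id`, `sex`,
#'   `age_years`, `pack_years`, `n_lesions`.
#' @export
patient_table <- function(cohort) {
  clin <- cohort$clinical
  idx <- !duplicated(clin$patient_id)
  out <- clin[idx, c("patient_id", "sex", "age_years", "pack_years")]
  out$n_lesions <- as.integer(table(clin$patient_id)[out$patient_id])
  rownames(out) <- NULL
  out
}

#' @export
print.mpla_cohort <- function(x, ...) {
  cat("sMPLA cohort:", length(unique(x$clinical$patient_id)), "patients,",
      nrow(x$clinical), "lesions,", nrow(x$calls), "variant calls\n")
  invisible(x)
}

## lesion ids of one patient, in stable order
patient_lesions <- function(cohort, patient_id) {
  sort(cohort$clinical$lesion_id[cohort$clinical$patient_id == patient_id])
}
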