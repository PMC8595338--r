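test_that("variant table reader parses rows, maps classes and round-trips", {
  path <- write_tsv_text(c(
    variant_header,
    "P25\tT3\tTP53\tR175H\tnonsynonymous_SNV\t17\t7675088\tC\tT\t0.12",
    "P25\tT2\tEGFR\t19del\tnonframeshift_deletion\t\t\t\t\t0.08"))
  calls <- read_variant_table(path)
  expect_equal(nrow(calls), 2)
  expect_equal(event_key(calls$gene[1], calls$alteration[1],
                         calls$variant_class[1]),
               event_key("TP53", "R175H", "nonsynonymous_SNV"))
  expect_true(is.na(calls$ref[2]))   # blank optional fields read back as NA
  out <- tempfile(fileext = ".tsv")
  write_variant_table(calls, out)
  expect_equal(read_variant_table(out), calls, ignore_attr = TRUE)
})

test_that("variant reader accepts a header-only file and honours dialects", {
  path <- write_tsv_text(variant_header)
  expect_equal(nrow(read_variant_table(path)), 0)
  maf <- write_tsv_text(c(
    "patient_id\tlesion_id\tHugo_Symbol\talteration\tvariant_class",
    "P1\tT1\tEGFR\tL858R\tnonsynonymous_SNV"))
  calls <- read_variant_table(maf, dialect = c(gene = "Hugo_Symbol"))
  expect_equal(calls$gene, "EGFR")
})

test_that("variant reader rejects malformed input with informative errors", {
  expect_error(read_variant_table(write_tsv_text(c(
    "patient_id\tlesion_id\tgene\talteration",
    "P1\tT1\tEGFR\tL858R"))), "variant_class")
  expect_error(read_variant_table(write_tsv_text(c(
    variant_header,
    "P1\tT1\tEGFR\tL858R\tnonsynonymous_SNV\t\t\t\t\t1.2"))), "vaf")
  dup <- c(variant_header,
           "P1\tT1\tEGFR\tL858R\tnonsynonymous_SNV\t\t\t\t\t0.2",
           "P1\tT1\tEGFR\t l858r \tnonsynonymous_SNV\t\t\t\t\t0.3")
  expect_error(read_variant_table(write_tsv_text(dup)), "duplicate.*1, 2")
  expect_error(read_variant_table(write_tsv_text(c(
    variant_header,
    "P1\tT1\tEGFR\tL858R\tweird_class\t\t\t\t\t0.2"))), "variant_class")
  expect_error(read_variant_table(write_tsv_text(c(
    variant_header,
    "P1\tT1\tEGFR\tL858R\tnonsynonymous_SNV\t7\t100\tTT\tG\t0.2"))),
    "single")
})

test_that("event identity is total and ignores case, whitespace, coordinates", {
  expect_identical(event_key("EGFR", " l858r ", "nonsynonymous_SNV"),
                   event_key("EGFR", "L858R", "nonsynonymous_SNV"))
  expect_false(event_key("EGFR", "L858R", "nonsynonymous_SNV") ==
                 event_key("EGFR", "19del", "nonframeshift_deletion"))
})

test_that("clinical reader assembles patients and enforces consistency", {
  path <- write_tsv_text(c(
    paste(c("patient_id", "lesion_id", "sex", "age_years", "pack_years",
            "lobe", "max_diameter_cm", "ctr", "pathology", "node_status",
            "stage", "resection"), collapse = "\t"),
    "P19\tT1\tfemale\t58\t0\tRUL\t0.8\t0\tAIS\tN0\t0\twedge",
    "P19\tT2\tfemale\t58\t0\tRUL\t0.6\t0\tAIS\tN0\t0\twedge"))
  clin <- read_clinical_table(path)
  pt <- patient_table(attach_calls(clin))
  expect_equal(nrow(pt), 1)
  expect_equal(pt$n_lesions, 2L)
  expect_equal(clin$ctr, c(0, 0))   # ctr 0 (pure GGO) is a legal boundary

  conflicting <- sub("P19\tT2\tfemale", "P19\tT2\tmale",
                     readLines(path))
  expect_error(read_clinical_table(write_tsv_text(conflicting)),
               "conflicting patient-level 'sex'")
  bad_tok <- sub("AIS\tN0\t0\twedge\\b", "Weird\tN0\t0\twedge", readLines(path))
  expect_error(read_clinical_table(write_tsv_text(bad_tok)), "pathology")
})

test_that("attach_calls links, orders, preserves counts and flags orphans", {
  clinical <- make_clinical(c("P1", "P2"), c(2, 2))
  calls <- make_calls(list("P1", "T2", "TP53", "R175H"),
                      list("P1", "T1", "EGFR", "L858R"))
  cohort <- attach_calls(clinical, calls)
  expect_equal(nrow(cohort$calls), 2)            # no silent drops
  expect_equal(cohort$calls$gene, c("EGFR", "TP53"))  # stable ordering
  ## zero calls: wild-type lesions are first-class
  wt <- attach_calls(clinical)
  expect_equal(nrow(wt$calls), 0)
  expect_equal(nrow(wt$clinical), 4)
  expect_error(attach_calls(clinical, make_calls(list("P1", "T9", "EGFR", "L858R"))),
               "T9")
})

test_that("VCF reader derives calls, VAFs and symbolic classes", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##ALT=<ID=DUP,Description=\"dup\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    "7\t55191822\t.\tT\tG\t.\tPASS\tGENE=EGFR;PCHANGE=L858R;VCLASS=nonsynonymous_SNV\tGT:AF\t0/1:0.23\t0/0:.",
    "12\t25245351\t.\tC\tA\t.\tPASS\tGENE=KRAS;PCHANGE=G12C;VCLASS=nonsynonymous_SNV\tGT:AD\t0/0:50,0\t0/1:60,40",
    "17\t39700000\t.\tN\t<DUP>\t.\tPASS\tGENE=ERBB2\tGT\t0/0\t0/1"), vcf)
  map <- data.frame(sample = c("S1", "S2"), patient_id = "P1",
                    lesion_id = c("T1", "T2"), stringsAsFactors = FALSE)
  calls <- read_vcf_calls(vcf, map)
  expect_equal(nrow(calls), 3)
  ## record 1: alt genotype in S1 only
  expect_equal(calls$lesion_id[calls$gene == "EGFR"], "T1")
  ## AD = 60,40 -> vaf 0.4
  expect_equal(calls$vaf[calls$gene == "KRAS"], 0.4)
  ## symbolic <DUP> maps to amplification; round-trips through the TSV writer
  expect_equal(calls$variant_class[calls$gene == "ERBB2"], "amplification")
  out <- tempfile(fileext = ".tsv")
  write_variant_table(calls, out)
  expect_equal(read_variant_table(out)$variant_class,
               calls$variant_class)
  expect_error(read_vcf_calls(vcf, map[1, , drop = FALSE]), "S2")
})
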