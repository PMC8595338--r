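## Independent oracles and tiny in-code fixtures shared across the suite.
## Every oracle is a direct enumeration / closed form, kept free of the code
## paths it audits.

## two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n1 <- a + c
  xs <- max(0, n1 - (N - K)):min(K, n1)
  pr <- stats::dhyper(xs, K, N - K, n1)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

## exact two-sided rank-sum p by enumeration of all rank splits (ties get
## midranks)
ranksum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(n1 + n2, n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  pl <- mean(w_all <= w_obs); pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

## minimal state changes for one binary character on a fixed rooted tree by
## enumeration of every internal labeling (root forced to 0)
parsimony_oracle <- function(flat, tip_states) {
  internal <- which(!flat$is_tip)
  internal <- setdiff(internal, 1L)       # root fixed at 0
  states <- integer(flat$n)
  for (v in which(flat$is_tip))
    states[v] <- if (flat$label[v] == "germline") 0L else
      tip_states[[flat$label[v]]]
  n_int <- length(internal)
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    if (n_int > 0)
      states[internal] <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1L), 1L)
    changes <- sum(states[2:flat$n] != states[flat$parent[2:flat$n]])
    best <- min(best, changes)
  }
  best
}

## a minimal clinical table for constructed patients
make_clinical <- function(patient_id, n_lesions, sex = "female",
                          pack_years = 0) {
  do.call(rbind, lapply(seq_along(patient_id), function(i) {
    data.frame(patient_id = patient_id[i],
               lesion_id = paste0("T", seq_len(n_lesions[i])),
               sex = if (length(sex) > 1) sex[i] else sex,
               age_years = 60L,
               pack_years = if (length(pack_years) > 1) pack_years[i] else
                 pack_years,
               lobe = "RUL", max_diameter_cm = 1.5, ctr = 0.4,
               pathology = "Acinar", node_status = "N0", stage = "IA1",
               resection = "lobectomy", stringsAsFactors = FALSE)
  }))
}

## call rows from compact (patient, lesion, gene, alteration[, class, vaf])
make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], lesion_id = r[[2]], gene = r[[3]],
               alteration = r[[4]],
               variant_class = if (length(r) >= 5) r[[5]] else
                 "nonsynonymous_SNV",
               chrom = NA_character_, pos = NA_integer_,
               ref = NA_character_, alt = NA_character_,
               vaf = if (length(r) >= 6) as.numeric(r[[6]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

## cohort with one patient realizing a given presence matrix
cohort_from_presence <- function(presence, patient_id = "PX") {
  n_lesions <- ncol(presence)
  clinical <- make_clinical(patient_id, n_lesions)
  rows <- list()
  for (i in seq_len(nrow(presence))) for (j in seq_len(n_lesions)) {
    if (presence[i, j])
      rows[[length(rows) + 1L]] <- list(patient_id, paste0("T", j),
                                        "GENE", paste0("M", i, "X"))
  }
  calls <- if (length(rows)) do.call(make_calls, rows) else NULL
  if (is.null(calls)) attach_calls(clinical) else attach_calls(clinical, calls)
}

## random presence matrix with no empty event rows
random_presence <- function(n_events, n_lesions) {
  m <- matrix(stats::runif(n_events * n_lesions) < 0.45, n_events, n_lesions)
  empty <- rowSums(m) == 0
  if (any(empty)) m[cbind(which(empty),
                          sample(n_lesions, sum(empty), replace = TRUE))] <- TRUE
  m
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

variant_header <- "patient_id\tlesion_id\tgene\talteration\tvariant_class\tchrom\tpos\tref\talt\tvaf"
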