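#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' commercial statistics packages this pipeline mirrors), unlike base
#' `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' t-based confidence interval for a proportion
#'
#' Treats the n binary indicators as observations and forms the mean +/- t
#' interval with the Bessel-corrected indicator standard deviation:
#' p-hat = k/n, s = sqrt(k(n-k) / (n(n-1))), half-width =
#' t(1-alpha/2, n-1) * s / sqrt(n). Bounds are deliberately not clipped to
#' [0,1] (for small k the lower bound can be negative). With k = 0 or k = n
#' the interval degenerates to a point and is flagged.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (n >= 2).
#' @param level Confidence level, default 0.95.
#' @return List of class `proportion_ci`: `k`, `n`, `level`, `estimate`,
#'   `lower`, `upper`, `method`, `degenerate`.
#' @examples
#' proportion_ci(57, 93)  # 0.512 to 0.714 at 3 dp
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n < 2) stop("proportion_ci requires n >= 2", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  est <- k / n
  s <- sqrt(k * (n - k) / (n * (n - 1)))
  hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  structure(list(k = k, n = n, level = level, estimate = est,
                 lower = est - hw, upper = est + hw,
                 method = "t-interval (Bessel-corrected indicator SD)",
                 degenerate = (k == 0 || k == n)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f (%.0f%% CI, %.3f to %.3f)%s\n", x$k, x$n,
              x$estimate, 100 * x$level,
              round_half_up(x$lower, 3), round_half_up(x$upper, 3),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

as_count_table <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != floor(m))) stop("counts must be non-negative integers",
                                             call. = FALSE)
  m
}

expected_counts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1), upper
#' tail p. All row and column marginals must be positive.
#'
#' @param table An r-by-c matrix (or table) of counts.
#' @return List of class `contingency_result`: `observed`, `expected`,
#'   `test_used` ("chi_square"), `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  m <- as_count_table(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square requires all marginals > 0", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(observed = m, expected = expected_counts(m),
                 test_used = "chi_square",
                 statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "contingency_result")
}

#' Fisher's exact test
#'
#' Two-sided exact p: the sum of probabilities, under fixed margins, of all
#' tables at most as probable as the one observed. 2x2 tables are always
#' enumerated exactly; larger tables are evaluated exactly while the
#' enumeration is tractable, else by Monte Carlo with a fixed seed.
#'
#' @param table Matrix of counts.
#' @param mc_reps Monte Carlo replicates when enumeration is infeasible.
#' @param mc_seed Seed for the Monte Carlo path (logged in the result).
#' @return A `contingency_result` with `test_used` "fisher_exact" or
#'   "fisher_mc" (the latter carries `mc_seed`/`mc_reps`); `statistic` is NA
#'   for exact tests.
#' @export
fisher_exact <- function(table, mc_reps = 1e5, mc_seed = 20211103) {
  m <- as_count_table(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ## a zero marginal fixes the table completely: no evidence against
    ## independence
    return(structure(list(observed = m, expected = expected_counts(m),
                          test_used = "fisher_exact", statistic = NA_real_,
                          df = NA_real_, p_value = 1),
                     class = "contingency_result"))
  }
  ## upper bound on the number of tables with these margins: for two-row
  ## tables each column is free within its sum; larger tables use a crude
  ## stars-and-bars product
  n_tables <- if (min(dim(m)) == 2) {
    mm <- if (nrow(m) == 2) m else t(m)
    prod(pmin(colSums(mm), sum(mm[1, ])) + 1)
  } else {
    prod(choose(rowSums(m) + ncol(m) - 1, ncol(m) - 1))
  }
  enumerable <- all(dim(m) == 2) || n_tables <= 1e7
  if (enumerable) {
    res <- stats::fisher.test(m, workspace = 2e7)
    structure(list(observed = m, expected = expected_counts(m),
                   test_used = "fisher_exact", statistic = NA_real_,
                   df = NA_real_, p_value = res$p.value),
              class = "contingency_result")
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(mc_seed)
    res <- stats::fisher.test(m, simulate.p.value = TRUE, B = mc_reps)
    structure(list(observed = m, expected = expected_counts(m),
                   test_used = "fisher_mc", statistic = NA_real_,
                   df = NA_real_, p_value = res$p.value,
                   mc_seed = mc_seed, mc_reps = mc_reps),
              class = "contingency_result")
  }
}

## save/restore the global RNG state so statistical kernels do not perturb
## user-visible streams
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration when both groups have at most 12
#' observations and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and no continuity correction. If all values are
#' identical across both groups, p = 1 with a notice.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List of class `rank_sum_result`: `n1`, `n2`, `U`, `p_value`,
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    message("wilcoxon_rank_sum: all values identical; p = 1")
    return(structure(list(n1 = length(x), n2 = length(y),
                          U = length(x) * length(y) / 2, p_value = 1,
                          exact = FALSE),
                     class = "rank_sum_result"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = FALSE))
  structure(list(n1 = length(x), n2 = length(y),
                 U = unname(res$statistic), p_value = res$p.value,
                 exact = exact),
            class = "rank_sum_result")
}

#' Test selection rule for contingency tables
#'
#' 2x2: chi-square if every expected count is >= 5, else Fisher exact.
#' Larger tables: chi-square if fewer than 20% of expected counts are below 5
#' and none is below 1, else Fisher (exact when enumerable, else Monte Carlo).
#'
#' @param table Matrix of counts.
#' @return A `contingency_result`; `test_used` names the test applied.
#' @export
select_test <- function(table) {
  m <- as_count_table(table)
  e <- expected_counts(m)
  use_chi <- if (all(dim(m) == 2)) {
    all(e >= 5)
  } else {
    mean(e < 5) < 0.2 && all(e >= 1)
  }
  if (use_chi) chi_square_test(m) else fisher_exact(m)
}

## ---- covariate binnings (closed, upper-inclusive where the field labels
## ---- bins "a-b") ----

bin_pack_years <- function(py) {
  cut(py, breaks = c(-Inf, 0, 30 - 1e-9, Inf),
      labels = c("0", "0-30", ">=30"))
}

bin_diameter <- function(cm) {
  cut(cm, breaks = c(0, 1, 2, 3, Inf), labels = c("<=1", "1-2", "2-3", ">3"),
      right = TRUE)
}

bin_ctr <- function(ctr) {
  cut(ctr, breaks = c(-1e-9, 0.25, 0.5, 1), labels = c("0-0.25", "0.25-0.5", "0.5-1"),
      right = TRUE)
}

collapse_stage <- function(stage) {
  out <- rep(NA_character_, length(stage))
  out[stage == "0"] <- "0"
  out[stage %in% c("IA1", "IA2", "IA3", "IB")] <- "I"
  out[stage %in% c("IIA", "IIB")] <- "II"
  out[stage %in% c("IIIA", "IIIB")] <- "III"
  out
}

## lesion-level covariate columns used by the screen
lesion_covariates <- function(clinical) {
  data.frame(
    patient_id = clinical$patient_id,
    lesion_id = clinical$lesion_id,
    sex = clinical$sex,
    pack_years_bin = as.character(bin_pack_years(clinical$pack_years)),
    diameter_bin = as.character(bin_diameter(clinical$max_diameter_cm)),
    pathology = clinical$pathology,
    ctr_bin = as.character(bin_ctr(clinical$ctr)),
    stage_group = collapse_stage(clinical$stage),
    stringsAsFactors = FALSE)
}

## per-lesion gene mutation status: >= 1 SNV/indel event in that gene
## (amplification and fusion excluded from gene-status tables)
gene_status <- function(cohort, gene, alteration = NULL,
                        exclude_alterations = NULL) {
  calls <- cohort$calls
  keep <- calls$gene == gene &
    !calls$variant_class %in% vaf_optional_classes()
  if (!is.null(alteration)) keep <- keep & calls$alteration == alteration
  key <- paste(cohort$clinical$patient_id, cohort$clinical$lesion_id)
  mut_key <- unique(paste(calls$patient_id, calls$lesion_id)[keep])
  status <- key %in% mut_key
  if (!is.null(exclude_alterations)) {
    ## lesions carrying an excluded alteration (and not the target) drop out
    excl <- calls$gene == gene & calls$alteration %in% exclude_alterations
    excl_key <- unique(paste(calls$patient_id, calls$lesion_id)[excl])
    status[!status & key %in% excl_key] <- NA
  }
  status
}

#' Gene-by-covariate association screen
#'
#' For each gene and each lesion-level covariate, tabulates mutated vs
#' wild-type lesion counts across covariate levels and applies the
#' [select_test()] rule. Covariates with a single observed level, and genes
#' with no mutant lesions, are skipped with a notice.
#'
#' @param cohort An `mpla_cohort`.
#' @param genes Character vector of gene symbols to screen.
#' @param covariates Covariate names among `sex`, `pack_years_bin`,
#'   `diameter_bin`, `pathology`, `ctr_bin`, `stage_group`.
#' @return List of class `association_screen`: `results` (one entry per
#'   gene-covariate pair with `observed`, `test_used`, `p_value`) and `table`
#'   (long-format data frame gene/covariate/level/mutated_n/wild_n/test/p).
#' @export
association_screen <- function(cohort,
                               genes = c("EGFR", "KRAS", "TP53"),
                               covariates = c("sex", "pack_years_bin",
                                              "diameter_bin", "pathology",
                                              "ctr_bin", "stage_group")) {
  cov <- lesion_covariates(cohort$clinical)
  results <- list()
  rows <- list()
  for (gene in genes) {
    status <- gene_status(cohort, gene)
    if (!any(status)) {
      message("association_screen: no mutant lesions for ", gene, "; skipped")
      next
    }
    for (cv in covariates) {
      levels_present <- unique(cov[[cv]])
      if (length(levels_present) < 2) {
        message("association_screen: covariate ", cv,
                " has a single observed level; skipped")
        next
      }
      tab <- table(factor(cov[[cv]]), factor(status, levels = c(TRUE, FALSE),
                                             labels = c("mutated", "wild")))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      res <- select_test(tab)
      id <- paste(gene, cv, sep = ".")
      results[[id]] <- list(gene = gene, covariate = cv, observed = tab,
                            test_used = res$test_used, p_value = res$p_value)
      for (lv in rownames(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, covariate = cv, level = lv,
          mutated_n = tab[lv, "mutated"], wild_n = tab[lv, "wild"],
          test = res$test_used, p = res$p_value, stringsAsFactors = FALSE)
    }
  }
  structure(list(results = results,
                 table = if (length(rows)) do.call(rbind, rows) else
                   data.frame()),
            class = "association_screen")
}

#' EGFR-subtype vs CTR screen
#'
#' Compares L858R-mutant and 19del-mutant lesions against EGFR wild-type
#' lesions across CTR bins, each subtype excluding lesions carrying any other
#' EGFR alteration (so the margins are subtype-mutant + EGFR-wild only).
#'
#' @param cohort An `mpla_cohort`.
#' @return List with one `contingency_result`-style entry per subtype
#'   (`L858R`, `19del`), each with `observed`, `test_used`, `p_value`.
#' @export
egfr_subtype_screen <- function(cohort) {
  cov <- lesion_covariates(cohort$clinical)
  any_egfr <- gene_status(cohort, "EGFR")
  out <- list()
  for (sub in c("L858R", "19del")) {
    this <- gene_status(cohort, "EGFR", alteration = sub)
    keep <- this | !any_egfr          # subtype-mutant or fully EGFR-wild
    tab <- table(factor(cov$ctr_bin[keep]),
                 factor(this[keep], levels = c(TRUE, FALSE),
                        labels = c("mutated", "wild")))
    res <- select_test(tab)
    out[[sub]] <- list(observed = tab, test_used = res$test_used,
                       p_value = res$p_value)
  }
  out
}
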