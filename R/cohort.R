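#' Seminoma study cohort metadata
#'
#' Per-patient clinical characteristics of the 15-patient seminoma cohort
#' (5 non-metastasized, 5 lymphogen metastasized, 5 occult metastasized):
#' age at diagnosis, primary tumor size, lymphatic/venous invasion (pL/pV),
#' pT stage, rete testis infiltration, initial clinical stage, total RNA
#' yield per 2.5 ml whole blood, and RNA integrity number (RIN).  These
#' values are inputs to [summarize_cohort()] and to downstream reporting.
#'
#' @return Data.frame with columns `sample_id`, `group`, `age`,
#'   `tumor_size_mm`, `pL`, `pV`, `pT`, `rete_testis`, `stage`,
#'   `total_rna_ug`, `rin`.
#' @export
#' @examples
#' aggregate(tumor_size_mm ~ group, seminoma_cohort(), mean)
seminoma_cohort <- function() {
  data.frame(
    sample_id = c(paste0("NM", 1:5), paste0("L", 1:5), paste0("O", 1:5)),
    group = rep(c("non_metastasized", "lymphogen", "occult"), each = 5),
    age = c(38, 50, 31, 42, 35,
            32, 50, 43, 42, 61,
            33, 37, 37, 31, 23),
    tumor_size_mm = c(14, 22, 19, 45, 19,
                      40, 12, 50, 45, 42,
                      55, 35, 30, 18, 55),
    pL = c(0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0),
    pV = rep(0, 15),
    pT = c(1, 1, 1, 1, 1, 1, 3, 1, 2, 1, 2, 1, 1, 1, 1),
    rete_testis = c("n", "n", "n", "y", "y",
                    "n", "n", "n", "y", "y",
                    "n", "y", "n", "n", "n"),
    stage = c(rep("cSI", 5),
              c("cSIIb", "cSIIc", "cSIIb", "cSIIb", "cSIIc"),
              rep("cSI", 5)),
    total_rna_ug = c(7.6, 8.6, 6.4, 3.9, 8.2,
                     5.0, 5.1, 8.1, 3.2, 3.2,
                     5.0, 4.1, 7.0, 8.1, 10.0),
    rin = c(7.8, 8.3, 7.0, 8.0, 7.6,
            8.5, 8.8, 8.3, 9.3, 8.2,
            6.0, 7.4, 7.8, 7.4, 6.4),
    stringsAsFactors = FALSE)
}

#' Published candidate small-RNA lists of the three comparisons
#'
#' The significant small RNAs of the univariate logistic screen for the
#' three comparisons against the non-metastasized reference: lymphogen
#' metastasized (33 ids), occult metastasized (34 ids) and both subtypes
#' combined (35 ids).  These lists are the input to [overlap_stats()] for
#' the study's Venn/overlap figures.
#'
#' @return Named list of three character vectors
#'   (`lymphogen`, `occult`, `combined`).
#' @export
seminoma_candidate_lists <- function() {
  list(
    lymphogen = c(
      "let-7f-1", "let-7f-2", "mir-15a", "mir-16-1", "mir-92a-1",
      "mir-92a-2", "mir-183", "let-7g", "mir-15b", "mir-23b", "mir-130a",
      "mir-142", "mir-191", "mir-126", "mir-296", "mir-331", "mir-425",
      "mir-451a", "mir-92b", "mir-574", "mir-4286", "mir-4454",
      "ENST00000516594", "ENST00000363271", "ENST00000459091",
      "ENST00000516350", "ENST00000517209", "ENST00000516507",
      "ENST00000363865", "ENST00000362808", "ENST00000364409",
      "ENST00000363745", "ENST00000461337"),
    occult = c(
      "let-7a-1", "let-7a-2", "let-7a-3", "let-7b", "let-7d", "let-7f-1",
      "let-7f-2", "mir-18a", "mir-92a-1", "mir-92a-2", "mir-99a", "let-7g",
      "mir-30b", "mir-130a", "mir-191", "mir-29c", "mir-296", "mir-378a",
      "mir-326", "mir-331", "mir-339", "mir-425", "mir-451a", "mir-92b",
      "mir-574", "mir-660", "mir-664", "mir-4286", "mir-4454",
      "ENST00000365160", "ENST00000387347", "ENST00000482884",
      "ENST00000459949", "ENST00000410361"),
    combined = c(
      "let-7f-1", "mir-16-1", "mir-18a", "mir-23a", "mir-92a-1",
      "mir-92a-2", "mir-99a", "mir-183", "let-7g", "mir-23b", "mir-130a",
      "mir-191", "mir-296", "mir-378a", "mir-326", "mir-331", "mir-339",
      "mir-425", "mir-451a", "mir-92b", "mir-574", "mir-4286", "mir-4454",
      "ENST00000516594", "ENST00000365160", "ENST00000363271",
      "ENST00000459091", "ENST00000516350", "ENST00000363865",
      "ENST00000362808", "ENST00000364409", "ENST00000363745",
      "ENST00000387347", "ENST00000459949", "ENST00000461337"))
}

#' Descriptive cohort summary
#'
#' Per-group arithmetic mean and n-1 standard deviation of the numeric
#' clinical variables (age, tumor size, total RNA yield, RIN), plus tallies
#' of the categorical variables (pL, pV, pT, rete testis infiltration,
#' clinical stage).  Display values are rounded to one decimal, half away
#' from zero; full-precision values are carried alongside and are the ones
#' used in any further computation.
#'
#' @param metadata Cohort data.frame (see [seminoma_cohort()] for the
#'   column layout); only columns present are summarized.
#' @return A list with `numeric` (long data.frame: `group`, `variable`,
#'   `n`, `mean`, `sd`, `mean_display`, `sd_display`; `sd` is `NA` for
#'   single-sample groups) and `categorical` (named list of
#'   group x level contingency tables).
#' @export
summarize_cohort <- function(metadata) {
  if (!"group" %in% names(metadata)) stopf("metadata needs a group column")
  num_vars <- intersect(c("age", "tumor_size_mm", "total_rna_ug", "rin"),
                        names(metadata))
  cat_vars <- intersect(c("pL", "pV", "pT", "rete_testis", "stage"),
                        names(metadata))
  for (v in num_vars)
    if (!is.numeric(metadata[[v]]))
      stopf("non-numeric value in numeric column '%s'", v)
  rows <- list()
  for (g in unique(metadata$group)) {
    sub <- metadata[metadata$group == g, , drop = FALSE]
    for (v in num_vars) {
      m <- mean(sub[[v]])
      s <- if (nrow(sub) >= 2) sd(sub[[v]]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, n = nrow(sub), mean = m, sd = s,
        mean_display = round_half_up(m, 1),
        sd_display = round_half_up(s, 1),
        stringsAsFactors = FALSE)
    }
  }
  cats <- lapply(setNames(cat_vars, cat_vars), function(v)
    table(metadata$group, metadata[[v]]))
  num <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), variable = character(), n = integer(),
               mean = numeric(), sd = numeric(), mean_display = numeric(),
               sd_display = numeric(), stringsAsFactors = FALSE)
  list(numeric = num, categorical = cats)
}
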