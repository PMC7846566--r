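mpus_feature_names <- c("sws", "swa", "bscan", "hscan", "pe_nlp", "wir_nlp")

#' Cohort specification for synthetic feature tables
#'
#' @param label one of `"normal"`, `"low_fat"`, `"high_fat"`.
#' @param n_subjects rows to draw (>= 2).
#' @param feature_means named 6-vector of cohort means in measurement units:
#'   `sws` (m/s), `swa` (Np/m), `bscan` (a.u.), `hscan` (dimensionless in
#'   (0, 1)), `pe_nlp`, `wir_nlp` (dimensionless).
#' @param feature_sds named 6-vector of within-cohort SDs (all > 0).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(label = c("normal", "low_fat", "high_fat"),
                        n_subjects, feature_means, feature_sds) {
  label <- match.arg(label)
  feature_means <- feature_means[mpus_feature_names]
  feature_sds <- feature_sds[mpus_feature_names]
  stopifnot(n_subjects >= 2,
            !anyNA(feature_means), !anyNA(feature_sds),
            all(feature_sds > 0))
  if (feature_means["hscan"] <= 0 || feature_means["hscan"] >= 1) {
    stop("hscan intensity mean must lie in (0, 1); it is a B/(R+B) ratio")
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 feature_means = feature_means, feature_sds = feature_sds),
            class = "cohort_spec")
}

#' Default study-mirroring cohorts
#'
#' Three cohorts sized like the rat study design: 21 animals (9 control + 12
#' on the steatogenic diet) imaged at 0, 2 and 6 weeks; "normal" pools the 21
#' baseline scans with the 9 control scans at each later week (39 rows);
#' "low_fat" and "high_fat" are the diet group at weeks 2 and 6 (12 rows
#' each). The means and SDs are package defaults chosen to mirror the
#' direction and rough scale of the reported group trends (the source study
#' publishes group boxplots, not numbers); the shear-wave values of the
#' high-fat cohort use the published example pair (1.36 m/s, 113.9 Np/m).
#'
#' @return list of three [cohort_spec()]s.
#' @export
study_cohorts <- function() {
  sds <- c(sws = 0.06, swa = 5, bscan = 0.08, hscan = 0.03,
           pe_nlp = 0.06, wir_nlp = 0.05)
  list(
    cohort_spec("normal", 39,
                c(sws = 1.48, swa = 96, bscan = 1.00, hscan = 0.40,
                  pe_nlp = 0.78, wir_nlp = 0.60), sds),
    cohort_spec("low_fat", 12,
                c(sws = 1.42, swa = 106, bscan = 1.25, hscan = 0.50,
                  pe_nlp = 0.60, wir_nlp = 0.45), sds),
    cohort_spec("high_fat", 12,
                c(sws = 1.36, swa = 113.9, bscan = 1.55, hscan = 0.58,
                  pe_nlp = 0.45, wir_nlp = 0.30), sds))
}

#' Generate a synthetic mpUS feature table
#'
#' Draws each subject row's six features independently from the cohort's
#' Gaussian. With the default [study_cohorts()] configuration the table has
#' 63 rows with class counts (39, 12, 12) and the study's subject/timepoint
#' bookkeeping: normal = 21 baseline + 9 control at week 2 + 9 at week 6;
#' low_fat = diet group at week 2; high_fat = diet group at week 6.
#'
#' @param cohorts list of [cohort_spec()]s with distinct labels.
#' @param seed integer seed.
#' @return a `data.frame` of class `feature_table` with columns
#'   `subject`, `timepoint`, `cohort`, and the six features.
#' @export
gen_feature_table <- function(cohorts = study_cohorts(), seed = 1) {
  labels <- vapply(cohorts, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("cohort labels must be distinct")
  rows <- with_seed_maybe(seed, {
    lapply(cohorts, function(co) {
      m <- vapply(mpus_feature_names, function(f) {
        rnorm(co$n_subjects, co$feature_means[[f]], co$feature_sds[[f]])
      }, numeric(co$n_subjects))
      if (co$n_subjects == 1) m <- matrix(m, nrow = 1)
      df <- as.data.frame(m)
      names(df) <- mpus_feature_names
      df$cohort <- co$label
      df
    })
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(subject_timepoint_design(vapply(cohorts, `[[`, 0L, "n_subjects"),
                                        labels), tab)
  tab <- tab[, c("subject", "timepoint", "cohort", mpus_feature_names)]
  class(tab) <- c("feature_table", "data.frame")
  rownames(tab) <- NULL
  tab
}

# study bookkeeping columns. For the default 39/12/12 design reconstruct the
# rat/week mapping; otherwise number subjects per cohort at week 0.
subject_timepoint_design <- function(n_per, labels) {
  if (identical(labels, c("normal", "low_fat", "high_fat")) &&
      identical(as.integer(n_per), c(39L, 12L, 12L))) {
    ids <- c(sprintf("C%02d", 1:9), sprintf("M%02d", 1:12))
    normal <- data.frame(subject = c(ids, ids[1:9], ids[1:9]),
                         timepoint = c(rep(0L, 21), rep(2L, 9), rep(6L, 9)))
    low <- data.frame(subject = ids[10:21], timepoint = 2L)
    high <- data.frame(subject = ids[10:21], timepoint = 6L)
    return(rbind(normal, low, high))
  }
  do.call(rbind, lapply(seq_along(labels), function(i) {
    data.frame(subject = sprintf("%s%03d", toupper(substr(labels[i], 1, 1)),
                                 seq_len(n_per[i])),
               timepoint = 0L)
  }))
}

#' Write / read a feature table as CSV
#'
#' Column order and header are fixed:
#' `subject,timepoint,cohort,sws,swa,bscan,hscan,pe_nlp,wir_nlp`.
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("subject", "timepoint", "cohort", mpus_feature_names)
  stopifnot(all(cols %in% names(table)))
  write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("subject", "timepoint", "cohort", mpus_feature_names)
  if (!all(cols %in% names(tab))) {
    stop("feature CSV must have header: ", paste(cols, collapse = ","))
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}
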