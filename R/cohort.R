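# Two-group comparison layer: Student t / Mann-Whitney U for continuous
# variables, chi-square / Fisher exact for categorical ones, with the
# auto-selection rules documented below, and a Table-style cohort summary.

#' Compare a continuous variable between two groups
#'
#' Two-sided two-sample comparison. `method = "t"` is the classical
#' equal-variance Student t test (Welch behind `welch = TRUE`);
#' `"mann_whitney"` is the Mann-Whitney U (Wilcoxon rank-sum) test.
#' `"auto"` picks Student t when a Shapiro-Wilk test does not reject
#' normality (p > 0.05) in either group, and Mann-Whitney otherwise —
#' the common clinical-reporting convention of reserving the rank test
#' for non-normal variables.
#'
#' @param a,b numeric vectors, the two groups' values.
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param welch use the Welch (unequal-variance) t statistic.
#' @param variable label carried into the output.
#' @return one-row `data.frame`: variable, n per group, mean/sd and
#'   median/range per group, test used, statistic, two-sided `p_value`.
#' @examples
#' compareContinuous(rnorm(20, 10), rnorm(20, 12), method = "t")
#' @export
compareContinuous <- function(a, b, method = c("auto", "t", "mann_whitney"),
                              welch = FALSE, variable = NA_character_) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (method == "auto") {
    normal <- function(x) {
      if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > 0.05
    }
    method <- if (normal(a) && normal(b)) "t" else "mann_whitney"
  }
  if (method == "t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t test needs at least two observations per group")
    if (stats::sd(c(a, b)) == 0)
      stop("degenerate-variance error: samples are constant and identical")
    ht <- stats::t.test(a, b, var.equal = !welch)
    test <- if (welch) "welch_t" else "t"
  } else {
    if (!length(a) || !length(b))
      stop("Mann-Whitney needs at least one observation per group")
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "mann_whitney"
  }
  data.frame(variable = variable, n_a = length(a), n_b = length(b),
             mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b),
             median_a = stats::median(a), min_a = min(a), max_a = max(a),
             median_b = stats::median(b), min_b = min(b), max_b = max(b),
             test = test, statistic = unname(ht$statistic),
             p_value = ht$p.value, stringsAsFactors = FALSE)
}

#' Build a 2x2 event table
#'
#' Arranges event counts as a 2x2 matrix with groups in columns and
#' event/no-event in rows, e.g. 3 of 66 versus 9 of 29 patients with
#' appropriate ICD therapy.
#'
#' @param eventsA,nA events and group size in group A.
#' @param eventsB,nB events and group size in group B.
#' @return 2x2 integer matrix (rows: event, no event; cols: A, B).
#' @examples
#' eventTable(3, 66, 9, 29)
#' @export
eventTable <- function(eventsA, nA, eventsB, nB) {
  if (any(c(eventsA, nA, eventsB, nB) < 0) || eventsA > nA || eventsB > nB)
    stop("invalid 2x2 table counts")
  matrix(as.integer(c(eventsA, nA - eventsA, eventsB, nB - eventsB)), 2L, 2L,
         dimnames = list(c("event", "no_event"), c("A", "B")))
}

#' Compare a categorical variable between two groups
#'
#' Two-sided test on a 2x2 contingency table. `"chi_square"` is Pearson's
#' chi-square (no continuity correction unless `correct = TRUE`);
#' `"fisher"` is the Fisher exact test with the two-sided p defined as the
#' sum of the probabilities of all tables (at fixed margins) no more
#' probable than the observed one. `"auto"` selects Fisher whenever any
#' expected cell count is below 5, chi-square otherwise.
#'
#' @param table 2x2 matrix of counts (see [eventTable()]).
#' @param method `"auto"`, `"chi_square"` or `"fisher"`.
#' @param correct apply the Yates continuity correction to chi-square.
#' @param variable label carried into the output.
#' @return one-row `data.frame` with counts, test used, statistic (NA for
#'   Fisher) and two-sided `p_value`.
#' @examples
#' compareCategorical(eventTable(3, 66, 9, 29))  # Fisher, p < 0.01
#' @export
compareCategorical <- function(table, method = c("auto", "chi_square", "fisher"),
                               correct = FALSE, variable = NA_character_) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 matrix of non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("margin error: every row and column margin must be positive")
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "fisher" else "chi_square"
  }
  if (method == "chi_square") {
    ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
    stat <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(table)
    stat <- NA_real_
  }
  data.frame(variable = variable,
             a = table[1L, 1L], b = table[2L, 1L],
             c = table[1L, 2L], d = table[2L, 2L],
             n_a = sum(table[, 1L]), n_b = sum(table[, 2L]),
             test = method, statistic = stat, p_value = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Table-style two-group summary of a cohort
#'
#' One comparison row per requested variable, in the style of a clinical
#' baseline/CMR characteristics table: continuous variables are compared
#' by the auto-selected t / Mann-Whitney test and summarized as mean +/-
#' SD (or median and range when non-normal); binary variables (logical or
#' 0/1) as frequencies with the auto-selected chi-square / Fisher test.
#' Optional strata repeat the comparisons within subsets (e.g. patients
#' with LVEF <= 35%, or anterior infarct localization); a stratum in which
#' either group is empty is flagged and not tested.
#'
#' @param records `data.frame`, one row per patient.
#' @param group name of the two-level grouping column.
#' @param variables character vector of columns to compare; default: all
#'   numeric and logical columns except `group` and `id`.
#' @param strata named list of logical vectors (length `nrow(records)`)
#'   defining subsets; comparisons for the full cohort appear under
#'   stratum `"all"`.
#' @return `data.frame` with one row per variable x stratum: summary
#'   strings per group, test used, p-value, group sizes, and a `note`
#'   column flagging untestable rows.
#' @export
summarizeCohort <- function(records, group = "group", variables = NULL,
                            strata = NULL) {
  stopifnot(is.data.frame(records), group %in% names(records))
  glab <- unique(as.character(records[[group]]))
  if (length(glab) != 2L)
    stop("grouping column must have exactly two levels, got: ",
         paste(glab, collapse = ", "))
  if (is.null(variables)) {
    keep <- vapply(records, function(x) is.numeric(x) || is.logical(x), TRUE)
    variables <- setdiff(names(records)[keep], c(group, "id"))
  }
  strata <- c(list(all = rep(TRUE, nrow(records))), strata)
  rows <- list()
  for (sn in names(strata)) {
    sub <- records[strata[[sn]] & !is.na(strata[[sn]]), , drop = FALSE]
    ga <- sub[sub[[group]] == glab[1L], , drop = FALSE]
    gb <- sub[sub[[group]] == glab[2L], , drop = FALSE]
    for (v in variables) {
      row <- .compareOne(ga[[v]], gb[[v]], v, glab)
      row$stratum <- sn
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("stratum", setdiff(names(out), "stratum"))]
}

.compareOne <- function(a, b, v, glab) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  skel <- data.frame(variable = v, group_a = glab[1L], group_b = glab[2L],
                     n_a = length(a), n_b = length(b),
                     summary_a = NA_character_, summary_b = NA_character_,
                     test = NA_character_, p_value = NA_real_,
                     note = "", stringsAsFactors = FALSE)
  if (!length(a) || !length(b)) {
    skel$note <- "empty stratum: not tested"
    return(skel)
  }
  binary <- (is.logical(a) && is.logical(b)) ||
    (all(a %in% 0:1) && all(b %in% 0:1) && length(unique(c(a, b))) <= 2)
  if (binary) {
    tab <- eventTable(sum(a), length(a), sum(b), length(b))
    if (any(rowSums(tab) == 0)) {
      skel$summary_a <- sprintf("%d (%.0f%%)", sum(a), 100 * mean(a))
      skel$summary_b <- sprintf("%d (%.0f%%)", sum(b), 100 * mean(b))
      skel$note <- "degenerate table: not tested"
      return(skel)
    }
    cmp <- compareCategorical(tab, variable = v)
    skel$summary_a <- sprintf("%d (%.0f%%)", sum(a), 100 * mean(a))
    skel$summary_b <- sprintf("%d (%.0f%%)", sum(b), 100 * mean(b))
    skel$test <- cmp$test
    skel$p_value <- cmp$p_value
    return(skel)
  }
  if (length(a) < 2L || length(b) < 2L || stats::sd(c(a, b)) == 0) {
    skel$note <- "insufficient data: not tested"
    return(skel)
  }
  cmp <- compareContinuous(a, b, method = "auto", variable = v)
  if (cmp$test == "t") {
    skel$summary_a <- sprintf("%.3g ± %.3g", cmp$mean_a, cmp$sd_a)
    skel$summary_b <- sprintf("%.3g ± %.3g", cmp$mean_b, cmp$sd_b)
  } else {
    skel$summary_a <- sprintf("%.3g (%.3g-%.3g)", cmp$median_a, cmp$min_a, cmp$max_a)
    skel$summary_b <- sprintf("%.3g (%.3g-%.3g)", cmp$median_b, cmp$min_b, cmp$max_b)
  }
  skel$test <- cmp$test
  skel$p_value <- cmp$p_value
  skel
}
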