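# Cohort-level statistics: first-snapshot selection, Wilcoxon rank-sum
# tests of each pathology group against normal tissue, Bonferroni
# correction, and a tabular report.

#' Select one snapshot per patient
#'
#' For each patient, the lowest-index snapshot that was not excluded
#' enters the statistical evaluation (the first snapshot normally; the
#' second when the first showed a segmentation irregularity). Patients
#' whose snapshots were all excluded are dropped.
#'
#' @param records data frame of per-snapshot cohort records with columns
#'   `patient_id`, `snapshot_index` and `excluded`.
#' @return data frame with at most one row per patient; dropped patients
#'   are listed in the `dropped_patients` attribute.
#' @export
select_snapshots <- function(records) {
  records <- as.data.frame(records)
  if (is.null(records$excluded)) records$excluded <- FALSE
  keep <- integer(0)
  dropped <- character(0)
  for (pid in unique(records$patient_id)) {
    rows <- which(records$patient_id == pid & !records$excluded)
    if (!length(rows)) {
      dropped <- c(dropped, as.character(pid))
      next
    }
    keep <- c(keep, rows[which.min(records$snapshot_index[rows])])
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_patients") <- dropped
  out
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. The exact null
#' distribution is used when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The method used is recorded in the result.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact force the exact (`TRUE`) or approximate (`FALSE`) method;
#'   `NULL` (default) selects automatically.
#' @return list with `p_value`, `statistic` (Mann-Whitney U of `x`) and
#'   `method` (`"exact"` or `"normal-approximation"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ties <- table(r)
  has_ties <- any(ties > 1)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- (nx + ny <= 12) && !has_ties
  if (exact && has_ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- 2 * min(stats::pwilcox(U, nx, ny),
                 1 - stats::pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- nx + ny
    tie_term <- sum(ties^3 - ties)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(list(p_value = 1, statistic = U,
                                 method = "normal-approximation"))
    z <- U - nx * ny / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(p_value = p, statistic = U, method = method)
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the declared number of tests `m` and
#' capped at 1.
#'
#' @param p_raw numeric vector of raw p-values.
#' @param m declared number of tests (>= 1; the study design declared 12:
#'   4 pathology groups x 3 parameters).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_raw, m = 12) {
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  if (m < length(p_raw))
    stop("m must be at least the number of tests performed")
  pmin(1, p_raw * m)
}

.parameters <- c(T_med = "T_med_um", sigma_T = "sigma_T_um",
                 C_s = "C_s_per_mm")

#' Compare pathology groups against Normal
#'
#' For each pathology group present and each parameter (T_med, sigma_T,
#' C_s), computes the group median, the difference to the Normal median,
#' a two-tailed Wilcoxon rank-sum p-value and its Bonferroni-adjusted
#' value. By default m = (number of pathology groups) x (number of
#' parameters); an override (e.g. a fixed 12) may be supplied.
#'
#' @param records per-patient cohort records (after [select_snapshots]),
#'   with `group` and the three metric columns.
#' @param m_tests Bonferroni test count override; `NULL` computes it from
#'   the design.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param exact Wilcoxon method forcing, see [wilcoxon_rank_sum].
#' @return data frame of class `comparison_result` with columns `group`,
#'   `parameter`, `group_median`, `normal_median`, `delta`, `p_raw`,
#'   `p_adjusted`, `significant`, `method`; the `m_tests` used is an
#'   attribute.
#' @export
compare_groups <- function(records, m_tests = NULL, alpha = 0.05,
                           exact = NULL) {
  records <- as.data.frame(records)
  if (!"Normal" %in% records$group)
    stop("Normal group missing: cannot compare against normal tissue")
  path_groups <- intersect(.group_levels, setdiff(unique(records$group),
                                                  "Normal"))
  if (!length(path_groups)) stop("no pathology group present")
  m <- m_tests %||% (length(path_groups) * length(.parameters))
  res <- list()
  for (g in path_groups) {
    for (pname in names(.parameters)) {
      col <- .parameters[[pname]]
      xg <- records[[col]][records$group == g]
      xn <- records[[col]][records$group == "Normal"]
      xg <- xg[!is.na(xg)]; xn <- xn[!is.na(xn)]
      w <- wilcoxon_rank_sum(xg, xn, exact = exact)
      res[[length(res) + 1]] <- data.frame(
        group = g, parameter = pname,
        group_median = median(xg), normal_median = median(xn),
        delta = median(xg) - median(xn),
        p_raw = w$p_value, method = w$method)
    }
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_raw, m)
  out$significant <- out$p_adjusted < alpha
  attr(out, "m_tests") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_result", "data.frame")
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Render a group-comparison report table
#'
#' One Normal row (deltas rendered "N/A") plus one row per pathology
#' group: group medians of the three parameters, differences to Normal
#' with raw and adjusted p-values, and significance stars on adjusted
#' values (* p < 0.05, ** p < 0.01).
#'
#' @param results a `comparison_result` from [compare_groups].
#' @param path optional output path (`.csv` or `.md`).
#' @return the report data frame, invisibly when written to `path`.
#' @export
render_report <- function(results, path = NULL) {
  stopifnot(inherits(results, "comparison_result"))
  groups <- unique(results$group)
  row_for <- function(g) {
    sub <- results[results$group == g, ]
    vals <- lapply(names(.parameters), function(p) {
      r <- sub[sub$parameter == p, ]
      c(median = r$group_median, delta = r$delta, p_raw = r$p_raw,
        p_adj = r$p_adjusted)
    })
    names(vals) <- names(.parameters)
    data.frame(
      group = g,
      T_med_um = vals$T_med[["median"]],
      sigma_T_um = vals$sigma_T[["median"]],
      C_s_per_mm = vals$C_s[["median"]],
      delta_T_med_um = sprintf("%.3g (p = %.3g)%s", vals$T_med[["delta"]],
                               vals$T_med[["p_adj"]],
                               significance_stars(vals$T_med[["p_adj"]])),
      delta_sigma_T_um = sprintf("%.3g (p = %.3g)%s", vals$sigma_T[["delta"]],
                                 vals$sigma_T[["p_adj"]],
                                 significance_stars(vals$sigma_T[["p_adj"]])),
      delta_C_s_per_mm = sprintf("%.3g (p = %.3g)%s", vals$C_s[["delta"]],
                                 vals$C_s[["p_adj"]],
                                 significance_stars(vals$C_s[["p_adj"]])))
  }
  normal_row <- data.frame(
    group = "Normal",
    T_med_um = results$normal_median[results$parameter == "T_med"][1],
    sigma_T_um = results$normal_median[results$parameter == "sigma_T"][1],
    C_s_per_mm = results$normal_median[results$parameter == "C_s"][1],
    delta_T_med_um = "N/A", delta_sigma_T_um = "N/A",
    delta_C_s_per_mm = "N/A")
  report <- rbind(normal_row, do.call(rbind, lapply(groups, row_for)))
  rownames(report) <- NULL
  if (!is.null(path)) {
    if (tolower(tools::file_ext(path)) == "md") {
      lines <- c(paste("|", paste(names(report), collapse = " | "), "|"),
                 paste("|", paste(rep("---", ncol(report)), collapse = " | "),
                       "|"),
                 apply(report, 1, function(r)
                   paste("|", paste(r, collapse = " | "), "|")))
      writeLines(lines, path)
    } else {
      write.csv(report, path, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
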