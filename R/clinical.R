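# Clinical association analysis: burden dichotomisation, contingency
# (Fisher) tests against clinicopathological variables, group burden
# summaries, quartile stratification and Kaplan-Meier / log-rank survival.
#
# The packaged fixture `table2_pdac.tsv` carries the 19-patient clinical
# table (gender, age, vital status, post-surgery metastasis, OS/DFS in
# months, average TMB, average CNV burden in percent, tumour location,
# differentiation, TNM, clinical stage, size class). One patient died of a
# non-disease cause within a week of surgery; his survival times are
# recorded as NA and he is excluded from survival analyses while remaining
# in the contingency tables.

#' Read a clinical table
#'
#' Reads the clinical TSV (the packaged 19-patient table by default) and
#' derives the analysis variables: `liver_metastasis`,
#' `relapse_or_metastasis` (any post-surgery metastasis/relapse), `dead`,
#' `lymph_node_metastasis` (TNM contains N1; NX counts as no),
#' `survival_excluded` (missing OS: non-disease death without follow-up)
#' and `disease_specific_death`.
#'
#' @param path Path to a clinical TSV; default is the packaged table.
#' @return Data.frame of clinical records.
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "table2_pdac.tsv",
                                                   package = "pdachet")) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  x$liver_metastasis <- grepl("liver", x$metastasis_after_surgery,
                              ignore.case = TRUE)
  x$relapse_or_metastasis <- grepl("^Yes", x$metastasis_after_surgery)
  x$dead <- x$status == "Dead"
  x$lymph_node_metastasis <- grepl("N1", x$tnm)
  x$survival_excluded <- is.na(x$os_months)
  x$disease_specific_death <- x$dead & !x$survival_excluded
  x
}

#' Median split of average CNV burden
#'
#' High burden means strictly greater than the cohort median; ties at the
#' median (and everything below) are low.
#'
#' @param records Clinical data.frame with `average_cnv_burden`.
#' @return The records with a `burden_group` factor ("low"/"high") added.
#' @export
median_split_burden <- function(records) {
  if (any(is.na(records$average_cnv_burden)))
    stop("burden missing for some patients")
  med <- median(records$average_cnv_burden)
  records$burden_group <- factor(
    ifelse(records$average_cnv_burden > med, "high", "low"),
    levels = c("low", "high"))
  records
}

#' Top-quartile split of average CNV burden
#'
#' Top quartile means strictly greater than the 75th percentile
#' (linear-interpolation percentile, [stats::quantile()] type 7).
#'
#' @param records Clinical data.frame with `average_cnv_burden`.
#' @return The records with a `quartile_group` factor ("rest"/"top") added.
#' @export
quartile_split <- function(records) {
  b <- records$average_cnv_burden
  if (length(b) < 4) stop("at least four patients required")
  q3 <- quantile(b, 0.75, type = 7, names = FALSE)
  grp <- ifelse(b > q3, "top", "rest")
  if (!any(grp == "top"))
    warning("top quartile empty (all burdens equal at the 75th percentile)")
  records$quartile_group <- factor(grp, levels = c("rest", "top"))
  records
}

#' Fisher exact association between a clinical variable and burden group
#'
#' Builds the 2x2 contingency table of a dichotomous clinical variable
#' against the low/high burden group and applies the two-sided Fisher
#' exact test (probability-mass rule: the p-value sums the probabilities
#' of all tables with the observed margins no more probable than the
#' observed one). The odds ratio is the sample OR with a 0.5 correction
#' when any cell is zero.
#'
#' @param records Output of [median_split_burden()].
#' @param variable Name of a logical/two-level column, or one of the
#'   Table-1 shorthand names: `"age60"` (age >= 60), `"gender"`,
#'   `"location"` (head vs body/tail), `"size"` (> 3 cm),
#'   `"lymph_node"`, `"relapse"`, `"liver"`, `"stage"` (I vs II).
#' @return List with `table` (2x2 counts), `p_value`, `odds_ratio`.
#' @export
fisher_association <- function(records, variable) {
  v <- switch(variable,
    age60 = records$age >= 60,
    gender = records$gender == "Male",
    location = records$location == "Head",
    size = records$max_diameter == ">3",
    lymph_node = records$lymph_node_metastasis,
    relapse = records$relapse_or_metastasis,
    liver = records$liver_metastasis,
    stage = grepl("^I[AB]?$", records$clinical_stage),
    records[[variable]])
  if (is.null(v)) stop("unknown variable: ", variable)
  if (!is.logical(v)) v <- as.logical(factor(v))
  tab <- table(factor(v, levels = c(TRUE, FALSE)),
               records$burden_group)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; p = 1")
    return(list(table = tab, p_value = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(tab)
  m <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(table = tab, p_value = ft$p.value, odds_ratio = unname(or))
}

#' Reproduce the full clinicopathological association table
#'
#' Runs [fisher_association()] for every Table-1 row against the median
#' burden split.
#'
#' @param records Clinical data.frame (will be median-split if needed).
#' @return Data.frame `variable`, `p_value` plus the per-group counts.
#' @export
burden_association_table <- function(records) {
  if (!"burden_group" %in% names(records))
    records <- median_split_burden(records)
  vars <- c("age60", "gender", "location", "size", "lymph_node", "relapse",
            "liver", "stage")
  rows <- lapply(vars, function(v) {
    fa <- fisher_association(records, v)
    data.frame(variable = v,
               yes_low = fa$table[1, "low"], yes_high = fa$table[1, "high"],
               no_low = fa$table[2, "low"], no_high = fa$table[2, "high"],
               p_value = fa$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median burden by group
#'
#' @param records Clinical data.frame.
#' @param by Name of a logical grouping column (default
#'   `"liver_metastasis"`).
#' @return Named numeric vector of per-group median `average_cnv_burden`
#'   (names "yes"/"no"); `NA` for an empty group.
#' @export
group_burden_summary <- function(records, by = "liver_metastasis") {
  g <- records[[by]]
  if (is.null(g)) stop("unknown grouping column: ", by)
  yes <- records$average_cnv_burden[g]
  no <- records$average_cnv_burden[!g]
  c(yes = if (length(yes)) median(yes) else NA_real_,
    no = if (length(no)) median(no) else NA_real_)
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' DFS events are disease relapse or metastasis; deaths without relapse
#' are censored at death (`dfs_death_as_event = TRUE` counts them as
#' events instead). OS events are death from any cause. Patients flagged
#' `survival_excluded` (non-disease death without follow-up) are dropped.
#'
#' @param records Clinical data.frame with a grouping column.
#' @param grouping Name of the grouping factor column (e.g.
#'   `"burden_group"` or `"quartile_group"`).
#' @param endpoint `"dfs"` or `"os"`.
#' @param dfs_death_as_event Treat non-relapse death as a DFS event
#'   (default FALSE).
#' @return List with `fit` (survfit), `chisq`, `p_value`, `median_by_group`.
#' @export
km_logrank <- function(records, grouping = "burden_group",
                       endpoint = c("dfs", "os"),
                       dfs_death_as_event = FALSE) {
  endpoint <- match.arg(endpoint)
  if (!grouping %in% names(records)) stop("unknown grouping: ", grouping)
  if ("survival_excluded" %in% names(records))
    records <- records[!records$survival_excluded, , drop = FALSE]
  if (endpoint == "os") {
    time <- records$os_months
    event <- as.integer(records$dead)
  } else {
    time <- records$dfs_months
    event <- as.integer(records$relapse_or_metastasis)
    if (dfs_death_as_event)
      event <- as.integer(records$relapse_or_metastasis | records$dead)
  }
  group <- droplevels(factor(records[[grouping]]))
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]
  event <- event[keep]
  group <- droplevels(group[keep])
  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ group)
  if (nlevels(group) < 2) stop("grouping has fewer than two levels")
  if (any(tapply(event, group, sum) == 0))
    warning("a group has zero events")
  sd <- survival::survdiff(surv ~ group)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  med <- summary(fit)$table
  med_by_group <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  list(fit = fit, chisq = unname(sd$chisq), p_value = p,
       median_by_group = med_by_group)
}

#' Cohort descriptives from the clinical table
#'
#' @param records Clinical data.frame.
#' @return Named list: `n_patients`, `n_relapse`, `relapse_pct`,
#'   `n_disease_death`, `disease_death_pct`.
#' @export
cohort_descriptives <- function(records) {
  n <- nrow(records)
  nr <- sum(records$relapse_or_metastasis)
  nd <- sum(records$disease_specific_death)
  list(n_patients = n, n_relapse = nr, relapse_pct = 100 * nr / n,
       n_disease_death = nd, disease_death_pct = 100 * nd / n)
}
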