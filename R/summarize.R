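# Cohort-level reporting: per-sample statistics aggregated to group
# mean +/- SEM (group-comparison statistics are deliberately left to
# standard tools; the summary stops at mean +/- SEM).

#' Summarise per-sample statistics by group
#'
#' @param data data.frame of per-sample rows.
#' @param value name of the numeric statistic column.
#' @param group name of the grouping column.
#' @param assay optional name of an assay column; a group mixing assays is
#'   refused (their statistics are not comparable).
#' @return data.frame: `group`, `n`, `mean`, `sem` (SEM = sd/sqrt(n); `NA`
#'   for single-sample groups), plus the per-sample values collapsed in
#'   `values`.
#' @examples
#' summarize_cohort(data.frame(g = "a", v = c(2, 4, 6)), "v", "g")
#' @export
summarize_cohort <- function(data, value = "value", group = "group",
                             assay = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("no per-sample results to summarise", call. = FALSE)
  if (!value %in% names(data) || !group %in% names(data))
    stop("missing column(s): ", value, " / ", group, call. = FALSE)
  v <- data[[value]]
  if (!is.numeric(v) || anyNA(v))
    stop("statistic column must be numeric without NA", call. = FALSE)
  g <- as.character(data[[group]])
  if (!is.null(assay)) {
    mixed <- tapply(as.character(data[[assay]]), g,
                    function(x) length(unique(x)) > 1)
    if (any(mixed))
      stop("group(s) mix assays: ", paste(names(mixed)[mixed], collapse = ", "),
           call. = FALSE)
  }
  groups <- unique(g)
  out <- data.frame(
    group = groups,
    n = vapply(groups, function(x) sum(g == x), integer(1)),
    mean = vapply(groups, function(x) mean(v[g == x]), numeric(1)),
    sem = vapply(groups, function(x) {
      vv <- v[g == x]
      if (length(vv) < 2) NA_real_ else sd(vv) / sqrt(length(vv))
    }, numeric(1)),
    values = vapply(groups, function(x)
      paste(format(v[g == x], trim = TRUE), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
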