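#' Paired t-test of one network variable between waves
#'
#' Subjects are matched by id; pairs with the variable observed at both
#' waves enter. Reports the paired t statistic, two-sided p, and paired
#' Cohen's d (mean difference / SD of differences). A zero-variance
#' difference vector with nonzero mean is reported with a `degenerate` flag
#' (p forced to 0) rather than failing; an all-zero difference vector gives
#' t = 0, p = 1, d = 0.
#'
#' @param wave1,wave2 [cohort_table()]s sharing subject ids.
#' @param variable network-node name.
#' @return list with `t`, `df`, `p`, `d`, `n_pairs`, `degenerate`.
#' @export
paired_wave_ttest <- function(wave1, wave2, variable) {
  if (!variable %in% colnames(wave1$values))
    stop("unknown variable: ", variable)
  common <- intersect(wave1$subject, wave2$subject)
  x1 <- wave1$values[match(common, wave1$subject), variable]
  x2 <- wave2$values[match(common, wave2$subject), variable]
  ok <- !is.na(x1) & !is.na(x2)
  if (sum(ok) < 2)
    stop("insufficient data: fewer than 2 complete pairs for ", variable)
  d <- x2[ok] - x1[ok]
  n <- length(d)
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, df = n - 1, p = 1, d = 0, n_pairs = n,
                  degenerate = FALSE))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, d = sign(md) * Inf,
                n_pairs = n, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), d = md / sdd,
       n_pairs = n, degenerate = FALSE)
}

cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Compare wave-1 characteristics of completers and dropouts
#'
#' For continuous variables (and age): Welch t-test plus Cohen's d. For
#' ordinal variables (depression, education, alcohol): Wilcoxon rank-sum
#' test with group mean ranks — d on the raw values is reported alongside,
#' as effect sizes are conventionally printed next to the mean ranks. For
#' binary variables and sex: chi-square test of independence.
#'
#' @param wave1 a [cohort_table()].
#' @param completer_flag logical per wave-1 subject (TRUE = completed the
#'   follow-up wave).
#' @return data frame with one row per variable: test used, statistic, p,
#'   Cohen's d where defined, and completer/dropout mean ranks for
#'   rank-sum comparisons.
#' @export
compare_completers <- function(wave1, completer_flag) {
  if (length(completer_flag) != length(wave1$subject))
    stop("completer_flag must match the wave-1 subjects")
  if (!any(completer_flag) || all(completer_flag))
    stop("insufficient data: both completer groups must be non-empty")
  sch <- wave1$schema
  rows <- list()
  add <- function(variable, test, statistic, p, d = NA_real_,
                  mean_rank_completer = NA_real_,
                  mean_rank_dropout = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic, p = p,
      cohens_d = d, mean_rank_completer = mean_rank_completer,
      mean_rank_dropout = mean_rank_dropout, stringsAsFactors = FALSE)
  }
  welch <- function(name, v) {
    x <- v[completer_flag]; y <- v[!completer_flag]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (stats::var(c(x, y)) == 0) {  # degenerate: identical constant groups
      add(name, "welch_t", 0, 1, 0)
      return(invisible())
    }
    tt <- stats::t.test(x, y)
    add(name, "welch_t", unname(tt$statistic), tt$p.value, cohens_d(x, y))
  }
  ranksum <- function(name, v) {
    x <- v[completer_flag]; y <- v[!completer_flag]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              exact = length(x) + length(y) <= 50))
    r <- rank(c(x, y))
    add(name, "rank_sum", unname(wt$statistic), wt$p.value, cohens_d(x, y),
        mean(r[seq_along(x)]), mean(r[length(x) + seq_along(y)]))
  }
  chisq <- function(name, v) {
    ok <- !is.na(v)
    tab <- table(completer_flag[ok], v[ok])
    ct <- suppressWarnings(stats::chisq.test(tab))
    add(name, "chi_square", unname(ct$statistic), ct$p.value)
  }
  if (!all(is.na(wave1$age))) welch("age", wave1$age)
  chisq("sex", as.integer(wave1$sex == "female"))
  for (name in node_names(sch)) {
    lev <- sch$level[sch$name == name]
    v <- wave1$values[, name]
    if (lev == "continuous") welch(name, v)
    else if (lev == "ordinal") ranksum(name, v)
    else chisq(name, v)
  }
  do.call(rbind, rows)
}
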