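#' Per-cell mean, SEM, and n summaries
#'
#' Summarizes an assay table (long format: one row per animal x minute)
#' the way the turn-rate tables report it: per genotype-by-condition
#' cell, mean turns/min for the requested minute, SEM = SD/sqrt(n), and
#' n. A single-observation cell has an undefined SEM (reported `NA`);
#' empty cells are omitted with a warning.
#'
#' @param table Data frame with at least the grouping columns, a
#'   `minute` column, and the response column.
#' @param minute Which minute to summarize (default 5, the assay's
#'   primary bin).
#' @param group_cols Character vector of grouping columns (default
#'   genotype and osmolarity condition).
#' @param response Response column name.
#' @return A tibble of the grouping columns plus `n`, `mean`, `sem`.
#' @export
summarize_rates <- function(table, minute = 5,
                            group_cols = c("genotype", "osmolarity_mosm"),
                            response = "turns_per_min") {
  stopifnot(all(c(group_cols, response) %in% names(table)))
  if ("minute" %in% names(table)) {
    if (!any(table$minute == minute)) {
      stop("requested minute ", minute, " not present in the table")
    }
    table <- table[table$minute == minute, , drop = FALSE]
  }
  key <- interaction(table[group_cols], drop = FALSE, sep = "\r")
  split_vals <- split(table[[response]], key)
  empty <- vapply(split_vals, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty cell(s) omitted: ",
            paste(gsub("\r", " x ", names(split_vals)[empty]),
                  collapse = ", "))
    split_vals <- split_vals[!empty]
  }
  cells <- do.call(rbind, strsplit(names(split_vals), "\r", fixed = TRUE))
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(out) <- group_cols
  out$n <- vapply(split_vals, length, integer(1))
  out$mean <- vapply(split_vals, mean, numeric(1))
  out$sem <- vapply(split_vals, function(v) {
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  }, numeric(1))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Two-group Student's t test (raw data or summary statistics)
#'
#' Two-sided pooled-variance (classical Student) t test, the form used
#' for the minute-5 turn-rate comparisons; Welch's correction is
#' available by flag for raw data. `two_group_t_summary()` computes the
#' identical pooled test from per-group mean, SEM, and n, for
#' re-testing published summary values.
#'
#' @param x,y Numeric vectors of per-animal rates (each n >= 2).
#' @param welch Use Welch's unequal-variance form instead.
#' @return A tibble of `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
#' @examples
#' # droplet-volume check: 23.6 +/- 0.31 vs 23.2 +/- 0.35 ul, n = 8
#' two_group_t_summary(23.6, 0.31, 8, 23.2, 0.35, 8)
two_group_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
  if (welch) {
    ht <- t.test(x, y)
    return(tibble::tibble(t = unname(ht$statistic),
                          df = unname(ht$parameter),
                          p_value = ht$p.value,
                          mean_x = mean(x), mean_y = mean(y)))
  }
  two_group_t_summary(mean(x), sd(x) / sqrt(length(x)), length(x),
                      mean(y), sd(y) / sqrt(length(y)), length(y))
}

#' @rdname two_group_t
#' @param mean_x,sem_x,n_x,mean_y,sem_y,n_y Per-group summary
#'   statistics (SEM = SD/sqrt(n)).
#' @export
two_group_t_summary <- function(mean_x, sem_x, n_x, mean_y, sem_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2, sem_x >= 0, sem_y >= 0)
  var_x <- (sem_x * sqrt(n_x))^2
  var_y <- (sem_y * sqrt(n_y))^2
  df <- n_x + n_y - 2
  pooled <- ((n_x - 1) * var_x + (n_y - 1) * var_y) / df
  if (pooled <= 0) stop("zero pooled variance: t test undefined")
  t_stat <- (mean_x - mean_y) / sqrt(pooled * (1 / n_x + 1 / n_y))
  tibble::tibble(t = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df),
                 mean_x = mean_x, mean_y = mean_y)
}

#' Genotype-by-osmolarity interaction ANOVA
#'
#' Two-way fixed-effects ANOVA with interaction on the chosen minute's
#' turn rates, the test used to compare how two genotypes respond to an
#' osmolarity treatment. Sums of squares are Type II, which is
#' invariant to cell-order and appropriate for the unbalanced cell
#' sizes these assays produce (on balanced designs Type II equals the
#' sequential decomposition). Missing cells are an error: the
#' interaction is not estimable and nothing is imputed.
#'
#' @param table Long-format data frame (see [summarize_rates()]).
#' @param factors Length-2 character vector naming the two factor
#'   columns (default genotype and osmolarity condition).
#' @param minute Minute to analyze when a `minute` column is present.
#' @param response Response column name.
#' @return A tibble of `term`, `sumsq`, `df`, `statistic`, `p_value`
#'   with rows for both main effects, the interaction, and residuals.
#' @export
interaction_anova <- function(table,
                              factors = c("genotype", "osmolarity_mosm"),
                              minute = 5, response = "turns_per_min") {
  stopifnot(length(factors) == 2,
            all(c(factors, response) %in% names(table)))
  if ("minute" %in% names(table)) {
    table <- table[table$minute == minute, , drop = FALSE]
    if (nrow(table) == 0) stop("requested minute not present")
  }
  f1 <- factor(table[[factors[1]]])
  f2 <- factor(table[[factors[2]]])
  counts <- table(f1, f2)
  if (any(counts == 0)) {
    stop("missing design cell(s): interaction not estimable")
  }
  if (any(counts < 2)) {
    stop("every design cell needs n >= 2")
  }
  dat <- data.frame(y = table[[response]], f1 = f1, f2 = f2)
  fit <- lm(y ~ f1 * f2, data = dat)
  aov2 <- car::Anova(fit, type = 2)
  terms <- rownames(aov2)
  terms <- sub("^f1:f2$", paste(factors, collapse = ":"), terms)
  terms <- sub("^f1$", factors[1], terms)
  terms <- sub("^f2$", factors[2], terms)
  tibble::tibble(
    term = terms,
    sumsq = aov2[["Sum Sq"]],
    df = aov2[["Df"]],
    statistic = aov2[["F value"]],
    p_value = aov2[["Pr(>F)"]]
  )
}
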