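# Curling-assay analytics: per-well metrics, condition summaries,
# vehicle normalization, hit calling, time-decay fits, group comparisons.

#' Per-well curling metrics
#'
#' Counts per posture class and the three percentage metrics computed
#' over the classified worms (Censored objects are excluded): percent
#' Coiled, percent Coiled+Curled, percent Coiled+Curled+NearCurled. Wells
#' with fewer than `min_worms` classified worms are flagged excluded.
#'
#' @param labels Character/factor vector of object labels for one well
#'   (pooled across its snapshots/rounds).
#' @param condition,well Identifiers carried into the output row.
#' @param min_worms Exclusion threshold (default 3 classified worms).
#' @return One-row data.frame (`well_result`).
#' @export
well_metrics <- function(labels, condition = NA_character_,
                         well = NA_character_, min_worms = 3) {
  labels <- factor(as.character(labels), levels = POSTURE_CLASSES)
  cnt <- table(labels)
  n_classified <- sum(cnt[WORM_CLASSES])
  pct <- function(x) if (n_classified == 0) 0 else 100 * x / n_classified
  data.frame(condition = condition, well = well,
             n_coiled = as.integer(cnt["Coiled"]),
             n_curled = as.integer(cnt["Curled"]),
             n_nearcurled = as.integer(cnt["NearCurled"]),
             n_noncurled = as.integer(cnt["NonCurled"]),
             n_censored = as.integer(cnt["Censored"]),
             n_classified = as.integer(n_classified),
             percent_coiled = pct(cnt[["Coiled"]]),
             percent_coiled_curled = pct(cnt[["Coiled"]] + cnt[["Curled"]]),
             percent_curling_all = pct(cnt[["Coiled"]] + cnt[["Curled"]] +
                                         cnt[["NearCurled"]]),
             excluded = n_classified < min_worms)
}

#' Per-well metrics for a table of classified objects
#'
#' @param objects data.frame with columns `condition`, `well`, and
#'   `label` (one row per scored object; snapshots pooled by well).
#' @param min_worms Well exclusion threshold.
#' @return data.frame of [well_metrics()] rows, one per well.
#' @export
summarize_wells <- function(objects, min_worms = 3) {
  stopifnot(all(c("condition", "well", "label") %in% names(objects)))
  out <- do.call(rbind, lapply(split(objects, objects$well), function(d)
    well_metrics(d$label, condition = d$condition[1], well = d$well[1],
                 min_worms = min_worms)))
  rownames(out) <- NULL
  out
}

metric_column <- function(metric = c("coiled", "coiled_curled", "all")) {
  switch(match.arg(metric), coiled = "percent_coiled",
         coiled_curled = "percent_coiled_curled", all = "percent_curling_all")
}

#' Condition-level summary of a well metric
#'
#' Excluded wells (fewer than 3 classified worms) are dropped before
#' averaging; the well is the statistical unit.
#'
#' @param well_table Output of [summarize_wells()].
#' @param metric `"coiled"` (default headline metric), `"coiled_curled"`,
#'   or `"all"`.
#' @return data.frame with one row per condition: mean, sd, n_wells,
#'   n_worms, and the per-well values (list column `values`).
#' @export
condition_summary <- function(well_table, metric = "coiled") {
  col <- metric_column(metric)
  keep <- !well_table$excluded
  out <- do.call(rbind, lapply(split(well_table[keep, ],
                                     well_table$condition[keep]),
    function(d) {
      data.frame(condition = d$condition[1], mean = mean(d[[col]]),
                 sd = sd(d[[col]]), n_wells = nrow(d),
                 n_worms = sum(d$n_classified), metric = col)
    }))
  out$values <- lapply(split(well_table[keep, ], well_table$condition[keep]),
                       function(d) d[[col]])
  rownames(out) <- NULL
  out
}

#' Mean ratio of a treatment condition to a control condition
#'
#' @param treatment,control Single rows of [condition_summary()] (or
#'   lists with a `mean` element).
#' @return Ratio of condition means; `NA` with a warning if the control
#'   mean is zero.
#' @export
mean_ratio <- function(treatment, control) {
  if (control$mean == 0) {
    warning("control mean is zero; mean ratio undefined")
    return(NA_real_)
  }
  treatment$mean / control$mean
}

#' Vehicle-normalized screen table with hit calls
#'
#' Expresses each condition's metric as a percentage of the vehicle mean
#' (vehicle = 100 by construction) and flags conditions below the hit
#' threshold (default: curling reduced to less than 50\% of
#' vehicle-treated levels).
#'
#' @param summaries [condition_summary()] rows for the drug conditions.
#' @param vehicle [condition_summary()] row of the vehicle condition.
#' @param hit_threshold Hit cutoff in percent of vehicle.
#' @return `screen_table` data.frame: condition, normalized percent, hit
#'   flag (vehicle row first).
#' @export
normalize_screen <- function(summaries, vehicle, hit_threshold = 50) {
  if (vehicle$mean == 0) {
    warning("vehicle mean is zero; cannot normalize")
    return(NULL)
  }
  pct <- 100 * summaries$mean / vehicle$mean
  out <- rbind(
    data.frame(condition = vehicle$condition, normalized_pct = 100,
               hit = FALSE, n_wells = vehicle$n_wells,
               n_worms = vehicle$n_worms, role = "vehicle"),
    data.frame(condition = summaries$condition, normalized_pct = pct,
               hit = pct < hit_threshold, n_wells = summaries$n_wells,
               n_worms = summaries$n_worms, role = "drug"))
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Linear fit of mean ratio against time
#'
#' Ordinary least squares of per-round mean ratios on round start times
#' (minutes after transfer to liquid), describing the decay of the
#' curling signal with episodic swimming onset.
#'
#' @param times Numeric times (minutes), length >= 3.
#' @param ratios Mean ratios at those times.
#' @return List with `slope`, `intercept`, and the `lm` fit.
#' @export
time_decay_fit <- function(times, ratios) {
  if (length(times) < 3 || length(ratios) != length(times))
    stop("need at least 3 (time, ratio) pairs")
  fit <- lm(ratios ~ times)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit = fit)
}

star_code <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare conditions on well-level values
#'
#' Two groups: two-tailed unpaired pooled-variance t-test. More than two:
#' one-way ANOVA with Dunnett's post-hoc comparisons against the control
#' group (multivariate-t quantiles via multcomp). Stars: */**/***/****
#' at 0.05/0.01/0.001/0.0001.
#'
#' @param groups Named list of numeric vectors (well-level metric values
#'   per condition), each of length >= 2.
#' @param control Name of the control group (default: first element).
#' @return `comparison_report`: data.frame with comparison, estimate,
#'   statistic, df, p-value and star code; the ANOVA F-test (if any) is
#'   in attribute `anova`.
#' @export
compare_conditions <- function(groups, control = names(groups)[1]) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 wells")
  if (length(groups) == 2) {
    # groups are compared in listed order: statistic = t(first, second)
    tt <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    out <- data.frame(comparison = paste(names(groups)[1], "vs",
                                         names(groups)[2]),
                      estimate = unname(tt$estimate[1] - tt$estimate[2]),
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value,
                      stars = star_code(tt$p.value))
    attr(out, "test") <- "two-tailed unpaired t-test (pooled variance)"
  } else {
    dat <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)),
                     levels = c(control, setdiff(names(groups), control))))
    fit <- aov(value ~ group, data = dat)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    out <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = unname(sm$test$coefficients),
                      statistic = unname(sm$test$tstat),
                      df = fit$df.residual,
                      p = unname(as.numeric(sm$test$pvalues)))
    out$stars <- vapply(out$p, star_code, character(1))
    af <- summary(fit)[[1]]
    attr(out, "anova") <- data.frame(F = af$`F value`[1],
                                     df1 = af$Df[1], df2 = af$Df[2],
                                     p = af$`Pr(>F)`[1])
    attr(out, "test") <- "one-way ANOVA with Dunnett post-hoc"
  }
  class(out) <- c("comparison_report", "data.frame")
  out
}
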