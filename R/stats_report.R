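# Group summaries and the study's statistical comparisons: nested
# (dish-level) aggregation, one-way ANOVA with Bonferroni or Tukey
# post-hoc pairwise comparisons, and the unpaired Student t-test.

#' Aggregate nested measurements to replicate-unit means
#'
#' Collapses nested observations (e.g. neurons within dishes) to one mean
#' per replicate unit, preserving group labels. This is the "nested"
#' reading of hierarchical comparisons used throughout: statistics are
#' computed on per-dish averages, not on pooled neurons, so dishes — the
#' independent experimental units — carry the degrees of freedom.
#'
#' @param data Data frame with columns `group`, `unit` (replicate-unit
#'   id) and `value`; an optional `nested` column is ignored (the nesting
#'   is implied by `unit`).
#' @return Data frame `group,unit,n,value` with one row per unit
#'   (`value` = mean of its observations).
#' @export
nest_aggregate <- function(data) {
  stopifnot(all(c("group", "unit", "value") %in% names(data)),
            all(is.finite(data$value)))
  key <- paste(data$group, data$unit, sep = "\r")
  parts <- split(data, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(group = d$group[1], unit = d$unit[1], n = nrow(d),
               value = mean(d$value))
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance on per-unit
#' values: F is the ratio of between-group to within-group mean squares,
#' with (k - 1, N - k) degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 units each.
#' @return List `f,df1,df2,p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  if (nlevels(groups) < 2) stop("one-way ANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 units for ANOVA")
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p_value = unname(fit$p.value))
}

#' Pairwise post-hoc comparisons after one-way ANOVA
#'
#' Bonferroni: per-pair Student t-tests with p-values multiplied by the
#' number of comparisons `k(k-1)/2` (capped at 1). Tukey: honest
#' significant differences from the studentized range distribution.
#'
#' @inheritParams one_way_anova
#' @param method `"bonferroni"` or `"tukey"`.
#' @return Data frame `group1,group2,p_adj`, one row per pair.
#' @export
pairwise_posthoc <- function(values, groups, method = c("bonferroni", "tukey")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("post-hoc comparison needs >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 units")
  if (method == "bonferroni") {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    m <- ncol(pairs)
    rows <- lapply(seq_len(m), function(i) {
      a <- values[groups == pairs[1, i]]
      b <- values[groups == pairs[2, i]]
      raw <- stats::t.test(a, b, var.equal = TRUE)$p.value
      data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                 p_adj = min(raw * m, 1))
    })
    out <- do.call(rbind, rows)
  } else {
    # remap levels to safe tokens so labels containing '-' parse cleanly
    safe <- factor(groups, labels = paste0("g", seq_len(nlevels(groups))))
    lut <- stats::setNames(levels(groups), levels(safe))
    fit <- stats::aov(values ~ safe)
    tk <- stats::TukeyHSD(fit)$safe
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(group1 = unname(lut[vapply(pair, `[`, character(1), 2)]),
                      group2 = unname(lut[vapply(pair, `[`, character(1), 1)]),
                      p_adj = unname(tk[, "p adj"]))
  }
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample t-test
#'
#' Classical Student t-test (equal variances pooled) by default; set
#' `var_equal = FALSE` for the Welch form.
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @param var_equal Pool variances (Student) or not (Welch).
#' @return List `t,df,p_value`.
#' @export
two_sample_test <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    stop("degenerate samples: zero variance in both groups")
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p_value = unname(fit$p.value))
}

#' Standard error of the mean
#'
#' @param x Numeric vector (SD uses the n-1 denominator).
#' @return `sd(x) / sqrt(length(x))`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-group mean and SEM
#'
#' @inheritParams one_way_anova
#' @return Data frame `group,n,mean,sem`.
#' @export
group_summary <- function(values, groups) {
  parts <- split(values, factor(groups, levels = unique(groups)))
  out <- do.call(rbind, lapply(names(parts), function(g) {
    data.frame(group = g, n = length(parts[[g]]), mean = mean(parts[[g]]),
               sem = sem(parts[[g]]))
  }))
  rownames(out) <- NULL
  out
}
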