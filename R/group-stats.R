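as_group_list <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  if (!is.list(values_by_group) || is.null(names(values_by_group))) {
    stopf("values_by_group must be a named list of numeric vectors")
  }
  lapply(values_by_group, as.numeric)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and a Levene test (one-way ANOVA on absolute
#' deviations from the group centre) across groups. No gating is performed:
#' p-values are returned for the caller to route post-hoc tests.
#'
#' @param values_by_group named list of numeric vectors, each `n >= 3`.
#' @param center centre for the Levene deviations: `"mean"` (classic Levene)
#'   or `"median"` (Brown-Forsythe).
#' @return list with `shapiro_p` (named per group) and `levene_p`.
#' @export
check_assumptions <- function(values_by_group, center = c("mean", "median")) {
  g <- as_group_list(values_by_group)
  center <- match.arg(center)
  ns <- lengths(g)
  if (any(ns < 3)) stopf("every group needs n >= 3 (got %s)",
                         paste(ns, collapse = ", "))
  if (any(vapply(g, stats::sd, numeric(1)) == 0)) {
    stopf("a group has zero variance; normality test degenerate")
  }
  shapiro_p <- vapply(g, function(x) stats::shapiro.test(x)$p.value, numeric(1))
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(g, function(x) abs(x - cfun(x)))
  levene_p <- oneway_anova(z)$p
  list(shapiro_p = shapiro_p, levene_p = levene_p)
}

#' One-way between-groups ANOVA
#'
#' Classical fixed-effects decomposition: `F = MSbetween / MSwithin` with
#' `df = (k - 1, N - k)`. Computed directly from sums of squares; group
#' labels and sizes, the significance flag at 0.05, and the dfs are returned.
#'
#' @param values_by_group named list of numeric vectors (each `n >= 2`), or a
#'   data.frame with `value` and `group` columns.
#' @return a `group_stats_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `significant`, `groups`, `n`, `grand_mean`, `ms_within`.
#' @export
oneway_anova <- function(values_by_group) {
  g <- as_group_list(values_by_group)
  if (length(g) < 2) stopf("need at least 2 groups")
  ns <- lengths(g)
  if (any(ns < 2)) stopf("every group needs n >= 2")
  k <- length(g)
  N <- sum(ns)
  means <- vapply(g, mean, numeric(1))
  grand <- sum(unlist(g)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  structure(
    list(F = f, df_between = dfb, df_within = dfw, p = p,
         significant = is.finite(p) && p < 0.05,
         groups = names(g), n = ns, group_means = means,
         grand_mean = grand, ms_within = msw),
    class = "group_stats_result"
  )
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise post-hoc comparisons after a one-way ANOVA
#'
#' Tukey HSD when variance homogeneity holds, Games-Howell otherwise; with
#' `route = "auto"` the Levene p-value decides (`levene_p < 0.05` routes to
#' Games-Howell). Both use the studentized-range distribution; Games-Howell
#' additionally uses per-pair Welch degrees of freedom and unpooled variances.
#'
#' @param values_by_group named list of numeric vectors.
#' @param route `"auto"`, `"tukey"` or `"games-howell"`.
#' @param levene_p required when `route = "auto"`.
#' @return data.frame with columns `pair`, `estimate` (difference of means),
#'   `p_adj`, `method`.
#' @export
posthoc <- function(values_by_group, route = c("auto", "tukey", "games-howell"),
                    levene_p = NULL) {
  g <- as_group_list(values_by_group)
  route <- match.arg(route)
  if (route == "auto") {
    if (is.null(levene_p)) stopf("route='auto' needs levene_p")
    route <- if (levene_p < 0.05) "games-howell" else "tukey"
  }
  k <- length(g)
  if (k < 2) stopf("need at least 2 groups")
  ns <- lengths(g)
  if (route == "tukey" && any(ns < 2)) stopf("Tukey needs n >= 2 per group")
  if (route == "games-howell" && any(ns < 2)) {
    stopf("Games-Howell needs n >= 2 per group")
  }
  means <- vapply(g, mean, numeric(1))
  vars <- vapply(g, stats::var, numeric(1))
  an <- oneway_anova(g)
  pairs <- utils::combn(k, 2)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- means[i1] - means[i2]
    if (route == "tukey") {
      se <- sqrt(an$ms_within / 2 * (1 / ns[i1] + 1 / ns[i2]))
      df <- an$df_within
    } else {
      se2 <- vars[i1] / ns[i1] + vars[i2] / ns[i2]
      se <- sqrt(se2 / 2)
      df <- se2^2 / (vars[i1]^2 / (ns[i1]^2 * (ns[i1] - 1)) +
                       vars[i2]^2 / (ns[i2]^2 * (ns[i2] - 1)))
      if (!is.finite(df)) df <- an$df_within
    }
    q <- if (se == 0) {
      if (diff == 0) 0 else Inf
    } else abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    out[[j]] <- data.frame(
      pair = paste(names(g)[i1], names(g)[i2], sep = " - "),
      estimate = unname(diff), p_adj = p, method = route)
  }
  do.call(rbind, out)
}

#' Group comparison of every extracted band outcome
#'
#' Runs the full statistical pipeline on a band-summary table: per
#' (roi, band, measure) outcome, Shapiro-Wilk per group, Levene, one-way
#' ANOVA, and routed post-hoc comparisons. No multiplicity correction is
#' applied across outcomes; `n_outcomes_tested` is reported so users can
#' correct post hoc.
#'
#' @param summaries data.frame from [extract_all()] (columns `group`, `roi`,
#'   `band`, `measure`, `value`).
#' @param groups optional character vector restricting/ordering groups.
#' @return list with `table` (one row per outcome: F, dfs, p, levene_p,
#'   min shapiro p, posthoc method) , `posthoc` (long data.frame), and
#'   `n_outcomes_tested`.
#' @export
group_stats <- function(summaries, groups = NULL) {
  stopifnot(is.data.frame(summaries))
  if (!is.null(groups)) summaries <- summaries[summaries$group %in% groups, ]
  keys <- unique(summaries[, c("roi", "band", "measure")])
  rows <- list(); ph <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- merge(summaries, keys[i, ])
    vg <- split(sub$value, sub$group)
    vg <- lapply(vg, function(x) x[!is.na(x)])
    asm <- tryCatch(check_assumptions(vg), error = function(e) NULL)
    an <- oneway_anova(vg)
    lev <- if (is.null(asm)) NA_real_ else asm$levene_p
    pc <- if (length(vg) >= 2 && !is.na(lev)) {
      posthoc(vg, route = "auto", levene_p = lev)
    } else NULL
    rows[[i]] <- data.frame(
      roi = keys$roi[i], band = keys$band[i], measure = keys$measure[i],
      F = an$F, df_between = an$df_between, df_within = an$df_within,
      p = an$p, levene_p = lev,
      shapiro_p_min = if (is.null(asm)) NA_real_ else min(asm$shapiro_p),
      posthoc_method = if (is.null(pc)) NA_character_ else pc$method[1])
    if (!is.null(pc)) {
      pc$roi <- keys$roi[i]; pc$band <- keys$band[i]
      pc$measure <- keys$measure[i]
      ph[[length(ph) + 1L]] <- pc
    }
  }
  list(table = do.call(rbind, rows),
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL,
       n_outcomes_tested = nrow(keys))
}
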