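# Experiment orchestration (waveform grids, replicates, ramp-memory test)
# and the delay-invariance statistics.

#' Specify a waveform-grid experiment
#'
#' The canonical bench design crosses pulse widths with (symmetric) delays
#' — e.g. 4 pulse widths x 3 delays = 12 waveforms — and delivers a full
#' voltage ramp to `n_replicates` fresh tissue samples per waveform.
#'
#' @param pulse_widths Pulse widths, us.
#' @param delays Delays, us; each applied as d1 = d2 unless `d_pairs` is
#'   given.
#' @param geometry A `geometry_spec`.
#' @param levels Ramp levels, V/cm (strictly increasing).
#' @param n_replicates Tissue samples per waveform (>= 2; bench convention
#'   is 8).
#' @param base_seed Integer seed from which all per-replicate seeds derive.
#' @param d_pairs Optional list of `c(d1, d2)` pairs overriding the
#'   symmetric-delay expansion (for reciprocal-waveform comparisons such as
#'   1-10-1-10 vs 10-1-10-1).
#' @param cycles Cycles per burst; `NULL` targets 100 us on-time per pulse
#'   width.
#' @param sampling_period Sampling period, ns.
#' @param bursts_per_level Bursts per ramp level (default 3).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(pulse_widths, delays, geometry, levels,
                        n_replicates = 8L, base_seed = 1L, d_pairs = NULL,
                        cycles = NULL, sampling_period = 2,
                        bursts_per_level = 3L) {
  stopifnot(inherits(geometry, "geometry_spec"))
  if (n_replicates < 2L) stop("'n_replicates' must be >= 2", call. = FALSE)
  if (is.null(d_pairs)) {
    if (!length(pulse_widths) || !length(delays))
      stop("empty waveform grid", call. = FALSE)
    grid <- expand.grid(pw = pulse_widths, d = delays,
                        KEEP.OUT.ATTRS = FALSE)
    wf <- data.frame(pw = grid$pw, d1 = grid$d, d2 = grid$d)
  } else {
    if (length(pulse_widths) != length(d_pairs))
      stop("'d_pairs' must pair one (d1, d2) with each pulse width",
           call. = FALSE)
    wf <- data.frame(pw = pulse_widths,
                     d1 = vapply(d_pairs, `[`, numeric(1), 1),
                     d2 = vapply(d_pairs, `[`, numeric(1), 2))
  }
  structure(list(waveforms = wf, geometry = geometry, levels = levels,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed), cycles = cycles,
                 sampling_period = sampling_period,
                 bursts_per_level = as.integer(bursts_per_level)),
            class = "design_spec")
}

# Deterministic 32-bit per-cell seed stream.
.derive_seed <- function(base_seed, idx) {
  as.integer((as.double(base_seed) + 7919 * as.double(idx)) %% 2147483629)
}

#' Run a waveform-grid experiment on the synthetic tissue
#'
#' For every waveform x replicate, simulates a full voltage ramp
#' ([simulate_ramp()]), processes it with the trace pipeline
#' ([process_ramp()]), and stacks the per-level results into one tidy
#' table. Fully deterministic given `base_seed`.
#'
#' @param design A [design_spec()].
#' @param params A [tissue_params()].
#' @return Data frame with one row per (waveform, replicate, level):
#'   columns `waveform`, `pulse_width`, `d1`, `d2`, `geometry`,
#'   `replicate`, `level`, `V`, `I`, `R`, and `thickness_mm` (the realized
#'   per-sample thickness; `NA` for needle geometries).
#' @export
run_design <- function(design, params) {
  stopifnot(inherits(design, "design_spec"),
            inherits(params, "tissue_params"))
  wf <- design$waveforms
  rows <- vector("list", nrow(wf) * design$n_replicates)
  idx <- 0L
  for (i in seq_len(nrow(wf))) {
    protocol <- burst_protocol(wf$pw[i], wf$d1[i], wf$d2[i],
                               cycles = design$cycles,
                               sampling_period = design$sampling_period)
    for (r in seq_len(design$n_replicates)) {
      idx <- idx + 1L
      seed <- .derive_seed(design$base_seed, idx)
      res <- tryCatch({
        ramp <- simulate_ramp(protocol, design$geometry, params,
                              levels = design$levels,
                              bursts_per_level = design$bursts_per_level,
                              seed = seed, replicate = r)
        lvl <- process_ramp(ramp, protocol)
        geom_act <- attr(ramp, "geometry")
        data.frame(waveform = protocol_label(protocol),
                   pulse_width = wf$pw[i], d1 = wf$d1[i], d2 = wf$d2[i],
                   geometry = design$geometry$kind, replicate = r,
                   level = lvl$level, V = lvl$V, I = lvl$I, R = lvl$R,
                   thickness_mm = if (geom_act$kind == "plate")
                     geom_act$thickness else NA_real_)
      }, error = function(e) {
        stop("waveform ", protocol_label(protocol), ", replicate ", r,
             ": ", conditionMessage(e), call. = FALSE)
      })
      rows[[idx]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch's unpaired two-tailed t-test
#'
#' Two-sample t-test without assuming equal variances
#' (Welch–Satterthwaite degrees of freedom); groups may have unequal
#' sizes. Thin wrapper over [stats::t.test()] returning the package's
#' `stat_result` structure.
#'
#' @param x,y Numeric vectors (each length >= 2, positive variance in at
#'   least one group).
#' @return An object of class `stat_result` with `method`, `statistic`
#'   (t), `df` (fractional), `p_value`, and `estimate` (mean difference).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both groups have zero variance: degenerate t-test", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(method = "Welch two-sample t-test",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate = unname(diff(rev(ht$estimate)))),
            class = "stat_result")
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' Fixed-effects one-way ANOVA (`F = MS_between / MS_within` on k-1 and
#' N-k degrees of freedom) followed by Tukey honest-significant-difference
#' adjusted pairwise comparisons from the studentized-range distribution.
#' Wraps [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param groups Named list of numeric vectors (k >= 2 groups, total
#'   N > k), or a numeric vector when `g` gives the grouping factor.
#' @param g Optional grouping factor matching a vector `groups`.
#' @return A `stat_result` with `statistic` (F), `df` (c(k-1, N-k)),
#'   `p_value`, and `pairwise`: a data frame of all k(k-1)/2 pairs with
#'   columns `group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
oneway_anova_tukey <- function(groups, g = NULL) {
  if (is.list(groups)) {
    if (is.null(names(groups)))
      names(groups) <- paste0("g", seq_along(groups))
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)),
                levels = names(groups))
  } else {
    y <- groups
    if (is.null(g)) stop("need a grouping factor 'g'", call. = FALSE)
    g <- factor(g)
  }
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(y) <= k)
    stop("need more observations than groups", call. = FALSE)
  if (all(vapply(split(y, g), stats::var, numeric(1)) == 0))
    stop("zero within-group variance everywhere: degenerate ANOVA",
         call. = FALSE)
  d <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = d)
  sm <- summary(fit)[[1]]
  Fst <- sm[["F value"]][1]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  structure(list(method = "one-way ANOVA + Tukey HSD",
                 statistic = Fst,
                 df = as.numeric(c(sm[["Df"]][1], sm[["Df"]][2])),
                 p_value = sm[["Pr(>F)"]][1],
                 pairwise = data.frame(group1 = pairs[, 2],
                                       group2 = pairs[, 1],
                                       diff = unname(tk[, "diff"]),
                                       lwr = unname(tk[, "lwr"]),
                                       upr = unname(tk[, "upr"]),
                                       p_adj = unname(tk[, "p adj"]))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, df = %s, p = %.4g>\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey-adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Ramp-memory test: does a preceding ramp change the final reading?
#'
#' For each target level, simulates (a) a full voltage ramp ending at the
#' target and (b) the target level alone with no preceding ramps, for `n`
#' replicates each, and compares the final-level resistances with Welch's
#' t-test. With the physical (memoryless) tissue model the arms differ
#' only by noise; setting `ramp_memory_frac` in the tissue parameters
#' injects a memory effect the test should detect.
#'
#' @param protocol A [burst_protocol()].
#' @param geometry A `geometry_spec`.
#' @param params A [tissue_params()].
#' @param target_levels Levels to test, V/cm (bench convention: 1000,
#'   1500, 2000).
#' @param levels Full ramp schedule from which each ramp arm takes the
#'   levels up to its target (default [ramp_levels()] `"potato_1cm"`).
#' @param n Replicates per arm (>= 2).
#' @param base_seed Integer seed.
#' @return Data frame with one row per target level: `level`, `t`, `df`,
#'   `p_value`, `mean_ramp`, `mean_standalone`.
#' @export
ramp_memory_test <- function(protocol, geometry, params,
                             target_levels = c(1000, 1500, 2000),
                             levels = ramp_levels("potato_1cm"),
                             n = 8L, base_seed = 1L) {
  if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
  idx <- 0L
  final_R <- function(lvls, target) {
    idx <<- idx + 1L
    ramp <- simulate_ramp(protocol, geometry, params, levels = lvls,
                          seed = .derive_seed(base_seed, idx))
    fin <- ramp[vapply(ramp, function(tr) tr$meta$level == target,
                       logical(1))]
    bm <- lapply(fin, burst_metrics, protocol = protocol)
    level_metrics(bm, target)$R
  }
  out <- lapply(target_levels, function(target) {
    lv <- levels[levels <= target]
    if (!length(lv) || lv[length(lv)] != target)
      lv <- sort(unique(c(lv, target)))
    r_ramp <- vapply(seq_len(n), function(i) final_R(lv, target),
                     numeric(1))
    r_alone <- vapply(seq_len(n), function(i) final_R(target, target),
                      numeric(1))
    wt <- welch_t_test(r_ramp, r_alone)
    data.frame(level = target, t = wt$statistic, df = wt$df,
               p_value = wt$p_value, mean_ramp = mean(r_ramp),
               mean_standalone = mean(r_alone))
  })
  do.call(rbind, out)
}

#' Delay-invariance statistics over a waveform-grid result table
#'
#' For each (pulse width, level) cell, runs a one-way ANOVA of the chosen
#' response across the delay groups (waveforms sharing the pulse width)
#' and counts significant cells at the chosen alpha. Cells with fewer than
#' two delay groups (or fewer than two replicates in a group) are reported
#' as skipped, never imputed.
#'
#' @param table Result table from [run_design()].
#' @param response Column to analyze: `"R"` (default) or `"I"`.
#' @param alpha Significance level (default 0.05).
#' @return List of class `delay_invariance_report`:
#'   `results` (one row per tested cell: `pulse_width`, `level`, `F`,
#'   `df1`, `df2`, `p_value`, `significant`), `skipped` (untestable cells),
#'   and `summary` (`n_cells`, `n_significant`, `fraction_significant`,
#'   `alpha`, `response`).
#' @export
delay_invariance_report <- function(table, response = "R", alpha = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("pulse_width", "level", "waveform", response) %in%
                  names(table)))
  cells <- unique(table[, c("pulse_width", "level")])
  cells <- cells[order(cells$pulse_width, cells$level), ]
  res <- list(); skip <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- table[table$pulse_width == cells$pulse_width[i] &
                   table$level == cells$level[i], ]
    grp <- split(sel[[response]], sel$waveform)
    grp <- grp[lengths(grp) > 0L]
    if (length(grp) < 2L || any(lengths(grp) < 2L)) {
      skip[[length(skip) + 1L]] <-
        data.frame(pulse_width = cells$pulse_width[i],
                   level = cells$level[i], n_groups = length(grp))
      next
    }
    a <- oneway_anova_tukey(grp)
    res[[length(res) + 1L]] <-
      data.frame(pulse_width = cells$pulse_width[i],
                 level = cells$level[i], F = a$statistic,
                 df1 = a$df[1], df2 = a$df[2], p_value = a$p_value,
                 significant = a$p_value < alpha)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(pulse_width = numeric(), level = numeric(), F = numeric(),
               df1 = numeric(), df2 = numeric(), p_value = numeric(),
               significant = logical())
  structure(list(
    results = results,
    skipped = if (length(skip)) do.call(rbind, skip) else NULL,
    summary = list(n_cells = nrow(results),
                   n_significant = sum(results$significant),
                   fraction_significant =
                     if (nrow(results)) mean(results$significant) else NA_real_,
                   alpha = alpha, response = response)),
    class = "delay_invariance_report")
}

#' @export
print.delay_invariance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<delay invariance (%s): %d/%d cells significant at alpha = %g (%.1f%%)>\n",
    s$response, s$n_significant, s$n_cells, s$alpha,
    100 * (s$fraction_significant %||% 0)))
  invisible(x)
}

#' Significance markers at conventional thresholds
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001,
#' `"****"` for p < 0.0001, `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
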