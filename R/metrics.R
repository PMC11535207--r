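#' NHPI variation metrics
#'
#' Six summary statistics of individual variation in NHPI coefficients
#' (the negative of the dissimilarity selection coefficients):
#'
#' * `nhpi_average(x)` — population average of individual-year coefficients.
#' * `nhpi_specialization(x)` — mean magnitude `mean(|x|)`; always at least
#'   `|average|`, and informative when a bimodal population averages to zero.
#' * `nhpi_heterogeneity(x)` — between-individual SD (n-1 denominator).
#' * `nhpi_consistency(xp, xs)` — mean absolute within-individual change
#'   between the prospecting and settlement phases; 0 means perfectly
#'   consistent.
#' * `nhpi_reversal(xp, xs)` — proportion of individuals whose coefficient
#'   changes sign between phases (a coefficient of exactly 0 counts as
#'   positive); bounded in \[0, 1\].
#' * `nhpi_interannual_consistency(records)` — per individual, the mean
#'   absolute difference between consecutive prospecting years, averaged
#'   over individuals.
#'
#' @param x Numeric vector of NHPI coefficients (one per individual-year).
#' @return A scalar metric value.
#' @name nhpi_metrics
NULL

#' @rdname nhpi_metrics
#' @export
nhpi_average <- function(x) {
  if (!length(x)) stop("empty coefficient vector")
  mean(x)
}

#' @rdname nhpi_metrics
#' @export
nhpi_specialization <- function(x) {
  if (!length(x)) stop("empty coefficient vector")
  mean(abs(x))
}

#' @rdname nhpi_metrics
#' @export
nhpi_heterogeneity <- function(x) {
  if (length(x) < 2) stop("need at least 2 coefficients for heterogeneity")
  sd(x)
}

# drop incomplete pairs, warning once
complete_pairs <- function(xp, xs) {
  ok <- is.finite(xp) & is.finite(xs)
  if (!any(ok)) stop("no complete phase pairs")
  if (any(!ok)) warning("excluding ", sum(!ok), " incomplete pair(s)")
  list(xp = xp[ok], xs = xs[ok])
}

#' @rdname nhpi_metrics
#' @param xp,xs Paired coefficients for the prospecting (`xp`) and
#'   settlement (`xs`) phase, one entry per individual.
#' @export
nhpi_consistency <- function(xp, xs) {
  pr <- complete_pairs(xp, xs)
  mean(abs(pr$xp - pr$xs))
}

#' @rdname nhpi_metrics
#' @export
nhpi_reversal <- function(xp, xs) {
  pr <- complete_pairs(xp, xs)
  sgn <- function(v) ifelse(v >= 0, 1, -1) # sign(0) counts as positive
  mean(sgn(pr$xp) != sgn(pr$xs))
}

#' @rdname nhpi_metrics
#' @param records data.frame with columns `id`, `year`, `x`: one coefficient
#'   per individual and prospecting year. Individuals with fewer than 2
#'   years are excluded with a warning.
#' @export
nhpi_interannual_consistency <- function(records) {
  stopifnot(all(c("id", "year", "x") %in% names(records)))
  per_id <- lapply(split(records, records$id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    if (nrow(d) < 2) return(NA_real_)
    mean(abs(diff(d$x)))
  })
  v <- unlist(per_id)
  if (any(is.na(v)))
    warning("excluding ", sum(is.na(v)),
            " individual(s) with fewer than 2 years")
  v <- v[!is.na(v)]
  if (!length(v)) stop("no individual has 2 or more years")
  mean(v)
}

# evaluate one named metric on a record table carrying column `x`
# (plus `phase` for pair metrics, `id`/`year` for interannual)
eval_metric <- function(metric, rec, warn = TRUE) {
  run <- function(expr) if (warn) expr else suppressWarnings(expr)
  switch(metric,
    average = nhpi_average(rec$x),
    specialization = nhpi_specialization(rec$x),
    heterogeneity = nhpi_heterogeneity(rec$x),
    consistency = ,
    reversal = {
      stopifnot(all(c("id", "phase") %in% names(rec)))
      ids <- unique(rec$id)
      xp <- rec$x[match(paste(ids, "p"), paste(rec$id, rec$phase))]
      xs <- rec$x[match(paste(ids, "s"), paste(rec$id, rec$phase))]
      if (metric == "consistency") run(nhpi_consistency(xp, xs))
      else run(nhpi_reversal(xp, xs))
    },
    interannual_consistency = run(nhpi_interannual_consistency(rec)),
    stop("unknown metric: ", metric))
}

#' Propagate coefficient uncertainty into the NHPI metrics
#'
#' Simulation-based uncertainty propagation: each coefficient is replaced,
#' independently across records and replicates, by a draw from
#' `Normal(x, se)`, and every requested metric is recomputed per group for
#' each of `n_sim` replicates. The point estimate is the metric on the
#' unperturbed coefficients.
#'
#' @param records data.frame with columns `x` (coefficient) and `se`
#'   (standard error), plus whatever the metrics need (`id`, `phase`,
#'   `year`) and any grouping columns. Records with a missing `se` are
#'   excluded with a warning.
#' @param metrics Character vector of metric names (see [nhpi_metrics]).
#' @param by Optional character vector of grouping columns (e.g. the natal
#'   habitat cluster, the phase); `NULL` pools everything.
#' @param n_sim Number of simulated replicates (default 1000).
#' @param seed Integer seed; the same seed reproduces the replicate sets.
#' @return An object of class `nhpi_metric_dist`: a data.frame with one row
#'   per metric x group (`metric`, `group`, `point`, `median`, `q2.5`,
#'   `q97.5`); the full replicate vectors are in `attr(., "replicates")`
#'   (a named list, names `"<metric>|<group>"`).
#' @export
propagate_uncertainty <- function(records,
                                  metrics = c("average", "specialization",
                                              "heterogeneity"),
                                  by = NULL, n_sim = 1000, seed) {
  stopifnot(all(c("x", "se") %in% names(records)))
  if (n_sim < 1) stop("n_sim must be >= 1")
  ok <- is.finite(records$x) & is.finite(records$se)
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " record(s) with missing x or se")
    records <- records[ok, , drop = FALSE]
  }
  if (!nrow(records)) stop("no usable records")
  if (!missing(seed)) set.seed(seed)

  groups <- if (is.null(by)) list(pooled = records) else
    split(records, interaction(records[, by, drop = FALSE], drop = TRUE,
                               sep = ":"))
  # perturbations drawn once per replicate for ALL records, so that groups
  # share no draws but a fixed seed fixes everything
  n <- nrow(records)
  noise <- matrix(rnorm(n * n_sim), n, n_sim) * records$se
  row_of <- seq_len(n)
  idx <- if (is.null(by)) list(pooled = row_of) else
    split(row_of, interaction(records[, by, drop = FALSE], drop = TRUE,
                              sep = ":"))

  rows <- list(); reps <- list()
  for (g in names(groups)) {
    rec <- groups[[g]]
    for (m in metrics) {
      point <- eval_metric(m, rec)
      rv <- vapply(seq_len(n_sim), function(r) {
        rec_r <- rec
        rec_r$x <- rec$x + noise[idx[[g]], r]
        eval_metric(m, rec_r, warn = FALSE)
      }, 0)
      key <- paste(m, g, sep = "|")
      reps[[key]] <- rv
      rows[[key]] <- data.frame(metric = m, group = g, point = point,
                                median = median(rv),
                                q2.5 = unname(quantile(rv, 0.025)),
                                q97.5 = unname(quantile(rv, 0.975)),
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  class(out) <- c("nhpi_metric_dist", class(out))
  out
}

#' Compare metric distributions between groups
#'
#' Fixed-effects ANOVA on replicate values with one or two group factors,
#' followed by Tukey HSD pairwise comparisons and a compact letter display
#' (groups sharing a letter do not differ at `alpha`). Letters are omitted
#' when the omnibus test is not significant. Because the replicate values
#' come from coefficient simulation rather than independent individuals,
#' the test is anti-conservative; report it alongside the replicate
#' quantile overlaps from [propagate_uncertainty()].
#'
#' @param values Numeric vector of replicate metric values.
#' @param f1 Group factor (e.g. natal habitat type).
#' @param f2 Optional second factor (e.g. dispersal phase) for a two-way
#'   design.
#' @param alpha Significance level for the letters (default 0.05).
#' @return List: `anova` (the ANOVA table), `omnibus_p` (cell-means model
#'   F-test p-value), `tukey` ([TukeyHSD] on the cell factor), `letters`
#'   (named character vector, or `NULL` when the omnibus test fails).
#' @export
compare_groups <- function(values, f1, f2 = NULL, alpha = 0.05) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2 && is.null(f2)) stop("need at least 2 groups")
  df <- data.frame(v = values, f1 = f1)
  if (!is.null(f2)) {
    df$f2 <- factor(f2)
    fit <- aov(v ~ f1 * f2, data = df)
    cells <- interaction(df$f1, df$f2, sep = ":", drop = TRUE)
  } else {
    fit <- aov(v ~ f1, data = df)
    cells <- df$f1
  }
  if (nlevels(cells) < 2) stop("need at least 2 groups")
  if (min(table(cells)) < 2) stop("each group needs at least 2 values")
  cell_fit <- aov(v ~ cells, data = data.frame(v = values, cells = cells))
  an <- anova(cell_fit)
  omnibus_p <- an[["Pr(>F)"]][1L]
  letters <- NULL
  if (is.finite(omnibus_p) && omnibus_p < alpha) {
    glt <- multcomp::glht(cell_fit, linfct = multcomp::mcp(cells = "Tukey"))
    letters <- multcomp::cld(glt, level = alpha)$mcletters$Letters
  }
  list(anova = summary(fit), omnibus_p = omnibus_p,
       tukey = TukeyHSD(cell_fit), letters = letters)
}
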