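#' Conditional logistic regression on matched strata
#'
#' Maximizes the conditional log-likelihood of a matched used/available
#' design,
#' \deqn{\ell(\beta) = \sum_s [\beta' x_{used(s)} - \log \sum_{j \in s}
#'   e^{\beta' x_j}],}
#' by Newton iteration with step-halving; the likelihood is concave.
#' Standard errors come from the inverse observed information at the
#' maximum. A covariate that is constant within every stratum cancels from
#' the likelihood: it is flagged non-identifiable and reported with
#' coefficient 0 and no standard error. Divergence of a coefficient beyond
#' `separation_bound` (on the standardized scale) is treated as complete
#' separation and flagged.
#'
#' @param design Design table with a stratum column, a logical used flag,
#'   and the covariate columns.
#' @param covariates Character vector of covariate column names (normally
#'   the standardized `_z` columns).
#' @param stratum_col,used_col Column names (defaults `"stratum"`,
#'   `"is_used"`).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @param separation_bound Coefficient magnitude treated as separation.
#' @return An object of class `nhpi_clogit`: `coefficients` (term, beta,
#'   se), `loglik`, `n_strata`, `converged`, `separation`,
#'   `non_identifiable`, `iterations`, and `nhpi` (the negative of the
#'   dissimilarity coefficient, when present).
#' @export
fit_clogit <- function(design, covariates, stratum_col = "stratum",
                       used_col = "is_used", tol = 1e-8, max_iter = 100,
                       separation_bound = 50) {
  X <- as.matrix(design[, covariates, drop = FALSE])
  if (any(!is.finite(X))) stop("covariates contain non-finite values")
  y <- as.logical(design[[used_col]])
  sid <- factor(design[[stratum_col]], levels = unique(design[[stratum_col]]))
  ns <- nlevels(sid)
  if (ns == 0) stop("empty design")
  cnt_used <- tapply(y, sid, sum)
  if (any(cnt_used != 1)) stop("each stratum must have exactly one used row")
  if (any(tabulate(sid) < 2)) stop("each stratum needs at least one available row")
  si <- as.integer(sid)

  # identifiability: a covariate constant within every stratum cancels
  within_var <- vapply(seq_len(ncol(X)), function(j) {
    mu <- tapply(X[, j], si, mean)[si]
    max(abs(X[, j] - mu))
  }, 0)
  active <- within_var > 1e-12
  beta_full <- setNames(numeric(ncol(X)), covariates)
  se_full <- setNames(rep(NA_real_, ncol(X)), covariates)
  separation <- FALSE; converged <- TRUE; iter <- 0L
  ll <- NA_real_

  loglik <- function(eta) {
    mx <- tapply(eta, si, max)
    denom <- mx + log(tapply(exp(eta - mx[si]), si, sum))
    sum(eta[y]) - sum(denom)
  }

  if (any(active)) {
    Xa <- X[, active, drop = FALSE]
    p_ac <- ncol(Xa)
    beta <- numeric(p_ac)
    eta <- drop(Xa %*% beta)
    ll <- loglik(eta)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      m <- as.vector(tapply(eta, si, max)[si])
      w <- exp(eta - m)
      p <- as.vector(w / tapply(w, si, sum)[si])
      g <- colSums(Xa[y, , drop = FALSE]) - drop(crossprod(Xa, p))
      if (max(abs(g)) < tol) { converged <- TRUE; break }
      M <- rowsum(Xa * p, si)                 # per-stratum E[x]
      H <- -(crossprod(Xa * sqrt(p)) - crossprod(M))
      step <- tryCatch(solve(-H, g), error = function(e) g * 0.1)
      # step-halving to guarantee ascent
      for (h in 0:30) {
        cand <- beta + step / 2^h
        eta_c <- drop(Xa %*% cand)
        ll_c <- loglik(eta_c)
        if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
          beta <- cand; eta <- eta_c; ll <- ll_c; break
        }
      }
      if (max(abs(beta)) > separation_bound) { separation <- TRUE; break }
    }
    if (separation) converged <- FALSE
    m <- as.vector(tapply(eta, si, max)[si])
    w <- exp(eta - m)
    p <- as.vector(w / tapply(w, si, sum)[si])
    M <- rowsum(Xa * p, si)
    info <- crossprod(Xa * sqrt(p)) - crossprod(M)
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
      rep(NA_real_, p_ac))
    beta_full[active] <- beta
    se_full[active] <- se
  } else {
    ll <- loglik(numeric(nrow(X)))
  }

  coefs <- data.frame(term = covariates, beta = unname(beta_full),
                      se = unname(se_full), stringsAsFactors = FALSE)
  diss_term <- grep("^dissimilarity", covariates, value = TRUE)
  nhpi <- if (length(diss_term) == 1L)
    -beta_full[[diss_term]] else NA_real_
  structure(list(coefficients = coefs, loglik = ll, n_strata = ns,
                 converged = converged, separation = separation,
                 non_identifiable = covariates[!active],
                 iterations = iter, nhpi = nhpi),
            class = "nhpi_clogit")
}

#' @export
print.nhpi_clogit <- function(x, ...) {
  cat("<nhpi_clogit> ", x$n_strata, " strata, logLik ",
      format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", if (x$separation) " [SEPARATION]",
      "\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  if (length(x$non_identifiable))
    cat("  non-identifiable: ", paste(x$non_identifiable, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# standardize a model dataset and fit the two-covariate clogit
fit_standard_clogit <- function(design, ...) {
  des <- standardize_design(design)
  fit <- fit_clogit(des, c("dissimilarity_z", "distance_z"), ...)
  attr(fit, "scaling") <- attr(des, "scaling")
  fit
}

#' Per individual-year conditional logistic fits
#'
#' Splits one individual's design by year, standardizes the covariates
#' within each model dataset, and fits the two-covariate conditional
#' logistic regression separately per year. The NHPI coefficient is the
#' negative of the (standardized-scale) dissimilarity coefficient.
#'
#' @param design Design table for one individual (with a `year` column).
#' @param ... Passed to [fit_clogit()].
#' @return data.frame of coefficient records: `year`, `phase` (modal label),
#'   `beta_dissim`, `se_dissim`, `beta_dist`, `se_dist`, `nhpi`, `se`
#'   (= `se_dissim`), `n_strata`, `converged`, `separation`, and the raw
#'   covariate SDs used for standardization.
#' @export
fit_individual_years <- function(design, ...) {
  if (!"year" %in% names(design)) design$year <- 1L
  out <- lapply(split(design, design$year), function(d) {
    fit <- fit_standard_clogit(d, ...)
    sc <- attr(fit, "scaling")
    co <- fit$coefficients
    data.frame(year = d$year[1L],
               phase = if ("phase" %in% names(d))
                 names(sort(table(d$phase), decreasing = TRUE))[1L] else NA,
               beta_dissim = co$beta[co$term == "dissimilarity_z"],
               se_dissim = co$se[co$term == "dissimilarity_z"],
               beta_dist = co$beta[co$term == "distance_z"],
               se_dist = co$se[co$term == "distance_z"],
               nhpi = fit$nhpi,
               se = co$se[co$term == "dissimilarity_z"],
               n_strata = fit$n_strata, converged = fit$converged,
               separation = fit$separation,
               sd_dissimilarity = sc$sd[sc$covariate == "dissimilarity"],
               sd_distance = sc$sd[sc$covariate == "distance"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# interaction-only clogit: covariate x level-specific coefficients, no main
# effects, as in the phase- and year-interaction models
fit_interaction_clogit <- function(design, factor_col, min_strata = 10, ...) {
  levs <- unique(design[[factor_col]])
  if (length(levs) < 2)
    stop("need at least 2 levels of '", factor_col, "' (got ",
         length(levs), ")")
  des <- standardize_design(design)
  terms <- character(0)
  for (cv in c("dissimilarity_z", "distance_z")) for (lv in levs) {
    nm <- paste0(cv, ":", factor_col, lv)
    des[[nm]] <- des[[cv]] * (des[[factor_col]] == lv)
    terms <- c(terms, nm)
  }
  fit <- fit_clogit(des, terms, ...)
  strata_per_level <- vapply(levs, function(lv)
    length(unique(des$stratum[des[[factor_col]] == lv])), 0L)
  co <- fit$coefficients
  rec <- do.call(rbind, lapply(seq_along(levs), function(i) {
    lv <- levs[i]
    dt <- paste0("dissimilarity_z:", factor_col, lv)
    kt <- paste0("distance_z:", factor_col, lv)
    data.frame(level = lv,
               beta_dissim = co$beta[co$term == dt],
               se_dissim = co$se[co$term == dt],
               beta_dist = co$beta[co$term == kt],
               se_dist = co$se[co$term == kt],
               nhpi = -co$beta[co$term == dt],
               se = co$se[co$term == dt],
               n_strata = strata_per_level[i],
               low_information = strata_per_level[i] < min_strata,
               stringsAsFactors = FALSE)
  }))
  names(rec)[1L] <- factor_col
  rownames(rec) <- NULL
  attr(rec, "fit") <- fit
  rec
}

#' Phase-interaction conditional logistic fit
#'
#' Single conditional logistic model over the last prospecting year and the
#' first settlement year with four interaction-only parameters
#' (dissimilarity and distance, each by phase; no main effects), yielding a
#' separate coefficient pair per dispersal phase for the consistency and
#' reversal metrics.
#'
#' @param design Design table containing both phases for one individual.
#' @param min_strata A phase with fewer strata is flagged low-information.
#' @param ... Passed to [fit_clogit()].
#' @return data.frame with one row per phase (`phase`, `beta_dissim`,
#'   `se_dissim`, `beta_dist`, `se_dist`, `nhpi`, `se`, `n_strata`,
#'   `low_information`); the underlying `nhpi_clogit` fit is in
#'   `attr(., "fit")`.
#' @export
fit_phase_interaction <- function(design, min_strata = 10, ...) {
  if (!"phase" %in% names(design)) stop("design lacks a 'phase' column")
  fit_interaction_clogit(design, "phase", min_strata = min_strata, ...)
}

#' Year-interaction conditional logistic fit
#'
#' As [fit_phase_interaction()], with year-specific coefficients over an
#' individual's prospecting years; feeds the interannual consistency metric.
#'
#' @param design Design table with a `year` column (at least 2 years).
#' @param min_strata A year with fewer strata is flagged low-information.
#' @param ... Passed to [fit_clogit()].
#' @return data.frame with one row per year; see [fit_phase_interaction()].
#' @export
fit_yearly <- function(design, min_strata = 10, ...) {
  if (!"year" %in% names(design)) stop("design lacks a 'year' column")
  fit_interaction_clogit(design, "year", min_strata = min_strata, ...)
}

#' K-fold cross-validation of a fitted design
#'
#' Strata are partitioned into `k` folds. For each fold the model is
#' refitted on the remaining strata and the held-out strata are scored by
#' the linear predictor; within each held-out stratum the used step's score
#' is ranked among the stratum members (rank 1 = highest score). The
#' frequencies of ranks 1..(n_avail + 1) are correlated with the rank index
#' by Spearman's rho, negated so that a well-performing model (used steps
#' concentrated at top ranks) gives positive rho.
#'
#' @param design Standardized design table.
#' @param covariates Covariate columns used for fitting and scoring.
#' @param k Number of folds (default 5).
#' @param seed Optional seed for the fold assignment.
#' @param ... Passed to [fit_clogit()].
#' @return List with `mean`, `sd`, and the per-fold `rho` values.
#' @export
kfold_cv <- function(design, covariates = c("dissimilarity_z", "distance_z"),
                     k = 5, seed = NULL, ...) {
  sids <- unique(design$stratum)
  if (k > length(sids)) stop("k exceeds the number of strata")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(sids)))
  names(fold) <- as.character(sids)
  rho <- numeric(k)
  for (f in seq_len(k)) {
    test_ids <- sids[fold[as.character(sids)] == f]
    train <- design[!design$stratum %in% test_ids, , drop = FALSE]
    test <- design[design$stratum %in% test_ids, , drop = FALSE]
    if (!nrow(test) || !length(unique(train$stratum)))
      stop("fold ", f, " has no strata")
    fit <- fit_clogit(train, covariates, ...)
    score <- as.matrix(test[, covariates, drop = FALSE]) %*%
      fit$coefficients$beta
    ranks <- vapply(split(seq_len(nrow(test)), test$stratum), function(ix) {
      s <- score[ix]
      u <- which(test$is_used[ix])
      sum(s > s[u]) + 1L
    }, 0L)
    nsize <- max(tabulate(factor(test$stratum)))
    freq <- tabulate(ranks, nbins = nsize)
    rho[f] <- -suppressWarnings(cor(seq_len(nsize), freq,
                                    method = "spearman"))
  }
  list(mean = mean(rho), sd = sd(rho), rho = rho)
}
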