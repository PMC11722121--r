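#' Iterative random-forest imputation of mixed-type data
#'
#' Missing cells are initialised with the column mean (numeric) or mode
#' (categorical) and then refined by iteratively regressing each
#' incomplete variable on all others with a random forest, sweeping
#' variables in order of increasing missingness. Iteration stops the
#' first time the change criterion increases for both the numeric and the
#' categorical variable sets, and the previous sweep's values are
#' returned.
#'
#' @param table data frame; character columns are treated as categorical.
#' @param seed integer seed (imputation is deterministic given the seed).
#' @param max_iter maximum sweeps (default 10).
#' @param n_trees trees per forest (default 100).
#' @param exclude columns never used as predictors or imputed (default
#'   `"patient_id"`).
#' @return the completed data frame.
#' @export
impute_rf <- function(table, seed = 1L, max_iter = 10L, n_trees = 100L,
                      exclude = "patient_id") {
  set.seed(seed)
  work <- table[, setdiff(names(table), exclude), drop = FALSE]
  for (v in names(work)) if (is.character(work[[v]]))
    work[[v]] <- factor(work[[v]])
  na_idx <- lapply(work, function(col) which(is.na(col)))
  n_miss <- vapply(na_idx, length, integer(1))
  if (any(n_miss == nrow(work)))
    stop(sprintf("variable '%s' is entirely missing",
                 names(which(n_miss == nrow(work)))[1]))
  if (all(n_miss == 0L)) return(table)
  ## mean/mode initialisation
  for (v in names(work)) {
    idx <- na_idx[[v]]
    if (!length(idx)) next
    if (is.numeric(work[[v]])) {
      work[[v]][idx] <- mean(work[[v]], na.rm = TRUE)
    } else {
      tab <- table(work[[v]])
      work[[v]][idx] <- names(tab)[which.max(tab)]
    }
  }
  sweep_order <- order(n_miss)
  sweep_order <- sweep_order[n_miss[sweep_order] > 0L]
  num_vars <- names(work)[vapply(work, is.numeric, logical(1))]
  prev <- work
  d_num_old <- Inf; d_cat_old <- Inf
  for (it in seq_len(max_iter)) {
    old <- work
    for (vi in sweep_order) {
      v <- names(work)[vi]
      idx <- na_idx[[v]]
      obs <- setdiff(seq_len(nrow(work)), idx)
      xs <- work[, setdiff(names(work), v), drop = FALSE]
      fit <- randomForest::randomForest(x = xs[obs, , drop = FALSE],
                                        y = work[[v]][obs],
                                        ntree = n_trees)
      pred <- stats::predict(fit, xs[idx, , drop = FALSE])
      work[[v]][idx] <- if (is.factor(work[[v]]))
        as.character(pred) else as.numeric(pred)
    }
    miss_num <- intersect(names(work)[n_miss > 0L], num_vars)
    miss_cat <- setdiff(names(work)[n_miss > 0L], num_vars)
    d_num <- if (length(miss_num)) {
      num <- den <- 0
      for (v in miss_num) {
        num <- num + sum((work[[v]] - old[[v]])^2)
        den <- den + sum(work[[v]]^2)
      }
      if (den > 0) num / den else 0
    } else 0
    d_cat <- if (length(miss_cat)) {
      mm <- 0; nn <- 0
      for (v in miss_cat) {
        mm <- mm + sum(work[[v]][na_idx[[v]]] != old[[v]][na_idx[[v]]])
        nn <- nn + length(na_idx[[v]])
      }
      if (nn > 0) mm / nn else 0
    } else 0
    worse_num <- length(miss_num) == 0L || d_num >= d_num_old
    worse_cat <- length(miss_cat) == 0L || d_cat >= d_cat_old
    if (it > 1L && worse_num && worse_cat) { work <- prev; break }
    prev <- old
    d_num_old <- d_num; d_cat_old <- d_cat
    prev <- work
  }
  out <- table
  for (v in names(work)) {
    col <- work[[v]]
    out[[v]] <- if (is.factor(col)) as.character(col) else col
  }
  out
}

#' Two-sided Fisher exact test by full enumeration
#'
#' Sums, under the fixed-margin (multivariate) hypergeometric null, the
#' probabilities of all tables whose probability does not exceed that of
#' the observed table. 2 x 2 tables use the hypergeometric distribution
#' directly; general r x c tables are enumerated recursively (feasible for
#' the cohort-scale counts this package targets).
#'
#' @param counts matrix of non-negative integer counts.
#' @return two-sided p-value. Degenerate margins (a zero row or column
#'   total, or a single row/column) return p = 1 with attribute
#'   `degenerate = TRUE`.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  tol <- 1 + 1e-7
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    x <- counts[1, 1]
    sup <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- stats::dhyper(sup, rs[1], rs[2], cs[1])
    p_obs <- stats::dhyper(x, rs[1], rs[2], cs[1])
    return(min(1, sum(probs[probs <= p_obs * tol])))
  }
  log_p_table <- function(tab) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(tab + 1))
  }
  lp_obs <- log_p_table(counts)
  total <- 0
  nrw <- nrow(counts); ncl <- ncol(counts)
  # recursive enumeration over tables with the observed margins
  recurse <- function(tab, i, j, row_left, col_left) {
    if (i == nrw) {
      # last row fixed by column margins
      if (any(col_left < 0)) return()
      tab[nrw, ] <- col_left
      lp <- log_p_table(tab)
      if (lp <= lp_obs + log(tol)) total <<- total + exp(lp)
      return()
    }
    if (j == ncl) {
      # last cell of row fixed
      v <- row_left
      if (v < 0 || v > col_left[ncl]) return()
      tab[i, ncl] <- v
      cl <- col_left; cl[ncl] <- cl[ncl] - v
      recurse(tab, i + 1L, 1L, rs[i + 1L], cl)
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      tab[i, j] <- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(tab, i, j + 1L, row_left - v, cl)
    }
  }
  recurse(matrix(0L, nrw, ncl), 1L, 1L, rs[1], cs)
  min(1, total)
}

#' Univariate screening of cohort variables
#'
#' Numeric variables are compared between PNP groups with an independent
#' two-sample t test (Welch by default); categorical variables with the
#' exact contingency test. Variables significant at `alpha` (default 10%)
#' are flagged for mixed-model retesting, as are the members of
#' `forced_retests` regardless of significance.
#'
#' @param table imputed cohort data frame with `pnp_present` in ("y","n").
#' @param alpha screening level (default 0.10).
#' @param forced_retests variables always flagged for retest. Default: FAZ
#'   area and both capillary tortuosity measures.
#' @param var_equal pooled-variance t test if TRUE (default FALSE =
#'   Welch).
#' @param exclude columns not screened.
#' @return data frame: variable, test, p_value, significant_at_10pct,
#'   retest_requested; skipped constant variables carry NA p with
#'   `test = "skipped"`.
#' @export
univariate_screen <- function(table, alpha = 0.10,
                              forced_retests = c("faz_area_mm2",
                                                 "tort_m1_capillaries",
                                                 "tort_m2_capillaries"),
                              var_equal = FALSE,
                              exclude = c("patient_id", "pnp_present")) {
  grp <- table$pnp_present
  if (is.null(grp)) stop("table lacks pnp_present")
  vars <- setdiff(names(table), exclude)
  res <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      if (stats::sd(x, na.rm = TRUE) < 1e-12)
        return(data.frame(variable = v, test = "skipped", p_value = NA_real_))
      p <- stats::t.test(x ~ grp, var.equal = var_equal)$p.value
      data.frame(variable = v, test = "t", p_value = p)
    } else {
      tab <- table(x, grp)
      if (nrow(tab) < 2)
        return(data.frame(variable = v, test = "skipped", p_value = NA_real_))
      data.frame(variable = v, test = "fisher",
                 p_value = as.numeric(fisher_exact(tab)))
    }
  })
  out <- do.call(rbind, res)
  out$significant_at_10pct <- !is.na(out$p_value) & out$p_value < alpha
  out$retest_requested <- out$significant_at_10pct |
    out$variable %in% forced_retests
  out
}

#' Linear mixed model for a numeric response with a patient random
#' intercept
#'
#' REML fit of `response ~ pnp_present + (1 | patient_id)` with optional
#' response transformation, plus Shapiro-Wilk normality and Levene
#' homogeneity checks on the residuals.
#'
#' @param table cohort data frame.
#' @param response name of the numeric response column.
#' @param transformation `"none"`, `"power1.05"` or `"sqrt"`; or
#'   `"auto"` to pick the first of none/sqrt/power1.05 whose residuals
#'   pass Shapiro-Wilk at 5%.
#' @return list (class `mixed_fit`): estimates, fixed-effect p-value,
#'   random-intercept SD, singular flag, convergence flag, AIC,
#'   transformation label, assumption p-values.
#' @export
fit_lmm <- function(table, response,
                    transformation = c("none", "power1.05", "sqrt", "auto")) {
  transformation <- match.arg(transformation)
  tf <- function(label, y) switch(label, none = y, power1.05 = y^1.05,
                                  sqrt = sqrt(pmax(y, 0)))
  fit_one <- function(label) {
    dat <- data.frame(y = tf(label, table[[response]]),
                      grp = factor(table$pnp_present),
                      pid = factor(table$patient_id))
    ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore")
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ grp + (1 | pid), data = dat, REML = TRUE,
                 control = ctrl)))
    res <- stats::residuals(fit)
    sw <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA)
    lv <- tryCatch(car::leveneTest(res ~ dat$grp)[1, "Pr(>F)"],
                   error = function(e) NA)
    cf <- summary(fit)$coefficients
    tval <- cf[2, "t value"]
    ngrp <- length(unique(dat$pid))
    pval <- 2 * stats::pt(-abs(tval), df = ngrp - 2)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_sd <- vc$sdcor[vc$grp == "pid"]
    structure(list(response = response, fixed_estimate = cf[2, "Estimate"],
                   fixed_se = cf[2, "Std. Error"], p_value = pval,
                   random_intercept_sd = ri_sd,
                   singular = lme4::isSingular(fit, tol = 1e-4),
                   converged = TRUE, aic = stats::AIC(fit),
                   transformation = label, shapiro_p = sw, levene_p = lv,
                   model = fit), class = "mixed_fit")
  }
  if (transformation != "auto") return(fit_one(transformation))
  for (label in c("none", "sqrt", "power1.05")) {
    f <- fit_one(label)
    if (!is.na(f$shapiro_p) && f$shapiro_p > 0.05) return(f)
  }
  f
}

#' Mixed logistic regression with a patient random intercept
#'
#' Maximum-likelihood fit of a binary response on the PNP group (or an
#' arbitrary formula right-hand side) with `(1 | patient_id)`, using
#' adaptive Gauss-Hermite quadrature.
#'
#' @param table cohort data frame.
#' @param response binary response column name (factor/character with two
#'   levels, or 0/1).
#' @param fixed right-hand-side of the fixed-effects formula (default
#'   `"pnp_present"`).
#' @param nagq quadrature nodes (default 15).
#' @return `mixed_fit` list; `separation` flags quasi-complete separation
#'   (|coef| above 10 on the logit scale), `singular` a random-intercept
#'   variance below 1e-6.
#' @export
fit_logistic_mixed <- function(table, response, fixed = "pnp_present",
                               nagq = 15L) {
  y <- table[[response]]
  if (!is.numeric(y)) y <- as.integer(factor(y)) - 1L
  if (length(unique(y)) != 2L) stop("response is not binary")
  dat <- table
  dat$.y <- y
  dat$pid <- factor(table$patient_id)
  fml <- stats::as.formula(paste(".y ~", fixed, "+ (1 | pid)"))
  conv <- TRUE
  fit <- withCallingHandlers(
    suppressMessages(lme4::glmer(fml, data = dat, family = stats::binomial,
                                 nAGQ = nagq)),
    warning = function(w) {
      if (grepl("converge|Hessian|deviance", conditionMessage(w)))
        conv <<- FALSE
      invokeRestart("muffleWarning")
    })
  cf <- suppressWarnings(summary(fit)$coefficients)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "pid"]
  sep <- any(abs(cf[, "Estimate"]) > 10) || any(cf[, "Std. Error"] > 50)
  structure(list(response = response,
                 coefficients = cf[, "Estimate"],
                 se = cf[, "Std. Error"],
                 p_values = cf[, "Pr(>|z|)"],
                 p_value = if (nrow(cf) >= 2) cf[2, "Pr(>|z|)"] else NA,
                 random_intercept_sd = ri_sd,
                 singular = ri_sd^2 < 1e-6,
                 converged = conv, separation = sep,
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 model = fit), class = "mixed_fit")
}

# Gauss-Hermite marginal log-likelihood of a baseline-category logit
# model with a shared patient intercept. y: integer 1..K, x: numeric
# covariate, pid: integer patient index. par = (alpha_2..K, beta_2..K,
# log_sigma).
multinom_mixed_loglik <- function(par, y, x, pid, K, nodes) {
  alpha <- par[seq_len(K - 1)]
  beta <- par[K - 1 + seq_len(K - 1)]
  lsig <- par[2 * (K - 1) + 1]
  sig <- exp(lsig)
  z <- nodes$x; w <- nodes$w
  ll <- 0
  for (i in unique(pid)) {
    sel <- which(pid == i)
    contrib <- vapply(seq_along(z), function(q) {
      b <- sqrt(2) * sig * z[q]
      lp <- 0
      for (j in sel) {
        eta <- c(0, alpha + beta * x[j] + b)
        lp <- lp + eta[y[j]] - log(sum(exp(eta)))
      }
      lp
    }, numeric(1))
    m <- max(contrib)
    ll <- ll + m + log(sum(w / sqrt(pi) * exp(contrib - m)))
  }
  ll
}

#' Multinomial mixed model with a shared patient random intercept
#'
#' Baseline-category logit for a response with three or more categories,
#' with a single shared normal random intercept per patient entering every
#' non-baseline logit, estimated by Gauss-Hermite quadrature. The overall
#' group effect is tested with a likelihood-ratio test against the model
#' without the covariate.
#'
#' @param table cohort data frame.
#' @param response categorical response column name.
#' @param fixed numeric or binary covariate column (default group
#'   indicator from `pnp_present`).
#' @param nagq quadrature nodes (default 15).
#' @return `mixed_fit` list with per-category coefficients, LRT p-value,
#'   random-intercept SD and dropped empty categories (flagged).
#' @export
fit_multinomial_mixed <- function(table, response, fixed = NULL,
                                  nagq = 15L) {
  yraw <- if (is.factor(table[[response]])) table[[response]] else
    factor(table[[response]])
  dropped <- levels(yraw)[tabulate(yraw, nlevels(yraw)) == 0]
  yraw <- droplevels(yraw)
  K <- nlevels(yraw)
  if (K < 2) stop("response needs at least 2 observed categories")
  y <- as.integer(yraw)
  x <- if (is.null(fixed)) as.integer(factor(table$pnp_present)) - 1L else {
    xx <- table[[fixed]]
    if (!is.numeric(xx)) as.integer(factor(xx)) - 1L else xx
  }
  pid <- as.integer(factor(table$patient_id))
  nodes <- pracma::gaussHermite(nagq)
  np <- 2 * (K - 1) + 1
  opt_full <- stats::optim(rep(0, np), function(p)
    -multinom_mixed_loglik(p, y, x, pid, K, nodes),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  # null model: beta = 0
  opt_null <- stats::optim(rep(0, K), function(p)
    -multinom_mixed_loglik(c(p[seq_len(K - 1)], rep(0, K - 1), p[K]),
                           y, x, pid, K, nodes),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  lrt <- 2 * (opt_null$value - opt_full$value)
  p <- stats::pchisq(max(lrt, 0), df = K - 1, lower.tail = FALSE)
  sig <- exp(opt_full$par[np])
  structure(list(response = response,
                 alpha = opt_full$par[seq_len(K - 1)],
                 beta = opt_full$par[K - 1 + seq_len(K - 1)],
                 random_intercept_sd = sig, singular = sig^2 < 1e-6,
                 converged = opt_full$convergence == 0,
                 p_value = p, loglik = -opt_full$value,
                 dropped_categories = dropped,
                 categories = levels(yraw)), class = "mixed_fit")
}

#' Prune strongly correlated candidate predictors
#'
#' Computes pairwise Pearson correlations among numeric candidates; within
#' each pair above `r_threshold`, drops the member with the larger mean
#' absolute correlation to all remaining candidates. Manual exclusions
#' (default: PRP, since PNP is itself an indication for PRP) are removed
#' unconditionally.
#'
#' @param table cohort data frame.
#' @param candidates character vector of candidate columns.
#' @param r_threshold correlation threshold (default 0.9).
#' @param manual_exclusions columns dropped regardless of correlation.
#' @return list: `kept`, `dropped` (data frame variable, reason, r).
#' @export
correlation_prune <- function(table, candidates, r_threshold = 0.9,
                              manual_exclusions = "prp") {
  dropped <- data.frame(variable = character(0), reason = character(0),
                        r = numeric(0))
  for (v in intersect(manual_exclusions, candidates)) {
    dropped <- rbind(dropped, data.frame(variable = v, reason = "manual",
                                         r = NA_real_))
    candidates <- setdiff(candidates, v)
  }
  num <- candidates[vapply(candidates, function(v)
    is.numeric(table[[v]]), logical(1))]
  repeat {
    if (length(num) < 2) break
    cm <- abs(stats::cor(table[, num, drop = FALSE],
                         use = "pairwise.complete.obs"))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= r_threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)[1, ]
    pair <- num[idx]
    mean_abs <- vapply(pair, function(v)
      mean(cm[v, setdiff(num, v)]), numeric(1))
    victim <- pair[which.max(mean_abs)]
    dropped <- rbind(dropped, data.frame(variable = victim,
                                         reason = "correlation", r = mx))
    num <- setdiff(num, victim)
    candidates <- setdiff(candidates, victim)
  }
  list(kept = candidates, dropped = dropped)
}

# fit a mixed logistic model for a term set; returns list(fit, aic, ok)
fit_selection_model <- function(table, terms, response = "pnp_present",
                                random = "patient_id") {
  dat <- table
  dat$.y <- as.integer(factor(dat[[response]])) - 1L
  dat$.pid <- factor(dat[[random]])
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .pid)"))
  ok <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lme4::glmer(fml, data = dat,
                                   family = stats::binomial, nAGQ = 1L)),
      warning = function(w) {
        if (grepl("failed to converge|degenerate|Downdated",
                  conditionMessage(w))) ok <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(list(fit = NULL, aic = Inf, ok = FALSE))
  list(fit = fit, aic = stats::AIC(fit), ok = ok)
}

#' Backward-AIC selection of a mixed logistic model
#'
#' First grows the "maximal model": candidates are ordered by the AIC of
#' their single-term models and added one at a time, keeping only terms
#' whose addition leaves the fit convergent. Backward elimination then
#' repeatedly removes the term whose deletion lowers the AIC most,
#' stopping when no deletion lowers it. Final p-values are Wald tests on
#' the final fit.
#'
#' @param table cohort data frame (imputed).
#' @param candidates candidate predictor columns.
#' @param response binary response column (default `pnp_present`).
#' @param random grouping column for the random intercept (default
#'   `patient_id`).
#' @return list (class `selection_result`): `final_terms`, `final_p`,
#'   `maximal_terms`, `trace` (data frame step, dropped, aic), `aic`,
#'   `model`.
#' @export
backward_aic_select <- function(table, candidates,
                                response = "pnp_present",
                                random = "patient_id") {
  if (length(candidates) == 0L) {
    base <- fit_selection_model(table, character(0), response, random)
    if (!is.finite(base$aic)) stop("no convergent model")
    return(structure(list(final_terms = character(0),
                          final_p = numeric(0),
                          maximal_terms = character(0),
                          trace = data.frame(step = integer(0),
                                             dropped = character(0),
                                             aic = numeric(0)),
                          aic = base$aic, model = base$fit),
                     class = "selection_result"))
  }
  single_aic <- vapply(candidates, function(v)
    fit_selection_model(table, v, response, random)$aic, numeric(1))
  ordered <- candidates[order(single_aic)]
  maximal <- character(0)
  for (v in ordered) {
    trial <- fit_selection_model(table, c(maximal, v), response, random)
    if (trial$ok && is.finite(trial$aic)) maximal <- c(maximal, v)
  }
  cur <- fit_selection_model(table, maximal, response, random)
  if (is.null(cur$fit)) stop("no convergent model could be built")
  terms <- maximal
  trace <- data.frame(step = 0L, dropped = "(maximal)", aic = cur$aic)
  step <- 0L
  while (length(terms) > 0L) {
    step <- step + 1L
    fits <- lapply(terms, function(v)
      fit_selection_model(table, setdiff(terms, v), response, random))
    aics <- vapply(fits, function(f)
      if (f$ok) f$aic else Inf, numeric(1))
    best <- which.min(aics)
    if (aics[best] < cur$aic) {
      trace <- rbind(trace, data.frame(step = step, dropped = terms[best],
                                       aic = aics[best]))
      cur <- fits[[best]]
      terms <- setdiff(terms, terms[best])
    } else break
  }
  cf <- suppressWarnings(summary(cur$fit)$coefficients)
  keep <- intersect(rownames(cf), terms)
  # factor terms expand coefficient names; map by prefix
  final_p <- vapply(terms, function(v) {
    rows <- grep(paste0("^", v), rownames(cf))
    if (length(rows)) min(cf[rows, "Pr(>|z|)"]) else NA_real_
  }, numeric(1))
  structure(list(final_terms = terms, final_p = final_p,
                 maximal_terms = maximal, trace = trace, aic = cur$aic,
                 model = cur$fit), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n final terms:",
      if (length(x$final_terms)) paste(x$final_terms, collapse = ", ")
      else "(none)", sprintf("\n AIC %.2f\n", x$aic))
  invisible(x)
}

#' Leave-one-out cross-validated ROC of a selected model
#'
#' For each eye, the mixed logistic model is refit on the remaining eyes
#' and the held-out eye's probability predicted at the population level
#' (random intercept set to zero). The AUC of the held-out scores is
#' estimated with its 95% DeLong confidence interval. Leave-one-patient-out
#' folding is available since bilateral eyes are correlated.
#'
#' @param table cohort data frame.
#' @param terms model terms.
#' @param response,random as in [backward_aic_select].
#' @param unit `"eye"` (default) or `"patient"`.
#' @return list: `auc`, `ci` (length 2), `scores`, `labels`, `skipped`
#'   (folds whose training data had a single class).
#' @export
loocv_auc <- function(table, terms, response = "pnp_present",
                      random = "patient_id", unit = c("eye", "patient")) {
  unit <- match.arg(unit)
  y <- as.integer(factor(table[[response]])) - 1L
  folds <- if (unit == "eye") as.list(seq_len(nrow(table))) else
    split(seq_len(nrow(table)), table[[random]])
  scores <- rep(NA_real_, nrow(table))
  skipped <- 0L
  for (f in folds) {
    train <- setdiff(seq_len(nrow(table)), f)
    if (length(unique(y[train])) < 2L) { skipped <- skipped + 1L; next }
    m <- fit_selection_model(table[train, , drop = FALSE], terms,
                             response, random)
    if (is.null(m$fit)) { skipped <- skipped + 1L; next }
    dat <- table[f, , drop = FALSE]
    dat$.pid <- factor(dat[[random]])
    scores[f] <- stats::predict(m$fit, newdata = dat, re.form = NA,
                                type = "response",
                                allow.new.levels = TRUE)
  }
  ok <- !is.na(scores)
  roc <- pROC::roc(response = y[ok], predictor = scores[ok], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)), ci = ci[c(1, 3)],
       scores = scores, labels = y, skipped = skipped)
}

#' Cross-classify eyes by normative metric thresholds and PNP status
#'
#' Counts eyes with "preserved" versus "reduced" perfusion density
#' (normal: PD strictly above `pd_cut`) and "preserved" versus "enlarged"
#' FAZ area (preserved: strictly below `faz_cut_mm2`), against the PNP
#' label.
#'
#' @param table data frame with `pnp_present`, `perfusion_density`,
#'   `faz_area_mm2`.
#' @param pd_cut normative perfusion density (default 0.45).
#' @param faz_cut_mm2 normative FAZ area (default 0.3 mm^2).
#' @return list of two 2 x 2 count matrices (`pd`, `faz`) and `excluded`
#'   row counts.
#' @export
stratify_thresholds <- function(table, pd_cut = 0.45, faz_cut_mm2 = 0.3) {
  lab <- factor(table$pnp_present, levels = c("y", "n"),
                labels = c("PNP", "noPNP"))
  pd_ok <- !is.na(table$perfusion_density)
  pd_grp <- factor(ifelse(table$perfusion_density > pd_cut,
                          "normal", "reduced"),
                   levels = c("normal", "reduced"))
  faz_ok <- !is.na(table$faz_area_mm2)
  faz_grp <- factor(ifelse(table$faz_area_mm2 < faz_cut_mm2,
                           "preserved", "enlarged"),
                    levels = c("preserved", "enlarged"))
  list(pd = table(pd_grp[pd_ok], lab[pd_ok]),
       faz = table(faz_grp[faz_ok], lab[faz_ok]),
       excluded = c(pd = sum(!pd_ok), faz = sum(!faz_ok)))
}
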