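#' Sex-standardize cohort columns
#'
#' Both nanostructural and reflectance variables differ between the sexes in
#' mean and often in variance, so before pooling the sexes each variable is
#' standardized within sex to mean zero and unit standard deviation
#' (sample sd, n - 1 denominator). New columns are appended with a `_z`
#' suffix.
#'
#' @param table A cohort data frame with a `sex` column (values `"M"`/`"F"`)
#'   and the columns to standardize.
#' @param columns Character vector of numeric column names.
#' @return The input as a tibble with `<column>_z` columns appended.
#' @export
sex_standardize <- function(table, columns) {
  stopifnot("sex" %in% names(table), all(columns %in% names(table)))
  out <- tibble::as_tibble(table)
  for (cl in columns) {
    z <- stats::ave(out[[cl]], out$sex, FUN = function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
      (x - mean(x)) / s
    })
    if (any(is.na(z) & !is.na(out[[cl]]))) {
      stop(sprintf("column `%s` has zero within-sex variance", cl))
    }
    out[[paste0(cl, "_z")]] <- z
  }
  out
}

# pooled-variance two-sample t that tolerates zero-variance (degenerate)
# inputs, where stats::t.test refuses to run
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  s2p <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  delta <- mean(x) - mean(y)
  if (s2p <= 0) {
    t <- if (delta == 0) 0 else Inf * sign(delta)
  } else {
    t <- delta / sqrt(s2p * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df,
       p = if (is.finite(t)) 2 * pt(abs(t), df, lower.tail = FALSE) else 0,
       delta = delta)
}

test_result <- function(statistic, value, df, p_value, direction = NA_real_) {
  tibble::tibble(statistic = statistic, value = value,
                 df1 = df[1], df2 = if (length(df) > 1) df[2] else NA_real_,
                 p_value = p_value, direction = direction)
}

#' Compare a variable between the sexes in mean and in variance
#'
#' Runs the two classical sex-difference checks for one variable: a pooled
#' two-sample Student's t-test for the means (df = n1 + n2 - 2) and a
#' variance-ratio F-test with the larger variance in the numerator and a
#' two-tailed p-value.
#'
#' @param table Cohort data frame with a `sex` column.
#' @param column Name of the numeric column to compare.
#' @return A two-row tibble (statistics `"t"` and `"F"`) with columns
#'   `statistic`, `value`, `df1`, `df2`, `p_value`, `direction` (sign of the
#'   male - female mean difference for t; which sex has the larger variance,
#'   +1 male, -1 female, for F).
#' @export
sex_mean_variance_tests <- function(table, column) {
  stopifnot("sex" %in% names(table), column %in% names(table))
  xm <- table[[column]][table$sex == "M"]
  xf <- table[[column]][table$sex == "F"]
  if (length(xm) < 2 || length(xf) < 2) {
    stop("both sexes need at least 2 observations")
  }
  tt <- pooled_t(xm, xf)
  vm <- var(xm); vf <- var(xf)
  if (vm >= vf) {
    fstat <- vm / vf; df <- c(length(xm) - 1, length(xf) - 1); dir_f <- 1
  } else {
    fstat <- vf / vm; df <- c(length(xf) - 1, length(xm) - 1); dir_f <- -1
  }
  if (vm == 0 && vf == 0) fstat <- 1
  p_f <- min(1, 2 * pf(fstat, df[1], df[2], lower.tail = FALSE))
  dplyr::bind_rows(
    test_result("t", tt$t, tt$df, tt$p, direction = sign(tt$delta)),
    test_result("F", fstat, df, p_f, direction = dir_f)
  )
}

#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise Pearson correlations among the given columns, with the two-sided
#' p-value of each coefficient from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param table Data frame of observations.
#' @param columns Character vector of numeric column names (n >= 3 rows).
#' @return A list with matrices `r` and `p` (symmetric, unit/zero diagonal)
#'   and a tidy tibble `pairs` (one row per unordered pair: `var1`, `var2`,
#'   `r`, `n`, `p_value`).
#' @export
pearson_matrix <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  x <- as.matrix(table[, columns])
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete rows")
  if (any(apply(x, 2, sd) == 0)) {
    stop("constant column: correlation undefined")
  }
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- 0
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble::tibble(
    var1 = columns[idx[, 1]], var2 = columns[idx[, 2]],
    r = r[idx], n = n, p_value = p[idx]
  )
  list(r = r, p = p, pairs = pairs)
}

# ---- backward-elimination linear models ------------------------------------

# partial (type-III-style) F for one term of a fitted lm, by deleting that
# term's model-matrix columns while keeping every other retained term
partial_f <- function(fit, term) {
  mm <- model.matrix(fit)
  asg <- attr(mm, "assign")
  labs <- attr(terms(fit), "term.labels")
  ti <- match(term, labs)
  drop_cols <- which(asg == ti)
  if (length(drop_cols) == 0) stop(sprintf("term `%s` not in model", term))
  y <- fit$model[[1]]
  rss1 <- sum(fit$residuals^2)
  df_res <- fit$df.residual
  f0 <- lm.fit(mm[, -drop_cols, drop = FALSE], y)
  rss0 <- sum(f0$residuals^2)
  df_t <- length(drop_cols)
  fstat <- ((rss0 - rss1) / df_t) / (rss1 / df_res)
  tibble::tibble(term = term, F = fstat, df1 = df_t, df2 = df_res,
                 p_value = pf(fstat, df_t, df_res, lower.tail = FALSE))
}

#' Backward-elimination linear model with term reintroduction
#'
#' Fits an ordinary least-squares linear model and simplifies it by backward
#' stepwise elimination: at each step the least significant *removable* term
#' (interactions are removable before their main effects; a main effect is
#' kept while any interaction containing it remains) with p > `alpha` is
#' dropped, until every removable term is significant. Each eliminated term
#' is then reintroduced alone into the final model to report the F and
#' degrees of freedom it would have had, so the output lists every candidate
#' term exactly once -- retained terms with their partial F in the final
#' model (given the other retained terms), dropped terms with their
#' reintroduction F.
#'
#' @param table Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param terms Character vector of model terms; interactions as `"a:b"`.
#' @param alpha Retention threshold (default 0.05). `alpha = 1` keeps the
#'   full model; `alpha = 0` reduces to the intercept.
#' @return An object of class `term_elimination`: a list with `table` (tibble:
#'   `term`, `F`, `df1`, `df2`, `p_value`, `retained`, `step`), `final_model`
#'   (the reduced `lm`), `formula_final`, `response`, `alpha`. [tidy()]
#'   returns the term table, [glance()] a one-row model summary.
#' @export
glm_backward_reintroduce <- function(table, response, terms, alpha = 0.05) {
  stopifnot(response %in% names(table))
  table <- as.data.frame(table)
  fml <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = table)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased coefficients: ",
         paste(bad, collapse = ", "))
  }
  dropped <- character(0)
  step <- 0L
  repeat {
    labs <- attr(terms(fit), "term.labels")
    if (length(labs) == 0) break
    d1 <- suppressWarnings(drop1(fit, test = "F"))
    cand <- rownames(d1)[-1] # removable terms only (marginality respected)
    pv <- d1[["Pr(>F)"]][-1]
    worst <- which(pv > alpha)
    if (length(worst) == 0) break
    kill <- cand[which.max(pv)]
    step <- step + 1L
    dropped <- c(dropped, kill)
    fit <- update(fit, as.formula(paste(". ~ . -", kill)))
  }
  kept <- attr(terms(fit), "term.labels")
  rows <- list()
  for (tm in kept) {
    r <- partial_f(fit, tm)
    r$retained <- TRUE
    r$step <- NA_integer_
    rows[[tm]] <- r
  }
  for (i in seq_along(dropped)) {
    tm <- dropped[i]
    aug <- update(fit, as.formula(paste(". ~ . +", tm)))
    an <- anova(fit, aug)
    rows[[tm]] <- tibble::tibble(
      term = tm, F = an$F[2], df1 = an$Df[2], df2 = aug$df.residual,
      p_value = an[["Pr(>F)"]][2], retained = FALSE, step = i
    )
  }
  tab <- dplyr::bind_rows(rows[terms[terms %in% names(rows)]])
  structure(
    list(table = tab, final_model = fit,
         formula_final = stats::formula(fit),
         response = response, alpha = alpha),
    class = "term_elimination"
  )
}

#' @export
print.term_elimination <- function(x, ...) {
  cat(sprintf("<term_elimination> %s ~ ... (alpha = %g)\n", x$response, x$alpha))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @describeIn glm_backward_reintroduce The per-term F table as a tibble.
#' @param x,object A `term_elimination` object.
#' @param ... Unused.
#' @export
tidy.term_elimination <- function(x, ...) x$table

#' @describeIn glm_backward_reintroduce One-row summary of the final model.
#' @export
glance.term_elimination <- function(object, ...) {
  s <- summary(object$final_model)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = object$final_model$df.residual,
    n_retained = sum(object$table$retained),
    n_dropped = sum(!object$table$retained)
  )
}

#' Decorrelate predictors with varimax-rotated principal components
#'
#' Computes the principal components of the correlation matrix of the given
#' columns, retains all of them, and applies a varimax rotation so each
#' rotated axis loads mainly on few variables. The returned scores are
#' standardized rotated component scores and are mutually uncorrelated; the
#' returned loadings matrix (rotated eigenvector basis) is orthonormal.
#'
#' @param table Data frame of observations (more rows than columns).
#' @param columns Character vector of >= 2 numeric column names.
#' @return A list with `scores` (tibble of rotated component scores `RC1`,
#'   `RC2`, ...), `loadings` (orthonormal matrix, variables x components) and
#'   `rotation` (the varimax rotation matrix applied in component space).
#' @export
varimax_orthogonalize <- function(table, columns) {
  stopifnot(length(columns) >= 2, all(columns %in% names(table)))
  x <- as.matrix(table[, columns])
  if (nrow(x) <= length(columns)) stop("need more rows than columns")
  if (any(apply(x, 2, sd) == 0)) stop("constant column cannot be orthogonalized")
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  L <- pc$rotation %*% diag(pc$sdev, length(pc$sdev)) # correlation-scale loadings
  rot <- if (ncol(L) > 1) varimax(L)$rotmat else diag(1)
  load_rot <- pc$rotation %*% rot
  # standardized (whitened) component scores, rotated by the same orthogonal
  # matrix: stays exactly uncorrelated with unit variance
  scores <- z %*% pc$rotation %*% diag(1 / pc$sdev, length(pc$sdev)) %*% rot
  colnames(scores) <- paste0("RC", seq_len(ncol(scores)))
  rownames(load_rot) <- columns
  colnames(load_rot) <- colnames(scores)
  list(scores = tibble::as_tibble(scores), loadings = load_rot, rotation = rot)
}

#' Residual sexual dichromatism after male-line structural correction
#'
#' Tests whether a sex difference in a reflectance variable is explained by
#' nanostructure: the structural regression is fitted on male rows only, its
#' coefficients are used to compute residuals for *all* rows (both sexes),
#' and the residuals are compared between the sexes with a pooled two-sample
#' t-test. If nanostructure fully mediates the dichromatism, the female
#' residuals centre on the male line and the test is non-significant.
#'
#' @param table Cohort data frame with `sex` and the model columns.
#' @param response Name of the reflectance response column.
#' @param predictors Character vector of structural predictor columns.
#' @return A list with `test` (one-row tibble: t statistic, df, p, direction
#'   = sign of male - female mean residual), `mean_residuals` (per-sex
#'   tibble) and `residuals` (the input table with a `residual` column).
#' @export
male_residual_dichromatism <- function(table, response, predictors) {
  stopifnot("sex" %in% names(table), response %in% names(table),
            all(predictors %in% names(table)))
  males <- table[table$sex == "M", , drop = FALSE]
  if (nrow(males) < length(predictors) + 2) {
    stop("too few male rows to fit the structural regression")
  }
  fml <- as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  mfit <- lm(fml, data = as.data.frame(males))
  X <- model.matrix(fml, data = as.data.frame(table))
  pred <- as.numeric(X %*% coef(mfit))
  resid <- table[[response]] - pred
  rm_ <- resid[table$sex == "M"]
  rf_ <- resid[table$sex == "F"]
  tt <- pooled_t(rm_, rf_)
  out_tab <- tibble::as_tibble(table)
  out_tab$residual <- resid
  list(
    test = test_result("t", tt$t, tt$df, tt$p, direction = sign(tt$delta)),
    mean_residuals = tibble::tibble(sex = c("M", "F"),
                                    mean_residual = c(mean(rm_), mean(rf_)),
                                    n = c(length(rm_), length(rf_))),
    residuals = out_tab
  )
}

#' Compare estimated and measured hue within samples and between sexes
#'
#' Each sample contributes a measured hue (spectrometry) and an estimated hue
#' (predicted from the primary peak position). The two-level repeated-measures
#' structure is analysed through the per-sample difference
#' `estimated - measured`: the sex-by-data-type interaction is the pooled
#' two-sample t-test of the differences between sexes (exactly equivalent to
#' the repeated-measures interaction F on two levels, F = t^2), and the
#' within-sex effects are paired t-tests (one-sample t on the differences).
#'
#' @param table Cohort data frame with `sex`, a measured hue column and a
#'   predicted hue column.
#' @param measured,estimated Names of the measured and estimated hue columns
#'   (defaults `"hue"`, `"predicted_hue"`).
#' @return A list with `interaction` (one-row tibble: t, df, p and the
#'   equivalent F = t^2), `per_sex` (one row per sex: mean difference,
#'   paired t, df, p) and `differences` (per-sample tibble).
#' @export
paired_hue_comparison <- function(table, measured = "hue",
                                  estimated = "predicted_hue") {
  stopifnot("sex" %in% names(table), measured %in% names(table),
            estimated %in% names(table))
  if (any(!is.finite(table[[estimated]]))) {
    stop("missing or non-finite estimated hue values")
  }
  d <- table[[estimated]] - table[[measured]]
  dm <- d[table$sex == "M"]
  df_ <- d[table$sex == "F"]
  if (length(dm) < 2 || length(df_) < 2) stop("both sexes must be represented")
  inter <- pooled_t(dm, df_)
  per_sex <- dplyr::bind_rows(lapply(list(M = dm, F = df_), function(x) {
    if (sd(x) == 0) {
      tibble::tibble(mean_difference = mean(x),
                     t = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                     df = length(x) - 1,
                     p_value = if (mean(x) == 0) 1 else 0)
    } else {
      tt <- t.test(x)
      tibble::tibble(mean_difference = mean(x), t = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    }
  }), .id = "sex")
  list(
    interaction = tibble::tibble(
      statistic = "sex x type t", t = inter$t, F = inter$t^2,
      df = inter$df, p_value = inter$p
    ),
    per_sex = per_sex,
    differences = tibble::tibble(
      sample = if ("sample" %in% names(table)) table$sample
               else as.character(seq_len(nrow(table))),
      sex = table$sex, difference = d)
  )
}

#' Between-round repeatability of nanostructural parameters
#'
#' Quantifies how repeatable each fitted parameter is across two independent
#' measurement rounds (samples disassembled and re-mounted between rounds):
#' both rounds are sex-standardized, then each parameter is correlated
#' between rounds (Pearson r). A sex difference in repeatability is tested
#' as the sex-by-round-1-value interaction in a linear model for the round-2
#' value.
#'
#' @param round1,round2 Cohort data frames with `sample`, `sex` and the
#'   parameter columns; samples are matched by id.
#' @param parameters Character vector of parameter column names.
#' @return A tibble with one row per parameter: `parameter`, `r`, `n`,
#'   `p_value` (for r), `r_male`, `r_female`, `interaction_F`, `df1`, `df2`,
#'   `interaction_p`.
#' @export
repeatability <- function(round1, round2, parameters) {
  stopifnot(all(c("sample", "sex") %in% names(round1)),
            all(c("sample", "sex") %in% names(round2)),
            all(parameters %in% names(round1)),
            all(parameters %in% names(round2)))
  ids <- intersect(round1$sample, round2$sample)
  if (length(ids) == 0) stop("no overlapping sample ids between rounds")
  r1 <- sex_standardize(round1[match(ids, round1$sample), , drop = FALSE],
                        parameters)
  r2 <- sex_standardize(round2[match(ids, round2$sample), , drop = FALSE],
                        parameters)
  purrr::map_dfr(parameters, function(pm) {
    x <- r1[[paste0(pm, "_z")]]
    y <- r2[[paste0(pm, "_z")]]
    sex <- factor(r1$sex)
    ct <- stats::cor.test(x, y)
    dat <- data.frame(x = x, y = y, sex = sex)
    fit <- lm(y ~ x * sex, data = dat)
    an <- anova(fit)
    i <- which(rownames(an) == "x:sex")
    rsex <- vapply(c("M", "F"), function(s) {
      sel <- sex == s
      if (sum(sel) >= 3) stats::cor(x[sel], y[sel]) else NA_real_
    }, numeric(1))
    tibble::tibble(
      parameter = pm, r = unname(ct$estimate), n = length(ids),
      p_value = ct$p.value,
      r_male = rsex[["M"]], r_female = rsex[["F"]],
      interaction_F = an$F[i], df1 = an$Df[i],
      df2 = fit$df.residual, interaction_p = an[["Pr(>F)"]][i]
    )
  })
}
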