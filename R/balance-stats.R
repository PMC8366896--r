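#' Standardize a numeric vector to z-scores
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (n - 1 denominator).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(values) {
  check_numeric(values, "values")
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant (zero-variance) vector",
         call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Isometric-scaling test by ordinary least squares
#'
#' Fits \code{y ~ x} by OLS and tests the slope both against zero (the usual
#' regression t) and against one.  With both variables standardized, a slope
#' of one is the isometric expectation -- the two components scale in exact
#' proportion -- and the fitted slope equals the Pearson correlation, so
#' \code{r_squared == slope^2}.
#'
#' @param y,x Numeric vectors of equal length, n >= 3.
#' @param standardize Standardize both variables first (default TRUE, the
#'   scaling convention under which slope 1 means isometry).
#' @return Object of class \code{isometry_test} (also a list): \code{slope},
#'   \code{intercept}, \code{slope_se}, \code{t_vs_zero}, \code{t_vs_one},
#'   \code{p_two_sided} (slope vs zero), \code{p_vs_one}, \code{r_squared},
#'   \code{df}, \code{n}.
#' @export
isometry_test <- function(y, x, standardize = TRUE) {
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (standardize) {
    x <- standardize(x)
    y <- standardize(y)
  }
  fit <- ols_fit(y, x)
  perfect <- fit$sigma2 < 1e-24        # exact fit: se degenerates to 0
  t1 <- if (perfect && abs(fit$slope - 1) < 1e-12) 0 else
    (fit$slope - 1) / fit$se
  out <- list(
    slope = fit$slope, intercept = fit$intercept, slope_se = fit$se,
    t_vs_zero = fit$slope / fit$se,
    t_vs_one = t1,
    p_two_sided = 2 * pt(abs(fit$slope / fit$se), fit$df, lower.tail = FALSE),
    p_vs_one = 2 * pt(abs(t1), fit$df, lower.tail = FALSE),
    r_squared = fit$r_squared, df = fit$df, n = n)
  class(out) <- "isometry_test"
  out
}

#' @export
print.isometry_test <- function(x, ...) {
  cat(sprintf(
    "OLS scaling test (n = %d): slope = %.4f +/- %.4f, R2 = %.3f\n",
    x$n, x$slope, x$slope_se, x$r_squared))
  cat(sprintf("  slope vs 0: t = %.3f (p = %.3g);  slope vs 1: t = %.3f (p = %.3g)\n",
              x$t_vs_zero, x$p_two_sided, x$t_vs_one, x$p_vs_one))
  invisible(x)
}

#' Balance ratio versus fiber content, with optional diet-type interaction
#'
#' Models the protein:(TNC+lipids) balance ratio as a linear function of the
#' fiber percentage.  Without \code{diet_type} this is a simple OLS fit
#' (standardized by default, matching the reporting convention of the
#' pooled-sample analysis).  With \code{diet_type} a full-interaction linear
#' model \code{ratio ~ fiber * diet_type} is fitted on the raw scale by
#' default, giving a slope and intercept per type and t-tests of the
#' interaction contrasts against the reference level.  A quasi-binomial GLM
#' on the ratio rescaled into (0, 1) by its ceiling is available as a
#' robustness cross-check for the bounded proportional scale.
#'
#' @param ratio Balance ratios (see [balance_ratio()]).
#' @param fiber_pct Fiber axis values (\% of total macronutrients).
#' @param diet_type Optional factor of diet-type labels (>= 2 levels).
#' @param standardize Standardize ratio and fiber before fitting.  Default
#'   TRUE for the simple regression, FALSE when \code{diet_type} is given.
#' @param family \code{"gaussian"} for the linear model (default) or
#'   \code{"quasibinomial"} for the bounded-scale variant.
#' @param ratio_max Ceiling used to map ratios into (0, 1) for the
#'   quasi-binomial variant; defaults to 1.02 x the observed maximum.
#' @return For the simple fit, an \code{isometry_test}-style result (class
#'   \code{ratio_fiber_fit}).  With \code{diet_type}, a list of class
#'   \code{ratio_fiber_interaction}: \code{model} (the \code{lm}/\code{glm}
#'   object), \code{per_type} (slope and intercept per diet type),
#'   \code{interaction} (contrast table with t and p), \code{df_residual}.
#' @export
ratio_fiber_model <- function(ratio, fiber_pct, diet_type = NULL,
                              standardize = is.null(diet_type),
                              family = c("gaussian", "quasibinomial"),
                              ratio_max = NULL) {
  family <- match.arg(family)
  if (length(ratio) != length(fiber_pct)) stop("length mismatch", call. = FALSE)
  if (is.null(diet_type)) {
    if (family == "gaussian") {
      out <- isometry_test(ratio, fiber_pct, standardize = standardize)
      class(out) <- c("ratio_fiber_fit", class(out))
      return(out)
    }
    diet <- NULL
  }
  dat <- data.frame(ratio = ratio, fiber = fiber_pct)
  if (!is.null(diet_type)) {
    if (length(diet_type) != length(ratio)) stop("length mismatch", call. = FALSE)
    dat$diet_type <- factor(diet_type)
    if (nlevels(dat$diet_type) < 2) {
      stop("diet-type interaction needs at least 2 diet types", call. = FALSE)
    }
  }
  if (standardize) {
    dat$ratio <- standardize(dat$ratio)
    dat$fiber <- standardize(dat$fiber)
  }
  if (family == "quasibinomial") {
    if (is.null(ratio_max)) ratio_max <- 1.02 * max(ratio)
    dat$ratio01 <- ratio / ratio_max
    if (any(dat$ratio01 <= 0 | dat$ratio01 >= 1)) {
      stop("ratio_max must strictly bound the ratios", call. = FALSE)
    }
    form <- if (is.null(diet_type)) ratio01 ~ fiber else
      ratio01 ~ fiber * diet_type
    model <- glm(form, data = dat, family = quasibinomial("logit"))
  } else {
    model <- lm(ratio ~ fiber * diet_type, data = dat)
  }
  if (is.null(diet_type)) {                 # quasi-binomial simple fit
    s <- summary(model)$coefficients
    out <- list(model = model, slope = s["fiber", 1], slope_se = s["fiber", 2],
                t_vs_zero = s["fiber", 3], p_two_sided = s["fiber", 4],
                df = df.residual(model), n = nrow(dat), family = family)
    class(out) <- "ratio_fiber_fit"
    return(out)
  }
  s <- summary(model)$coefficients
  lv <- levels(dat$diet_type)
  ref <- lv[1]
  slopes <- setNames(numeric(length(lv)), lv)
  ints <- setNames(numeric(length(lv)), lv)
  for (l in lv) {
    slopes[l] <- s["fiber", 1] +
      if (l == ref) 0 else s[paste0("fiber:diet_type", l), 1]
    ints[l] <- s["(Intercept)", 1] +
      if (l == ref) 0 else s[paste0("diet_type", l), 1]
  }
  irows <- grep("^fiber:diet_type", rownames(s), value = TRUE)
  interaction <- data.frame(
    contrast = paste0(sub("^fiber:diet_type", "", irows), " vs ", ref),
    estimate = s[irows, 1], se = s[irows, 2],
    t = s[irows, 3], p = s[irows, 4], row.names = NULL)
  out <- list(model = model, per_type = data.frame(
    diet_type = lv, slope = unname(slopes), intercept = unname(ints)),
    interaction = interaction, df_residual = df.residual(model),
    family = family, reference = ref)
  class(out) <- "ratio_fiber_interaction"
  out
}

#' @export
print.ratio_fiber_interaction <- function(x, ...) {
  cat("Ratio ~ fiber with diet-type interaction (", x$family, ")\n", sep = "")
  print(x$per_type, row.names = FALSE)
  cat("Interaction contrasts vs", x$reference, "\n")
  print(x$interaction, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise Pearson correlations across the columns of a table, with
#' two-sided p-values from the t distribution on n - 2 degrees of freedom.
#' Constant columns give NA correlations and are reported in the
#' \code{flagged} element instead of propagating silently.
#'
#' @param table Data frame or matrix, samples in rows, constituents in
#'   columns (>= 3 rows).
#' @return Object of class \code{pearson_matrix}: list with \code{r}
#'   (correlations, unit diagonal), \code{p} (two-sided p-values, NA on the
#'   diagonal), \code{n}, \code{flagged} (names of constant columns).
#' @export
pearson_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table))
  if (!is.numeric(m)) stop("all columns must be numeric", call. = FALSE)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(m, 2, sd)
  flagged <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  r[flagged, ] <- NA; r[, flagged] <- NA
  diag(r) <- ifelse(colnames(m) %in% flagged, NA, 1)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0                 # exact colinearity
  diag(p) <- NA
  out <- list(r = r, p = p, n = n, flagged = flagged)
  class(out) <- "pearson_matrix"
  out
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (n =", x$n, ")\n")
  print(round(x$r, digits))
  if (length(x$flagged)) {
    cat("Constant columns flagged:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classical one-way analysis of variance followed by Tukey's honest
#' significant difference comparisons (studentized-range distribution,
#' family-wise alpha 0.05).
#'
#' @param values Numeric response vector.
#' @param groups Group labels; >= 2 groups with >= 2 members each.
#' @param conf_level Confidence level for the Tukey intervals.
#' @return Object of class \code{anova_tukey}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{group_means}, \code{tukey} (data
#'   frame: comparison, diff, lwr, upr, p_adj, significant).
#' @export
anova_tukey <- function(values, groups, conf_level = 0.95) {
  check_numeric(values, "values")
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  tab <- table(groups)
  if (nlevels(groups) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  fit <- aov(values ~ groups)
  at <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = conf_level)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 1 - conf_level,
                      row.names = NULL)
  out <- list(F = at$`F value`[1], df_between = at$Df[1],
              df_within = at$Df[2], p = at$`Pr(>F)`[1],
              group_means = tapply(values, groups, mean), tukey = tukey)
  class(out) <- "anova_tukey"
  out
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Subpopulation balance ratio versus mean calf body mass
#'
#' Regresses subpopulation mean calf body mass on the subpopulation mean
#' protein:(TNC+lipids) ratio by OLS (df = n - 2).  The default aggregation
#' is the mean of per-sample ratios within each subpopulation; the ratio of
#' subpopulation mean protein to mean TNC is available as a sensitivity
#' variant.
#'
#' @param samples Data frame with columns \code{mmu}, \code{ratio} and
#'   \code{calf_body_mass} (per-sample; only calf rows should carry body
#'   mass), or a pre-aggregated data frame with \code{mmu},
#'   \code{mean_ratio}, \code{mean_calf_bm}.
#' @param aggregate \code{"mean_ratio"} (default) or \code{"ratio_of_means"}.
#' @return \code{isometry_test}-style regression result (slope of body mass
#'   on ratio, unstandardized), plus the aggregated subpopulation table in
#'   \code{$subpops}.
#' @export
subpop_ratio_vs_bodymass <- function(samples,
                                     aggregate = c("mean_ratio",
                                                   "ratio_of_means")) {
  aggregate <- match.arg(aggregate)
  samples <- as.data.frame(samples)
  if (all(c("mean_ratio", "mean_calf_bm") %in% names(samples))) {
    sub <- samples
  } else {
    if (!all(c("mmu", "ratio", "calf_body_mass") %in% names(samples))) {
      stop("samples must have mmu, ratio, calf_body_mass columns",
           call. = FALSE)
    }
    mr <- if (aggregate == "mean_ratio") {
      tapply(samples$ratio, samples$mmu, mean)
    } else {
      if (!all(c("ap_total", "tnc_total") %in% names(samples))) {
        stop("ratio_of_means aggregation needs ap_total and tnc_total",
             call. = FALSE)
      }
      tapply(samples$ap_total, samples$mmu, mean) /
        tapply(samples$tnc_total, samples$mmu, mean)
    }
    bm <- tapply(samples$calf_body_mass, samples$mmu,
                 function(v) mean(v, na.rm = TRUE))
    sub <- data.frame(mmu = names(mr), mean_ratio = as.numeric(mr),
                      mean_calf_bm = as.numeric(bm))
  }
  sub <- sub[is.finite(sub$mean_ratio) & is.finite(sub$mean_calf_bm), ]
  if (nrow(sub) < 3) stop("need at least 3 subpopulations", call. = FALSE)
  fit <- ols_fit(sub$mean_calf_bm, sub$mean_ratio)
  out <- list(slope = fit$slope, intercept = fit$intercept,
              slope_se = fit$se, t_vs_zero = fit$slope / fit$se,
              p_two_sided = 2 * pt(abs(fit$slope / fit$se), fit$df,
                                   lower.tail = FALSE),
              r_squared = fit$r_squared, df = fit$df, n = nrow(sub),
              subpops = sub)
  class(out) <- "isometry_test"
  out
}

# Simple-OLS plumbing shared by the regression wrappers (delegates to lm).
ols_fit <- function(y, x) {
  if (sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  list(slope = co[2, 1], intercept = co[1, 1], se = co[2, 2],
       sigma2 = s$sigma^2, df = fit$df.residual,
       r_squared = s$r.squared)
}
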