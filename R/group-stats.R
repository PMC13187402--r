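# Group-level characterisation of substate metrics with linear mixed-effects
# models: emotion x condition x substate fixed effects, by-subject random
# intercept and condition slope, Satterthwaite Type III tests,
# Bonferroni-corrected contrasts, and Nakagawa R-squared.

#' Fit the substate mixed-effects model
#'
#' Fits `value ~ emotion * condition * substate + (1 + condition | subject)`
#' by REML with sum-to-zero contrasts, Satterthwaite denominator degrees of
#' freedom, and Type III F tests. Entropy responses are log-transformed
#' (`log1p`, robust to zero entropies) before fitting; speed is modelled on
#' its original scale. A singular or non-converging fit falls back down the
#' ladder random slope -> random intercept -> fixed effects only, with a
#' logged warning at each step.
#'
#' @param data Long-format data frame with columns `subject`, `emotion`,
#'   `condition`, `substate`, `value` (for entropy, `substate` may be a
#'   single level).
#' @param response `"speed"` (identity scale) or `"entropy"`
#'   (log1p-transformed).
#' @return An object of class `substate_lmm`: list with `model`, `anova`
#'   (Type III F table), `varcomp`, `r2` (marginal, conditional),
#'   `random_structure`, `response`.
#' @export
fit_substate_lmm <- function(data, response = c("speed", "entropy")) {
  response <- match.arg(response)
  data <- as.data.frame(data)
  need <- c("subject", "emotion", "condition", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, emotion, condition, value",
         call. = FALSE)
  if (length(unique(data$subject)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  data$subject <- factor(data$subject)
  for (v in c("emotion", "condition", "substate"))
    if (v %in% names(data)) data[[v]] <- factor(data[[v]])
  if (response == "entropy") data$value <- log1p(data$value)

  has_substate <- "substate" %in% names(data) &&
    nlevels(data$substate) > 1L
  fixed <- if (has_substate) "emotion * condition * substate"
  else "emotion * condition"

  # sum-to-zero contrasts so Type III tests are meaningful
  contr <- lapply(c("emotion", "condition",
                    if (has_substate) "substate"), function(v) "contr.sum")
  names(contr) <- c("emotion", "condition", if (has_substate) "substate")

  fit_one <- function(ranef_term) {
    fml <- stats::as.formula(paste("value ~", fixed,
                                   if (nzchar(ranef_term))
                                     paste("+", ranef_term) else ""))
    if (nzchar(ranef_term))
      lmerTest::lmer(fml, data = data, REML = TRUE, contrasts = contr)
    else stats::lm(fml, data = data, contrasts = contr)
  }

  ladder <- c("(1 + condition | subject)", "(1 | subject)", "")
  model <- NULL; used <- ""
  for (term in ladder) {
    m <- tryCatch(suppressMessages(fit_one(term)), error = function(e) NULL)
    if (is.null(m)) next
    if (nzchar(term) && lme4::isSingular(m, tol = 1e-5)) {
      warning(sprintf("singular fit with %s; simplifying random structure",
                      term))
      next
    }
    model <- m; used <- term
    break
  }
  if (is.null(model)) { model <- fit_one(""); used <- "" }

  is_mixed <- inherits(model, "lmerMod")
  anova_tab <- if (is_mixed) {
    as.data.frame(stats::anova(model, type = 3, ddf = "Satterthwaite"))
  } else {
    as.data.frame(car_type3_lm(model))
  }
  vc <- if (is_mixed) as.data.frame(lme4::VarCorr(model)) else NULL
  r2 <- r_squared(model)
  structure(list(model = model, anova = anova_tab, varcomp = vc, r2 = r2,
                 random_structure = if (nzchar(used)) used else "none",
                 response = response, data = data),
            class = "substate_lmm")
}

# Type III F tests for a plain lm fallback (drop each term from the full
# model under sum-to-zero contrasts)
car_type3_lm <- function(model) {
  a <- stats::drop1(model, scope = stats::terms(model), test = "F")
  a[-1, c("Df", "F value", "Pr(>F)"), drop = FALSE]
}

#' @export
print.substate_lmm <- function(x, ...) {
  cat(sprintf("Substate LMM (%s response), random structure: %s\n",
              x$response, x$random_structure))
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Bonferroni-corrected pairwise contrasts
#'
#' Estimated-marginal-means contrasts for a factor (`"emotion"`) or a
#' simple-effects slice of an interaction (`"emotion|substate"`), corrected
#' with Bonferroni within the family.
#'
#' @param fit A `substate_lmm`.
#' @param family Factor name, or `"factor|slicer"` for simple effects
#'   within each level of the slicing factor.
#' @param correction Multiplicity adjustment (default `"bonferroni"`).
#' @return Data frame of contrasts with estimates, SE, df, t and corrected p.
#' @export
pairwise_contrasts <- function(fit, family, correction = "bonferroni") {
  stopifnot(inherits(fit, "substate_lmm"))
  parts <- strsplit(family, "|", fixed = TRUE)[[1]]
  mf_vars <- all.vars(stats::formula(fit$model))
  if (!all(parts %in% mf_vars))
    stop(sprintf("unknown factor family '%s'", family), call. = FALSE)
  spec <- if (length(parts) == 2L)
    stats::as.formula(paste("~", parts[1], "|", parts[2]))
  else stats::as.formula(paste("~", parts[1]))
  emm <- suppressMessages(
    emmeans::emmeans(fit$model, spec, lmer.df = "satterthwaite",
                     data = fit$data))
  out <- suppressMessages(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = correction)))
  attr(out, "mesg") <- NULL
  out
}

#' Marginal and conditional R-squared
#'
#' Nakagawa-style variance partition for a mixed model: marginal R2 is the
#' fixed-effect variance over the total (fixed + random + residual);
#' conditional R2 adds the random-effect variance to the numerator. Random
#' slope contributions are evaluated as the mean per-observation variance
#' `z_i' Sigma z_i` of the random design. For a plain linear model both
#' equal the classical R2.
#'
#' @param model A fitted `lmerMod`/`lmerModLmerTest`, `substate_lmm`, or
#'   `lm`.
#' @return Named vector `c(marginal, conditional)`.
#' @export
r_squared <- function(model) {
  if (inherits(model, "substate_lmm")) model <- model$model
  if (inherits(model, "lm") && !inherits(model, "lmerMod")) {
    r2 <- summary(model)$r.squared
    return(c(marginal = r2, conditional = r2))
  }
  stopifnot(inherits(model, "lmerMod"))
  var_f <- stats::var(stats::predict(model, re.form = NA))
  Zt <- lme4::getME(model, "Zt")
  vc <- lme4::VarCorr(model)
  # block-diagonal covariance of the stacked random effects, in Zt's order
  blocks <- list()
  flist <- lme4::getME(model, "flist")
  cnms <- lme4::getME(model, "cnms")
  for (g in seq_along(cnms)) {
    fac <- flist[[names(cnms)[g]]]
    Sg <- as.matrix(vc[[g]])
    blocks <- c(blocks, rep(list(Sg), nlevels(fac)))
  }
  Sigma <- Matrix::bdiag(blocks)
  var_r <- mean(Matrix::colSums((Sigma %*% Zt) * Zt))
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
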