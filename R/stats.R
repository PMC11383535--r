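#' Specify a crossed random-intercept mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed categorical factors; with
#'   `interactions = TRUE` the full factorial is fitted.
#' @param random character vector of grouping factors, each contributing a
#'   random intercept (at least one).
#' @param interactions `TRUE` for the full factorial, `FALSE` for main
#'   effects only, or a character vector of extra interaction terms (e.g.
#'   `"phase:memory"`).
#' @export
mixed_spec <- function(response, fixed, random, interactions = TRUE) {
  if (length(random) < 1) stop("need >= 1 random intercept")
  structure(list(response = response, fixed = fixed, random = random,
                 interactions = interactions),
            class = "mixed_spec")
}

.spec_formula <- function(spec) {
  fx <- if (isTRUE(spec$interactions)) paste(spec$fixed, collapse = " * ")
  else if (identical(spec$interactions, FALSE)) paste(spec$fixed, collapse = " + ")
  else paste(c(spec$fixed, spec$interactions), collapse = " + ")
  rd <- paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", fx, "+", rd))
}

#' Fit a crossed random-intercept mixed model by REML
#'
#' Fixed factors are converted to factors with sum-to-zero contrasts (the
#' convention under which Type III sums of squares are meaningful) and the
#' model is fitted by restricted maximum likelihood. Convergence is
#' reported honestly in the `converged` flag; non-converged fits are meant
#' to be excluded downstream with a log entry, never silently refitted.
#'
#' @param data data frame holding the response, fixed factors and grouping
#'   factors named in `spec`.
#' @param spec a [mixed_spec()].
#' @return An `lmm_result`: list with `fit` (a `lmerModLmerTest`),
#'   `converged`, `singular`, and `spec`.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "mixed_spec"))
  miss <- setdiff(c(spec$response, spec$fixed, spec$random), names(data))
  if (length(miss)) stop("columns missing from data: ", paste(miss, collapse = ", "))
  if (!all(is.finite(data[[spec$response]]))) stop("response must be finite")
  for (f in spec$fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("fixed factor '", f, "' has fewer than 2 levels")
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  for (g in spec$random) data[[g]] <- factor(data[[g]])
  fit <- NULL
  msgs <- character(0)
  withCallingHandlers(
    fit <- lmerTest::lmer(.spec_formula(spec), data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  # a boundary (singular) fit is convergence at the edge of the parameter
  # space, not an optimizer failure; only genuine failures are flagged
  all_msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  fail_pat <- "failed to converge|convergence code|unable to evaluate|pwrssUpdate"
  conv_fail <- any(grepl(fail_pat, all_msgs, ignore.case = TRUE))
  structure(list(fit = fit, converged = !conv_fail,
                 singular = lme4::isSingular(fit), spec = spec,
                 data = data),
            class = "lmm_result")
}

#' Type III F tests with Satterthwaite denominator df
#'
#' One F test per fixed term (main effects and interactions) on Type III
#' sums of squares under sum-to-zero coding, with denominator degrees of
#' freedom from Satterthwaite's method.
#'
#' @param result a converged [fit_lmm()] result.
#' @return data frame with `effect`, `sum_sq`, `df_num`, `df_den`, `F`, `p`.
#' @export
type3_anova <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  if (!result$converged)
    stop("model did not converge; exclude it rather than testing it")
  a <- stats::anova(result$fit, type = 3, ddf = "Satterthwaite")
  data.frame(effect = rownames(a), sum_sq = a[["Sum Sq"]],
             df_num = a[["NumDF"]], df_den = a[["DenDF"]],
             F = a[["F value"]], p = a[["Pr(>F)"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: monotone in the p-value ranks and capped at 1.
#' The multiple-testing family is whatever vector is passed in - for the
#' ROI-wise analyses that is all ROIs by all fixed-effect terms.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Post hoc marginal-mean contrasts within each phase
#'
#' Least-squares (marginal) mean differences of a factor within each level
#' of another, with Satterthwaite degrees of freedom - the standard follow
#' up on a significant interaction. The contrast is second level minus
#' first (with default level ordering, `remembered - forgotten`).
#'
#' @param result a converged [fit_lmm()] result whose model contains the
#'   `factor:by` interaction.
#' @param factor factor to contrast (default `"memory"`).
#' @param by conditioning factor (default `"phase"`).
#' @return data frame with columns `<by>`, `contrast`, `estimate`, `se`,
#'   `df`, `t`, `p`.
#' @export
posthoc_means <- function(result, factor = "memory", by = "phase") {
  stopifnot(inherits(result, "lmm_result"))
  if (!result$converged) stop("model did not converge")
  trm <- attr(stats::terms(result$fit), "term.labels")
  has_int <- any(vapply(strsplit(trm, ":"), function(s)
    all(c(factor, by) %in% s), logical(1)))
  if (!has_int)
    stop("model has no '", factor, ":", by, "' interaction term")
  emm <- suppressMessages(
    emmeans::emmeans(result$fit, stats::as.formula(paste0("~", factor, "|", by)),
                     lmer.df = "satterthwaite", data = result$data))
  grid <- as.data.frame(emm)
  if (anyNA(grid$emmean))
    stop("empty cell in the ", factor, " x ", by, " grid")
  cc <- as.data.frame(emmeans::contrast(emm, method = "revpairwise", by = by))
  out <- data.frame(cc[[by]], contrast = as.character(cc$contrast),
                    estimate = cc$estimate, se = cc$SE, df = cc$df,
                    t = cc$t.ratio, p = cc$p.value, stringsAsFactors = FALSE)
  names(out)[1] <- by
  out
}

#' Sort a region's interaction into a qualitative pattern
#'
#' Given the two phase-wise remembered-forgotten contrasts of one ROI,
#' assigns `"retrieval_success"` (success effect at retrieval only),
#' `"encoding_retrieval_flip"` (success at retrieval plus a reversed,
#' negative encoding contrast), or `"none"`. Either pattern requires a
#' positive, significant retrieval contrast. The encoding-side rule is
#' configurable because the boundary between "no encoding effect" and "a
#' reversed encoding effect" is a matter of judgment: by default any
#' negative encoding estimate counts toward a flip
#' (`flip_rule = "negative_estimate"`); with
#' `flip_rule = "significant_negative"` the encoding contrast must itself be
#' significantly negative at `enc_alpha`.
#'
#' @param contrasts data frame as returned by [posthoc_means()] with one
#'   `"encoding"` and one `"retrieval"` row.
#' @param alpha significance level for the retrieval gate.
#' @param flip_rule `"negative_estimate"` or `"significant_negative"`.
#' @param enc_alpha level for the encoding contrast under
#'   `"significant_negative"`.
#' @return one of `"retrieval_success"`, `"encoding_retrieval_flip"`,
#'   `"none"`.
#' @export
classify_flip_pattern <- function(contrasts, alpha = 0.05,
                                  flip_rule = c("negative_estimate",
                                                "significant_negative"),
                                  enc_alpha = 0.05) {
  flip_rule <- match.arg(flip_rule)
  enc <- contrasts[contrasts$phase == "encoding", ]
  ret <- contrasts[contrasts$phase == "retrieval", ]
  if (nrow(enc) != 1 || nrow(ret) != 1)
    stop("need exactly one encoding and one retrieval contrast")
  if (!(ret$t > 0 && ret$p < alpha)) return("none")
  flip <- switch(flip_rule,
                 negative_estimate = enc$estimate < 0,
                 significant_negative = enc$estimate < 0 && enc$p < enc_alpha)
  if (flip) "encoding_retrieval_flip" else "retrieval_success"
}

#' Phase-by-area model over remembered trials
#'
#' Tests whether the encoding-versus-retrieval difference in
#' representational strength differs between occipito-temporal (OTC) and
#' inferior-parietal (IPC) regions, using remembered trials only, with
#' random intercepts for feature type, participant, stimulus and ROI.
#' Treating the 2-level feature-type factor as a random grouping is
#' unusual; `feature_type_random = FALSE` instead includes it as an
#' additive fixed effect.
#'
#' @param iraf IRAF table (only rows with `memory == "remembered"` are
#'   used).
#' @param area_map named character vector mapping `roi_id` to `"IPC"` or
#'   `"OTC"`.
#' @param feature_type_random include feature type as a random intercept
#'   (default) or as a fixed effect.
#' @return list with `result` (the [fit_lmm()] fit), `anova`
#'   (Type III tests), and `posthoc` (phase contrast within each area).
#' @export
fit_area_model <- function(iraf, area_map, feature_type_random = TRUE) {
  d <- iraf[iraf$memory == "remembered" & iraf$roi_id %in% names(area_map), ]
  d$area <- unname(area_map[d$roi_id])
  if (length(unique(d$area)) < 2) stop("both areas must be represented")
  per_area <- tapply(d$roi_id, d$area, function(x) length(unique(x)))
  if (any(per_area < 2))
    warning("area(s) with a single ROI: ROI intercept weakly identified")
  rand <- c("participant", "item", "roi_id",
            if (feature_type_random) "feature_type")
  spec <- mixed_spec("iraf",
                     fixed = c("phase", "area"),
                     random = rand, interactions = TRUE)
  if (!feature_type_random) {
    spec$interactions <- "phase:area"
    spec$fixed <- c("phase", "area", "feature_type")
  }
  res <- fit_lmm(d, spec)
  emm <- suppressMessages(
    emmeans::emmeans(res$fit, ~ phase | area, lmer.df = "satterthwaite",
                     data = res$data))
  cc <- as.data.frame(emmeans::contrast(emm, method = "pairwise", by = "area"))
  posthoc <- data.frame(area = cc$area, contrast = as.character(cc$contrast),
                        estimate = cc$estimate, se = cc$SE, df = cc$df,
                        t = cc$t.ratio, p = cc$p.value, stringsAsFactors = FALSE)
  list(result = res, anova = type3_anova(res), posthoc = posthoc)
}

#' Simulation-based power analysis for the mixed-model design
#'
#' Simulates the study's crossed design - participants by items by phases by
#' feature types with participant and item random intercepts - plants a
#' fixed binary-condition effect of `d` residual standard deviations, fits
#' the mixed model, and tests the condition effect (Satterthwaite t test)
#' at `alpha`. Power is the rejection proportion over `reps` replicates.
#'
#' @param d standardized effect size (difference between condition levels
#'   in residual-SD units).
#' @param alpha significance level.
#' @param n_participants,n_items,n_phases,n_types design dimensions; the
#'   condition factor is the memory phase, so `n_phases` must be 2.
#' @param reps number of simulation replicates (>= 1).
#' @param seed integer seed.
#' @param sd_participant,sd_item random-intercept SDs in residual-SD units.
#' @return A `power_estimate`: list with `power`, `reps`, `mc_se`
#'   (`sqrt(power (1 - power) / reps)`), `effect_size_d`, `alpha`.
#' @export
power_sim <- function(d, alpha = 0.05, n_participants = 19, n_items = 300,
                      n_phases = 2, n_types = 2, reps = 50, seed = 1,
                      sd_participant = 0.1, sd_item = 0.1) {
  if (reps < 1) stop("`reps` must be >= 1")
  if (n_phases != 2)
    stop("infeasible design: the binary condition factor needs 2 phases")
  if (n_participants < 2 || n_items < 2 || n_types < 1)
    stop("infeasible design: every factor needs >= 2 levels (>= 1 type)")
  set.seed(as.integer(seed))
  grid <- expand.grid(participant = factor(seq_len(n_participants)),
                      item = factor(seq_len(n_items)),
                      phase = factor(seq_len(n_phases)),
                      type = factor(seq_len(n_types)))
  cond <- as.numeric(grid$phase == levels(grid$phase)[2])
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    u <- stats::rnorm(n_participants, 0, sd_participant)
    v <- stats::rnorm(n_items, 0, sd_item)
    grid$y <- d * cond + u[grid$participant] + v[grid$item] +
      stats::rnorm(nrow(grid))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ phase + (1 | participant) + (1 | item), data = grid,
                     REML = TRUE)))
    p <- stats::coef(summary(fit))["phase2", "Pr(>|t|)"]
    reject[r] <- is.finite(p) && p < alpha
  }
  power <- mean(reject)
  structure(list(power = power, reps = as.integer(reps),
                 mc_se = sqrt(power * (1 - power) / reps),
                 effect_size_d = d, alpha = alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> d = %.2f, alpha = %.3f: power %.3f (MC SE %.3f, %d reps)\n",
              x$effect_size_d, x$alpha, x$power, x$mc_se, x$reps))
  invisible(x)
}
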