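#' Long-format table of local metrics for a cohort
#'
#' Thresholds every connectome at `tau` and computes the four local metrics
#' in both binary and weighted variants for every node, yielding one row
#' per (subject, session, node, metric, variant). This is the input to the
#' per-node mixed-effects comparison.
#'
#' @param cohort List of subject records.
#' @param tau Proportional threshold.
#' @return Data frame with columns `subject_id`, `group`, `session`,
#'   `node`, `metric`, `weighted`, `value`.
#' @export
build_metric_table <- function(cohort, tau = 0.35) {
  if (length(cohort) == 0L) stop("cohort is empty")
  out <- vector("list", length(cohort) * 2L)
  pos <- 0L
  for (rec in cohort) {
    G <- threshold_graph(rec$matrix, tau)
    labels <- rec$matrix$node_labels
    for (wflag in c(FALSE, TRUE)) {
      mets <- all_local_metrics(G, weighted = wflag)
      pos <- pos + 1L
      out[[pos]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group,
        session = rec$session,
        node = rep(labels, times = 4L),
        metric = rep(c("degree", "betweenness", "clustering", "efficiency"),
                     each = length(labels)),
        weighted = wflag,
        value = c(as.numeric(mets$D), as.numeric(mets$BC),
                  as.numeric(mets$CC), as.numeric(mets$E)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-node linear mixed-effects model
#'
#' Fits the longitudinal group-comparison model for one (node, metric,
#' variant) slice: `value ~ group + session + (1 | subject_id)`, i.e. fixed
#' effects for clinical phenotype and scan session plus a random intercept
#' per subject. Phenotype uses treatment coding with a configurable
#' reference group. Fixed effects are tested with the Satterthwaite
#' denominator-degrees-of-freedom approximation (`ddf = "satterthwaite"`,
#' the default) or asymptotic Wald/likelihood-ratio tests (`ddf = "wald"`).
#' Degenerate slices where the mixed model cannot be estimated (e.g. zero
#' residual variance) fall back to a fixed-effects-only linear model and
#' are flagged as not converged.
#'
#' @param data Data frame with columns `subject_id`, `group`, `session`,
#'   `value` (one slice of [build_metric_table()]).
#' @param reference Reference phenotype level (default: first level).
#' @param ddf Degrees-of-freedom method, `"satterthwaite"` or `"wald"`.
#' @return An `lmm_fit`: fixed-effect estimates, omnibus phenotype and
#'   session p-values, variance components, convergence flag, and the
#'   underlying fit object for post-hoc contrasts.
#' @export
fit_node_lmm <- function(data, reference = NULL, ddf = "satterthwaite") {
  stopifnot(all(c("subject_id", "group", "session", "value") %in% names(data)))
  ddf <- match.arg(ddf, c("satterthwaite", "wald"))
  if (length(unique(data$group)) < 2L) stop("need at least 2 groups")
  data$group <- factor(data$group)
  if (!is.null(reference)) data$group <- stats::relevel(data$group, ref = reference)
  data$subject_id <- factor(data$subject_id)

  # convergence diagnostics are surfaced through the `converged` flag
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(value ~ group + session + (1 | subject_id),
                     data = data,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore")))),
    error = function(e) NULL)

  if (!is.null(fit)) {
    est <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    subj_var <- vc$vcov[vc$grp == "subject_id"][1L]
    resid_var <- vc$vcov[vc$grp == "Residual"][1L]
    an <- tryCatch(
      if (ddf == "satterthwaite") stats::anova(fit, type = 3)
      else NULL,
      error = function(e) NULL)
    if (!is.null(an) && "Pr(>F)" %in% names(an)) {
      p_group <- an["group", "Pr(>F)"]
      p_session <- an["session", "Pr(>F)"]
    } else {
      # Wald chi-square tests on the fixed effects
      p_group <- wald_term_p(fit, grep("^group", names(est)))
      p_session <- wald_term_p(fit, which(names(est) == "session"))
    }
    converged <- length(fit@optinfo$conv$lme4$messages) == 0L
    structure(list(estimates = est, p_group = p_group, p_session = p_session,
                   subject_var = subj_var, resid_var = resid_var,
                   converged = converged, model = fit, ddf = ddf,
                   groups = levels(data$group)),
              class = "lmm_fit")
  } else {
    # degenerate slice: fixed-effects-only fallback
    fit_lm <- stats::lm(value ~ group + session, data = data)
    est <- stats::coef(fit_lm)
    an <- tryCatch(stats::anova(fit_lm), error = function(e) NULL)
    p_group <- if (!is.null(an)) an["group", "Pr(>F)"] else NA_real_
    p_session <- if (!is.null(an)) an["session", "Pr(>F)"] else NA_real_
    structure(list(estimates = est, p_group = p_group, p_session = p_session,
                   subject_var = 0, resid_var = stats::sigma(fit_lm)^2,
                   converged = FALSE, model = fit_lm, ddf = ddf,
                   groups = levels(data$group)),
              class = "lmm_fit")
  }
}

wald_term_p <- function(fit, idx) {
  if (length(idx) == 0L) return(NA_real_)
  b <- lme4::fixef(fit)[idx]
  V <- as.matrix(stats::vcov(fit))[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit: %d groups, phenotype p = %.4g, session p = %.4g, %s>\n",
              length(x$groups), x$p_group, x$p_session,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Post-hoc pairwise group contrasts
#'
#' All pairwise contrasts of estimated marginal group means with Tukey
#' multiplicity adjustment, following the gating rule that contrasts are
#' only extracted when the omnibus phenotype effect is significant (set
#' `gate = FALSE` to always compute them).
#'
#' @param fit An `lmm_fit` from [fit_node_lmm()].
#' @param alpha Gate significance level (default 0.05).
#' @param gate Only run contrasts when the omnibus phenotype p-value is
#'   below `alpha`.
#' @param adjust Multiplicity adjustment passed to emmeans
#'   (default `"tukey"`).
#' @return Data frame with columns `contrast`, `estimate`, `se`,
#'   `p_adjusted`; zero rows when gated out.
#' @export
posthoc_contrasts <- function(fit, alpha = 0.05, gate = TRUE,
                              adjust = "tukey") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (length(fit$groups) < 2L) stop("contrasts require at least two groups")
  empty <- data.frame(contrast = character(0), estimate = numeric(0),
                      se = numeric(0), p_adjusted = numeric(0))
  if (gate && (is.na(fit$p_group) || fit$p_group >= alpha)) return(empty)
  emm <- emmeans::emmeans(fit$model, "group")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  data.frame(contrast = as.character(prs$contrast),
             estimate = prs$estimate, se = prs$SE,
             p_adjusted = prs$p.value, stringsAsFactors = FALSE)
}

#' Node-level group comparison across a whole metric table
#'
#' Convenience wrapper applying [fit_node_lmm()] and [posthoc_contrasts()]
#' to every (node, metric, variant) slice of a metric table.
#'
#' @param table Output of [build_metric_table()].
#' @param reference Reference phenotype level.
#' @param alpha Gate level for post-hoc contrasts.
#' @param ddf Degrees-of-freedom method (see [fit_node_lmm()]).
#' @return Data frame with one row per slice and contrast: `node`,
#'   `metric`, `weighted`, `p_group`, `contrast`, `estimate`, `p_adjusted`.
#' @export
compare_groups <- function(table, reference = NULL, alpha = 0.05,
                           ddf = "satterthwaite") {
  slices <- split(table, list(table$node, table$metric, table$weighted),
                  drop = TRUE)
  out <- lapply(slices, function(sl) {
    fit <- fit_node_lmm(sl, reference = reference, ddf = ddf)
    ph <- posthoc_contrasts(fit, alpha = alpha)
    if (nrow(ph) == 0L)
      ph <- data.frame(contrast = NA_character_, estimate = NA_real_,
                       se = NA_real_, p_adjusted = NA_real_)
    data.frame(node = sl$node[1L], metric = sl$metric[1L],
               weighted = sl$weighted[1L], p_group = fit$p_group,
               ph, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
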