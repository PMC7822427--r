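#' Observed and independent effect sizes for combined-stress analysis
#'
#' Effect sizes are dimensionless absolute relative deviations from the
#' control mean. `observed_effect_size()` scores each combined-treatment
#' plant: |ob - control_mean| / control_mean. `independent_effect_size()`
#' scores a single-stress treatment mean the same way.
#'
#' @param ob Per-plant measured trait value(s) under the combined treatment.
#' @param stress_mean Single-stress treatment mean.
#' @param control_mean Control treatment mean (non-zero).
#' @return Non-negative numeric vector of effect sizes.
#' @examples
#' observed_effect_size(500, 336)       # 0.488...
#' independent_effect_size(531, 336)    # 0.580...
#' @export
observed_effect_size <- function(ob, control_mean) {
  .check_control_mean(control_mean)
  abs(ob - control_mean) / abs(control_mean)
}

#' @rdname observed_effect_size
#' @export
independent_effect_size <- function(stress_mean, control_mean) {
  .check_control_mean(control_mean)
  abs(stress_mean - control_mean) / abs(control_mean)
}

.check_control_mean <- function(control_mean) {
  if (!is.numeric(control_mean) || any(!is.finite(control_mean)) ||
      any(control_mean == 0)) {
    stop("control mean must be finite and non-zero", call. = FALSE)
  }
  invisible(control_mean)
}

#' Expected additive effect under the multiplicative risk model
#'
#' Combines two independent single-stressor effect sizes into the additive
#' expectation `a + b - a*b`. Compared with plain addition this removes the
#' over-inflated response of summing overlapping effects; for effects in
#' \[0, 1\] it is bounded by both `max(a, b)` and `a + b`.
#'
#' @param ind_a,ind_b Non-negative independent effect sizes.
#' @return Expected additive effect size(s).
#' @examples
#' expected_additive(0.5804, 0.1786)  # 0.6553...
#' @export
expected_additive <- function(ind_a, ind_b) {
  if (any(ind_a < 0) || any(ind_b < 0)) {
    stop("effect sizes must be non-negative", call. = FALSE)
  }
  ind_a + ind_b - ind_a * ind_b
}

#' Classify a combined-stress response as synergistic, additive or antagonistic
#'
#' Forms the per-plant differences between observed effect sizes and the
#' expected additive effect, then a two-sided 95\% confidence interval on
#' their mean (Student-t by default, percentile bootstrap optionally).
#' Synergistic when the whole interval lies above zero, antagonistic when it
#' lies below, additive when it crosses zero.
#'
#' @param ob_values Observed effect sizes, one per combined-treatment plant
#'   (>= 2).
#' @param ex Scalar expected additive effect size.
#' @param alpha Two-sided interval level is `1 - alpha` (default 0.05).
#' @param method `"t"` (default) or `"bootstrap"` (percentile).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (required when `method = "bootstrap"`).
#' @return List of class `"interaction_result"`: `mean_diff`, `ci_low`,
#'   `ci_high`, `label`, `n`, `method`.
#' @examples
#' classify_interaction(c(0.30, 0.35, 0.31, 0.36), ex = 0)  # synergistic
#' @export
classify_interaction <- function(ob_values, ex, alpha = 0.05,
                                 method = c("t", "bootstrap"),
                                 n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  if (length(ob_values) < 2L) {
    stop("need >= 2 observations to form a confidence interval",
         call. = FALSE)
  }
  stopifnot(is.numeric(ex), length(ex) == 1L, is.finite(ex))
  diffs <- ob_values - ex
  m <- mean(diffs)
  if (method == "t") {
    se <- stats::sd(diffs) / sqrt(length(diffs))
    tq <- stats::qt(1 - alpha / 2, df = length(diffs) - 1L)
    ci <- c(m - tq * se, m + tq * se)
  } else {
    if (is.null(seed)) stop("bootstrap method needs a seed", call. = FALSE)
    set.seed(seed)
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(diffs, replace = TRUE)), numeric(1))
    ci <- unname(stats::quantile(bm, c(alpha / 2, 1 - alpha / 2)))
  }
  label <- if (ci[1L] > 0) "synergistic"
           else if (ci[2L] < 0) "antagonistic"
           else "additive"
  structure(list(mean_diff = m, ci_low = ci[1L], ci_high = ci[2L],
                 label = label, n = length(diffs), method = method),
            class = "interaction_result")
}

#' Deterministic effect-size table from treatment means
#'
#' Computes, per root type x trait, the mean-level observed effect size of
#' the combined treatment, the two independent single-stress effect sizes,
#' the multiplicative-risk additive expectation and their difference --
#' the deterministic skeleton of the interaction classification, usable
#' directly on published cell means.
#'
#' @param summary Treatment summary table (`root_type`, `trait`, `treatment`,
#'   `mean`), e.g. [builtin_table_fixtures()] or [summarize_treatments()].
#' @return Data.frame per trait: `ob_mean`, `ind_drought`, `ind_heat`, `ex`,
#'   `diff` (= ob_mean - ex), `direction` of the raw combined-vs-control
#'   change ("increase"/"decrease").
#' @export
effect_size_table <- function(summary) {
  stopifnot(all(c("root_type", "trait", "treatment", "mean") %in%
                  names(summary)))
  need <- c("Control", "Drought", "Heat", "Combined")
  if (!all(need %in% summary$treatment)) {
    stop("summary must contain Control, Drought, Heat and Combined",
         call. = FALSE)
  }
  combos <- unique(summary[c("root_type", "trait")])
  get_mean <- function(rt, tr, t) {
    v <- summary$mean[summary$root_type == rt & summary$trait == tr &
                        summary$treatment == t]
    if (length(v) != 1L) NA_real_ else v
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rt <- combos$root_type[i]; tr <- combos$trait[i]
    con <- get_mean(rt, tr, "Control")
    if (!is.finite(con) || con == 0) return(NULL)
    dro <- get_mean(rt, tr, "Drought"); hea <- get_mean(rt, tr, "Heat")
    com <- get_mean(rt, tr, "Combined")
    if (anyNA(c(dro, hea, com))) return(NULL)
    ind_d <- independent_effect_size(dro, con)
    ind_h <- independent_effect_size(hea, con)
    ex <- expected_additive(ind_d, ind_h)
    ob <- observed_effect_size(com, con)
    data.frame(root_type = rt, trait = tr, ob_mean = ob,
               ind_drought = ind_d, ind_heat = ind_h, ex = ex,
               diff = ob - ex,
               direction = if (com >= con) "increase" else "decrease",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interaction screen over a plant dataset
#'
#' For each root type x trait (optionally restricted to traits whose
#' combined-treatment Tukey letter differs from Control's -- the published
#' workflow of classifying only traits significantly modified by the
#' combined stress), computes per-plant observed effect sizes for the
#' combined treatment, the expectation from the two single-stress means, and
#' the confidence-interval classification.
#'
#' @param dataset Tidy `plant_dataset` containing all four treatments.
#' @param traits Optional trait subset.
#' @param alpha Significance level for both eligibility screen and CI.
#' @param eligibility `"combined_vs_control"` (default; keep traits whose
#'   Combined letter set is disjoint from Control's) or `"all"`.
#' @param method,seed Passed to [classify_interaction()].
#' @return Data.frame per classified trait: `root_type`, `trait`,
#'   `ind_drought`, `ind_heat`, `ex`, `ob_mean`, `mean_diff`, `ci_low`,
#'   `ci_high`, `label`, `direction`.
#' @export
interaction_screen <- function(dataset, traits = NULL, alpha = 0.05,
                               eligibility = c("combined_vs_control", "all"),
                               method = c("t", "bootstrap"), seed = NULL) {
  .check_dataset(dataset)
  eligibility <- match.arg(eligibility)
  method <- match.arg(method)
  need <- c("Control", "Drought", "Heat", "Combined")
  miss <- setdiff(need, unique(dataset$treatment))
  if (length(miss)) {
    stop("dataset lacks treatment(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- dataset
  if (!is.null(traits)) d <- d[d$trait %in% traits, ]
  combos <- unique(d[c("root_type", "trait")])
  if (eligibility == "combined_vs_control") {
    scr <- trait_screen(d, alpha = alpha, letters = TRUE)
    elig <- scr$cells[scr$cells$treatment == "Combined" &
                        scr$cells$differs_from_control %in% TRUE,
                      c("root_type", "trait")]
    combos <- merge(combos, elig)
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rt <- combos$root_type[i]; tr <- combos$trait[i]
    di <- d[d$root_type == rt & d$trait == tr, ]
    con <- di$value[di$treatment == "Control"]
    com <- di$value[di$treatment == "Combined"]
    dro <- di$value[di$treatment == "Drought"]
    hea <- di$value[di$treatment == "Heat"]
    if (length(com) < 2L || !length(con) || mean(con) == 0) return(NULL)
    ind_d <- independent_effect_size(mean(dro), mean(con))
    ind_h <- independent_effect_size(mean(hea), mean(con))
    ex <- expected_additive(ind_d, ind_h)
    ob <- observed_effect_size(com, mean(con))
    cls <- classify_interaction(ob, ex, alpha = alpha, method = method,
                                seed = seed)
    data.frame(root_type = rt, trait = tr, ind_drought = ind_d,
               ind_heat = ind_h, ex = ex, ob_mean = mean(ob),
               mean_diff = cls$mean_diff, ci_low = cls$ci_low,
               ci_high = cls$ci_high, label = cls$label,
               direction = if (mean(com) >= mean(con)) "increase"
                           else "decrease",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
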