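#' Log-transform repeated-measures responses
#'
#' Percentages of fibrosis/adipose tissue are right-skewed with
#' variance increasing in the mean; the natural-log transform
#' `ln(response + offset)` reduces both. The offset admits exact zeros
#' (default 0.5 percentage points).
#'
#' @param table Tibble with a `response` column (nonnegative).
#' @param offset Added before the log; must be > 0 if zeros occur.
#' @return The table with `response` replaced by its log.
#' @export
log_transform <- function(table, offset = 0.5) {
  if (any(table$response < 0, na.rm = TRUE)) {
    fq_validation_error("responses must be >= 0")
  }
  dplyr::mutate(table, response = log(.data$response + offset))
}

check_rm_table <- function(table) {
  req <- c("subject", "condition", "region", "response")
  if (!all(req %in% names(table))) {
    fq_validation_error("RM table needs columns: %s", paste(req, collapse = ", "))
  }
  tab <- table(table$subject, table$region)
  if (any(tab != 1)) {
    fq_validation_error(
      "unbalanced RM table: every subject must have every region exactly once")
  }
  subj_cond <- dplyr::distinct(table, .data$subject, .data$condition)
  if (anyDuplicated(subj_cond$subject)) {
    fq_validation_error("a subject appears under more than one condition")
  }
  n_by_cond <- table(subj_cond$condition)
  if (any(n_by_cond < 2)) {
    fq_validation_error("need >= 2 subjects per condition for variance estimation")
  }
  if (length(unique(n_by_cond)) != 1L) {
    fq_validation_error("unbalanced design: unequal subjects per condition")
  }
  invisible(table)
}

# orthonormal within-subject contrasts (k-1 x k), for the GG epsilon
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k) # k x (k-1), orthogonal columns
  t(sweep(H, 2, sqrt(colSums(H^2)), "/"))
}

#' Greenhouse-Geisser epsilon from a within-subject covariance matrix
#'
#' The standard trace formula on the contrast-transformed covariance:
#' with `Sc = C S C'` for orthonormal contrasts `C`,
#' `epsilon = tr(Sc)^2 / ((k - 1) * tr(Sc %*% Sc))`. Bounded in
#' `[1/(k-1), 1]`, and exactly 1 for spherical covariance (and always for
#' `k = 2`).
#'
#' @param S `k x k` pooled within-subject covariance matrix.
#' @return The epsilon estimate.
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  if (k < 2L) fq_validation_error("need at least 2 within-subject levels")
  C <- orthonormal_contrasts(k)
  Sc <- C %*% S %*% t(C)
  (sum(diag(Sc)))^2 / ((k - 1) * sum(Sc * Sc))
}

#' Split-plot repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate split-plot decomposition for a balanced design with
#' one between-subject factor (condition) and one within-subject factor
#' (region): the condition effect is tested against the subject-within-
#' condition error in the between-subject stratum; region and the
#' region x condition interaction are tested against the subject x region
#' error in the within-subject stratum. Sphericity violation is compensated
#' by multiplying the within-stratum degrees of freedom by the
#' Greenhouse-Geisser epsilon estimated from the pooled within-subject
#' covariance matrix.
#'
#' @param table Balanced RM tibble (`subject`, `condition`, `region`,
#'   `response`); transform with [log_transform()] first if desired. No
#'   imputation is performed: incomplete subjects are an error.
#' @param alpha Significance level for the interaction gate.
#' @return Object of class `fq_rm_anova`: ANOVA tibble (term, df, corrected
#'   df, SS, MS, F, p), `epsilon`, `interaction_significant`, and design
#'   sizes.
#' @examples
#' d <- generate_rm_dataset(rm_dataset_spec(seed = 2))
#' fit <- rm_anova_gg(d)
#' glance(fit)
#' @export
rm_anova_gg <- function(table, alpha = 0.05) {
  check_rm_table(table)
  table <- dplyr::mutate(table,
                         subject = factor(.data$subject),
                         condition = factor(.data$condition),
                         region = factor(.data$region))
  a <- nlevels(table$condition)
  k <- nlevels(table$region)
  n <- nlevels(table$subject) / a
  y <- table$response
  grand <- mean(y)

  m_cond <- tapply(y, table$condition, mean)
  m_reg <- tapply(y, table$region, mean)
  m_cell <- tapply(y, list(table$condition, table$region), mean)
  m_subj <- tapply(y, table$subject, mean)
  cond_of_subj <- tapply(as.character(table$condition), table$subject, `[`, 1L)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((m_subj - grand)^2)
  ss_cond <- n * k * sum((m_cond - grand)^2)
  ss_subj_err <- ss_between_subj - ss_cond
  ss_region <- n * a * sum((m_reg - grand)^2)
  dev <- m_cell - outer(m_cond, rep(1, k)) - outer(rep(1, a), m_reg) + grand
  ss_inter <- n * sum(dev^2)
  ss_within_err <- ss_total - ss_between_subj - ss_region - ss_inter

  df_cond <- a - 1; df_subj_err <- a * (n - 1)
  df_region <- k - 1; df_inter <- (a - 1) * (k - 1)
  df_within_err <- a * (n - 1) * (k - 1)

  ms <- c(cond = ss_cond / df_cond, subj = ss_subj_err / df_subj_err,
          region = ss_region / df_region, inter = ss_inter / df_inter,
          werr = ss_within_err / df_within_err)
  F_cond <- ms[["cond"]] / ms[["subj"]]
  F_region <- ms[["region"]] / ms[["werr"]]
  F_inter <- ms[["inter"]] / ms[["werr"]]

  # pooled within-subject covariance (subject region-vectors, centred per
  # condition)
  Y <- matrix(NA_real_, a * n, k)
  subj_levels <- levels(table$subject)
  for (si in seq_along(subj_levels)) {
    rows <- table$subject == subj_levels[si]
    Y[si, as.integer(table$region[rows])] <- table$response[rows]
  }
  centred <- Y - t(vapply(cond_of_subj[subj_levels], function(cn) {
    colMeans(Y[cond_of_subj[subj_levels] == cn, , drop = FALSE])
  }, numeric(k)))
  S <- crossprod(centred) / (a * n - a)
  eps <- gg_epsilon(S)

  p_cond <- pf(F_cond, df_cond, df_subj_err, lower.tail = FALSE)
  p_region <- pf(F_region, df_region * eps, df_within_err * eps,
                 lower.tail = FALSE)
  p_inter <- pf(F_inter, df_inter * eps, df_within_err * eps,
                lower.tail = FALSE)

  tbl <- tibble::tibble(
    term = c("condition", "subject(condition)", "region",
             "region:condition", "subject:region"),
    stratum = c("between", "between", "within", "within", "within"),
    df = c(df_cond, df_subj_err, df_region, df_inter, df_within_err),
    df_corrected = c(df_cond, df_subj_err, df_region * eps, df_inter * eps,
                     df_within_err * eps),
    sumsq = c(ss_cond, ss_subj_err, ss_region, ss_inter, ss_within_err),
    meansq = c(ms[["cond"]], ms[["subj"]], ms[["region"]], ms[["inter"]],
               ms[["werr"]]),
    statistic = c(F_cond, NA, F_region, F_inter, NA),
    p.value = c(p_cond, NA, p_region, p_inter, NA)
  )
  structure(list(
    table = tbl, epsilon = eps, alpha = alpha,
    interaction_significant = isTRUE(p_inter < alpha),
    n_conditions = a, n_regions = k, n_per_condition = n,
    data = table
  ), class = "fq_rm_anova")
}

#' @export
print.fq_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Split-plot repeated-measures ANOVA (%d conditions x %d subjects x %d regions)\n",
    x$n_conditions, x$n_per_condition, x$n_regions))
  cat(sprintf("Greenhouse-Geisser epsilon: %.4f\n", x$epsilon))
  print(as.data.frame(x$table), digits = 4)
  cat(sprintf("Interaction %ssignificant at alpha = %g\n",
              if (x$interaction_significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname rm_anova_gg
#' @param x An `fq_rm_anova` object.
#' @param ... Unused.
#' @export
tidy.fq_rm_anova <- function(x, ...) x$table

#' @rdname rm_anova_gg
#' @export
glance.fq_rm_anova <- function(x, ...) {
  tibble::tibble(
    epsilon = x$epsilon,
    interaction_significant = x$interaction_significant,
    p_condition = x$table$p.value[x$table$term == "condition"],
    p_region = x$table$p.value[x$table$term == "region"],
    p_interaction = x$table$p.value[x$table$term == "region:condition"],
    n_conditions = x$n_conditions,
    n_regions = x$n_regions,
    n_per_condition = x$n_per_condition
  )
}

#' Tukey HSD post-hoc contrasts between conditions
#'
#' Performed only in the absence of a significant region x condition
#' interaction (the gate the repeated-measures analysis prescribes): with an
#' interaction present, condition main effects are not interpretable and the
#' returned object is marked not-performed. Contrasts compare condition means
#' averaged over regions (subject means), with the studentized-range
#' distribution on the between-subject error degrees of freedom.
#'
#' @param table Balanced RM tibble.
#' @param anova The matching [rm_anova_gg()] fit.
#' @return Object of class `fq_tukey`: `performed` flag and (if performed) a
#'   tibble of pairwise contrasts with Tukey-adjusted p-values.
#' @export
tukey_hsd <- function(table, anova) {
  stopifnot(inherits(anova, "fq_rm_anova"))
  if (anova$interaction_significant) {
    return(structure(list(
      performed = FALSE,
      reason = "not performed - significant region:condition interaction",
      contrasts = NULL
    ), class = "fq_tukey"))
  }
  check_rm_table(table)
  sm <- table |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
  fit <- aov(response ~ condition, data = sm)
  tk <- TukeyHSD(fit)$condition
  pairs <- rownames(tk)
  structure(list(
    performed = TRUE,
    reason = NULL,
    contrasts = tibble::tibble(
      contrast = pairs,
      estimate = unname(tk[, "diff"]),
      conf.low = unname(tk[, "lwr"]),
      conf.high = unname(tk[, "upr"]),
      adj.p.value = unname(tk[, "p adj"])
    )
  ), class = "fq_tukey")
}

#' @export
print.fq_tukey <- function(x, ...) {
  if (!x$performed) {
    cat("Tukey HSD:", x$reason, "\n")
  } else {
    cat("Tukey HSD pairwise condition contrasts (subject means over regions):\n")
    print(as.data.frame(x$contrasts), digits = 4)
  }
  invisible(x)
}

#' @rdname tukey_hsd
#' @param x An `fq_tukey` object.
#' @param ... Unused.
#' @export
tidy.fq_tukey <- function(x, ...) {
  if (!x$performed) {
    return(tibble::tibble(contrast = character(), estimate = numeric(),
                          conf.low = numeric(), conf.high = numeric(),
                          adj.p.value = numeric()))
  }
  x$contrasts
}

#' Full statistical analysis of per-region values
#'
#' Log-transforms, fits the split-plot ANOVA with GG correction, and runs the
#' Tukey HSD post-hoc when the interaction gate allows it.
#'
#' @param table RM tibble on the percentage scale.
#' @param offset Log offset (percentage points).
#' @param alpha Interaction gate level.
#' @return List of class `fq_stats_report`: `anova`, `posthoc`, `offset`.
#' @export
analyze_regions <- function(table, offset = 0.5, alpha = 0.05) {
  lt <- log_transform(table, offset = offset)
  an <- rm_anova_gg(lt, alpha = alpha)
  ph <- tukey_hsd(lt, an)
  structure(list(anova = an, posthoc = ph, offset = offset),
            class = "fq_stats_report")
}

#' @export
print.fq_stats_report <- function(x, ...) {
  print(x$anova); cat("\n"); print(x$posthoc)
  invisible(x)
}
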