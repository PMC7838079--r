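# Comparison harness: group tests in both frameworks (tree-model delta-G2
# vs algebraic-score t tests), the algebraic identity checks linking them,
# and trait correlations.

#' Two-group t tests on individual CAN parameters
#'
#' Pooled-variance Student's t tests (two-tailed) on the individual C, N and
#' A scores of exactly two groups, with Cohen's d from the pooled SD.
#' Welch's correction is available behind `var_equal = FALSE`.
#'
#' @param battery a `can_battery` with a group column, or a [can_scores()]
#'   data frame with a `group` column.
#' @param group_col name of the group column, default `"group"`.
#' @param var_equal pool the variances (classic df = n1 + n2 - 2)?
#'   Default `TRUE`.
#' @return data frame with one row per parameter: group means, `t`, `df`,
#'   `p_value` and `d`. The difference is group 1 minus group 2 in sorted
#'   label order.
#' @export
compare_groups_can <- function(battery, group_col = "group",
                               var_equal = TRUE) {
  scores <- if (inherits(battery, "can_battery")) can_scores(battery)
            else battery
  if (is.null(scores[[group_col]])) {
    stop("no '", group_col, "' column in the data", call. = FALSE)
  }
  g <- factor(as.character(scores[[group_col]]))
  if (nlevels(g) != 2L) {
    stop("need exactly two groups, got ", nlevels(g),
         " (", paste(levels(g), collapse = ", "), "); ",
         "run pairwise comparisons for more", call. = FALSE)
  }
  lv <- levels(g)
  rows <- lapply(c("C", "N", "A"), function(par) {
    x1 <- scores[[par]][g == lv[1]]
    x2 <- scores[[par]][g == lv[2]]
    n1 <- length(x1); n2 <- length(x2)
    sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
                 (n1 + n2 - 2))
    if (sp == 0) {
      # both groups constant: identical means are no difference at all,
      # unequal constant means are a deterministic one
      diff <- mean(x1) - mean(x2)
      tt <- list(statistic = c(t = if (diff == 0) 0 else sign(diff) * Inf),
                 parameter = c(df = n1 + n2 - 2),
                 p.value = if (diff == 0) 1 else 0)
      d <- if (diff == 0) 0 else sign(diff) * Inf
    } else {
      tt <- t.test(x1, x2, var.equal = var_equal)
      d <- (mean(x1) - mean(x2)) / sp
    }
    data.frame(parameter = par, group1 = lv[1], group2 = lv[2],
               n1 = n1, n2 = n2, mean1 = mean(x1), mean2 = mean(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, d = d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlations between a trait and individual CAN parameters
#'
#' @param battery a `can_battery` carrying a trait column, or a
#'   [can_scores()] data frame.
#' @param trait_col name of the trait column, default `"trait"`.
#' @return data frame with one row per parameter: `r`, `p_value` (two-tailed
#'   t transform with df = n - 2), `n` after listwise deletion of missing
#'   traits, and a `degenerate` flag for zero-variance inputs.
#' @export
correlate_traits <- function(battery, trait_col = "trait") {
  scores <- if (inherits(battery, "can_battery")) can_scores(battery)
            else battery
  if (is.null(scores[[trait_col]])) {
    stop("no '", trait_col, "' column in the data", call. = FALSE)
  }
  trait <- suppressWarnings(as.numeric(scores[[trait_col]]))
  keep <- !is.na(trait)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " participant(s) without a trait score")
  }
  if (sum(keep) < 3L) {
    stop("need trait scores for at least 3 participants", call. = FALSE)
  }
  rows <- lapply(c("C", "N", "A"), function(par) {
    x <- scores[[par]][keep]
    y <- trait[keep]
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(parameter = par, r = NA_real_, p_value = NA_real_,
                        n = length(x), degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, y, method = "pearson")
    data.frame(parameter = par, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check the algebraic identities linking the CAN scores to the CNI fit
#'
#' Fits the CNI tree to the pooled counts and contrasts it with the mean
#' individual CAN scores:
#' * H1 — the consequence parameters agree: `|mean(C_CAN) - C_CNI|`;
#' * H2 — the CNI norm parameter equals the CAN one inflated by
#'   1/(1 - C): `|N_CNI - mean(N_CAN)/(1 - mean(C_CAN))|`;
#' * H3 — the CNI inaction parameter and the CAN action preference are
#'   reversed around 0.5: `sign(I_CNI - 0.5) == -sign(A_CAN - 0.5)`, with a
#'   boundary flag when either side is within `boundary_tol` of 0.5.
#'
#' @param battery a `can_battery`.
#' @param tolerance pass threshold on the H1/H2 absolute discrepancies;
#'   default 0.02 (use ~1e-3 for noise-free model-generated data).
#' @param boundary_tol closeness to 0.5 at which H3 is reported as a
#'   boundary case rather than a sign comparison; default 1e-6.
#' @return a `hypothesis_checks` list with the fitted CNI triple, the CAN
#'   means, the discrepancies, pass flags and the H3 sign report. If the CNI
#'   fit is degenerate (C at 1, so the H2 ratio is undefined) the checks are
#'   marked not evaluable.
#' @export
run_hypothesis_checks <- function(battery, tolerance = 0.02,
                                  boundary_tol = 1e-6) {
  stopifnot(inherits(battery, "can_battery"))
  fit <- fit_mpt(aggregate_counts(battery), "cni")
  est <- fit$estimates[[1]]
  names(est) <- rownames(fit$estimates)
  scores <- can_scores(battery)
  can_means <- c(C = mean(scores$C), N = mean(scores$N), A = mean(scores$A))

  evaluable <- fit$converged && (1 - can_means[["C"]]) > 1e-6
  h1 <- abs(can_means[["C"]] - est[["C"]])
  h2 <- if (evaluable) {
    abs(est[["N"]] - can_means[["N"]] / (1 - can_means[["C"]]))
  } else NA_real_
  i_dev <- est[["I"]] - 0.5
  a_dev <- can_means[["A"]] - 0.5
  h3_boundary <- abs(i_dev) <= boundary_tol || abs(a_dev) <= boundary_tol
  h3_opposite <- if (h3_boundary) NA else sign(i_dev) == -sign(a_dev)

  structure(list(
    cni = est, can_means = can_means, fit = fit, evaluable = evaluable,
    h1_discrepancy = h1, h1_pass = evaluable && h1 <= tolerance,
    h2_discrepancy = h2, h2_pass = evaluable && isTRUE(h2 <= tolerance),
    h3 = list(i_minus_half = i_dev, a_minus_half = a_dev,
              boundary = h3_boundary, opposite_signs = h3_opposite),
    tolerance = tolerance
  ), class = "hypothesis_checks")
}

#' @export
print.hypothesis_checks <- function(x, ...) {
  cat("Identity checks (CAN vs CNI fit)\n")
  cat(sprintf("  CNI fit:   C = %.4f  N = %.4f  I = %.4f\n",
              x$cni[["C"]], x$cni[["N"]], x$cni[["I"]]))
  cat(sprintf("  CAN means: C = %.4f  N = %.4f  A = %.4f\n",
              x$can_means[["C"]], x$can_means[["N"]], x$can_means[["A"]]))
  if (!x$evaluable) {
    cat("  checks not evaluable (degenerate CNI fit)\n")
    return(invisible(x))
  }
  cat(sprintf("  H1 |C_CAN - C_CNI| = %.5f (%s at tol %.3g)\n",
              x$h1_discrepancy, if (x$h1_pass) "pass" else "FAIL",
              x$tolerance))
  cat(sprintf("  H2 |N_CNI - N_CAN/(1-C)| = %.5f (%s at tol %.3g)\n",
              x$h2_discrepancy, if (x$h2_pass) "pass" else "FAIL",
              x$tolerance))
  if (x$h3$boundary) {
    cat("  H3 boundary case: I and/or A at 0.5\n")
  } else {
    cat(sprintf("  H3 I - 0.5 = %+.4f, A - 0.5 = %+.4f (signs %s)\n",
                x$h3$i_minus_half, x$h3$a_minus_half,
                if (isTRUE(x$h3$opposite_signs)) "opposite, as predicted"
                else "NOT opposite"))
  }
  invisible(x)
}

#' Side-by-side group-comparison report in both frameworks
#'
#' For a two-group battery, pairs each tree-model likelihood-ratio test
#' (delta G2 on C, N, I across groups) with the corresponding individual
#' score t test (C, N, A; the inaction and action-preference parameters are
#' each framework's third row), flags whether the two frameworks reach the
#' same conclusion at `alpha`, runs the H1-H3 identity checks on the pooled
#' data, and optionally appends trait correlations.
#'
#' @param battery a `can_battery` with a group column.
#' @param group_col name of the group column, default `"group"`.
#' @param trait_col optional trait column for [correlate_traits()].
#' @param model tree model for the likelihood-ratio side, default `"cni"`.
#' @param alpha significance level for the agreement flags, default 0.05.
#' @return a `comparison_report` list: `rows` (data frame pairing the two
#'   frameworks), `hypotheses` ([run_hypothesis_checks()] result),
#'   `correlations` (or NULL), plus the inputs used.
#' @export
build_comparison_report <- function(battery, group_col = "group",
                                    trait_col = NULL, model = "cni",
                                    alpha = 0.05) {
  stopifnot(inherits(battery, "can_battery"))
  if (is.null(battery[[group_col]])) {
    stop("no '", group_col, "' column in the battery", call. = FALSE)
  }
  g <- factor(as.character(battery[[group_col]]))
  if (nlevels(g) != 2L) {
    stop("need exactly two groups, got ", nlevels(g), call. = FALSE)
  }
  lv <- levels(g)
  counts <- stats::setNames(
    lapply(lv, function(l) aggregate_counts(battery, group = l)), lv)
  mod <- .get_model(model)
  can_tests <- compare_groups_can(battery, group_col = group_col)
  can_side <- can_tests[match(c("C", "N", "A"), can_tests$parameter), ]

  rows <- lapply(seq_len(3L), function(i) {
    mpt_par <- mod$par_names[i]
    dt <- delta_g2_test(counts, model, parameter = mpt_par)
    ct <- can_side[i, ]
    data.frame(
      mpt_parameter = mpt_par, delta_g2 = dt$delta_g2, mpt_df = dt$df,
      mpt_p = dt$p_value, w = dt$w,
      can_parameter = ct$parameter, t = ct$t, can_df = ct$df,
      can_p = ct$p_value, d = ct$d,
      agreement = (dt$p_value < alpha) == (ct$p_value < alpha),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  correlations <- if (!is.null(trait_col)) {
    correlate_traits(battery, trait_col = trait_col)
  }
  structure(list(rows = rows, groups = lv, model = mod$name, alpha = alpha,
                 hypotheses = run_hypothesis_checks(battery),
                 correlations = correlations),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Group comparison (", paste(x$groups, collapse = " vs "), ") -- ",
      x$model, " model vs CAN scores, alpha = ", x$alpha, "\n\n", sep = "")
  r <- x$rows
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %s: dG2(%d) = %6.2f, p = %.4g  |  %s: t(%g) = %6.2f, p = %.4g, d = %.3f  [%s]\n",
                r$mpt_parameter[i], r$mpt_df[i], r$delta_g2[i], r$mpt_p[i],
                r$can_parameter[i], r$can_df[i], r$t[i], r$can_p[i], r$d[i],
                if (r$agreement[i]) "identical conclusion" else "DIVERGENT"))
  }
  cat("\n")
  print(x$hypotheses)
  if (!is.null(x$correlations)) {
    cat("\nTrait correlations:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report's paired rows to CSV
#'
#' @param report a [build_comparison_report()] result.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  write.csv(report$rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
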