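# CAN algorithm: closed-form individual-level consequence sensitivity (C),
# norm sensitivity (N) and overall action preference (A).

#' CAN parameters from cell probabilities
#'
#' Computes the three algebraic scores from the four cell action
#' probabilities:
#' \deqn{C = (p_1 - p_2 + p_3 - p_4)/2}
#' \deqn{N = (p_3 - p_1 + p_4 - p_2)/2}
#' \deqn{A = (p_1 + p_2 + p_3 + p_4)/4}
#' C averages the benefit-greater minus benefit-smaller contrast over the two
#' norm types; N averages the prescriptive minus proscriptive contrast over
#' the two consequence types; A is the mean action probability. No clamping
#' is applied: the formulas are exact linear maps of (p1..p4).
#'
#' @param cells numeric vector `c(p1, p2, p3, p4)` with each value in
#'   \[0, 1\] (e.g. from [cell_probabilities()] or one of the forward maps).
#' @return named numeric vector `c(C, N, A)` with `C`, `N` in \[-1, 1\] and
#'   `A` in \[0, 1\].
#' @examples
#' can_parameters(cni_forward(c(0.3, 0.5, 0.4)))  # C = 0.30, N = 0.35, A = 0.535
#' @export
can_parameters <- function(cells) {
  p <- .check_cells(cells)
  c(C = (p[1] - p[2] + p[3] - p[4]) / 2,
    N = (p[3] - p[1] + p[4] - p[2]) / 2,
    A = (p[1] + p[2] + p[3] + p[4]) / 4)
}

.check_cells <- function(cells) {
  p <- unname(as.numeric(unlist(cells)))
  if (length(p) != 4L || anyNA(p)) {
    stop("cells must be four non-missing probabilities (p1..p4)",
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("cell probabilities must lie in [0, 1]; got (",
         paste(signif(p, 6), collapse = ", "), ")", call. = FALSE)
  }
  p
}

#' Per-participant CAN scores for a whole battery
#'
#' @param battery a `can_battery`.
#' @return data frame with one row per participant: `participant`, optional
#'   `group` and `trait`, the empirical `p1..p4`, and `C`, `N`, `A`.
#' @export
can_scores <- function(battery) {
  stopifnot(inherits(battery, "can_battery"))
  pf <- factor(battery$participant, levels = unique(battery$participant))
  cf <- factor(battery$cell, levels = 1:4)
  acts <- tapply(battery$response, list(pf, cf), sum)
  tots <- tapply(battery$response, list(pf, cf), length)
  p <- acts / tots
  out <- data.frame(participant = rownames(p), stringsAsFactors = FALSE)
  for (opt in c("group", "trait")) {
    if (!is.null(battery[[opt]])) {
      first <- !duplicated(battery$participant)
      out[[opt]] <- battery[[opt]][first][match(out$participant,
                                                battery$participant[first])]
    }
  }
  colnames(p) <- paste0("p", 1:4)
  out <- cbind(out, as.data.frame(p, row.names = NULL))
  out$C <- (out$p1 - out$p2 + out$p3 - out$p4) / 2
  out$N <- (out$p3 - out$p1 + out$p4 - out$p2) / 2
  out$A <- (out$p1 + out$p2 + out$p3 + out$p4) / 4
  rownames(out) <- NULL
  out
}

#' Group summary of CAN parameters with one-sample tests
#'
#' For each parameter, reports mean, SD, SE and a two-tailed one-sample
#' t test against its neutral point: 0 for C and N (no sensitivity),
#' 0.5 for A (no overall action/inaction preference). Groups in which a
#' parameter has zero variance are reported with the exact mean and flagged
#' `degenerate` rather than producing an infinite t statistic.
#'
#' @param scores data frame with columns `C`, `N`, `A` (e.g. from
#'   [can_scores()]), one row per participant.
#' @return data frame with rows C, N, A and columns `parameter`, `null`,
#'   `n`, `mean`, `sd`, `se`, `t`, `df`, `p_value`, `degenerate`.
#' @export
group_summary <- function(scores) {
  for (cn in c("C", "N", "A")) {
    if (is.null(scores[[cn]])) {
      stop("scores must contain columns C, N and A", call. = FALSE)
    }
  }
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 participants for a variance estimate",
                   call. = FALSE)
  nulls <- c(C = 0, N = 0, A = 0.5)
  rows <- lapply(names(nulls), function(par) {
    x <- scores[[par]]
    m <- mean(x)
    s <- sd(x)
    degenerate <- s == 0
    if (degenerate) {
      tval <- NA_real_
      pval <- NA_real_
    } else {
      tval <- (m - nulls[[par]]) / (s / sqrt(n))
      pval <- 2 * pt(-abs(tval), df = n - 1)
    }
    data.frame(parameter = par, null = nulls[[par]], n = n, mean = m,
               sd = s, se = s / sqrt(n), t = tval, df = n - 1L,
               p_value = pval, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("can_group_summary", "data.frame")
  out
}

#' Qualitative classification of a group from its CAN summary
#'
#' Applies the decision rules on the group means: C (and likewise N) above 0
#' with a significant test means sensitivity *supporting* the consequence
#' (norm), below 0 *opposing* it, and a non-significant test means
#' *insensitive*. A above 0.5 with a significant test is an overall
#' action preference, below 0.5 an inaction preference, otherwise
#' *neutral*. A neutral group with at least one significant sensitivity has
#' a *pure morality* attitude (utilitarian and/or deontological without an
#' action bias); a neutral group with neither sensitivity is classified as
#' answering *randomly*; any group with an action or inaction preference is
#' *mixed*.
#'
#' Degenerate (zero-variance) parameters are classified by their exact mean:
#' equal to the neutral point counts as insensitive/neutral, anything else as
#' a real (deterministic) deviation.
#'
#' @param summary a [group_summary()] result.
#' @param alpha two-tailed significance level, default 0.05.
#' @return a `can_classification` list with elements `consequence`, `norm`
#'   (supporting/opposing/insensitive), `overall` (action_preference /
#'   inaction_preference / neutral) and `summary` (mixed / pure_morality /
#'   random).
#' @export
classify_group <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "data.frame"), alpha > 0, alpha < 1)
  row_of <- function(par) summary[summary$parameter == par, , drop = FALSE]
  significant <- function(r) {
    if (isTRUE(r$degenerate)) r$mean != r$null else r$p_value < alpha
  }
  sens_label <- function(r) {
    if (!significant(r)) "insensitive"
    else if (r$mean > r$null) "supporting"
    else "opposing"
  }
  rC <- row_of("C"); rN <- row_of("N"); rA <- row_of("A")
  overall <- if (!significant(rA)) "neutral"
             else if (rA$mean > 0.5) "action_preference"
             else "inaction_preference"
  consequence <- sens_label(rC)
  norm <- sens_label(rN)
  summary_label <- if (overall != "neutral") "mixed"
                   else if (consequence == "insensitive" && norm == "insensitive") "random"
                   else "pure_morality"
  structure(list(consequence = consequence, norm = norm, overall = overall,
                 summary = summary_label, alpha = alpha),
            class = "can_classification")
}

#' @export
print.can_classification <- function(x, ...) {
  cat("CAN classification (alpha = ", x$alpha, "):\n", sep = "")
  cat("  consequence sensitivity:", x$consequence, "\n")
  cat("  norm sensitivity:       ", x$norm, "\n")
  cat("  overall preference:     ", x$overall, "\n")
  cat("  summary:                ", x$summary, "\n")
  invisible(x)
}

#' Write per-participant CAN scores to CSV
#'
#' @param scores result of [can_scores()].
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
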