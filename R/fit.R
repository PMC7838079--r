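# Maximum-likelihood fitting of the processing trees to aggregated cell
# counts, with G-squared goodness of fit and delta-G-squared likelihood-ratio
# constraint tests.
#
# Likelihood: independent binomials across the four cells of each group's
# aggregated counts (participants pooled within group, matching the original
# group-level fitting practice). Optimization is bounded quasi-Newton
# (L-BFGS-B) on logit-transformed parameters, multi-started from a fixed
# 3x3x3 interior grid plus the closed-form inversion of the observed
# proportions; the best likelihood wins, ties broken by the first start.

.PBOUND <- 1e-6          # parameter box [.PBOUND, 1 - .PBOUND]
.BOUNDARY_FLAG <- 1e-4   # estimates this close to the box are flagged

.as_counts_list <- function(counts) {
  if (inherits(counts, "cell_counts")) counts <- list(counts)
  if (!is.list(counts) || !all(vapply(counts, inherits, TRUE, "cell_counts"))) {
    stop("counts must be a cell_counts object or a list of them",
         call. = FALSE)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    names(counts) <- paste0("group", seq_along(counts))
  }
  counts
}

# Saturated-model negative log-likelihood (0 log 0 = 0 convention).
.nll_saturated <- function(counts) {
  tot <- 0
  for (cc in counts) {
    a <- cc$actions; T <- cc$totals; b <- T - a
    tot <- tot - sum(ifelse(a > 0, a * log(a / T), 0)) -
      sum(ifelse(b > 0, b * log(b / T), 0))
  }
  tot
}

.nll_counts <- function(p, actions, totals) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(actions * log(p) + (totals - actions) * log(1 - p))
}

# Build the free-parameter bookkeeping for (model x groups x constraints).
# Returns: slot index matrix [3 x G] (0 = fixed), fixed-value matrix,
# number of free slots.
.build_slots <- function(par_names, n_groups, constraints) {
  idx <- matrix(0L, nrow = 3L, ncol = n_groups,
                dimnames = list(par_names, NULL))
  fixed <- matrix(NA_real_, nrow = 3L, ncol = n_groups,
                  dimnames = list(par_names, NULL))
  slot <- 0L
  if (!is.null(constraints)) {
    unknown <- setdiff(names(constraints), par_names)
    if (length(unknown) > 0L) {
      stop("constraint on unknown parameter(s): ",
           paste(unknown, collapse = ", "), " (model parameters are ",
           paste(par_names, collapse = ", "), ")", call. = FALSE)
    }
  }
  for (pn in par_names) {
    con <- constraints[[pn]]
    if (is.numeric(con)) {
      if (con < 0 || con > 1) {
        stop("point constraint on ", pn, " must lie in [0, 1]", call. = FALSE)
      }
      fixed[pn, ] <- con
    } else if (identical(con, "equal")) {
      if (n_groups < 2L) {
        stop("equality constraint on ", pn, " needs at least two groups",
             call. = FALSE)
      }
      slot <- slot + 1L
      idx[pn, ] <- slot
    } else if (is.null(con)) {
      for (g in seq_len(n_groups)) {
        slot <- slot + 1L
        idx[pn, g] <- slot
      }
    } else {
      stop("constraint on ", pn, " must be a numeric value or \"equal\"",
           call. = FALSE)
    }
  }
  list(idx = idx, fixed = fixed, n_free = slot)
}

# Probability-scale parameter matrix [3 x G] from a logit-scale theta vector.
.theta_to_par <- function(theta, slots) {
  par <- slots$fixed
  free <- slots$idx > 0L
  par[free] <- plogis(theta[slots$idx[free]])
  par
}

# Start matrices (probability scale): fixed 3x3x3 interior grid replicated
# across groups, plus per-group closed-form inversion of the observed
# proportions clamped to [0.02, 0.98].
.start_grid <- function(model, counts) {
  g <- as.matrix(expand.grid(a = c(0.25, 0.5, 0.75),
                             b = c(0.25, 0.5, 0.75),
                             c = c(0.25, 0.5, 0.75)))
  n_groups <- length(counts)
  starts <- lapply(seq_len(nrow(g)), function(i) {
    matrix(rep(g[i, ], n_groups), nrow = 3L,
           dimnames = list(model$par_names, NULL))
  })
  inv <- try({
    m <- vapply(counts, function(cc) {
      p <- cc$actions / cc$totals
      pmin(pmax(unname(model$invert(p)), 0.02), 0.98)
    }, numeric(3))
    dimnames(m) <- list(model$par_names, NULL)
    m
  }, silent = TRUE)
  if (!inherits(inv, "try-error") && all(is.finite(inv))) {
    starts <- c(list(inv), starts)
  }
  starts
}

.fit_engine <- function(counts, model, slots, starts) {
  acts <- lapply(counts, `[[`, "actions")
  tots <- lapply(counts, `[[`, "totals")
  n_groups <- length(counts)
  lo <- qlogis(.PBOUND)
  hi <- qlogis(1 - .PBOUND)

  nll <- function(theta) {
    par <- .theta_to_par(theta, slots)
    tot <- 0
    for (g in seq_len(n_groups)) {
      p <- model$forward(par[, g])
      tot <- tot + .nll_counts(p, acts[[g]], tots[[g]])
    }
    tot
  }

  # analytic gradient: chain rule through the forward map and the logistic
  # reparameterization, accumulated over the free slots
  nll_grad <- function(theta) {
    par <- .theta_to_par(theta, slots)
    grad <- numeric(slots$n_free)
    for (g in seq_len(n_groups)) {
      x <- par[, g]
      p <- pmin(pmax(model$forward(x), 1e-12), 1 - 1e-12)
      w <- -(acts[[g]] / p - (tots[[g]] - acts[[g]]) / (1 - p))
      gpar <- drop(crossprod(model$jacobian(x), w)) * x * (1 - x)
      sl <- slots$idx[, g]
      for (j in which(sl > 0L)) grad[sl[j]] <- grad[sl[j]] + gpar[j]
    }
    grad
  }

  theta_from_par <- function(par) {
    theta <- numeric(slots$n_free)
    free <- which(slots$idx > 0L)
    # equality-shared slots get the mean of the proposed group values
    for (s in seq_len(slots$n_free)) {
      vals <- par[slots$idx == s]
      theta[s] <- qlogis(min(max(mean(vals), .PBOUND), 1 - .PBOUND))
    }
    theta
  }

  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    theta0 <- theta_from_par(st)
    res <- try(optim(theta0, nll, gr = nll_grad, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 500L)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) {
    return(list(converged = FALSE, n_starts_used = n_used))
  }
  par_hat <- .theta_to_par(best$par, slots)
  list(converged = best$convergence == 0, n_starts_used = n_used,
       par = par_hat, nll = best$value)
}

#' Fit a processing-tree model to cell counts by maximum likelihood
#'
#' Maximizes the product-binomial likelihood of the four-cell action counts
#' of one or more groups under the chosen tree, and reports the G-squared
#' goodness-of-fit statistic
#' \deqn{G^2 = 2 \sum \mathrm{obs} \, \ln(\mathrm{obs}/\mathrm{exp})}
#' summed over the action and inaction counts of every cell (terms with a
#' zero observed count contribute zero). Degrees of freedom are the number
#' of free cell probabilities (4 per group) minus the number of free model
#' parameters.
#'
#' @param counts a [cell_counts()] object or a named list of them (one per
#'   group, e.g. from [aggregate_counts()]).
#' @param model `"cni"`, `"nci"` or `"dna"`.
#' @param constraints optional named list constraining parameters: a numeric
#'   value fixes the parameter at that value in every group; the string
#'   `"equal"` forces it to be equal across groups. E.g.
#'   `list(N = "equal")` or `list(I = 0.5)`.
#' @return an `mpt_fit` object: list with `model`, `estimates` (data frame,
#'   parameters x groups), `g2`, `df`, `p_value`, `log_likelihood`,
#'   `converged`, `n_starts_used`, `boundary` (logical matrix flagging
#'   estimates within 1e-4 of the optimization box) and the inputs.
#' @examples
#' cc <- cell_counts(actions = c(306, 126, 516, 336), totals = rep(600, 4))
#' fit_mpt(cc, "cni")
#' @export
fit_mpt <- function(counts, model = c("cni", "nci", "dna"),
                    constraints = NULL) {
  counts <- .as_counts_list(counts)
  model <- match.arg(model)
  mod <- .get_model(model)

  # without cross-group equality constraints the likelihood factorizes over
  # groups: fit each one separately (3-parameter problems) and combine
  has_equal <- any(vapply(constraints, identical, TRUE, "equal"))
  if (length(counts) > 1L && !has_equal) {
    fits <- lapply(counts, function(cc) fit_mpt(cc, model, constraints))
    est <- do.call(cbind, lapply(fits, `[[`, "estimates"))
    names(est) <- names(counts)
    g2 <- sum(vapply(fits, `[[`, numeric(1), "g2"))
    df <- sum(vapply(fits, `[[`, integer(1), "df"))
    return(structure(list(
      model = mod$name, estimates = est, g2 = g2, df = df,
      p_value = if (df > 0L) pchisq(g2, df, lower.tail = FALSE) else NA_real_,
      log_likelihood = sum(vapply(fits, `[[`, numeric(1), "log_likelihood")),
      converged = all(vapply(fits, `[[`, logical(1), "converged")),
      n_starts_used = sum(vapply(fits, `[[`, integer(1), "n_starts_used")),
      boundary = do.call(cbind, lapply(fits, `[[`, "boundary")),
      constraints = constraints, counts = counts
    ), class = "mpt_fit"))
  }

  slots <- .build_slots(mod$par_names, length(counts), constraints)
  if (slots$n_free == 0L) {
    # fully constrained model: nothing to optimize
    par_hat <- slots$fixed
    nll_hat <- 0
    for (g in seq_along(counts)) {
      p <- mod$forward(par_hat[, g])
      nll_hat <- nll_hat + .nll_counts(p, counts[[g]]$actions,
                                       counts[[g]]$totals)
    }
    eng <- list(converged = TRUE, n_starts_used = 0L, par = par_hat,
                nll = nll_hat)
  } else {
    eng <- .fit_engine(counts, mod, slots, .start_grid(mod, counts))
  }
  if (is.null(eng$par)) {
    stop("optimization failed from every start; check the counts",
         call. = FALSE)
  }
  g2 <- 2 * (eng$nll - .nll_saturated(counts))
  g2 <- max(g2, 0)
  df <- 4L * length(counts) - slots$n_free
  est <- as.data.frame(eng$par)
  names(est) <- names(counts)
  structure(list(
    model = mod$name,
    estimates = est,
    g2 = g2,
    df = df,
    p_value = if (df > 0L) pchisq(g2, df, lower.tail = FALSE) else NA_real_,
    log_likelihood = -eng$nll,
    converged = eng$converged,
    n_starts_used = eng$n_starts_used,
    boundary = eng$par <= .PBOUND + .BOUNDARY_FLAG |
      eng$par >= 1 - .PBOUND - .BOUNDARY_FLAG,
    constraints = constraints,
    counts = counts
  ), class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, digits = 4, ...) {
  cat(x$model, "model fit (", length(x$counts), "group(s))\n")
  print(round(x$estimates, digits))
  cat(sprintf("G2(%d) = %.4g, p = %.4g, logLik = %.4g\n",
              x$df, x$g2, x$p_value, x$log_likelihood))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (any(x$boundary)) cat("note: estimate(s) at the parameter boundary\n")
  invisible(x)
}

#' Likelihood-ratio (delta G-squared) constraint test
#'
#' Tests a parameter either for equality across two groups or against a
#' fixed value, by comparing the G-squared fit of the constrained model with
#' the unconstrained one: \eqn{\Delta G^2 = G^2_{constrained} -
#' G^2_{unconstrained}}, referred to a chi-square distribution with one
#' degree of freedom (one constraint). The constrained fit reuses the
#' unconstrained optimum as a warm start in addition to the standard start
#' grid.
#'
#' Also reports Cohen's w = sqrt(delta G2 / total observations) as a
#' descriptive effect size for the constraint.
#'
#' @param counts a named list of two [cell_counts()] (equality test) or a
#'   single `cell_counts` (point test).
#' @param model `"cni"`, `"nci"` or `"dna"`.
#' @param parameter name of the parameter to constrain (e.g. `"N"`).
#' @param value optional numeric: test `parameter == value` in a single
#'   group instead of equality across groups.
#' @return an `mpt_constraint_test` list with `constraint`, `delta_g2`,
#'   `df`, `p_value`, `w`, and the two `mpt_fit` objects.
#' @export
delta_g2_test <- function(counts, model = c("cni", "nci", "dna"),
                          parameter, value = NULL) {
  counts <- .as_counts_list(counts)
  model <- match.arg(model)
  mod <- .get_model(model)
  if (!(parameter %in% mod$par_names)) {
    stop("parameter must be one of ", paste(mod$par_names, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(value)) {
    if (length(counts) != 2L) {
      stop("equality test needs exactly two groups; pass value= for a ",
           "point constraint", call. = FALSE)
    }
    constraints <- stats::setNames(list("equal"), parameter)
    desc <- sprintf("%s equal across groups %s", parameter,
                    paste(names(counts), collapse = " vs "))
  } else {
    if (length(counts) != 1L) {
      stop("point-constraint test takes a single group", call. = FALSE)
    }
    constraints <- stats::setNames(list(as.numeric(value)), parameter)
    desc <- sprintf("%s = %g", parameter, value)
  }

  free_fit <- fit_mpt(counts, model)

  # constrained fit: standard grid plus warm start at the free optimum
  slots <- .build_slots(mod$par_names, length(counts), constraints)
  warm <- as.matrix(free_fit$estimates)
  starts <- c(list(warm), .start_grid(mod, counts))
  eng <- .fit_engine(counts, mod, slots, starts)
  if (is.null(eng$par)) {
    stop("constrained optimization failed from every start", call. = FALSE)
  }
  g2_con <- max(2 * (eng$nll - .nll_saturated(counts)), 0)
  delta <- g2_con - free_fit$g2
  if (delta < -1e-6) {
    stop(sprintf(paste0("constrained fit beat the unconstrained one ",
                        "(delta G2 = %.3g): optimization failure, ",
                        "try more starts"), delta), call. = FALSE)
  }
  delta <- max(delta, 0)
  n_obs <- sum(vapply(counts, function(cc) sum(cc$totals), numeric(1)))
  est_con <- as.data.frame(eng$par)
  names(est_con) <- names(counts)
  con_fit <- structure(list(
    model = mod$name,
    estimates = est_con,
    g2 = g2_con, df = 4L * length(counts) - slots$n_free,
    p_value = pchisq(g2_con, 4L * length(counts) - slots$n_free,
                     lower.tail = FALSE),
    log_likelihood = -eng$nll, converged = eng$converged,
    n_starts_used = eng$n_starts_used,
    boundary = eng$par <= .PBOUND + .BOUNDARY_FLAG |
      eng$par >= 1 - .PBOUND - .BOUNDARY_FLAG,
    constraints = constraints, counts = counts
  ), class = "mpt_fit")
  structure(list(
    constraint = desc, model = mod$name, delta_g2 = delta, df = 1L,
    p_value = pchisq(delta, 1L, lower.tail = FALSE),
    w = sqrt(delta / n_obs),
    unconstrained = free_fit, constrained = con_fit
  ), class = "mpt_constraint_test")
}

#' @export
print.mpt_constraint_test <- function(x, ...) {
  cat(x$model, "constraint test:", x$constraint, "\n")
  cat(sprintf("delta G2(%d) = %.4g, p = %.4g, w = %.3g\n",
              x$df, x$delta_g2, x$p_value, x$w))
  invisible(x)
}
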