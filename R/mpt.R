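# The three processing trees: forward equations mapping latent parameter
# triples to the four cell action probabilities, plus closed-form inversions.
#
# Cell order is always (p1, p2, p3, p4) as defined in battery.R.

.check_triple <- function(params, names3) {
  x <- unname(as.numeric(unlist(params)))
  if (length(x) != 3L || anyNA(x)) {
    stop("parameters must be three non-missing values (",
         paste(names3, collapse = ", "), ")", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("parameters must lie in [0, 1]; got (",
         paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
  }
  names(x) <- names3
  x
}

#' CNI forward equations
#'
#' Sequential consequences -> norms -> generalized inaction tree. With
#' consequence sensitivity C, norm sensitivity N and generalized inaction
#' preference I:
#' \deqn{p_1 = C + (1-C)(1-N)(1-I)}
#' \deqn{p_2 = (1-C)(1-N)(1-I)}
#' \deqn{p_3 = C + (1-C)N + (1-C)(1-N)(1-I)}
#' \deqn{p_4 = (1-C)N + (1-C)(1-N)(1-I)}
#'
#' @param params numeric `c(C, N, I)`, each in \[0, 1\].
#' @return named numeric vector `c(p1, p2, p3, p4)`.
#' @examples
#' cni_forward(c(0.3, 0.5, 0.4))  # (0.51, 0.21, 0.86, 0.56)
#' @export
cni_forward <- function(params) {
  x <- .check_triple(params, c("C", "N", "I"))
  C <- x[["C"]]; N <- x[["N"]]; I <- x[["I"]]
  q <- (1 - C) * (1 - N) * (1 - I)
  m <- (1 - C) * N
  c(p1 = C + q, p2 = q, p3 = C + m + q, p4 = m + q)
}

#' NCI forward equations
#'
#' Same tree with the norm stage first (N -> C -> I):
#' \deqn{p_1 = (1-N)C + (1-N)(1-C)(1-I)}
#' \deqn{p_2 = (1-N)(1-C)(1-I)}
#' \deqn{p_3 = N + (1-N)C + (1-N)(1-C)(1-I)}
#' \deqn{p_4 = N + (1-N)(1-C)(1-I)}
#'
#' @param params numeric `c(N, C, I)`, each in \[0, 1\].
#' @return named numeric vector `c(p1, p2, p3, p4)`.
#' @examples
#' nci_forward(c(0.5, 0.3, 0.4))  # (0.36, 0.21, 0.86, 0.71)
#' @export
nci_forward <- function(params) {
  x <- .check_triple(params, c("N", "C", "I"))
  N <- x[["N"]]; C <- x[["C"]]; I <- x[["I"]]
  q <- (1 - N) * (1 - C) * (1 - I)
  c(p1 = (1 - N) * C + q, p2 = q, p3 = N + (1 - N) * C + q, p4 = N + q)
}

#' DNA forward equations
#'
#' Parallel-drive tree: with probability D the choice is driven by moral
#' principles (norms dominating with probability N, consequences with 1-N);
#' otherwise an overall action preference A applies:
#' \deqn{p_1 = (1-D)A + D(1-N)}
#' \deqn{p_2 = (1-D)A}
#' \deqn{p_3 = (1-D)A + D}
#' \deqn{p_4 = (1-D)A + DN}
#'
#' @param params numeric `c(D, N, A)`, each in \[0, 1\].
#' @return named numeric vector `c(p1, p2, p3, p4)`.
#' @examples
#' dna_forward(c(0.8, 0.6, 0.5))  # (0.42, 0.10, 0.90, 0.58)
#' @export
dna_forward <- function(params) {
  x <- .check_triple(params, c("D", "N", "A"))
  D <- x[["D"]]; N <- x[["N"]]; A <- x[["A"]]
  base <- (1 - D) * A
  c(p1 = base + D * (1 - N), p2 = base, p3 = base + D, p4 = base + D * N)
}

#' Closed-form inversion of the CNI equations
#'
#' For cells that lie exactly on the CNI manifold (p1 - p2 = p3 - p4):
#' \deqn{C = ((p_1 - p_2) + (p_3 - p_4))/2}
#' \deqn{N = (-p_1 - p_2 + p_3 + p_4)/(2 - p_1 + p_2 - p_3 + p_4)}
#' \deqn{I = 1 - p_2 / ((1-C)(1-N))}
#' Round-tripping with [cni_forward()] is exact for interior parameters.
#'
#' @param cells numeric `c(p1, p2, p3, p4)`.
#' @param tol consistency tolerance on `|(p1-p2) - (p3-p4)|`, default 1e-8.
#' @return named numeric vector `c(C, N, I)`.
#' @section Errors: cells off the CNI manifold raise an inconsistency error
#'   reporting both differences; `C = 1` or `N = 1` (zero denominators, the
#'   tree short-circuits and I is unidentified) raise a degenerate
#'   parameterization error.
#' @examples
#' cni_invert(c(0.51, 0.21, 0.86, 0.56))  # (0.3, 0.5, 0.4)
#' @export
cni_invert <- function(cells, tol = 1e-8) {
  p <- .check_cells(cells)
  d12 <- p[1] - p[2]
  d34 <- p[3] - p[4]
  if (abs(d12 - d34) > tol) {
    stop(sprintf(paste0("cells are not CNI-consistent: p1 - p2 = %.6g but ",
                        "p3 - p4 = %.6g"), d12, d34), call. = FALSE)
  }
  C <- (d12 + d34) / 2
  den <- 2 - p[1] + p[2] - p[3] + p[4]
  if (abs(den) <= tol) {
    stop("degenerate parameterization: denominator 2 - p1 + p2 - p3 + p4 ",
         "is zero (C or N at 1; I unidentified)", call. = FALSE)
  }
  N <- (-p[1] - p[2] + p[3] + p[4]) / den
  rest <- (1 - C) * (1 - N)
  if (abs(rest) <= tol) {
    stop("degenerate parameterization: (1 - C)(1 - N) = 0, ",
         "I is unidentified", call. = FALSE)
  }
  I <- 1 - p[2] / rest
  c(C = C, N = N, I = I)
}

#' Closed-form inversion of the NCI equations
#'
#' N is the prescriptive-minus-proscriptive contrast (p3 - p1 = p4 - p2 = N
#' on the NCI manifold); C and I follow by back-substitution. Used as an
#' optimizer warm start and in the model-equivalence checks.
#'
#' @inheritParams cni_invert
#' @return named numeric vector `c(N, C, I)`.
#' @export
nci_invert <- function(cells, tol = 1e-8) {
  p <- .check_cells(cells)
  d31 <- p[3] - p[1]
  d42 <- p[4] - p[2]
  if (abs(d31 - d42) > tol) {
    stop(sprintf(paste0("cells are not NCI-consistent: p3 - p1 = %.6g but ",
                        "p4 - p2 = %.6g"), d31, d42), call. = FALSE)
  }
  N <- (d31 + d42) / 2
  if (abs(1 - N) <= tol) {
    stop("degenerate parameterization: N = 1, C and I unidentified",
         call. = FALSE)
  }
  C <- (p[1] - p[2]) / (1 - N)
  if (abs(1 - C) <= tol) {
    stop("degenerate parameterization: C = 1, I unidentified", call. = FALSE)
  }
  I <- 1 - p[2] / ((1 - N) * (1 - C))
  c(N = N, C = C, I = I)
}

# Model registry used by the fitting engine and the simulator. `jacobian`
# returns the 4x3 matrix dp/dpar used for analytic likelihood gradients.
.mpt_models <- list(
  cni = list(
    name = "CNI", par_names = c("C", "N", "I"), forward = cni_forward,
    invert = function(p) cni_invert(p, tol = Inf),
    jacobian = function(x) {
      C <- x[1]; N <- x[2]; I <- x[3]
      dq <- c(-(1 - N) * (1 - I), -(1 - C) * (1 - I), -(1 - C) * (1 - N))
      dm <- c(-N, 1 - C, 0)
      rbind(p1 = c(1, 0, 0) + dq,
            p2 = dq,
            p3 = c(1, 0, 0) + dm + dq,
            p4 = dm + dq)
    }
  ),
  nci = list(
    name = "NCI", par_names = c("N", "C", "I"), forward = nci_forward,
    invert = function(p) nci_invert(p, tol = Inf),
    jacobian = function(x) {
      N <- x[1]; C <- x[2]; I <- x[3]
      dq <- c(-(1 - C) * (1 - I), -(1 - N) * (1 - I), -(1 - N) * (1 - C))
      du <- c(-C, 1 - N, 0)
      rbind(p1 = du + dq,
            p2 = dq,
            p3 = c(1, 0, 0) + du + dq,
            p4 = c(1, 0, 0) + dq)
    }
  ),
  dna = list(
    name = "DNA", par_names = c("D", "N", "A"), forward = dna_forward,
    invert = function(p) {
      D <- p[3] - p[2]  # p3 - p2 = D on the DNA manifold
      N <- if (D > 0) ((p[4] - p[2]) / D) else 0.5
      A <- if (D < 1) (p[2] / (1 - D)) else 0.5
      c(D = D, N = N, A = A)
    },
    jacobian = function(x) {
      D <- x[1]; N <- x[2]; A <- x[3]
      rbind(p1 = c(1 - N - A, -D, 1 - D),
            p2 = c(-A, 0, 1 - D),
            p3 = c(1 - A, 0, 1 - D),
            p4 = c(N - A, D, 1 - D))
    }
  )
)

.get_model <- function(model) {
  model <- match.arg(tolower(model), names(.mpt_models))
  .mpt_models[[model]]
}
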