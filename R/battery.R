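# Response data model: long-format batteries, validation, cell probabilities
# and aggregated cell counts (the sufficient statistic for the MPT fits).

# Canonical cell indexing shared by every module:
#   cell 1: proscriptive norm,  benefits greater than costs
#   cell 2: proscriptive norm,  benefits smaller than costs
#   cell 3: prescriptive norm,  benefits greater than costs
#   cell 4: prescriptive norm,  benefits smaller than costs
.norm_levels <- c("proscriptive", "prescriptive")
.consequence_levels <- c("benefits_greater", "benefits_smaller")

.cell_index <- function(norm, consequence) {
  # proscriptive -> rows 1:2, prescriptive -> rows 3:4
  2L * (match(norm, .norm_levels) - 1L) +
    match(consequence, .consequence_levels)
}

.default_column_map <- c(
  participant = "participant", dilemma = "dilemma", norm = "norm",
  consequence = "consequence", response = "response",
  group = "group", trait = "trait"
)

.canon_norm <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("proscriptive", "pro")] <- "proscriptive"
  out[x %in% c("prescriptive", "pre")] <- "prescriptive"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown norm type value(s): ", paste(bad, collapse = ", "),
         " (expected proscriptive/prescriptive)", call. = FALSE)
  }
  out
}

.canon_consequence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("benefits_greater", "greater", "benefits>costs", "g")] <-
    "benefits_greater"
  out[x %in% c("benefits_smaller", "smaller", "benefits<costs", "s")] <-
    "benefits_smaller"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown consequence type value(s): ", paste(bad, collapse = ", "),
         " (expected benefits_greater/benefits_smaller)", call. = FALSE)
  }
  out
}

#' Construct and validate a dilemma battery
#'
#' A battery is a long-format table with one row per participant x dilemma
#' trial. `as_battery()` normalises the categorical codings, checks that the
#' response is binary, and verifies that every participant has at least one
#' trial in each of the four norm-by-consequence design cells (the CAN
#' formulas are undefined otherwise).
#'
#' @param df data frame with columns `participant`, `dilemma`, `norm`
#'   (proscriptive/prescriptive), `consequence` (benefits_greater /
#'   benefits_smaller, "greater"/"smaller" accepted), `response` (0/1) and
#'   optionally `group` and `trait`.
#' @param allow_incomplete drop (with a message) participants missing a design
#'   cell instead of failing. Default `FALSE`: missing cells are an error.
#' @return a `can_battery`: the validated data frame with canonical codings,
#'   an integer `cell` column (1-4) and attribute `trials_per_cell` (the
#'   common per-cell trial count, or `NA` if it varies across participants
#'   or cells).
#' @seealso [read_battery()], [cell_probabilities()], [aggregate_counts()]
#' @export
as_battery <- function(df, allow_incomplete = FALSE) {
  required <- c("participant", "dilemma", "norm", "consequence", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("battery is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  out$participant <- as.character(out$participant)
  out$dilemma <- as.character(out$dilemma)
  out$norm <- .canon_norm(out$norm)
  out$consequence <- .canon_consequence(out$consequence)

  resp <- out$response
  if (is.logical(resp)) resp <- as.integer(resp)
  if (is.character(resp) || is.factor(resp)) {
    resp <- suppressWarnings(as.numeric(as.character(resp)))
  }
  if (anyNA(resp) || !all(resp %in% c(0, 1))) {
    stop("response must be binary 0/1 (action = 1, inaction = 0); ",
         "use read_battery(response_codes=) for other codings",
         call. = FALSE)
  }
  out$response <- as.integer(resp)
  out$cell <- .cell_index(out$norm, out$consequence)

  # every participant needs all four design cells
  have <- table(out$participant, out$cell)
  complete <- ncol(have) == 4L & rowSums(have > 0L) == 4L
  if (!all(complete)) {
    bad <- rownames(have)[!complete]
    if (allow_incomplete) {
      message("dropping ", length(bad),
              " participant(s) missing one or more design cells: ",
              paste(bad, collapse = ", "))
      out <- out[!(out$participant %in% bad), , drop = FALSE]
      if (nrow(out) == 0L) {
        stop("no participants remain after dropping incomplete ones",
             call. = FALSE)
      }
      have <- table(out$participant, out$cell)
    } else {
      stop("participant(s) missing one or more design cells: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  k <- unique(as.vector(have))
  attr(out, "trials_per_cell") <- if (length(k) == 1L) as.integer(k) else NA_integer_
  rownames(out) <- NULL
  class(out) <- c("can_battery", "data.frame")
  out
}

#' @export
print.can_battery <- function(x, ...) {
  k <- attr(x, "trials_per_cell")
  cat("Moral-dilemma battery: ", length(unique(x$participant)),
      " participant(s), ", nrow(x), " trials",
      if (!is.na(k)) paste0(" (", k, " per cell)"), "\n", sep = "")
  if (!is.null(x$group)) {
    cat("Groups:", paste(sort(unique(as.character(x$group))), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a long-format battery from a delimited text file
#'
#' @param path path to a delimited text file with a header row. Lines
#'   starting with `#` are treated as comments (the simulator writes its
#'   spec there).
#' @param column_map named character vector mapping canonical names
#'   (`participant`, `dilemma`, `norm`, `consequence`, `response`, and
#'   optionally `group`, `trait`) to the file's column names. Unmapped
#'   canonical names default to themselves.
#' @param response_codes named character vector `c(action = ..., inaction
#'   = ...)` giving the file's response coding; default `c(action = "1",
#'   inaction = "0")`.
#' @param sep field separator, default comma.
#' @inheritParams as_battery
#' @return a validated [as_battery()] object.
#' @export
read_battery <- function(path, column_map = NULL,
                         response_codes = c(action = "1", inaction = "0"),
                         sep = ",", allow_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  map <- .default_column_map
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown) > 0L) {
      stop("column_map has unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  required <- c("participant", "dilemma", "norm", "consequence", "response")
  for (cn in required) {
    if (!(map[[cn]] %in% names(raw))) {
      stop("required column '", map[[cn]], "' (", cn, ") not found in ", path,
           call. = FALSE)
    }
  }
  df <- data.frame(
    participant = raw[[map[["participant"]]]],
    dilemma = raw[[map[["dilemma"]]]],
    norm = raw[[map[["norm"]]]],
    consequence = raw[[map[["consequence"]]]],
    response = raw[[map[["response"]]]],
    stringsAsFactors = FALSE
  )
  for (opt in c("group", "trait")) {
    if (map[[opt]] %in% names(raw)) df[[opt]] <- raw[[map[[opt]]]]
  }

  codes <- trimws(as.character(df$response))
  if (!identical(sort(unname(response_codes)), c("0", "1")) ||
      !all(codes %in% c("0", "1"))) {
    recoded <- rep(NA_integer_, length(codes))
    recoded[codes == as.character(response_codes[["action"]])] <- 1L
    recoded[codes == as.character(response_codes[["inaction"]])] <- 0L
    if (anyNA(recoded)) {
      bad <- unique(codes[is.na(recoded)])
      stop("unknown response code(s): ", paste(bad, collapse = ", "),
           " (expected '", response_codes[["action"]], "' or '",
           response_codes[["inaction"]], "')", call. = FALSE)
    }
    df$response <- recoded
  }
  as_battery(df, allow_incomplete = allow_incomplete)
}

#' Write a battery back to CSV
#'
#' Inverse of [read_battery()] with default codings: the canonical columns
#' round-trip exactly.
#'
#' @param battery a `can_battery`.
#' @param path output file path.
#' @export
write_battery <- function(battery, path) {
  stopifnot(inherits(battery, "can_battery"))
  cols <- intersect(c("participant", "dilemma", "norm", "consequence",
                      "response", "group", "trait"), names(battery))
  write.csv(as.data.frame(battery)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Empirical cell action probabilities for one participant
#'
#' @param battery a `can_battery`.
#' @param participant participant identifier present in the battery.
#' @return named numeric vector `c(p1, p2, p3, p4)` of observed action
#'   proportions in the four design cells.
#' @export
cell_probabilities <- function(battery, participant) {
  stopifnot(inherits(battery, "can_battery"))
  rows <- battery$participant == as.character(participant)
  if (!any(rows)) {
    stop("unknown participant: ", participant, call. = FALSE)
  }
  sub <- battery[rows, , drop = FALSE]
  acts <- tapply(sub$response, factor(sub$cell, levels = 1:4), sum)
  tots <- tapply(sub$response, factor(sub$cell, levels = 1:4), length)
  p <- as.numeric(acts) / as.numeric(tots)
  names(p) <- paste0("p", 1:4)
  p
}

#' Aggregate action/inaction counts per design cell
#'
#' Sums action counts and trial totals over participants (optionally within
#' one group). The result is the sufficient statistic for the group-level
#' processing-tree likelihood.
#'
#' @param battery a `can_battery`.
#' @param group optional group label; only participants carrying it are
#'   pooled.
#' @return a `cell_counts` object: list with integer vectors `actions` and
#'   `totals` of length 4.
#' @export
aggregate_counts <- function(battery, group = NULL) {
  stopifnot(inherits(battery, "can_battery"))
  sub <- battery
  if (!is.null(group)) {
    if (is.null(battery$group)) {
      stop("battery has no group column", call. = FALSE)
    }
    sub <- battery[as.character(battery$group) == as.character(group), ,
                   drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no participants in group '", group, "'", call. = FALSE)
    }
  }
  f <- factor(sub$cell, levels = 1:4)
  cell_counts(
    actions = as.integer(tapply(sub$response, f, sum, default = 0L)),
    totals = as.integer(tapply(sub$response, f, length, default = 0L))
  )
}

#' Cell counts container
#'
#' @param actions integer vector of action counts for cells 1-4.
#' @param totals integer vector of trial totals for cells 1-4.
#' @return a `cell_counts` object.
#' @export
cell_counts <- function(actions, totals) {
  actions <- as.numeric(actions)
  totals <- as.numeric(totals)
  if (length(actions) != 4L || length(totals) != 4L) {
    stop("actions and totals must each have length 4", call. = FALSE)
  }
  if (any(totals <= 0) || any(actions < 0) || any(actions > totals)) {
    stop("need 0 <= actions_i <= totals_i and totals_i > 0 in every cell",
         call. = FALSE)
  }
  structure(list(actions = actions, totals = totals), class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("Cell counts (action/total):",
      paste(sprintf("p%d: %d/%d", 1:4, as.integer(x$actions),
                    as.integer(x$totals)), collapse = "  "), "\n")
  invisible(x)
}
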