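# Synthetic populations and trial-level responses under the CNI, NCI, DNA
# or direct cell-probability processes, for parameter-recovery and
# calibration studies.
#
# Latent heterogeneity is modelled on the logit scale: each participant's
# parameters are plogis(rnorm(qlogis(mean), sd)), which respects the (0, 1)
# range by construction. A single seed governs all randomness; per-participant
# sub-seeds are split off it so results do not depend on participant order.

#' Specify a synthetic population
#'
#' @param n_participants number of participants to simulate.
#' @param process generating process: `"cni"`, `"nci"`, `"dna"` (latent
#'   parameter triple pushed through the corresponding forward equations) or
#'   `"direct"` (the four cell probabilities given directly).
#' @param latent_means numeric vector of latent means: length 3 for the tree
#'   processes (in each model's parameter order), length 4 (p1..p4) for
#'   `"direct"`. Values in \[0, 1\]; strictly interior when `latent_sds > 0`.
#' @param latent_sds logit-scale SDs of the latent draws; scalar or one per
#'   parameter. `0` (default) gives every participant exactly
#'   `latent_means`.
#' @param trials_per_cell trials per design cell per participant; the
#'   default 6 gives the standard 24-trial battery (4 cells x 6 trials).
#' @param seed integer seed governing all randomness of the population.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_participants, process = c("cni", "nci", "dna",
                                                        "direct"),
                            latent_means, latent_sds = 0,
                            trials_per_cell = 6L, seed = 1L) {
  process <- match.arg(process)
  k <- if (process == "direct") 4L else 3L
  latent_means <- as.numeric(latent_means)
  if (length(latent_means) != k) {
    stop("latent_means must have length ", k, " for process '", process, "'",
         call. = FALSE)
  }
  if (any(latent_means < 0 | latent_means > 1)) {
    stop("latent_means must lie in [0, 1]", call. = FALSE)
  }
  latent_sds <- rep_len(as.numeric(latent_sds), k)
  if (any(latent_sds < 0)) stop("latent_sds must be nonnegative", call. = FALSE)
  if (any(latent_sds > 0 & (latent_means <= 0 | latent_means >= 1))) {
    stop("latent_means must be strictly inside (0, 1) when latent_sds > 0",
         call. = FALSE)
  }
  n_participants <- as.integer(n_participants)
  trials_per_cell <- as.integer(trials_per_cell)
  if (n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (trials_per_cell < 1L) stop("trials_per_cell must be >= 1", call. = FALSE)
  structure(list(n_participants = n_participants, process = process,
                 latent_means = latent_means, latent_sds = latent_sds,
                 trials_per_cell = trials_per_cell, seed = as.integer(seed)),
            class = "population_spec")
}

.param_names_for <- function(process) {
  if (process == "direct") paste0("p", 1:4)
  else .get_model(process)$par_names
}

.split_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw per-participant latent parameters
#'
#' Logit-normal draws around the spec's latent means (exact means when the
#' SDs are zero). Reproducible given the spec's seed, and each participant's
#' draw depends only on their own sub-seed.
#'
#' @param spec a [population_spec()].
#' @return a `latent_population` data frame: `participant` plus one column
#'   per latent parameter; attributes `process` and `spec`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  nm <- .param_names_for(spec$process)
  k <- length(nm)
  n <- spec$n_participants
  lat <- matrix(rep(spec$latent_means, each = n), nrow = n,
                dimnames = list(NULL, nm))
  if (any(spec$latent_sds > 0)) {
    seeds <- .split_seeds(spec$seed, n)
    mu <- qlogis(spec$latent_means)
    for (i in seq_len(n)) {
      set.seed(seeds[i])
      z <- rnorm(k, mean = mu, sd = spec$latent_sds)
      lat[i, ] <- ifelse(spec$latent_sds > 0, plogis(z), spec$latent_means)
    }
  }
  out <- data.frame(participant = sprintf("p%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(lat))
  attr(out, "process") <- spec$process
  attr(out, "spec") <- spec
  class(out) <- c("latent_population", "data.frame")
  out
}

#' Simulate trial-level responses from latent parameters
#'
#' Each participant's responses in design cell i are independent
#' Bernoulli(p_i) draws, with p_i from the generating process's forward
#' equations (or the direct cell probabilities). The returned battery passes
#' [as_battery()] validation.
#'
#' @param latents a `latent_population` from [simulate_population()].
#' @param trials_per_cell trials per cell (default: the spec's value).
#' @param seed integer seed for the response draws.
#' @param group optional group label stored in the battery's `group` column.
#' @param id_prefix optional prefix for participant ids (useful when
#'   combining simulated groups).
#' @return a `can_battery`.
#' @export
simulate_responses <- function(latents, trials_per_cell = NULL, seed = 1L,
                               group = NULL, id_prefix = "") {
  stopifnot(inherits(latents, "latent_population"))
  process <- attr(latents, "process")
  spec <- attr(latents, "spec")
  K <- if (is.null(trials_per_cell)) spec$trials_per_cell
       else as.integer(trials_per_cell)
  nm <- .param_names_for(process)
  n <- nrow(latents)
  fwd <- if (process == "direct") identity else .get_model(process)$forward
  seeds <- .split_seeds(seed, n)

  norm_of_cell <- .norm_levels[c(1, 1, 2, 2)]
  cons_of_cell <- .consequence_levels[c(1, 2, 1, 2)]
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    p <- fwd(as.numeric(unlist(latents[i, nm])))
    set.seed(seeds[i])
    resp <- unlist(lapply(1:4, function(cell) rbinom(K, 1L, p[cell])))
    blocks[[i]] <- data.frame(
      participant = paste0(id_prefix, latents$participant[i]),
      dilemma = paste0("d", rep(1:4, each = K), "_", rep(seq_len(K), 4)),
      norm = rep(norm_of_cell, each = K),
      consequence = rep(cons_of_cell, each = K),
      response = resp,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, blocks)
  if (!is.null(group)) df$group <- group
  as_battery(df)
}

#' Simulate a full battery from a population spec
#'
#' Convenience wrapper: draws the latent population and the trial-level
#' responses with sub-seeds derived from the spec's seed.
#'
#' @inheritParams simulate_responses
#' @param spec a [population_spec()].
#' @return a `can_battery` with the spec attached as attribute `spec`.
#' @export
simulate_battery <- function(spec, group = NULL, id_prefix = "") {
  stopifnot(inherits(spec, "population_spec"))
  seeds <- .split_seeds(spec$seed, 2L)
  spec_pop <- spec
  spec_pop$seed <- seeds[1]
  latents <- simulate_population(spec_pop)
  bat <- simulate_responses(latents, trials_per_cell = spec$trials_per_cell,
                            seed = seeds[2], group = group,
                            id_prefix = id_prefix)
  attr(bat, "spec") <- spec
  attr(bat, "latents") <- latents
  bat
}

#' Combine simulated group batteries
#'
#' Row-binds batteries (e.g. one per simulated group) into a single
#' validated battery. Participant ids must not collide; use
#' `id_prefix` in the simulators to keep them distinct.
#'
#' @param ... `can_battery` objects.
#' @return a `can_battery`.
#' @export
combine_batteries <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "can_battery")))
  ids <- unlist(lapply(parts, function(b) unique(b$participant)))
  if (anyDuplicated(ids)) {
    stop("participant ids collide across batteries; use id_prefix= when ",
         "simulating", call. = FALSE)
  }
  cols <- Reduce(union, lapply(parts, names))
  parts <- lapply(parts, function(b) {
    d <- as.data.frame(b)
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  })
  as_battery(do.call(rbind, parts))
}
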