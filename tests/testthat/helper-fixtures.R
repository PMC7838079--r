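# Fixture builders: batteries constructed in code from per-cell action
# counts, so tests control the empirical cell probabilities exactly.

.cell_norms <- c("proscriptive", "proscriptive", "prescriptive", "prescriptive")
.cell_cons <- c("benefits_greater", "benefits_smaller",
                "benefits_greater", "benefits_smaller")

# one participant's rows: actions[i] action responses out of k trials in cell i
participant_rows <- function(id, actions, k = 6L, group = NULL,
                             trait = NULL) {
  stopifnot(length(actions) == 4L, all(actions >= 0), all(actions <= k))
  df <- data.frame(
    participant = id,
    dilemma = paste0("d", rep(1:4, each = k), "_", rep(seq_len(k), 4)),
    norm = rep(.cell_norms, each = k),
    consequence = rep(.cell_cons, each = k),
    response = unlist(lapply(1:4, function(i) {
      c(rep(1L, actions[i]), rep(0L, k - actions[i]))
    })),
    stringsAsFactors = FALSE
  )
  if (!is.null(group)) df$group <- group
  if (!is.null(trait)) df$trait <- trait
  df
}

# battery with one row of `action_matrix` (participants x 4 cells) per person
make_battery <- function(action_matrix, k = 6L, ids = NULL, groups = NULL,
                         traits = NULL) {
  action_matrix <- rbind(action_matrix)
  n <- nrow(action_matrix)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  blocks <- lapply(seq_len(n), function(i) {
    participant_rows(ids[i], action_matrix[i, ], k = k,
                     group = if (!is.null(groups)) groups[i],
                     trait = if (!is.null(traits)) traits[i])
  })
  as_battery(do.call(rbind, blocks))
}

# battery whose empirical cell probabilities are exactly `cells` (requires
# cells * k to be whole numbers), replicated over n participants
exact_battery <- function(cells, k, n = 1L, ids = NULL, groups = NULL) {
  actions <- round(cells * k)
  stopifnot(max(abs(actions - cells * k)) < 1e-9)
  make_battery(matrix(rep(actions, each = n), nrow = n), k = k, ids = ids,
               groups = groups)
}
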