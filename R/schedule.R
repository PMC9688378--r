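#' Pseudo-randomized session schedule
#'
#' Builds the trial order for one session: `n_blocks` blocks, each with
#' `trials_per_condition` trials of every condition, ordered so that all
#' conditions precede one another to an equal extent. Concretely, for every
#' ordered pair of distinct conditions (a, b) the number of immediate
#' transitions a -> b and b -> a over the whole session differ by at most
#' one. The order is found by a greedy constrained shuffle (each step picks,
#' among the conditions still owed in the block, one that minimises the
#' current transition imbalance, with seeded random tie-breaks) and is
#' rejected and retried if the balance invariant fails.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_condition Trials of each condition per block (default 13).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A `session_schedule` list: `trials` (data.frame with `block`,
#'   `trial`, `condition`), `n_blocks`, `trials_per_condition`, `seed`.
#' @export
#' @examples
#' sch <- make_schedule(4, 13, seed = 7)
#' nrow(sch$trials)  # 156
make_schedule <- function(n_blocks = 4L, trials_per_condition = 13L, seed = 1L) {
  if (!is.numeric(n_blocks) || n_blocks < 1 || n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(trials_per_condition) || trials_per_condition < 1 ||
      trials_per_condition != round(trials_per_condition)) {
    stop("`trials_per_condition` must be a positive integer", call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  trials_per_condition <- as.integer(trials_per_condition)
  labels <- names(btt_conditions())

  with_seed(seed, {
    for (attempt in seq_len(200L)) {
      seq_out <- schedule_attempt(n_blocks, trials_per_condition, labels)
      if (transitions_balanced(seq_out, labels)) {
        trials <- data.frame(
          block = rep(seq_len(n_blocks), each = 3L * trials_per_condition),
          trial = seq_along(seq_out),
          condition = seq_out,
          stringsAsFactors = FALSE
        )
        return(structure(
          list(trials = trials, n_blocks = n_blocks,
               trials_per_condition = trials_per_condition, seed = seed),
          class = "session_schedule"
        ))
      }
    }
    stop("could not balance condition transitions after 200 attempts",
         call. = FALSE)
  })
}

# One greedy pass over all blocks; returns the full condition sequence.
schedule_attempt <- function(n_blocks, trials_per_condition, labels) {
  k <- length(labels)
  trans <- matrix(0L, k, k, dimnames = list(labels, labels))
  out <- character(0L)
  prev <- NA_character_
  for (b in seq_len(n_blocks)) {
    remaining <- stats::setNames(rep(trials_per_condition, k), labels)
    for (i in seq_len(k * trials_per_condition)) {
      cand <- names(remaining)[remaining > 0L]
      if (is.na(prev)) {
        pick <- sample(cand, 1L)
      } else {
        # prefer the transition currently least used relative to its reverse
        score <- vapply(cand, function(cc) {
          if (cc == prev) 0L else trans[prev, cc] - trans[cc, prev]
        }, integer(1L))
        best <- cand[score == min(score)]
        pick <- if (length(best) == 1L) best else sample(best, 1L)
      }
      if (!is.na(prev)) trans[prev, pick] <- trans[prev, pick] + 1L
      out <- c(out, pick)
      remaining[pick] <- remaining[pick] - 1L
      prev <- pick
    }
  }
  out
}

# Check the |a->b - b->a| <= 1 invariant for all distinct ordered pairs.
transitions_balanced <- function(seq_out, labels) {
  tc <- transition_counts(seq_out, labels)
  for (a in labels) {
    for (b in labels) {
      if (a < b && abs(tc[a, b] - tc[b, a]) > 1L) return(FALSE)
    }
  }
  TRUE
}

#' Condition transition counts of a schedule
#'
#' @param seq_out Character vector of condition labels in trial order.
#' @param labels Condition labels (defaults to the three task conditions).
#' @return Integer matrix of counts of immediate transitions a -> b.
#' @export
transition_counts <- function(seq_out, labels = names(btt_conditions())) {
  k <- length(labels)
  tc <- matrix(0L, k, k, dimnames = list(labels, labels))
  if (length(seq_out) >= 2L) {
    for (i in seq_len(length(seq_out) - 1L)) {
      tc[seq_out[i], seq_out[i + 1L]] <- tc[seq_out[i], seq_out[i + 1L]] + 1L
    }
  }
  tc
}
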