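## Event-related design generation: one-back history-balanced trial orders
## and exact trial timing.

#' Generate a trial sequence balanced for one-trial-back history
#'
#' Produces an order of condition labels in which every condition occurs
#' exactly `reps` times among analyzed trials and every ordered pair of
#' conditions (self-pairs included) occurs equally often as a consecutive
#' transition, so each trial is equally likely to be preceded by any
#' condition. A single unanalyzed dummy trial is prepended so that the
#' history of the first analyzed trial is balanced too.
#'
#' The construction draws a random Eulerian circuit on the complete digraph
#' over conditions (self-loops included), each arc duplicated
#' `reps / n_conditions` times, via Hierholzer's algorithm with seeded random
#' arc choice. A circuit with `n_conditions * reps` arcs visits
#' `n_conditions * reps + 1` vertices; the first visit is the dummy trial and
#' its label necessarily equals the last trial's label (the circuit closes).
#'
#' @param n_conditions Number of distinct condition labels.
#' @param reps Repetitions of each condition among analyzed trials; must be a
#'   positive multiple of `n_conditions` so the transition matrix can be
#'   exactly uniform.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param labels Optional character vector of condition labels (default
#'   `"c1"`, ..., `"cN"`).
#' @param run_id Integer run identifier stored with the sequence.
#' @return A `trial_sequence` object: list with `conditions` (character,
#'   length `n_conditions * reps + 1`), `dummy_first = TRUE`, `labels`,
#'   `n_conditions`, `reps`, `run_id`.
#' @examples
#' s <- generate_balanced_sequence(11, 11, seed = 1)
#' length(s$conditions) # 122 trials: 121 analyzed plus one dummy
#' @export
generate_balanced_sequence <- function(n_conditions, reps, seed,
                                       labels = NULL, run_id = 1L) {
  abort_if(n_conditions < 1, "n_conditions must be >= 1")
  abort_if(reps < 1 || reps %% n_conditions != 0,
           "reps (%s) must be a positive multiple of n_conditions (%s) so that every ordered pair of conditions can occur equally often",
           reps, n_conditions)
  if (is.null(labels)) labels <- paste0("c", seq_len(n_conditions))
  abort_if(length(labels) != n_conditions, "labels must have length n_conditions")

  mult <- reps %/% n_conditions # copies of each ordered pair
  n <- n_conditions
  path <- with_seed(seed, {
    # remaining[i, j]: arcs left from i to j
    remaining <- matrix(mult, n, n)
    out_left <- rowSums(remaining)
    start <- sample.int(n, 1)
    # Hierholzer: iterative, with random arc choice at each step
    stack <- c(start)
    circuit <- integer(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      if (out_left[v] > 0) {
        nxt <- which(remaining[v, ] > 0)
        w <- if (length(nxt) == 1) nxt else sample(nxt, 1, prob = remaining[v, nxt])
        remaining[v, w] <- remaining[v, w] - 1
        out_left[v] <- out_left[v] - 1
        stack <- c(stack, w)
      } else {
        circuit <- c(circuit, v)
        stack <- stack[-length(stack)]
      }
    }
    rev(circuit)
  })
  stopifnot(length(path) == n * reps + 1, path[1] == path[length(path)])
  structure(
    list(conditions = labels[path], dummy_first = TRUE, labels = labels,
         n_conditions = n, reps = reps, run_id = as.integer(run_id)),
    class = "trial_sequence"
  )
}

#' Count one-back transitions in a trial sequence
#'
#' @param seq A `trial_sequence` or character vector of condition labels
#'   (dummy first).
#' @return Square matrix of counts of consecutive ordered pairs, rows =
#'   preceding condition.
#' @export
transition_counts <- function(seq) {
  conds <- if (inherits(seq, "trial_sequence")) seq$conditions else seq
  labs <- if (inherits(seq, "trial_sequence")) seq$labels else sort(unique(conds))
  from <- factor(conds[-length(conds)], levels = labs)
  to <- factor(conds[-1], levels = labs)
  table(from, to)
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("trial_sequence: %d conditions x %d reps = %d analyzed trials + 1 dummy (run %d)\n",
              x$n_conditions, x$reps, x$n_conditions * x$reps, x$run_id))
  invisible(x)
}

#' Assign trial timing to a balanced sequence
#'
#' Lays trials out in contiguous fixed-duration slots after a lead-in
#' fixation interval. Each trial starts with a brief stimulus presentation
#' followed by a variable delay of 1.2 s (75% of trials) or 1.4 s (25%),
#' after which a response cue appears; the cue is removed 0.3 s before the
#' next trial onset. Delay counts follow the 3:1 split by nearest integer
#' (ties toward 1.2 s) and are assigned to trials by a seeded shuffle.
#'
#' @param seq A `trial_sequence`.
#' @param trial_duration Trial slot length in seconds (default 3).
#' @param lead_fixation,tail_fixation Fixation bookends in seconds (default 9).
#' @param stimulus_duration Stimulus presentation in seconds (default 0.3).
#' @param delays Candidate delays in seconds (default `c(1.2, 1.4)`).
#' @param delay_props Proportions for `delays` (default `c(0.75, 0.25)`).
#' @param seed Integer seed for the delay shuffle.
#' @return An `event_table`: data.frame with columns `onset`, `duration`,
#'   `trial_type`, `stimulus_duration`, `delay`, `cue_onset`, `cue_offset`,
#'   `dummy`, `run_id`, plus attributes `total_duration` and `run_id`.
#' @examples
#' s <- generate_balanced_sequence(11, 11, seed = 1)
#' ev <- assign_timing(s, seed = 2)
#' attr(ev, "total_duration") # 384 s for 122 trials with 9 s bookends
#' @export
assign_timing <- function(seq, trial_duration = 3, lead_fixation = 9,
                          tail_fixation = 9, stimulus_duration = 0.3,
                          delays = c(1.2, 1.4), delay_props = c(0.75, 0.25),
                          seed = 1L) {
  stopifnot(inherits(seq, "trial_sequence") || is.character(seq))
  conds <- if (inherits(seq, "trial_sequence")) seq$conditions else seq
  run_id <- if (inherits(seq, "trial_sequence")) seq$run_id else 1L
  n <- length(conds)
  cue_gap <- 0.3 # cue offset precedes next onset by this much
  abort_if(trial_duration <= 0 || lead_fixation < 0 || tail_fixation < 0,
           "durations must be positive")
  abort_if(trial_duration < stimulus_duration + max(delays) + cue_gap,
           "trial_duration too short for stimulus + delay + cue window")
  total <- lead_fixation + trial_duration * n + tail_fixation

  if (n == 0) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     trial_type = character(0), stimulus_duration = numeric(0),
                     delay = numeric(0), cue_onset = numeric(0),
                     cue_offset = numeric(0), dummy = integer(0),
                     run_id = integer(0))
  } else {
    # 3:1 delay allocation by nearest count, ties toward the short delay
    n1 <- round(n * delay_props[1])
    delay_pool <- c(rep(delays[1], n1), rep(delays[2], n - n1))
    delay_vec <- with_seed(seed, sample(delay_pool))
    onset <- lead_fixation + trial_duration * (seq_len(n) - 1)
    ev <- data.frame(
      onset = onset,
      duration = rep(trial_duration, n),
      trial_type = conds,
      stimulus_duration = rep(stimulus_duration, n),
      delay = delay_vec,
      cue_onset = onset + stimulus_duration + delay_vec,
      cue_offset = onset + trial_duration - cue_gap,
      dummy = c(1L, rep(0L, n - 1)),
      run_id = rep(as.integer(run_id), n),
      stringsAsFactors = FALSE
    )
  }
  attr(ev, "total_duration") <- total
  attr(ev, "run_id") <- as.integer(run_id)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write or read an events table as BIDS-style TSV
#'
#' Columns: onset, duration, trial_type, delay, dummy.
#'
#' @param ev An `event_table`.
#' @param path File path.
#' @return `read_events_tsv` returns an `event_table` (total duration is
#'   recovered only if a `total_duration` attribute comment is not needed by
#'   the caller).
#' @export
write_events_tsv <- function(ev, path) {
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$trial_type, delay = ev$delay,
                    dummy = ev$dummy)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("event_table", "data.frame")
  df
}
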