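#' Define the stable/volatile associative-learning task
#'
#' Constructs the design of a two-block probabilistic associative-learning
#' task. In the stable block one shape carries a constant high reward
#' probability (default 75%, the other shape 25%). In the volatile block the
#' high-probability assignment (default 80%/20%) reverses between the two
#' shapes every `run_length` trials. Defaults reproduce the canonical
#' 180-trial design: 80 stable trials plus 100 volatile trials with
#' reversals every 20 trials.
#'
#' Outcomes of the two shapes are complementary: on every trial exactly one
#' shape is rewarded, so the low-probability shape's reward probability is
#' `1 - p_high`.
#'
#' @param stable_trials number of trials in the stable block.
#' @param volatile_trials number of trials in the volatile block; must be a
#'   multiple of `run_length`.
#' @param stable_p_high probability that the high shape is rewarded on a
#'   stable-block trial, in (0.5, 1].
#' @param volatile_p_high probability that the currently-high shape is
#'   rewarded on a volatile-block trial, in (0.5, 1].
#' @param run_length trials per volatile contingency run (reversal period).
#' @param block_order `"stable_first"` or `"volatile_first"`. Block order was
#'   counterbalanced across subjects in the original task; downstream
#'   analyses are order-agnostic.
#' @param initial_high_shape which shape (`"A"` or `"B"`) starts as the
#'   high-probability shape in each block.
#' @return an object of class `task_design`.
#' @seealso [make_schedule()], [reversal_points()]
#' @export
task_design <- function(stable_trials = 80L,
                        volatile_trials = 100L,
                        stable_p_high = 0.75,
                        volatile_p_high = 0.80,
                        run_length = 20L,
                        block_order = c("stable_first", "volatile_first"),
                        initial_high_shape = c("A", "B")) {
  block_order <- match.arg(block_order)
  initial_high_shape <- match.arg(initial_high_shape)
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
        x != round(x)) {
      stop_config(nm, "must be a positive whole number")
    }
  }
  chk_count(stable_trials, "stable_trials")
  chk_count(volatile_trials, "volatile_trials")
  chk_count(run_length, "run_length")
  chk_p <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) ||
        p <= 0.5 || p > 1) {
      stop_config(nm, "must be a probability in (0.5, 1]")
    }
  }
  chk_p(stable_p_high, "stable_p_high")
  chk_p(volatile_p_high, "volatile_p_high")
  if (volatile_trials %% run_length != 0) {
    stop_config("volatile_trials", sprintf(
      "must be divisible by run_length (%d %%%% %d != 0)",
      as.integer(volatile_trials), as.integer(run_length)))
  }
  structure(
    list(stable_trials = as.integer(stable_trials),
         volatile_trials = as.integer(volatile_trials),
         stable_p_high = stable_p_high,
         volatile_p_high = volatile_p_high,
         run_length = as.integer(run_length),
         block_order = block_order,
         initial_high_shape = initial_high_shape),
    class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Associative-learning task design\n")
  cat(sprintf("  stable:   %d trials, p(high rewarded) = %.2f\n",
              x$stable_trials, x$stable_p_high))
  cat(sprintf("  volatile: %d trials, p(high rewarded) = %.2f, reversal every %d trials\n",
              x$volatile_trials, x$volatile_p_high, x$run_length))
  cat(sprintf("  block order: %s; initial high shape: %s\n",
              x$block_order, x$initial_high_shape))
  invisible(x)
}

other_shape <- function(shape) ifelse(shape == "A", "B", "A")

# Deterministic high-shape trajectory for one block.
block_high_shape <- function(n, start, run_length = NULL) {
  if (is.null(run_length)) return(rep(start, n))
  runs <- n / run_length
  shapes <- rep(c(start, other_shape(start)), length.out = runs)
  rep(shapes, each = run_length)
}

#' Realize a trial schedule from a task design
#'
#' Generates the per-trial contingency trajectory and realized outcome
#' assignment. The high-probability shape trajectory is a deterministic
#' function of the design (constant in the stable block; flipping every
#' `run_length` trials in the volatile block). Outcome realization is a
#' single Bernoulli draw per trial: with probability `p_high` of the current
#' block the high shape is the rewarded one, otherwise the other shape is.
#' The two shapes' outcomes are therefore complementary — exactly one shape
#' is rewarded on every trial — matching the coupled reward schedules of
#' reversal-learning tasks with 75/25 and 80/20 contingencies.
#'
#' @param design a [task_design()].
#' @param seed integer seed; the schedule is bit-identical given the same
#'   seed. Only the outcome draws consume randomness.
#' @return a `trial_schedule`: a data.frame with columns `trial` (0-based),
#'   `block` (`"stable"`/`"volatile"`), `high_shape`, and `rewarded_shape`,
#'   with the design and seed attached as attributes.
#' @examples
#' sched <- make_schedule(task_design(), seed = 1)
#' table(sched$block)
#' @export
make_schedule <- function(design = task_design(), seed = 1L) {
  if (!inherits(design, "task_design")) {
    stop_config("design", "must be a task_design object")
  }
  stable <- data.frame(
    block = "stable",
    high_shape = block_high_shape(design$stable_trials,
                                  design$initial_high_shape),
    p_high = design$stable_p_high,
    stringsAsFactors = FALSE)
  volatile <- data.frame(
    block = "volatile",
    high_shape = block_high_shape(design$volatile_trials,
                                  design$initial_high_shape,
                                  design$run_length),
    p_high = design$volatile_p_high,
    stringsAsFactors = FALSE)
  blocks <- if (design$block_order == "stable_first") {
    rbind(stable, volatile)
  } else {
    rbind(volatile, stable)
  }
  n <- nrow(blocks)
  high_rewarded <- with_seed(seed, stats::rbinom(n, 1L, blocks$p_high))
  sched <- data.frame(
    trial = seq_len(n) - 1L,
    block = blocks$block,
    high_shape = blocks$high_shape,
    rewarded_shape = ifelse(high_rewarded == 1L, blocks$high_shape,
                            other_shape(blocks$high_shape)),
    stringsAsFactors = FALSE)
  attr(sched, "design") <- design
  attr(sched, "seed") <- as.integer(seed)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Trial indices at which the reward contingency reverses
#'
#' @param schedule a `trial_schedule`.
#' @return integer vector of 0-based trial indices at which `high_shape`
#'   differs from the preceding trial, strictly increasing; empty when the
#'   contingency never changes (e.g. a stable block taken alone).
#' @export
reversal_points <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule") ||
            all(c("trial", "high_shape") %in% names(schedule)))
  hs <- schedule$high_shape
  if (length(hs) < 2L) return(integer(0))
  idx <- which(hs[-1L] != hs[-length(hs)])
  as.integer(schedule$trial[idx + 1L])
}

#' Write / read a trial schedule as delimited text
#'
#' Schedules round-trip as TSV with columns `trial`, `block`, `high_shape`,
#' `rewarded_shape`.
#'
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @rdname schedule_io
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial", "block", "high_shape", "rewarded_shape")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("schedule file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("trial_schedule", "data.frame")
  x
}
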