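#' Condition specifications
#'
#' A condition couples a stimulus intensity (low/high pain) with the pneumatic
#' rise time: 1 s (fast; the pressure steps by 1/10 of the target every 0.1 s)
#' or 3 s (slow; 1/30 steps), always followed by a 3 s hold at target.
#' Study one additionally used a non-painful touch intensity, which the
#' classification stage discards. The binary class label is 0 for low and
#' 1 for high pain; touch trials carry label `NA`.
#'
#' @param intensity One of `"touch"`, `"low"`, `"high"`.
#' @param rise_time Rise time in seconds, 1 or 3.
#' @param hold_time Plateau duration in seconds (fixed at 3).
#' @return A one-row tibble with columns `condition`, `intensity`,
#'   `rise_time`, `hold_time`, `label`.
#' @export
#' @examples
#' condition_spec("high", rise_time = 1)
condition_spec <- function(intensity = c("low", "high", "touch"),
                           rise_time = 1, hold_time = 3) {
  intensity <- match.arg(intensity)
  if (!rise_time %in% c(1, 3)) {
    stop_painerd("`rise_time` must be 1 (fast) or 3 (slow) seconds.",
                 "painerd_config_error")
  }
  if (hold_time != 3) {
    stop_painerd("`hold_time` is fixed at 3 seconds in this paradigm.",
                 "painerd_config_error")
  }
  rise_tag <- if (rise_time == 1) "fast" else "slow"
  tibble::tibble(
    condition = if (intensity == "touch") "touch" else paste(intensity, rise_tag, sep = "_"),
    intensity = intensity,
    rise_time = rise_time,
    hold_time = hold_time,
    label = switch(intensity, low = 0L, high = 1L, touch = NA_integer_)
  )
}

#' Study designs for the two pressure-pain experiments
#'
#' `study_design("one")` reproduces the training-study layout: 3 blocks of
#' 40 trials over three intensities (touch, low, high) with rotating
#' per-block quotas of 13/13/14 so that each condition occurs 40 times in
#' total (120 trials). `study_design("two")` is the external-validation
#' layout: 3 blocks of 48 trials over the 2 x 2 intensity-by-rise-time
#' design, 12 trials per condition per block (144 trials). Both studies
#' pseudo-randomise so that no two consecutive trials share a condition.
#'
#' @param study `"one"` or `"two"`.
#' @return A list of class `study_design` with elements `study_id`,
#'   `n_blocks`, `trials_per_block`, `conditions` (tibble of condition
#'   specs), `per_block_quota` (matrix block x condition),
#'   `min_isi`, `constraint_no_repeat`.
#' @export
#' @examples
#' d <- study_design("one")
#' d$per_block_quota
study_design <- function(study = c("one", "two")) {
  study <- match.arg(study)
  if (study == "one") {
    conds <- dplyr::bind_rows(
      condition_spec("touch"),
      condition_spec("low", 1),
      condition_spec("high", 1)
    )
    # rotate which condition receives the 14-trial quota so every
    # condition totals 40 over the three blocks
    quota <- rbind(c(14, 13, 13), c(13, 14, 13), c(13, 13, 14))
    colnames(quota) <- conds$condition
    design <- list(
      study_id = "one", n_blocks = 3L, trials_per_block = 40L,
      conditions = conds, per_block_quota = quota,
      min_isi = 16, constraint_no_repeat = TRUE
    )
  } else {
    conds <- dplyr::bind_rows(
      condition_spec("low", 1), condition_spec("low", 3),
      condition_spec("high", 1), condition_spec("high", 3)
    )
    quota <- matrix(12L, nrow = 3, ncol = 4,
                    dimnames = list(NULL, conds$condition))
    design <- list(
      study_id = "two", n_blocks = 3L, trials_per_block = 48L,
      conditions = conds, per_block_quota = quota,
      min_isi = 16, constraint_no_repeat = TRUE
    )
  }
  class(design) <- "study_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  q <- design$per_block_quota
  if (nrow(q) != design$n_blocks) {
    stop_painerd("Quota matrix must have one row per block.",
                 "painerd_config_error")
  }
  if (!all(rowSums(q) == design$trials_per_block)) {
    stop_painerd("Per-block quotas must sum to `trials_per_block` in every block.",
                 "painerd_config_error")
  }
  invisible(design)
}

#' Generate a pseudo-randomised trial schedule
#'
#' Draws a trial order satisfying the design's per-block condition quotas
#' and, when required, the constraint that no two consecutive trials share
#' a condition (enforced across block boundaries within the schedule).
#' Sampling is sequential with backtracking-free feasibility: at each slot
#' a condition is drawn with probability proportional to its remaining
#' quota, restricted to conditions whose choice leaves a colourable
#' remainder (no remaining count may exceed half the remaining slots,
#' rounded up).
#'
#' @param design A [study_design()] (or compatible list).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A tibble with columns `block`, `trial` (within block),
#'   `trial_global`, `condition`, `intensity`, `rise_time`, `label`.
#' @export
#' @examples
#' sched <- make_schedule(study_design("one"), seed = 1)
#' nrow(sched)  # 120
make_schedule <- function(design, seed = 1L) {
  validate_design(design)
  conds <- design$per_block_quota
  cond_ids <- colnames(conds)
  if (design$constraint_no_repeat) {
    if (length(cond_ids) < 2) {
      stop_painerd("No-repeat constraint needs at least two conditions.",
                   "painerd_schedule_error")
    }
    # feasibility: within a block no quota may exceed ceiling(block/2);
    # rotation across blocks keeps the boundary constraint satisfiable
    if (any(conds > ceiling(design$trials_per_block / 2))) {
      stop_painerd(
        "Infeasible design: a per-block quota exceeds half the block length, so a no-repeat ordering cannot exist.",
        "painerd_schedule_error")
    }
  }
  with_seed(seed, {
    out <- vector("list", design$n_blocks)
    prev <- NA_character_
    for (b in seq_len(design$n_blocks)) {
      remaining <- conds[b, ]
      order_b <- character(design$trials_per_block)
      for (i in seq_len(design$trials_per_block)) {
        slots_left <- design$trials_per_block - i + 1L
        cand <- cond_ids[remaining > 0]
        if (design$constraint_no_repeat) {
          cand <- setdiff(cand, prev)
          # keep only choices that leave an orderable remainder: with n slots
          # left and the just-picked condition forbidden next, a no-repeat
          # order exists iff max count <= ceil(n/2) and the forbidden
          # condition's count <= floor(n/2)
          ok <- vapply(cand, function(cid) {
            rem <- remaining
            rem[cid] <- rem[cid] - 1L
            n2 <- slots_left - 1L
            if (n2 == 0L) return(TRUE)
            max(rem) <= ceiling(n2 / 2) && rem[cid] <= floor(n2 / 2)
          }, logical(1))
          cand <- cand[ok]
        }
        if (length(cand) == 0) {
          stop_painerd(
            "Schedule sampling reached a dead end; quotas and the no-repeat constraint are jointly infeasible.",
            "painerd_schedule_error")
        }
        w <- remaining[cand]
        pick <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
        order_b[i] <- pick
        remaining[pick] <- remaining[pick] - 1L
        prev <- pick
      }
      out[[b]] <- tibble::tibble(block = b, trial = seq_along(order_b),
                                 condition = order_b)
    }
    sched <- dplyr::bind_rows(out)
    sched$trial_global <- seq_len(nrow(sched))
    sched <- dplyr::left_join(sched, design$conditions, by = "condition")
    sched[, c("block", "trial", "trial_global", "condition",
              "intensity", "rise_time", "hold_time", "label")]
  })
}

#' Check schedule constraints
#'
#' Verifies per-block quotas and (optionally) the no-consecutive-repeat
#' constraint for a schedule against its design.
#'
#' @param schedule A schedule tibble from [make_schedule()].
#' @param design The [study_design()] it was generated from.
#' @return `TRUE` invisibly; aborts with a descriptive error otherwise.
#' @export
check_schedule <- function(schedule, design) {
  counts <- table(schedule$block, schedule$condition)
  q <- design$per_block_quota
  for (b in seq_len(design$n_blocks)) {
    for (cid in colnames(q)) {
      got <- if (cid %in% colnames(counts)) counts[as.character(b), cid] else 0L
      if (got != q[b, cid]) {
        stop_painerd(sprintf("Block %d has %d '%s' trials; quota is %d.",
                             b, got, cid, q[b, cid]), "painerd_schedule_error")
      }
    }
  }
  if (isTRUE(design$constraint_no_repeat)) {
    reps <- sum(schedule$condition[-1] == schedule$condition[-nrow(schedule)])
    if (reps > 0) {
      stop_painerd(sprintf("%d adjacent trials share a condition.", reps),
                   "painerd_schedule_error")
    }
  }
  invisible(TRUE)
}
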