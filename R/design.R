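# Trial scheduler reproducing the speed-matching experiment: 12 conditions
# (3 reference/test contrast pairs x 4 reference speeds) split into a
# low-speed and a high-speed block, 5 sessions, with 2 (low) or 8 (high)
# staircases per condition per session and 35 trials per staircase.

CONTRAST_PAIRS <- list(c(0.03, 0.15), c(0.03, 0.95), c(0.15, 0.95))
REFERENCE_SPEEDS <- c(1, 4, 8, 12)

#' Build the experimental design
#'
#' Enumerates all conditions (contrast pairs crossed with reference speeds)
#' and attaches the block structure and session/staircase counts. Defaults
#' reproduce the standard design: 12 conditions; the six conditions at 1 and
#' 4 deg/s form the low-speed block (2 staircases per condition per session,
#' 420 trials per session), the six at 8 and 12 deg/s the high-speed block
#' (8 staircases per condition per session, 1680 trials per session); 5
#' sessions in total.
#'
#' @param reference_speeds reference grating speeds in deg/s.
#' @param contrast_pairs list of `c(c_ref, c_test)` contrast fractions with
#'   `c_ref < c_test`.
#' @param sessions number of sessions.
#' @param staircases_per_session named vector or list with elements
#'   `low_speed` and `high_speed`.
#' @param trials_per_staircase trials per staircase.
#' @param spatial_frequency grating spatial frequency in cycles/deg.
#' @param low_speed_max largest reference speed assigned to the low-speed
#'   block.
#' @return an object of class `experiment_design`; `$conditions` is a data
#'   frame with columns `condition_id`, `v_ref`, `c_ref`, `c_test`, `block`.
#' @export
build_design <- function(reference_speeds = REFERENCE_SPEEDS,
                         contrast_pairs = CONTRAST_PAIRS,
                         sessions = 5,
                         staircases_per_session = c(low_speed = 2, high_speed = 8),
                         trials_per_staircase = 35,
                         spatial_frequency = 2,
                         low_speed_max = 4) {
  if (any(reference_speeds <= 0)) stop("reference speeds must be positive")
  bad <- vapply(contrast_pairs, function(p) {
    length(p) != 2 || any(p <= 0) || any(p >= 1) || p[1] >= p[2]
  }, logical(1))
  if (any(bad)) {
    stop("each contrast pair must be fractions in (0,1) with c_ref < c_test")
  }
  if (sessions < 1 || trials_per_staircase < 1) {
    stop("sessions and trials_per_staircase must be >= 1")
  }
  sps <- as.list(staircases_per_session)
  if (is.null(sps$low_speed) || is.null(sps$high_speed) ||
      sps$low_speed < 1 || sps$high_speed < 1) {
    stop("staircases_per_session needs positive low_speed and high_speed counts")
  }
  grid <- expand.grid(pair = seq_along(contrast_pairs),
                      v_ref = reference_speeds)
  conditions <- data.frame(
    v_ref = grid$v_ref,
    c_ref = vapply(contrast_pairs[grid$pair], `[`, numeric(1), 1),
    c_test = vapply(contrast_pairs[grid$pair], `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )
  conditions$block <- ifelse(conditions$v_ref <= low_speed_max,
                             "low_speed", "high_speed")
  conditions$condition_id <- sprintf("v%g_c%g_%g", conditions$v_ref,
                                     100 * conditions$c_ref,
                                     100 * conditions$c_test)
  conditions <- conditions[, c("condition_id", "v_ref", "c_ref", "c_test", "block")]
  structure(
    list(conditions = conditions,
         sessions = as.integer(sessions),
         staircases_per_session = list(low_speed = as.integer(sps$low_speed),
                                       high_speed = as.integer(sps$high_speed)),
         trials_per_staircase = as.integer(trials_per_staircase),
         spatial_frequency = spatial_frequency),
    class = "experiment_design"
  )
}

#' Trials per session in one block
#'
#' @param design an [build_design()] result.
#' @param block `"low_speed"` or `"high_speed"`.
#' @return trial count: conditions in block x staircases per session x trials
#'   per staircase.
#' @export
block_trials_per_session <- function(design, block) {
  stopifnot(inherits(design, "experiment_design"))
  block <- match.arg(block, c("low_speed", "high_speed"))
  n_cond <- sum(design$conditions$block == block)
  n_cond * design$staircases_per_session[[block]] * design$trials_per_staircase
}

#' Staircases pooled per condition over all sessions
#'
#' @param design an [build_design()] result.
#' @return named integer vector over condition ids.
#' @export
staircases_per_condition <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n <- vapply(design$conditions$block, function(b) {
    design$sessions * design$staircases_per_session[[b]]
  }, integer(1))
  stats::setNames(n, design$conditions$condition_id)
}

#' Generate a complete synthetic dataset
#'
#' Runs every staircase the design schedules against the generative observer.
#' Each staircase gets its own seed drawn reproducibly from `master_seed`, so
#' any single staircase can be re-run in isolation; the whole dataset is
#' byte-identical under the same master seed.
#'
#' @param observer an [observer_spec()]; retained in the result as the ground
#'   truth for recovery checks.
#' @param design an [build_design()] result.
#' @param master_seed integer master seed.
#' @param quest a [quest_config()]; its `n_trials` is overridden by the
#'   design's `trials_per_staircase`, and the per-condition initial guess is
#'   the reference speed.
#' @return an object of class `speed_dataset` with `$staircases` (list of
#'   [run_staircase()] results), `$design`, `$observer`, `$master_seed`.
#' @export
generate_dataset <- function(observer, design = build_design(),
                             master_seed = 1, quest = quest_config()) {
  stopifnot(inherits(observer, "observer_spec"),
            inherits(design, "experiment_design"))
  quest$n_trials <- design$trials_per_staircase
  schedule <- do.call(rbind, lapply(seq_len(design$sessions), function(s) {
    per <- vapply(design$conditions$block,
                  function(b) design$staircases_per_session[[b]], integer(1))
    data.frame(session = s,
               cond_row = rep(seq_len(nrow(design$conditions)), per))
  }))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1, nrow(schedule))
  staircases <- vector("list", nrow(schedule))
  sc_counter <- integer(nrow(design$conditions))
  for (i in seq_len(nrow(schedule))) {
    r <- schedule$cond_row[i]
    sc_counter[r] <- sc_counter[r] + 1L
    staircases[[i]] <- run_staircase(
      observer, design$conditions[r, ], config = quest, rng_seed = seeds[i],
      session = schedule$session[i], staircase_id = sc_counter[r]
    )
  }
  structure(
    list(design = design, observer = observer, staircases = staircases,
         master_seed = master_seed),
    class = "speed_dataset"
  )
}

#' Flatten a dataset's trial logs into one data frame
#'
#' One row per trial with the fixed header: session, condition_id,
#' staircase_id, trial_index, v_ref, c_ref, v_test, c_test, reference_side,
#' response_test_faster.
#'
#' @param dataset a `speed_dataset` (or list of `staircase_result`s).
#' @return a data frame of trials.
#' @export
trial_log <- function(dataset) {
  sc <- if (inherits(dataset, "speed_dataset")) dataset$staircases else dataset
  do.call(rbind, lapply(sc, `[[`, "trials"))
}

#' Per-staircase results table
#'
#' One row per staircase: ids, recorded PSE and trial count.
#'
#' @param dataset a `speed_dataset` (or list of `staircase_result`s).
#' @return a data frame: condition_id, session, staircase_id, pse, n_trials.
#' @export
staircase_table <- function(dataset) {
  sc <- if (inherits(dataset, "speed_dataset")) dataset$staircases else dataset
  data.frame(
    condition_id = vapply(sc, `[[`, character(1), "condition_id"),
    session = vapply(sc, `[[`, integer(1), "session"),
    staircase_id = vapply(sc, `[[`, integer(1), "staircase_id"),
    pse = vapply(sc, `[[`, numeric(1), "pse"),
    n_trials = vapply(sc, `[[`, integer(1), "n_trials"),
    stringsAsFactors = FALSE
  )
}

#' Per-condition PSE summary table
#'
#' Pools staircases across sessions and reports, per condition, the mean PSE
#' and the across-staircase variance of the PSE (sample variance, denominator
#' n-1): the squared standard error of a single staircase's PSE estimate.
#' This pair is the sole input of the fast fitting method.
#'
#' @param dataset a `speed_dataset`, or a list of `staircase_result`s
#'   together with a `conditions` data frame.
#' @param conditions condition table (taken from the dataset's design when
#'   omitted).
#' @return a data frame of class `pse_table`: condition_id, v_ref, c_ref,
#'   c_test, n_staircases, mean_pse, pse_var.
#' @export
pse_summary <- function(dataset, conditions = NULL) {
  if (inherits(dataset, "speed_dataset")) {
    conditions <- dataset$design$conditions
    staircases <- dataset$staircases
  } else {
    staircases <- dataset
    if (is.null(conditions)) stop("conditions table required")
  }
  pses <- data.frame(
    condition_id = vapply(staircases, `[[`, character(1), "condition_id"),
    pse = vapply(staircases, `[[`, numeric(1), "pse"),
    stringsAsFactors = FALSE
  )
  out <- conditions[, c("condition_id", "v_ref", "c_ref", "c_test")]
  out$n_staircases <- NA_integer_
  out$mean_pse <- NA_real_
  out$pse_var <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- pses$pse[pses$condition_id == out$condition_id[i]]
    if (length(x) < 2) {
      stop("need at least 2 staircases per condition for a PSE variance")
    }
    out$n_staircases[i] <- length(x)
    out$mean_pse[i] <- mean(x)
    out$pse_var[i] <- stats::var(x)
  }
  class(out) <- c("pse_table", "data.frame")
  out
}

#' Write / read a PSE table as CSV
#'
#' @param table a `pse_table`.
#' @param path CSV path.
#' @export
write_pse_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pse_table
#' @export
read_pse_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition_id", "v_ref", "c_ref", "c_test", "n_staircases",
              "mean_pse", "pse_var")
  if (!all(needed %in% names(out))) {
    stop("PSE table must have columns: ", paste(needed, collapse = ", "))
  }
  class(out) <- c("pse_table", "data.frame")
  out
}
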