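# The TrialPanel container: per-participant covariates plus a long
# participant-by-wave table of utilities, cost components, and productivity
# days, with observation and structural-missingness flags.

#' Construct a trial panel
#'
#' Bundles the participant table (one row per participant: arm and baseline
#' covariates) with the wave table (one row per participant and assessment
#' wave: utility, cost components, productivity days, observation flags) and
#' validates the container invariants: utilities at most 1, costs and days
#' non-negative, a complete wave grid per participant, and structurally
#' missing waves (control follow-up beyond the truncation wave) flagged
#' distinctly from dropout.
#'
#' @param participants Data frame with columns `participant_id`, `arm`
#'   (`"intervention"`/`"control"`), `age`, `gender` (`"female"`/`"male"`),
#'   `antidepressant_use` (logical).
#' @param waves Data frame with columns `participant_id`, `wave` (0-based),
#'   `time` (years), `utility`, `drug`, `treatment`, `diagnostic`,
#'   `lost_days`, `reduced_days`, `observed`, `structural`.
#' @param grid The [time_grid()] of the assessments.
#' @return Object of class `trial_panel`.
#' @export
trial_panel <- function(participants, waves, grid) {
  stopifnot(inherits(grid, "cua_time_grid"))
  need_p <- c("participant_id", "arm", "age", "gender", "antidepressant_use")
  need_w <- c("participant_id", "wave", "time", "utility", "drug",
              "treatment", "diagnostic", "lost_days", "reduced_days",
              "observed", "structural")
  if (!all(need_p %in% names(participants))) {
    stop("participant table is missing columns: ",
         paste(setdiff(need_p, names(participants)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_w %in% names(waves))) {
    stop("wave table is missing columns: ",
         paste(setdiff(need_w, names(waves)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(participants$participant_id)) {
    stop("exactly one baseline record per participant is required",
         call. = FALSE)
  }
  if (!all(participants$arm %in% c("intervention", "control"))) {
    stop("`arm` must be 'intervention' or 'control'", call. = FALSE)
  }
  k <- length(grid$times)
  tab <- table(waves$participant_id)
  if (!all(tab == k) || length(tab) != nrow(participants)) {
    stop("every participant needs one row per assessment wave", call. = FALSE)
  }
  if (any(waves$utility > 1, na.rm = TRUE)) {
    stop("utilities must not exceed 1", call. = FALSE)
  }
  for (col in c("drug", "treatment", "diagnostic", "lost_days",
                "reduced_days")) {
    if (any(waves[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("`%s` must be non-negative", col), call. = FALSE)
    }
  }
  st <- waves$structural
  if (any(st & waves$observed)) {
    stop("structurally missing waves cannot be flagged observed",
         call. = FALSE)
  }
  if (any(st & !is.na(waves$utility))) {
    stop("structurally missing waves must carry no values", call. = FALSE)
  }
  participants <- participants[order(participants$participant_id), ]
  waves <- waves[order(waves$participant_id, waves$wave), ]
  rownames(waves) <- NULL
  rownames(participants) <- NULL
  structure(list(participants = participants, waves = waves, grid = grid),
            class = "trial_panel")
}

#' @export
print.trial_panel <- function(x, ...) {
  n <- nrow(x$participants)
  cat(sprintf("Trial panel: %d participants (%d intervention / %d control), %d waves\n",
              n, sum(x$participants$arm == "intervention"),
              sum(x$participants$arm == "control"), length(x$grid$times)))
  invisible(x)
}

#' Write / read a trial panel as delimited tables
#'
#' The panel is exchanged as two CSV files, `<prefix>_participants.csv` and
#' `<prefix>_waves.csv`, one row per participant and per participant-wave
#' respectively.
#'
#' @param panel A [trial_panel()].
#' @param prefix Path prefix for the two files.
#' @return `write_panel` returns the two paths invisibly; `read_panel`
#'   returns the reconstructed `trial_panel`.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "trial_panel"))
  pp <- paste0(prefix, "_participants.csv")
  pw <- paste0(prefix, "_waves.csv")
  utils::write.csv(panel$participants, pp, row.names = FALSE)
  utils::write.csv(panel$waves, pw, row.names = FALSE)
  invisible(c(participants = pp, waves = pw))
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  participants <- utils::read.csv(paste0(prefix, "_participants.csv"),
                                  stringsAsFactors = FALSE)
  waves <- utils::read.csv(paste0(prefix, "_waves.csv"),
                           stringsAsFactors = FALSE)
  participants$antidepressant_use <- as.logical(participants$antidepressant_use)
  waves$observed <- as.logical(waves$observed)
  waves$structural <- as.logical(waves$structural)
  times <- sort(unique(waves$time))
  trial_panel(participants, waves, time_grid(times))
}

# One row per participant with wide per-wave columns u<t> (utility),
# dc<t> (direct cost), ic<t> (indirect cost), obs<t>, str<t>. The wage model
# is needed to value productivity days.
panel_wide <- function(panel, wage) {
  stopifnot(inherits(panel, "trial_panel"), inherits(wage, "wage_model"))
  p <- panel$participants
  w <- panel$waves
  k <- length(panel$grid$times)
  out <- data.frame(
    participant_id = p$participant_id,
    arm = p$arm,
    treatment = as.numeric(p$arm == "intervention"),
    age = p$age,
    gender = p$gender,
    gender_male = as.numeric(p$gender == "male"),
    antidepressant_use = as.numeric(p$antidepressant_use),
    stringsAsFactors = FALSE
  )
  w <- w[order(w$participant_id, w$wave), ]
  ord <- match(out$participant_id, unique(w$participant_id))
  for (t in seq_len(k) - 1L) {
    wt <- w[w$wave == t, ]
    wt <- wt[match(out$participant_id, wt$participant_id), ]
    direct <- wt$drug + wt$treatment + wt$diagnostic
    indirect <- wage$daily_wage *
      (wt$lost_days + wage$presenteeism_weight * wt$reduced_days)
    out[[paste0("u", t)]] <- wt$utility
    out[[paste0("dc", t)]] <- direct
    out[[paste0("ic", t)]] <- indirect
    out[[paste0("obs", t)]] <- wt$observed
    out[[paste0("str", t)]] <- wt$structural
  }
  attr(out, "grid") <- panel$grid
  attr(out, "n_waves") <- k
  out
}
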