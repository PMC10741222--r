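# Cognitive task generators and scorers: the go/no-go sustained-attention
# task (press for any letter except "X"), the adaptive arithmetic task
# (difficulty steps up past 70% running accuracy), and the transfer
# paradigm (alternating 30 s Rest / Regulation blocks).

#' Go/no-go task configuration
#'
#' A block holds 20 trials of ~2 s each: ~750 ms fixation cross, ~250 ms
#' letter, ~1000 ms response window, with uniform jitter around each nominal
#' duration renormalized so the trial stays 2 s. Exactly 25% of the trials
#' show the no-go letter "X".
#'
#' @param n_trials trials per block (20).
#' @param nogo_frac fraction of no-go trials (0.25; must give a whole
#'   number of trials).
#' @param t_fix_ms,t_stim_ms,t_resp_ms nominal durations (ms).
#' @param jitter_frac uniform jitter fraction around each nominal duration.
#' @param rt_limit_ms responses slower than this count as omissions (1000).
#' @return list of class `gonogo_config`.
#' @export
gonogo_config <- function(n_trials = 20L, nogo_frac = 0.25,
                          t_fix_ms = 750, t_stim_ms = 250, t_resp_ms = 1000,
                          jitter_frac = 0.1, rt_limit_ms = 1000) {
  n_nogo <- n_trials * nogo_frac
  if (abs(n_nogo - round(n_nogo)) > 1e-9) {
    stop_nfb("nogo_frac * n_trials must be an integer")
  }
  structure(list(n_trials = as.integer(n_trials), nogo_frac = nogo_frac,
                 t_fix_ms = t_fix_ms, t_stim_ms = t_stim_ms,
                 t_resp_ms = t_resp_ms, jitter_frac = jitter_frac,
                 rt_limit_ms = rt_limit_ms),
            class = "gonogo_config")
}

#' Generate one go/no-go block
#'
#' @param config a [gonogo_config()].
#' @param block_id integer block identifier.
#' @param condition `"with"` or `"without"` distractions.
#' @param seed RNG seed; the letter sequence is deterministic given it.
#' @return data.frame of trials: `block_id`, `trial`, `letter`, `is_nogo`,
#'   `condition`, `t_fix_ms`, `t_stim_ms`, `t_resp_ms`, `onset` (s from
#'   block start).
#' @export
generate_gonogo_block <- function(config = gonogo_config(), block_id = 1L,
                                  condition = c("without", "with"),
                                  seed = 1) {
  condition <- match.arg(condition)
  n <- config$n_trials
  n_nogo <- as.integer(round(n * config$nogo_frac))
  with_seed(seed, {
    nogo_pos <- sample.int(n, n_nogo)
    letters_go <- sample(setdiff(LETTERS, "X"), n, replace = TRUE)
    letter <- letters_go
    letter[nogo_pos] <- "X"
    jit <- function(nominal) {
      nominal * stats::runif(n, 1 - config$jitter_frac, 1 + config$jitter_frac)
    }
    d <- cbind(jit(config$t_fix_ms), jit(config$t_stim_ms),
               jit(config$t_resp_ms))
    total <- config$t_fix_ms + config$t_stim_ms + config$t_resp_ms
    d <- d * (total / rowSums(d))       # renormalize each trial to 2 s
    onset <- c(0, cumsum(rowSums(d))[-n]) / 1000
    data.frame(block_id = block_id, trial = seq_len(n), letter = letter,
               is_nogo = letter == "X", condition = condition,
               t_fix_ms = d[, 1L], t_stim_ms = d[, 2L], t_resp_ms = d[, 3L],
               onset = onset, stringsAsFactors = FALSE)
  })
}

#' Score a go/no-go log
#'
#' A go trial without a press, or with a press slower than the response
#' limit (1 s after stimulus), is an omission; a press on "X" is a
#' commission. Accuracy is `(hits + correct rejections) / n_trials`. RT
#' statistics are computed over go hits only, after [clean_rt()].
#'
#' @param trials data.frame from [generate_gonogo_block()] (any number of
#'   blocks row-bound); needs `is_nogo` and optionally `condition`.
#' @param responses data.frame aligned to `trials` with columns `responded`
#'   (logical) and `rt_ms`.
#' @param config a [gonogo_config()] (for the 1 s response limit).
#' @return list of class `gonogo_score`: counts, `accuracy`, `rt_mean`,
#'   `rt_sd`, plus `per_condition` when a `condition` column is present.
#' @export
score_gonogo <- function(trials, responses, config = gonogo_config()) {
  if (nrow(trials) != nrow(responses)) {
    stop_nfb("trials (%d) and responses (%d) differ in length",
             nrow(trials), nrow(responses))
  }
  score_subset <- function(tr, rs) {
    go <- !tr$is_nogo
    pressed_ok <- rs$responded & !is.na(rs$rt_ms) &
      rs$rt_ms <= config$rt_limit_ms
    hits <- sum(go & pressed_ok)
    omissions <- sum(go & !pressed_ok)
    commissions <- sum(!go & rs$responded)
    correct_rejections <- sum(!go & !rs$responded)
    rts <- rs$rt_ms[go & pressed_ok]
    if (length(rts) >= 2L) {
      keep <- clean_rt(rts, error_flags = rep(FALSE, length(rts)))
      rts <- rts[keep]
    }
    list(n_trials = nrow(tr), hits = hits, omissions = omissions,
         commissions = commissions, correct_rejections = correct_rejections,
         accuracy = (hits + correct_rejections) / nrow(tr),
         rt_mean = if (length(rts)) mean(rts) else NA_real_,
         rt_sd = if (length(rts) > 1L) stats::sd(rts) else NA_real_)
  }
  out <- score_subset(trials, responses)
  if ("condition" %in% names(trials)) {
    out$per_condition <- lapply(split(seq_len(nrow(trials)),
                                      trials$condition),
                                function(i) score_subset(trials[i, ],
                                                         responses[i, ]))
  }
  class(out) <- "gonogo_score"
  out
}

#' Clean reaction times
#'
#' Error trials are removed first; the per-subject mean and SD are then
#' computed on the remaining correct trials, and trials faster or slower
#' than three SDs from that mean are excluded (single pass, no
#' re-iteration).
#'
#' @param rts numeric reaction times (ms), one per trial.
#' @param error_flags logical, `TRUE` for error trials.
#' @param n_sd SD multiplier (3).
#' @return logical mask of retained trials (errors are `FALSE`).
#' @export
clean_rt <- function(rts, error_flags = rep(FALSE, length(rts)), n_sd = 3) {
  stopifnot(length(rts) == length(error_flags))
  correct <- !error_flags & !is.na(rts)
  if (sum(correct) == 0L) stop_nfb("all trials are errors")
  if (sum(correct) < 2L) return(correct)
  m <- mean(rts[correct]); s <- stats::sd(rts[correct])
  keep <- correct & rts >= m - n_sd * s & rts <= m + n_sd * s
  keep
}

#' Adaptive arithmetic task: next trial
#'
#' While the running success rate stays below 70% only single-digit
#' addition and subtraction are presented (e.g. 9 + 4, 7 - 3); once it
#' exceeds 70% the pool widens to two-digit addition/subtraction and
#' single-digit multiplication (e.g. 34 + 8, 5 x 9). Difficulty is
#' symmetric: falling back under 70% returns to level 1. Each trial offers
#' three answer options including exactly one correct.
#'
#' @param history data.frame of past trials with a logical `correct` column
#'   (empty allowed: the task starts easy).
#' @param threshold accuracy threshold (0.70, strict `>` to step up).
#' @param distractor_dist maximum distance of wrong options from the true
#'   answer.
#' @param seed RNG seed.
#' @return list of class `calc_trial`: `level`, `a`, `b`, `op`,
#'   `expression`, `answer`, `options` (3 integers), `correct_index`.
#' @export
next_calc_trial <- function(history = NULL, threshold = 0.70,
                            distractor_dist = 10, seed = 1) {
  n_hist <- if (is.null(history)) 0L else nrow(history)
  acc <- if (n_hist > 0L) mean(history$correct) else 0
  level <- if (n_hist > 0L && acc > threshold) 2L else 1L
  with_seed(seed, {
    if (level == 1L) {
      op <- sample(c("+", "-"), 1L)
      a <- sample(0:9, 1L); b <- sample(0:9, 1L)
      if (op == "-" && b > a) { tmp <- a; a <- b; b <- tmp }
    } else {
      form <- sample(c("add2", "sub2", "mul1"), 1L)
      if (form == "mul1") {
        op <- "x"; a <- sample(2:9, 1L); b <- sample(2:9, 1L)
      } else {
        op <- if (form == "add2") "+" else "-"
        a <- sample(10:89, 1L); b <- sample(1:9, 1L)
        if (op == "+" && a + b > 99) a <- 99 - b
        if (op == "-" && b > a) { tmp <- a; a <- b; b <- tmp }
      }
    }
    answer <- switch(op, "+" = a + b, "-" = a - b, "x" = a * b)
    opts <- answer
    while (length(opts) < 3L) {
      cand <- answer + sample(c(-distractor_dist:-1, 1:distractor_dist), 1L)
      if (cand >= 0 && !cand %in% opts) opts <- c(opts, cand)
    }
    opts <- sample(opts)
    structure(list(level = level, a = a, b = b, op = op,
                   expression = sprintf("%d %s %d", a, op, b),
                   answer = answer, options = opts,
                   correct_index = match(answer, opts)),
              class = "calc_trial")
  })
}

#' Transfer paradigm block structure
#'
#' Periods of self-regulation interleaved with rest every 30 s, six blocks
#' per condition (12 blocks, 360 s by default).
#'
#' @param block_len_s block length (s).
#' @param n_per_condition blocks per condition.
#' @param first first block's condition (`"Rest"` or `"Regulation"`).
#' @return event data.frame (`onset`, `duration`, `trial_type`) suitable for
#'   [write_events()].
#' @export
transfer_paradigm <- function(block_len_s = 30, n_per_condition = 6L,
                              first = c("Rest", "Regulation")) {
  first <- match.arg(first)
  labels <- rep(c(first, setdiff(c("Rest", "Regulation"), first)),
                n_per_condition)
  data.frame(onset = (seq_along(labels) - 1L) * block_len_s,
             duration = block_len_s, trial_type = labels,
             stringsAsFactors = FALSE)
}
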