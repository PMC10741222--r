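# Feedback actuators of the closed loop: the helicopter altitude dynamics
# and the attention-proportional distraction scheduler.
#
# Altitude update: h(t) = h(t-1) + vd(t) + gd(t) with
#   vd = nfb * speed * dt   (vertical displacement)
#   gd = -0.5 * speed * dt  (gravity displacement)
# speed is a constant 10 m/s, and h is clamped between the bottom and the
# top of the whiteboard. nfb = 0.5 is the exact equilibrium.

#' Helicopter feedback state
#'
#' @param h current altitude (m).
#' @param h_min,h_max clamp bounds (m): bottom and top of the whiteboard
#'   (defaults 0 and 2.4, the screen height).
#' @param speed constant speed (m/s), 10 by default.
#' @return list of class `helicopter_state`.
#' @export
helicopter_state <- function(h = 0, h_min = 0, h_max = 2.4, speed = 10) {
  stopifnot(h_min <= h_max, speed > 0)
  h <- clip(h, h_min, h_max)
  structure(list(h = h, h_min = h_min, h_max = h_max, speed = speed),
            class = "helicopter_state")
}

#' Advance the helicopter by one feedback step
#'
#' @param state a [helicopter_state()].
#' @param nfb normalized feedback value in `[0, 1]`.
#' @param dt elapsed time (s), > 0.
#' @return the updated state with
#'   `h' = clip(h + nfb*speed*dt - 0.5*speed*dt, h_min, h_max)`.
#' @export
helicopter_step <- function(state, nfb, dt) {
  stopifnot(inherits(state, "helicopter_state"), dt > 0,
            nfb >= 0, nfb <= 1)
  # vd + gd = nfb*speed*dt - 0.5*speed*dt, factored so the nfb = 0.5
  # equilibrium is exact in floating point
  state$h <- clip(state$h + (nfb - 0.5) * state$speed * dt,
                  state$h_min, state$h_max)
  state
}

#' Simulate a helicopter trajectory from an nfb series
#'
#' @param nfb numeric vector of feedback values per step.
#' @param dt step duration (s).
#' @param state initial [helicopter_state()].
#' @return data.frame `t`, `h` (altitude after each step).
#' @export
helicopter_trajectory <- function(nfb, dt = 1, state = helicopter_state()) {
  h <- numeric(length(nfb))
  for (i in seq_along(nfb)) {
    state <- helicopter_step(state, nfb[i], dt)
    h[i] <- state$h
  }
  data.frame(t = seq_along(nfb) * dt, h = h)
}

#' Distraction catalogue
#'
#' The panel of classroom distractions: school mistress and headmaster
#' actions, classmates, phone, bell, insects, each with a modality and a
#' default duration.
#'
#' @return data.frame with columns `kind`, `modality`, `duration_s`.
#' @export
distraction_catalogue <- function() {
  data.frame(
    kind = c("mistress_walk", "mistress_cough", "mistress_yawn",
             "mistress_speak", "headmaster_enter_exit", "headmaster_walk",
             "headmaster_cough", "headmaster_yawn", "headmaster_speak",
             "kid_raise_hand", "kid_speak", "phone_vibrate", "bell",
             "insects"),
    modality = c("visual", "audio", "audiovisual",
                 "audio", "visual", "visual",
                 "audio", "audiovisual", "audio",
                 "visual", "audio", "audio", "audio",
                 "audiovisual"),
    duration_s = c(2.5, 1.0, 1.5, 2.0, 2.5, 2.5, 1.0, 1.5, 2.0,
                   1.5, 1.5, 1.0, 1.5, 2.0),
    stringsAsFactors = FALSE)
}

#' Block plan for distraction scheduling
#'
#' @param block_len_s block length (s), 30 by default.
#' @param first_block_distraction_free logical; the first block of each task
#'   stays distraction-free.
#' @param min_events_per_block at least this many distractions per
#'   distraction block (1).
#' @param min_interval_s minimum inter-onset interval (3 s; at full focus
#'   one distraction occurs every 3 s).
#' @return list of class `block_plan`.
#' @export
block_plan <- function(block_len_s = 30, first_block_distraction_free = TRUE,
                       min_events_per_block = 1L, min_interval_s = 3) {
  stopifnot(block_len_s > 0, min_events_per_block >= 1, min_interval_s > 0)
  structure(list(block_len_s = block_len_s,
                 first_block_distraction_free = first_block_distraction_free,
                 min_events_per_block = min_events_per_block,
                 min_interval_s = min_interval_s),
            class = "block_plan")
}

#' Schedule distractions proportionally to concentration
#'
#' The more focused the child (higher nfb), the more frequent the
#' distractions: the target inter-onset interval is
#' `min_interval_s / max(nfb, eps)` with `eps = min_interval_s /
#' block_len_s`, so full focus (nfb = 1) yields one distraction every 3 s
#' and nfb -> 0 degrades to the floor of one distraction per block. Events
#' never overlap and only one occurs at a time; the first block is
#' distraction-free.
#'
#' @param n_blocks number of 30 s blocks (including the distraction-free
#'   first block).
#' @param nfb_trace function of time (s) returning nfb, or a numeric vector
#'   sampled at 1 Hz from t = 0.
#' @param catalogue data.frame as [distraction_catalogue()].
#' @param seed RNG seed (kind selection).
#' @param plan a [block_plan()].
#' @return data.frame of events: `onset`, `duration`, `kind`, `modality`,
#'   `block`.
#' @export
schedule_distractions <- function(n_blocks, nfb_trace,
                                  catalogue = distraction_catalogue(),
                                  seed = 1, plan = block_plan()) {
  if (!nrow(catalogue)) stop_nfb("empty distraction catalogue")
  nfb_at <- if (is.function(nfb_trace)) nfb_trace else {
    v <- as.numeric(nfb_trace)
    function(t) stats::approx(seq_along(v) - 1, v, xout = t, rule = 2)$y
  }
  eps <- plan$min_interval_s / plan$block_len_s
  with_seed(seed, {
    rows <- list()
    next_allowed <- -Inf   # min-interval constraint carries across blocks
    for (b in seq_len(n_blocks)) {
      if (b == 1L && plan$first_block_distraction_free) next
      b0 <- (b - 1L) * plan$block_len_s
      b1 <- b * plan$block_len_s
      t <- max(b0, next_allowed)
      while (t < b1 - 1e-9) {
        nfb <- clip(nfb_at(t), 0, 1)
        kind_i <- sample.int(nrow(catalogue), 1L)
        dur <- min(catalogue$duration_s[kind_i], plan$min_interval_s,
                   b1 - t)
        rows[[length(rows) + 1L]] <-
          data.frame(onset = t, duration = dur,
                     kind = catalogue$kind[kind_i],
                     modality = catalogue$modality[kind_i],
                     block = b)
        gap <- plan$min_interval_s / max(nfb, eps)
        t <- t + max(gap, plan$min_interval_s)
        next_allowed <- t
      }
    }
    if (!length(rows)) {
      return(data.frame(onset = numeric(0), duration = numeric(0),
                        kind = character(0), modality = character(0),
                        block = integer(0)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Session plan for a closed-loop run
#'
#' @param run_len_s length of each helicopter run (s); the protocol uses two
#'   3-minute runs.
#' @param n_runs number of helicopter runs.
#' @param calib_phase_s length of each of the four calibration phases (s).
#' @param sfreq simulated EEG sampling rate (Hz).
#' @param ch_names simulated montage.
#' @param n_calc_trials arithmetic trials between runs.
#' @return list of class `session_plan`.
#' @export
session_plan <- function(run_len_s = 180, n_runs = 2L, calib_phase_s = 20,
                         sfreq = 500,
                         ch_names = c("Fp1", "Fp2", "F3", "Fz", "F4", "T7",
                                      "C3", "Cz", "C4", "T8", "Pz", "Oz",
                                      "ECG"),
                         n_calc_trials = 10L) {
  stopifnot(run_len_s >= 0, n_runs >= 0, calib_phase_s > 0)
  structure(list(run_len_s = run_len_s, n_runs = n_runs,
                 calib_phase_s = calib_phase_s, sfreq = sfreq,
                 ch_names = ch_names, n_calc_trials = n_calc_trials),
            class = "session_plan")
}

#' Attention agent: a simulated child
#'
#' @param focus_target attention level during focused states / helicopter
#'   runs.
#' @param relax_target attention level during relaxation.
#' @param volatility attention volatility (see [attention_params()]).
#' @return list of class `attention_agent`.
#' @export
attention_agent <- function(focus_target = 0.7, relax_target = 0.3,
                            volatility = 0.08) {
  structure(list(focus_target = focus_target, relax_target = relax_target,
                 volatility = volatility),
            class = "attention_agent")
}

#' Run a complete closed-loop session against a simulated child
#'
#' Orchestrates calibration (two relaxing and two focusing periods of 20 s,
#' interleaved), then alternates helicopter runs with the adaptive
#' arithmetic task: per run, the agent's attention trace drives the
#' synthetic EEG, the engine streams normalized TBR, the helicopter
#' integrates it and distractions are scheduled from the nfb trace.
#'
#' @param agent an [attention_agent()].
#' @param engine an [engine_config()].
#' @param bounds optional pre-computed [calibration_bounds()]; when `NULL`
#'   the calibration phase is simulated first.
#' @param plan a [session_plan()].
#' @param seed RNG seed; the whole session is deterministic given it.
#' @return list of class `session_log`: `bounds`, `tbr` (with absolute
#'   time and run id), `helicopter`, `distractions`, `calc_trials`,
#'   `summary` (mean altitude, mean raw TBR over runs).
#' @export
run_closed_loop <- function(agent = attention_agent(),
                            engine = engine_config(), bounds = NULL,
                            plan = session_plan(), seed = 1) {
  synth_p <- synth_eeg_params()
  ## --- calibration ---------------------------------------------------------
  if (is.null(bounds)) {
    targets <- c(agent$relax_target, agent$focus_target,
                 agent$relax_target, agent$focus_target)
    calib_samples <- list()
    for (ph in seq_along(targets)) {
      tr <- simulate_attention_trace(plan$calib_phase_s, rate_hz = 1,
                                     attention_params(target = targets[ph],
                                                      volatility = agent$volatility),
                                     seed = derive_seed(seed, ph))
      rec <- synthesize_eeg(tr, plan$ch_names, plan$sfreq, synth_p,
                            seed = derive_seed(seed, 100 + ph))
      calib_samples[[ph]] <- stream_tbr(rec, engine)
    }
    bounds <- calibrate(do.call(rbind, calib_samples))
  }
  ## --- runs ----------------------------------------------------------------
  tbr_all <- list(); heli_all <- list(); dist_all <- list()
  calc_all <- list()
  t0 <- 0
  if (plan$run_len_s > 0 && plan$n_runs > 0) {
    for (run in seq_len(plan$n_runs)) {
      tr <- simulate_attention_trace(plan$run_len_s, rate_hz = 1,
                                     attention_params(target = agent$focus_target,
                                                      volatility = agent$volatility),
                                     seed = derive_seed(seed, 200 + run))
      rec <- synthesize_eeg(tr, plan$ch_names, plan$sfreq, synth_p,
                            seed = derive_seed(seed, 300 + run))
      tbr <- stream_tbr(rec, engine, bounds)
      heli <- helicopter_trajectory(tbr$nfb, dt = engine$hop_s,
                                    state = helicopter_state())
      nfb_fun <- function(t) {
        stats::approx(tbr$t, tbr$nfb, xout = t, rule = 2)$y
      }
      dist <- schedule_distractions(
        n_blocks = max(1L, floor(plan$run_len_s / 30)),
        nfb_trace = nfb_fun, seed = derive_seed(seed, 400 + run))
      tbr$t <- tbr$t + t0; tbr$run <- run
      heli$t <- heli$t + t0; heli$run <- run
      if (nrow(dist)) { dist$onset <- dist$onset + t0; dist$run <- run }
      tbr_all[[run]] <- tbr; heli_all[[run]] <- heli; dist_all[[run]] <- dist
      t0 <- t0 + plan$run_len_s
      ## interleaved arithmetic task
      if (plan$n_calc_trials > 0 && run < plan$n_runs) {
        hist <- data.frame(level = integer(0), correct = logical(0))
        att_now <- mean(tr$values)
        for (k in seq_len(plan$n_calc_trials)) {
          trial <- next_calc_trial(hist, seed = derive_seed(seed, 500 + run * 50 + k))
          correct <- with_seed(derive_seed(seed, 600 + run * 50 + k),
                               stats::runif(1) < 0.5 + 0.4 * att_now)
          hist <- rbind(hist, data.frame(level = trial$level, correct = correct))
        }
        hist$t <- t0 + seq_len(nrow(hist)) * 5
        hist$run_after <- run
        calc_all[[run]] <- hist
        t0 <- t0 + plan$n_calc_trials * 5
      }
    }
  }
  tbr <- if (length(tbr_all)) do.call(rbind, tbr_all) else NULL
  heli <- if (length(heli_all)) do.call(rbind, heli_all) else NULL
  dist <- if (length(dist_all)) do.call(rbind, dist_all) else NULL
  structure(list(
    bounds = bounds, tbr = tbr, helicopter = heli, distractions = dist,
    calc_trials = if (length(calc_all)) do.call(rbind, calc_all) else NULL,
    summary = list(
      mean_altitude = if (is.null(heli)) NA_real_ else mean(heli$h),
      mean_tbr_raw = if (is.null(tbr)) NA_real_ else
        mean(tbr$tbr_raw[!tbr$gated], na.rm = TRUE),
      mean_nfb = if (is.null(tbr)) NA_real_ else
        mean(tbr$nfb[!tbr$gated], na.rm = TRUE))),
    class = "session_log")
}
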