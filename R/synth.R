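RHYTHMS <- c("nsr", "af", "vf", "bg", "tg", "qg", "couplet", "triplet", "vt")

# per-rhythm repeating PVC pattern (1 = PVC); NULL for non-beat rhythms
pvc_pattern <- function(rhythm) {
  switch(rhythm,
    nsr = 0L, af = 0L,
    bg = c(1L, 0L), tg = c(1L, 0L, 0L), qg = c(1L, 0L, 0L, 0L),
    couplet = c(1L, 1L, 0L), triplet = c(1L, 1L, 1L, 0L), vt = 1L,
    NULL)
}

# Gaussian bump; evaluated only on a local support for speed
add_bump <- function(y, t, mu, sd_s, amp) {
  lo <- max(1L, findInterval(mu - 5 * sd_s, t))
  hi <- min(length(t), findInterval(mu + 5 * sd_s, t) + 1L)
  if (hi < lo) return(y)
  idx <- lo:hi
  y[idx] <- y[idx] + amp * exp(-(t[idx] - mu)^2 / (2 * sd_s^2))
  y
}

# PQRST template parameters: center offset from R (s), width sd (s),
# amplitude (mV). PVC: no P wave, QRS widened x2, R/S amplitudes scaled so
# the peak-to-valley excursion is x1.6, discordant (inverted, wider) T.
beat_bumps <- function(pvc) {
  if (!pvc) {
    list(c(-0.17, 0.022, 0.12),   # P
         c(-0.028, 0.009, -0.10), # Q
         c(0, 0.012, 1.00),       # R
         c(0.028, 0.010, -0.25),  # S
         c(0.22, 0.045, 0.30))    # T
  } else {
    list(c(-0.056, 0.018, -0.16),
         c(0, 0.024, 1.60),
         c(0.056, 0.020, -0.40),
         c(0.26, 0.060, -0.35))
  }
}

#' Generate a labelled synthetic single-lead ECG record
#'
#' Template-based synthesis used throughout the test-suite and the
#' acceptance checks, emulating the statistical structure each cascade
#' stage discriminates on:
#' * `nsr` - a PQRST Gaussian-bump template train at `hr_bpm` with uniform
#'   RR jitter of +/- 2%;
#' * PVC-pattern rhythms (`bg`, `tg`, `qg`, `couplet`, `triplet`, `vt`) -
#'   the NSR train with PVC beats substituted in the repeating pattern of
#'   the rhythm (bigeminy every 2nd beat, trigeminy every 3rd, quadrigeminy
#'   every 4th, couplet/triplet as 2/3 consecutive, VT all). PVC beats have
#'   no P wave, a doubled QRS width, a 1.6x peak-to-valley excursion,
#'   arrive 0.8x RR early and are followed by a 1.2x RR compensatory pause;
#' * `af` - the template train with the P wave removed and RR intervals
#'   drawn iid from U(0.4, 1.2) s (irregularly irregular);
#' * `vf` - no discrete beats: the sum of three amplitude-varied 3-7 Hz
#'   oscillators whose phases follow random walks, giving the disorganized
#'   broadband trajectory characteristic of fibrillation.
#'
#' Additive white Gaussian noise of standard deviation `noise_sd` (mV) is
#' applied to every rhythm. Output is deterministic given `seed`.
#'
#' @param rhythm One of `"nsr"`, `"af"`, `"vf"`, `"bg"`, `"tg"`, `"qg"`,
#'   `"couplet"`, `"triplet"`, `"vt"`.
#' @param duration_s Record length in seconds (>= 8).
#' @param hr_bpm Mean heart rate in beats per minute (30-220); ignored for
#'   `"vf"` and used only as the template rate for `"af"`.
#' @param noise_sd Additive Gaussian noise amplitude in mV (R peak = 1 mV).
#' @param fs Sampling rate of the generated record in Hz.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `record` (an [ecg_record()]), `beats` (tibble with
#'   `time_s`, `index`, `pvc` truth marks; empty for `"vf"`), and `rhythm`.
#' @examples
#' synth_ecg("bg", duration_s = 16, seed = 7)$beats
#' @export
synth_ecg <- function(rhythm = RHYTHMS, duration_s = 8, hr_bpm = 70,
                      noise_sd = 0.02, fs = 300, seed = NULL) {
  rhythm <- match.arg(rhythm)
  if (duration_s < 8) ecg_abort("`duration_s` must be >= 8.", "config")
  if (hr_bpm < 30 || hr_bpm > 220) ecg_abort("`hr_bpm` must be in [30, 220].", "config")
  gen <- function() {
    n <- as.integer(round(duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    if (rhythm == "vf") {
      y <- synth_vf_samples(n, fs)
      beats <- tibble(time_s = numeric(0), index = integer(0), pvc = integer(0))
    } else {
      sched <- schedule_beats(rhythm, duration_s, hr_bpm)
      y <- numeric(n)
      for (i in seq_len(nrow(sched))) {
        # respiratory-style beat-to-beat amplitude modulation (+/- 10%)
        amp <- runif(1, 0.9, 1.1)
        for (bp in beat_bumps(sched$pvc[i] == 1L)) {
          y <- add_bump(y, t, sched$time_s[i] + bp[1], bp[2], amp * bp[3])
        }
      }
      keep <- sched$time_s >= 0 & sched$time_s < duration_s
      beats <- tibble(time_s = sched$time_s[keep],
                      index = as.integer(round(sched$time_s[keep] * fs)) + 1L,
                      pvc = sched$pvc[keep])
    }
    y <- y + rnorm(n, 0, noise_sd)
    list(record = ecg_record(y, fs = fs, record_id = paste0("synth-", rhythm)),
         beats = beats, rhythm = rhythm)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# beat times and PVC flags for a template rhythm; PVCs are premature
# (interval in scaled x0.8) with a compensatory pause after (x1.2)
schedule_beats <- function(rhythm, duration_s, hr_bpm) {
  rr <- 60 / hr_bpm
  n_max <- ceiling(duration_s / (0.8 * rr)) + 4L
  pat <- rep_len(pvc_pattern(rhythm), n_max)
  tm <- numeric(n_max)
  tm[1] <- 0.35 * rr
  for (i in 2:n_max) {
    base <- if (rhythm == "af") {
      runif(1, 0.4, 1.2)
    } else {
      # PVCs are premature: coupling interval 0.65 x RR (typical 60-80%
      # coupling), followed by a full compensatory pause (1.35 x RR)
      scale <- if (pat[i] == 1L) 0.65 else if (pat[i - 1L] == 1L) 1.35 else 1
      rr * scale * runif(1, 0.98, 1.02)
    }
    tm[i] <- tm[i - 1L] + base
  }
  keep <- tm < duration_s + 0.5  # allow a partial beat at the edge
  tibble(time_s = tm[keep], pvc = pat[keep])
}

synth_vf_samples <- function(n, fs) {
  y <- numeric(n)
  for (k in 1:3) {
    f <- runif(1, 3, 7)
    a <- runif(1, 0.5, 1)
    phase <- cumsum(2 * pi * f / fs + rnorm(n, 0, 0.05))
    y <- y + a * sin(phase)
  }
  # bring the summed oscillators to roughly the 1 mV scale of the R peak
  y / 2
}

#' Generate a multi-rhythm synthetic recording from blocks
#'
#' Concatenates independently synthesized rhythm blocks into one long
#' recording, e.g. the 128 s sequence of normal sinus rhythm and the six
#' PVC patterns used to exercise the full cascade. Block boundaries carry
#' the truth labels needed to score per-segment episode classification.
#'
#' @param rhythms Character vector of rhythm names (see [synth_ecg()]).
#' @param block_s Duration of each block in seconds (>= 8).
#' @param hr_bpm,noise_sd,fs Passed to [synth_ecg()].
#' @param seed Integer seed.
#' @return A list: `record` (concatenated [ecg_record()]), `blocks` (tibble
#'   `rhythm`, `start_s`, `end_s`), `beats` (truth beat tibble with
#'   absolute `time_s`).
#' @examples
#' seq <- synth_sequence(c("nsr", "bg", "vt"), block_s = 16, seed = 1)
#' seq$blocks
#' @export
synth_sequence <- function(rhythms, block_s = 16, hr_bpm = 70,
                           noise_sd = 0.02, fs = 300, seed = NULL) {
  stopifnot(length(rhythms) >= 1L)
  gen <- function() {
    parts <- lapply(seq_along(rhythms), function(i) {
      synth_ecg(rhythms[i], duration_s = block_s, hr_bpm = hr_bpm,
                noise_sd = noise_sd, fs = fs)
    })
    samples <- unlist(lapply(parts, function(p) p$record$samples))
    starts <- (seq_along(rhythms) - 1L) * block_s
    beats <- bind_rows(lapply(seq_along(parts), function(i) {
      b <- parts[[i]]$beats
      b$time_s <- b$time_s + starts[i]
      b$index <- b$index + as.integer(starts[i] * fs)
      b
    }))
    list(
      record = ecg_record(samples, fs = fs, record_id = "synth-sequence"),
      blocks = tibble(rhythm = rhythms, start_s = starts,
                      end_s = starts + block_s),
      beats = beats
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a balanced labelled feature dataset for one cascade stage
#'
#' Runs the real feature pipeline on freshly synthesized records and
#' returns a ready-to-classify feature table. The negative class of each
#' stage mirrors the population that stage faces in the cascade:
#' * `"vf"` - per-segment stage-1 features ([vf_features()]);
#'   ventricular-fibrillation segments versus non-VF segments (half normal
#'   sinus, half drawn from atrial fibrillation and the PVC-pattern
#'   rhythms);
#' * `"af"` - per-segment stage-2 RR features ([af_features()]); atrial
#'   fibrillation versus non-AF segments (half normal sinus, half
#'   PVC-pattern rhythms; segments whose features are not computable are
#'   re-drawn);
#' * `"pvc"` - per-beat stage-3 features ([pvc_features()]); PVC versus
#'   normal beats harvested from a rotation of normal-sinus, bigeminy,
#'   trigeminy, couplet and VT recordings, with truth labels matched from
#'   the generator schedule (within 100 ms).
#'
#' Heart rate is drawn per record from U(55, 95) bpm to give realistic
#' between-record variability. Deterministic given `seed`.
#'
#' @param stage `"vf"`, `"af"` or `"pvc"`.
#' @param n_per_class Samples per class (>= 10).
#' @param seed Integer seed.
#' @param noise_sd Additive noise level passed to [synth_ecg()].
#' @return A tibble of numeric features plus a two-level factor column
#'   `label`; the positive class (`"vf"`, `"af"` or `"pvc"`) is the last
#'   level.
#' @examples
#' d <- synth_dataset("vf", n_per_class = 10, seed = 1)
#' dplyr::count(d, label)
#' @export
synth_dataset <- function(stage = c("vf", "af", "pvc"), n_per_class = 100L,
                          seed = 1L, noise_sd = 0.02) {
  stage <- match.arg(stage)
  if (n_per_class < 10L) ecg_abort("`n_per_class` must be >= 10.", "config")
  withr::with_seed(seed, switch(stage,
    vf = synth_dataset_vf(n_per_class, noise_sd),
    af = synth_dataset_af(n_per_class, noise_sd),
    pvc = synth_dataset_pvc(n_per_class, noise_sd)
  ))
}

first_segment <- function(rhythm, noise_sd, hr_bpm = runif(1, 55, 95)) {
  rec <- synth_ecg(rhythm, duration_s = 8, hr_bpm = hr_bpm,
                   noise_sd = noise_sd)$record
  preprocess_ecg(rec)[1, ]
}

# negative-class rhythm pools: half normal sinus, half other non-target
# rhythms, mimicking the mixed arrhythmia populations each stage screens
non_vf_pool <- c("nsr", "af", "bg", "tg", "qg", "couplet", "triplet", "vt")
non_af_pool <- c("nsr", "bg", "tg", "qg", "couplet", "triplet", "vt")

draw_negative <- function(i, pool) {
  if (i %% 2L == 1L) "nsr" else sample(setdiff(pool, "nsr"), 1L)
}

synth_dataset_vf <- function(n_per_class, noise_sd) {
  feats <- function(i, rhythm) vf_features(first_segment(rhythm, noise_sd))[, -(1:2)]
  neg <- bind_rows(lapply(seq_len(n_per_class), function(i) {
    feats(i, draw_negative(i, non_vf_pool))
  }))
  pos <- bind_rows(lapply(seq_len(n_per_class), function(i) feats(i, "vf")))
  d <- bind_rows(neg, pos)
  d$label <- factor(rep(c("non-vf", "vf"), each = n_per_class),
                    levels = c("non-vf", "vf"))
  as_tibble(d)
}

synth_dataset_af <- function(n_per_class, noise_sd) {
  feats <- function(rhythm_for) {
    rows <- list()
    tries <- 0L
    while (length(rows) < n_per_class) {
      tries <- tries + 1L
      if (tries > 50L * n_per_class) {
        ecg_abort("too many unusable segments while building the AF dataset.",
                  "config")
      }
      f <- af_features(first_segment(rhythm_for(tries), noise_sd))
      if (f$usable) rows[[length(rows) + 1L]] <- f[, c("se_rr", "tpr", "rmssd_n")]
    }
    bind_rows(rows)
  }
  d <- bind_rows(feats(function(i) draw_negative(i, non_af_pool)),
                 feats(function(i) "af"))
  d$label <- factor(rep(c("non-af", "af"), each = n_per_class),
                    levels = c("non-af", "af"))
  as_tibble(d)
}

synth_dataset_pvc <- function(n_per_class, noise_sd) {
  # Per-segment normalization rescales beat amplitudes with rhythm content
  # (a normal beat in pure NSR is 'larger' than a PVC in pure VT), so each
  # class is harvested in equal shares from every segment context in which
  # it occurs; quotas per (class, source rhythm) keep the contexts balanced.
  pvc_src <- c("bg", "tg", "couplet", "vt")
  n_src <- c("nsr", "bg", "tg", "couplet")
  share <- ceiling(n_per_class / 4)
  pvc_rows <- list(); n_rows <- list()
  pvc_got <- setNames(rep(0L, 4), pvc_src)
  n_got <- setNames(rep(0L, 4), n_src)
  sources <- c("nsr", "bg", "tg", "couplet", "vt")
  k <- 0L
  while (length(pvc_rows) < n_per_class || length(n_rows) < n_per_class) {
    k <- k + 1L
    if (k > 100L * length(sources)) {
      ecg_abort("beat harvest did not converge.", "config")
    }
    rhythm <- sources[(k - 1L) %% length(sources) + 1L]
    want_pvc <- rhythm %in% pvc_src && pvc_got[rhythm] < share &&
      length(pvc_rows) < n_per_class
    want_n <- rhythm %in% n_src && n_got[rhythm] < share &&
      length(n_rows) < n_per_class
    if (!want_pvc && !want_n) next
    s <- synth_ecg(rhythm, duration_s = 16, hr_bpm = runif(1, 55, 95),
                   noise_sd = noise_sd)
    segs <- preprocess_ecg(s$record)
    beats <- extract_beats(segs)
    if (nrow(beats) == 0L) next
    truth <- match_beat_truth(beats, segs, s$beats)
    # training-set curation: drop beats whose 200-sample window overlaps an
    # opposite-class neighbour's QRS-T support (at fast rates a premature
    # PVC's wide QRS bleeds into the preceding normal beat's window); such
    # transitional windows carry both morphologies and no clean label
    start <- segs$start_s[match(beats$segment_id, segs$segment_id)]
    abs_t <- start + (beats$r_index - 1L) / segs$fs[[1]]
    clean <- vapply(seq_len(nrow(beats)), function(i) {
      if (is.na(truth[i])) return(FALSE)
      others <- s$beats$time_s[s$beats$pvc != truth[i]]
      length(others) == 0L || all(abs(others - abs_t[i]) >= 0.55)
    }, logical(1))
    f <- pvc_features(beats)
    for (i in seq_len(nrow(f))) {
      if (is.na(truth[i]) || !clean[i]) next
      row <- f[i, c("lmmd", "msa", "wse", "kurt")]
      if (truth[i] == 1L && want_pvc && pvc_got[rhythm] < share &&
          length(pvc_rows) < n_per_class) {
        pvc_rows[[length(pvc_rows) + 1L]] <- row
        pvc_got[rhythm] <- pvc_got[rhythm] + 1L
      } else if (truth[i] == 0L && want_n && n_got[rhythm] < share &&
                 length(n_rows) < n_per_class) {
        n_rows[[length(n_rows) + 1L]] <- row
        n_got[rhythm] <- n_got[rhythm] + 1L
      }
    }
    # once every per-source quota is met but totals are short, let any
    # source top the class up
    if (all(pvc_got >= share)) pvc_got[] <- 0L
    if (all(n_got >= share)) n_got[] <- 0L
  }
  d <- bind_rows(bind_rows(n_rows), bind_rows(pvc_rows))
  d$label <- factor(rep(c("n", "pvc"), each = n_per_class),
                    levels = c("n", "pvc"))
  as_tibble(d)
}

# map detected beats back to generator truth: nearest scheduled beat within
# 100 ms; NA when unmatched (spurious detection)
match_beat_truth <- function(beats, segs, truth_beats, tol_s = 0.1) {
  if (nrow(truth_beats) == 0L) return(rep(NA_integer_, nrow(beats)))
  start <- segs$start_s[match(beats$segment_id, segs$segment_id)]
  fs <- segs$fs[[1]]
  abs_t <- start + (beats$r_index - 1L) / fs
  vapply(abs_t, function(tt) {
    j <- which.min(abs(truth_beats$time_s - tt))
    if (abs(truth_beats$time_s[j] - tt) <= tol_s) truth_beats$pvc[j] else NA_integer_
  }, integer(1))
}
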