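#' Simulation configuration for synthetic single-trial current densities
#'
#' Collects every knob of the synthetic generator. Defaults reproduce the
#' study design the downstream analysis assumes: 22 subjects (13 control,
#' 9 patient), 2014 control and 1580 patient trials, a 400 samples/s epoch
#' covering [-200, 1500) ms, and a patient-specific activity increase in the
#' named effect regions during a raised-cosine temporal window on 100-300 ms
#' that peaks at 200 ms, inside the analysed 150-250 ms period.
#'
#' @param n_subjects_control,n_subjects_patient subject counts (13, 9).
#' @param trials_per_subject either `NULL` (default: a deterministic schedule
#'   distributing `trials_total_control`/`trials_total_patient` over subjects,
#'   first subjects taking the remainder) or a single count applied to every
#'   subject.
#' @param trials_total_control,trials_total_patient group trial totals used
#'   when `trials_per_subject` is `NULL` (defaults 2014 and 1580).
#' @param sampling_rate samples per second (400).
#' @param epoch_ms half-open epoch `[t0, t1)` in ms (default `c(-200, 1500)`,
#'   giving 680 samples with t = 0 on a sample).
#' @param baseline constant baseline current density added to every vertex.
#' @param effect_size named vector of per-region patient-minus-control effect
#'   amplitudes (current-density units at the temporal peak). Names must be
#'   region labels of the source space. Default: 1.0 for each of the six
#'   default regions.
#' @param effect_window_ms support of the raised-cosine temporal bump
#'   (default `c(100, 300)`; peak at its midpoint).
#' @param subject_sd between-subject SD of the per-vertex random offset.
#' @param noise_sd within-trial sample noise SD.
#' @param clinical_coupling data frame (`score`, `region`, `slope`,
#'   `noise_sd`) mapping patient clinical scores to the subject-mean activity
#'   of a region over the 150-250 ms window; multiple rows per score add up.
#'   See [default_clinical_coupling()].
#' @param clinical_intercept named vector of score intercepts.
#' @param clinical_uncoupled_sd SD (scale points) of the noise given to
#'   scores with no configured coupling, so every score varies across
#'   subjects.
#' @param eog_blink_prob per-trial probability of an ocular blink.
#' @param eog_blink_amp_mean,eog_blink_amp_sd blink amplitude distribution
#'   (microvolts).
#' @param eog_noise_sd background EOG noise SD (microvolts).
#' @param seed integer seed; the whole generation is a pure function of the
#'   configuration including this seed.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects_control = 13L,
                              n_subjects_patient = 9L,
                              trials_per_subject = NULL,
                              trials_total_control = 2014L,
                              trials_total_patient = 1580L,
                              sampling_rate = 400,
                              epoch_ms = c(-200, 1500),
                              baseline = 0,
                              effect_size = NULL,
                              effect_window_ms = c(100, 300),
                              subject_sd = 0.2,
                              noise_sd = 1.0,
                              clinical_coupling = default_clinical_coupling(),
                              clinical_intercept = NULL,
                              clinical_uncoupled_sd = 2,
                              eog_blink_prob = 0.1,
                              eog_blink_amp_mean = 120,
                              eog_blink_amp_sd = 30,
                              eog_noise_sd = 10,
                              seed = 1L) {
  if (is.null(effect_size)) {
    effect_size <- c(superior_frontal = 1, inferior_temporal = 1, insular = 1,
                     superior_parietal = 1, lateral_occipital = 1,
                     superior_temporal = 1)
  }
  if (is.null(clinical_intercept)) {
    clinical_intercept <- c(IRLS = 20, PSQI = 10, ESS = 10, ISI = 12,
                            BDI = 12, HADS_anxiety = 8, HADS_depression = 8)
  }
  cfg <- list(
    n_subjects_control = as.integer(n_subjects_control),
    n_subjects_patient = as.integer(n_subjects_patient),
    trials_per_subject = trials_per_subject,
    trials_total_control = as.integer(trials_total_control),
    trials_total_patient = as.integer(trials_total_patient),
    sampling_rate = sampling_rate,
    epoch_ms = epoch_ms,
    baseline = baseline,
    effect_size = effect_size,
    effect_window_ms = effect_window_ms,
    subject_sd = subject_sd,
    noise_sd = noise_sd,
    clinical_coupling = clinical_coupling,
    clinical_intercept = clinical_intercept,
    clinical_uncoupled_sd = clinical_uncoupled_sd,
    eog_blink_prob = eog_blink_prob,
    eog_blink_amp_mean = eog_blink_amp_mean,
    eog_blink_amp_sd = eog_blink_amp_sd,
    eog_noise_sd = eog_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$subject_sd < 0 || cfg$noise_sd < 0 || cfg$eog_noise_sd < 0) {
    stop_("all standard deviations must be non-negative")
  }
  if (length(cfg$epoch_ms) != 2L || cfg$epoch_ms[1] >= cfg$epoch_ms[2]) {
    stop_("epoch_ms must be an increasing pair")
  }
  if (cfg$epoch_ms[1] > 150 || cfg$epoch_ms[2] < 250) {
    stop_("epoch must cover the 150-250 ms analysis window")
  }
  if (cfg$n_subjects_control < 1L || cfg$n_subjects_patient < 1L) {
    stop_("need at least one subject per group")
  }
  invisible(cfg)
}

#' Default clinical-score couplings
#'
#' Region-to-score couplings with the sign pattern of the study design the
#' generator emulates: the left insular region couples positively to PSQI,
#' ISI, HADS anxiety and IRLS; the left inferior temporal region negatively
#' to PSQI and IRLS; the right superior temporal region negatively to ESS.
#' BDI and HADS depression are left uncoupled.
#'
#' @param slope absolute slope in score points per current-density unit.
#' @param noise_sd score noise SD in scale points.
#' @return data frame (`score`, `region`, `slope`, `noise_sd`).
#' @export
default_clinical_coupling <- function(slope = 5, noise_sd = 2) {
  data.frame(
    score = c("PSQI", "ISI", "HADS_anxiety", "IRLS",
              "PSQI", "IRLS", "ESS"),
    region = c("insular", "insular", "insular", "insular",
               "inferior_temporal", "inferior_temporal", "superior_temporal"),
    slope = c(slope, slope, slope, slope, -slope, -slope, -slope),
    noise_sd = noise_sd,
    stringsAsFactors = FALSE
  )
}

#' Clinical score names in the canonical table order
#' @return character vector of the seven score names.
#' @export
clinical_score_names <- function() {
  c("ESS", "ISI", "BDI", "PSQI", "HADS_anxiety", "HADS_depression", "IRLS")
}

# Deterministic per-subject trial schedule: floor(total/n) each, remainder
# given one extra trial to the first subjects.
distribute_trials <- function(total, n) {
  base <- total %/% n
  extra <- total - base * n
  base + as.integer(seq_len(n) <= extra)
}

# Sample times (ms) of the half-open epoch [t0, t1) at `fs` samples/s, with
# t = 0 on a sample when the epoch brackets zero.
epoch_times <- function(epoch_ms, fs) {
  step <- 1000 / fs
  seq(epoch_ms[1], epoch_ms[2] - step / 2, by = step)
}

# Raised-cosine bump on [w1, w2], peak 1 at the midpoint, 0 outside.
raised_cosine <- function(t, window) {
  w <- numeric(length(t))
  inside <- t >= window[1] & t <= window[2]
  w[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - window[1]) /
                                (window[2] - window[1])))
  w
}

#' Generate synthetic single-trial current densities and clinical scores
#'
#' Draws a full trial set on a cortical source space under the additive model
#' \deqn{x(v,t) = \mu + g\,\delta_{r(v)} w(t) + b_s(v) + \varepsilon(v,t)}
#' where \eqn{g = 1} for patient trials and 0 for controls, \eqn{w(t)} is a
#' raised-cosine bump on the configured effect window, \eqn{b_s(v)} is a
#' subject-by-vertex random offset with SD `subject_sd`, and
#' \eqn{\varepsilon} is white noise with SD `noise_sd`. Patient clinical
#' scores are generated as linear functions of the subject's mean activity
#' over each coupled region in the 150-250 ms window, plus noise.
#'
#' The bump is normalized to unit mean over the samples falling in the
#' 150-250 ms analysis window, so `effect_size` equals the expected group
#' difference of window-averaged current density in the affected region.
#'
#' @param space a `cortical_space` from [generate_source_space()].
#' @param config a `sim_config` from [simulation_config()].
#' @return list with components `trials` (class `trial_set`: `data` array
#'   trials x vertices x time, `subject`, `group`, `eog` matrix trials x time,
#'   `times`, `retained`) and `clinical` (data frame, one row per patient
#'   subject with the seven scores).
#' @examples
#' sp <- generate_source_space(60, region_spec = default_region_spec())
#' cfg <- simulation_config(n_subjects_control = 2, n_subjects_patient = 2,
#'                          trials_per_subject = 3, epoch_ms = c(0, 400),
#'                          seed = 7)
#' sim <- generate_trials(sp, cfg)
#' dim(sim$trials$data)
#' @export
generate_trials <- function(space, config) {
  stopifnot(inherits(space, "cortical_space"), inherits(config, "sim_config"))
  validate_sim_config(config)

  n_c <- config$n_subjects_control
  n_p <- config$n_subjects_patient
  if (is.null(config$trials_per_subject)) {
    sched_c <- distribute_trials(config$trials_total_control, n_c)
    sched_p <- distribute_trials(config$trials_total_patient, n_p)
  } else {
    sched_c <- rep(as.integer(config$trials_per_subject), n_c)
    sched_p <- rep(as.integer(config$trials_per_subject), n_p)
  }

  subjects <- c(sprintf("C%02d", seq_len(n_c)), sprintf("P%02d", seq_len(n_p)))
  groups <- rep(c("control", "patient"), c(n_c, n_p))
  sched <- c(sched_c, sched_p)
  n_trials <- sum(sched)

  times <- epoch_times(config$epoch_ms, config$sampling_rate)
  n_t <- length(times)
  verts <- space$vertices
  n_v <- nrow(verts)

  delta_v <- numeric(n_v)
  if (length(config$effect_size)) {
    for (r in names(config$effect_size)) {
      delta_v[verts$region == r] <- config$effect_size[[r]]
    }
  }
  # Raised-cosine bump, normalized so its mean over the samples of the
  # 150-250 ms analysis window is 1: effect_size is then exactly the
  # patient-minus-control difference of window-averaged activity.
  w_t <- raised_cosine(times, config$effect_window_ms)
  crit <- times >= 150 & times <= 250
  wbar <- mean(w_t[crit])
  if (is.finite(wbar) && wbar > 0) w_t <- w_t / wbar

  trial_subject <- rep(subjects, sched)
  trial_group <- rep(groups, sched)

  with_seed(config$seed, {
    data <- array(0, dim = c(n_trials, n_v, n_t))
    eog <- matrix(0, n_trials, n_t)

    b_subj <- matrix(rnorm(length(subjects) * n_v, sd = config$subject_sd),
                     nrow = length(subjects))
    row0 <- 0L
    for (s in seq_along(subjects)) {
      g <- as.numeric(groups[s] == "patient")
      mean_vt <- config$baseline + b_subj[s, ] +
        if (g > 0) outer(delta_v, w_t) else 0
      if (is.null(dim(mean_vt))) mean_vt <- matrix(mean_vt, n_v, n_t)
      for (k in seq_len(sched[s])) {
        noise <- if (config$noise_sd > 0) {
          matrix(rnorm(n_v * n_t, sd = config$noise_sd), n_v, n_t)
        } else 0
        data[row0 + k, , ] <- mean_vt + noise
      }
      row0 <- row0 + sched[s]
    }

    # EOG channel: background noise plus occasional raised-cosine blinks.
    eog[] <- rnorm(n_trials * n_t, sd = config$eog_noise_sd)
    blink <- runif(n_trials) < config$eog_blink_prob
    for (i in which(blink)) {
      amp <- rnorm(1, config$eog_blink_amp_mean, config$eog_blink_amp_sd)
      centre <- runif(1, min(times) + 100, max(times) - 100)
      eog[i, ] <- eog[i, ] + amp * raised_cosine(times, c(centre - 100, centre + 100))
    }

    trials <- structure(
      list(data = data, subject = trial_subject, group = trial_group,
           eog = eog, times = times, retained = rep(TRUE, n_trials),
           space_n_vertices = n_v),
      class = "trial_set"
    )

    clinical <- make_clinical(trials, verts, config)
    list(trials = trials, clinical = clinical)
  })
}

# Patient clinical scores from subject-mean regional activity (150-250 ms).
make_clinical <- function(trials, verts, config) {
  pat_subjects <- unique(trials$subject[trials$group == "patient"])
  win <- trials$times >= 150 & trials$times <= 250
  scores <- clinical_score_names()
  out <- data.frame(subject = pat_subjects, stringsAsFactors = FALSE)
  coup <- config$clinical_coupling
  coupled <- if (is.null(coup)) character(0) else unique(coup$score)
  for (sc in scores) {
    out[[sc]] <- config$clinical_intercept[[sc]] +
      if (sc %in% coupled) 0 else rnorm(length(pat_subjects),
                                        sd = config$clinical_uncoupled_sd)
  }
  # subject-mean activity per coupled region
  for (i in seq_len(nrow(coup %||% data.frame()))) {
    region_v <- which(verts$region == coup$region[i])
    if (!length(region_v)) next
    act <- vapply(pat_subjects, function(s) {
      rows <- which(trials$subject == s)
      mean(trials$data[rows, region_v, win])
    }, numeric(1))
    sc <- coup$score[i]
    out[[sc]] <- out[[sc]] + coup$slope[i] * act +
      rnorm(length(pat_subjects), sd = coup$noise_sd[i])
  }
  out
}

#' @export
print.trial_set <- function(x, ...) {
  cat("Trial set:", dim(x$data)[1], "trials x", dim(x$data)[2], "vertices x",
      dim(x$data)[3], "samples\n")
  cat("Groups:", paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                       collapse = ", "), "\n")
  cat("Subjects:", length(unique(x$subject)),
      "| retained trials:", sum(x$retained), "/", length(x$retained), "\n")
  invisible(x)
}
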