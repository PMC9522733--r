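#' Synthetic cohort generator configuration
#'
#' Distributional knobs for the synthetic control and sagittal-synostosis
#' cohorts. Defaults emulate the clinical setting the pipeline targets:
#' control mean thickness centred at 380 um with a subject-level SD of 63 um
#' (so the 95% central range spans roughly 256-504 um and the control median
#' sits near 378 um), a median patient elevation of ~24 um, a latent
#' intracranial-hypertension (ICH) state in ~12% of patients driving a large
#' thickness elevation, fundoscopic papilledema (overall prevalence ~4.3%)
#' and the clinical signs, pseudopapilledema (~2%) tied to high hyperopia
#' with a normal-range volume, 78%/44% male fractions, ages within the
#' pediatric screening window, and two eyes per subject with high inter-eye
#' correlation.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param seed Master seed; every subject draws from a counter-based
#'   substream of it, so changing a cohort size does not reshuffle earlier
#'   subjects.
#' @param control_trt_mean Control subject-level mean thickness, um.
#' @param control_trt_sd SD of the subject-level mean thickness, um.
#' @param patient_trt_shift Median patient elevation, um.
#' @param papilledema_prevalence Overall fundoscopic papilledema prevalence
#'   among patients (papilledema occurs only in latent-ICH subjects).
#' @param papilledema_trt_effect Extra thickness elevation in latent-ICH
#'   subjects (and, thickness-only, in pseudopapilledema), um.
#' @param pseudopapilledema_prevalence Pseudopapilledema prevalence among
#'   patients.
#' @param ich_latent_prevalence Latent ICH prevalence among patients.
#' @param sign_probabilities Named list (`growth_arrest`, `fingerprinting`,
#'   `headache`) of length-2 vectors: P(sign | no ICH), P(sign | ICH).
#' @param sign_missing_rates Named list of per-sign missingness rates.
#' @param sector_noise_sd Within-eye per-sector noise SD, um.
#' @param intereye_correlation Correlation of the two eyes' subject-level
#'   means, in \[0, 1\].
#' @param male_fraction_controls,male_fraction_patients Male fractions.
#' @param missing_sector_rate Per-sector missingness rate.
#' @param trv_noise_sd SD of the multiplicative (log-scale) noise linking
#'   sector volume to the thickness-implied volume.
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_controls = 64,
                             n_patients = 93,
                             seed = 1,
                             control_trt_mean = 380,
                             control_trt_sd = 63,
                             patient_trt_shift = 24,
                             papilledema_prevalence = 0.043,
                             papilledema_trt_effect = 150,
                             pseudopapilledema_prevalence = 0.022,
                             ich_latent_prevalence = 0.12,
                             sign_probabilities = list(
                               growth_arrest  = c(0.03, 0.50),
                               fingerprinting = c(0.23, 0.57),
                               headache       = c(0.07, 0.27)),
                             sign_missing_rates = list(
                               growth_arrest  = 0.03,
                               fingerprinting = 0.40,
                               headache       = 0.25),
                             sector_noise_sd = 20,
                             intereye_correlation = 0.9,
                             male_fraction_controls = 0.44,
                             male_fraction_patients = 0.78,
                             missing_sector_rate = 0.01,
                             trv_noise_sd = 0.03) {
  cfg <- as.list(environment())
  props <- c("papilledema_prevalence", "pseudopapilledema_prevalence",
             "ich_latent_prevalence", "intereye_correlation",
             "male_fraction_controls", "male_fraction_patients",
             "missing_sector_rate")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("generator config: ", p, " must be in [0, 1]", call. = FALSE)
  }
  if (cfg$papilledema_prevalence > cfg$ich_latent_prevalence)
    stop("generator config: papilledema_prevalence cannot exceed ",
         "ich_latent_prevalence (papilledema arises from latent ICH)",
         call. = FALSE)
  for (p in c("control_trt_sd", "sector_noise_sd", "trv_noise_sd"))
    if (cfg[[p]] < 0) stop("generator config: ", p, " must be >= 0",
                           call. = FALSE)
  stopifnot(cfg$n_controls >= 1, cfg$n_patients >= 0,
            cfg$control_trt_sd^2 > cfg$sector_noise_sd^2 / 8)
  for (s in names(cfg$sign_probabilities))
    stopifnot(all(cfg$sign_probabilities[[s]] >= 0),
              all(cfg$sign_probabilities[[s]] <= 1))
  structure(cfg, class = "generator_config")
}

# Sector mean profile (um), canonical sector order; anchored so that ring
# and sector means sit at the midpoints of the published normative ranges
# while the offsets sum to zero around the configurable overall mean.
.sector_midpoints <- c(392.40, 376.85, 370.90, 430.50,
                       422.00, 437.60, 336.45, 313.45)
.sector_offsets <- .sector_midpoints - mean(.sector_midpoints)

# Counter-based substream: one deterministic seed per (domain, subject).
.substream_seed <- function(seed, domain, i) {
  ((as.double(seed) %% 65536) * 32003 + domain * 1000003 + i * 7919) %%
    2147483647
}

.draw_eye_sectors <- function(base_mean, sector_noise_sd, trv_noise_sd,
                              missing_sector_rate, trt_extra = 0) {
  trt <- base_mean + .sector_offsets + stats::rnorm(8, 0, sector_noise_sd)
  trt_obs <- trt + trt_extra
  ring <- rep(c("outer", "inner"), 4)
  area <- ifelse(ring == "outer", sector_area("outer"), sector_area("inner"))
  # volume follows the *unelevated-or-elevated* thickness passed via trt for
  # volume purposes; caller controls coherence by choosing trt_extra_for_trv
  trv <- (trt / 1000) * area * exp(stats::rnorm(8, 0, trv_noise_sd))
  miss <- stats::runif(8) < missing_sector_rate
  trt_obs[miss] <- NA_real_
  trv[miss] <- NA_real_
  list(trt = trt_obs, trv = trv)
}

.eye_row <- function(sid, group, sex, age, re, eye, fundoscopy, headache,
                     f1, f2, sec) {
  row <- data.frame(subject_id = sid, group = group, sex = sex,
                    age_years = age, re_diopters = re, eye = eye,
                    fundoscopy = fundoscopy, headache = headache,
                    fingerprint_r1 = f1, fingerprint_r2 = f2,
                    stringsAsFactors = FALSE)
  row[sector_columns("trt")] <- as.list(sec$trt)
  row[sector_columns("trv")] <- as.list(sec$trv)
  row
}

#' Generate a synthetic control + patient cohort
#'
#' Draws the control and sagittal-synostosis cohorts described in
#' [generator_config()]. Each subject has two eyes; sector thickness is a
#' shared subject effect plus an eye effect (inter-eye correlation as
#' configured) plus a canonical sector profile plus noise; sector volume is
#' derived geometrically from thickness with small multiplicative noise. In
#' patients a latent ICH state drives a large thickness elevation,
#' fundoscopic papilledema and the clinical signs; pseudopapilledema
#' subjects get high hyperopia (>= +4 D) and a thickness-only elevation, so
#' their volume stays in the normal range. Output is bit-identical for a
#' given config.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (validated subject-eye data frame, two rows
#'   per subject) and `truth` (per-subject latent states: `ich`,
#'   `papilledema`, `pseudopapilledema`, true `growth_arrest`,
#'   `fingerprinting`, `headache`, plus `sex` and `age_years` for the
#'   trajectory generator).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  cfg <- config
  eff_var <- cfg$control_trt_sd^2 - cfg$sector_noise_sd^2 / 8
  sd_shared <- sqrt(cfg$intereye_correlation * eff_var)
  sd_eye <- sqrt((1 - cfg$intereye_correlation) * eff_var)

  rows <- vector("list", 2 * (cfg$n_controls + cfg$n_patients))
  truth <- vector("list", cfg$n_controls + cfg$n_patients)
  k <- 0L; tk <- 0L

  for (i in seq_len(cfg$n_controls)) {
    set.seed(.substream_seed(cfg$seed, 1, i))
    sid <- sprintf("C%03d", i)
    sex <- if (stats::runif(1) < cfg$male_fraction_controls) "M" else "F"
    age <- 4 + stats::rbeta(1, 2.2, 1.6) * 6.8
    re <- round(stats::runif(1, -2.4, 3.9), 2)
    u <- stats::rnorm(1, 0, sd_shared)
    for (eye in c("OD", "OS")) {
      v <- stats::rnorm(1, 0, sd_eye)
      sec <- .draw_eye_sectors(cfg$control_trt_mean + u + v,
                               cfg$sector_noise_sd, cfg$trv_noise_sd,
                               cfg$missing_sector_rate)
      k <- k + 1L
      rows[[k]] <- .eye_row(sid, "control", sex, age, re, eye, "normal",
                            NA_integer_, NA_integer_, NA_integer_, sec)
    }
    tk <- tk + 1L
    truth[[tk]] <- data.frame(
      subject_id = sid, group = "control", sex = sex, age_years = age,
      ich = FALSE, papilledema = FALSE, pseudopapilledema = FALSE,
      growth_arrest = NA, fingerprinting = NA, headache = NA,
      stringsAsFactors = FALSE)
  }

  p_pap_given_ich <- if (cfg$ich_latent_prevalence > 0)
    cfg$papilledema_prevalence / cfg$ich_latent_prevalence else 0
  for (i in seq_len(cfg$n_patients)) {
    set.seed(.substream_seed(cfg$seed, 2, i))
    sid <- sprintf("P%03d", i)
    sex <- if (stats::runif(1) < cfg$male_fraction_patients) "M" else "F"
    age <- 3 + stats::rbeta(1, 2, 3) * 7
    ich <- stats::runif(1) < cfg$ich_latent_prevalence
    pap <- ich && stats::runif(1) < p_pap_given_ich
    pseudo <- !ich && stats::runif(1) <
      cfg$pseudopapilledema_prevalence / max(1e-12, 1 - cfg$ich_latent_prevalence)
    re <- if (pseudo) round(stats::runif(1, 4.5, 8), 1) else NA_real_
    fundo <- if (pap) "papilledema" else if (pseudo) "pseudopapilledema" else "normal"

    sp <- cfg$sign_probabilities
    arrest_true <- stats::runif(1) < sp$growth_arrest[1 + ich]
    finger_true <- stats::runif(1) < sp$fingerprinting[1 + ich]
    heada_true  <- stats::runif(1) < sp$headache[1 + ich]
    # observed signs with per-sign missingness
    mr <- cfg$sign_missing_rates
    heada_obs <- if (stats::runif(1) < mr$headache) NA_integer_ else
      as.integer(heada_true)
    finger_missing <- stats::runif(1) < mr$fingerprinting
    base_score <- if (finger_true) 2L else if (stats::runif(1) < 0.35) 1L else 0L
    jit <- function(s) {
      if (stats::runif(1) < 0.95) s else
        max(0L, min(2L, s + sample(c(-1L, 1L), 1)))
    }
    f1 <- if (finger_missing) NA_integer_ else jit(base_score)
    f2 <- if (finger_missing) NA_integer_ else jit(base_score)

    u <- stats::rnorm(1, 0, sd_shared)
    elev <- if (ich) cfg$papilledema_trt_effect * stats::runif(1, 0.8, 1.2) else 0
    pseudo_elev <- if (pseudo) cfg$papilledema_trt_effect * stats::runif(1, 0.8, 1.1) else 0
    for (eye in c("OD", "OS")) {
      v <- stats::rnorm(1, 0, sd_eye)
      base <- cfg$control_trt_mean + cfg$patient_trt_shift + u + v + elev
      sec <- .draw_eye_sectors(base, cfg$sector_noise_sd, cfg$trv_noise_sd,
                               cfg$missing_sector_rate,
                               trt_extra = pseudo_elev)
      k <- k + 1L
      rows[[k]] <- .eye_row(sid, "sagittal", sex, age, re, eye, fundo,
                            heada_obs, f1, f2, sec)
    }
    tk <- tk + 1L
    truth[[tk]] <- data.frame(
      subject_id = sid, group = "sagittal", sex = sex, age_years = age,
      ich = ich, papilledema = pap, pseudopapilledema = pseudo,
      growth_arrest = arrest_true, fingerprinting = finger_true,
      headache = heada_true, stringsAsFactors = FALSE)
  }

  cohort <- do.call(rbind, rows[seq_len(k)])
  list(cohort = validate_cohort(cohort),
       truth = do.call(rbind, truth[seq_len(tk)]))
}

#' Synthetic head-circumference growth reference
#'
#' A smooth synthetic stand-in for a national occipitofrontal-circumference
#' (OFC) growth standard: per sex, mean and SD of OFC (cm) on a dense age
#' grid. It is *not* a population standard; real standards can be supplied
#' to [ofc_to_sds()] in the same schema (`sex`, `age_years`, `mean_cm`,
#' `sd_cm`).
#'
#' @param ages Age grid in years (default 0.25 to 12 by 0.25).
#' @return Data frame with columns `sex`, `age_years`, `mean_cm`, `sd_cm`.
#' @export
synthetic_growth_reference <- function(ages = seq(0.25, 12, by = 0.25)) {
  one <- function(sex) {
    base <- 36 + 11.5 * (1 - exp(-ages / 0.55)) + 0.45 * ages
    data.frame(sex = sex,
               age_years = ages,
               mean_cm = base + if (sex == "M") 1.0 else 0,
               sd_cm = 1.4 + 0.02 * ages,
               stringsAsFactors = FALSE)
  }
  rbind(one("M"), one("F"))
}

#' Generate synthetic OFC trajectories
#'
#' For each patient, draws 4-8 (age, OFC) points from a post-surgical
#' baseline to the scan age. Subjects marked arrest-positive in the truth
#' table decline by at least 0.5 SD over every 2-year window (linear decline
#' of 0.7-1.2 SD per 2 years plus small noise); arrest-negative subjects
#' fluctuate within about +/-0.3 SD. SD scores are converted to centimetres
#' against the supplied growth reference.
#'
#' @param config A [generator_config()] (supplies the master seed).
#' @param truth Truth table from [generate_cohort()].
#' @param growth_ref Growth reference table
#'   (default [synthetic_growth_reference()]).
#' @return Data frame with columns `subject_id`, `age_years`, `ofc_cm`.
#' @export
generate_trajectories <- function(config, truth,
                                  growth_ref = synthetic_growth_reference()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  pts <- list()
  pat <- truth[truth$group == "sagittal", , drop = FALSE]
  for (i in seq_len(nrow(pat))) {
    set.seed(.substream_seed(config$seed, 3, i))
    sid <- pat$subject_id[i]
    scan_age <- pat$age_years[i]
    baseline_age <- max(0.8, min(2.0, scan_age - 2.2))
    npt <- sample(4:8, 1)
    ages <- sort(c(baseline_age, stats::runif(npt - 2, baseline_age, scan_age),
                   scan_age))
    s0 <- stats::rnorm(1, 0.3, 0.7)
    if (isTRUE(pat$growth_arrest[i])) {
      slope <- stats::runif(1, 0.35, 0.6)          # SD per year, downward
      sds <- s0 - slope * (ages - baseline_age) + stats::rnorm(npt, 0, 0.03)
    } else {
      phase <- stats::runif(1, 0, 2 * pi)
      sds <- s0 + 0.12 * sin(phase + ages) + stats::rnorm(npt, 0, 0.03)
    }
    mu <- .interp_ref(growth_ref, pat$sex[i], ages, "mean_cm")
    sg <- .interp_ref(growth_ref, pat$sex[i], ages, "sd_cm")
    pts[[i]] <- data.frame(subject_id = sid, age_years = ages,
                           ofc_cm = mu + sds * sg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}
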