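# Synthetic billing-data generator: hospitals on trial steps, physicians with
# multi-hospital billing shares, patient encounters dense enough that
# within-hospital subnetworks are complete, and participation outcomes from a
# sequential adoption process with known coefficients.

#' Configuration for a synthetic billing study
#'
#' Defines the full set of generating conditions for a synthetic
#' stepped-wedge physician-participation study: the hospital/physician/patient
#' population, multi-hospital billing behaviour, and the coefficients of the
#' logistic adoption process. Defaults emulate the observed cohort structure:
#' 40 acute-care hospitals randomized over 5 steps, roughly 350 invited
#' hospitalists averaging ~1.7 billing hospitals (range 1-9), near-complete
#' within-hospital patient sharing, mean age ~42 with ~15% missing, and
#' peer-effect coefficients equal to the log odds ratios the participation
#' analysis reports.
#'
#' @param n_hospitals number of hospitals.
#' @param n_steps number of trial steps; hospitals are assigned to steps as
#'   evenly as possible.
#' @param physicians_per_hospital integer or `c(lo, hi)` range of physicians
#'   recruited at each hospital.
#' @param multi_site_fraction proportion of physicians billing at more than
#'   one hospital.
#' @param max_sites maximum number of billing hospitals per physician.
#' @param site_share_concentration concentration of the symmetric
#'   Dirichlet-type draw of a multi-site physician's billing shares; small
#'   values give one dominant hospital plus minor secondary activity.
#' @param patients_per_hospital integer or range of inpatients per hospital.
#' @param encounters_per_patient integer or range of billed encounters for
#'   each physician-patient pair that occurs.
#' @param patient_share_rate probability scale with which a physician billing
#'   at a hospital sees each of its (non-handoff) patients; the realized
#'   probability is `patient_share_rate` times the physician's billing share
#'   there, so encounter volume tracks shares.
#' @param n_handoff_patients number of patients per hospital seen by every
#'   physician billing there (long-stay inpatients handed between the whole
#'   hospitalist group); guarantees complete within-hospital subnetworks and
#'   a positive volume at every billing site.
#' @param beta named list of generating coefficients on the logit scale:
#'   `b0` intercept, `b1` named vector over covariate columns (see
#'   [derive_covariates()]), `b2` Shannon diversity, `b3` within-hospital
#'   peer participation (percent scale), `b4` across-hospital peer
#'   participation (transformed scale), `b5` its modification by the number
#'   of non-primary billing hospitals.
#' @param tau standard deviation of the hospital-level random intercepts.
#' @param age_missing_rate proportion of physicians with unrecorded age.
#' @param age_mean,age_sd,years_mean,years_sd,sex_male_prob moments of the
#'   physician characteristic distributions.
#' @param across_transform transform applied to the raw across-hospital
#'   exposure inside the adoption process; see [transform_across()].
#' @param window two dates bounding billing dates (ISO-8601 strings or
#'   Dates).
#' @param seed integer root seed; every generator stage derives its own
#'   stream from it, so an identical config yields byte-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_hospitals = 5, physicians_per_hospital = 4,
#'                   patients_per_hospital = 10, seed = 7)
#' @export
sim_config <- function(n_hospitals = 40L,
                       n_steps = 5L,
                       physicians_per_hospital = c(6L, 12L),
                       multi_site_fraction = 0.36,
                       max_sites = 9L,
                       site_share_concentration = 0.05,
                       patients_per_hospital = c(30L, 60L),
                       encounters_per_patient = c(1L, 4L),
                       patient_share_rate = 0.7,
                       n_handoff_patients = 2L,
                       beta = list(b0 = -2.6,
                                   b1 = c(years_c = log(1.52)),
                                   b2 = log(7.28),
                                   b3 = log(1.05),
                                   b4 = 0,
                                   b5 = log(1.12)),
                       tau = 0.126,
                       age_missing_rate = 0.146,
                       age_mean = 42.27, age_sd = 8.32,
                       years_mean = 3.62, years_sd = 0.85,
                       sex_male_prob = 0.623,
                       across_transform = "ln1p-percent",
                       window = c("2019-01-01", "2019-12-31"),
                       seed = 1L) {
  check_count(n_hospitals, "n_hospitals")
  check_count(n_steps, "n_steps")
  check_count(physicians_per_hospital, "physicians_per_hospital")
  check_count(patients_per_hospital, "patients_per_hospital")
  check_count(encounters_per_patient, "encounters_per_patient")
  check_count(max_sites, "max_sites")
  check_count(n_handoff_patients, "n_handoff_patients")
  check_prop(multi_site_fraction, "multi_site_fraction")
  check_prop(age_missing_rate, "age_missing_rate")
  check_prop(sex_male_prob, "sex_male_prob")
  if (!is.numeric(patient_share_rate) || patient_share_rate <= 0 ||
      patient_share_rate > 1)
    stopf("configuration error: 'patient_share_rate' must be in (0, 1]")
  if (!is.numeric(site_share_concentration) || site_share_concentration <= 0)
    stopf("configuration error: 'site_share_concentration' must be positive")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stopf("configuration error: 'tau' must be a nonnegative number")
  if (n_steps > n_hospitals)
    stopf("configuration error: 'n_steps' exceeds 'n_hospitals'")
  need <- c("b0", "b1", "b2", "b3", "b4", "b5")
  if (!is.list(beta) || !all(need %in% names(beta)))
    stopf("configuration error: 'beta' must name %s",
          paste(need, collapse = ", "))
  if (length(beta$b1) > 0 && is.null(names(beta$b1)))
    stopf("configuration error: 'beta$b1' entries must be named after covariates")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("configuration error: 'seed' must be a single integer")
  cfg <- list(n_hospitals = as.integer(n_hospitals),
              n_steps = as.integer(n_steps),
              physicians_per_hospital = as.integer(physicians_per_hospital),
              multi_site_fraction = multi_site_fraction,
              max_sites = as.integer(max_sites),
              site_share_concentration = site_share_concentration,
              patients_per_hospital = as.integer(patients_per_hospital),
              encounters_per_patient = as.integer(encounters_per_patient),
              patient_share_rate = patient_share_rate,
              n_handoff_patients = as.integer(n_handoff_patients),
              beta = beta, tau = tau,
              age_missing_rate = age_missing_rate,
              age_mean = age_mean, age_sd = age_sd,
              years_mean = years_mean, years_sd = years_sd,
              sex_male_prob = sex_male_prob,
              across_transform = across_transform,
              window = as_date_window(window),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  hospitals: %d on %d steps\n", x$n_hospitals, x$n_steps))
  cat(sprintf("  physicians/hospital: %s; multi-site fraction %.2f (max %d sites)\n",
              paste(x$physicians_per_hospital, collapse = "-"),
              x$multi_site_fraction, x$max_sites))
  cat(sprintf("  patients/hospital: %s; encounters/patient: %s\n",
              paste(x$patients_per_hospital, collapse = "-"),
              paste(x$encounters_per_patient, collapse = "-")))
  cat(sprintf("  adoption coefficients: b0=%.3g b2=%.3g b3=%.3g b4=%.3g b5=%.3g; tau=%.3g\n",
              x$beta$b0, x$beta$b2, x$beta$b3, x$beta$b4, x$beta$b5, x$tau))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Generate the hospital and physician population
#'
#' Assigns hospitals to trial steps as evenly as possible, recruits
#' physicians at each hospital, gives a configurable minority of them
#' additional billing hospitals with Dirichlet-type billing shares (largest
#' share defines the primary hospital), and draws personal characteristics
#' (age with missingness, sex, years with the organization).
#'
#' @param config a [sim_config()].
#' @return list with `hospitals` (hospital_id, step) and `physicians`
#'   (physician_id, primary_hospital_id, n_sites, age, age_observed, sex,
#'   years_org, invited, participated = NA, plus list columns `sites` and
#'   `shares` used by [simulate_encounters()]).
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("configuration error: 'config' must be a sim_config")
  set.seed(stage_seed(config$seed, "population"))

  nh <- config$n_hospitals
  hosp_id <- pad_id("h", seq_len(nh), nh)
  step <- sample(rep_len(seq_len(config$n_steps), nh))
  hospitals <- data.frame(hospital_id = hosp_id, step = step,
                          stringsAsFactors = FALSE)

  n_per <- draw_range(nh, config$physicians_per_hospital)
  home <- rep(hosp_id, n_per)
  np <- length(home)
  phys_id <- pad_id("p", seq_len(np), np)

  multi <- runif(np) < config$multi_site_fraction & nh > 1L
  sites <- vector("list", np)
  shares <- vector("list", np)
  for (i in seq_len(np)) {
    if (!multi[i]) {
      sites[[i]] <- home[i]
      shares[[i]] <- 1
    } else {
      n_extra <- min(1L + stats::rgeom(1L, 0.5), config$max_sites - 1L, nh - 1L)
      extra <- sample(setdiff(hosp_id, home[i]), n_extra)
      s <- c(home[i], extra)
      # symmetric Dirichlet via normalized gammas; home hospital gets a
      # boosted draw so it usually remains primary
      g <- rgamma(length(s), shape = config$site_share_concentration)
      g[1] <- g[1] + rgamma(1, shape = 1)
      p <- g / sum(g)
      sites[[i]] <- s
      shares[[i]] <- p
    }
  }
  # primary = largest share, ties to the lexicographically smallest id
  primary <- vapply(seq_len(np), function(i) {
    s <- sites[[i]]; p <- shares[[i]]
    cand <- s[p == max(p)]
    sort(cand)[1]
  }, character(1))

  age <- rnorm(np, config$age_mean, config$age_sd)
  age_observed <- as.integer(runif(np) >= config$age_missing_rate)
  age[age_observed == 0L] <- NA_real_
  sex <- ifelse(runif(np) < config$sex_male_prob, "Male", "Female")
  years_org <- pmax(0.5, rnorm(np, config$years_mean, config$years_sd))

  physicians <- data.frame(physician_id = phys_id,
                           primary_hospital_id = primary,
                           n_sites = lengths(sites),
                           age = round(age, 1),
                           age_observed = age_observed,
                           sex = sex,
                           years_org = round(years_org, 2),
                           invited = 1L,
                           participated = NA_integer_,
                           stringsAsFactors = FALSE)
  physicians$sites <- sites
  physicians$shares <- shares
  list(hospitals = hospitals, physicians = physicians)
}

#' Generate billing encounters for a simulated population
#'
#' Each hospital receives its own inpatients. A small set of "handoff"
#' patients per hospital is seen by every physician billing there (ensuring
#' complete within-hospital patient sharing); remaining patients are seen by
#' each physician with probability proportional to that physician's billing
#' share at the hospital, so multi-site physicians accrue encounters at
#' their hospitals in proportion to their shares. Each realized
#' physician-patient pair contributes one or more dated billing rows.
#'
#' @param population output of [simulate_population()].
#' @param config the same [sim_config()].
#' @return data.frame of billing rows: physician_id, patient_id,
#'   hospital_id, date.
#' @export
simulate_encounters <- function(population, config) {
  if (!inherits(config, "sim_config"))
    stopf("configuration error: 'config' must be a sim_config")
  if (!is.list(population) ||
      !all(c("hospitals", "physicians") %in% names(population)))
    stopf("structural error: 'population' must come from simulate_population()")
  if (nrow(population$hospitals) != config$n_hospitals)
    stopf("structural error: population has %d hospitals but config expects %d",
          nrow(population$hospitals), config$n_hospitals)
  set.seed(stage_seed(config$seed, "encounters"))

  phys <- population$physicians
  hosp <- population$hospitals$hospital_id
  window <- config$window
  day_pool <- as.integer(window[2] - window[1])

  # per-hospital roster of (physician index, share)
  roster_i <- split(rep(seq_len(nrow(phys)), phys$n_sites), unlist(phys$sites))
  roster_s <- split(unlist(phys$shares), unlist(phys$sites))

  out <- vector("list", length(hosp))
  n_pat <- draw_range(length(hosp), config$patients_per_hospital)
  for (h in seq_along(hosp)) {
    hid <- hosp[h]
    ri <- roster_i[[hid]]
    if (is.null(ri) || length(ri) == 0L) next
    rs <- roster_s[[hid]]
    npat <- n_pat[h]
    pat_id <- sprintf("t%s_%04d", hid, seq_len(npat))
    n_hand <- min(config$n_handoff_patients, npat)
    # inclusion matrix physicians x patients
    probs <- pmin(1, config$patient_share_rate * rs)
    inc <- matrix(runif(length(ri) * npat) < rep(probs, npat),
                  nrow = length(ri))
    if (n_hand > 0) inc[, seq_len(n_hand)] <- TRUE
    idx <- which(inc, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    n_enc <- draw_range(nrow(idx), config$encounters_per_patient)
    # handoff encounters scale with the physician's billing share here (at
    # least one), so low-share visitors log brief contacts, not full loads
    hand <- idx[, 2] <= n_hand
    n_enc[hand] <- pmax(1L, as.integer(round(n_enc[hand] * rs[idx[hand, 1]])))
    rep_row <- rep.int(seq_len(nrow(idx)), n_enc)
    out[[h]] <- data.frame(
      physician_id = phys$physician_id[ri[idx[rep_row, 1]]],
      patient_id = pat_id[idx[rep_row, 2]],
      hospital_id = hid,
      date = window[1] + sample.int(day_pool + 1L, length(rep_row),
                                    replace = TRUE) - 1L,
      stringsAsFactors = FALSE)
  }
  billing <- do.call(rbind, out)
  rownames(billing) <- NULL
  billing
}

#' Generate participation outcomes by a sequential adoption process
#'
#' Builds the shared-patient network and exposures from the generated
#' billing, draws hospital-level intercepts, then processes hospitals in
#' trial-step order (random order within a step) and physicians within a
#' hospital in uniformly random order. Each physician's within-hospital
#' exposure is the participation fraction among *already-decided*
#' same-primary-hospital network peers, and the across-hospital exposure the
#' fraction among already-decided network peers whose primary hospital is at
#' the same step or earlier; the participation outcome is then drawn from
#' the logistic adoption model. Sequential decisions make the
#' exposure-to-outcome direction well defined, avoiding the simultaneity
#' that afflicts cross-sectional within-hospital exposures.
#'
#' @param population output of [simulate_population()].
#' @param billing output of [simulate_encounters()].
#' @param config the same [sim_config()].
#' @return list with `physicians` (the population table with `participated`
#'   filled in) and `truth`, a `sim_truth` object recording the generating
#'   coefficients, hospital effects, adoption order, and the exposure values
#'   actually used at each decision.
#' @export
simulate_outcomes <- function(population, billing, config) {
  if (!inherits(config, "sim_config"))
    stopf("configuration error: 'config' must be a sim_config")
  set.seed(stage_seed(config$seed, "outcomes"))

  phys <- population$physicians
  hospitals <- population$hospitals
  step <- setNames(hospitals$step, hospitals$hospital_id)

  Z <- build_encounter_matrix(billing)
  A <- project_shared_patients(Z, scheme = "shared-count")
  B <- binarize(A, a_low = 0)
  attribution <- attribute_physicians(billing)
  stopifnot(identical(attribution$physician_id, B$physicians))
  H <- shannon_diversity(attr(attribution, "volumes"))
  dec <- decompose_network(B, attribution)

  n <- length(B$physicians)
  stopifnot(identical(B$physicians, phys$physician_id))
  prim <- attribution$primary_hospital_id
  phys_step <- step[prim]
  N_np <- attribution$n_nonprimary

  # neighbor lists
  nb <- function(M) {
    tr <- Matrix::summary(M)
    lapply(split(tr$j, factor(tr$i, levels = seq_len(n))), as.integer)
  }
  nb_wi <- nb(dec$B_wi)
  nb_ac <- nb(dec$B_ac)
  # across-eligible peers: primary hospital at same step or earlier
  nb_ac_elig <- lapply(seq_len(n), function(i) {
    js <- nb_ac[[i]]
    js[phys_step[js] <= phys_step[i]]
  })

  theta <- setNames(rnorm(nrow(hospitals), 0, config$tau),
                    hospitals$hospital_id)

  cov_df <- derive_covariates(phys, age_center = config$age_mean,
                              years_center = config$years_mean)
  b1 <- config$beta$b1
  xb1 <- if (length(b1) == 0) numeric(n) else {
    miss <- setdiff(names(b1), names(cov_df))
    if (length(miss))
      stopf("configuration error: beta$b1 names %s not among derived covariates",
            paste(miss, collapse = ", "))
    as.numeric(as.matrix(cov_df[names(b1)]) %*% b1)
  }

  # decision order: hospitals by step (random within step), physicians
  # randomly within hospital
  h_ord <- hospitals$hospital_id[order(hospitals$step,
                                       runif(nrow(hospitals)))]
  order_idx <- integer(0)
  for (hid in h_ord) {
    members <- which(prim == hid)
    if (length(members))
      order_idx <- c(order_idx, members[sample.int(length(members))])
  }
  stopifnot(length(order_idx) == n)

  y <- rep(NA_integer_, n)
  decided <- logical(n)
  wy_wi <- numeric(n); wy_ac <- numeric(n)
  flag_wi <- logical(n); flag_ac <- logical(n)
  pi_used <- numeric(n)
  b <- config$beta
  for (i in order_idx) {
    dwi <- nb_wi[[i]][decided[nb_wi[[i]]]]
    dac <- nb_ac_elig[[i]][decided[nb_ac_elig[[i]]]]
    wy_wi[i] <- if (length(dwi)) 100 * mean(y[dwi]) else 0
    flag_wi[i] <- length(dwi) == 0L
    wy_ac[i] <- if (length(dac)) mean(y[dac]) else 0
    flag_ac[i] <- length(dac) == 0L
    g_ac <- transform_across(wy_ac[i], method = config$across_transform)
    lp <- b$b0 + xb1[i] + b$b2 * H[i] + b$b3 * wy_wi[i] +
      (b$b4 + b$b5 * N_np[i]) * g_ac + theta[prim[i]]
    pi_used[i] <- plogis(lp)
    y[i] <- rbinom(1L, 1L, pi_used[i])
    decided[i] <- TRUE
  }

  phys$participated <- y
  truth <- structure(list(
    beta = b, tau = config$tau,
    hospital_effects = theta,
    adoption_order = phys$physician_id[order_idx],
    exposures = data.frame(
      physician_id = phys$physician_id,
      primary_hospital_id = prim,
      step = as.integer(phys_step),
      H = as.numeric(H),
      n_nonprimary = N_np,
      wy_wi = wy_wi, wy_wi_flagged = flag_wi,
      wy_ac = wy_ac, wy_ac_flagged = flag_ac,
      wy_ac_trans = transform_across(wy_ac,
                                     method = config$across_transform),
      prob = pi_used,
      participated = y,
      stringsAsFactors = FALSE)),
    class = "sim_truth")
  list(physicians = phys, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Sequential adoption truth: %d physicians, tau = %.3g\n",
              nrow(x$exposures), x$tau))
  cat(sprintf("  participation rate: %.1f%%\n",
              100 * mean(x$exposures$participated)))
  invisible(x)
}

#' Run the full synthetic study
#'
#' Convenience wrapper chaining [simulate_population()],
#' [simulate_encounters()] and [simulate_outcomes()].
#'
#' @param config a [sim_config()].
#' @return list with `hospitals`, `physicians` (outcomes filled), `billing`,
#'   `truth` and the `config` used.
#' @examples
#' study <- simulate_study(sim_config(n_hospitals = 6,
#'   physicians_per_hospital = 4, patients_per_hospital = 12, seed = 3))
#' table(study$physicians$participated)
#' @export
simulate_study <- function(config = sim_config()) {
  population <- simulate_population(config)
  billing <- simulate_encounters(population, config)
  outc <- simulate_outcomes(population, billing, config)
  list(hospitals = population$hospitals,
       physicians = outc$physicians,
       billing = billing,
       truth = outc$truth,
       config = config)
}

#' Write a simulated study to delimited text files
#'
#' Writes `billing.csv` (physician_id, patient_id, hospital_id, date),
#' `physicians.csv` (physician_id, primary_hospital_id, age, age_observed,
#' sex, years_org, invited, participated), `hospitals.csv` (hospital_id,
#' step) and `sim_truth.json`, all UTF-8 with header rows.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("billing.csv", "physicians.csv", "hospitals.csv",
                        "sim_truth.json"))
  billing <- study$billing
  billing$date <- format(billing$date, "%Y-%m-%d")
  write.csv(billing, p[1], row.names = FALSE, quote = FALSE)
  keep <- c("physician_id", "primary_hospital_id", "age", "age_observed",
            "sex", "years_org", "invited", "participated")
  write.csv(study$physicians[keep], p[2], row.names = FALSE, quote = FALSE)
  write.csv(study$hospitals, p[3], row.names = FALSE, quote = FALSE)
  truth <- study$truth
  jsonlite::write_json(
    list(beta = truth$beta, tau = truth$tau,
         hospital_effects = as.list(truth$hospital_effects),
         adoption_order = truth$adoption_order,
         exposures = truth$exposures),
    p[4], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Derive model covariates from a physician table
#'
#' Encodes the analysis covariates: `age_c_obs` is centered age multiplied
#' by the `age_observed` indicator (0 when age is missing, so a missing age
#' contributes nothing to the linear predictor while the `age_observed` main
#' effect absorbs the missingness shift), `sex_male` a 0/1 indicator, and
#' `years_c` centered years with the organization.
#'
#' @param physicians data.frame with age, age_observed, sex, years_org.
#' @param age_center,years_center centering constants; default to the
#'   observed means.
#' @return data.frame of numeric covariate columns aligned to the input.
#' @export
derive_covariates <- function(physicians, age_center = NULL,
                              years_center = NULL) {
  if (is.null(age_center))
    age_center <- mean(physicians$age, na.rm = TRUE)
  if (is.null(years_center))
    years_center <- mean(physicians$years_org, na.rm = TRUE)
  age <- physicians$age
  obs <- as.integer(physicians$age_observed)
  age_c <- ifelse(is.na(age), 0, age - age_center)
  data.frame(age_c_obs = age_c * obs,
             age_observed = obs,
             sex_male = as.integer(physicians$sex == "Male"),
             years_c = physicians$years_org - years_center)
}
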