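test_that("identical configs yield identical populations, billing and outcomes", {
  cfg <- small_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$hospitals, s2$hospitals)
  expect_identical(s1$billing, s2$billing)
  expect_identical(s1$physicians$participated, s2$physicians$participated)
  expect_identical(s1$truth$exposures, s2$truth$exposures)
})

test_that("step assignment is balanced and degenerate configs are rejected", {
  cfg <- sim_config(n_hospitals = 5L, n_steps = 5L,
                    physicians_per_hospital = 3L,
                    patients_per_hospital = 8L, seed = 2)
  pop <- simulate_population(cfg)
  expect_equal(sort(pop$hospitals$step), 1:5)

  cfg10 <- sim_config(n_hospitals = 10L, n_steps = 4L,
                      physicians_per_hospital = 3L,
                      patients_per_hospital = 8L, seed = 2)
  tab <- table(simulate_population(cfg10)$hospitals$step)
  expect_lte(max(tab) - min(tab), 1)

  expect_error(sim_config(patients_per_hospital = 0L), "patients_per_hospital")
  expect_error(sim_config(multi_site_fraction = 1.2), "multi_site_fraction")
  expect_error(sim_config(tau = -1), "tau")
  expect_error(sim_config(n_steps = 9, n_hospitals = 4), "n_steps")
})

test_that("single-site populations have zero diversity and no across edges", {
  cfg <- small_config(seed = 5, multi_site_fraction = 0)
  study <- simulate_study(cfg)
  expect_true(all(study$physicians$n_sites == 1L))
  att <- attribute_physicians(study$billing)
  expect_true(all(shannon_diversity(attr(att, "volumes")) == 0))
  B <- binarize(project_shared_patients(build_encounter_matrix(study$billing)), 0)
  dec <- decompose_network(B, att)
  expect_equal(sum(dec$B_ac), 0)
})

test_that("default sampling makes every within-hospital subnetwork complete", {
  study <- simulate_study(small_config(seed = 7))
  att <- attribute_physicians(study$billing)
  B <- binarize(project_shared_patients(build_encounter_matrix(study$billing)), 0)
  sub <- subnetwork_density(B, att)
  expect_true(all(sub$per_hospital$density == 1, na.rm = TRUE))
})

test_that("equal billing shares split encounters evenly between two hospitals", {
  cfg <- small_config(seed = 13, multi_site_fraction = 0)
  pop <- simulate_population(cfg)
  # force one physician to bill 50/50 at two hospitals
  pop$physicians$sites[[1]] <- pop$hospitals$hospital_id[1:2]
  pop$physicians$shares[[1]] <- c(0.5, 0.5)
  pop$physicians$n_sites[1] <- 2L
  billing <- simulate_encounters(pop, cfg)
  mine <- billing[billing$physician_id == pop$physicians$physician_id[1], ]
  counts <- table(factor(mine$hospital_id,
                         levels = pop$hospitals$hospital_id[1:2]))
  pt <- prop.test(counts[1], sum(counts), p = 0.5)
  expect_gt(pt$p.value, 0.001)
})

test_that("limit cases of the adoption model behave as the logistic form implies", {
  beta0 <- list(b0 = 0, b1 = c(years_c = 0), b2 = 0, b3 = 0, b4 = 0, b5 = 0)
  cfg <- sim_config(n_hospitals = 25L, physicians_per_hospital = 40L,
                    patients_per_hospital = c(10L, 14L),
                    beta = beta0, tau = 0, seed = 21)
  study <- simulate_study(cfg)
  expect_gt(nrow(study$physicians), 999)
  expect_lt(abs(mean(study$physicians$participated) - 0.5), 0.05)

  beta_neg <- modifyList(beta0, list(b0 = -20))
  cfg2 <- small_config(seed = 22, beta = beta_neg, tau = 0)
  study2 <- simulate_study(cfg2)
  expect_true(all(study2$physicians$participated == 0))
})

test_that("a strong within-hospital peer effect clusters participation by hospital", {
  beta_null <- list(b0 = -1, b1 = c(years_c = 0), b2 = 0, b3 = 0,
                    b4 = 0, b5 = 0)
  # same baseline propensity; the peer arm adds strong positive feedback,
  # so hospitals either cascade to high uptake or stall near baseline,
  # spreading the between-hospital rates out
  beta_peer <- modifyList(beta_null, list(b3 = 0.05))
  n_pairs <- 50
  var_between <- function(study) {
    rates <- tapply(study$physicians$participated,
                    study$physicians$primary_hospital_id, mean)
    var(as.numeric(rates))
  }
  d <- vapply(seq_len(n_pairs), function(r) {
    v0 <- var_between(simulate_study(small_config(seed = 1000 + r,
                                                  beta = beta_null, tau = 0)))
    v1 <- var_between(simulate_study(small_config(seed = 1000 + r,
                                                  beta = beta_peer, tau = 0)))
    v1 - v0
  }, numeric(1))
  expect_gt(mean(d), 0)
  expect_gt(mean(d > 0), 0.6)
})

test_that("recorded adoption exposures equal a restricted recomputation", {
  study <- simulate_study(small_config(seed = 31))
  tr <- study$truth
  phys <- study$physicians$physician_id
  expect_setequal(tr$adoption_order, phys)
  expect_equal(anyDuplicated(tr$adoption_order), 0)

  att <- attribute_physicians(study$billing)
  B <- binarize(project_shared_patients(build_encounter_matrix(study$billing)), 0)
  dec <- decompose_network(B, att)
  steps <- setNames(study$hospitals$step, study$hospitals$hospital_id)
  phys_step <- steps[dec$primary]
  y <- setNames(study$physicians$participated, phys)
  pos <- match(phys, tr$adoption_order)
  Bwi <- as.matrix(dec$B_wi)
  Bac <- as.matrix(dec$B_ac)
  for (i in seq_along(phys)) {
    decided <- pos < pos[i]
    dwi <- which(Bwi[i, ] > 0 & decided)
    expect_equal(tr$exposures$wy_wi[i],
                 if (length(dwi)) 100 * mean(y[dwi]) else 0)
    expect_identical(tr$exposures$wy_wi_flagged[i], length(dwi) == 0L)
    dac <- which(Bac[i, ] > 0 & decided & phys_step <= phys_step[i])
    expect_equal(tr$exposures$wy_ac[i],
                 if (length(dac)) mean(y[dac]) else 0)
  }
})

test_that("write_study emits the documented delimited schemas", {
  study <- simulate_study(small_config(seed = 41))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  billing <- read.csv(file.path(dir, "billing.csv"),
                      colClasses = "character")
  expect_identical(names(billing),
                   c("physician_id", "patient_id", "hospital_id", "date"))
  expect_equal(nrow(billing), nrow(study$billing))
  phys <- read.csv(file.path(dir, "physicians.csv"))
  expect_identical(names(phys),
                   c("physician_id", "primary_hospital_id", "age",
                     "age_observed", "sex", "years_org", "invited",
                     "participated"))
  truth <- jsonlite::read_json(file.path(dir, "sim_truth.json"))
  expect_named(truth, c("beta", "tau", "hospital_effects", "adoption_order",
                        "exposures"))
})
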