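test_that("top-fraction selection sizes and ordering are exact", {
  set.seed(51)
  expect_length(top_fraction_mask(rnorm(100), 0.03), 3)
  expect_length(top_fraction_mask(rnorm(57), 1.0), 57)

  rel <- 10:1
  expect_equal(top_fraction_mask(rel, 0.2), c(1L, 2L))

  # ties at the cutoff resolve by ascending vertex id
  relt <- c(5, 5, 5, 1)
  expect_equal(top_fraction_mask(relt, 0.5), c(1L, 2L))

  expect_warning(ids <- top_fraction_mask(rep(3, 10), 0.3), "all relevance")
  expect_equal(ids, 1:3)

  for (n in c(10, 33, 101, 1502)) {
    for (f in c(0.03, 0.1, 0.5)) {
      if (round(f * n) < 1) next   # empty selection is an error by contract
      expect_length(top_fraction_mask(rnorm(n), f), round(f * n))
    }
  }
  expect_error(top_fraction_mask(rnorm(10), 0.03), "selects no vertices")
})

test_that("region activity averages trials then vertices per subject", {
  w <- structure(
    list(data = matrix(c(1, 3, 2, 4,      # vertex 1
                         5, 7, 6, 8),     # vertex 2
                       nrow = 4),
         subject = c("P1", "P1", "P2", "P2"),
         group = rep("patient", 4),
         window = c(150, 250), n_samples = 41, rejected = character(0)),
    class = "windowed_trials")
  act <- region_activity(w, vertex_ids = 1:2)
  # P1: mean(1,3,5,7) = 4; P2: mean(2,4,6,8) = 5
  expect_equal(unname(act), c(4, 5))

  # constant data
  wc <- w; wc$data[] <- 3.3
  expect_equal(unname(region_activity(wc, 1:2)), c(3.3, 3.3))

  expect_warning(region_activity(w, 1:2, subjects = c("P1", "P9")),
                 "no retained trials")
  expect_error(region_activity(w, integer(0)), "empty")
})

test_that("Spearman rho and p follow the rank formulation", {
  x <- 1:8
  expect_equal(spearman_cor(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)       # monotone invariance
  expect_equal(spearman_cor(x, x^3)$p, 0)

  # worked 5-point example: 1 - 6*sum(d^2)/(n(n^2-1)) = 0.8
  ex <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(ex$rho, 0.8)
  expect_equal(ex$n, 5)
  # t-approximation p-value
  tval <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(ex$p, 2 * pt(-tval, df = 3))

  # rho matches the reference implementation (oracle, not implementation)
  set.seed(53)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(spearman_cor(a, b)$rho,
               unname(cor.test(a, b, method = "spearman")$estimate))

  # invariance under strictly monotone transforms of either argument
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)

  z <- rep(1, 5)
  flat <- spearman_cor(z, rnorm(5))
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("correlation table recovers configured couplings", {
  sp <- tiny_space(300, seed = 4)
  coup <- data.frame(score = c("PSQI", "ESS"),
                     region = c("insular", "superior_temporal"),
                     slope = c(5, -5), noise_sd = 1e-6)
  cfg <- simulation_config(
    n_subjects_control = 3, n_subjects_patient = 9,
    trials_per_subject = 5, epoch_ms = c(0, 400),
    effect_size = c(insular = 1, superior_temporal = 1),
    subject_sd = 0.5, noise_sd = 0.2,
    clinical_coupling = coup, seed = 61
  )
  sim <- generate_trials(sp, cfg)
  tr <- sim$trials
  w <- window_average(tr)

  # ground-truth-based "critical regions": the configured caps themselves
  groups <- list(
    left.insular = sp$vertices$vertex_id[sp$vertices$region == "insular"],
    right.superior_temporal =
      sp$vertices$vertex_id[sp$vertices$region == "superior_temporal"]
  )
  regs <- structure(list(vertex_ids = unlist(groups), fraction = 0.03,
                         groups = groups,
                         regions = data.frame(hemisphere = c("left", "right"),
                                              region = names(groups))),
                    class = "critical_regions")
  wpat <- cortexlrp:::windowed_subset(w, w$group == "patient")
  tab <- build_correlation_table(regs, wpat, sim$clinical)

  expect_equal(dim(tab$rho), c(2L, 7L))        # 14 cells here; 6 x 7 = 42 in full
  expect_equal(tab$n, 9)
  expect_gt(tab$rho["left.insular", "PSQI"], 0.9)
  expect_true(tab$flagged["left.insular", "PSQI"])
  expect_lt(tab$rho["right.superior_temporal", "ESS"], -0.9)
  expect_true(tab$flagged["right.superior_temporal", "ESS"])

  expect_error(build_correlation_table(regs, wpat, sim$clinical[1:2, ]),
               "at least 3")
})

test_that("coupling signs are recovered across seeded replicates", {
  sp <- tiny_space(250, seed = 9)
  hits <- 0L
  n_rep <- 8L
  for (s in seq_len(n_rep)) {
    coup <- data.frame(score = "PSQI", region = "insular",
                       slope = 5, noise_sd = 0.05)
    cfg <- simulation_config(
      n_subjects_control = 2, n_subjects_patient = 9,
      trials_per_subject = 4, epoch_ms = c(0, 400),
      effect_size = c(insular = 1), subject_sd = 0.5, noise_sd = 0.2,
      clinical_coupling = coup, seed = 100 + s
    )
    sim <- generate_trials(sp, cfg)
    w <- window_average(sim$trials)
    ins <- sp$vertices$vertex_id[sp$vertices$region == "insular"]
    wpat <- cortexlrp:::windowed_subset(w, w$group == "patient")
    act <- region_activity(wpat, ins, subjects = sim$clinical$subject)
    rho <- spearman_cor(act, sim$clinical$PSQI)$rho
    if (rho > 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("42-cell table shape for six regions and seven scores", {
  groups <- split(1:60, rep(paste0("left.r", 1:6), each = 10))
  regs <- structure(list(vertex_ids = 1:60, fraction = 0.03, groups = groups,
                         regions = data.frame(hemisphere = "left",
                                              region = names(groups))),
                    class = "critical_regions")
  set.seed(71)
  w <- structure(
    list(data = matrix(rnorm(27 * 60), 27), subject = rep(sprintf("P%d", 1:9), 3),
         group = rep("patient", 27), window = c(150, 250), n_samples = 41,
         rejected = character(0)),
    class = "windowed_trials")
  clin <- data.frame(subject = sprintf("P%d", 1:9))
  for (s in clinical_score_names()) clin[[s]] <- rnorm(9)
  tab <- build_correlation_table(regs, w, clin)
  expect_equal(dim(tab$rho), c(6L, 7L))
  expect_equal(length(tab$rho), 42L)
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))
  # uncoupled scores: strong flags should be rare
  expect_lte(mean(tab$flagged), 0.25)
})
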