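test_that("wrong-modality and single-task error rules flag runs as stated", {
  cfg <- pipelineConfig()
  # 16-trial single block, 6 wrong-modality responses -> run flagged
  tr <- trialRows("s1", "r1", "b1", "single", "compatible", "VM", 16,
                  difficulty = "easy")
  tr$response_modality[1:6] <- "vocal"
  out <- applyExclusionCriteria(tr, cfg)
  wm <- out$report[out$report$rule == "wrong_modality", ]
  expect_true(wm$flagged)
  # 5 wrong trials is tolerated
  tr$response_modality <- "manual"; tr$response_modality[1:5] <- "vocal"
  out <- applyExclusionCriteria(tr, cfg)
  expect_false(out$report[out$report$rule == "wrong_modality", "flagged"])

  # single-task run at 31% errors flagged, at 29% retained
  mk <- function(nerr) {
    t2 <- trialRows("s1", "r1", "b1", "single", "compatible", "VM", 100,
                    difficulty = "easy")
    t2$correct[seq_len(nerr)] <- FALSE
    t2
  }
  r31 <- applyExclusionCriteria(mk(31), cfg)$report
  r29 <- applyExclusionCriteria(mk(29), cfg)$report
  expect_true(r31[r31$rule == "error_rate", "flagged"])
  expect_false(r29[r29$rule == "error_rate", "flagged"])
})

test_that("dual-task runs are judged on congruent trials averaged over pairings", {
  cfg <- pipelineConfig()
  mkDual <- function(run, pairing, congErr, incongErr, n = 64) {
    cong <- trialRows("s1", run, "b1", "dual", pairing, "VM+AV", n,
                      congruency = "congruent")
    cong$correct[seq_len(round(congErr * n))] <- FALSE
    incong <- trialRows("s1", run, "b1", "dual", pairing, "VM+AV", n,
                        congruency = "incongruent")
    incong$correct[seq_len(round(incongErr * n))] <- FALSE
    rbind(cong, incong)
  }
  # 50% overall errors but 20% congruent errors in both runs -> retained
  tr <- rbind(mkDual("d1", "compatible", 0.20, 0.80),
              mkDual("d2", "incompatible", 0.20, 0.80))
  out <- applyExclusionCriteria(tr, cfg)
  expect_false(any(out$report[out$report$rule == "congruent_error_rate",
                              "flagged"]))
  expect_length(out$excluded_subjects, 0L)

  # 35% congruent errors averaged across runs -> both dual runs flagged,
  # and one bad dual run suffices to exclude the participant
  tr2 <- rbind(mkDual("d1", "compatible", 0.35, 0.10),
               mkDual("d2", "incompatible", 0.35, 0.10))
  out2 <- applyExclusionCriteria(tr2, cfg)
  expect_true(all(out2$report[out2$report$rule == "congruent_error_rate",
                              "flagged"]))
  expect_identical(out2$excluded_subjects, "s1")

  # within-run scope: one clean and one bad run -> only the bad run flagged
  cfgW <- pipelineConfig(dualCongruentScope = "within")
  tr3 <- rbind(mkDual("d1", "compatible", 0.10, 0.10),
               mkDual("d2", "incompatible", 0.40, 0.10))
  rep3 <- applyExclusionCriteria(tr3, cfgW)$report
  cer <- rep3[rep3$rule == "congruent_error_rate", ]
  expect_identical(sort(cer$flagged), c(FALSE, TRUE))
})

test_that("exclusion is monotone: adding error trials never un-flags a run", {
  cfg <- pipelineConfig()
  base <- trialRows("s1", "r1", "b1", "single", "compatible", "VM", 50,
                    difficulty = "easy")
  base$correct[1:16] <- FALSE   # 32% > 30%: flagged
  flagged0 <- applyExclusionCriteria(base, cfg)$report
  expect_true(flagged0[flagged0$rule == "error_rate", "flagged"])
  for (extra in c(5L, 20L)) {
    more <- trialRows("s1", "r1", "b1", "single", "compatible", "VM", extra,
                      correct = FALSE, difficulty = "easy")
    rep2 <- applyExclusionCriteria(rbind(base, more), cfg)$report
    expect_true(rep2[rep2$rule == "error_rate", "flagged"])
  }
})

test_that("BIS matches the hand-evaluated z-difference on a two-subject toy", {
  mkCells <- function(sub, rt, acc, n = 10) {
    ok <- round(acc * n)
    tr <- trialRows(sub, "d1", "b1", "dual", "compatible", "VM+AV", n,
                    congruency = "congruent", rt = rt)
    tr$correct <- c(rep(TRUE, ok), rep(FALSE, n - ok))
    tr
  }
  trials <- rbind(mkCells("s1", 500, 0.9), mkCells("s2", 700, 0.7))
  bis <- computeBIS(trials)
  cells <- bisCells(bis)
  # pooled z over two cells: z(500) = -1/sqrt(2), z(0.9) = +1/sqrt(2)
  b1 <- cells$bis[cells$subject_id == "s1"]
  b2 <- cells$bis[cells$subject_id == "s2"]
  expect_equal(b1, sqrt(2), tolerance = 1e-10)
  expect_equal(b2, -sqrt(2), tolerance = 1e-10)
  expect_gt(b1, b2)   # faster and more accurate -> strictly larger BIS
})

test_that("degenerate standardization and missing cells are handled", {
  # identical cells everywhere -> all bis 0, all costs 0
  tr <- rbind(
    trialRows("s1", "d1", "b1", "dual", "compatible", "VM+AV", 8,
              congruency = "congruent"),
    trialRows("s1", "s1r", "b1", "single", "compatible", "VM", 8,
              difficulty = "easy"),
    trialRows("s1", "s2r", "b1", "single", "compatible", "AV", 8,
              difficulty = "easy"),
    trialRows("s2", "d1", "b1", "dual", "compatible", "VM+AV", 8,
              congruency = "congruent"),
    trialRows("s2", "s1r", "b1", "single", "compatible", "VM", 8,
              difficulty = "easy"),
    trialRows("s2", "s2r", "b1", "single", "compatible", "AV", 8,
              difficulty = "easy"))
  bis <- computeBIS(tr)
  expect_true(all(bisCells(bis)$bis == 0))
  expect_true(all(dualTaskCosts(bis)$dual_task_cost == 0))

  # a subject with only dual trials has an undefined cost, flagged as NA
  tr2 <- trialRows("s3", "d1", "b1", "dual", "incompatible", "VV+AM", 8,
                   congruency = "congruent", rt = 600)
  bis2 <- computeBIS(rbind(tr, tr2))
  costs <- dualTaskCosts(bis2)
  expect_true(all(is.na(costs$dual_task_cost[costs$subject_id == "s3"])))
})

test_that("BIS is invariant to affine rescaling of RT units and z-scores sum to zero", {
  cfg <- simulationConfig(nSubjects = 8L, parcels = toyParcels(4L),
                          nTimepoints = 20L, seed = 31L)
  trials <- simulateBehavior(cfg)
  bis1 <- computeBIS(trials)
  ms <- trials; ms$rt <- ms$rt / 1000   # ms -> s
  bis2 <- computeBIS(ms)
  expect_equal(bisCells(bis1)$bis, bisCells(bis2)$bis, tolerance = 1e-10)

  cells <- bisCells(bis1)
  zrt <- (cells$mean_rt - mean(cells$mean_rt)) / sd(cells$mean_rt)
  zacc <- (cells$accuracy - mean(cells$accuracy)) / sd(cells$accuracy)
  expect_lt(abs(sum(zrt)), 1e-10)
  expect_lt(abs(sum(zacc)), 1e-10)
  expect_equal(cells$bis, zacc - zrt, tolerance = 1e-10)
})

test_that("single-task cells use easy blocks and average the component tasks", {
  mkSingle <- function(task, rt, diff = "easy") {
    trialRows("s1", paste0(task, diff), "b1", "single",
              unname(dualconn:::.pairingOf[task]), task, 10, rt = rt,
              difficulty = diff)
  }
  trials <- rbind(
    mkSingle("VM", 400), mkSingle("AV", 600),
    mkSingle("VM", 2000, diff = "difficult"),   # must be ignored
    trialRows("s1", "d1", "b1", "dual", "compatible", "VM+AV", 10,
              congruency = "congruent", rt = 800),
    mkSingle("VV", 500), mkSingle("AM", 500),
    trialRows("s1", "d2", "b1", "dual", "incompatible", "VV+AM", 10,
              congruency = "congruent", rt = 900))
  cells <- bisCells(computeBIS(trials))
  sc <- cells[cells$task_type == "single" & cells$pairing == "compatible", ]
  expect_equal(sc$mean_rt, 500)   # mean of 400 and 600; difficult excluded
})

test_that("behavioral contrast recovers a planted pairing cost difference", {
  # identical cost columns -> t = 0, BF10 < 1
  costs <- data.frame(subject_id = rep(sprintf("s%d", 1:10), 2),
                      pairing = rep(c("compatible", "incompatible"), each = 10),
                      dual_task_cost = rep(rnorm(10), 2))
  bis <- new("BISResult", cells = data.frame(), costs = costs)
  res <- behavioralContrast(bis)
  expect_equal(res$t_statistic, 0)
  expect_lt(res$bf10, 1)

  # constant +1 difference: degenerate infinite t with warning
  costs2 <- costs
  costs2$dual_task_cost[costs2$pairing == "incompatible"] <-
    costs2$dual_task_cost[costs2$pairing == "compatible"] + 1
  expect_warning(res2 <- behavioralContrast(
    new("BISResult", cells = data.frame(), costs = costs2)), "infinite")
  expect_identical(abs(res2$t_statistic), Inf)

  # planted difference 2.0 (SD 1), n = 61: CI covers and BF10 > 100
  set.seed(33)
  covered <- 0L; strongBF <- 0L; nRep <- 50L
  for (r in seq_len(nRep)) {
    cc <- rnorm(61, 2, 1); ci <- cc + rnorm(61, 2, 1)
    costs3 <- data.frame(subject_id = rep(sprintf("s%d", 1:61), 2),
                         pairing = rep(c("compatible", "incompatible"),
                                       each = 61),
                         dual_task_cost = c(cc, ci))
    res3 <- behavioralContrast(new("BISResult", cells = data.frame(),
                                   costs = costs3))
    if (res3$ci95[1] <= -2 && -2 <= res3$ci95[2]) covered <- covered + 1L
    if (res3$bf10 > 100) strongBF <- strongBF + 1L
  }
  expect_gte(strongBF / nRep, 0.95)
  # CI coverage is nominally 95%; allow binomial slack below the nominal rate
  expect_gte(covered / nRep, 0.86)
})

test_that("simulated cohorts show the modality-compatibility cost direction", {
  cfg <- simulationConfig(nSubjects = 24L, parcels = toyParcels(4L),
                          nTimepoints = 20L, seed = 37L)
  trials <- simulateBehavior(cfg)
  bis <- computeBIS(trials)
  costs <- dualTaskCosts(bis)
  mc <- tapply(costs$dual_task_cost, costs$pairing, mean, na.rm = TRUE)
  # dual 869 ms / 34% errors vs 752 ms / 17% at matched-ish singles:
  # incompatible pairing must carry the larger dual-task cost
  expect_gt(mc[["incompatible"]], mc[["compatible"]])
  res <- behavioralContrast(bis)
  expect_lt(res$t_statistic, 0)   # compatible - incompatible is negative
  expect_lt(res$p_value, 0.001)
})
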