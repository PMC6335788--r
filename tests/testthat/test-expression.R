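test_that("profile classification follows the floor/fold rule", {
  expect_equal(classify_profile(c(0, 0, 0)), "not_expressed")
  expect_equal(classify_profile(c(0.5, 0.9, 0.2)), "not_expressed")
  expect_equal(classify_profile(c(10, 2, 1)), "I")
  expect_equal(classify_profile(c(2, 10, 3)), "II")
  expect_equal(classify_profile(c(10, 1, 8)), "III")
  expect_equal(classify_profile(c(20, 18, 22)), "IV")
  expect_error(classify_profile(c(-1, 2, 3)), "negative")
  # every gene gets exactly one label
  set.seed(2)
  m <- matrix(rexp(300, 1 / 10), ncol = 3)
  lab <- classify_profile(m)
  expect_length(lab, 100L)
  expect_true(all(lab %in% c("not_expressed", "I", "II", "III", "IV")))
  # scale invariance above the floor
  keep <- apply(m * 10, 1, min) >= 1
  expect_equal(classify_profile(m[keep, ] * 10),
               classify_profile(m[keep, ] * 1000))
})

test_that("planted profile groups are recovered from noisy FPKM", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    sim <- make_expression_data(group_sizes = c(not_expressed = 20, I = 20,
                                                II = 20, III = 20, IV = 20),
                                fold = 5, noise_cv = 0.1, seed = s)
    got <- classify_profile(sim$fpkm)
    hits <- hits + sum(got == sim$labels)
    total <- total + length(got)
  }
  expect_gte(hits / total, 0.95)
})

test_that("only not-expressed labels appear when only silent genes are planted", {
  sim <- make_expression_data(group_sizes = c(not_expressed = 5, I = 0,
                                              II = 0, III = 0, IV = 0),
                              seed = 3)
  expect_equal(classify_profile(sim$fpkm), rep("not_expressed", 5))
})

test_that("2^-ddCt has its closed form, shift invariance and planted recovery", {
  # treatment Ct 24 vs control gene 20; reference Ct 26 vs 20 -> fold 4
  ct <- data.frame(gene = "g", condition = rep(c("treatment", "control"),
                                               each = 3),
                   time_h = 1, replicate = rep(1:3, 2),
                   ct = c(24, 24, 24, 26, 26, 26),
                   ct_control = 20)
  rel <- relative_expression_ddct(ct)
  expect_equal(rel$ddct, -2)
  expect_equal(rel$fold, 4)
  expect_equal(rel$se, 0)
  # identical dCt in both conditions -> fold 1
  ct1 <- ct; ct1$ct <- 25
  expect_equal(relative_expression_ddct(ct1)$fold, 1)
  # additive Ct shifts cancel
  ct2 <- ct; ct2$ct <- ct2$ct + 3; ct2$ct_control <- ct2$ct_control + 3
  expect_equal(relative_expression_ddct(ct2)$fold, 4)
  # simulated planted ddCt = -2 recovered up to noise
  sim <- simulate_qpcr_ct(5, ddct = -2, times = 1, ct_sd = 0.1, seed = 8)
  rel2 <- relative_expression_ddct(sim)
  expect_true(all(abs(rel2$fold - 4) < 1.2))
  expect_equal(mean(rel2$fold), 4, tolerance = 0.15)
})

test_that("ddCt equivariance: one extra cycle halves the fold", {
  sim <- simulate_qpcr_ct(3, ddct = -1, times = 1, ct_sd = 0, seed = 2)
  base <- relative_expression_ddct(sim)
  shifted <- sim
  shifted$ct[shifted$condition == "treatment"] <-
    shifted$ct[shifted$condition == "treatment"] + 1
  expect_equal(relative_expression_ddct(shifted)$fold, base$fold / 2)
})

test_that("time-course summaries count significant changes per direction", {
  rel <- data.frame(gene = paste0("g", 1:6), time_h = 1,
                    fold = c(2, 3, 0.4, 1.5, 0.8, 1),
                    p_value = c(0.01, 0.2, 0.03, 0.04, 0.5, 0.001))
  s <- de_time_course_summary(rel)
  expect_equal(s$n_up, 2L)
  expect_equal(s$n_down, 1L)
  expect_equal(s$n_tested, 6L)
  # all folds at 1: nothing is called
  rel1 <- rel; rel1$fold <- 1
  s1 <- de_time_course_summary(rel1)
  expect_equal(s1$n_up + s1$n_down, 0L)
  # planted up/down split mirrors a one-hour treatment contrast
  dd <- matrix(0, nrow = 30, ncol = 1)
  dd[1:14, 1] <- -2.5
  dd[15:20, 1] <- 2.5
  sim <- simulate_qpcr_ct(30, ddct = dd, times = 1, ct_sd = 0.15, seed = 6)
  s2 <- de_time_course_summary(relative_expression_ddct(sim))
  expect_equal(s2$n_up, 14L)
  expect_equal(s2$n_down, 6L)
  # a BH flag is available
  s3 <- de_time_course_summary(relative_expression_ddct(sim), adjust = "BH")
  expect_lte(s3$n_up + s3$n_down, s2$n_up + s2$n_down)
})

test_that("replicate requirements are enforced", {
  ct <- data.frame(gene = "g", condition = c("treatment", "control"),
                   time_h = 1, replicate = 1, ct = c(24, 26),
                   ct_control = 20)
  expect_error(relative_expression_ddct(ct), "replicates")
})
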