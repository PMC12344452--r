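# AUC, DeLong, survey analytics, correlations, permutation test.

brute_auc <- function(scores, labels) {
  pos <- scores[labels == "target"]; neg <- scores[labels != "target"]
  acc <- 0
  for (x in pos) for (y in neg) {
    acc <- acc + (x > y) + 0.5 * (x == y)
  }
  acc / (length(pos) * length(neg))
}

test_that("roc_auc equals the brute-force pairwise probability", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("target", "target", "non_target",
                                        "non_target")), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("target", "non_target"), 5)), 0.5)
  set.seed(30)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- sample(c("target", "non_target"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("target", 3)), "both classes")
})

test_that("the paired DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    a <- y + rnorm(n); b <- 0.5 * y + rnorm(n)
    labels <- ifelse(y == 1, "target", "non_target")
    got <- delong_paired_test(a, b, labels)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(got$auc_a, as.numeric(pROC::auc(pROC::roc(y, a,
                                                           quiet = TRUE))))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    expect_equal(abs(got$z), abs(as.numeric(ref$statistic)),
                 tolerance = 1e-9)
    v <- delong_auc_variance(a, labels)
    expect_equal(v, as.numeric(pROC::var(pROC::roc(y, a, quiet = TRUE),
                                         method = "delong")),
                 tolerance = 1e-9)
  }
})

test_that("DeLong degenerate cases are reported, not guessed", {
  labels <- rep(c("target", "non_target"), each = 5)
  s <- c(6:10, 1:5)
  same <- delong_paired_test(s, s, labels)
  expect_equal(same$auc_a, same$auc_b)
  expect_equal(same$p, 1)
  expect_true(is.na(same$z))
})

test_that("DeLong variance and covariance are well behaved", {
  set.seed(32)
  for (i in 1:20) {
    n <- 40
    y <- rep(c(1, 0), each = n / 2)
    a <- 0.8 * y + rnorm(n); b <- a + 0.3 * rnorm(n)
    labels <- ifelse(y == 1, "target", "non_target")
    r <- delong_paired_test(a, b, labels)
    expect_gte(r$var_a, 0); expect_gte(r$var_b, 0)
    # covariance matrix positive semi-definite
    expect_gte(r$var_a * r$var_b - r$cov^2, -1e-15)
  }
})

test_that("expert accuracy is computed over answered videos only", {
  truth <- setNames(rep(c("target", "non_target"), each = 2),
                    paste0("video0", 1:4))
  resp <- rbind(
    c("target_present", "target_present", "target_absent", "target_absent"),
    c("skipped", "skipped", "skipped", "target_present"),
    rep("skipped", 4))
  colnames(resp) <- names(truth); rownames(resp) <- 1:3
  tab <- structure(list(responses = resp,
                        demographics = data.frame(participant_id = 1:3,
                                                  paid_years = c(3, 0, 0))),
                   class = "expert_response_table")
  expect_message(res <- expert_accuracy(tab, truth), "zero answers")
  expect_equal(res$per_participant$accuracy, c(1, 0, NA))
  expect_equal(res$per_participant$n_answered, c(4, 1, 0))
  expect_equal(res$pooled, 0.5)
  expect_equal(res$by_stratum$accuracy[res$by_stratum$stratum == "paid"], 1)
})

test_that("a synthetic ten-participant fixture matches the hand average", {
  truth <- setNames(rep(c("target", "non_target"), each = 4),
                    paste0("video", 1:8))
  tab <- simulate_expert_responses(truth, n_participants = 10,
                                   p_correct = 0.7, skip_rate = 0.1,
                                   seed = 33)
  res <- expert_accuracy(tab, truth)
  hand <- vapply(1:10, function(i) {
    r <- tab$responses[i, ]
    ans <- r != "skipped"
    mean((r[ans] == "target_present") == (truth[ans] == "target"))
  }, numeric(1))
  expect_equal(res$per_participant$accuracy, hand)
  expect_equal(res$pooled, mean(hand, na.rm = TRUE))
  # survey table round trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  df <- cbind(tab$demographics, as.data.frame(tab$responses))
  write.csv(df, path, row.names = FALSE)
  back <- read_survey_table(path)
  expect_identical(unname(back$responses), unname(tab$responses))
  expect_equal(expert_video_scores(back)$score,
               expert_video_scores(tab)$score)
})

test_that("accuracy correlations match the textbook formula", {
  m <- data.frame(dog_id = letters[1:5], accuracy = c(0.9, 0.8, 0.7, 0.6,
                                                      0.5))
  expect_equal(per_dog_accuracy_correlation(m, m), 1)
  anti <- m; anti$accuracy <- rev(anti$accuracy)
  expect_equal(per_dog_accuracy_correlation(m, anti), -1)
  set.seed(34)
  e <- m; e$accuracy <- runif(5)
  r <- per_dog_accuracy_correlation(m, e)
  x <- m$accuracy; y <- e$accuracy
  expect_equal(r, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  flat <- m; flat$accuracy <- rep(0.5, 5)
  expect_warning(expect_true(is.na(per_dog_accuracy_correlation(m, flat))),
                 "zero variance")

  lens <- c(2, 4, 9, 12); acc <- c(0.9, 0.8, 0.6, 0.3)
  expect_equal(length_accuracy_correlation(lens, acc), cor(lens, acc))
  expect_equal(length_accuracy_correlation(lens, rev(sort(acc))),
               cor(lens, rev(sort(acc))))
})

perm_fixture <- function(n_dogs = 4, n_sessions = 2, per_cell = 4,
                         shift = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(dog_id = paste0("d", seq_len(n_dogs)),
                      session = seq_len(n_sessions),
                      rep = seq_len(per_cell),
                      sub_label = c("target", "no_odour"),
                      stringsAsFactors = FALSE)
  grid$amp_negative <- rnorm(nrow(grid), 40, 5) +
    ifelse(grid$sub_label == "target", shift, 0)
  grid
}

test_that("permutation test is safe with no effect and detects a real one", {
  suppressMessages({
    flat <- perm_fixture(shift = 0, seed = 35)
    flat$amp_negative <- 40  # identical feature everywhere
    r0 <- area_effect_permutation(flat, "amp_negative", n_perm = 199,
                                  seed = 36)
    expect_gte(r0$p, 0.5)
    expect_equal(r0$statistic, 0)

    eff <- perm_fixture(shift = 10, seed = 37)  # 2 SD shift
    r1 <- area_effect_permutation(eff, "amp_negative", n_perm = 499,
                                  seed = 38)
    expect_lt(r1$p, 0.01)
    expect_gt(r1$statistic, 5)
  })
  expect_true(r1$p > 0 && r1$p <= 1)
})

test_that("permutation p-values are deterministic given the seed", {
  df <- perm_fixture(shift = 3, seed = 39)
  suppressMessages({
    a <- area_effect_permutation(df, "amp_negative", n_perm = 99, seed = 40)
    b <- area_effect_permutation(df, "amp_negative", n_perm = 99, seed = 40)
  })
  expect_identical(a$p, b$p)
  expect_identical(a$null, b$null)
})
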