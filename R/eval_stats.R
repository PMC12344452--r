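# Model-versus-expert evaluation statistics: rank-based ROC AUC, the paired
# DeLong test for correlated AUCs, expert-survey analytics, accuracy
# correlations, and a dog-stratified permutation test for area effects on
# kinematic features.

#' ROC AUC via the rank (Mann-Whitney) formulation
#'
#' Mid-ranks handle ties, so identical scores for all observations give
#' exactly 0.5.
#'
#' @param scores Numeric classifier scores (higher = more target-like).
#' @param labels Character/factor/logical labels; \code{positive} marks the
#'   positive class.
#' @param positive Positive-class label (default \code{"target"}).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "target") {
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

# Structural components of the AUC (per DeLong): V10 over positives, V01
# over negatives, via midranks.
.delong_components <- function(scores, pos) {
  m <- sum(pos); n <- sum(!pos)
  r_all <- rank(scores)
  r_pos <- rank(scores[pos])
  r_neg <- rank(scores[!pos])
  v10 <- (r_all[pos] - r_pos) / n
  v01 <- 1 - (r_all[!pos] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Both score vectors refer to the same observations (e.g. the model and
#' the pooled experts scoring the same videos). Variances and the
#' covariance of the two AUCs are estimated from the structural components;
#' the test statistic is
#' \code{z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)} with a
#' two-sided normal p-value.
#'
#' @param scores_a,scores_b Numeric score vectors of equal length.
#' @param labels Labels shared by both.
#' @param positive Positive-class label.
#' @return List with \code{auc_a, auc_b, var_a, var_b, cov, z, p}. When the
#'   variance of the difference is zero the statistic is degenerate and
#'   \code{z}/\code{p} are \code{NA}.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               positive = "target") {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")
  ca <- .delong_components(scores_a, pos)
  cb <- .delong_components(scores_b, pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(var_diff) || var_diff <= 0) {
    z <- NA_real_; p <- NA_real_
    if (isTRUE(all.equal(ca$auc, cb$auc))) p <- 1
  } else {
    z <- (ca$auc - cb$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, var_a = S[1, 1], var_b = S[2, 2],
       cov = S[1, 2], z = z, p = p)
}

#' Variance of a single AUC (DeLong estimator)
#'
#' @param scores,labels,positive As in [roc_auc()].
#' @return Estimated variance of the AUC.
#' @export
delong_auc_variance <- function(scores, labels, positive = "target") {
  pos <- labels == positive
  cc <- .delong_components(scores, pos)
  stats::var(cc$v10) / sum(pos) + stats::var(cc$v01) / sum(!pos)
}

#' Read an expert-survey response table
#'
#' CSV with one row per participant: a participant id column, demographic
#' columns (\code{age, experience, paid_years, continent} when present),
#' and one column per video holding \code{target_present},
#' \code{target_absent} or \code{skipped} (empty cells count as skipped).
#'
#' @param path File path.
#' @param video_prefix Prefix identifying video columns (default
#'   \code{"video"}).
#' @return List of class \code{expert_response_table} with
#'   \code{responses} (participant x video character matrix) and
#'   \code{demographics}.
#' @export
read_survey_table <- function(path, video_prefix = "video") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vid_cols <- grep(paste0("^", video_prefix), names(raw), value = TRUE)
  if (length(vid_cols) == 0) stop("no video response columns found")
  resp <- as.matrix(raw[vid_cols])
  resp[is.na(resp) | resp == ""] <- "skipped"
  bad <- setdiff(unique(as.vector(resp)),
                 c("target_present", "target_absent", "skipped"))
  if (length(bad)) stop("unknown response value(s): ",
                        paste(bad, collapse = ", "))
  rownames(resp) <- if ("participant_id" %in% names(raw))
    raw$participant_id else seq_len(nrow(raw))
  structure(list(responses = resp,
                 demographics = raw[setdiff(names(raw), vid_cols)]),
            class = "expert_response_table")
}

#' Per-participant and pooled expert accuracy
#'
#' Accuracy is computed over the videos each participant chose to answer;
#' participants who answered nothing are excluded (with a note). When a
#' \code{paid_years} demographic is available, accuracies are also pooled
#' by paid versus no-paid detection-handling experience.
#'
#' @param table An \code{expert_response_table}.
#' @param truth Named character vector, video id to
#'   \code{"target"}/\code{"non_target"}.
#' @return List with \code{per_participant} (data frame), \code{pooled}
#'   (mean of per-participant accuracies) and \code{by_stratum}.
#' @export
expert_accuracy <- function(table, truth) {
  resp <- table$responses
  vids <- intersect(colnames(resp), names(truth))
  if (length(vids) == 0) stop("no overlap between responses and truth")
  resp <- resp[, vids, drop = FALSE]
  tv <- truth[vids]
  acc <- rep(NA_real_, nrow(resp))
  n_ans <- integer(nrow(resp))
  for (i in seq_len(nrow(resp))) {
    answered <- resp[i, ] != "skipped"
    n_ans[i] <- sum(answered)
    if (n_ans[i] == 0) next
    correct <- (resp[i, answered] == "target_present") ==
      (tv[answered] == "target")
    acc[i] <- mean(correct)
  }
  excluded <- sum(n_ans == 0)
  if (excluded) message(excluded, " participant(s) with zero answers excluded")
  per <- data.frame(participant = rownames(resp), n_answered = n_ans,
                    accuracy = acc, stringsAsFactors = FALSE)
  by_stratum <- NULL
  if ("paid_years" %in% names(table$demographics)) {
    paid <- table$demographics$paid_years > 0
    by_stratum <- data.frame(
      stratum = c("paid", "no_paid"),
      n = c(sum(paid & n_ans > 0), sum(!paid & n_ans > 0)),
      accuracy = c(mean(acc[paid], na.rm = TRUE),
                   mean(acc[!paid], na.rm = TRUE)))
  }
  list(per_participant = per, pooled = mean(acc, na.rm = TRUE),
       by_stratum = by_stratum)
}

#' Pooled expert score per video
#'
#' The expert "score" of a video is the fraction of responding
#' participants who answered \code{target_present} (skips excluded) — the
#' standard vote-fraction pooling for comparing a rater panel against a
#' probabilistic model on the ROC scale.
#'
#' @param table An \code{expert_response_table}.
#' @return Data frame with \code{video, score, n_responses}.
#' @export
expert_video_scores <- function(table) {
  resp <- table$responses
  n_resp <- colSums(resp != "skipped")
  score <- ifelse(n_resp > 0,
                  colSums(resp == "target_present") / pmax(n_resp, 1),
                  NA_real_)
  data.frame(video = colnames(resp), score = score, n_responses = n_resp,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Correlation with explicit degenerate handling.
.safe_cor <- function(x, y, method) {
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Correlation of per-dog accuracies between model and experts
#'
#' @param model_per_dog Data frame \code{dog_id, accuracy} (e.g. the
#'   \code{per_dog} table of an \code{eval_report}).
#' @param expert_per_dog Data frame \code{dog_id, accuracy} of expert
#'   accuracy on each dog's videos.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Correlation coefficient.
#' @export
per_dog_accuracy_correlation <- function(model_per_dog, expert_per_dog,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- merge(model_per_dog, expert_per_dog, by = "dog_id",
             suffixes = c("_model", "_expert"))
  if (nrow(m) < 3) stop("need at least 3 dogs")
  .safe_cor(m$accuracy_model, m$accuracy_expert, method)
}

#' Correlation of video length with classification accuracy
#'
#' @param lengths Video durations (s).
#' @param accuracy Mean per-video correctness.
#' @param method Correlation method.
#' @return Correlation coefficient.
#' @export
length_accuracy_correlation <- function(lengths, accuracy,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .safe_cor(lengths, accuracy, match.arg(method))
}

#' Dog-stratified permutation test for an area effect
#'
#' Tests whether a kinematic feature differs between the target area and a
#' comparison area while respecting the repeated-measures structure: the
#' observed statistic is the difference of within-dog mean feature values
#' (target minus comparison), averaged over dogs contributing to both, and
#' the null distribution is built by permuting area labels within
#' dog-by-session strata so each dog and session keeps its own segment
#' composition. The p-value uses the add-one correction
#' \code{p = (1 + #permuted |stat| >= |observed|) / (n_perm + 1)}, which is
#' exactly valid under the null.
#'
#' @param features Kinematic feature data frame with \code{dog_id},
#'   \code{session}, \code{sub_label} and the feature column.
#' @param feature Feature column name (e.g. \code{"amp_negative"}).
#' @param comparison Comparison area content: \code{"no_odour"},
#'   \code{"distractor"}, or \code{"non_target"} to pool both.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with \code{statistic}, \code{p}, \code{n_perm},
#'   \code{null} (the permuted statistics).
#' @export
area_effect_permutation <- function(features, feature,
                                    comparison = c("no_odour", "distractor",
                                                   "non_target"),
                                    n_perm = 999L, seed = 1L) {
  comparison <- match.arg(comparison)
  lab <- features$sub_label
  grp <- ifelse(lab == "target", "target",
                ifelse(comparison == "non_target" | lab == comparison,
                       "comp", NA_character_))
  keep <- !is.na(grp) & !is.na(features[[feature]])
  df <- data.frame(dog = features$dog_id[keep],
                   stratum = interaction(features$dog_id[keep],
                                         features$session[keep], drop = TRUE),
                   grp = grp[keep], value = features[[feature]][keep],
                   stringsAsFactors = FALSE)
  if (length(unique(df$grp)) < 2) stop("need both target and comparison segments")
  if (length(unique(df$dog)) < 2) stop("need >= 2 dogs")
  singletons <- names(which(table(df$stratum) < 2))
  if (length(singletons)) {
    message(length(singletons),
            " stratum/strata with a single segment contribute nothing")
  }
  stat_fun <- function(g) {
    mt <- tapply(df$value[g == "target"], df$dog[g == "target"], mean)
    mc <- tapply(df$value[g == "comp"], df$dog[g == "comp"], mean)
    common <- intersect(names(mt), names(mc))
    if (length(common) == 0) return(NA_real_)
    mean(mt[common] - mc[common])
  }
  obs <- stat_fun(df$grp)
  strata <- split(seq_len(nrow(df)), df$stratum)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      g <- df$grp
      for (idx in strata) {
        if (length(idx) > 1) g[idx] <- g[idx][sample.int(length(idx))]
      }
      stat_fun(g)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
  list(statistic = obs, p = p, n_perm = n_perm, null = null)
}

#' Simulate expert-survey responses (synthetic)
#'
#' A synthetic stand-in for a survey panel. Videos differ in how readable
#' they are: each video v gets a difficulty-adjusted probability of a
#' correct judgement, drawn from a Beta distribution with mean
#' \code{p_correct} and standard deviation \code{difficulty_sd}, and every
#' participant then judges it correctly with that probability
#' (independently), skipping with probability \code{skip_rate}. Without
#' the per-video difficulty term (\code{difficulty_sd = 0}) the pooled
#' vote fraction concentrates tightly around \code{p_correct} and the
#' panel's ROC behaviour degenerates; heterogeneous difficulty is what
#' real panels show.
#'
#' @param truth Named character vector video -> label.
#' @param n_participants Panel size.
#' @param p_correct Mean probability a given answer is correct.
#' @param difficulty_sd Between-video SD of the correctness probability
#'   (must satisfy \code{difficulty_sd^2 < p_correct * (1 - p_correct)}).
#' @param skip_rate Per-video skip probability.
#' @param paid_fraction Fraction of participants flagged as paid-experience.
#' @param seed Integer seed.
#' @return An \code{expert_response_table}.
#' @export
simulate_expert_responses <- function(truth, n_participants = 190,
                                      p_correct = 0.46,
                                      difficulty_sd = 0.25,
                                      skip_rate = 0.05,
                                      paid_fraction = 0.48, seed = 1L) {
  stopifnot(difficulty_sd^2 < p_correct * (1 - p_correct))
  with_seed(seed, {
    q <- if (difficulty_sd > 0) {
      nu <- p_correct * (1 - p_correct) / difficulty_sd^2 - 1
      stats::rbeta(length(truth), p_correct * nu, (1 - p_correct) * nu)
    } else {
      rep(p_correct, length(truth))
    }
    resp <- matrix("skipped", n_participants, length(truth),
                   dimnames = list(seq_len(n_participants), names(truth)))
    for (i in seq_len(n_participants)) {
      answered <- stats::runif(length(truth)) >= skip_rate
      correct <- stats::runif(length(truth)) < q
      says_target <- (truth == "target") == correct
      resp[i, answered] <- ifelse(says_target[answered], "target_present",
                                  "target_absent")
    }
    demo <- data.frame(
      participant_id = seq_len(n_participants),
      age = sample(18:84, n_participants, replace = TRUE),
      paid_years = ifelse(stats::runif(n_participants) < paid_fraction,
                          sample(1:20, n_participants, replace = TRUE), 0))
    structure(list(responses = resp, demographics = demo),
              class = "expert_response_table")
  })
}
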