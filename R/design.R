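# Trial design and behavioural outcomes for the intermittent-rivalry paradigm.
#
# Each trial is S1 (1000 ms) - gap (200 ms) - S2 (1000 ms) - mask (1000 ms) -
# ITI (2000 ms), so successive S1 onsets are exactly 5200 ms apart. Half the
# trials in every block present rival gratings (orthogonal orientations in the
# two eyes); the other half present fused gratings (identical orientations),
# for which a perceptual change can only arise from a physical change of the
# stimulus after the gap.

TRIAL_MS <- c(s1 = 1000, gap = 200, s2 = 1000, mask = 1000, iti = 2000)
TRIAL_TOTAL_MS <- sum(TRIAL_MS)  # 5200

#' Generate a counterbalanced trial table
#'
#' Builds `n_blocks` blocks of `trials_per_block` trials. Within every block,
#' rivalry and fusion trials are equally frequent; rivalry trials are split
#' exactly in half by which eye views the vertical grating; fusion trials are
#' split in half by orientation and in half by whether the gratings change
#' physically after the gap. Trial order is randomised afresh for each block,
#' except that the condition of each block's first trial alternates
#' (rivalry-first or fusion-first on block 1, per `rivalry_first`).
#'
#' @param n_blocks Number of blocks (the study used 16).
#' @param trials_per_block Trials per block; must be divisible by 4 for the
#'   condition-by-orientation counterbalance (the study used 40).
#' @param seed Optional RNG seed for the per-block shuffles.
#' @param rivalry_first Does block 1 start with a rivalry trial?
#' @return A trial-table `data.frame` with columns `trial_id`, `block`,
#'   `condition`, `eye_left_orientation`, `eye_right_orientation`,
#'   `s2_physical_change` (fusion only, `NA` for rivalry), `s1_onset_ms`,
#'   `outcome` (`NA` until [simulate_behavior()]), `response_correct`
#'   (fusion only).
#' @export
#' @examples
#' d <- make_design(1, 4, seed = 0)
#' d$s1_onset_ms  # 0, 5200, 10400, 15600
make_design <- function(n_blocks, trials_per_block, seed = NULL,
                        rivalry_first = TRUE) {
  if (n_blocks < 1L) stopf("n_blocks must be >= 1")
  if (trials_per_block %% 4L != 0L) {
    stopf("trials_per_block must be divisible by 4 (got %d)", trials_per_block)
  }
  n_half <- trials_per_block %/% 2L
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      riv <- data.frame(
        condition = "rivalry",
        eye_left_orientation = rep(c("vertical", "horizontal"), each = n_half %/% 2L),
        s2_physical_change = NA,
        stringsAsFactors = FALSE
      )
      riv$eye_right_orientation <- ifelse(riv$eye_left_orientation == "vertical",
                                          "horizontal", "vertical")
      fus <- data.frame(
        condition = "fusion",
        eye_left_orientation = rep(c("horizontal", "vertical"), each = n_half %/% 2L),
        s2_physical_change = rep_len(c(TRUE, FALSE), n_half),
        stringsAsFactors = FALSE
      )
      fus$eye_right_orientation <- fus$eye_left_orientation
      blk <- rbind(riv[, c("condition", "eye_left_orientation",
                           "eye_right_orientation", "s2_physical_change")],
                   fus[, c("condition", "eye_left_orientation",
                           "eye_right_orientation", "s2_physical_change")])
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      first_cond <- if (xor(b %% 2L == 1L, rivalry_first)) "fusion" else "rivalry"
      if (blk$condition[1L] != first_cond) {
        k <- which(blk$condition == first_cond)[1L]
        blk[c(1L, k), ] <- blk[c(k, 1L), ]
      }
      blk$block <- b
      blk
    })
    tab <- do.call(rbind, blocks)
    tab$trial_id <- seq_len(nrow(tab))
    tab$s1_onset_ms <- (tab$trial_id - 1L) * TRIAL_TOTAL_MS
    tab$outcome <- NA_character_
    tab$response_correct <- NA
    rownames(tab) <- NULL
    tab[, c("trial_id", "block", "condition", "eye_left_orientation",
            "eye_right_orientation", "s2_physical_change", "s1_onset_ms",
            "outcome", "response_correct")]
  })
}

#' Behavioural outcome probabilities
#'
#' Defaults are the group means reported for this paradigm: on rivalry trials
#' the percept changed on 37% of trials, stayed the same on 57% and drew no
#' response on 6%; fusion-trial responses were correct on 94% of trials.
#'
#' @param p_change_rivalry,p_same_rivalry,p_noresponse_rivalry Rivalry outcome
#'   probabilities; must sum to 1.
#' @param p_correct_fusion Probability a fusion trial is answered correctly.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(p_change_rivalry = 0.37, p_same_rivalry = 0.57,
                            p_noresponse_rivalry = 0.06,
                            p_correct_fusion = 0.94) {
  p <- c(p_change_rivalry, p_same_rivalry, p_noresponse_rivalry,
         p_correct_fusion)
  if (any(p < 0) || any(p > 1)) stopf("probabilities must lie in [0, 1]")
  if (abs(p_change_rivalry + p_same_rivalry + p_noresponse_rivalry - 1) > 1e-8) {
    stopf("rivalry outcome probabilities must sum to 1")
  }
  structure(list(p_change_rivalry = p_change_rivalry,
                 p_same_rivalry = p_same_rivalry,
                 p_noresponse_rivalry = p_noresponse_rivalry,
                 p_correct_fusion = p_correct_fusion),
            class = "behavior_params")
}

#' Between-participant spread of behavioural probabilities
#'
#' The study reports between-participant standard deviations alongside the
#' group means (14% for rivalry change, 10% for no response, 7% for fusion
#' accuracy), so per-participant probabilities are drawn from Beta
#' distributions moment-matched to those means and SDs.
#'
#' @param mean_change,sd_change,mean_noresponse,sd_noresponse,mean_correct_fusion,sd_correct_fusion
#'   Hyperprior moments.
#' @return A `behavior_hyperprior` list.
#' @export
behavior_hyperprior <- function(mean_change = 0.37, sd_change = 0.14,
                                mean_noresponse = 0.06, sd_noresponse = 0.10,
                                mean_correct_fusion = 0.94,
                                sd_correct_fusion = 0.07) {
  structure(as.list(environment()), class = "behavior_hyperprior")
}

.rbeta_mom <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  v <- s^2
  if (v >= m * (1 - m)) stopf("infeasible Beta moments: mean %g, sd %g", m, s)
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Draw one participant's behavioural probabilities
#'
#' @param hyper A [behavior_hyperprior()].
#' @param seed Optional seed.
#' @return A [behavior_params()] object for one participant.
#' @export
draw_participant_behavior <- function(hyper = behavior_hyperprior(),
                                      seed = NULL) {
  with_seed(seed, {
    p_change <- .rbeta_mom(1, hyper$mean_change, hyper$sd_change)
    p_nr <- .rbeta_mom(1, hyper$mean_noresponse, hyper$sd_noresponse)
    # keep the multinomial proper when both draws are extreme
    p_nr <- min(p_nr, 0.95 * (1 - p_change))
    behavior_params(p_change, 1 - p_change - p_nr, p_nr,
                    .rbeta_mom(1, hyper$mean_correct_fusion,
                               hyper$sd_correct_fusion))
  })
}

#' Simulate behavioural outcomes for a trial table
#'
#' Rivalry outcomes are i.i.d. draws from the
#' changed/same/no-response multinomial; fusion trials are answered correctly
#' with probability `p_correct_fusion`, the recorded outcome being the
#' reported percept (the physical truth when correct, its opposite when not).
#'
#' @param trials Trial table from [make_design()].
#' @param behavior A [behavior_params()].
#' @param seed Optional seed.
#' @return The trial table with `outcome` and `response_correct` filled in.
#' @export
simulate_behavior <- function(trials, behavior = behavior_params(),
                              seed = NULL) {
  stopifnot(inherits(behavior, "behavior_params"))
  with_seed(seed, {
    riv <- trials$condition == "rivalry"
    trials$outcome[riv] <- sample(
      c("changed", "same", "no_response"), sum(riv), replace = TRUE,
      prob = c(behavior$p_change_rivalry, behavior$p_same_rivalry,
               behavior$p_noresponse_rivalry))
    fus <- !riv
    correct <- stats::runif(sum(fus)) < behavior$p_correct_fusion
    truth <- ifelse(trials$s2_physical_change[fus], "changed", "same")
    trials$outcome[fus] <- ifelse(correct, truth,
                                  ifelse(truth == "changed", "same", "changed"))
    trials$response_correct[fus] <- correct
    trials
  })
}

#' Write / read a trial table as TSV
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(outcome = "character"))
}
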