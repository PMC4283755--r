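#' Early-endpoint-only selection rule
#'
#' Selects the experimental arm with the maximal early-endpoint statistic
#' \eqn{\tilde Z_i}; ties are broken toward the lowest arm index.
#'
#' @param z_early numeric vector of `k` early-endpoint statistics
#'   (see [early_z()]).
#' @return selected arm index in `1..k`.
#' @export
select_friede <- function(z_early) {
  if (length(z_early) < 1L) stop("empty statistic vector")
  unname(which.max(z_early))
}

#' Efficient-score selection rule
#'
#' Selects the experimental arm with the maximal score statistic \eqn{S_i}
#' (combining interim final-endpoint and early-endpoint data); ties broken
#' toward the lowest arm index.
#'
#' @param score numeric vector of `k` score statistics
#'   (see [score_statistics_known()], [score_statistics_estimated()]).
#' @return selected arm index in `1..k`.
#' @export
select_stallard <- function(score) {
  if (length(score) < 1L) stop("empty statistic vector")
  unname(which.max(score))
}

#' Data-driven selection rule
#'
#' Applies both the early-endpoint rule (on [early_z()] with the pooled
#' interim estimate of `sigma0`) and the score rule (on
#' [score_statistics_estimated()]) to the same interim dataset. If the two
#' candidates coincide, that arm is selected. Otherwise the endpoint model is
#' estimated from the interim data ([estimate_model()]) and each rule's
#' plug-in selection probability *for its own candidate* is evaluated
#' ([friede_selection_prob()], [stallard_selection_prob()] at the estimates);
#' the candidate of the rule with the larger estimated probability is
#' selected. An exact probability tie goes to the score-rule candidate
#' (the rule using more of the data).
#'
#' @param stage1 a `stage1_trial` with `n1 >= 3`.
#' @param design a [trial_design()].
#' @return An object of class `selection_outcome`: list with `selected`,
#'   `rule_used` (one of `"data_driven:agree"`, `"data_driven:friede"`,
#'   `"data_driven:stallard"`), both candidates, both estimated candidate
#'   probabilities (`NA` when the rules agree and no evaluation is needed),
#'   the statistics and the estimated model used.
#' @export
select_data_driven <- function(stage1, design) {
  design <- validate_design(design)
  if (stage1$k != design$k) stop("data and design disagree on k")
  est <- estimate_model(stage1)
  z_early <- early_z(stage1, est$sigma0)
  sc <- score_statistics_estimated(stage1)
  cand_f <- select_friede(z_early)
  cand_s <- select_stallard(sc$score)
  stats <- list(z_early = z_early, score = sc$score, info = sc$info)
  if (cand_f == cand_s) {
    out <- list(selected = cand_f, rule_used = "data_driven:agree",
                candidate_friede = cand_f, candidate_stallard = cand_s,
                prob_friede_candidate = NA_real_,
                prob_stallard_candidate = NA_real_,
                statistics = stats, estimates = est)
  } else {
    p_f <- friede_selection_prob(cand_f, est$mu_b, est$sigma0, design$N1)
    p_s <- stallard_selection_prob(cand_s, est, design$n1, design$N1)
    if (p_f > p_s)
      out <- list(selected = cand_f, rule_used = "data_driven:friede",
                  candidate_friede = cand_f, candidate_stallard = cand_s,
                  prob_friede_candidate = p_f, prob_stallard_candidate = p_s,
                  statistics = stats, estimates = est)
    else
      out <- list(selected = cand_s, rule_used = "data_driven:stallard",
                  candidate_friede = cand_f, candidate_stallard = cand_s,
                  prob_friede_candidate = p_f, prob_stallard_candidate = p_s,
                  statistics = stats, estimates = est)
  }
  class(out) <- "selection_outcome"
  out
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("Selected arm %d (%s)\n", x$selected, x$rule_used))
  cat(sprintf("  candidates: early rule -> %d, score rule -> %d\n",
              x$candidate_friede, x$candidate_stallard))
  if (!is.na(x$prob_friede_candidate))
    cat(sprintf("  plug-in probabilities: early %.4f, score %.4f\n",
                x$prob_friede_candidate, x$prob_stallard_candidate))
  invisible(x)
}

#' Serialize a selection outcome as JSON
#'
#' @param outcome a `selection_outcome` from [select_data_driven()].
#' @param file optional path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `file`).
#' @export
selection_to_json <- function(outcome, file = NULL) {
  stopifnot(inherits(outcome, "selection_outcome"))
  x <- unclass(outcome)
  x$estimates <- unclass(x$estimates)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
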