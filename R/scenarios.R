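#' Monte-Carlo operating characteristics of the selection rules
#'
#' Simulates `n_reps` complete two-stage trials. In every replicate all
#' requested rules are applied to the *same* stage-1 dataset (paired
#' comparison; required for the agreement decomposition): the early-endpoint
#' rule to [early_z()], the score rule to [score_statistics_estimated()]
#' (double-regression plug-in, as used in practice), and the data-driven
#' rule choosing between those two candidates via plug-in selection
#' probabilities. For each selected arm, stage-2 data are simulated
#' (identical across rules that select the same arm, independent otherwise)
#' and the closed test is run.
#'
#' Reported per rule: the probability of selecting arm 1 (by convention the
#' arm whose operating characteristics are tracked), the power in the strict
#' sense (select arm 1 *and* reject its null hypothesis), and the
#' probability of rejecting any hypothesis. For the data-driven rule the
#' selections of arm 1 are decomposed into score-rule-only, early-rule-only
#' and both-rules categories, and two benchmarks are attached: the
#' probability that at least one of the two base rules picks arm 1 (an upper
#' bound for any rule choosing between them) and the average of the two base
#' rules' selection probabilities (a random choice between discordant
#' candidates).
#'
#' @param model an [endpoint_model()].
#' @param design a [trial_design()].
#' @param n_reps number of simulated trials (>= 1).
#' @param seed master seed; replicate `r` uses substreams derived from
#'   `(seed, r)`, so results are fully reproducible.
#' @param rules character subset of
#'   `c("friede", "stallard", "data_driven")`.
#' @param run_test logical; if `FALSE`, skip stage 2 and the closed test
#'   (selection probabilities only, much faster).
#' @return An object of class `scenario_result`: list with a per-rule data
#'   frame `rules` (`select_1`, `power_1`, `reject_any`, and Monte-Carlo
#'   standard errors), `decomposition`, `upper_bound`, `average`, `n_reps`
#'   and `seed`.
#' @export
run_scenario <- function(model, design, n_reps, seed,
                         rules = c("friede", "stallard", "data_driven"),
                         run_test = TRUE) {
  stopifnot(inherits(model, "endpoint_model"))
  design <- validate_design(design)
  rules <- match.arg(rules, several.ok = TRUE)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  need_dd <- "data_driven" %in% rules
  nr <- length(rules)
  sel <- matrix(NA_integer_, n_reps, nr, dimnames = list(NULL, rules))
  rej1 <- rej_any <- matrix(NA, n_reps, nr, dimnames = list(NULL, rules))
  cand_f1 <- cand_s1 <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    s1 <- simulate_stage1(model, design, seed, replicate = r)
    est <- estimate_model(s1)
    zt <- early_z(s1, est$sigma0)
    sc <- score_statistics_estimated(s1)
    cf <- select_friede(zt)
    cs <- select_stallard(sc$score)
    cand_f1[r] <- cf == 1L
    cand_s1[r] <- cs == 1L
    picks <- integer(nr)
    for (j in seq_len(nr)) {
      picks[j] <- switch(rules[j],
        friede = cf,
        stallard = cs,
        data_driven = if (cf == cs) cf else {
          p_f <- friede_selection_prob(cf, est$mu_b, est$sigma0, design$N1)
          p_s <- stallard_selection_prob(cs, est, design$n1, design$N1)
          if (p_f > p_s) cf else cs
        })
    }
    sel[r, ] <- picks
    if (run_test) {
      z1 <- final_z_stage1(s1, model$sigma)
      for (arm in unique(picks)) {
        s2 <- simulate_stage2(model, design, arm, seed, replicate = r,
                              stream = 10L + arm)
        ct <- closed_test(z1, arm, final_z_stage2(s2, model$sigma), design)
        hit <- picks == arm
        rej1[r, hit] <- ct$rejected[1L]
        rej_any[r, hit] <- any(ct$rejected)
      }
    }
  }
  se <- function(p) sqrt(pmax(p * (1 - p), 0) / n_reps)
  p_sel <- colMeans(sel == 1L)
  tab <- data.frame(rule = rules,
                    select_1 = p_sel,
                    se_select = se(p_sel),
                    power_1 = if (run_test) colMeans(sel == 1L & rej1) else NA_real_,
                    reject_any = if (run_test) colMeans(rej_any) else NA_real_,
                    row.names = NULL)
  if (run_test) tab$se_reject <- se(tab$reject_any)
  decomp <- NULL
  if (need_dd) {
    dd1 <- sel[, "data_driven"] == 1L
    decomp <- c(stallard_only = mean(dd1 & cand_s1 & !cand_f1),
                friede_only = mean(dd1 & cand_f1 & !cand_s1),
                both = mean(dd1 & cand_f1 & cand_s1))
  }
  structure(list(rules = tab,
                 decomposition = decomp,
                 upper_bound = mean(cand_f1 | cand_s1),
                 average = mean(cand_f1 / 2 + cand_s1 / 2),
                 n_reps = n_reps, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %d replicates (seed %s)\n", x$n_reps,
              format(x$seed)))
  print(transform(x$rules,
                  select_1 = round(select_1, 4),
                  se_select = round(se_select, 4),
                  power_1 = round(power_1, 4),
                  reject_any = round(reject_any, 4)), row.names = FALSE)
  if (!is.null(x$decomposition))
    cat("  data-driven decomposition:",
        paste(names(x$decomposition), round(x$decomposition, 4),
              sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  at-least-one bound %.4f, two-rule average %.4f\n",
              x$upper_bound, x$average))
  invisible(x)
}

#' Worked-example selection probabilities
#'
#' Evaluates both rules' analytic per-arm selection probabilities for the
#' packaged hypertension example ([hypertension_example()]) at one of its two
#' interim-analysis timings.
#'
#' @param setting `"i"` (N1 = 45, n1 = 10) or `"ii"` (N1 = 25, n1 = 5).
#' @return list with numeric 4-vectors `stallard` and `friede` (named by
#'   dose regimen), and the setting's `N1`, `n1`.
#' @examples
#' worked_example("i")$stallard
#' @export
worked_example <- function(setting = c("i", "ii")) {
  setting <- match.arg(setting)
  fx <- hypertension_example()
  sz <- fx$settings[[setting]]
  N1 <- sz[["N1"]]; n1 <- sz[["n1"]]
  k <- fx$model$k
  st <- vapply(seq_len(k), stallard_selection_prob, numeric(1),
               model = fx$model, n1 = n1, N1 = N1)
  fr <- vapply(seq_len(k), friede_selection_prob, numeric(1),
               mu_b = fx$model$mu_b, sigma0 = fx$model$sigma0, N1 = N1)
  list(stallard = setNames(st, fx$arms), friede = setNames(fr, fx$arms),
       N1 = N1, n1 = n1)
}
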