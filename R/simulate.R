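#' @keywords internal
#' Lehmer step on the multiplicative group mod 2^31 - 1; inputs/outputs stay
#' in [1, 2^31 - 2], exact in double arithmetic (16807 * 2^31 < 2^53).
lehmer <- function(x) (16807 * x) %% 2147483647

#' Derive a reproducible substream seed
#'
#' Maps a master seed, a replicate id and a stream tag to an integer seed for
#' R's Mersenne-Twister generator. The scheme is fixed (three Lehmer steps
#' interleaved with the tags), so identical `(seed, replicate, stream)`
#' triples always reproduce identical data across runs and platforms, while
#' distinct replicates get well-separated seeds.
#'
#' @param seed master integer seed.
#' @param replicate replicate id (>= 1).
#' @param stream stream tag separating independent uses within a replicate
#'   (stage 1 = 1, stage 2 = 2, ...).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, replicate = 1L, stream = 1L) {
  s <- lehmer((abs(seed) %% 2147483646) + 1)
  s <- lehmer((s + stream) %% 2147483646 + 1)
  s <- lehmer((s + replicate) %% 2147483646 + 1)
  as.integer(s)
}

#' Simulate stage-1 trial data
#'
#' Draws, for each of the `k + 1` groups, `N1` i.i.d. bivariate-normal
#' (early, final) endpoint pairs with means `(mu_b[i], mu_B[i])`, standard
#' deviations `(sigma0, sigma)` and within-patient correlation `rho_w`;
#' groups are mutually independent. At the interim only the first `n1` final
#' observations per group are observed; all `N1` are available at the final
#' analysis.
#'
#' @param model an [endpoint_model()].
#' @param design a [trial_design()].
#' @param seed master integer seed.
#' @param replicate replicate id for independent substreams (default 1).
#' @return An object of class `stage1_trial`: a list with matrices
#'   `early` (`N1 x (k+1)`), `final_interim` (`n1 x (k+1)`) and
#'   `final_all` (`N1 x (k+1)`), columns `arm0` (control) to `armk`; the
#'   interim finals are the first `n1` rows of `final_all`.
#' @examples
#' d <- trial_design(k = 3, N1 = 32, n1 = 4, n2 = 64)
#' m <- endpoint_model(rep(0, 4), rep(0, 4), 1, 1, 0.5)
#' s1 <- simulate_stage1(m, d, seed = 1)
#' dim(s1$early)
#' @export
simulate_stage1 <- function(model, design, seed, replicate = 1L) {
  stopifnot(inherits(model, "endpoint_model"))
  design <- validate_design(design)
  if (model$k != design$k) stop("model and design disagree on k")
  set.seed(substream_seed(seed, replicate, stream = 1L))
  N1 <- design$N1; n1 <- design$n1; k <- design$k
  early <- matrix(NA_real_, N1, k + 1L)
  final_all <- matrix(NA_real_, N1, k + 1L)
  r <- model$rho_w; rr <- sqrt(max(0, 1 - r^2))
  for (i in seq_len(k + 1L)) {
    zx <- rnorm(N1)
    zy <- rnorm(N1)
    early[, i] <- model$mu_b[i] + model$sigma0 * zx
    final_all[, i] <- model$mu_B[i] + model$sigma * (r * zx + rr * zy)
  }
  colnames(early) <- colnames(final_all) <- paste0("arm", 0:k)
  structure(list(early = early,
                 final_interim = final_all[seq_len(n1), , drop = FALSE],
                 final_all = final_all,
                 N1 = N1, n1 = n1, k = k),
            class = "stage1_trial")
}

#' Simulate stage-2 trial data
#'
#' Draws `n2` i.i.d. normal final-endpoint values per group for the control
#' and the selected treatment, independent of stage one (patients newly
#' recruited in stage two).
#'
#' @inheritParams simulate_stage1
#' @param selected selected experimental arm index, in `1..k`.
#' @param stream substream tag (default 2); use distinct tags to obtain
#'   independent stage-2 datasets for the same replicate.
#' @return An object of class `stage2_data`: list with `selected`,
#'   `control` and `treatment` (numeric vectors of length `n2`).
#' @export
simulate_stage2 <- function(model, design, selected, seed, replicate = 1L,
                            stream = 2L) {
  stopifnot(inherits(model, "endpoint_model"))
  design <- validate_design(design)
  selected <- as.integer(selected)
  if (selected < 1L || selected > design$k) stop("selected arm out of range 1..k")
  set.seed(substream_seed(seed, replicate, stream = stream))
  structure(list(selected = selected,
                 control = rnorm(design$n2, model$mu_B[1L], model$sigma),
                 treatment = rnorm(design$n2, model$mu_B[selected + 1L], model$sigma)),
            class = "stage2_data")
}

#' Export / import stage-1 data as tidy CSV
#'
#' One row per patient with columns `arm` (0 = control), `patient`,
#' `early_value` and `final_value`; `final_value` is empty for patients whose
#' final endpoint is unobserved at the interim analysis. External datasets in
#' the same shape can be read back and analysed with the package's
#' statistics.
#'
#' @param stage1 a `stage1_trial` object.
#' @param file path of the CSV file.
#' @param interim_only logical; if `TRUE` (default) final values are written
#'   only for the `n1` interim patients per arm, otherwise all `N1`.
#' @return `write_stage1_csv()` returns `file` invisibly;
#'   `read_stage1_csv()` returns a `stage1_trial` (with `final_all` present
#'   only when every patient has a final value).
#' @export
write_stage1_csv <- function(stage1, file, interim_only = TRUE) {
  stopifnot(inherits(stage1, "stage1_trial"))
  k <- stage1$k; N1 <- stage1$N1; n1 <- stage1$n1
  fin <- if (interim_only) {
    f <- matrix(NA_real_, N1, k + 1L)
    f[seq_len(n1), ] <- stage1$final_interim
    f
  } else stage1$final_all
  df <- data.frame(arm = rep(0:k, each = N1),
                   patient = rep(seq_len(N1), k + 1L),
                   early_value = as.vector(stage1$early),
                   final_value = as.vector(fin))
  write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_stage1_csv
#' @export
read_stage1_csv <- function(file) {
  df <- read.csv(file)
  req <- c("arm", "patient", "early_value", "final_value")
  if (!all(req %in% names(df))) stop("CSV lacks columns: ",
                                     paste(setdiff(req, names(df)), collapse = ", "))
  arms <- sort(unique(df$arm))
  if (!identical(arms, 0:max(arms))) stop("arm indices must be 0..k without gaps")
  k <- max(arms)
  df <- df[order(df$arm, df$patient), ]
  N1 <- unique(table(df$arm))
  if (length(N1) != 1L) stop("every arm must have the same number of patients")
  early <- matrix(df$early_value, N1, k + 1L)
  fin <- matrix(df$final_value, N1, k + 1L)
  obs <- !is.na(fin)
  n1 <- unique(colSums(obs))
  if (length(n1) != 1L || !all(obs[seq_len(n1), ]))
    stop("final values must be observed for the first n1 patients of every arm")
  colnames(early) <- colnames(fin) <- paste0("arm", 0:k)
  structure(list(early = early,
                 final_interim = fin[seq_len(n1), , drop = FALSE],
                 final_all = if (n1 == N1) fin else NULL,
                 N1 = N1, n1 = as.integer(n1), k = k),
            class = "stage1_trial")
}

#' Batch simulation of stage-1 selection statistics
#'
#' Simulates many independent stage-1 trials at once and returns the three
#' statistic families per replicate: the early-endpoint statistics, the
#' stage-1 final statistics on all `N1` patients, and the known-parameter
#' efficient-score statistics. Patient-level data are generated in chunks and
#' reduced to the per-arm sufficient statistics, which makes replication
#' counts of 10^6 practical for Monte-Carlo validation of the analytic
#' selection probabilities.
#'
#' @inheritParams simulate_stage1
#' @param n_reps number of replicates.
#' @param chunk replicates generated per chunk (memory/time trade-off).
#' @return list of matrices (`n_reps x k`): `z_early`, `z1_final`, `score`;
#'   plus `info`, the score information per comparison.
#' @export
simulate_selection_batch <- function(model, design, n_reps, seed,
                                     chunk = 50000L) {
  stopifnot(inherits(model, "endpoint_model"))
  design <- validate_design(design)
  k <- design$k; N1 <- design$N1; n1 <- design$n1
  s0 <- model$sigma0; s <- model$sigma; r <- model$rho_w
  gamma <- r * s / s0
  info <- score_information(n1, N1, s, r)
  z_early <- z1 <- score <- matrix(NA_real_, n_reps, k)
  done <- 0L; ch <- 0L
  while (done < n_reps) {
    B <- min(chunk, n_reps - done)
    ch <- ch + 1L
    set.seed(substream_seed(seed, replicate = ch, stream = 9L))
    xbarN <- xbar1 <- ybar1 <- ybarN <- matrix(NA_real_, B, k + 1L)
    for (i in seq_len(k + 1L)) {
      zx <- matrix(rnorm(N1 * B), N1, B)
      zy <- matrix(rnorm(N1 * B), N1, B)
      x <- model$mu_b[i] + s0 * zx
      y <- model$mu_B[i] + s * (r * zx + sqrt(max(0, 1 - r^2)) * zy)
      xbarN[, i] <- colMeans(x)
      xbar1[, i] <- colMeans(x[seq_len(n1), , drop = FALSE])
      ybar1[, i] <- colMeans(y[seq_len(n1), , drop = FALSE])
      ybarN[, i] <- colMeans(y)
    }
    idx <- done + seq_len(B)
    dN <- xbarN[, -1L, drop = FALSE] - xbarN[, 1L]
    d1 <- xbar1[, -1L, drop = FALSE] - xbar1[, 1L]
    dy <- ybar1[, -1L, drop = FALSE] - ybar1[, 1L]
    z_early[idx, ] <- dN * sqrt(N1 / 2) / s0
    z1[idx, ] <- (ybarN[, -1L, drop = FALSE] - ybarN[, 1L]) * sqrt(N1 / 2) / s
    score[idx, ] <- (dy - gamma * (d1 - dN)) * sqrt(info)
    done <- done + B
  }
  list(z_early = z_early, z1_final = z1, score = score, info = info)
}
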