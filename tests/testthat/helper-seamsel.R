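# Construct a stage1_trial directly from matrices (columns arm0..armk).
make_stage1 <- function(early, final_interim, final_all = NULL) {
  early <- as.matrix(early)
  final_interim <- as.matrix(final_interim)
  structure(list(early = early, final_interim = final_interim,
                 final_all = if (!is.null(final_all)) as.matrix(final_all),
                 N1 = nrow(early), n1 = nrow(final_interim),
                 k = ncol(early) - 1L),
            class = "stage1_trial")
}

# Independent quasi-Monte-Carlo orthant oracle (mvtnorm GenzBretz), kept
# separate from the package's deterministic integration routes.
oracle_orthant <- function(mean, cov, seed = 99) {
  set.seed(seed)
  as.numeric(mvtnorm::pmvnorm(upper = rep(0, length(mean)), mean = mean,
                              sigma = cov,
                              algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                             maxpts = 500000)))
}

null_design_61 <- function() trial_design(k = 3, N1 = 32, n1 = 4, n2 = 64)

null_model_61 <- function(rho_w = 0.5)
  endpoint_model(rep(0, 4), rep(0, 4), sigma0 = 1, sigma = 1, rho_w = rho_w)
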