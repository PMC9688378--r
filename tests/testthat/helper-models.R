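# Shared simulators for the model-layer and acceptance tests.

# Inverse-Gaussian tracking-error data: participant random intercepts on
# the identity-link mean, optional group effect, optional pure-noise
# covariate.
sim_ig_data <- function(seed, b = 0.12, np = 39, nt = 24, u_sd = 0.03,
                        shape = 2, null_cov = FALSE) {
  withr::with_seed(seed, {
    grp <- rep(c("YOUNGER", "OLDER"), length.out = np)
    u <- rnorm(np, 0, u_sd)
    d <- do.call(rbind, lapply(seq_len(np), function(i) {
      mu <- 0.12 + b * (grp[i] == "OLDER") + u[i]
      data.frame(participant = sprintf("P%02d", i), group = grp[i],
                 tracking_error = rinvgauss(nt, mean = max(mu, 0.02), shape = shape),
                 stringsAsFactors = FALSE)
    }))
    d$group <- factor(d$group, levels = c("YOUNGER", "OLDER"))
    if (null_cov) d$z <- rnorm(nrow(d))
    d
  })
}

# Gaussian LMM data with one strong (x) and one null (z) covariate.
sim_lmm_data <- function(seed, b_strong = 1, b_null = 0, np = 40, nt = 5) {
  withr::with_seed(seed, {
    u <- rnorm(np, 0, 0.5)
    do.call(rbind, lapply(seq_len(np), function(i) {
      x <- rnorm(nt)
      z <- rnorm(nt)
      data.frame(participant = sprintf("P%02d", i),
                 x = x, z = z,
                 y = b_strong * x + b_null * z + u[i] + rnorm(nt),
                 stringsAsFactors = FALSE)
    }))
  })
}
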