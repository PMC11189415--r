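# Shared fixtures, all built in code at test time.

# Points exactly on a logarithmic limb K = a*ln(H) + b.
log_limb_points <- function(a, b, H = c(0.6, 0.8, 1.0, 1.2, 1.4, 1.55)) {
  list(H = H, K = a * log(H) + b)
}

# Points exactly on sigma = alpha*K^2 + beta*K + gamma over both signs.
quadratic_points <- function(alpha, beta, gamma,
                             K = c(-1.8, -1.4, -1.0, -0.6, 0.6, 1.0, 1.4, 1.8)) {
  list(K = K, sigma = alpha * K^2 + beta * K + gamma)
}

# A small, complete rating table for one participant: every category has
# both signs with varied magnitudes (profile-friendly).
complete_ratings <- function(participant = "P1") {
  set.seed(99)
  co <- generate_cohort(cohort_spec(n_participants = 2, seed = 7))
  r <- co$ratings[co$ratings$participant == "P00001", ]
  r$participant <- participant
  r
}

# Cached mid-size cohort with the default planted effect, shared across
# tests that need cohort-scale data.
.fixture_env <- new.env(parent = emptyenv())

planted_cohort <- function(n = 2000, seed = 1) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    co <- generate_cohort(cohort_spec(n_participants = n, seed = seed))
    stai <- score_stai_s(co$survey[paste0("stai_", 1:20)])
    prof <- compute_profiles(co$ratings)
    ctx <- cbind(participant = co$survey$participant,
                 encode_contextuals(co$survey))
    cohort <- assemble_cohort_table(
      prof, ctx,
      data.frame(participant = co$survey$participant, stai_s = stai))
    .fixture_env[[key]] <- list(raw = co, profiles = prof, cohort = cohort,
                                stai = stai)
  }
  .fixture_env[[key]]
}
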