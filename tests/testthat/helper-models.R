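# shared fixture builders (everything is generated in code)

grid_models <- function() {
  g <- expand.grid(lambda = c(0.2, 0.3, 0.4), p = c(4, 5, 6, 7, 15))
  lapply(seq_len(nrow(g)),
         function(i) one_factor_model(rep(g$lambda[i], g$p[i])))
}

seeded_moments <- function(lambda, p, N, seed) {
  compute_moments(generate_sample(one_factor_model(rep(lambda, p)), N,
                                  seed = seed))
}

# the indefinite triad correlation matrix with the planted Heywood
# solution theta1 = -2.6 (lambda1 = sqrt(r12 r13 / r23) = 1.8974)
triad_planted <- function() {
  matrix(c(1, .9, .8,
           .9, 1, .2,
           .8, .2, 1), 3, 3)
}

# a positive-definite triad whose exact solution is also a Heywood case
# (lambda1 = sqrt(.72/.6), theta1 = -0.2)
triad_pd_heywood <- function() {
  matrix(c(1, .9, .8,
           .9, 1, .6,
           .8, .6, 1), 3, 3)
}
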