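test_that("the spike window sits dt_delay behind t_curr and tiles time", {
  cfg <- decoder_config(n_bins = 41, dt_ms = 6, dt_delay_ms = 30)
  expect_equal(bin_window(100, cfg), c(lower = 64, upper = 70))
  cfg0 <- decoder_config(n_bins = 41, dt_ms = 6, dt_delay_ms = 0)
  expect_equal(bin_window(100, cfg0)[["upper"]], 100)
  # consecutive t_curr steps of dt tile time without gap or overlap
  w <- t(vapply(seq(36, 96, by = 6), bin_window, numeric(2), config = cfg0))
  expect_equal(w[-1, "lower"], w[-nrow(w), "upper"])
  expect_error(bin_window(10, cfg))  # before the first full window
})

test_that("no-spike likelihood reduces to exp(-ground * dt) per group", {
  nb <- 5
  zero <- list(list(ground = rep(0, nb), jmi = list()),
               list(ground = rep(0, nb), jmi = list()))
  expect_equal(likelihood_clusterless(zero, 0.006)$likelihood, rep(1, nb))

  gr <- c(1, 5, 2, 0.5, 3)
  one <- list(list(ground = gr, jmi = list()))
  r <- likelihood_clusterless(one, 0.01)
  expect_equal(exp(r$log_likelihood), exp(-gr * 0.01), tolerance = 1e-12)
})

test_that("multi-group multi-spike likelihood matches a naive product oracle", {
  set.seed(19)
  nb <- 12; delta <- 0.006
  for (rep in 1:10) {
    gr <- lapply(1:3, function(i) {
      nspk <- sample(0:2, 1)
      list(ground = runif(nb, 0, 40),
           jmi = lapply(seq_len(nspk), function(j) runif(nb, 0, 60)))
    })
    got <- likelihood_clusterless(gr, delta)$likelihood
    # naive per-bin product, independently coded
    oracle <- rep(1, nb)
    for (g in gr) {
      f <- exp(-g$ground * delta)
      for (jmi in g$jmi) f <- f * jmi * delta
      oracle <- oracle * f
    }
    oracle <- oracle / max(oracle)
    expect_lt(max(abs(got - oracle)) / max(oracle), 1e-12)
  }
})

test_that("likelihood is invariant to positive rescaling of a group's factors", {
  set.seed(40)
  nb <- 8; delta <- 0.006
  gr <- list(list(ground = runif(nb, 0, 10), jmi = list(runif(nb, 0, 5))),
             list(ground = runif(nb, 0, 10), jmi = list()))
  base <- likelihood_clusterless(gr, delta)$likelihood
  gr2 <- gr
  gr2[[1]]$jmi[[1]] <- gr2[[1]]$jmi[[1]] * 37.5   # constant positive rescale
  scaled <- likelihood_clusterless(gr2, delta)$likelihood
  p1 <- posterior_update(rep(1 / nb, nb), base)$posterior
  p2 <- posterior_update(rep(1 / nb, nb), scaled)$posterior
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(likelihood_clusterless(
    list(list(ground = rep(-1, nb), jmi = list())), delta), "negative")
})

test_that("prediction through the transition model is the matrix product", {
  nb <- 9
  p <- (1:nb) / sum(1:nb)
  expect_equal(predict_prior(p, transition_model("identity", nb)), p)
  expect_equal(predict_prior(p, transition_model("uniform", nb)),
               rep(1 / nb, nb))
  rw <- transition_model("random_walk", nb, sd_bins = 1.5)
  expect_true(all(abs(rowSums(rw$matrix) - 1) < 1e-12))
  delta_post <- c(rep(0, 4), 1, rep(0, 4))
  got <- predict_prior(delta_post, rw)
  oracle <- numeric(nb)                      # explicit matrix multiply
  for (j in 1:nb) for (i in 1:nb) oracle[j] <- oracle[j] +
      rw$matrix[i, j] * delta_post[i]
  expect_equal(got, oracle / sum(oracle), tolerance = 1e-12)
  expect_gt(got[5], got[7])                  # bump centered on the delta bin
  expect_error(predict_prior(p, matrix(1, nb, nb)), "sum to 1")
})

test_that("posterior update normalises prior x likelihood", {
  nb <- 6
  lik <- runif(nb)
  u <- posterior_update(rep(1 / nb, nb), lik)
  expect_equal(u$posterior, lik / sum(lik), tolerance = 1e-12)
  prior <- (1:nb) / sum(1:nb)
  expect_equal(posterior_update(prior, rep(0.3, nb))$posterior, prior)
  expect_warning(z <- posterior_update(prior, rep(0, nb)), "degenerate")
  expect_equal(z$posterior, prior)
  expect_equal(sum(u$posterior), 1, tolerance = 1e-9)
})

test_that("chained predict/update matches an independently coded forward filter", {
  set.seed(77)
  nb <- 50; nT <- 50
  lik <- matrix(runif(nT * nb, 0.01, 1), nT, nb)
  for (kind in c("uniform", "random_walk")) {
    tm <- transition_model(kind, nb, sd_bins = 2)
    got <- forward_filter(lik, tm)
    # reference filter written with explicit loops, no shared code path
    p <- rep(1 / nb, nb)
    ref <- matrix(0, nT, nb)
    for (k in 1:nT) {
      prior <- numeric(nb)
      for (j in 1:nb) prior[j] <- sum(tm$matrix[, j] * p)
      prior <- prior / sum(prior)
      post <- prior * lik[k, ]
      p <- post / sum(post)
      ref[k, ] <- p
    }
    expect_lt(max(abs(got - ref)), 1e-10)
    expect_true(all(abs(rowSums(got) - 1) < 1e-9))
  }
  # uniform non-informative transition: posterior is the normalised likelihood
  got_u <- forward_filter(lik, transition_model("uniform", nb))
  expect_equal(got_u, lik / rowSums(lik), tolerance = 1e-12)
})
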