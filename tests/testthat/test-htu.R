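test_that("z_from_alpha inverts the standard normal upper tail", {
  expect_equal(z_from_alpha(0.5), 0)
  # frozen values computed with the series-CDF bisection oracle
  expect_equal(z_from_alpha(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(z_from_alpha(0.025), 1.9600, tolerance = 1e-4)
  expect_equal(z_from_alpha(0.05), qnorm_bisect(0.95), tolerance = 1e-8)
  expect_equal(z_from_alpha(0.025), qnorm_bisect(0.975), tolerance = 1e-8)
  expect_error(z_from_alpha(0), "alpha")
  expect_error(z_from_alpha(1), "alpha")
})

test_that("superiority probability follows the normal-gap formula with degenerate limits", {
  expect_equal(superiority_probability(2, 1, 2, 1), 0.5)
  expect_equal(superiority_probability(3, 0, 1, 0), 1)
  expect_equal(superiority_probability(1, 0, 3, 0), 0)
  expect_equal(superiority_probability(2, 0, 2, 0), 0.5)
  # mu gap 1, sigma 0.5 each: Phi(1/sqrt(0.5)) = 0.92135, series oracle
  expect_equal(superiority_probability(3, 0.5, 2, 0.5), 0.92135,
               tolerance = 1e-4)
  expect_equal(superiority_probability(3, 0.5, 2, 0.5),
               phi_series(1 / sqrt(0.5)), tolerance = 1e-10)
  expect_error(superiority_probability(1, -0.1, 1, 0), "sigma")
})

test_that("the epistemic screen retains exactly the undominated candidates", {
  params <- htu_params(alpha = 0.05)
  certain <- data.frame(id = c("a", "b", "c"), meld = 20, mu = c(3, 2, 1),
                        sigma = 0, h = 0.1, blood_type = "O")
  expect_identical(epistemic_screen(certain, params), "a")

  tied <- data.frame(id = c("a", "b"), meld = 20, mu = c(2, 2), sigma = 1,
                     h = 0.1, blood_type = "O")
  expect_identical(epistemic_screen(tied, params), c("a", "b"))

  mixed <- data.frame(id = c("a", "b", "c"), meld = 20, mu = c(4, 3.9, 1),
                      sigma = c(0.5, 0.5, 0.1), h = 0.1, blood_type = "O")
  expect_identical(epistemic_screen(mixed, params), c("a", "b"))

  # boundary is strict: a probability of exactly 1 - alpha does not exclude
  # (degenerate equal candidates give P = 0.5 exactly; at alpha = 0.5 the
  # threshold is also exactly 0.5)
  edge <- data.frame(id = c("hi", "lo"), meld = 20, mu = c(2, 2),
                     sigma = 0, h = 0.1, blood_type = "O")
  expect_identical(epistemic_screen(edge, htu_params(alpha = 0.5)),
                   c("hi", "lo"))
})

test_that("harm counts tally the other patients above threshold", {
  df <- data.frame(id = c("a", "b", "c"), meld = 20, mu = 2, sigma = 0.5,
                   h = c(0.5, 0.1, 0.4), blood_type = "O")
  expect_equal(harm_count(df, "a", 0.30), 1)
  expect_equal(harm_count(df, "b", 0.30), 2)
  expect_equal(harm_count(df, "c", 0.30), 1)
  expect_equal(harm_count(df, "a", 0.95), 0)  # empty catastrophic set
  one <- df[1, ]; one$h <- 0.30
  expect_equal(harm_count(one, "a", 0.30), 0)  # no other patients
  expect_error(harm_count(df, "zz", 0.30), "not in pool")
})

test_that("harm-count closed-form identity holds on random pools", {
  set.seed(202)
  for (rep in 1:200) {
    df <- random_candidates(sample(2:8, 1))
    hcrit <- runif(1)
    cc <- sum(df$h >= hcrit)
    for (k in seq_len(nrow(df)))
      expect_identical(harm_count(df, df$id[k], hcrit),
                       cc - as.integer(df$h[k] >= hcrit))
  }
})

test_that("adjusted benefit subtracts the z-scaled uncertainty without clamping", {
  p05 <- htu_params(alpha = 0.05)
  expect_equal(adjusted_benefit(3, 0, p05), 3)
  expect_equal(adjusted_benefit(3, 1, p05), 3 - qnorm_bisect(0.95),
               tolerance = 1e-6)
  expect_equal(adjusted_benefit(3, 1, p05), 1.3551, tolerance = 1e-3)
  expect_equal(adjusted_benefit(0.5, 1, p05), -1.1449, tolerance = 1e-3)
})

test_that("select_htu resolves each stage as specified", {
  params <- htu_params(alpha = 0.05, hcrit = 0.30)
  z <- params$z

  # certainty: reduces to classical utilitarian argmax
  d1 <- select_htu(data.frame(id = c("a", "b", "c"), meld = 20,
                              mu = c(3, 2, 1), sigma = 0, h = 0.1,
                              blood_type = "O"), params)
  expect_identical(d1$selected_id, "a")
  expect_identical(d1$stage, "screen_resolved")
  expect_length(d1$tie_set, 1L)

  # harm stage overrides a large benefit advantage
  mk_tied_pair <- function(h) {
    madj <- c(1, 4)
    sig <- c(2, 0.3)
    data.frame(id = c("urgent", "fit"), meld = 20, mu = madj + z * sig,
               sigma = sig, h = h, blood_type = "O")
  }
  pair <- mk_tied_pair(c(0.5, 0.1))
  expect_identical(epistemic_screen(pair, params), c("urgent", "fit"))
  d2 <- select_htu(pair, params)
  expect_identical(d2$selected_id, "urgent")
  expect_identical(d2$stage, "harm_resolved")
  expect_equal(unname(d2$harm_counts), c(0L, 1L))

  # both catastrophic: each counts the other, benefit breaks the tie
  d3 <- select_htu(mk_tied_pair(c(0.5, 0.6)), params)
  expect_identical(d3$selected_id, "fit")
  expect_identical(d3$stage, "benefit_tiebreak")
  expect_equal(unname(d3$harm_counts), c(1L, 1L))

  # trace invariants
  for (d in list(d1, d2, d3)) {
    expect_true(d$selected_id %in% d$tie_set)
    expect_identical(names(d$harm_counts), d$tie_set)
  }
})

test_that("select_htu agrees with the brute-force oracle on random pools", {
  set.seed(303)
  for (rep in 1:300) {
    df <- random_candidates(sample(2:6, 1))
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    hcrit <- sample(c(0.1, 0.3, 0.7), 1)
    got <- select_htu(df, htu_params(alpha, hcrit))$selected_id
    expect_identical(got, oracle_select_htu(df, alpha, hcrit))
  }
})

test_that("raising alpha never grows the tie set", {
  set.seed(404)
  alphas <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  for (rep in 1:50) {
    df <- random_candidates(6)
    sets <- lapply(alphas, function(a) epistemic_screen(df, htu_params(a)))
    for (k in 2:length(sets))
      expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
})

test_that("selection is invariant to pool order when no exact ties exist", {
  set.seed(505)
  for (rep in 1:50) {
    df <- random_candidates(6)
    params <- htu_params(sample(c(0.05, 0.2), 1), runif(1))
    base <- select_htu(df, params)$selected_id
    perm <- df[sample(nrow(df)), ]
    expect_identical(select_htu(perm, params)$selected_id, base)
  }
})

test_that("degenerate parameter settings reduce HTU to simpler rules", {
  set.seed(606)
  for (rep in 1:60) {
    # (a) no uncertainty, distinct mu: argmax mu
    df <- random_candidates(5, zero_sigma = TRUE)
    expect_identical(select_htu(df, htu_params(0.05, 0.3))$selected_id,
                     df$id[which.max(df$mu)])
    # (b) hcrit above every h and fully tied screen: argmax mu_adj
    df2 <- random_candidates(5, h_max = 0.8)
    df2$sigma <- runif(5, 3, 4)   # large enough that no one dominates
    df2$mu <- runif(5, 2, 3)
    params <- htu_params(0.05, 0.9)
    expect_length(epistemic_screen(df2, params), 5L)
    madj <- adjusted_benefit(df2$mu, df2$sigma, params)
    expect_identical(select_htu(df2, params)$selected_id,
                     df2$id[which.max(madj)])
    # (c) hcrit = 0: everyone catastrophic, equal counts, argmax mu_adj
    params0 <- htu_params(0.05, 0)
    expect_identical(select_htu(df2, params0)$selected_id,
                     df2$id[which.max(madj)])
  }
})
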