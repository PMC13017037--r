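random_table <- function(n, k, seed) {
  set.seed(seed)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * k), n, k)))
  names(tab) <- paste0("v", seq_len(k))
  tab
}

test_that("correlation matrix is symmetric with sensible extremes", {
  tab <- random_table(120, 4, seed = 1)
  tab$v5 <- tab$v1 # duplicated column
  tab$v6 <- -tab$v2 # negation
  cm <- correlation_matrix(tab)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 6))
  expect_equal(cm$rho["v1", "v5"], 1)
  expect_equal(cm$rho["v2", "v6"], -1)
  expect_true(all(cm$rho >= -1 & cm$rho <= 1))
  expect_warning(
    correlation_matrix(dplyr::mutate(tab, flat = 1)), "constant"
  )
  expect_error(correlation_matrix(tab[1:3, ]), "subjects")
})

test_that("pooled correlations Fisher-average the completed tables", {
  set.seed(2)
  t1 <- random_table(30, 3, seed = 2)
  t2 <- random_table(30, 3, seed = 3)
  imp <- structure(
    list(completed_tables = list(t1, t2), m = 2L),
    class = "imputation_set"
  )
  cm <- correlation_matrix(imp)
  r1 <- correlation_matrix(t1)$rho["v1", "v2"]
  r2 <- correlation_matrix(t2)$rho["v1", "v2"]
  expect_equal(cm$rho["v1", "v2"], tanh((atanh(r1) + atanh(r2)) / 2))
})

test_that("regularized network is empty under independence, finds structure", {
  # identity correlation input: no dependence, no edges
  net0 <- estimate_network(random_table(500, 5, seed = 4))
  expect_true(all(net0$weights == 0))
  expect_identical(net0$estimator, "ebicglasso")

  # x3 = x1 + small noise, x2 independent
  set.seed(5)
  x1 <- rnorm(500)
  tab <- tibble::tibble(x1 = x1, x2 = rnorm(500), x3 = x1 + 0.3 * rnorm(500))
  net <- estimate_network(tab)
  expect_gt(net$weights["x1", "x3"], 0.5)
  expect_lt(max(abs(net$weights["x2", c("x1", "x3")])), 0.1)
})

test_that("partial correlations remove chain-induced marginal association", {
  set.seed(6)
  n <- 1000
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + 0.6 * rnorm(n)
  x3 <- 0.8 * x2 + 0.6 * rnorm(n)
  tab <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)
  net <- estimate_network(tab)
  cm <- correlation_matrix(tab)
  expect_gt(cm$rho["x1", "x3"], 0.4) # marginally correlated
  expect_lt(abs(net$weights["x1", "x3"]), 0.12) # conditionally near-zero
  expect_gt(net$weights["x1", "x2"], 0.4)
  expect_gt(net$weights["x2", "x3"], 0.4)
})

test_that("graphical lasso at zero penalty equals the matrix-inverse partials", {
  set.seed(7)
  m <- matrix(rnorm(400 * 5), 400, 5)
  m[, 2] <- m[, 1] * 0.5 + m[, 2]
  S <- cor(m)
  fit <- traitnet:::glasso_cpp(S, 0)
  theta_direct <- solve(S)
  pc_glasso <- -fit$theta / sqrt(diag(fit$theta) %o% diag(fit$theta))
  pc_direct <- -theta_direct / sqrt(diag(theta_direct) %o% diag(theta_direct))
  expect_lt(max(abs(pc_glasso - pc_direct)), 1e-6)
})

test_that("centrality equals a brute-force oracle on random 5-node networks", {
  oracle <- function(w) {
    p <- nrow(w)
    strength <- numeric(p)
    ei <- numeric(p)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i != j) {
          strength[i] <- strength[i] + abs(w[i, j])
          ei[i] <- ei[i] + w[i, j]
        }
      }
    }
    # power iteration on |w| from a positive start
    v <- rep(1, p)
    for (it in 1:10000) v <- abs(w) %*% v / sqrt(sum((abs(w) %*% v)^2))
    list(strength = strength, ei = ei, eig = as.vector(v / max(v)))
  }
  for (seed in 1:10) {
    set.seed(seed)
    w <- matrix(0, 5, 5)
    w[upper.tri(w)] <- runif(10, -1, 1) * rbinom(10, 1, 0.7)
    w <- w + t(w)
    net <- traitnet:::new_trait_network(w, paste0("n", 1:5), "cor")
    cent <- centrality(net)
    ref <- oracle(w)
    expect_equal(cent$strength, ref$strength, tolerance = 1e-8)
    expect_equal(cent$expected_influence, ref$ei, tolerance = 1e-8)
    expect_equal(cent$eigenvector, ref$eig, tolerance = 1e-6)
    expect_true(all(cent$strength >= abs(cent$expected_influence) - 1e-12))
    # node totals: strength and expected influence double-count each edge
    expect_equal(sum(cent$strength), 2 * sum(abs(w[upper.tri(w)])))
    expect_equal(sum(cent$expected_influence), 2 * sum(w[upper.tri(w)]))
  }
})

test_that("empty networks degrade gracefully in centrality", {
  net <- traitnet:::new_trait_network(
    matrix(0, 3, 3), paste0("n", 1:3), "cor"
  )
  expect_warning(cent <- centrality(net), "empty")
  expect_equal(cent$strength, rep(0, 3))
  expect_equal(cent$eigenvector, rep(0, 3))
})

test_that("edge bootstrap flags strong dependence and is seed-stable", {
  set.seed(8)
  n <- 100
  x <- rnorm(n)
  tab <- tibble::tibble(
    a = x, b = 0.9 * x + sqrt(1 - 0.81) * rnorm(n),
    c = rnorm(n), d = rnorm(n), e = rnorm(n)
  )
  eb <- edge_bootstrap(tab, estimator = "cor", n_boot = 150, seed = 3)
  ab <- dplyr::filter(eb$edges, node_a == "a", node_b == "b")
  expect_true(ab$significant)
  expect_gt(ab$ci_low, 0.5)
  expect_equal(ab$sign_agreement, 1)
  eb2 <- edge_bootstrap(tab, estimator = "cor", n_boot = 150, seed = 3)
  expect_identical(eb$edges, eb2$edges)
  # the mask is carried onto the network as its unweighted view
  expect_identical(sum(eb$network$mask[upper.tri(eb$network$mask)]),
    sum(eb$edges$significant))
  expect_error(edge_bootstrap(tab[1:5, ]), "8 subjects")
})

test_that("bootstrap CIs show near-nominal false-positive rates on noise", {
  rates <- vapply(1:3, function(s) {
    tab <- random_table(100, 8, seed = 20 + s)
    eb <- edge_bootstrap(tab, estimator = "cor", n_boot = 120, seed = s)
    mean(eb$edges$significant)
  }, numeric(1))
  expect_lt(mean(rates), 0.15) # ~5% nominal, generous Monte-Carlo slack
  expect_gt(mean(rates), 0.001)
})

test_that("case-dropping stability separates strong signal from pure noise", {
  # replicating a strong-signal cohort makes every subset agree
  base <- random_table(12, 6, seed = 30)
  base$v2 <- base$v1 + 0.2 * rnorm(12)
  base$v4 <- -base$v3 + 0.2 * rnorm(12)
  strong <- dplyr::bind_rows(replicate(20, base, simplify = FALSE))
  cs_strong <- cs_coefficient(
    strong,
    metrics = "strength", estimator = "cor",
    n_boot = 40, seed = 1
  )
  expect_equal(glance(cs_strong)$cs_coefficient, 0.75)
  expect_true(glance(cs_strong)$reliable)

  # pure noise at cohort size 24 is unstable
  cs_noise <- cs_coefficient(
    random_table(24, 6, seed = 31),
    metrics = "strength", estimator = "cor",
    n_boot = 40, seed = 2
  )
  expect_lt(glance(cs_noise)$cs_coefficient, 0.25)
  expect_false(glance(cs_noise)$reliable)
})

test_that("CS-coefficient is monotone non-increasing in the r threshold", {
  tab <- random_table(48, 6, seed = 32)
  tab$v2 <- tab$v1 + 0.4 * rnorm(48)
  cs <- cs_coefficient(tab,
    metrics = c("strength", "expected_influence"),
    estimator = "cor", n_boot = 60, seed = 3
  )
  for (thr in c(0.5, 0.8, 0.9)) {
    re <- cs_rethreshold(cs, thr)
    if (thr > cs$r_threshold) {
      expect_true(all(glance(re)$cs_coefficient <=
        glance(cs)$cs_coefficient))
    } else {
      expect_true(all(glance(re)$cs_coefficient >=
        glance(cs)$cs_coefficient))
    }
  }
})

test_that("drop proportions leaving too few subjects are trimmed", {
  tab <- random_table(12, 5, seed = 33)
  expect_warning(
    cs <- cs_coefficient(tab,
      metrics = "strength", estimator = "cor",
      n_boot = 10, seed = 1
    ),
    "< 4 subjects"
  )
  expect_lt(max(cs$drop_grid), 0.75)
})
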