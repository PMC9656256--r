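test_that("weight policies transform entries as defined", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- -0.4
  R[1, 3] <- R[3, 1] <- 0.6
  Wa <- apply_weight_policy(R, "absolute")
  Wp <- apply_weight_policy(R, "positive_only")
  Wr <- apply_weight_policy(R, "raw")
  expect_equal(Wa[1, 2], 0.4)
  expect_equal(Wp[1, 2], 0)
  expect_equal(Wr[1, 2], -0.4)
  expect_true(all(diag(Wa) == 0) && all(diag(Wp) == 0) && all(diag(Wr) == 0))
  Rpos <- abs(R); diag(Rpos) <- 1
  expect_equal(apply_weight_policy(Rpos, "absolute"),
               apply_weight_policy(Rpos, "positive_only"), ignore_attr = TRUE)
})

test_that("node strength matches the loop oracle and forced cases", {
  K <- matrix(1, 166, 166); diag(K) <- 0
  expect_equal(node_strength(K), rep(165, 166))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
  set.seed(10)
  W <- random_weight_matrix(6)
  expect_equal(node_strength(W), strength_oracle(W), tolerance = 1e-12)
})

test_that("eigenvector centrality matches closed forms and power iteration", {
  # uniform complete graph: theta_i = 1/sqrt(n)
  n <- 5
  K <- matrix(1, n, n); diag(K) <- 0
  ec <- eigenvector_centrality(K)
  expect_equal(ec$theta, rep(1 / sqrt(n), n), tolerance = 1e-12)
  expect_equal(ec$lambda, n - 1, tolerance = 1e-12)
  # 3-node path: closed-form spectrum
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  ec <- eigenvector_centrality(P)
  expect_equal(ec$theta, c(1 / 2, sqrt(2) / 2, 1 / 2), tolerance = 1e-12)
  expect_equal(ec$lambda, sqrt(2), tolerance = 1e-12)
  # eigen identity and power-iteration agreement on random graphs
  set.seed(11)
  for (rep in 1:5) {
    W <- random_weight_matrix(8)
    ec <- eigenvector_centrality(W)
    expect_lt(max(abs(W %*% ec$theta - ec$lambda * ec$theta)), 1e-10)
    po <- power_iteration_oracle(W)
    expect_equal(ec$theta, po$theta, tolerance = 1e-8)
    expect_true(all(ec$theta >= -1e-12))   # Perron-Frobenius
  }
})

test_that("degenerate leading eigenvalues and zero matrices are rejected", {
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "zero matrix")
  # two disconnected identical edges: leading eigenvalue has multiplicity 2
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  expect_error(eigenvector_centrality(W), "degenerate")
})

test_that("clustering coefficient matches hand values and the triple-loop oracle", {
  # unit triangle: numerator 2 (ordered pairs), l = 2, denominator 2 -> 1
  Tri <- matrix(1, 3, 3); diag(Tri) <- 0
  expect_equal(clustering_coefficient(Tri), rep(1, 3))
  # star graph: no closed triples
  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S[2:5, 1] <- 1
  expect_equal(clustering_coefficient(S), rep(0, 5))
  set.seed(12)
  W <- random_weight_matrix(5)
  expect_equal(clustering_coefficient(W), clustering_oracle(W), tolerance = 1e-12)
  expect_error(clustering_coefficient(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("binary graphs reduce to the triangle-count formula", {
  set.seed(13)
  for (rep in 1:5) {
    A <- matrix(rbinom(49, 1, 0.5), 7, 7)
    A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
    cc <- clustering_coefficient(A)
    tri <- diag(A %*% A %*% A)   # 2x triangle count per node
    k <- rowSums(A)
    want <- ifelse(k > 1, tri / (k * (k - 1)), 0)
    expect_equal(cc, as.numeric(want), tolerance = 1e-12)
  }
})

test_that("measures are scale-covariant and relabeling-equivariant", {
  set.seed(14)
  for (rep in 1:10) {
    W <- random_weight_matrix(8)
    c0 <- runif(1, 0.5, 4)
    expect_equal(node_strength(c0 * W), c0 * node_strength(W), tolerance = 1e-12)
    expect_equal(eigenvector_centrality(c0 * W)$theta,
                 eigenvector_centrality(W)$theta, tolerance = 1e-9)
    # clustering is scale-covariant only in the large-strength limit (the
    # denominator l(l-1) is not homogeneous); assert oracle equivalence of
    # the rescaled graph instead
    expect_equal(clustering_coefficient(c0 * W),
                 clustering_oracle(c0 * W), tolerance = 1e-11)
    perm <- sample(8)
    Wp <- W[perm, perm]
    expect_equal(node_strength(Wp), node_strength(W)[perm], tolerance = 1e-12)
    expect_equal(clustering_coefficient(Wp),
                 clustering_coefficient(W)[perm], tolerance = 1e-11)
    expect_equal(eigenvector_centrality(Wp)$theta,
                 eigenvector_centrality(W)$theta[perm], tolerance = 1e-9)
  }
})

test_that("network mean is the arithmetic mean with the documented edge cases", {
  expect_equal(network_mean(rep(3.7, 12)), 3.7)
  expect_equal(network_mean(c(0, 1)), 0.5)
  v <- rnorm(9)
  expect_equal(network_mean(v), network_mean(sample(v)))
  expect_error(network_mean(numeric(0)), "empty")
})

test_that("node_measures bundles vectors with consistent invariants", {
  set.seed(15)
  R <- random_connectivity(12, id = "subj-9")
  nm <- node_measures(R)
  expect_equal(length(nm$clustering), 12)
  expect_equal(sum(nm$centrality^2), 1, tolerance = 1e-12)
  expect_true(all(nm$centrality >= -1e-12))
  expect_true(all(nm$strength >= 0))
  expect_equal(unname(nm$means["strength"]), mean(nm$strength))
  expect_identical(nm$subject_id, "subj-9")
  M <- measure_matrix(list(nm, nm), "centrality")
  expect_equal(dim(M), c(2L, 12L))
})
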