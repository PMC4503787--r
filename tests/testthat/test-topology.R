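test_that("solve_in_out conserves the average and honors the ratio", {
  ## ratio 1 degenerates to the unclustered value
  io <- solve_in_out(0.2, 1, 0.3)
  expect_equal(unname(io), c(0.2, 0.2))
  ## closed form: out = avg / (1 + f_in (ratio - 1)), checked by
  ## substitution (reference values frozen from the closed form)
  f_in <- (80 - 1) / (1600 - 1)
  io <- solve_in_out(0.2, 3.4, f_in, prob = TRUE)
  expect_equal(io[["out"]], 0.1787991, tolerance = 1e-6)
  expect_equal(io[["in"]], 0.6079168, tolerance = 1e-6)
  ## conservation and ratio hold for random inputs, including negative
  ## (inhibitory) averages
  set.seed(1)
  for (i in 1:50) {
    avg <- stats::runif(1, -1, 1)
    ratio <- stats::runif(1, 0.1, 6)
    f <- stats::runif(1, 0.01, 0.9)
    io <- solve_in_out(avg, ratio, f)
    expect_equal(f * io[["in"]] + (1 - f) * io[["out"]], avg)
    expect_equal(io[["in"]], ratio * io[["out"]])
  }
  expect_error(solve_in_out(0.2, 50, 0.05, prob = TRUE), "exceeds 1")
})

test_that("weights scale as 1/N relative to the N = 2000 reference", {
  expect_equal(scale_weights_for_size(0.0156, 1000), 0.0312)
  expect_equal(scale_weights_for_size(c(a = 1, b = -2), 2000), c(a = 1, b = -2))
  w <- c(0.0156, -0.0297)
  expect_equal(scale_weights_for_size(scale_weights_for_size(w, 500),
                                      2000 * 2000 / 500), w)
})

test_that("unclustered generator hits the target block densities and weights", {
  net <- generate_network(network_spec("unclustered", N = 1000, c = 10,
                                       seed = 3))
  ty <- net$types
  expect_equal(sum(ty == "E"), 800)
  for (blk in list(c("E", "E", 0.2), c("I", "E", 0.5), c("E", "I", 0.5),
                   c("I", "I", 0.5))) {
    B <- net$W[ty == blk[1], ty == blk[2]]
    p <- as.numeric(blk[3])
    n_pairs <- length(B) - (blk[1] == blk[2]) * sum(ty == blk[1])
    tol3sd <- 3 * sqrt(p * (1 - p) / n_pairs)
    expect_lt(abs(sum(B != 0) / n_pairs - p), tol3sd)
  }
  ## weights: scaled by 2000/1000 = 2, single sign per presynaptic type
  EE <- net$W[ty == "E", ty == "E"]
  expect_equal(unique(EE[EE != 0]), 0.0312)
  for (j in which(ty == "I")) expect_true(all(net$W[, j] <= 0))
  for (j in which(ty == "E")) expect_true(all(net$W[, j] >= 0))
  expect_true(all(diag(net$W) == 0))
})

test_that("balanced construction gives net inhibitory expected input", {
  ## expectation from the baseline parameters:
  ## 0.2 * 1600 * 0.0156 + 0.5 * 400 * (-0.0297) = -0.948
  net <- generate_network(network_spec("unclustered", N = 2000, seed = 9))
  bal <- validate_balance(net)
  e_row <- bal[bal$post_type == "E", ]
  expect_equal(e_row$net_in, -0.948, tolerance = 0.05)
  expect_true(attr(bal, "balanced"))
  ## the 1/N weight scaling cancels against connection counts
  net1k <- generate_network(network_spec("unclustered", N = 1000, c = 10,
                                         seed = 9))
  bal1k <- validate_balance(net1k)
  expect_equal(bal1k[bal1k$post_type == "E", "net_in"], -0.948,
               tolerance = 0.08)
  ## a silent matrix is flagged as non-recurrent
  empty <- list(W = matrix(0, 10, 10), types = rep(c("E", "I"), c(8, 2)))
  expect_message(b0 <- validate_balance(empty), "no recurrence")
  expect_equal(b0$net_in, c(0, 0))
})

test_that("probability clustering realizes the in/out ratio and conserves density", {
  spec <- network_spec("clustered_prob", N = 1000, c = 10, R_EE = 3, seed = 4)
  net <- generate_network(spec)
  grp <- net$partition$group[1:800]
  EE <- net$W[1:800, 1:800] != 0
  diag(EE) <- NA
  same <- outer(grp, grp, "==")
  d_in <- mean(EE[same], na.rm = TRUE)
  d_out <- mean(EE[!same], na.rm = TRUE)
  expect_equal(d_in / d_out, 3, tolerance = 0.15)
  ## overall density conserved at 0.2
  expect_equal(mean(EE, na.rm = TRUE), 0.2, tolerance = 0.01)
  ## too-large ratios are rejected with the probability bound
  expect_error(generate_network(network_spec("clustered_prob", N = 1000,
                                             c = 10, R_EE = 12, seed = 1)),
               "exceeds 1")
})

test_that("weight clustering conserves the average weight at uniform density", {
  spec <- network_spec("clustered_weight", N = 1000, c = 10, W_EE = 4,
                       seed = 5)
  net <- generate_network(spec)
  grp <- net$partition$group[1:800]
  EE <- net$W[1:800, 1:800]
  same <- outer(grp, grp, "==")
  diag(same) <- NA
  w_ref <- 0.0312  # scaled base weight at N = 1000
  ## per potential pair the expected weight is p * w; with uniform p the
  ## realized-edge average converges to the conserved average weight
  edges <- EE != 0
  expect_equal(mean(EE[edges]), w_ref, tolerance = 0.01)
  w_in <- unique(EE[edges & same & !is.na(same)])
  w_out <- unique(EE[edges & !same & !is.na(same)])
  expect_equal(w_in / w_out, 4, tolerance = 1e-10)
  ## density stays uniform at 0.2
  expect_equal(mean(edges[!is.na(same)]), 0.2, tolerance = 0.01)
})

test_that("degenerate ratios reproduce the unclustered law", {
  for (kind in c("clustered_prob", "clustered_weight", "ei_coclustered",
                 "small_world")) {
    net <- generate_network(small_spec(kind, N = 500, c = 5, seed = 8))
    ty <- net$types
    EE <- net$W[ty == "E", ty == "E"]
    n_pairs <- length(EE) - nrow(EE)
    expect_lt(abs(sum(EE != 0) / n_pairs - 0.2),
              3 * sqrt(0.2 * 0.8 / n_pairs))
    expect_equal(unique(EE[EE != 0]), 0.0156 * 4)
  }
})

test_that("identical spec and seed reproduce the matrix bit-for-bit", {
  for (kind in c("unclustered", "clustered_prob", "scale_free",
                 "hierarchical")) {
    s <- if (kind == "hierarchical")
      network_spec(kind, N = 400, c = 8, c_top = 4, R_top = 1.3,
                   R_sub = 2, seed = 13)
    else small_spec(kind, N = 400, c = 8, R_EE = 2, d = 8, seed = 13)
    n1 <- generate_network(s)
    n2 <- generate_network(s)
    expect_identical(n1$W, n2$W)
    expect_identical(n1$partition, n2$partition)
  }
})

test_that("E-I co-clustering applies direct and inverse ratios and conserves averages", {
  spec <- network_spec("ei_coclustered", N = 1000, c = 10,
                       R_EI = 2, R_IE = 2, W_EI = 3, W_IE = 3, seed = 6)
  net <- generate_network(spec)
  eidx <- 1:800; iidx <- 801:1000
  pair_E <- net$partition$group[eidx]
  pair_I <- net$partition$group[iidx]
  expect_equal(net$partition$scope, "E+I")
  ## I -> E block: inverse ratio means weaker in-pair inhibition
  EI <- net$W[eidx, iidx]
  same <- outer(pair_E, pair_I, "==")
  w_in <- unique(EI[EI != 0 & same])
  w_out <- unique(EI[EI != 0 & !same])
  expect_lt(abs(w_in), abs(w_out))
  expect_equal(abs(w_out) / abs(w_in), 3, tolerance = 1e-10)
  ## potential-pair average weight conserved at the scaled base value
  f <- 1 / 10
  expect_equal(f * w_in + (1 - f) * w_out, -0.0297 * 2, tolerance = 1e-10)
  ## in-pair connection probability reduced by the inverse ratio
  d_in <- mean(EI[same] != 0); d_out <- mean(EI[!same] != 0)
  expect_equal(d_out / d_in, 2, tolerance = 0.2)
  ## E -> I block: ordinary ratio, elevated in-pair
  IE <- net$W[iidx, eidx]
  same_ie <- outer(pair_I, pair_E, "==")
  expect_gt(mean(IE[same_ie] != 0) / mean(IE[!same_ie] != 0), 1.5)
  expect_equal(f * unique(IE[IE != 0 & same_ie]) +
                 (1 - f) * unique(IE[IE != 0 & !same_ie]),
               0.0074 * 2, tolerance = 1e-10)
})

test_that("small-world ring carries the elevated probability and conserves density", {
  spec <- network_spec("small_world", N = 1000, c = 10, R_sw = 3, seed = 2)
  net <- generate_network(spec)
  N_E <- 800
  EE <- net$W[1:N_E, 1:N_E] != 0
  ring <- abs(outer(1:N_E, 1:N_E, "-"))
  ring <- pmin(ring, N_E - ring) <= 40
  diag(ring) <- NA
  d_in <- mean(EE[ring & !is.na(ring)])
  d_out <- mean(EE[!ring & !is.na(ring)])
  expect_equal(d_in / d_out, 3, tolerance = 0.15)
  expect_equal(mean(EE[!is.na(ring)]), 0.2, tolerance = 0.01)
})

test_that("scale-free attachment yields a symmetric hub-dominated E-E block", {
  spec <- network_spec("scale_free", N = 500, c = 5, d = 8, seed = 10)
  net <- generate_network(spec)
  EE <- net$W[1:400, 1:400]
  expect_true(isSymmetric(EE))
  expect_true(all(EE %in% c(0, 0.0156 * 4)))
  deg <- rowSums(EE != 0)
  ## preferential attachment: early nodes (the seed clique) end up as hubs
  expect_true(mean(net$hub_order[1:8] <= 40) > 0.5)
  expect_gt(max(deg), 4 * stats::median(deg))
  expect_equal(net$partition$scope, "none")
  ## d = 1 grows a tree on the excitatory nodes
  tiny <- generate_network(network_spec("scale_free", N = 5, c = 1, d = 1,
                                        seed = 1))
  A <- tiny$W[1:4, 1:4] != 0
  expect_true(isSymmetric(A))
  expect_equal(sum(A) / 2, 3)  # N_E - 1 undirected edges
})

test_that("hierarchical tiers average to the baseline density exactly", {
  spec <- network_spec("hierarchical", N = 2000, c = 32, c_top = 16,
                       R_top = 1.45, R_sub = 3.7, seed = 1)
  ## analytic check of the three-tier solve
  n_sub <- 50; N_E <- 1600
  f_sub <- (n_sub - 1) / (N_E - 1)
  f_grp <- n_sub / (N_E - 1)
  f_out <- (N_E - 2 * n_sub) / (N_E - 1)
  p_out <- 0.2 / (f_sub * 3.7 * 1.45 + f_grp * 1.45 + f_out)
  p_grp <- 1.45 * p_out; p_sub <- 3.7 * p_grp
  expect_equal(f_sub * p_sub + f_grp * p_grp + f_out * p_out, 0.2)
  net <- generate_network(spec)
  sub <- net$partition$levels$sub[1:N_E]
  top <- net$partition$levels$top[1:N_E]
  ## nesting: each subgroup lies wholly inside one top group
  for (g in unique(sub)) expect_length(unique(top[sub == g]), 1)
  EE <- net$W[1:N_E, 1:N_E]
  same_sub <- outer(sub, sub, "==")
  diag(same_sub) <- NA
  expect_equal(mean(EE[same_sub & !is.na(same_sub)] != 0), p_sub,
               tolerance = 0.02)
  expect_equal(mean(EE != 0) * N_E^2 / (N_E^2 - N_E), 0.2, tolerance = 0.01)
  ## within-subgroup weights are elevated (w_sub), others at baseline
  expect_equal(sort(unique(EE[EE != 0])), c(0.0156, 0.0163))
  w_in_sub <- EE[same_sub & !is.na(same_sub) & EE != 0]
  ## ratio 1 with baseline w_sub degenerates to unclustered
  flat <- generate_network(network_spec("hierarchical", N = 500, c = 8,
                                        c_top = 4, R_top = 1, R_sub = 1,
                                        w_sub = 0.0156, seed = 2))
  EEf <- flat$W[1:400, 1:400]
  expect_equal(unique(EEf[EEf != 0]), 0.0156 * 4)
  expect_equal(sum(EEf != 0) / (400 * 399), 0.2, tolerance = 0.02)
})

test_that("network round-trips through Matrix Market plus JSON sidecar", {
  net <- generate_network(network_spec("hierarchical", N = 400, c = 8,
                                       c_top = 4, R_top = 1.3, R_sub = 2,
                                       seed = 3))
  mtx <- tempfile(fileext = ".mtx")
  write_network(net, mtx)
  back <- read_network(mtx)
  expect_equal(back$W, unname(net$W), tolerance = 1e-12)
  expect_identical(back$types, net$types)
  expect_identical(back$partition$group, net$partition$group)
  expect_identical(back$partition$levels$top, net$partition$levels$top)
  unlink(c(mtx, sub("\\.mtx$", ".json", mtx)))
})
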