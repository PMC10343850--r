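chain_onto <- function() disease_ontology(c("d", "p", "g"),
                                          rbind(c("d", "p"), c("p", "g")))
diamond_onto <- function() disease_ontology(
  c("d", "p1", "p2", "g"),
  rbind(c("d", "p1"), c("d", "p2"), c("p1", "g"), c("p2", "g")))

test_that("ancestor closures cover chains, diamonds and bare roots", {
  ch <- ancestor_closure(chain_onto(), "d")
  expect_setequal(ch$nodes, c("d", "p", "g"))
  expect_equal(nrow(ch$edges), 2)

  di <- ancestor_closure(diamond_onto(), "d")
  expect_setequal(di$nodes, c("d", "p1", "p2", "g"))
  expect_equal(nrow(di$edges), 4)

  iso <- disease_ontology(c("d3"), matrix(character(), 0, 2))
  cl <- ancestor_closure(iso, "d3")
  expect_equal(cl$nodes, "d3")
  expect_equal(nrow(cl$edges), 0)
})

test_that("decay contributions follow the mu-per-step rule", {
  c1 <- semantic_contribution_wang(ancestor_closure(chain_onto(), "d"))
  expect_equal(c1[c("d", "p", "g")], c(d = 1, p = 0.5, g = 0.25))
  expect_equal(semantic_value(c1), 1.75)

  solo <- semantic_contribution_wang(
    ancestor_closure(disease_ontology("d", matrix(character(), 0, 2)), "d"))
  expect_equal(unname(solo), 1)
  expect_equal(semantic_value(solo), 1)

  cd <- semantic_contribution_wang(ancestor_closure(diamond_onto(), "d"))
  expect_equal(cd[["g"]], 0.25)   # 0.5 * max(0.5, 0.5)

  # worked example: DS(d1) over {d1, p}
  we <- make_worked_example()
  c1_d1 <- semantic_contribution_wang(ancestor_closure(we$onto, "d1"))
  expect_equal(semantic_value(c1_d1), 1.5)
})

test_that("decay contributions equal mu^shortest-ancestor-path on random DAGs", {
  mu <- 0.5
  for (seed in 1:25) {
    n <- 3 + (seed %% 10)  # DAGs up to 12 nodes
    dag <- random_dag_edges(n, seed)
    onto <- disease_ontology(dag$nodes, dag$edges)
    d <- dag$nodes[n]
    cl <- ancestor_closure(onto, d)
    c1 <- semantic_contribution_wang(cl, semantic_params(mu = mu))
    dist <- igraph::distances(onto$graph, v = d, to = cl$nodes, mode = "out")
    expect_equal(c1[cl$nodes], mu^dist[1, cl$nodes], ignore_attr = TRUE)
  }
})

test_that("information-content contributions count DAG membership", {
  # four diseases all containing a shared root g
  onto <- disease_ontology(c("a", "b", "c", "e", "g"),
                           rbind(c("a", "g"), c("b", "g"), c("c", "g"),
                                 c("e", "g")))
  xu <- semantic_contribution_xuan(onto, c("a", "b", "c", "e"))
  expect_equal(xu$C2[["g"]], 0)            # present in all 4 DAGs
  expect_equal(xu$C2[["a"]], log(4))       # NG = 1, nd = 4, natural log
  expect_true(all(table(unlist(lapply(xu$closures, `[[`, "nodes"))) >= 1))
  # configurable log base
  xu2 <- semantic_contribution_xuan(onto, c("a", "b", "c", "e"),
                                    semantic_params(log_base = 2))
  expect_equal(xu2$C2[["a"]], 2)
})

test_that("semantic similarity reproduces the worked example and its edge cases", {
  we <- make_worked_example()
  ids <- we$assoc$disease_ids
  dss1 <- semantic_similarity(we$onto, ids, scheme = "wang")
  expect_equal(dss1$values["d1", "d2"], 1 / 3)
  expect_equal(diag(dss1$values), rep(1, 3), ignore_attr = TRUE)
  # d3 uncovered -> missing off-diagonal entries
  expect_true(dss1$missing["d1", "d3"])

  # disjoint ancestor sets -> similarity 0
  onto2 <- disease_ontology(c("x", "y", "px", "py"),
                            rbind(c("x", "px"), c("y", "py")))
  d0 <- semantic_similarity(onto2, c("x", "y"), scheme = "wang")
  expect_equal(d0$values["x", "y"], 0)

  # information-content scheme on the worked example, computed by hand:
  # shared term p with C2(p) = -log(2/3); DS2(d1) = DS2(d2) = log 3 + log 1.5
  dss2 <- semantic_similarity(we$onto, ids, scheme = "xuan")
  expect_equal(dss2$values["d1", "d2"], log(1.5) / (log(3) + log(1.5)))

  dss <- combined_semantic_similarity(dss1, dss2)
  expect_equal(dss$values["d1", "d2"], (1 / 3 + log(1.5) / (log(3) + log(1.5))) / 2)
  expect_equal(diag(dss$values), rep(1, 3), ignore_attr = TRUE)
  expect_true(dss$missing["d1", "d3"])  # missing in either input -> missing
})

test_that("semantic similarity is permutation-equivariant", {
  onto <- generate_ontology(15, max_parents = 2, seed = 3, prefix = "d")
  ids <- sprintf("d%d", 1:15)
  perm <- withr::with_seed(5, sample(15))
  s1 <- semantic_similarity(onto, ids, scheme = "wang")
  s2 <- semantic_similarity(onto, ids[perm], scheme = "wang")
  expect_equal(s2$values, s1$values[perm, perm], ignore_attr = TRUE)
})

test_that("GIP bandwidth normalizes by the mean squared profile norm", {
  profs <- rbind(c(1, 0), c(0, 1))
  expect_equal(gip_bandwidth(profs, 1), 1)
  expect_equal(gip_bandwidth(profs * sqrt(2), 1), 0.5)  # doubling sq norms halves alpha
  expect_equal(gip_bandwidth(profs, 2), 2)
  expect_error(gip_bandwidth(matrix(0, 3, 4), 1), "degenerate")
})

test_that("GIP kernel matches the analytic values and a brute-force oracle", {
  profs <- rbind(c(1, 0), c(0, 1))
  K <- gip_kernel(profs, 1)
  expect_equal(K$values[1, 2], exp(-2))
  expect_equal(diag(K$values), rep(1, 2), ignore_attr = TRUE)

  A <- withr::with_seed(13, matrix(rbinom(60, 1, 0.4), 10, 6))
  alpha <- gip_bandwidth(A, 1)
  K2 <- gip_kernel(A, alpha)
  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- exp(-alpha * sum((A[i, ] - A[j, ])^2))
  expect_lt(max(abs(K2$values - oracle)), 1e-12)
  expect_true(all(K2$values > 0 & K2$values <= 1))
})

test_that("with a fixed bandwidth, removing an association only touches its row/column", {
  A <- withr::with_seed(2, matrix(rbinom(80, 1, 0.4), 10, 8))
  A[3, 5] <- 1
  alpha <- gip_bandwidth(A, 1)
  K_before <- gip_kernel(A, alpha)$values
  A2 <- A; A2[3, 5] <- 0
  K_after <- gip_kernel(A2, alpha)$values
  expect_equal(diag(K_after), rep(1, 10), ignore_attr = TRUE)
  expect_equal(K_after[-3, -3], K_before[-3, -3])
  expect_false(isTRUE(all.equal(K_after[3, ], K_before[3, ])))
})

test_that("integration averages where the primary similarity exists and falls back otherwise", {
  ids <- c("a", "b", "c")
  primary <- similarity_matrix(rbind(c(1, 0.4, NA),
                                     c(0.4, 1, 0.8),
                                     c(NA, 0.8, 1)), ids)
  gip <- similarity_matrix(rbind(c(1, 0.6, 0.6),
                                 c(0.6, 1, 0.8),
                                 c(0.6, 0.8, 1)), ids)
  ms <- integrate_similarity(primary, gip)
  expect_equal(ms$values["a", "b"], 0.5)   # mean branch
  expect_equal(ms$values["a", "c"], 0.6)   # fallback branch
  expect_equal(ms$values["b", "c"], 0.8)   # equal inputs stay put
  expect_false(any(ms$missing))
  expect_error(integrate_similarity(primary,
                                    similarity_matrix(diag(3), c("x", "y", "z"))),
               "id mismatch")
})

test_that("all pipeline similarity outputs are symmetric with unit diagonal", {
  dat <- tiny_dataset()
  for (nmx in c("MS", "DS", "DSS", "KSM", "KSD")) {
    s <- dat$sims[[nmx]]
    expect_lt(max(abs(s$values - t(s$values)), na.rm = TRUE), 1e-12)
    expect_equal(diag(s$values), rep(1, length(s$ids)), ignore_attr = TRUE)
  }
  expect_false(any(dat$sims$MS$missing))
  expect_false(any(dat$sims$DS$missing))
})
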