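test_that("single strong edge and worked four-node cascade simulate exactly", {
  nodes <- data.frame(acronym = c("A", "B"), x_mm = c(0, 1), y_mm = 0,
                      z_mm = 0)
  chain <- connectome(nodes, data.frame(src = "A", tgt = "B", weight = 2,
                                        p_value = 0.01))
  r <- run_alt(chain, "A", alt_params(theta = 1))
  expect_equal(unname(r$activation_time[c("A", "B")]), c(0, 1))
  expect_equal(r$dag[, c("src", "tgt")],
               data.frame(src = "A", tgt = "B"))
  expect_true(r$complete)

  # A->B(d1,w2), A->C(d2,w0.6), B->C(d1,w0.6), C->D(d1,w2), theta = 1:
  # C needs both 0.6 inputs, which accumulate at t = 2; the causal DAG
  # keeps the individually sub-threshold contributor A->C
  toy <- toy_fig1_network()
  r <- run_alt(toy, "A", alt_params(theta = 1))
  expect_equal(unname(r$activation_time[c("A", "B", "C", "D")]),
               c(0, 1, 2, 3))
  expect_setequal(paste(r$dag$src, r$dag$tgt),
                  c("A B", "A C", "B C", "C D"))
  expect_equal(r$activation_time,
               oracle_alt_times(toy, "A", 1))

  # theta above every achievable input: only the source activates
  r10 <- run_alt(toy, "A", alt_params(theta = 10))
  expect_equal(sum(!is.na(r10$activation_time)), 1)
  expect_equal(nrow(r10$dag), 0)

  expect_error(run_alt(toy, "Z", alt_params(1)), "unknown source")
  expect_error(alt_params(theta = 0), "positive")
})

test_that("event-driven simulator equals the time-stepping oracle", {
  for (seed in 1:25) {
    con <- rand_connectome(sample(4:12, 1), 0.35, seed = seed)
    theta <- stats::runif(1, 0.2, 1.5)
    src <- con$nodes$acronym[1]
    r <- run_alt(con, src, alt_params(theta = theta))
    expect_equal(r$activation_time, oracle_alt_times(con, src, theta),
                 info = paste("seed", seed))
  }
})

test_that("causal DAG rule holds edge-by-edge and rejects broken times", {
  con <- rand_connectome(10, 0.4, seed = 42)
  r <- run_alt(con, con$nodes$acronym[1], alt_params(theta = 0.4))
  # every DAG edge satisfies t_tgt >= t_src + delay
  del <- stats::setNames(con$edges$delay,
                         paste(con$edges$src, con$edges$tgt))
  for (k in seq_len(nrow(r$dag)))
    expect_gte(r$dag$t_tgt[k] + 1e-9,
               r$dag$t_src[k] + del[[paste(r$dag$src[k], r$dag$tgt[k])]])
  # DAG is acyclic
  g <- igraph::graph_from_data_frame(r$dag[, c("src", "tgt")])
  expect_true(igraph::is_dag(g))
  # times claiming an active non-source with no causal in-edge are rejected
  bad_times <- r$activation_time
  active <- names(bad_times)[!is.na(bad_times)]
  bad_times[active[2]] <- 0.0001   # activated before any input can arrive
  expect_error(build_cascade_dag(con, bad_times, con$nodes$acronym[1]),
               "integrity")
})

test_that("raising theta never activates new nodes; edges never delay", {
  for (seed in 1:8) {
    con <- rand_connectome(10, 0.35, seed = 100 + seed)
    src <- con$nodes$acronym[1]
    prev <- NULL
    for (th in c(0.3, 0.7, 1.2, 2)) {
      act <- !is.na(run_alt(con, src, alt_params(th))$activation_time)
      if (!is.null(prev)) expect_true(all(!act | prev))
      prev <- act
    }
    # adding one edge is monotone: no activation happens later
    t1 <- run_alt(con, src, alt_params(0.7))$activation_time
    nodes <- con$nodes$acronym
    free <- expand.grid(src = nodes, tgt = nodes,
                        stringsAsFactors = FALSE)
    free <- free[free$src != free$tgt, ]
    have <- paste(con$edges$src, con$edges$tgt)
    free <- free[!(paste(free$src, free$tgt) %in% have), ][1, ]
    con2 <- con
    con2$edges <- rbind(con$edges,
                        data.frame(src = free$src, tgt = free$tgt,
                                   weight = 1.5, p_value = 0.01,
                                   length_mm = 1, delay = 1))
    t2 <- run_alt(con2, src, alt_params(0.7))$activation_time
    expect_true(all(is.na(t1) | (!is.na(t2) & t2 <= t1 + 1e-9)))
  }
})

test_that("multi-source cascades are at least as fast as either source", {
  for (seed in 1:5) {
    con <- rand_connectome(10, 0.4, seed = 200 + seed)
    ab <- con$nodes$acronym[1:2]
    p <- alt_params(0.6)
    t_a <- run_alt(con, ab[1], p)$activation_time
    t_b <- run_alt(con, ab[2], p)$activation_time
    t_ab <- run_alt(con, ab, p)$activation_time
    best <- pmin(t_a, t_b, na.rm = TRUE)
    both_na <- is.na(t_a) & is.na(t_b)
    expect_true(all(both_na | (!is.na(t_ab) & t_ab <= best + 1e-9)))
  }
})

test_that("theta sweep is non-increasing and critical theta matches oracle", {
  toy <- toy_fig1_network()
  sw <- theta_sweep(toy, "A", c(0.5, 1.0, 1.5))
  # at 1.5 the strong A->B edge (w=2) still fires but C's summed 1.2 < 1.5
  expect_equal(sw$fraction_active, c(1.0, 1.0, 0.5))
  expect_true(all(diff(sw$fraction_active) <= 0))
  expect_error(theta_sweep(toy, "A", numeric(0)), "empty")

  # huge theta blocks all spread
  sw2 <- theta_sweep(toy, "A", c(0.5, 1e6))
  expect_equal(sw2$fraction_active[2], 1 / 4)

  # complete at 1.1 (C gets 1.2 > 1.1), incomplete at 1.3
  expect_equal(find_critical_theta(toy, "A", c(0.9, 1.0, 1.1, 1.3)), 1.1)
  expect_equal(find_critical_theta(toy, "A", c(5, 10)), NA_real_)
  expect_equal(find_critical_theta(toy, "A", c(0.5, 0.9)), 0.9)
})

test_that("in-normalized weight mode rescales thresholds as fractions", {
  toy <- toy_fig1_network()
  # C's in-weights (0.6, 0.6) normalize to (0.5, 0.5); with theta = 0.6
  # C still needs both inputs, arriving at t = 2
  r <- run_alt(toy, "A", alt_params(theta = 0.6,
                                    weight_mode = "in_normalized"))
  expect_equal(unname(r$activation_time[c("A", "B", "C", "D")]),
               c(0, 1, 2, 3))
  expect_equal(r$activation_time,
               oracle_alt_times(toy, "A", 0.6, "in_normalized"))
})
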