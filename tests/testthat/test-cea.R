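published_base <- function() {
  utils::read.csv(system.file("extdata", "published", "base_case.csv",
                              package = "afcua"))
}

test_that("raw cost/utility ratios match the published base case", {
  expect_equal(raw_cu_ratio(7289, 3.5368), 2061)
  expect_equal(raw_cu_ratio(7749, 3.5453), 2186)
  expect_equal(raw_cu_ratio(8494, 3.7897), 2241)
  expect_equal(raw_cu_ratio(0, 1), 0)
  expect_error(raw_cu_ratio(100, 0), "mean_qaly")
})

test_that("incremental cost-utility ratio", {
  expect_equal(icur(7289, 3.5368, 8494, 3.7897), 4765)
  expect_equal(icur(7289, 3.5368, 7749, 3.5453), 54118)
  expect_equal(icur(10, 1, 10, 2), 0)
  expect_warning(r <- icur(10, 1, 20, 1), "undefined")
  expect_true(is.na(r))
})

test_that("net monetary benefit and the ICUR identity", {
  expect_equal(nmb(500, 2, 0), -500)
  expect_equal(nmb(8494, 3.7897, 50000), 180991)
  set.seed(5)
  for (i in 1:50) {
    rc <- runif(1, 1000, 20000); rq <- runif(1, 1, 5)
    ac <- runif(1, 1000, 20000); aq <- rq + runif(1, 0.01, 1)
    l <- runif(1, 0, 1e5)
    ic <- icur(rc, rq, ac, aq, rounded = FALSE)
    expect_equal(nmb(ac, aq, l) - nmb(rc, rq, l), (aq - rq) * (l - ic),
                 tolerance = 1e-8)
  }
})

test_that("dominance frontier reproduces the published labels and ICURs", {
  fr <- dominance_frontier(published_base())
  expect_equal(fr$status[fr$arm == "gtw"], "extended_dominated")
  expect_equal(fr$status[fr$arm == "sdw"], "on_frontier")
  dab <- fr[fr$arm == "dab150", ]
  expect_equal(dab$status, "on_frontier")
  expect_equal(dab$comparator, "sdw")
  expect_equal(dab$delta_cost, 1205)
  expect_equal(dab$delta_qaly, 0.2529)
  expect_equal(dab$icur, 4765)
  # the cheap-dabigatran scenario strictly dominates both warfarin arms
  low <- data.frame(arm = c("dab150", "sdw", "gtw"),
                    mean_cost = c(5217, 7289, 7749),
                    mean_qaly = c(3.7897, 3.5368, 3.5453))
  fr2 <- dominance_frontier(low)
  expect_equal(fr2$status[fr2$arm == "sdw"], "strictly_dominated")
  expect_equal(fr2$status[fr2$arm == "gtw"], "strictly_dominated")
  expect_equal(fr2$status[fr2$arm == "dab150"], "on_frontier")
})

test_that("frontier is order-invariant, tie-tolerant, with increasing ICURs", {
  df <- published_base()
  ref <- dominance_frontier(df)
  set.seed(9)
  for (i in 1:10) {
    perm <- dominance_frontier(df[sample(nrow(df)), ])
    expect_equal(perm, ref)
  }
  # exact ties share the frontier
  tie <- data.frame(arm = c("a", "b"), mean_cost = c(100, 100),
                    mean_qaly = c(1, 1))
  expect_true(all(dominance_frontier(tie)$status == "on_frontier"))
  # property: ICURs strictly increase along random frontiers
  for (i in 1:20) {
    k <- sample(3:6, 1)
    df2 <- data.frame(arm = paste0("s", 1:k),
                      mean_cost = runif(k, 0, 1e4),
                      mean_qaly = runif(k, 0, 5))
    fr <- dominance_frontier(df2)
    ics <- fr$icur[!is.na(fr$icur)]
    if (length(ics) >= 2) expect_true(all(diff(ics) > 0))
    expect_setequal(fr$arm, df2$arm)
  }
})

test_that("acceptability curve: degenerate, split and monotone cases", {
  # comparator dominant in every draw
  draws <- rbind(
    data.frame(iteration = 1:10, arm = "sdw", mean_cost = 100, mean_qaly = 1),
    data.frame(iteration = 1:10, arm = "dab150", mean_cost = 50, mean_qaly = 2))
  cc <- build_ceac(draws, "sdw", "dab150", thresholds = c(0, 5e4, 1e5))
  expect_true(all(cc$probability_ce == 1))
  expect_equal(cc$p_dominant[1], 1)
  # exactly half of draws favorable at a threshold
  draws2 <- rbind(
    data.frame(iteration = 1:10, arm = "sdw", mean_cost = 100, mean_qaly = 1),
    data.frame(iteration = 1:10, arm = "dab150",
               mean_cost = 100 + c(rep(-10, 5), rep(10, 5)), mean_qaly = 1))
  cc2 <- build_ceac(draws2, "sdw", "dab150", thresholds = 0)
  expect_equal(cc2$probability_ce, 0.5)
  # fixed deltas step from 0 to 1 exactly at the ICUR
  draws3 <- rbind(
    data.frame(iteration = 1:5, arm = "sdw", mean_cost = 7289, mean_qaly = 3.5368),
    data.frame(iteration = 1:5, arm = "dab150", mean_cost = 7289 + 1205,
               mean_qaly = 3.5368 + 0.2529))
  cc3 <- build_ceac(draws3, "sdw", "dab150",
                    thresholds = c(0, 4000, 4764, 4765, 4766, 50000))
  expect_equal(cc3$probability_ce, c(0, 0, 0, 1, 1, 1))
  # monotone whenever the QALY gain is positive in every draw
  set.seed(21)
  draws4 <- rbind(
    data.frame(iteration = 1:200, arm = "sdw",
               mean_cost = runif(200, 5e3, 9e3), mean_qaly = runif(200, 3, 4)),
    data.frame(iteration = 1:200, arm = "dab150",
               mean_cost = runif(200, 5e3, 12e3),
               mean_qaly = runif(200, 3, 4) + runif(200, 0.01, 0.5)))
  draws4$mean_qaly[draws4$arm == "dab150"] <-
    draws4$mean_qaly[draws4$arm == "sdw"] + runif(200, 0.01, 0.5)
  cc4 <- build_ceac(draws4, "sdw", "dab150")
  expect_true(all(diff(cc4$probability_ce) >= 0))
  expect_error(build_ceac(draws4[0, ], "sdw", "dab150"), "empty")
})
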