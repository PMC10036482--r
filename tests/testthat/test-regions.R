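wf <- list(base = c(0, 0), tip = c(2000, 0),
           leading = c(0, 0), trailing = c(0, 800))

test_that("normalized wing coordinates are anchored and invertible", {
  expect_equal(normalizeCoordinates(rbind(c(0, 0)), wf),
               rbind(c(0, 0)), ignore_attr = TRUE)
  expect_equal(normalizeCoordinates(rbind(c(1000, 400)), wf),
               rbind(c(0.5, 0.5)), ignore_attr = TRUE)
  pts <- cbind(runif(20, 0, 2000), runif(20, 0, 800))
  back <- normalizeCoordinates(normalizeCoordinates(pts, wf), wf,
                               inverse = TRUE)
  expect_equal(back, pts, tolerance = 1e-12, ignore_attr = TRUE)
  degenerate <- list(base = c(0, 0), tip = c(0, 0),
                     leading = c(0, 0), trailing = c(0, 800))
  expect_error(normalizeCoordinates(pts, degenerate), "degenerate")
})

test_that("region assignment follows the map with deterministic tie-breaks", {
  expect_equal(assignRegion(c(0.1, 0.05)), "leading_edge")
  expect_equal(assignRegion(c(0.7, 0.1)), "membrane")
  expect_equal(assignRegion(c(0.95, 0.5)), "wing_tip")
  expect_equal(assignRegion(c(0.3, 0.9)), "trailing_edge")
  expect_equal(assignRegion(c(0.3, 0.5)), "lattice")
  # boundary points resolve identically on repeated evaluation
  onEdge <- c(0.55, 0.1)                  # leading_edge / membrane border
  expect_equal(assignRegion(onEdge), assignRegion(onEdge))
  expect_equal(assignRegion(onEdge), "leading_edge")  # priority order
  expect_equal(assignRegion(c(1.2, 0.5)), "unassigned")
})

test_that("the wing polygons partition the unit domain", {
  map <- defaultRegionMap()
  grid <- expand.grid(s = seq(0.01, 0.99, by = 0.07),
                      c = seq(0.01, 0.99, by = 0.07))
  labels <- vapply(seq_len(nrow(grid)), function(i)
    assignRegion(c(grid$s[i], grid$c[i]), map), "")
  expect_true(all(labels %in% regionLabels(map)))
  expect_setequal(unique(labels),
                  c("leading_edge", "membrane", "wing_tip", "lattice",
                    "trailing_edge"))
})

test_that("mean vein radius averages positive measurements", {
  r <- meanVeinRadius(rep(100, 25))
  expect_equal(as.numeric(r), 100)
  expect_equal(attr(r, "n"), 25L)
  expect_equal(as.numeric(meanVeinRadius(c(80, 120))), 100)
  set.seed(2)
  lead <- runif(25, 85, 125)
  m <- meanVeinRadius(lead)
  expect_true(m >= 85 && m <= 125)
  expect_error(meanVeinRadius(numeric()), "no radius")
  expect_error(meanVeinRadius(c(100, -3)), "positive")
})

test_that("region summaries aggregate trajectory kinematics", {
  kin <- data.frame(track_id = 1:3,
                    v_max_mm_s = c(1, 3, 0.8),
                    v_median_mm_s = c(0.8, 2.4, 0.5),
                    pulse_freq_hz = c(0.5, 0.7, 0.3),
                    region = c("leading_edge", "leading_edge", "wing_tip"))
  s <- summarizeRegions(kin)
  lead <- s[s$region == "leading_edge", ]
  expect_equal(lead$n_trajectories, 2L)
  expect_equal(lead$v_max_mm_s, 2)        # mean of 1 and 3
  expect_equal(lead$pulse_freq_hz, 0.6)
  # dimensionless numbers recomputed from region-level quantities
  map <- defaultRegionMap()
  expect_equal(lead$Pe, peclet(map@radii[["leading_edge"]], 2e-3))
  expect_equal(lead$Re, reynolds(map@radii[["leading_edge"]], 2e-3))
  expect_equal(lead$Wo, womersley(map@radii[["leading_edge"]], 0.6))
  # single-trajectory region equals that trajectory; empty regions omitted
  tip <- s[s$region == "wing_tip", ]
  expect_equal(tip$v_max_mm_s, 0.8)
  expect_false("trailing_edge" %in% s$region)
  # aggregation consistency: means lie within member ranges
  expect_true(lead$v_max_mm_s >= 1 && lead$v_max_mm_s <= 3)
})

test_that("flow behaviors classify by stops, reversals and floors", {
  expect_equal(classifyFlowBehavior(rep(1.2, 50)), "aperiodic")
  expect_equal(classifyFlowBehavior(sin(seq(0, 6 * pi, length.out = 100))),
               "pulsatile")
  expect_equal(classifyFlowBehavior(c(1, 1, 1)), "indeterminate")
  # modulated but never near zero stays aperiodic
  t <- seq(0, 4, by = 0.02)
  expect_equal(classifyFlowBehavior(
    hemoflow:::signedAperiodic(t, 300, 0.4, 0.5) / 1000), "aperiodic")
  # touching zero without sign change is already pulsatile
  expect_equal(classifyFlowBehavior(pmax(sin(seq(0, 6 * pi,
                                                 length.out = 100)), 0)),
               "pulsatile")
})

test_that("behavior labels recover imposed modes on generated series", {
  t <- seq(0, 10, by = 0.04)
  hits <- 0L; n <- 0L
  set.seed(5)
  for (k in 1:20) {
    if (k %% 2 == 0) {
      v <- hemoflow:::signedPulsatile(t, runif(1, 0.3, 1.5), 400,
                                      runif(1, 0, 0.6))
      want <- "pulsatile"
    } else {
      v <- hemoflow:::signedAperiodic(t, runif(1, 200, 600),
                                      runif(1, 0, 0.6), 0.5,
                                      runif(1, 0, 2 * pi))
      want <- "aperiodic"
    }
    v <- v + rnorm(length(v), 0, 8)       # mild measurement noise
    n <- n + 1L
    if (classifyFlowBehavior(v / 1000) == want) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})
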