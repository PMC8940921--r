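# Helper: minimal hand-built WellTimeSeries for the summary functions.
mkSeries <- function(time, doc, nitrate = doc * 0, dists = NULL) {
  nwell <- ncol(doc)
  ids <- paste0("W", seq_len(nwell))
  if (is.null(dists)) dists <- (seq_len(nwell) - 1) * 8
  wells <- data.frame(id = ids, x_mm = dists, y_mm = 0, distance_mm = dists,
                      volume_ul = 100, role = c("alga", rep("bacteria", nwell - 1)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[-nwell], to = ids[-1], thickness_mm = 0.9,
                      area_mm2 = 10, d_eff_doc = 2e-10, d_eff_nitrate = 5e-10,
                      stringsAsFactors = FALSE)
  layout <- buildLayout("custom", wells = wells, edges = edges,
                        reservoir = list(nitrate = 882, doc = 0,
                                         volume_ml = 25, fixed = TRUE))
  colnames(doc) <- colnames(nitrate) <- ids
  new("WellTimeSeries", time = time, wells = ids, doc = doc,
      nitrate = nitrate, algae = doc * 0, bacteria = list(), layout = layout)
}

test_that("layout presets have the documented geometry", {
  hex <- buildLayout("hex7")
  w <- wellsOf(hex); e <- edgesOf(hex)
  expect_equal(nrow(w), 7)
  expect_equal(sum(w$distance_mm == 0), 1)
  expect_true(all(w$distance_mm[w$id != "C0"] == 8))
  # centre: 6 internal edges, no reservoir edge
  centre_edges <- e[e$from == "C0" | e$to == "C0", ]
  expect_equal(nrow(centre_edges), 6)
  expect_false(any(centre_edges$from == "RESERVOIR" |
                   centre_edges$to == "RESERVOIR"))
  # each outer well touches the reservoir
  res_edges <- e[e$from == "RESERVOIR" | e$to == "RESERVOIR", ]
  expect_equal(sort(unique(c(res_edges$from, res_edges$to))),
               sort(c("RESERVOIR", w$id[w$id != "C0"])))

  comm <- buildLayout("community_layers")
  wc <- wellsOf(comm)
  expect_setequal(unique(wc$distance_mm[wc$role == "bacteria"]), c(8, 16))
  expect_equal(sum(wc$role == "blank"), 6)

  iso <- buildLayout("isolate_rings")
  expect_setequal(unique(wellsOf(iso)$distance_mm), c(0, 7, 14, 21))

  single <- buildLayout("single_well")
  expect_equal(nrow(wellsOf(single)), 1)
  expect_equal(nrow(edgesOf(single)), 1)
})

test_that("invalid layouts are rejected", {
  w <- data.frame(id = c("A", "B"), x_mm = c(0, 0), y_mm = c(0, 0),
                  distance_mm = c(0, 0), volume_ul = 100, role = "alga",
                  stringsAsFactors = FALSE)
  e <- data.frame(from = "A", to = "B", thickness_mm = 0.9, area_mm2 = 10,
                  d_eff_doc = 2e-10, d_eff_nitrate = 5e-10,
                  stringsAsFactors = FALSE)
  expect_error(buildLayout("custom", wells = w, edges = e), "overlapping")
  w$x_mm <- c(0, 8)
  expect_error(buildLayout("custom", wells = w,
                           edges = e[integer(0), , drop = FALSE]),
               "disconnected")
})

test_that("wall flux is Fickian: antisymmetric, linear, unit-checked", {
  w <- wallParams(d_eff_doc = 1e-10, area_mm2 = 10, thickness_mm = 0.9)
  expect_equal(diffusiveFlux(5, 5, w), 0)
  expect_equal(diffusiveFlux(3, 7, w), -diffusiveFlux(7, 3, w))
  expect_equal(diffusiveFlux(100, 0, wallParams(d_eff_doc = 1e-10,
                                                area_mm2 = 20,
                                                thickness_mm = 0.9)),
               2 * diffusiveFlux(100, 0, w))
  expect_equal(diffusiveFlux(100, 0, wallParams(d_eff_doc = 1e-10,
                                                area_mm2 = 10,
                                                thickness_mm = 1.8)),
               diffusiveFlux(100, 0, w) / 2)
  # hand-checked arithmetic: 1e-10 m2/s * 86400 s/d * 1e-5 m2 * 0.1 mol/m3
  # / 9e-4 m = 9.6e-9 mol/d = 9.6 nmol/d
  expect_equal(diffusiveFlux(100, 0, w), 9.6, tolerance = 1e-12)
  expect_error(wallParams(d_eff_doc = 1e-9, medium = mediumParams()),
               "cannot exceed")
})

test_that("Peclet check flags negligible advection", {
  expect_equal(pecletCheck(0, 9e-4, 1e-9)$Pe, 0)
  pc <- pecletCheck(1e-8, 9e-4, 1e-9)
  expect_equal(pc$Pe, 9e-3)
  expect_true(pc$negligible)
  expect_equal(pecletCheck(2e-8, 9e-4, 1e-9)$Pe, 2 * pc$Pe)
  expect_false(pecletCheck(1e-3, 9e-4, 1e-9)$negligible)
  expect_error(pecletCheck(1e-8, 9e-4, 0), "diffusivity")
})

test_that("abiotic wells relax monotonically to the reservoir value", {
  layout <- buildLayout("hex7", reservoir = list(nitrate = 882, doc = 0,
                                                 volume_ml = 25,
                                                 fixed = TRUE))
  run <- simulatePlate(layout, alga = NULL, t_span = c(0, 10), dt_out = 0.5,
                       init_nitrate = 0)
  no3 <- wellMatrix(run, "nitrate")
  # monotone rise everywhere (up to sub-ppb integrator wiggle at the plateau)
  expect_true(all(diff(no3) >= -1e-4))
  expect_equal(unname(no3[nrow(no3), ]), rep(882, 7), tolerance = 1e-3)
})

test_that("sealed plates conserve solute mass to 1e-8 over 20 days", {
  layout <- sealLayout(buildLayout("community_layers"))
  # uneven initial field so there is real transport to integrate
  nw <- nrow(wellsOf(layout))
  run <- simulatePlate(layout, alga = NULL, t_span = c(0, 20), dt_out = 1,
                       init_doc = seq(0, 300, length.out = nw),
                       init_nitrate = seq(882, 0, length.out = nw))
  for (what in c("doc", "nitrate")) {
    m0 <- totalMoles(run, what, 1)
    mT <- totalMoles(run, what, length(timePoints(run)))
    expect_lt(abs(mT - m0) / m0, 1e-8)
  }
})

test_that("two-compartment equilibration matches the closed-form rate", {
  # two equal wells, one wall, no organisms: dC difference decays with
  # k = G * (1/V1 + 1/V2); simulated half-life within 0.5% of ln2/k
  w <- data.frame(id = c("A", "B"), x_mm = c(0, 8), y_mm = 0,
                  distance_mm = c(0, 8), volume_ul = 100,
                  role = "medium-control", stringsAsFactors = FALSE)
  e <- data.frame(from = "A", to = "B", thickness_mm = 0.9, area_mm2 = 10,
                  d_eff_doc = 2e-10, d_eff_nitrate = 5e-10,
                  stringsAsFactors = FALSE)
  layout <- buildLayout("custom", wells = w, edges = e,
                        reservoir = list(nitrate = 0, doc = 0,
                                         volume_ml = 25, fixed = TRUE))
  run <- simulatePlate(layout, alga = NULL, t_span = c(0, 1), dt_out = 0.001,
                       init_doc = c(100, 0), init_nitrate = c(0, 0))
  doc <- wellMatrix(run, "doc")
  dC <- doc[, "A"] - doc[, "B"]
  g_nmol <- diffusiveFlux(1, 0, wallParams(d_eff_doc = 2e-10, area_mm2 = 10,
                                           thickness_mm = 0.9))
  k <- g_nmol * (1 / 100 + 1 / 100) * 1e3    # 1/d
  t_half_theory <- log(2) / k
  t_half_sim <- stats::approx(dC / dC[1], timePoints(run), xout = 0.5)$y
  expect_lt(abs(t_half_sim - t_half_theory) / t_half_theory, 0.005)
})

test_that("an algal centre well imposes opposing monotone spatial gradients", {
  layout <- buildLayout("community_layers")
  run <- simulatePlate(layout, algalPopulation(), t_span = c(0, 7),
                       dt_out = 0.5)
  w <- wellsOf(layout)
  ord <- order(w$distance_mm)
  dist_sorted <- w$distance_mm[ord]
  for (ti in seq_along(timePoints(run))) {
    doc_by_d <- geoMeanBy(wellMatrix(run, "doc")[ti, w$id[ord]], dist_sorted)
    no3_by_d <- geoMeanBy(wellMatrix(run, "nitrate")[ti, w$id[ord]],
                          dist_sorted)
    expect_true(all(diff(doc_by_d) <= 1e-9))
    expect_true(all(diff(no3_by_d) >= -1e-9))
  }
})

test_that("depletion time interpolates and flags never-depleted wells", {
  ts <- mkSeries(time = 0:3,
                 doc = matrix(1, 4, 2),
                 nitrate = cbind(c(800, 400, 8, 1), c(800, 790, 780, 770)))
  # crossing exactly at a grid point (threshold 1% of 800 = 8 at t = 2)
  expect_equal(nitrateDepletionTime(ts, "W1"), 2)
  # linear interpolation between t=1 (400) and t=2 (8)
  expect_equal(nitrateDepletionTime(ts, "W1", threshold_fraction = 0.1),
               1 + (400 - 80) / (400 - 8))
  expect_identical(nitrateDepletionTime(ts, "W2"), Inf)
  expect_error(nitrateDepletionTime(ts, "nope"), "unknown well")
  expect_error(nitrateDepletionTime(ts, "W1", threshold_fraction = 2),
               "threshold_fraction")
})

test_that("DOC fold across wells is near/far with depletion flagging", {
  ts <- mkSeries(time = 0:1, doc = rbind(c(7, 7, 7), c(50, 25, 10)))
  expect_equal(docFoldAcrossWells(ts, t = 0), 1)
  expect_equal(docFoldAcrossWells(ts, t = 1), 5)
  ts0 <- mkSeries(time = 0:1, doc = rbind(c(1, 1), c(50, 0)))
  f <- docFoldAcrossWells(ts0, t = 1)
  expect_identical(as.numeric(f), Inf)
  expect_true(attr(f, "depleted"))
})

test_that("negative initial states are rejected", {
  layout <- buildLayout("single_well")
  expect_error(simulatePlate(layout, alga = NULL, init_doc = -1,
                             t_span = c(0, 1)),
               "non-negative")
})
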