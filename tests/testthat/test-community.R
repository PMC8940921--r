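# Single well sealed off from the reservoir: the minimal chemostat/batch
# testbed for the bacterial growth model.
singleSealed <- function(doc0, no30) {
  w <- data.frame(id = "W1", x_mm = 0, y_mm = 0, distance_mm = 0,
                  volume_ul = 100, role = "bacteria",
                  stringsAsFactors = FALSE)
  # a second, far well keeps the graph non-trivial but unconnected edges
  # are not allowed, so use a genuinely sealed single-well graph
  layout <- buildLayout("custom", wells = w,
                        edges = data.frame(from = character(0),
                                           to = character(0),
                                           thickness_mm = numeric(0),
                                           area_mm2 = numeric(0),
                                           d_eff_doc = numeric(0),
                                           d_eff_nitrate = numeric(0)),
                        reservoir = list(nitrate = no30, doc = doc0,
                                         volume_ml = 25, fixed = TRUE))
  layout
}

test_that("with no resources and no mortality, densities stay constant", {
  layout <- singleSealed(0, 0)
  tx <- taxonParams("idle", "generalist", mu_max_doc = 2, km_doc = 10,
                    mu_max_n = 1, km_n = 5, mortality = 0,
                    initial_density = 1e6)
  out <- simulateCocultures(layout, alga = NULL, taxa = list(idle = tx),
                            t_span = c(0, 10), geo_sd = 1, dt_out = 1)
  dens <- wellMatrix(out$series, "idle")
  expect_equal(unname(dens[, 1]), rep(1e6, nrow(dens)), tolerance = 1e-10)
})

test_that("constant-resource growth matches the closed-form Monod rate", {
  layout <- singleSealed(doc0 = 40, no30 = 100)
  tx <- taxonParams("tx", "generalist", mu_max_doc = 1.2, km_doc = 20,
                    mu_max_n = 0.5, km_n = 10, mortality = 0.05,
                    initial_density = 1e5)
  out <- simulateCocultures(layout, alga = NULL, taxa = list(tx = tx),
                            t_span = c(0, 5), geo_sd = 1, dt_out = 1,
                            hold_resources = TRUE)
  dens <- wellMatrix(out$series, "tx")[, 1]
  expected <- monodExponential(1e5, 1.2, 20, 40, 0.5, 10, 100, 0.05,
                               t = timePoints(out$series))
  expect_equal(unname(dens), expected, tolerance = 1e-6)
})

test_that("an exudate specialist cannot grow in a DOC-free control plate", {
  layout <- buildLayout("isolate_rings", center_role = "medium-control",
                        reservoir = list(nitrate = 882, doc = 0,
                                         volume_ml = 25, fixed = TRUE))
  taxa <- isolateTaxa()["Algoriphagus"]
  out <- simulateCocultures(layout, alga = NULL, taxa = taxa,
                            t_span = c(0, 20), geo_sd = 1, dt_out = 1,
                            placement = "mixed")
  d <- abundanceData(out$abundance)
  final <- geoMeanBy(d$density, d$distance_mm)
  expect_true(all(final <= taxa$Algoriphagus@initial_density))
})

test_that("resource accounting balances cells produced against substrate", {
  layout <- singleSealed(doc0 = 100, no30 = 0)
  tx <- taxonParams("tx", "exudate_specialist", mu_max_doc = 2, km_doc = 30,
                    yield_doc = 5e7, mortality = 0, initial_density = 1e5)
  out <- simulateCocultures(layout, alga = NULL, taxa = list(tx = tx),
                            t_span = c(0, 15), geo_sd = 1, dt_out = 1)
  s <- out$series
  nT <- length(timePoints(s))
  cells_made <- wellMatrix(s, "tx")[nT, 1] - wellMatrix(s, "tx")[1, 1]
  doc_used_uM <- wellMatrix(s, "doc")[1, 1] - wellMatrix(s, "doc")[nT, 1]
  # uM -> umol/ml; yield in cells/umol
  cells_expected <- doc_used_uM / 1e3 * 5e7
  expect_equal(cells_made, cells_expected, tolerance = 1e-6)
})

test_that("mu_max is recovered within 5% from noise-free growth curves", {
  doc <- 500
  tx <- taxonParams("tx", "exudate_specialist", mu_max_doc = 1.7,
                    km_doc = 40, mortality = 0, initial_density = 1e5)
  layout <- singleSealed(doc0 = doc, no30 = 0)
  out <- simulateCocultures(layout, alga = NULL, taxa = list(tx = tx),
                            t_span = c(0, 4), geo_sd = 1, dt_out = 1,
                            hold_resources = TRUE)
  dens <- wellMatrix(out$series, "tx")[, 1]
  fit <- specificGrowthRate(dens, times = timePoints(out$series),
                            t1 = 0, t2 = 4)
  mu_max_hat <- fit$mu * (40 + doc) / doc # invert the Monod factor
  expect_lt(abs(mu_max_hat - 1.7) / 1.7, 0.05)
})

test_that("replicate noise is seeded, reproducible, and refused unseeded", {
  layout <- buildLayout("isolate_rings")
  expect_error(simulateCocultures(layout, taxa = isolateTaxa(),
                                  t_span = c(0, 2), geo_sd = 1.3),
               "seed")
  a <- simulateCocultures(layout, taxa = isolateTaxa(), t_span = c(0, 2),
                          seed = 7, geo_sd = 1.3, placement = "arms")
  b <- simulateCocultures(layout, taxa = isolateTaxa(), t_span = c(0, 2),
                          seed = 7, geo_sd = 1.3, placement = "arms")
  c <- simulateCocultures(layout, taxa = isolateTaxa(), t_span = c(0, 2),
                          seed = 8, geo_sd = 1.3, placement = "arms")
  expect_identical(abundanceData(a$abundance), abundanceData(b$abundance))
  expect_false(identical(abundanceData(a$abundance),
                         abundanceData(c$abundance)))
})

test_that("arm placement produces per-well monocultures", {
  layout <- buildLayout("isolate_rings")
  out <- simulateCocultures(layout, taxa = isolateTaxa(), t_span = c(0, 1),
                            geo_sd = 1, placement = "arms")
  d <- abundanceData(out$abundance)
  per_well <- table(d$well_id)
  expect_true(all(per_well == length(unique(d$replicate))))
  # each taxon occupies 3 of the 6 arms at each of 3 distances
  expect_equal(as.integer(table(d$taxon[d$replicate == 1])), c(9L, 9L))
})

test_that("relative abundances are compositional and unbiased", {
  mk_tab <- function(dens) {
    n <- length(dens)
    new("AbundanceTable", data = data.frame(
      well_id = "W1", layer = 1, distance_mm = 8, treatment = "with_alga",
      taxon = paste0("t", seq_len(n)), density = dens,
      rel_abundance = NA_real_, replicate = 1, timepoint = 7,
      stringsAsFactors = FALSE))
  }
  # single taxon -> 1.0 regardless of depth
  one <- toRelativeAbundance(mk_tab(5e6), sequencing_depth = 1e4, seed = 1)
  expect_equal(abundanceData(one)$rel_abundance, 1)

  # analytic limit: no overdispersion, infinite depth -> exact ratios
  exact <- toRelativeAbundance(mk_tab(c(3e6, 1e6)), sequencing_depth = Inf,
                               overdispersion = 0)
  expect_equal(abundanceData(exact)$rel_abundance, c(0.75, 0.25))

  # sampled at depth 1e6 the proportions converge on the density ratios
  samp <- toRelativeAbundance(mk_tab(c(3e6, 1e6)), sequencing_depth = 1e6,
                              overdispersion = 0, seed = 11)
  expect_equal(abundanceData(samp)$rel_abundance, c(0.75, 0.25),
               tolerance = 0.005)

  # equal densities -> 0.5/0.5 in expectation
  reps <- vapply(1:400, function(s) {
    abundanceData(toRelativeAbundance(mk_tab(c(1e6, 1e6)),
                                      sequencing_depth = 1e3,
                                      overdispersion = 0.3,
                                      seed = s))$rel_abundance[1]
  }, numeric(1))
  expect_equal(mean(reps), 0.5, tolerance = 0.05)

  # zero-density sample flagged
  expect_warning(z <- toRelativeAbundance(mk_tab(c(0, 0)),
                                          sequencing_depth = 1e3, seed = 2),
                 "zero total density")
  expect_equal(abundanceData(z)$rel_abundance, c(0, 0))

  # sums to one per sample at finite depth
  layout <- buildLayout("community_layers")
  run <- simulateCocultures(layout, algalPopulation(), communityTaxa(),
                            t_span = c(0, 3), seed = 3, geo_sd = 1.2,
                            dt_out = 0.5)
  tab <- toRelativeAbundance(run$abundance, sequencing_depth = 1e4,
                             overdispersion = 0.2, seed = 4)
  d <- abundanceData(tab)
  sums <- tapply(d$rel_abundance,
                 interaction(d$well_id, d$replicate, drop = TRUE), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
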