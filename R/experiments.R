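## Experiment pipelines: chain the modules into the three plate experiments
## (algal growth, bacterial isolates, mixed community) plus the two-scale
## model comparison, writing tidy CSVs and a JSON run manifest.

.writeCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.manifest <- function(name, cfg, seed, files, extra = list()) {
  files <- files[!vapply(files, is.null, logical(1))]
  man <- c(list(
    experiment = name,
    package_version = as.character(utils::packageVersion("phycogradients")),
    seed = seed,
    config = cfg,
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  ), extra)
  man
}

#' Run a named experiment pipeline
#'
#' \describe{
#'   \item{fig3_growth}{Algal growth in the hex7 plate versus the sealed
#'     (batch-equivalent) plate over 20 days: per-well trajectories, specific
#'     growth rates in centre versus surrounding wells, reservoir gain.}
#'   \item{fig4_model}{The two-scale model comparison: normalised phycosphere
#'     DOC/nitrate profiles (both growth phases, preset species) next to
#'     normalised plate profiles from the 7-day community-layout run;
#'     reports the plate DOC fold and centre-well nitrate depletion time.}
#'   \item{fig5_isolates}{Two-strain co-culture in the isolate-rings layout
#'     (distances up to 21 mm), with and without the alga, abundance
#'     snapshots in early (day 6) and late (day 20) phase, and distance
#'     fold-changes per strain.}
#'   \item{fig6_community}{Eight-taxon community in the community-layers
#'     layout for 7 days, both treatments, 16S-like relative abundances, and
#'     per-genus layer-by-treatment interaction ANOVA with BH correction.}
#' }
#'
#' @param name Experiment name (see Details).
#' @param config Configuration list from \code{loadConfig}/\code{defaultConfig}.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly; also written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
runExperiment <- function(name = c("fig3_growth", "fig4_model",
                                   "fig5_isolates", "fig6_community"),
                          config = defaultConfig(), seed = 1,
                          out_dir = ".") {
  name <- match.arg(name)
  .validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  files <- list()
  extra <- list()

  if (name == "fig3_growth") {
    layout <- .configLayout(cfg, preset = "hex7")
    alga <- .configAlga(cfg)
    days <- max(cfg$plate$days, 20)
    porous <- simulatePlate(layout, alga, .configMedium(cfg),
                            t_span = c(0, days), dt_out = cfg$plate$dt_out)
    sealed <- simulatePlate(sealLayout(layout), alga, .configMedium(cfg),
                            t_span = c(0, days), dt_out = cfg$plate$dt_out)
    files$porous <- .writeCSV(asDataFrame(porous),
                              file.path(out_dir, "growth_porous.csv"))
    files$sealed <- .writeCSV(asDataFrame(sealed),
                              file.path(out_dir, "growth_sealed.csv"))
    t_idx <- timePoints(porous)
    centre <- wellMatrix(porous, "algae")[, "C0"]
    outer_ids <- setdiff(wellsOf(layout)$id, "C0")
    outer <- rowMeans(wellMatrix(porous, "algae")[, outer_ids])
    win <- c(3, 5)
    mu_centre <- specificGrowthRate(centre[t_idx %in% win], times = win)
    mu_outer <- specificGrowthRate(outer[t_idx %in% win], times = win)
    extra$summary <- list(
      final_density_centre = unname(centre[length(centre)]),
      final_density_outer = unname(outer[length(outer)]),
      final_density_sealed = unname(mean(
        wellMatrix(sealed, "algae")[length(t_idx), ])),
      reservoir_gain = unname(mean(wellMatrix(porous, "algae")[length(t_idx), ]) /
        mean(wellMatrix(sealed, "algae")[length(t_idx), ])),
      mu_centre = mu_centre$mu, mu_outer = mu_outer$mu
    )
  } else if (name == "fig4_model") {
    presets <- speciesPresets()
    prof_rows <- do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
      p <- presets[i, ]
      cell <- cellParams(p$species, p$radius_um, p$q_exu, p$u_max,
                         p$km_uptake, p$phase)
      med <- mediumParams(d_doc = cfg$medium$d_doc,
                          d_nitrate = cfg$medium$d_nitrate,
                          bulk_doc = p$bulk_doc, bulk_nitrate = p$bulk_nitrate)
      doc <- suppressWarnings(normalizeProfile(docProfile(cell, med)))
      no3 <- suppressWarnings(normalizeProfile(nitrateProfile(cell, med)))
      cbind(species = p$species, phase = p$phase,
            rbind(asDataFrame(doc), asDataFrame(no3)))
    }))
    files$phycosphere <- .writeCSV(
      prof_rows, file.path(out_dir, "phycosphere_profiles.csv"))

    layout <- .configLayout(cfg, preset = "community_layers")
    run <- simulatePlate(layout, .configAlga(cfg), .configMedium(cfg),
                         t_span = c(0, cfg$plate$days),
                         dt_out = cfg$plate$dt_out)
    w <- wellsOf(layout)
    last <- length(timePoints(run))
    by_dist <- vapply(split(w$id, w$distance_mm), function(ids) {
      c(doc = mean(wellMatrix(run, "doc")[last, ids]),
        nitrate = mean(wellMatrix(run, "nitrate")[last, ids]))
    }, numeric(2))
    dists <- as.numeric(colnames(by_dist))
    plate_prof <- data.frame(
      r = rep(dists / max(dists), 2),
      conc = c(by_dist["doc", ] / max(by_dist["doc", ]),
               if (max(by_dist["nitrate", ]) > 0)
                 by_dist["nitrate", ] / max(by_dist["nitrate", ])
               else by_dist["nitrate", ]),
      solute = rep(c("DOC", "nitrate"), each = length(dists)),
      normalized = TRUE
    )
    files$plate <- .writeCSV(plate_prof,
                             file.path(out_dir, "plate_profiles.csv"))
    extra$summary <- list(
      phycosphere_folds = phycosphereFolds(presets)$fold,
      plate_doc_fold = docFoldAcrossWells(run),
      nitrate_depletion_day = nitrateDepletionTime(run, "C0")
    )
  } else if (name == "fig5_isolates") {
    alga <- .configAlga(cfg)
    alga@n0 <- 1e7 # pre-acclimated algal culture in the isolates design
    taxa <- isolateTaxa()
    days <- max(cfg$plate$days, 20)
    runs <- lapply(c(test = "alga", control = "medium-control"),
      function(role) {
        layout <- .configLayout(cfg, preset = "isolate_rings",
                                center_role = role)
        simulateCocultures(layout,
                           alga = if (role == "alga") alga else NULL,
                           taxa = taxa, medium = .configMedium(cfg),
                           t_span = c(0, days), seed = seed,
                           timepoints = c(6, days),
                           n_replicates = cfg$community$n_replicates,
                           geo_sd = cfg$community$geo_sd,
                           dt_out = cfg$plate$dt_out, placement = "arms")
      })
    ab <- rbind(abundanceData(runs$test$abundance),
                abundanceData(runs$control$abundance))
    files$abundance <- .writeCSV(ab, file.path(out_dir,
                                               "isolate_abundance.csv"))
    files$series <- .writeCSV(asDataFrame(runs$test$series),
                              file.path(out_dir, "isolate_series_test.csv"))
    test_tab <- runs$test$abundance
    extra$summary <- list(
      fold_specialist = foldChangeByDistance(test_tab, "Algoriphagus",
                                             t = days)$fold,
      fold_generalist = foldChangeByDistance(test_tab, "Marinobacter",
                                             t = days)$fold
    )
  } else { # fig6_community
    alga <- .configAlga(cfg)
    taxa <- communityTaxa()
    runs <- lapply(c(with_alga = "alga", control = "medium-control"),
      function(role) {
        layout <- .configLayout(cfg, preset = "community_layers",
                                center_role = role)
        simulateCocultures(layout,
                           alga = if (role == "alga") alga else NULL,
                           taxa = taxa, medium = .configMedium(cfg),
                           t_span = c(0, cfg$plate$days), seed = seed,
                           n_replicates = cfg$community$n_replicates,
                           geo_sd = cfg$community$geo_sd,
                           dt_out = cfg$plate$dt_out)
      })
    tabs <- lapply(runs, function(r) {
      toRelativeAbundance(r$abundance,
                          sequencing_depth = cfg$community$sequencing_depth,
                          overdispersion = cfg$community$overdispersion,
                          seed = seed)
    })
    ab <- rbind(abundanceData(tabs$with_alga), abundanceData(tabs$control))
    files$abundance <- .writeCSV(ab, file.path(out_dir,
                                               "community_abundance.csv"))
    # layer x treatment interaction per genus, on log densities
    genera <- unique(ab$taxon)
    stats_rows <- do.call(rbind, lapply(genera, function(g) {
      d <- ab[ab$taxon == g, ]
      res <- twoWayAnovaInteraction(log(pmax(d$density, 1e3)),
                                    d$layer, d$treatment)
      data.frame(taxon = g,
                 f_interaction = res$f[res$term == "A:B"],
                 p_interaction = res$p[res$term == "A:B"],
                 stringsAsFactors = FALSE)
    }))
    stats_rows$fdr_interaction <- adjustFDR(stats_rows$p_interaction)
    files$stats <- .writeCSV(stats_rows,
                             file.path(out_dir, "community_interaction.csv"))
    extra$summary <- list(
      n_genera = length(genera),
      n_significant_interaction = sum(stats_rows$p_interaction < 0.05)
    )
  }

  man <- .manifest(name, cfg, seed, files, extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
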