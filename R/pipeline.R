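#' Build a pipeline run configuration
#'
#' Collects the module specifications and seeds for one reproducible
#' end-to-end run. Defaults are the full study design (three areas, 40
#' units each, 4 analysed replicates standardized to c. 1320 m^2);
#' simulation-heavy stages (effort curves, permutation counts) can be
#' scaled through the dedicated fields.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param areas Named list of area rectangles.
#' @param bathymetry Named list of [generate_bathymetry()] arguments, or
#'   `NULL` to skip the bathymetry/terrain stage.
#' @param community A [community_spec()].
#' @param nodules Named list (per area) of [nodule_field_spec()] objects;
#'   default Flat 10.1%, Ridge 6.3%, Trough 3.8% mean cover.
#' @param survey A [survey_spec()].
#' @param sediment Named list of [generate_sediment()] arguments.
#' @param hard_substrata_ha Per-area expected hard-substrata densities
#'   (items ha^-1) emulated as Poisson marks on images.
#' @param n_perm Permutations for PERMANOVA and metric group tests.
#' @param effort_reps Replicates per size for effort curves.
#' @param nmds_restarts Random starts for the ordination.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       areas = default_area_polygons(),
                       bathymetry = list(),
                       community = community_spec(),
                       nodules = list(
                         Flat = nodule_field_spec(mean_cover = 10.1),
                         Ridge = nodule_field_spec(mean_cover = 6.3),
                         Trough = nodule_field_spec(mean_cover = 3.8)),
                       survey = survey_spec(),
                       sediment = list(),
                       hard_substrata_ha = c(Flat = 62, Ridge = 682,
                                             Trough = 64),
                       n_perm = 999, effort_reps = 1000,
                       nmds_restarts = 20) {
  if (survey$replicates_per_area < 1) {
    stop("at least one replicate unit per area required", call. = FALSE)
  }
  if (!setequal(names(areas), names(nodules))) {
    stop("'nodules' must name the same areas as 'areas'", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), areas = areas,
                 bathymetry = bathymetry, community = community,
                 nodules = nodules, survey = survey, sediment = sediment,
                 hard_substrata_ha = hard_substrata_ha,
                 n_perm = n_perm, effort_reps = effort_reps,
                 nmds_restarts = nmds_restarts),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] (seed, permutation counts, densities,
#' survey numbers...) can be overridden from a YAML file; list-valued specs
#' are rebuilt from the corresponding keys.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  for (f in c("n_perm", "effort_reps", "nmds_restarts")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$survey)) args$survey <- do.call(survey_spec, y$survey)
  if (!is.null(y$community)) {
    args$community <- do.call(community_spec, y$community)
  }
  if (!is.null(y$nodules)) {
    args$nodules <- lapply(y$nodules, function(n) {
      do.call(nodule_field_spec, n)
    })
  }
  if (!is.null(y$areas)) args$areas <- lapply(y$areas, unlist)
  do.call(run_config, args)
}

#' Run the full survey-simulation and analysis pipeline
#'
#' Orchestrates every stage on one configuration: synthetic bathymetry and
#' terrain classification; nodule fields; community model; simulated
#' zig-zag surveys; unit standardization; environmental metrics (nodule
#' cover, sediment grain size, carbonate, C:N); per-unit community metrics
#' with permutation group comparisons; Bray-Curtis composition analyses
#' (nMDS, PERMANOVA with pairwise tests, SIMPER, Spearman correlations);
#' and the sampling-unit-size evaluation. Deterministic under the config
#' seed. Every result table carries the seed, the config hash and the
#' package version as provenance attributes.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, tables are written as CSV
#'   and grids as ESRI ASCII.
#' @param effort Run the (relatively expensive) effort-evaluation stage
#'   (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result` with elements `bathy`,
#'   `terrain`, `community`, `survey_raw` (image geometry only),
#'   `survey` (standardized + populated), `unit_summary`, `env`,
#'   `abundance`, `metrics`, `group_tests`, `multivar`, `effort`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         effort = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  prov <- list(seed = seed, config_hash = config_hash(config),
               version = as.character(utils::packageVersion("benthosurvey")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("stage synth: bathymetry, nodule fields, community")
  bathy <- terrain <- NULL
  if (!is.null(config$bathymetry)) {
    bathy <- stage("bathymetry", do.call(generate_bathymetry,
      c(config$bathymetry, list(seed = child_seed(seed, 2)))))
    terrain <- stage("terrain", terrain_maps(bathy))
  }
  nodule_fields <- stage("nodules", {
    nf <- lapply(names(config$areas), function(a) {
      generate_nodule_field(config$nodules[[a]], config$areas[[a]],
                            seed = child_seed(seed, 10 + match(a, names(config$areas))))
    })
    names(nf) <- names(config$areas)
    nf
  })
  community <- stage("community",
                     generate_community(config$community,
                                        seed = child_seed(seed, 3)))

  say("stage survey: simulation and standardization")
  survey_raw <- stage("survey", simulate_survey(
    areas = config$areas, survey = config$survey, community = community,
    nodule_fields = nodule_fields, bathy = bathy, populate = FALSE,
    seed = child_seed(seed, 4)))
  std <- stage("standardize", standardize_units(
    survey_raw, seed = child_seed(seed, 5)))
  std <- stage("populate", populate_images(std, seed = child_seed(seed, 6)))
  # hard substrata: sparse Poisson marks per image
  std$images$hard_substrata <- stage("hard-substrata", with_seed(
    child_seed(seed, 7), {
      lam <- config$hard_substrata_ha[std$images$area] / 1e4 *
        std$images$footprint
      stats::rpois(nrow(std$images), lam)
    }))

  say("stage envmetrics")
  sed <- stage("sediment", do.call(generate_sediment,
    c(config$sediment, list(seed = child_seed(seed, 8)))))
  bounds <- attr(sed, "bounds_um")
  fcols <- grep("^f_", names(sed))
  grain <- do.call(rbind, lapply(seq_len(nrow(sed)), function(i) {
    g <- grain_stats(bounds, as.numeric(sed[i, fcols]))
    data.frame(area = sed$area[i], sample = sed$sample[i],
               gm_size_um = g$gm_size_um, mud_pct = g$mud_pct)
  }))
  chem <- cbind(sed[, c("area", "sample")],
                carbonate_cn(sed$tc, sed$toc, sed$tn))
  nod <- stage("nodule-cover", nodule_cover(std))
  nod$units$area <- std$unit_table$area[match(nod$units$unit,
                                              std$unit_table$unit)]

  say("stage community metrics")
  abund <- stage("abundance", abundance_table(std, taxon = "metazoan"))
  abund_x <- stage("abundance-xeno",
                   abundance_table(std, taxon = "xenophyophore"))
  metrics <- stage("metrics", unit_metrics(abund))
  metrics_x <- stage("metrics-xeno", unit_metrics(abund_x))
  unit_summary <- merge(metrics, nod$units[, c("unit", "cover", "total_m2",
                                               "hard_substrata_ha")],
                        by = "unit")
  unit_summary$xeno_density <- metrics_x$density[
    match(unit_summary$unit, metrics_x$unit)]

  say("stage group tests and multivariate analysis")
  groups <- metrics$area
  gt <- lapply(c("density", "biomass", "S", "expH", "invD"), function(m) {
    stage(paste0("group-", m),
          group_compare(metrics[[m]], groups, n_perm = config$n_perm,
                        seed = child_seed(seed, 20 + match(m, c(
                          "density", "biomass", "S", "expH", "invD")))))
  })
  names(gt) <- c("density", "biomass", "S", "expH", "invD")
  d <- stage("bray-curtis", bray_curtis(abund))
  mv <- list(
    dissimilarity = d,
    nmds = stage("nmds", nmds(d, restarts = config$nmds_restarts,
                              seed = child_seed(seed, 30))),
    permanova = stage("permanova",
                      permanova(d, groups, n_perm = config$n_perm,
                                seed = child_seed(seed, 31))),
    kdom = stage("kdom", k_dominance(abund)),
    rarefaction = stage("rarefaction", rarefy_richness(abund)),
    simper = NULL,
    spearman = stage("spearman", spearman_cor(
      metrics$density, unit_summary$xeno_density,
      seed = child_seed(seed, 33))))
  lv <- unique(groups)
  mv$simper <- lapply(utils::combn(lv, 2, simplify = FALSE), function(pr) {
    sel <- groups %in% pr
    stage("simper", simper(abund$counts[sel, , drop = FALSE], groups[sel],
                           areas_m2 = abund$areas_m2[sel]))
  })
  names(mv$simper) <- vapply(utils::combn(lv, 2, simplify = FALSE),
                             paste, collapse = "_", FUN.VALUE = "")

  eff <- NULL
  if (effort) {
    say("stage effort evaluation")
    eff <- lapply(unique(groups), function(a) {
      pool <- effort_pool(std, a)
      sizes <- effort_sizes(pool)
      list(
        density = resample_parameter(pool, "density", sizes,
                                     reps = config$effort_reps,
                                     seed = child_seed(seed, 40)),
        richness = resample_parameter(pool, "richness", sizes,
                                      reps = config$effort_reps,
                                      replace = FALSE,
                                      seed = child_seed(seed, 41)),
        autosimilarity = autosimilarity(pool,
                                        sizes = sizes[2 * sizes <= pool$n_images],
                                        reps = config$effort_reps,
                                        seed = child_seed(seed, 42)))
    })
    names(eff) <- unique(groups)
  }

  res <- structure(list(
    bathy = bathy, terrain = terrain, community = community,
    survey_raw = survey_raw, survey = std, unit_summary = unit_summary,
    env = list(grain = grain, chem = chem, nodules = nod$units,
               sediment = sed),
    abundance = abund, abundance_xeno = abund_x,
    metrics = metrics, metrics_xeno = metrics_x,
    group_tests = gt, multivar = mv, effort = eff,
    provenance = prov), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  prov <- res$provenance
  writeLines(yaml::as.yaml(prov), file.path(outdir, "provenance.yaml"))
  w(res$unit_summary, "unit_summary")
  w(res$metrics, "unit_metrics")
  w(cbind(unit = rownames(res$abundance$counts), res$abundance$counts),
    "abundance")
  w(res$env$grain, "sediment_grain")
  w(res$env$chem, "sediment_chem")
  w(res$env$nodules, "nodule_metrics")
  w(res$multivar$kdom, "k_dominance")
  w(res$multivar$rarefaction, "rarefaction")
  w(data.frame(unit = rownames(res$multivar$nmds$points),
               res$multivar$nmds$points,
               stress = res$multivar$nmds$stress), "nmds")
  if (!is.null(res$effort)) {
    for (a in names(res$effort)) {
      for (p in names(res$effort[[a]])) {
        w(res$effort[[a]][[p]], sprintf("effort_%s_%s", a, p))
      }
    }
  }
  if (!is.null(res$bathy)) {
    write_ascii_grid(res$bathy, file.path(outdir, "bathymetry.asc"))
    write_ascii_grid(res$terrain$bpi, file.path(outdir, "bpi.asc"),
                     cell_size = res$bathy$cell_size)
    write_ascii_grid(res$terrain$tri, file.path(outdir, "tri.asc"),
                     cell_size = res$bathy$cell_size)
  }
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  cat(sprintf("  %d standardized units, %d metazoan morphospecies, %d individuals\n",
              nrow(x$unit_summary), ncol(x$abundance$counts),
              sum(x$abundance$counts)))
  cat(sprintf("  PERMANOVA R2 = %.2f (p = %.3g), nMDS stress = %.3f\n",
              x$multivar$permanova$R2, x$multivar$permanova$p,
              x$multivar$nmds$stress))
  invisible(x)
}

#' Permutation one-way comparison of a unit-level metric
#'
#' Distribution-free replacement for per-metric GLM fitting: the one-way
#' F statistic on the unit values is referred to its permutation
#' distribution under free relabelling, and pairwise mean differences are
#' tested the same way with Holm adjustment. With few units per group and
#' small group counts the complete relabelling enumeration is used, giving
#' exact p-values.
#'
#' @param values Numeric metric per unit.
#' @param groups Group label per unit; >= 2 groups of >= 2.
#' @param n_perm Permutations (default 9999).
#' @param seed Integer seed.
#' @return List of class `group_test`: `F`, `p`, `n_perm`, `exact`,
#'   `pairwise` data frame (`group1`, `group2`, `diff`, `p`, `p_adj`),
#'   `means`.
#' @export
group_compare <- function(values, groups, n_perm = 9999, seed = NULL) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with n >= 2 each", call. = FALSE)
  }
  fstat <- function(v, g) {
    m <- tapply(v, g, mean)
    n <- tapply(v, g, length)
    ssa <- sum(n * (m - mean(v))^2)
    ssw <- sum((v - m[g])^2)
    dfa <- length(m) - 1
    dfw <- length(v) - length(m)
    (ssa / dfa) / (ssw / dfw)
  }
  obs <- fstat(values, groups)
  n_arr <- exp(lgamma(length(groups) + 1) - sum(lgamma(tab + 1)))
  exact <- is.finite(n_arr) && n_arr <= n_perm
  tol <- 1e-12
  if (exact) {
    Fs <- vapply(label_arrangements(groups), function(g) fstat(values, g),
                 numeric(1))
    p <- sum(Fs >= obs - tol) / length(Fs)
  } else {
    p <- with_seed(seed, {
      Fs <- vapply(seq_len(n_perm), function(i) {
        fstat(values, sample(groups))
      }, numeric(1))
      (1 + sum(Fs >= obs - tol)) / (1 + n_perm)
    })
  }
  prs <- utils::combn(names(tab), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(seq_along(prs), function(k) {
    sel <- groups %in% prs[[k]]
    v <- values[sel]; g <- groups[sel]
    dobs <- abs(diff(tapply(v, g, mean)))
    n_arr2 <- choose(length(v), sum(g == prs[[k]][1]))
    if (n_arr2 <= n_perm) {
      ds <- vapply(label_arrangements(g), function(gg) {
        abs(diff(tapply(v, gg, mean)))
      }, numeric(1))
      pk <- sum(ds >= dobs - tol) / length(ds)
    } else {
      pk <- with_seed(child_seed(seed, k), {
        ds <- vapply(seq_len(n_perm), function(i) {
          abs(diff(tapply(v, sample(g), mean)))
        }, numeric(1))
        (1 + sum(ds >= dobs - tol)) / (1 + n_perm)
      })
    }
    data.frame(group1 = prs[[k]][1], group2 = prs[[k]][2],
               diff = unname(diff(tapply(v, g, mean))), p = pk,
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, "holm")
  structure(list(F = obs, p = p, n_perm = n_perm, exact = exact,
                 pairwise = pw, means = tapply(values, groups, mean)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("permutation one-way test: F = %.3f, p = %.4g%s\n",
              x$F, x$p, if (x$exact) " (exact)" else ""))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
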