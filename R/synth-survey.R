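#' Specification of an AUV photo-transect survey
#'
#' Defaults describe the survey design this package emulates: zig-zag tracks
#' of 40 straight-line sampling units per study area, a 3 m target altitude
#' at which one vertical photograph images 1.71 m^2 of seabed, photographs
#' about one metre apart along-track, an altitude acceptance window of
#' 2--4 m, discard of every second image (overlap control) and of images at
#' track junctions, standardization of each analysed unit to c. 1320 m^2
#' (accepted range 1321--1324 m^2), and random selection of 4 replicate
#' units per area.
#'
#' @param units_per_area Straight-line sampling units surveyed per area.
#' @param replicates_per_area Units randomly selected for analysis.
#' @param unit_length Length of one straight-line unit (m).
#' @param image_spacing Along-track image spacing (m); the default is the
#'   1.2 m s^-1 cruise speed times the 0.85 s photographic interval.
#' @param target_altitude Programmed altitude (m).
#' @param altitude_sd Standard deviation of altitude noise (m); altitudes
#'   are truncated-normal within `altitude_limits`.
#' @param altitude_limits Physical altitude range the vehicle actually
#'   flies (m); wider than the acceptance window.
#' @param altitude_window Acceptance window (m); images outside are
#'   discarded during standardization.
#' @param footprint_at_target Image footprint (m^2) at the target altitude;
#'   footprints scale with altitude squared.
#' @param discard_every_second Discard alternate images to avoid overlap.
#' @param junction_buffer Images within this along-track distance (m) of a
#'   unit's endpoints are treated as junction images and discarded.
#' @param unit_area_range Accepted standardized unit area interval (m^2).
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(units_per_area = 40, replicates_per_area = 4,
                        unit_length = 1700, image_spacing = 1.02,
                        target_altitude = 3, altitude_sd = 0.4,
                        altitude_limits = c(1.5, 4.5),
                        altitude_window = c(2, 4),
                        footprint_at_target = 1.71,
                        discard_every_second = TRUE,
                        junction_buffer = 10,
                        unit_area_range = c(1321, 1324)) {
  if (units_per_area < replicates_per_area) {
    stop("'units_per_area' must be >= 'replicates_per_area'", call. = FALSE)
  }
  if (any(altitude_window <= 0) || altitude_window[1] >= altitude_window[2]) {
    stop("'altitude_window' must be a positive increasing interval",
         call. = FALSE)
  }
  if (unit_area_range[1] >= unit_area_range[2]) {
    stop("'unit_area_range' must be increasing", call. = FALSE)
  }
  structure(list(
    units_per_area = as.integer(units_per_area),
    replicates_per_area = as.integer(replicates_per_area),
    unit_length = unit_length, image_spacing = image_spacing,
    target_altitude = target_altitude, altitude_sd = altitude_sd,
    altitude_limits = altitude_limits, altitude_window = altitude_window,
    footprint_at_target = footprint_at_target,
    discard_every_second = discard_every_second,
    junction_buffer = junction_buffer,
    unit_area_range = unit_area_range), class = "survey_spec")
}

#' Default study-area rectangles
#'
#' Three 8 x 2 km rectangles, one per landscape type, laid out side by side.
#' Any named list of `c(xmin, xmax, ymin, ymax)` rectangles can be supplied
#' instead, e.g. drawn around [classify_landscape()] output.
#'
#' @return Named list of extent vectors (m).
#' @export
default_area_polygons <- function() {
  list(Flat   = c(0, 8000, 0, 2000),
       Ridge  = c(0, 8000, 3000, 5000),
       Trough = c(0, 8000, 6000, 8000))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Zig-zag track for one area: segment vertices alternating between two
# east-west lines, random start easting and phase.
zigzag_track <- function(area, n_units, unit_length, margin = 50) {
  w <- area[2] - area[1]
  h <- area[4] - area[3]
  v <- min(h - 2 * margin, 0.995 * unit_length)
  if (v <= 0) stop("area too small for the requested track", call. = FALSE)
  dx <- sqrt(unit_length^2 - v^2)
  span <- n_units * dx
  if (span > w - 2 * margin) {
    stop(sprintf(
      "area too small for requested track length: need %.0f m easting, have %.0f m",
      span + 2 * margin, w), call. = FALSE)
  }
  x0 <- area[1] + margin + stats::runif(1, 0, w - 2 * margin - span)
  ylo <- area[3] + margin
  up_first <- stats::runif(1) < 0.5
  verts_x <- x0 + dx * (0:n_units)
  verts_y <- ylo + v * ((seq_len(n_units + 1L) + up_first) %% 2L)
  list(x = verts_x, y = verts_y)
}

#' Simulate AUV photo-transect surveys
#'
#' Lays zig-zag tracks of straight-line sampling units through each study
#' area, draws a noisy altitude for every photograph, tags photographs with
#' their altitude-dependent footprint (`footprint = footprint_at_target *
#' (altitude / target)^2`), and optionally populates each image with nodule
#' areas and specimen records from the supplied generators. Deterministic
#' under a fixed seed.
#'
#' @param areas Named list of area rectangles (see
#'   [default_area_polygons()]).
#' @param survey A [survey_spec()].
#' @param community A `community_model`, or `NULL` to skip specimens.
#' @param nodule_fields Named list of `nodule_field` objects (one per area),
#'   a single [nodule_field_spec()] applied to every area, or `NULL`.
#' @param bathy Optional [bathy_grid()]; if given, each image records the
#'   seafloor depth under it.
#' @param populate Populate images with specimens and nodules now
#'   (default). With `FALSE` only image geometry is generated; call
#'   [populate_images()] later (typically after [standardize_units()], so
#'   only analysed images are annotated).
#' @param seed Integer seed.
#' @return An object of class `survey_sim`: list with `images`, `specimens`,
#'   `nodules` data frames plus `survey`, `areas`, `community`,
#'   `nodule_fields`.
#' @export
simulate_survey <- function(areas = default_area_polygons(),
                            survey = survey_spec(),
                            community = NULL, nodule_fields = NULL,
                            bathy = NULL, populate = TRUE, seed = NULL) {
  stopifnot(inherits(survey, "survey_spec"))
  if (inherits(nodule_fields, "nodule_field_spec")) {
    spec <- nodule_fields
    nodule_fields <- lapply(seq_along(areas), function(i) {
      generate_nodule_field(spec, areas[[i]], seed = child_seed(seed, 100 + i))
    })
    names(nodule_fields) <- names(areas)
  }
  images <- with_seed(seed, {
    do.call(rbind, lapply(names(areas), function(a) {
      trk <- zigzag_track(areas[[a]], survey$units_per_area,
                          survey$unit_length)
      n_per <- floor(survey$unit_length / survey$image_spacing) + 1L
      do.call(rbind, lapply(seq_len(survey$units_per_area), function(u) {
        f <- (seq_len(n_per) - 1L) * survey$image_spacing
        t <- f / survey$unit_length
        x <- trk$x[u] + t * (trk$x[u + 1L] - trk$x[u])
        y <- trk$y[u] + t * (trk$y[u + 1L] - trk$y[u])
        alt <- rtruncnorm1(n_per, survey$target_altitude, survey$altitude_sd,
                           survey$altitude_limits[1], survey$altitude_limits[2])
        junc <- f < survey$junction_buffer |
          f > survey$unit_length - survey$junction_buffer
        data.frame(
          area = a, unit = sprintf("%s-%02d", a, u), seq = seq_len(n_per),
          x = x, y = y, altitude = alt,
          footprint = survey$footprint_at_target *
            (alt / survey$target_altitude)^2,
          junction = junc, stringsAsFactors = FALSE)
      }))
    }))
  })
  images$image_id <- paste0(images$unit, "-", images$seq)
  if (!is.null(bathy)) {
    d <- dim(bathy$depths)
    ci <- pmin(d[2], pmax(1L, ceiling((images$x - bathy$origin_x) /
                                        bathy$cell_size)))
    ri <- pmin(d[1], pmax(1L, ceiling(
      (d[1] * bathy$cell_size - (images$y - bathy$origin_y)) /
        bathy$cell_size)))
    images$depth <- bathy$depths[cbind(ri, ci)]
  }
  sim <- structure(list(images = images, specimens = empty_specimens(),
                        nodules = data.frame(image_id = character(),
                                             area_cm2 = numeric()),
                        survey = survey, areas = areas,
                        community = community,
                        nodule_fields = nodule_fields,
                        populated = FALSE),
                   class = "survey_sim")
  if (populate) sim <- populate_images(sim, seed = child_seed(seed, 1))
  sim
}

#' Populate survey images with specimens and nodules
#'
#' Attaches specimen records (from the community model) and per-nodule areas
#' (from the nodule fields) to the images of a simulated survey. Usually
#' called implicitly by [simulate_survey()]; calling it after
#' [standardize_units()] annotates only the retained images, which is how
#' the full-design pipeline avoids annotating discarded photographs.
#'
#' @param sim A `survey_sim`.
#' @param community,nodule_fields Override the generators stored in `sim`.
#' @param seed Integer seed.
#' @return `sim` with `specimens` and `nodules` filled in.
#' @export
populate_images <- function(sim, community = NULL, nodule_fields = NULL,
                            seed = NULL) {
  stopifnot(inherits(sim, "survey_sim"))
  community <- community %||% sim$community
  nodule_fields <- nodule_fields %||% sim$nodule_fields
  img <- sim$images
  specimens <- empty_specimens()
  nodules <- data.frame(image_id = character(), area_cm2 = numeric())
  with_seed(seed, {
    for (a in unique(img$area)) {
      sel <- img$area == a
      if (!is.null(community)) {
        sp <- sample_images(community, a, img$footprint[sel],
                            image_id = img$image_id[sel])
        specimens <- rbind(specimens, sp)
      }
      nf <- nodule_fields[[a]]
      if (!is.null(nf)) {
        ii <- which(sel)
        nod <- lapply(ii, function(i) {
          nf$sample_nodules(img$footprint[i], img$x[i], img$y[i])
        })
        n_per <- lengths(nod)
        if (sum(n_per) > 0) {
          nodules <- rbind(nodules, data.frame(
            image_id = rep(img$image_id[ii], n_per),
            area_cm2 = unlist(nod)))
        }
      }
    }
  })
  sim$specimens <- specimens
  sim$nodules <- nodules
  sim$community <- community
  sim$nodule_fields <- nodule_fields
  sim$populated <- TRUE
  sim
}

#' @export
print.survey_sim <- function(x, ...) {
  cat(sprintf("survey_sim: %d images in %d units across %d areas%s\n",
              nrow(x$images), length(unique(x$images$unit)),
              length(unique(x$images$area)),
              if (isTRUE(x$standardized)) " (standardized)" else ""))
  if (nrow(x$specimens)) {
    cat(sprintf("  %d specimen records, %d nodules\n",
                nrow(x$specimens), nrow(x$nodules)))
  }
  invisible(x)
}

#' Standardize sampling units to a fixed analysed seabed area
#'
#' Applies the image-selection chain that turns raw photo-transect units
#' into replicate observation units: junction images are removed, every
#' second image is removed (overlap control), images outside the altitude
#' acceptance window are removed, the remaining images are randomly
#' permuted and the shortest prefix whose summed footprint first enters the
#' accepted interval (default 1321--1324 m^2) is retained, and finally the
#' requested number of replicate units is randomly selected per area. Units
#' that cannot reach the interval are excluded with a warning.
#'
#' @param sim A `survey_sim` from [simulate_survey()].
#' @param survey Override the stored [survey_spec()].
#' @param select_replicates Randomly select `replicates_per_area` units per
#'   area (default). With `FALSE` all standardizable units are kept.
#' @param seed Integer seed controlling both the subsampling and the unit
#'   selection.
#' @return A `survey_sim` restricted to the retained images, with
#'   `standardized = TRUE`, a `unit_table` data frame (unit, area, images
#'   retained, analysed m^2), and specimen/nodule tables subset to the
#'   retained images (when already populated).
#' @export
standardize_units <- function(sim, survey = NULL, select_replicates = TRUE,
                              seed = NULL) {
  stopifnot(inherits(sim, "survey_sim"))
  survey <- survey %||% sim$survey
  rng <- survey$unit_area_range
  img <- sim$images
  with_seed(seed, {
    keep_ids <- character(0)
    rows <- list()
    for (u in unique(img$unit)) {
      ui <- img[img$unit == u, , drop = FALSE]
      ui <- ui[order(ui$seq), , drop = FALSE]
      ui <- ui[!ui$junction, , drop = FALSE]
      if (survey$discard_every_second && nrow(ui) > 0) {
        ui <- ui[seq(1L, nrow(ui), by = 2L), , drop = FALSE]
      }
      ui <- ui[ui$altitude >= survey$altitude_window[1] &
                 ui$altitude <= survey$altitude_window[2], , drop = FALSE]
      sel <- NULL
      if (nrow(ui) > 0 && sum(ui$footprint) >= rng[1]) {
        for (try in 1:25) {   # rare overshoot past the upper bound: re-draw
          perm <- sample.int(nrow(ui))
          cs <- cumsum(ui$footprint[perm])
          k <- which(cs >= rng[1])[1]
          if (!is.na(k) && cs[k] <= rng[2]) {
            sel <- ui[perm[seq_len(k)], , drop = FALSE]
            break
          }
        }
      }
      if (is.null(sel)) {
        warning(sprintf(
          "unit %s cannot be standardized to [%g, %g] m^2; excluded",
          u, rng[1], rng[2]), call. = FALSE)
        next
      }
      keep_ids <- c(keep_ids, sel$image_id)
      rows[[u]] <- data.frame(unit = u, area = sel$area[1],
                              n_images = nrow(sel),
                              area_m2 = sum(sel$footprint),
                              stringsAsFactors = FALSE)
    }
    unit_table <- do.call(rbind, rows)
    if (is.null(unit_table)) {
      stop("no unit could be standardized to the target area window",
           call. = FALSE)
    }
    rownames(unit_table) <- NULL
    if (select_replicates) {
      sel_units <- unlist(lapply(split(unit_table$unit, unit_table$area),
                                 function(us) {
        if (length(us) < survey$replicates_per_area) {
          stop("fewer standardizable units than replicates requested",
               call. = FALSE)
        }
        sample(us, survey$replicates_per_area)
      }))
      unit_table <- unit_table[unit_table$unit %in% sel_units, , drop = FALSE]
      keep_ids <- keep_ids[img$unit[match(keep_ids, img$image_id)] %in%
                             sel_units]
    }
    out <- sim
    out$images <- img[match(keep_ids, img$image_id), , drop = FALSE]
    rownames(out$images) <- NULL
    out$unit_table <- unit_table[order(unit_table$unit), , drop = FALSE]
    if (nrow(sim$specimens)) {
      out$specimens <- sim$specimens[sim$specimens$image_id %in% keep_ids, ,
                                     drop = FALSE]
    }
    if (nrow(sim$nodules)) {
      out$nodules <- sim$nodules[sim$nodules$image_id %in% keep_ids, ,
                                 drop = FALSE]
    }
    out$standardized <- TRUE
    out
  })
}

#' Build a units-by-morphospecies abundance table
#'
#' Aggregates specimen records of a (typically standardized) survey into the
#' count matrix that feeds all diversity and multivariate analyses.
#'
#' @param sim A populated `survey_sim`.
#' @param taxon `"metazoan"` (default), `"xenophyophore"`, or `"both"`
#'   (the joint mode used to examine the influence of xenophyophore tests).
#' @param drop_empty Drop morphospecies with zero total count.
#' @return An object of class `abundance_table`: `counts` (units x species
#'   integer matrix), `areas_m2` (named analysed area per unit), `units`
#'   (unit metadata incl. area/group), `species` (metadata for retained
#'   species), `specimens` (the contributing specimen records).
#' @export
abundance_table <- function(sim, taxon = c("metazoan", "xenophyophore",
                                           "both"),
                            drop_empty = TRUE) {
  taxon <- match.arg(taxon)
  stopifnot(inherits(sim, "survey_sim"))
  if (!nrow(sim$specimens)) stop("survey has no specimen records",
                                 call. = FALSE)
  if (is.null(sim$unit_table)) stop("standardize the survey first",
                                    call. = FALSE)
  sp <- sim$specimens
  if (taxon != "both") sp <- sp[sp$taxon == taxon, , drop = FALSE]
  sp$unit <- sim$images$unit[match(sp$image_id, sim$images$image_id)]
  units <- sim$unit_table
  counts <- table(factor(sp$unit, levels = units$unit), sp$msp)
  counts <- matrix(as.integer(counts), nrow = nrow(units),
                   dimnames = list(units$unit, colnames(counts)))
  if (drop_empty && ncol(counts)) {
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
  }
  meta <- if (!is.null(sim$community)) {
    sim$community$species[match(colnames(counts), sim$community$species$msp), ]
  } else {
    unique(sp[, c("msp", "taxon", "group", "guild", "habit")])[
      match(colnames(counts),
            unique(sp[, c("msp", "taxon", "group", "guild", "habit")]$msp)), ]
  }
  structure(list(counts = counts,
                 areas_m2 = stats::setNames(units$area_m2, units$unit),
                 units = units, species = meta, specimens = sp),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d units x %d morphospecies, %d individuals\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
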