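## End-to-end workbench: wires the analysis stages together from a single
## declarative config, writes TSV/JSON artifacts and a reproducible run
## manifest. All randomness is funneled through the single seed in the
## config, so identical configs reproduce identical artifacts.

.known_config_keys <- c("seed", "output_dir", "stages", "trajectory",
                        "contacts", "events", "geometry", "saltbridges",
                        "conserve", "tevc")

#' Default pipeline configuration
#'
#' A complete demo configuration: simulate a pocket trajectory and a set
#' of voltage-clamp recordings, then run every analysis stage on them
#' plus conservation on the bundled synthetic family alignment.
#'
#' @param output_dir artifact directory.
#' @param seed run seed.
#' @param n_frames trajectory length for the simulated input.
#' @return nested config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(output_dir = tempfile("ionsite_run"),
                               seed = 1L, n_frames = 2000L) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    stages = c("contacts", "events", "geometry", "saltbridges",
               "conserve", "tevc"),
    trajectory = list(simulate = TRUE, n_frames = as.integer(n_frames)),
    contacts = list(cutoff = 4.0, counting = "ion_frame_pairs",
                    rel_threshold = 1.0, link_cutoff = 8.0),
    events = list(debounce = 0L, dwell_statistic = "mean"),
    geometry = list(proximity = c(Na = 2.6, K = 3.0),
                    occupancy_fraction = 0.25, min_frames = 50L),
    saltbridges = list(
      list(label = "K504-D75", basic_resid = 504L, basic_name = "NZ",
           acidic_resid = 75L, acidic_names = c("OD1", "OD2")),
      list(label = "K504-D501", basic_resid = 504L, basic_name = "NZ",
           acidic_resid = 501L, acidic_names = c("OD1", "OD2"))),
    conserve = list(alignment = "synthetic",
                    positions = c(71L, 75L, 501L, 504L)),
    tevc = list(simulate = TRUE, statistic = "avg",
                normalize_to = list(solution = "Na30K1", voltage = -145),
                settle = 0.025, window = 0.025))
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (contacts, events, geometry,
#' saltbridges on the trajectory; conserve on the alignment; tevc on the
#' recordings), writing one or more TSV artifacts per stage plus a
#' `manifest.json` capturing the package version, the full parameter set,
#' input checksums and the seed. Any stage failure aborts with an error
#' naming the stage; artifacts of completed stages are retained.
#'
#' @param config nested list as produced by [default_run_config()], or
#'   the path to a YAML file holding the same structure; unknown
#'   top-level keys are rejected before any computation.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) named list of artifact paths.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[ionsite] ", ...)
  artifacts <- list()
  input_files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  traj <- NULL; site <- NULL
  needs_traj <- any(c("contacts", "events", "geometry", "saltbridges") %in%
                      config$stages)
  if (needs_traj) stage("trajectory", {
    tc <- config$trajectory
    if (isTRUE(tc$simulate)) {
      sim <- simulate_trajectory(traj_sim_config(
        n_frames = tc$n_frames %||% 2000L, seed = config$seed))
      traj <- sim$traj; site <- sim$site
    } else {
      top <- read_topology(tc$topology, tc$format %||% "auto")
      traj <- read_frames(tc$path, top, tc$format %||% "auto")
      input_files <- c(input_files, tc$topology, tc$path)
      sc <- tc$site
      site <- site_definition(sc$name, atom_selection(
        chain = sc$chain, resid = sc$resid), sc$cutoff %||% 4.0)
    }
    log("trajectory: ", n_atoms(traj), " atoms, ", n_frames(traj),
        " frames, ", length(unlist(traj$topology$ion_sets)), " ions")
    traj <- traj; site <- site
  })

  ref_xyz <- if (needs_traj) traj$coords[, , 1] else NULL

  if ("contacts" %in% config$stages) stage("contacts", {
    cc <- config$contacts
    tab <- count_contacts(traj, contact_parameters(cc$cutoff %||% 4.0,
      counting = cc$counting %||% "ion_frame_pairs"))
    tab <- combine_species(tab)
    artifacts$contacts <- .write_tsv(tab, config$output_dir,
                                      "contacts.tsv")
    sites <- identify_candidate_sites(tab, traj$topology, ref_xyz,
                                      cc$rel_threshold %||% 1.0,
                                      cc$link_cutoff %||% 8.0,
                                      box = traj$box)
    log("contacts: ", nrow(tab), " residues, ", length(sites),
        " candidate site(s)")
  })

  ev <- NULL
  if ("events" %in% config$stages) stage("events", {
    ec <- config$events
    ev <- site_events(traj, site, debounce_gap = ec$debounce %||% 0L)
    artifacts$events <- .write_tsv(ev$events, config$output_dir,
                                    "events.tsv")
    summ <- summarize_events(ev, n_frames(traj),
                             ec$dwell_statistic %||% "mean")
    artifacts$event_summary <- .write_tsv(summ, config$output_dir,
                                           "event_summary.tsv")
    log("events: ", nrow(ev$events), " approaches over ",
        length(ev$masks), " ions")
  })

  if ("geometry" %in% config$stages) stage("geometry", {
    gc <- config$geometry
    if (is.null(ev)) ev <- site_events(traj, site)
    rows <- list()
    for (sp in unique(unname(ev$species_of))) {
      ions <- as.integer(names(ev$species_of)[ev$species_of == sp])
      prox <- (gc$proximity %||% c(Na = 2.6, K = 3.0))[[sp]]
      # the species' most site-active ion gets the full geometry workup
      occ <- vapply(as.character(ions), function(i) sum(ev$masks[[i]]), 0L)
      ion <- ions[which.max(occ)]
      oxy <- atom_selection(chain = "A", name = c("O", "OD1", "OD2", "NZ"))
      ser <- distance_series(traj, ion, oxy)
      st <- in_site_stats(ser, ev$masks[[as.character(ion)]],
                          proximity = prox)
      if (!is.null(st)) {
        call <- coordination_call(st, sp,
          proximity = gc$proximity %||% c(Na = 2.6, K = 3.0),
          occupancy_fraction = gc$occupancy_fraction %||% 0.25,
          min_frames = gc$min_frames %||% 50L)
        st$species <- sp
        st$is_coordinating <- if (!is.null(call)) call$is_coordinating
                              else NA
        rows[[sp]] <- st
      }
    }
    geom <- do.call(rbind, rows)
    if (!is.null(geom))
      artifacts$geometry <- .write_tsv(geom, config$output_dir,
                                        "geometry.tsv")
    log("geometry: ", if (is.null(geom)) 0L else nrow(geom),
        " atom/species calls")
  })

  if ("saltbridges" %in% config$stages) stage("saltbridges", {
    rows <- lapply(config$saltbridges, function(sb) {
      pair <- salt_bridge_pair(
        atom_selection(resid = sb$basic_resid, name = sb$basic_name),
        atom_selection(resid = sb$acidic_resid, name = sb$acidic_names),
        sb$label)
      st <- bridge_stats(bridge_series(traj, pair))
      data.frame(label = st$label, occupancy_formed = st$occupancy_formed,
                 occupancy_possible = st$occupancy_possible,
                 median_min = st$median_min,
                 q1 = st$fivenum_min[2], q3 = st$fivenum_min[4])
    })
    artifacts$saltbridges <- .write_tsv(do.call(rbind, rows),
                                         config$output_dir,
                                         "saltbridges.tsv")
    log("saltbridges: ", length(rows), " pair(s)")
  })

  if ("conserve" %in% config$stages) stage("conserve", {
    cv <- config$conserve
    aln <- if (identical(cv$alignment, "synthetic"))
      synthetic_hkt_alignment()
    else {
      input_files <- c(input_files, cv$alignment)
      read_alignment(cv$alignment, cv$ref_name)
    }
    prof <- conservation_profile(aln, cv$positions)
    artifacts$conservation <- .write_tsv(prof, config$output_dir,
                                          "conservation.tsv")
    log("conserve: ", length(aln$seqs), " sequences, ",
        nrow(prof), " positions")
  })

  if ("tevc" %in% config$stages) stage("tevc", {
    tv <- config$tevc
    recs <- if (isTRUE(tv$simulate)) {
      simulate_recording(tevc_sim_config(seed = config$seed))$recordings
    } else {
      input_files <- c(input_files, unlist(tv$manifests))
      lapply(tv$manifests, read_recording)
    }
    iv <- build_iv(recs, tv$statistic %||% "avg",
                   tv$normalize_to %||% list(solution = "Na30K1",
                                             voltage = -145),
                   settle = tv$settle %||% 0.025,
                   window = tv$window %||% 0.025)
    artifacts$iv <- .write_tsv(iv, config$output_dir, "iv.tsv")
    deact <- do.call(rbind, lapply(recs, function(r)
      cbind(solution = r$solution,
            deactivation_stats(r, tv$settle %||% 0.025,
                               tv$window %||% 0.025))))
    artifacts$deactivation <- .write_tsv(deact, config$output_dir,
                                          "deactivation.tsv")
    vrev <- do.call(rbind, lapply(split(iv, iv$solution), function(g)
      data.frame(solution = g$solution[1],
                 vrev = suppressWarnings(
                   estimate_vrev(g$voltage, g$current)))))
    artifacts$vrev <- .write_tsv(vrev, config$output_dir, "vrev.tsv")
    log("tevc: ", length(recs), " recordings, ",
        sum(!is.na(vrev$vrev)), " reversal potentials")
  })

  manifest <- list(
    tool = "ionsite",
    version = as.character(utils::packageVersion("ionsite")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "output_dir")],
    input_checksums = as.list(tools::md5sum(input_files)),
    artifacts = lapply(artifacts, basename))
  mpath <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts$manifest <- mpath
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
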