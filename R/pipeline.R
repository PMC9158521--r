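#' Read a species configuration file
#'
#' YAML file assigning each species its life form, spring event and chilling
#' model, e.g.:
#'
#' ```yaml
#' species:
#'   - name: Jasminum nudiflorum
#'     life_form: shrub
#'     event: FFD
#'     chill_model: {kind: threshold, T1: 5}
#' ```
#'
#' The package ships a 14-species temperate panel (Beijing deciduous shrubs
#' and trees) as `system.file("extdata", "species_beijing.yaml", package =
#' "chillforce")`.
#'
#' @param path YAML file path.
#' @return A named list, one entry per species: `list(name, life_form,
#'   event, model)` with `model` a [chill_model].
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) stop("config has no 'species' list", call. = FALSE)
  out <- lapply(cfg$species, function(s) {
    cm <- s$chill_model
    model <- chill_model(kind = cm$kind, T1 = cm$T1, T2 = cm$T2, T3 = cm$T3,
                         Top = cm$Top,
                         half_width = if (is.null(cm$half_width)) 7
                                      else cm$half_width)
    list(name = s$name, life_form = s$life_form, event = s$event,
         model = model)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Run the full chilling-forcing analysis pipeline
#'
#' Orchestrates every stage in dependency order: ingest daily weather,
#' species configuration and twig-experiment records; compute (CA, FR)
#' points and fit the exponential curve per species; derive chilling
#' sensitivity and basic FR on the reference winter; simulate annual onsets
#' over the whole climate series with the chilling/forcing decomposition;
#' and compute trends, trait correlations and life-form comparisons. All
#' outputs are CSV files in `out_dir` plus a `manifest.json` recording the
#' configuration and output checksums; a rerun with the same inputs is
#' bit-identical.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `weather`: path to a daily weather CSV (`date,tmin,tmax`),
#'   * `experiment`: path to a twig-experiment CSV
#'     (`species,sample_date,twig_id,onset_date,season`),
#'   * `species`: path to a species-configuration YAML,
#'   * `out_dir`: output directory,
#'   * optional `reference_period` (default `c(1961, 1990)`), `Tb` (5),
#'     `trough_hour` (3), `reference_winter_year` (first calendar year of
#'     the winter used for lowc/highc; default the experiment's first
#'     season).
#' @return Invisibly, a list with the in-memory stage results (`points`,
#'   `fits`, `sensitivity`, `annual`, `trends`, `correlations`,
#'   `group_tests`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("weather", "experiment", "species", "out_dir"))
    if (is.null(config[[f]])) stop("config missing '", f, "'", call. = FALSE)
  ref_period <- if (is.null(config$reference_period)) c(1961, 1990)
                else as.integer(config$reference_period)
  Tb <- if (is.null(config$Tb)) 5 else config$Tb
  trough_hour <- if (is.null(config$trough_hour)) 3 else config$trough_hour
  for (p in c("weather", "experiment", "species"))
    if (!file.exists(config[[p]]))
      stop("input file not found: ", config[[p]], call. = FALSE)

  daily <- read_daily_weather(config$weather, label = "observed")
  species_cfg <- read_species_config(config$species)
  samples <- read_experiment(config$experiment)

  # validate the reference period against the climate span before any compute
  y_span <- range(year_of(daily$date))
  ref_years <- ref_period[1]:ref_period[2]
  if (as.Date(sprintf("%d-11-01", min(ref_years) - 1L)) < min(daily$date) ||
      as.Date(sprintf("%d-07-31", max(ref_years))) > max(daily$date))
    stop("reference period ", ref_period[1], "-", ref_period[2],
         " not covered by the weather series (", y_span[1], "-", y_span[2],
         ")", call. = FALSE)

  hourly <- hourly_from_daily(daily, trough_hour = trough_hour)
  chamber <- chamber_profile()

  sp_names <- unique(vapply(samples, `[[`, character(1), "species"))
  missing_cfg <- setdiff(sp_names, names(species_cfg))
  if (length(missing_cfg))
    stop("species without configuration: ",
         paste(missing_cfg, collapse = ", "), call. = FALSE)

  message("stage fit: ", length(sp_names), " species, ",
          length(samples), " samples")
  points <- do.call(rbind, lapply(sp_names, function(sp) {
    s <- samples[vapply(samples, `[[`, character(1), "species") == sp]
    samples_to_points(s, hourly, chamber, species_cfg[[sp]]$model, Tb = Tb)
  }))
  fits <- lapply(stats::setNames(sp_names, sp_names), function(sp)
    fit_ca_fr(points[points$species == sp, ]))
  fits_df <- do.call(rbind, lapply(sp_names, function(sp) {
    f <- fits[[sp]]
    data.frame(species = sp, a = f$a, b = f$b, c = f$c, r2 = f$r2,
               n_points = f$n_points)
  }))

  message("stage sensitivity")
  ref_winter_year <- if (!is.null(config$reference_winter_year))
    as.integer(config$reference_winter_year)
  else year_of(season_start(min(points$sample_date)))
  sens <- do.call(rbind, lapply(sp_names, function(sp) {
    wc <- window_chill(hourly, species_cfg[[sp]]$model,
                       t0 = as.Date(sprintf("%d-11-01", ref_winter_year)),
                       t_low = as.Date(sprintf("%d-12-21", ref_winter_year)),
                       t_high = as.Date(sprintf("%d-02-28",
                                                ref_winter_year + 1L)))
    chilling_sensitivity(fits[[sp]], wc["lowc"], wc["highc"], species = sp)
  }))
  sens$life_form <- vapply(sens$species,
                           function(sp) species_cfg[[sp]]$life_form,
                           character(1))

  message("stage simulate: years ", y_span[1] + 1, "-", y_span[2])
  species_fits <- lapply(sp_names, function(sp)
    list(species = sp, fit = fits[[sp]], model = species_cfg[[sp]]$model))
  annual <- run_scenario(daily, species_fits, ref_years = ref_years,
                         Tb = Tb, trough_hour = trough_hour)
  n_flagged <- sum(annual$flag != "ok")
  if (n_flagged)
    warning(n_flagged, " species-years had no onset within the search window",
            call. = FALSE)

  message("stage trends")
  trends <- do.call(rbind, lapply(sp_names, function(sp) {
    a <- annual[annual$species == sp & annual$flag == "ok", ]
    data.frame(species = sp,
               onset_trend = linear_trend(a$year, a$P)$slope_per_decade,
               onset_p = linear_trend(a$year, a$P)$p_value,
               C_trend = linear_trend(a$year, a$C)$slope_per_decade,
               F_trend = linear_trend(a$year, a$F)$slope_per_decade)
  }))
  traits <- data.frame(species = sens$species, cs = sens$cs,
                       basic_fr = sens$fr_high)
  correlations <- if (nrow(traits) >= 4)
    trait_correlations(trends[c("species", "onset_trend", "C_trend",
                                "F_trend")], traits)
  else NULL
  group_tests <- NULL
  if (all(table(sens$life_form) >= 2) &&
      length(unique(sens$life_form)) == 2) {
    gt_cs <- group_compare(sens$cs, sens$life_form)
    gt_fr <- group_compare(sens$fr_high, sens$life_form)
    group_tests <- data.frame(
      trait = c("cs", "basic_fr"),
      t = c(gt_cs$t, gt_fr$t),
      p_value = c(gt_cs$p_value, gt_fr$p_value),
      mean_shrub = c(gt_cs$group_means["shrub"],
                     gt_fr$group_means["shrub"]),
      mean_tree = c(gt_cs$group_means["tree"], gt_fr$group_means["tree"]))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(name) file.path(config$out_dir, name)
  wr <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, out_file(name), row.names = FALSE)
  }
  points_out <- points
  points_out$sample_date <- format(points_out$sample_date)
  wr(points_out, "points.csv")
  wr(fits_df, "fits.csv")
  wr(sens, "sensitivity.csv")
  wr(annual, "annual.csv")
  wr(trends, "trends.csv")
  wr(correlations, "correlations.csv")
  wr(group_tests, "group_tests.csv")

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  writeLines(cfg_json, out_file("config.json"))
  outputs <- list.files(config$out_dir, pattern = "\\.csv$")
  manifest <- list(
    config_md5 = unname(tools::md5sum(out_file("config.json"))),
    package_version = as.character(utils::packageVersion("chillforce")),
    reference_period = ref_period,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, outputs))), outputs)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             out_file("manifest.json"))

  invisible(list(points = points, fits = fits, sensitivity = sens,
                 annual = annual, trends = trends,
                 correlations = correlations, group_tests = group_tests,
                 manifest = manifest))
}
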