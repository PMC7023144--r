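# canonical display order for the six ToxTracker reporter lines
.REPORTER_ORDER <- c("Srxn1", "Blvrb", "Rtkn", "Bscl2", "Ddit3", "Btg2")

#' Build the summary heatmap table
#'
#' One row per particle: the particle size, an LD50 label taken from the
#' Srxn1 reporter line's cytotoxicity (censored fits labelled
#' `"> <max dose>"`), and one verdict cell per reporter. Reporters missing
#' for a particle are marked `"not_tested"`.
#'
#' @param fits Fit table from [fit_hill_table()].
#' @param calls Call table from [call_reporter_table()].
#' @param specs Optional named list of [particle_spec()] used for the size
#'   column.
#' @param ld50_reporter Reporter line whose viability sources the LD50
#'   column. Default `"Srxn1"`; falls back to the first reporter present.
#' @return Tibble: `particle`, `size_nm`, `ld50_label`, then one column per
#'   reporter.
#' @export
build_summary <- function(fits, calls, specs = NULL,
                          ld50_reporter = "Srxn1") {
  check_columns(fits, c("particle", "reporter", "ld50", "censored",
                        "bound"), "fit table")
  check_columns(calls, c("particle", "reporter", "verdict"), "call table")
  particles <- unique(c(fits$particle, calls$particle))
  reporters <- unique(calls$reporter)
  reporters <- c(intersect(.REPORTER_ORDER, reporters),
                 setdiff(reporters, .REPORTER_ORDER))
  if (!ld50_reporter %in% fits$reporter) ld50_reporter <- fits$reporter[1]

  rows <- lapply(particles, function(p) {
    frow <- fits[fits$particle == p & fits$reporter == ld50_reporter, ]
    ld50_label <- if (nrow(frow) == 0) {
      "not_tested"
    } else if (frow$censored[1]) {
      paste0("> ", format(frow$bound[1]))
    } else {
      format(signif(frow$ld50[1], 3))
    }
    size <- if (!is.null(specs) && !is.null(specs[[p]])) {
      specs[[p]]$diameter_nm
    } else {
      NA_real_
    }
    verdicts <- vapply(reporters, function(r) {
      crow <- calls[calls$particle == p & calls$reporter == r, ]
      if (nrow(crow) == 0) "not_tested" else crow$verdict[1]
    }, "")
    tibble::tibble(particle = p, size_nm = size, ld50_label = ld50_label,
                   !!!stats::setNames(as.list(verdicts), reporters))
  })
  dplyr::bind_rows(rows)
}

# read a pipeline config from a YAML file or pass a list through
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_validation("config must be a file path or a named list")
  }
  defaults <- list(
    seed = 1L, equi_response_level = 20, positive_threshold = 2,
    weak_threshold = 1.5, viability_gate = 25,
    classification_tolerance = 0.75
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
      message("config: using default ", nm, " = ", defaults[[nm]])
    }
  }
  config
}

# turn a config synthesis block into a panel_config
panel_config_from_block <- function(block, seed) {
  rows_to_tibble <- function(rows) {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  particles <- particle_specs_from_df(rows_to_tibble(block$particles))
  ld50s <- if (is.list(block$true_ld50s)) {
    rows_to_tibble(block$true_ld50s)
  } else {
    block$true_ld50s %||% 20
  }
  folds <- if (!is.null(block$fold_curves)) {
    rows_to_tibble(block$fold_curves)
  } else {
    NULL
  }
  panel_config(
    particles = particles,
    reporters = block$reporters %||% .REPORTER_ORDER,
    true_ld50s = ld50s,
    fold_curves = folds,
    noise_cv = block$noise_cv %||% 0.1,
    n_replicates = block$n_replicates %||% 3,
    control_gfp = block$control_gfp %||% 200,
    autofluorescence_per_ug = block$autofluorescence_per_ug %||% 0,
    seed = seed
  )
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates every stage: load (or synthesize) the screen and particle
#' metadata, fit per-cell Hill LD50s, call reporter activation, identify
#' the dose metric per reporter where the panel is a size series with at
#' least three non-censored fits, and build the summary heatmap table. All
#' intermediate tables are written as CSV into `out_dir`; the run is
#' deterministic given the config (including its seed).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Either `screen_csv` + `particles_csv` paths, or a `synthesis` block
#'   (particle metadata plus generative parameters) must be given. Optional
#'   keys (logged defaults): `seed`, `equi_response_level`,
#'   `positive_threshold`, `weak_threshold`, `viability_gate`,
#'   `classification_tolerance`.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with `screen`, `fits`, `calls`, `dose_metric`,
#'   `summary` and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthesis)) {
    pc <- panel_config_from_block(config$synthesis, config$seed)
    screen <- generate_screen(pc)
    specs <- pc$particles
    readr::write_csv(screen, file.path(out_dir, "screen.csv"))
    readr::write_csv(particle_specs_to_df(specs),
                     file.path(out_dir, "particles.csv"))
    message("synthesized screen: ", nrow(screen), " wells")
  } else {
    if (is.null(config$screen_csv) || is.null(config$particles_csv)) {
      abort_schema(
        "config needs either a 'synthesis' block or screen_csv + particles_csv"
      )
    }
    screen <- readr::read_csv(config$screen_csv, show_col_types = FALSE)
    check_columns(screen, c("particle", "reporter", "dose_ug_ml",
                            "viability_pct", "gfp_mean"), "screen CSV")
    specs <- read_particle_table(config$particles_csv)
    unknown <- setdiff(unique(screen$particle), names(specs))
    if (length(unknown) > 0) {
      abort_schema(paste0(
        "screen particles missing from metadata: ",
        paste(unknown, collapse = ", ")
      ), missing = unknown)
    }
  }

  fits <- fit_hill_table(screen)
  message("fitted ", nrow(fits), " (particle, reporter) Hill curves; ",
          sum(fits$censored), " censored")
  calls <- call_reporter_table(
    screen,
    positive_threshold = config$positive_threshold,
    weak_threshold = config$weak_threshold,
    viability_gate = config$viability_gate
  )

  metric_rows <- lapply(unique(fits$reporter), function(r) {
    rf <- fits[fits$reporter == r, ]
    usable <- rf[!rf$censored, ]
    dia <- vapply(usable$particle,
                  function(p) specs[[p]]$diameter_nm, 0)
    if (length(unique(dia)) < 3) return(NULL)
    id <- identify_dose_metric(usable, specs,
                               level = config$equi_response_level,
                               tolerance = config$classification_tolerance)
    message("dose metric for ", r, ": ", id$call$metric,
            " (slope ", signif(id$fit$slope_m, 4), ")")
    tibble::tibble(
      reporter = r, slope = id$fit$slope_m,
      intercept = id$fit$intercept_q, r_squared = id$fit$r_squared,
      n_sizes = id$fit$n_sizes, metric = id$call$metric,
      tolerance = config$classification_tolerance,
      equi_response_level = config$equi_response_level
    )
  })
  dose_metric <- dplyr::bind_rows(metric_rows)

  summary_tbl <- build_summary(fits, calls, specs)

  readr::write_csv(fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(calls, file.path(out_dir, "calls.csv"))
  readr::write_csv(dose_metric, file.path(out_dir, "dose_metric.csv"))
  readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"))
  writeLines(format_summary_text(summary_tbl),
             file.path(out_dir, "summary.txt"))

  invisible(list(
    screen = screen, fits = fits, calls = calls,
    dose_metric = dose_metric, summary = summary_tbl,
    out_dir = out_dir
  ))
}

# plain-text aligned rendering of the summary table
format_summary_text <- function(summary_tbl) {
  df <- as.data.frame(summary_tbl)
  df[] <- lapply(df, function(x) format(x, trim = TRUE))
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(x) max(nchar(x)), 0))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(mapply(pad, names(df), widths), collapse = "  ")
  body <- apply(mapply(pad, df, widths), 1, paste, collapse = "  ")
  c(header, body)
}
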