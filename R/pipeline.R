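#' Configuration for a full pipeline run
#'
#' Collects every setting the staged analysis needs: input paths (or the
#' synthetic-region parameters when simulating), significance and correlation
#' thresholds, MCMC settings, stage toggles, and the master seed that makes
#' the whole run reproducible.
#'
#' Stage dependencies are validated up front: `select` requires `screen` and
#' `map`; `ecoreg` requires `select`.
#'
#' @param areas_csv,gal Paths to an area-table CSV (`area_id`, `O`, `E`,
#'   exposure columns) and a GAL adjacency file; `NULL` to simulate instead.
#' @param out_dir Output directory (created if needed).
#' @param simulate Named list of arguments passed to [simulate_region()] when
#'   no input paths are given.
#' @param alpha Family-wise error level of the screen.
#' @param rho_max Correlation threshold for covariate clustering.
#' @param prefer Optional expert-override representatives for
#'   [select_covariates()].
#' @param chains,iter MCMC settings for the mapping stages.
#' @param map_all If `TRUE`, the disease-mapping stage fits every screened
#'   variable; default `FALSE` fits only variables significant in the screen
#'   (the only ones the selection rule can admit).
#' @param stages Character vector of stages to run, in pipeline order, from
#'   `c("screen", "map", "select", "ecoreg")`.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(areas_csv = NULL, gal = NULL,
                            out_dir = tempfile("spenwas_run_"),
                            simulate = list(), alpha = 0.05, rho_max = 0.7,
                            prefer = NULL, chains = 2, iter = 2000,
                            map_all = FALSE,
                            stages = c("screen", "map", "select", "ecoreg"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  needs <- list(select = c("screen", "map"), ecoreg = "select")
  for (st in names(needs)) {
    missing_dep <- setdiff(needs[[st]], stages)
    if (st %in% stages && length(missing_dep)) {
      stop("Stage `", st, "` requires stage(s) ",
           paste(missing_dep, collapse = ", "), ".", call. = FALSE)
    }
  }
  if (xor(is.null(areas_csv), is.null(gal))) {
    stop("Provide both `areas_csv` and `gal`, or neither (to simulate).",
         call. = FALSE)
  }
  structure(
    list(areas_csv = areas_csv, gal = gal, out_dir = out_dir,
         simulate = simulate, alpha = alpha, rho_max = rho_max,
         prefer = prefer, chains = chains, iter = iter, map_all = map_all,
         stages = stages, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the staged spatial EnWAS pipeline
#'
#' Executes the full analysis end to end: (synthesise or load data) ->
#' indirect standardisation -> frequentist EnWAS screen -> Bayesian disease
#' mapping of screened variables plus the covariate-free risk surface ->
#' dual-screen covariate selection -> multivariable spatial ecological
#' regression. Every stage writes its outputs (CSV/JSON) under
#' `config$out_dir` and is logged in a manifest JSON recording the package
#' version, seed, per-stage wall time and input hashes. With a fixed seed
#' the outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `data` (graph + areas),
#'   `screen`, `mapping` (covariate-free fit), `mapping_by_variable`,
#'   `selection`, `ecoreg`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "spenwas",
                   version = as.character(utils::packageVersion("spenwas")),
                   seed = config$seed, stages = character(0))
  timings <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      report <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(report, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("Pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    timings[[name]] <<-
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    value
  }

  # ---- data: load or synthesise ----
  if (!is.null(config$areas_csv)) {
    data <- t_stage("load", {
      areas <- read_area_table(config$areas_csv)
      graph <- read_gal(config$gal)
      list(graph = graph, areas = areas)
    })
    manifest$inputs <- list(
      areas_csv = unname(tools::md5sum(config$areas_csv)),
      gal = unname(tools::md5sum(config$gal))
    )
    region <- NULL
  } else {
    region <- t_stage("simulate", {
      args <- utils::modifyList(list(seed = config$seed), config$simulate)
      do.call(simulate_region, args)
    })
    data <- t_stage("standardise", {
      # recompute E by indirect standardisation from the stratified counts
      areas <- region$areas
      E <- expected_counts(region$population)
      areas$E <- E$E[match(areas$area_id, E$area_id)]
      write_area_table(areas, file.path(config$out_dir, "areas.csv"))
      write_gal(region$graph, file.path(config$out_dir, "graph.gal"))
      jsonlite::write_json(
        list(seed = region$truth$seed, beta = region$truth$beta,
             intercept = region$truth$intercept, sigma = region$truth$sigma,
             phi = region$truth$phi),
        file.path(config$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
      )
      list(graph = region$graph, areas = areas)
    })
  }
  vars <- setdiff(names(data$areas)[vapply(data$areas, is.numeric, TRUE)],
                  c("O", "E", "risk", "O_period1", "O_period2"))

  screen <- mapping <- map_by_var <- selection <- ecoreg <- NULL

  if ("screen" %in% config$stages) {
    screen <- t_stage("screen", {
      s <- enwas_screen(data$areas, variables = vars, alpha = config$alpha)
      utils::write.csv(tidy(s), file.path(config$out_dir, "screen.csv"),
                       row.names = FALSE)
      s
    })
  }

  if ("map" %in% config$stages) {
    mapping <- t_stage("map", {
      fit <- fit_bym2(data$areas, data$graph, chains = config$chains,
                      iter = config$iter, seed = config$seed + 100L)
      utils::write.csv(fit$areas,
                       file.path(config$out_dir, "disease_map.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(glance(fit)),
                           file.path(config$out_dir, "disease_map.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    })
    map_by_var <- t_stage("map_by_variable", {
      to_map <- if (config$map_all || is.null(screen)) vars
                else screen$variable[screen$significant]
      fits <- purrr::imap(
        stats::setNames(to_map, to_map),
        function(v, nm) {
          f <- fit_bym2(data$areas, data$graph, covariates = v,
                        chains = config$chains, iter = config$iter,
                        seed = config$seed + 200L + match(v, vars))
          dplyr::filter(tidy(f), .data$term == v)
        }
      )
      tab <- dplyr::bind_rows(fits) |>
        dplyr::transmute(variable = .data$term, rr = .data$rr,
                         rr_low = .data$rr_low, rr_high = .data$rr_high,
                         rhat = .data$rhat, ess = .data$ess)
      utils::write.csv(tab, file.path(config$out_dir, "mapping_by_variable.csv"),
                       row.names = FALSE)
      tab
    })
  }

  if ("select" %in% config$stages) {
    selection <- t_stage("select", {
      # variables never mapped (screen-insignificant) cannot pass both gates;
      # enter them with an interval spanning 1
      map_tab <- tibble::tibble(variable = vars, rr_low = 0, rr_high = Inf)
      hit <- match(map_by_var$variable, map_tab$variable)
      map_tab$rr_low[hit] <- map_by_var$rr_low
      map_tab$rr_high[hit] <- map_by_var$rr_high
      corr <- spearman_matrix(data$areas, variables = vars)
      sel <- select_covariates(screen, map_tab, corr,
                               rho_max = config$rho_max,
                               prefer = config$prefer, alpha = config$alpha)
      utils::write.csv(sel, file.path(config$out_dir, "selection.csv"),
                       row.names = FALSE)
      sel
    })
  }

  if ("ecoreg" %in% config$stages) {
    ecoreg <- t_stage("ecoreg", {
      chosen <- selection$variable[selection$selected]
      fit <- ecological_regression(data$areas, data$graph, covariates = chosen,
                                   chains = config$chains, iter = config$iter,
                                   seed = config$seed + 300L)
      utils::write.csv(tidy(fit), file.path(config$out_dir, "ecoreg.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$areas, file.path(config$out_dir, "ecoreg_areas.csv"),
                       row.names = FALSE)
      fit
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  # wall times go to a separate log so the manifest (and every analytical
  # output) is byte-identical across same-seed runs
  jsonlite::write_json(timings, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(list(data = data, region = region, screen = screen,
                 mapping = mapping, mapping_by_variable = map_by_var,
                 selection = selection, ecoreg = ecoreg, manifest = manifest,
                 timings = timings))
}

#' Read and write area tables
#'
#' Area tables are plain CSV keyed by a mandatory `area_id` column, with
#' observed counts `O`, expected counts `E` and one column per exposure.
#'
#' @param path CSV path.
#' @return `read_area_table()` returns a tibble; `write_area_table()` returns
#'   `path` invisibly.
#' @export
read_area_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"area_id" %in% names(out)) {
    stop("Area table must have an `area_id` column.", call. = FALSE)
  }
  out$area_id <- as.character(out$area_id)
  out
}

#' @rdname read_area_table
#' @param areas Area table to write.
#' @export
write_area_table <- function(areas, path) {
  utils::write.csv(areas, path, row.names = FALSE)
  invisible(path)
}
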