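# Run configuration handling and file exporters: JSON/YAML configs, TSV
# tables, GraphML/DOT graphs, gzipped-JSON kernels.  The subcommand runners
# tie the pipeline together for the command-line front end.

#' Default run configuration
#'
#' @return A named list with the documented defaults: fixture parameters
#'   (`ses_type`, `climate_level`, `seed`), `schedule` (start/horizon/step),
#'   `grid_n` (kernel grid points per dimension), `security_aggregate`,
#'   `optimality_aggregate`, `check_every_step`, `top_fraction`,
#'   `max_pathways` (expansion cap), `pathway` (arrangement sequence for the
#'   `simulate` subcommand) and `output_dir`.
#' @export
default_run_config <- function() {
  list(
    ses_type = "rural",
    climate_level = 0,
    seed = 1,
    schedule = list(start = 2020, horizon = 30, step = 5),
    grid_n = 21,
    security_aggregate = "mean",
    optimality_aggregate = "mean",
    check_every_step = TRUE,
    top_fraction = 0.10,
    max_pathways = 2e5,
    contrast = "RH_vs_PH",
    perturbation_size = 0.1,
    pathway = rep("CCA1|KCA1", 7),
    output_dir = "dappmap_out"
  )
}

#' Read and validate a run configuration
#'
#' Reads JSON (`.json`) or YAML (`.yml`/`.yaml`), fills unset fields with
#' [default_run_config()] values and validates the result against the
#' structural schema shipped in `inst/schema/run_config.json`.
#'
#' @param path Config file path, or a named list (validated in place).
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param config A named list of configuration entries.
#' @return The configuration completed with defaults; stops with a one-line
#'   message naming the offending field otherwise.
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("config error: unknown field(s) ", paste(unknown, collapse = ","),
         call. = FALSE)
  }
  cfg <- utils::modifyList(def, config)
  fail <- function(f, why) stop("config error: field '", f, "' ", why,
                                call. = FALSE)
  if (!cfg$ses_type %in% c("rural", "peri_urban")) {
    fail("ses_type", "must be 'rural' or 'peri_urban'")
  }
  if (!cfg$climate_level %in% 0:2) fail("climate_level", "must be 0, 1 or 2")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    fail("seed", "must be a single integer")
  }
  s <- cfg$schedule
  if (!all(c("start", "horizon", "step") %in% names(s))) {
    fail("schedule", "needs start, horizon, step")
  }
  if (s$horizon %% s$step != 0) fail("schedule", "step must divide horizon")
  if (!is.numeric(cfg$grid_n) || cfg$grid_n < 2) {
    fail("grid_n", "must be an integer >= 2")
  }
  if (!cfg$security_aggregate %in% c("mean", "min")) {
    fail("security_aggregate", "must be 'mean' or 'min'")
  }
  if (!cfg$optimality_aggregate %in% c("mean", "terminal")) {
    fail("optimality_aggregate", "must be 'mean' or 'terminal'")
  }
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    fail("top_fraction", "must be in (0, 1]")
  }
  if (!cfg$contrast %in% names(.contrast_classes)) {
    fail("contrast", "unknown contrast")
  }
  epochs <- s$horizon / s$step + 1
  if (length(cfg$pathway) != epochs) {
    fail("pathway", sprintf("must have %d entries (one per epoch)", epochs))
  }
  cfg
}

resolved_fixture <- function(cfg) {
  fx <- default_fixture(cfg$ses_type, cfg$climate_level, cfg$seed)
  fx$schedule <- decision_schedule(cfg$schedule$start, cfg$schedule$horizon,
                                   cfg$schedule$step)
  fx
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Convert a DAPP graph to an igraph object
#'
#' Vertices are (epoch, arrangement) decision nodes named
#' `t<epoch>_<arrangement id>`; edges carry the `traversals` count and the
#' grayscale `shade` attribute.
#'
#' @param graph A `"dapp_graph"`.
#' @param drop_empty Drop edges with zero traversals (default).
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph, drop_empty = TRUE) {
  ids <- graph$arrangement_ids
  if (is.null(ids)) ids <- paste0("A", seq_len(graph$n_arrangements))
  L <- graph$schedule$epochs
  vname <- function(l, a) sprintf("t%d_%s", l - 1, ids[a])
  verts <- expand.grid(a = seq_len(graph$n_arrangements), l = seq_len(L))
  vdf <- data.frame(name = vname(verts$l, verts$a), epoch = verts$l - 1,
                    arrangement = ids[verts$a])
  e <- graph$edges
  if (drop_empty) e <- e[e$traversals > 0, , drop = FALSE]
  edf <- data.frame(from = vname(e$layer, e$arr_from),
                    to = vname(e$layer + 1, e$arr_to),
                    traversals = e$traversals, shade = e$shade)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Export a DAPP graph to GraphML and DOT
#'
#' @param graph A `"dapp_graph"`.
#' @param basename Output path without extension.
#' @return Character vector of the two files written.
#' @export
export_dapp_graph <- function(graph, basename) {
  g <- as_igraph(graph)
  files <- paste0(basename, c(".graphml", ".dot"))
  igraph::write_graph(g, files[1], format = "graphml")
  igraph::write_graph(g, files[2], format = "dot")
  files
}

#' Export a viability kernel as gzipped JSON
#'
#' Writes the grid specification and the per-epoch membership bitsets
#' (0/1 vectors in node order).
#'
#' @param kernel A `"viability_kernel"`.
#' @param path Output path (conventionally `.json.gz`).
#' @return The path, invisibly.
#' @export
export_kernel <- function(kernel, path) {
  payload <- list(
    grid = list(lower = kernel$grid$lower, upper = kernel$grid$upper,
                n = kernel$grid$n, names = kernel$grid$names),
    epochs = ncol(kernel$membership),
    arrangements = kernel$arrangement_ids,
    membership = lapply(seq_len(ncol(kernel$membership)),
                        function(k) as.integer(kernel$membership[, k])),
    n_out_of_bounds = kernel$n_out_of_bounds
  )
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

# ---- subcommand runners -----------------------------------------------

run_fixture <- function(cfg, out_dir) {
  fx <- resolved_fixture(cfg)
  files <- character()
  model_file <- file.path(out_dir, "fixture.json")
  payload <- list(
    ses_type = fx$ses_type, climate_level = fx$climate_level, seed = fx$seed,
    classes = fx$model$classes,
    initial_state = as.list(unclass(fx$initial_state)),
    base_weights = as.list(unclass(fx$base_weights)),
    arrangement_weights = lapply(fx$weights, function(w) as.list(unclass(w))),
    domain = list(name = fx$domain$name, sign = fx$domain$sign,
                  bound = fx$domain$bound),
    es = list(names = fx$model$es_names, signs = fx$model$es_signs)
  )
  jsonlite::write_json(payload, model_file, auto_unbox = TRUE, digits = NA)
  files <- c(files, model_file)
  for (id in fx$model$arrangement_ids) {
    f <- file.path(out_dir, paste0("transition_",
                                   gsub("[^A-Za-z0-9]", "_", id), ".tsv"))
    M <- fx$model$effective[[match(id, fx$model$arrangement_ids)]]
    write_tsv(data.frame(from = rownames(M), round(M, 8)), f)
    files <- c(files, f)
  }
  files
}

run_simulate <- function(cfg, out_dir) {
  fx <- resolved_fixture(cfg)
  model <- as_pathway_model(fx)
  res <- simulate_pathway(model, fx$initial_state, cfg$pathway, fx$schedule,
                          fx$domain, aggregate = cfg$security_aggregate)
  f1 <- write_tsv(es_trajectories(res), file.path(out_dir, "es_trajectory.tsv"))
  f2 <- file.path(out_dir, "simulate_summary.json")
  jsonlite::write_json(
    list(pathway = res$arrangement_ids, viable = res$viable,
         security = res$security, first_violation = res$first_violation),
    f2, auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

run_kernel <- function(cfg, out_dir) {
  fx <- resolved_fixture(cfg)
  model <- as_pathway_model(fx)
  kern <- compute_kernel(model, fx$domain, fx$schedule, grid = cfg$grid_n,
                         check_every_step = cfg$check_every_step)
  f1 <- export_kernel(kern, file.path(out_dir, "kernel.json.gz"))
  sl <- kernel_slice(kern, c("TR", "SR"))
  f2 <- write_tsv(cbind(TR = rownames(sl), as.data.frame(sl * 1)),
                  file.path(out_dir, "kernel_slice_TR_SR.tsv"))
  c(f1, f2)
}

run_dapp <- function(cfg, out_dir) {
  fx <- resolved_fixture(cfg)
  model <- as_pathway_model(fx)
  graph <- enumerate_viable(model, fx$initial_state, fx$schedule, fx$domain,
                            check_every_step = cfg$check_every_step)
  files <- export_dapp_graph(graph, file.path(out_dir, "dapp_probability"))
  summary_payload <- list(
    total_pathways = graph$total_pathways,
    total_viable = graph$total_viable,
    viable_fraction = graph$total_viable / graph$total_pathways
  )
  if (graph$total_viable > 0 && graph$total_viable <= cfg$max_pathways) {
    ps <- collect_pathways(graph, max_pathways = cfg$max_pathways)
    top <- top_secured(ps, cfg$top_fraction)
    files <- c(files, export_dapp_graph(pathway_graph(top),
                                        file.path(out_dir, "dapp_secured")))
    opt_rows <- list()
    for (i in seq_along(.hedgerow_es_names)) {
      es <- .hedgerow_es_names[i]
      sense <- if (.hedgerow_es_signs[i] == "service") "maximize" else "minimize"
      opt <- optimal_for_es(ps, es, sense)
      first <- subset_pathway_set(opt, 1)
      opt_rows[[es]] <- data.frame(
        es = es, sense = sense, n_co_optimal = nrow(opt$paths),
        aggregate = opt$es_mean[1, es],
        pathway = paste(ps$arrangement_ids[first$paths[1, ]], collapse = " -> "))
      files <- c(files, export_dapp_graph(
        pathway_graph(opt),
        file.path(out_dir, paste0("dapp_optimal_", es))))
    }
    files <- c(files, write_tsv(do.call(rbind, opt_rows),
                                file.path(out_dir, "optimal_pathways.tsv")))
    summary_payload$top_secured <- list(
      fraction = cfg$top_fraction, n = nrow(top$paths),
      best_security = max(top$security),
      best_pathway = paste(ps$arrangement_ids[top$paths[1, ]],
                           collapse = " -> "))
  } else if (graph$total_viable > cfg$max_pathways) {
    summary_payload$note <- "viable set larger than max_pathways; maps limited to probability map"
  }
  f <- file.path(out_dir, "dapp_summary.json")
  jsonlite::write_json(summary_payload, f, auto_unbox = TRUE, digits = NA)
  c(files, f)
}

run_sensitivity <- function(cfg, out_dir) {
  fx <- resolved_fixture(cfg)
  model <- as_pathway_model(fx)
  graph <- enumerate_viable(model, fx$initial_state, fx$schedule, fx$domain,
                            check_every_step = cfg$check_every_step)
  # bounded pathway sample: the viable set if small, plus random pathways
  set.seed(cfg$seed)
  n_arr <- model$n_arrangements
  epochs <- fx$schedule$epochs
  rand <- matrix(sample.int(n_arr, 200 * epochs, replace = TRUE), ncol = epochs)
  paths <- rand
  if (graph$total_viable > 0 && graph$total_viable <= 2000) {
    ps <- collect_pathways(graph, max_pathways = 2000)
    paths <- rbind(ps$paths, rand)
  }
  an <- delta_security(fx, paths, contrast = cfg$contrast,
                       perturbation_size = cfg$perturbation_size)
  long <- do.call(rbind, lapply(colnames(an$delta), function(es) {
    data.frame(pathway = seq_len(nrow(an$delta)), es = es,
               contrast = an$contrast, delta = an$delta[, es],
               viable = an$viable)
  }))
  f1 <- write_tsv(long, file.path(out_dir, "delta_es.tsv"))
  f2 <- file.path(out_dir, "delta_es_summary.json")
  jsonlite::write_json(
    lapply(an$distributions, function(d) list(
      es_name = d$es_name,
      all = d$all[c("n", "median", "q25", "q75")],
      viable_only = if (isTRUE(d$viable_only$empty)) list(n = 0)
                    else d$viable_only[c("n", "median", "q25", "q75")]
    )),
    f2, auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

#' Run a pipeline subcommand
#'
#' Entry point behind the command-line interface: resolves and validates the
#' configuration, creates the output directory, writes the resolved config
#' next to the outputs, and dispatches to the requested stage.  All outputs
#' are deterministic given the configuration and seed.
#'
#' @param subcommand One of `"fixture"`, `"simulate"`, `"kernel"`, `"dapp"`,
#'   `"sensitivity"`.
#' @param config A config file path or named list (see
#'   [default_run_config()]).
#' @return Invisibly, the character vector of files written.
#' @export
dappmap_run <- function(subcommand = c("fixture", "simulate", "kernel",
                                       "dapp", "sensitivity"),
                        config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- read_run_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- file.path(out_dir, paste0(subcommand, "_config.json"))
  jsonlite::write_json(cfg, resolved, auto_unbox = TRUE, digits = NA)
  t0 <- Sys.time()
  files <- switch(subcommand,
                  fixture = run_fixture(cfg, out_dir),
                  simulate = run_simulate(cfg, out_dir),
                  kernel = run_kernel(cfg, out_dir),
                  dapp = run_dapp(cfg, out_dir),
                  sensitivity = run_sensitivity(cfg, out_dir))
  message(sprintf("[dappmap] %s: %d file(s) in %.1fs (seed %d)",
                  subcommand, length(files) + 1,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  as.integer(cfg$seed)))
  invisible(c(resolved, files))
}
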