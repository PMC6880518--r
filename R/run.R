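.nf_registry <- function() {
  list(
    birth = list(build = scenario_birth, t_end = 100),
    decay = list(build = scenario_decay, t_end = 5),
    bimolecular = list(build = scenario_bimolecular, t_end = 3e-4),
    free_diffusion = list(build = scenario_free_diffusion, n_steps = 2000L),
    division = list(build = scenario_division, n_steps = 500L),
    vesicle = list(build = scenario_vesicle, n_steps = 2000L),
    yeast = list(build = scenario_yeast, n_steps = 200L),
    raft = list(build = scenario_raft, n_steps = 500L))
}

#' List the packaged scenarios
#'
#' @return character vector of scenario names usable with [run_scenario()]
#'   and the `nestforce` command line.
#' @export
list_scenarios <- function() names(.nf_registry())

#' Build a packaged scenario
#'
#' @param name scenario name (see [list_scenarios()]).
#' @param seed RNG seed.
#' @param overrides named list of arguments forwarded to the scenario
#'   builder.
#' @return an `nf_state`.
#' @export
build_scenario <- function(name, seed = 1L, overrides = list()) {
  reg <- .nf_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  out <- do.call(reg[[name]]$build, c(list(seed = seed), overrides))
  if (inherits(out, "nf_state")) out else out$state
}

#' Run a packaged scenario and write its outputs
#'
#' Deterministic under (scenario, seed, config): writes a species-counts CSV,
#' an extended-XYZ trajectory, a full JSON snapshot of the final state and a
#' run log echoing the configuration.
#'
#' @param name scenario name.
#' @param seed RNG seed.
#' @param t_end simulated end time (s); alternatively give `n_steps`.
#' @param n_steps number of engine steps.
#' @param out_dir output directory (created if missing).
#' @param observe subset of `c("counts", "trajectory")`.
#' @param interval observer recording interval (s); default every 10 steps.
#' @param overrides named list forwarded to the scenario builder.
#' @return invisibly, a list with the final state and the written file paths.
#' @export
run_scenario <- function(name, seed = 1L, t_end = NULL, n_steps = NULL,
                         out_dir = ".", observe = c("counts", "trajectory"),
                         interval = NULL, overrides = list()) {
  reg <- .nf_registry()
  st <- build_scenario(name, seed, overrides)
  if (is.null(t_end) && is.null(n_steps)) {
    t_end <- reg[[name]]$t_end
    n_steps <- reg[[name]]$n_steps
  }
  obs <- list()
  if ("counts" %in% observe)
    obs$counts <- counts_observer(interval = interval,
                                  every = if (is.null(interval)) 10L)
  if ("trajectory" %in% observe)
    obs$trajectory <- trajectory_observer(interval = interval,
                                          every = if (is.null(interval)) 10L)
  if (!is.null(n_steps)) run_steps(st, n_steps, obs)
  else run_until(st, t_end, obs)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(obs$counts))
    paths$counts <- write_counts(obs$counts, file.path(out_dir, "counts.csv"))
  if (!is.null(obs$trajectory))
    paths$trajectory <- write_trajectory(obs$trajectory,
                                         file.path(out_dir, "trajectory.xyz"))
  paths$snapshot <- write_snapshot(st, file.path(out_dir, "snapshot.json"))
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("nestforce %s",
            as.character(utils::packageVersion("nestforce"))),
    sprintf("scenario: %s", name), sprintf("seed: %d", as.integer(seed)),
    sprintf("end: %s", if (!is.null(n_steps)) paste(n_steps, "steps")
            else paste(t_end, "s")),
    sprintf("final time: %s s", format(st$time)),
    sprintf("final particles: %d", st$n),
    sprintf("overrides: %s",
            if (length(overrides))
              jsonlite::toJSON(overrides, auto_unbox = TRUE) else "none")),
    log_path)
  paths$log <- log_path
  invisible(list(state = st, paths = paths))
}

#' Command-line entry point
#'
#' Implements the `nestforce` command line: `nestforce run <scenario> --seed
#' INT --t-end FLOAT --steps INT --config FILE --out DIR --observe
#' counts,trajectory`, `nestforce list-scenarios` and `nestforce validate`
#' (runs the scenario smoke matrix and prints a pass/fail table). Installed
#' packages cannot place executables on the PATH, so invoke it as
#' `Rscript -e 'nestforce::nestforce_main()' <command> ...` or via the
#' wrapper script in `inst/cli/`.
#'
#' @param args command-line arguments (default: those of the Rscript call).
#' @return exit status, invisibly (0 on success).
#' @export
nestforce_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: nestforce <run|list-scenarios|validate> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- .nf_parse_args(args[-1])
  if (cmd == "list-scenarios") {
    cat(paste(list_scenarios(), collapse = "\n"), "\n")
    return(invisible(0L))
  }
  if (cmd == "run") {
    name <- opts$positional[1]
    if (is.na(name)) stop("nestforce run needs a scenario name",
                          call. = FALSE)
    overrides <- if (!is.null(opts$config))
      jsonlite::fromJSON(opts$config, simplifyVector = TRUE) else list()
    res <- run_scenario(
      name, seed = as.integer(opts$seed %||% 1L),
      t_end = if (!is.null(opts$`t-end`)) as.numeric(opts$`t-end`),
      n_steps = if (!is.null(opts$steps)) as.integer(opts$steps),
      out_dir = opts$out %||% ".",
      observe = strsplit(opts$observe %||% "counts,trajectory", ",")[[1]],
      overrides = overrides)
    cat("wrote:", paste(unlist(res$paths), collapse = " "), "\n")
    return(invisible(0L))
  }
  if (cmd == "validate") {
    ok <- TRUE
    for (name in list_scenarios()) {
      res <- tryCatch({
        st <- build_scenario(name, seed = 1L,
                             overrides = .nf_smoke_overrides(name))
        run_steps(st, 50L)
        audit_forest(st)
        length(audit_containment(st)) == 0L
      }, error = function(e) conditionMessage(e))
      pass <- isTRUE(res)
      ok <- ok && pass
      cat(sprintf("%-16s %s\n", name,
                  if (pass) "PASS" else paste("FAIL:", res)))
    }
    return(invisible(if (ok) 0L else 1L))
  }
  stop("unknown command: ", cmd, call. = FALSE)
}

# small desk-scale overrides for smoke runs
.nf_smoke_overrides <- function(name) {
  switch(name,
         decay = list(n0 = 100L),
         bimolecular = list(n_each = 20L),
         free_diffusion = list(n = 64L),
         division = list(n_content = 5L),
         vesicle = list(scale = 0.005),
         yeast = list(n_cells = 2L, k_emit = 0.5, t_step = 1e-5),
         raft = list(n_each = 20L),
         list())
}

.nf_parse_args <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts$positional <- c(opts$positional, NA_character_)
  opts
}
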