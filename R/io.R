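#' Load a run configuration from a YAML file
#'
#' A configuration is a flat key-value file; omitted keys take the
#' reference defaults of [crypt_params()] and [mutation_config()].  Unknown
#' keys are rejected, as are out-of-range values.  Recognised keys are the
#' fields of [crypt_params()] and [mutation_config()] plus `experiment`,
#' `n_replicates`, `master_seed` and `output_dir`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object: list with elements `params`
#'   (`crypt_params`), `mutation` (`mutation_config`), `experiment`,
#'   `n_replicates`, `master_seed`, `output_dir`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("ps: 0.2\nn_replicates: 10", f)
#' load_config(f)$params$ps
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)

  param_keys <- setdiff(names(formals(crypt_params)), "")
  mut_keys <- setdiff(names(formals(mutation_config)), "")
  run_keys <- c("experiment", "n_replicates", "master_seed", "output_dir")
  unknown <- setdiff(names(raw), c(param_keys, mut_keys, run_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  params <- do.call(crypt_params, raw[intersect(names(raw), param_keys)])
  mutation <- do.call(mutation_config, raw[intersect(names(raw), mut_keys)])
  cfg <- list(params = params, mutation = mutation,
              experiment = raw$experiment %||% "run",
              n_replicates = as.integer(raw$n_replicates %||% 20L),
              master_seed = as.integer(raw$master_seed %||% 1L),
              output_dir = raw$output_dir %||% ".")
  if (cfg$n_replicates < 1) stop("n_replicates must be positive", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: the written file loads back to an identical
#' configuration.
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- c(unclass(config$params),
            unclass(config$mutation),
            list(experiment = config$experiment,
                 n_replicates = config$n_replicates,
                 master_seed = config$master_seed,
                 output_dir = config$output_dir))
  flat <- flat[!vapply(flat, function(v) length(v) == 1 && is.na(v), logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

state_codes <- c("Q", "G1", "SG2", "M")

#' Render the final lattice state as a character grid
#'
#' One row of the matrix per lattice row with the luminal (top) row first;
#' each occupied site is rendered `state:stemness:ancestor`, multiple
#' occupants are joined with `|`, and empty sites are `.`.
#'
#' @param run A `crypt_run`.
#' @return A character matrix of dimension `n_rows` x `n_cols`.
#' @export
snapshot_grid <- function(run) {
  stopifnot(inherits(run, "crypt_run"))
  p <- run$params
  cells <- run$cells
  g <- matrix(".", nrow = p$n_rows, ncol = p$n_cols)
  lab <- sprintf("%s:%s:SC%d", state_codes[cells$state + 1L],
                 vapply(cells$stemness, format, character(1), digits = 3),
                 cells$ancestor)
  for (i in seq_len(nrow(cells))) {
    r <- p$n_rows - cells$y[i]      # top row first
    cc <- cells$x[i] + 1L
    g[r, cc] <- if (g[r, cc] == ".") lab[i] else paste(g[r, cc], lab[i], sep = "|")
  }
  g
}

#' Write a plain-text grid snapshot
#'
#' @param run A `crypt_run`.
#' @param path Output path (TSV; one line per lattice row, top row first).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(run, path) {
  g <- snapshot_grid(run)
  write.table(g, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the niche trace of a run as CSV
#'
#' Columns: `iteration`, `n_stem`, and one column per founding ancestor
#' (requires a run recorded with `record = "trace"`).
#'
#' @param run A `crypt_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  stopifnot(inherits(run, "crypt_run"))
  if (is.null(run$ancestor_counts))
    stop("run was not recorded with record = \"trace\"", call. = FALSE)
  df <- data.frame(iteration = seq_along(run$ns), n_stem = run$ns,
                   run$ancestor_counts, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the event log of a run as CSV
#'
#' Events: niche succession, second APC hit, extinction, overflow or
#' censoring at the iteration cap, with the iteration at which each
#' occurred.
#'
#' @param run A `crypt_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(run, path) {
  stopifnot(inherits(run, "crypt_run"))
  ev <- data.frame(iteration = integer(0), event = character(0),
                   detail = character(0))
  add <- function(it, event, detail) rbind(ev, data.frame(
    iteration = it, event = event, detail = detail))
  if (!is.null(run$succession$iteration))
    ev <- add(run$succession$iteration, "succession", run$succession$ancestor)
  if (!is.null(run$second_hit$any_iteration))
    ev <- add(run$second_hit$any_iteration, "second_hit", "any_cell")
  if (!is.null(run$second_hit$stem_iteration))
    ev <- add(run$second_hit$stem_iteration, "second_hit", "stem")
  if (run$outcome == "extinction")
    ev <- add(run$n_iter, "extinction", "")
  if (run$outcome == "stem_overflow")
    ev <- add(run$n_iter, "stem_overflow", "")
  if (run$outcome == "max_iterations")
    ev <- add(run$n_iter, "censored", "")
  write.table(ev, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
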