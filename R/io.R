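#' Read a whitespace-delimited numeric matrix
#'
#' Reads square connectome (`weights.txt`) or gain matrices in the plain
#' text convention: one row per line, whitespace-separated numeric tokens.
#'
#' @param path File path.
#' @return A numeric matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("%s: empty matrix file", path))
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val)) {
      abort(sprintf("%s: non-numeric token on line %d", path, i),
            class = "vepfit_parse_error")
    }
    val
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1) {
    bad <- which(len != len[1])[1]
    abort(sprintf("%s: ragged row on line %d (%d values, expected %d)",
                  path, bad, len[bad], len[1]),
          class = "vepfit_parse_error")
  }
  do.call(rbind, rows)
}

#' Write a numeric matrix as whitespace-delimited text
#'
#' Full double precision (`%.17g`), so a write-then-read round trip
#' reproduces values exactly.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  lines <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

write_series_tsv <- function(series, path) {
  df <- as.data.frame(series)
  df[] <- lapply(df, function(c) sprintf("%.17g", c))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_series_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Write a benchmark problem bundle to a directory
#'
#' Emits the flat-file form of a benchmark: `weights.txt` (connectome),
#' `gain.txt`, `truth.json` (zone labels, true excitabilities, coupling,
#' thresholds, seeds), `observed.tsv`, and `problem.cfg` (flat key=value
#' configuration), so a fit can be reproduced from files alone.
#'
#' @param pb A list with `problem` and `observed` from [make_problem()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_problem_bundle <- function(pb, dir) {
  problem <- pb$problem
  observed <- pb$observed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(problem$model$connectome, file.path(dir, "weights.txt"))
  write_matrix(problem$gain$values, file.path(dir, "gain.txt"))
  truth <- problem$truth
  jsonlite::write_json(
    list(
      labels = as.character(truth$label),
      eta_true = truth$eta,
      K_true = problem$K_true,
      eta_c = attr(truth, "eta_c"),
      delta_eta = attr(truth, "delta_eta"),
      seed = problem$seed,
      generator_seed = attr(observed, "generator_seed")
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_series_tsv(observed, file.path(dir, "observed.tsv"))
  cfg <- c(
    problem_id = problem$problem_id,
    n_regions = problem$model$n_regions,
    observation_level = problem$observation_level,
    coupling_regime = problem$coupling_regime,
    stochastic = tolower(problem$stochastic),
    tau = problem$model$tau,
    current = problem$model$current,
    dt = problem$model$dt,
    noise_std = problem$model$noise_std,
    duration = problem$duration,
    store_every = problem$store_every,
    cost_mode = problem$cost_mode,
    eta_lower = problem$bounds$lower[1],
    eta_upper = problem$bounds$upper[1],
    K_lower = problem$bounds$lower[length(problem$bounds$lower)],
    K_upper = problem$bounds$upper[length(problem$bounds$upper)],
    seed = problem$seed
  )
  writeLines(paste0(names(cfg), " = ", cfg), file.path(dir, "problem.cfg"))
  invisible(dir)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  setNames(lapply(kv, function(p) {
    v <- p[[2]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("true", "false")) v == "true" else v
  }), vapply(kv, `[[`, "", 1))
}

#' Read a benchmark problem bundle from a directory
#'
#' @param dir Directory written by [write_problem_bundle()].
#' @return A list with `problem` and `observed`, as from [make_problem()].
#' @export
read_problem_bundle <- function(dir) {
  cfg <- read_flat_config(file.path(dir, "problem.cfg"))
  C <- read_matrix(file.path(dir, "weights.txt"))
  G <- read_matrix(file.path(dir, "gain.txt"))
  truth_j <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  n <- nrow(C)
  truth <- tibble::tibble(
    region = seq_len(n),
    label = factor(truth_j$labels, levels = ZONE_LEVELS),
    eta = truth_j$eta_true
  )
  attr(truth, "eta_c") <- truth_j$eta_c
  attr(truth, "delta_eta") <- truth_j$delta_eta
  class(truth) <- c("epi_map", class(truth))
  model <- vep_model(C, excitability = truth$eta, coupling = truth_j$K_true,
                     tau = cfg$tau, current = cfg$current, dt = cfg$dt,
                     noise_std = cfg$noise_std)
  observed <- read_series_tsv(file.path(dir, "observed.tsv"))
  class(observed) <- c("vep_observed", "sensor_series", class(observed))
  attr(observed, "level") <- cfg$observation_level
  attr(observed, "generator_seed") <- truth_j$generator_seed
  attr(observed, "problem_id") <- cfg$problem_id
  problem <- structure(
    list(
      problem_id = as.integer(cfg$problem_id),
      observation_level = cfg$observation_level,
      coupling_regime = cfg$coupling_regime,
      stochastic = isTRUE(cfg$stochastic),
      model = model,
      gain = gain_matrix(G),
      truth = truth,
      K_true = truth_j$K_true,
      duration = cfg$duration,
      store_every = as.integer(cfg$store_every),
      bounds = list(
        lower = c(rep(cfg$eta_lower, n), cfg$K_lower),
        upper = c(rep(cfg$eta_upper, n), cfg$K_upper)
      ),
      cost_mode = cfg$cost_mode,
      seed = as.integer(cfg$seed)
    ),
    class = "vep_problem"
  )
  list(problem = problem, observed = observed)
}

#' Write an optimization result to a directory
#'
#' Emits `result.json` (best parameters, cost, best-so-far trace) and
#' `archive.tsv` (all evaluated solutions with costs, worker ids, and
#' evaluation seeds).
#'
#' @param fit A `vep_fit`.
#' @param dir Output directory.
#' @param seed Seed recorded in the result for provenance.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      best_theta = fit$best_theta,
      best_cost = fit$best_cost,
      n_evals = fit$n_evals,
      n_workers = fit$n_workers,
      seed = seed,
      trace = list(evals = fit$trace$evals, cost = fit$trace$cost)
    ),
    file.path(dir, "result.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_series_tsv(fit$archive, file.path(dir, "archive.tsv"))
  invisible(dir)
}

#' Read an archive written by [write_fit()]
#'
#' @param path Path to `archive.tsv`.
#' @return The archive tibble.
#' @export
read_archive <- function(path) read_series_tsv(path)

#' Write uncertainty bands as a delimited table
#'
#' @param bands A `uq_bands` tibble from [percentile_bands()].
#' @param path Output path (`uq_bands.tsv`).
#' @export
write_uq_bands <- function(bands, path) {
  utils::write.table(as.data.frame(bands), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_manifest <- function(dir, command, args, seed = NULL) {
  jsonlite::write_json(
    list(
      command = command,
      args = args,
      seed = seed,
      package = "vepfit",
      version = as.character(utils::packageVersion("vepfit")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE
  )
}
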