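#' Read and write flat key-value configuration files
#'
#' Configurations are stored as diff-able flat text: one `key = value`
#' assignment per line, `#` comments. Values are parsed as numeric when
#' possible, `TRUE`/`FALSE` as logical, everything else as character.
#'
#' @param path File path.
#' @param config Named list.
#' @return `read_config` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                  else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 17), collapse = ",")) },
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Tabular artifact I/O
#'
#' All estimates and traces are written as tab-separated text with a
#' header, and round-trip through [read_table_artifact()].
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_table_artifact <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_artifact
#' @export
read_table_artifact <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Write a population trace with its manifest
#'
#' The trace is written as a (time_ms, m1..m4) table; a manifest with the
#' complete resolved parameter set, seeds, and package version is written
#' alongside every artifact.
#'
#' @param trace A `"population_trace"`.
#' @param path Output path (TSV).
#' @param params The [network_params()] used (for the manifest).
#' @export
write_trace <- function(trace, path, params = NULL) {
  df <- data.frame(time_ms = trace$times, trace$m)
  write_table_artifact(df, path)
  if (!is.null(params)) write_manifest(params, paste0(path, ".manifest"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read_table_artifact(path)
  population_trace(df$time_ms, as.matrix(df[, c("m1", "m2", "m3", "m4")]))
}

#' @rdname write_trace
#' @param spikes A `"spike_record"` data frame.
#' @export
write_spikes <- function(spikes, path, params = NULL) {
  write_table_artifact(spikes, path)
  if (!is.null(params)) write_manifest(params, paste0(path, ".manifest"))
  invisible(path)
}

write_manifest <- function(params, path) {
  p <- params
  cfg <- list(package = "balancedline",
              version = as.character(utils::packageVersion("balancedline")),
              N = p$N, K = p$K, J_E = p$J_E, J_I = p$J_I,
              J_tilde = p$J_tilde, E0 = p$E0,
              tau_E = p$tau_E, tau_I = p$tau_I,
              T = paste(p$T, collapse = ","),
              cross_mode = p$cross_mode, mirrored = p$mirrored,
              seed_connectivity = p$seeds$connectivity,
              seed_schedule = p$seeds$schedule,
              seed_init = p$seeds$init)
  if (!is.null(p$input_noise)) {
    cfg$tau_noise <- p$input_noise$tau_noise
    cfg$sigma_noise <- p$input_noise$sigma_noise
  }
  write_config(cfg, path)
}

#' Build network parameters from a configuration list
#'
#' @param cfg Named list (e.g. from [read_config()]); recognized keys are
#'   the arguments of [network_params()] plus `seed` (expanded into the
#'   three seed streams) and `tau_noise`/`sigma_noise`.
#' @return A [network_params()] object.
#' @export
params_from_config <- function(cfg) {
  seeds <- if (!is.null(cfg$seed))
    list(connectivity = as.integer(cfg$seed),
         schedule = as.integer(cfg$seed) + 1L,
         init = as.integer(cfg$seed) + 2L)
  else list(connectivity = as.integer(cfg$seed_connectivity %||% 101),
            schedule = as.integer(cfg$seed_schedule %||% 202),
            init = as.integer(cfg$seed_init %||% 303))
  noise <- if (!is.null(cfg$sigma_noise) && cfg$sigma_noise > 0)
    list(tau_noise = cfg$tau_noise %||% 30, sigma_noise = cfg$sigma_noise)
  else NULL
  p <- network_params(
    N = cfg$N %||% 10000, K = cfg$K %||% 100,
    J_E = cfg$J_E %||% 4, J_I = cfg$J_I %||% 2.5,
    J_tilde = cfg$J_tilde %||% ((cfg$J_E %||% 4) - (cfg$J_I %||% 2.5)),
    E0 = cfg$E0 %||% 0.3, tau_E = cfg$tau_E %||% 10,
    tau_I = cfg$tau_I %||% 8, T = cfg$T %||% 1,
    cross_mode = cfg$cross_mode %||% "all_to_all",
    mirrored = cfg$mirrored %||% TRUE,
    input_noise = noise, seeds = seeds)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
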