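#' Experimental (or synthetic) observation series
#'
#' @param kind `"free-volume"` (aggregate volume vs time) or
#'   `"capsule-radius"` (inner radius vs time).
#' @param times_s Strictly increasing times, s.
#' @param values Positive observations (m^3 or m).
#' @param metadata Optional named list (capsule R_in, h, E_alg, ...).
#' @return Object of class `experiment_series`.
#' @export
experiment_series <- function(kind = c("free-volume", "capsule-radius"),
                              times_s, values, metadata = list()) {
  kind <- match.arg(kind)
  if (length(times_s) != length(values))
    stop("times and values must match", call. = FALSE)
  if (any(diff(times_s) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  structure(list(kind = kind, times_s = as.numeric(times_s),
                 values = as.numeric(values), metadata = metadata),
            class = c("experiment_series", "list"))
}

#' Read an observation series from CSV
#'
#' Expected header: a time column (`time_s`, or `time_day` converted on
#' read) and a value column (`volume_m3` / `volume_mm3` for free growth;
#' `R_in_m` / `R_in_um` for capsule tracks). Units are normalized to SI.
#'
#' @param path CSV file path.
#' @return An [experiment_series()].
#' @export
read_experiment_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- names(df)
  tcol <- intersect(c("time_s", "time_day"), cn)
  vcol <- intersect(c("volume_m3", "volume_mm3", "R_in_m", "R_in_um"), cn)
  if (!length(tcol) || !length(vcol))
    stop("missing columns in ", path, ": need time_s|time_day and ",
         "volume_m3|volume_mm3|R_in_m|R_in_um", call. = FALSE)
  t <- df[[tcol[1]]]
  if (tcol[1] == "time_day") t <- t * 86400
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop("non-monotone time at data line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  v <- df[[vcol[1]]]
  v <- switch(vcol[1], volume_mm3 = v * 1e-9, R_in_um = v * 1e-6, v)
  kind <- if (grepl("^volume", vcol[1])) "free-volume" else "capsule-radius"
  meta <- as.list(df[1, setdiff(cn, c(tcol, vcol)), drop = FALSE])
  experiment_series(kind, t, v, meta)
}

#' Write an observation series to CSV
#'
#' @param series An [experiment_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_experiment_csv <- function(series, path) {
  stopifnot(inherits(series, "experiment_series"))
  vname <- if (series$kind == "free-volume") "volume_m3" else "R_in_m"
  df <- data.frame(time_s = series$times_s, v = series$values)
  names(df)[2] <- vname
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Specification of a synthetic experiment
#'
#' @param kind Observable to sample (as in [experiment_series()]).
#' @param domain,disc,params Forward-model configuration.
#' @param times_s Sampling times, s.
#' @param noise Relative multiplicative Gaussian noise level (default 0.02).
#' @param seed Integer random seed (fixed seed gives bit-identical output).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("free-volume", "capsule-radius"),
                           domain, disc, params, times_s,
                           noise = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(noise >= 0, inherits(domain, "domain_spec"))
  structure(list(kind = kind, domain = domain, disc = disc, params = params,
                 times_s = times_s, noise = noise, seed = as.integer(seed)),
            class = c("synthetic_spec", "list"))
}

# evaluate expr with a local RNG seed, restoring global RNG state after
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic observation series from the forward model
#'
#' Runs the forward model at the spec's parameters, samples the requested
#' observable at the spec's times, and applies multiplicative Gaussian
#' noise `value * (1 + noise * Z)` with the spec's seed (the global RNG
#' state is left untouched).
#'
#' @param spec A [synthetic_spec()].
#' @param sim Optional precomputed `simulation_result` matching the spec
#'   (to reuse one forward run for several noise draws).
#' @return An [experiment_series()] with the generating metadata recorded.
#' @export
generate_synthetic_experiment <- function(spec, sim = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(sim)) sim <- run_simulation(spec$domain, spec$disc, spec$params)
  s <- sim$series
  clean <- if (spec$kind == "free-volume") {
    stats::approx(s$time_s, s$V_tumor_m3, xout = spec$times_s)$y
  } else {
    stats::approx(s$time_s, s$R_in_m, xout = spec$times_s)$y
  }
  if (anyNA(clean))
    stop("sampling times outside the simulated horizon", call. = FALSE)
  vals <- if (spec$noise > 0) {
    .with_seed(spec$seed,
               clean * (1 + spec$noise * stats::rnorm(length(clean))))
  } else clean
  experiment_series(spec$kind, spec$times_s, vals,
                    metadata = list(noise = spec$noise, seed = spec$seed,
                                    confluence_time_s =
                                      sim$confluence_time_s))
}

#' Export the scalar time series of a simulation as CSV
#'
#' @param result A `simulation_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}
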